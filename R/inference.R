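#' Paired Wilcoxon signed-rank test on pre/post cover
#'
#' Two-sided paired Wilcoxon signed-rank test of pre- versus post-storm
#' values (each site-storm combination is one paired observation). Zero
#' differences are dropped, as the signed-rank procedure requires; if every
#' difference is zero there is nothing to test and a degenerate result is
#' returned rather than an error. The exact distribution is used for n <= 25
#' informative pairs (no ties), the normal approximation with continuity
#' correction above that.
#'
#' @param pre,post Equal-length numeric vectors of paired values.
#' @return One-row tibble `statistic` (V), `p_value`, `n_used` (pairs after
#'   dropping zero differences), `degenerate`.
#' @export
paired_wilcoxon <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  ok <- !is.na(pre) & !is.na(post)
  d <- post[ok] - pre[ok]
  d <- d[d != 0]
  if (length(d) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n_used = 0L, degenerate = TRUE))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_used = length(d), degenerate = FALSE)
}

#' Kruskal-Wallis test across groups (e.g. decades)
#'
#' Rank-based H test with tie correction, used to ask whether resistance
#' differs between decades.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return One-row tibble `H`, `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) {
    stop("Kruskal-Wallis requires at least two non-empty groups", call. = FALSE)
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n_groups = nlevels(groups))
}

#' Non-parametric percentile bootstrap confidence interval
#'
#' Percentile interval of a statistic from `B` resamples with replacement.
#' Deterministic for a given `seed`; the endpoints always lie within the
#' sample range.
#'
#' @param values Numeric vector, length >= 2.
#' @param statistic Function of a numeric vector (default `mean`).
#' @param B Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed (mandatory so results are reproducible).
#' @return One-row tibble `lo`, `hi`, `estimate`, `B`, `level`.
#' @export
bootstrap_ci <- function(values, statistic = mean, B = 1000, level = 0.95,
                         seed = 1L) {
  if (length(values) < 2) {
    stop("bootstrap_ci requires at least two values", call. = FALSE)
  }
  stopifnot(is.numeric(seed), B >= 1, level > 0, level < 1)
  stats_boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(B),
           function(i) statistic(sample(values, length(values), replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- unname(stats::quantile(stats_boot, c(alpha, 1 - alpha), type = 7))
  tibble::tibble(lo = qs[1], hi = qs[2], estimate = statistic(values),
                 B = B, level = level)
}

#' Signed cube-root transform
#'
#' Odd, strictly monotone transform sign(x) |x|^(1/3), suitable for responses
#' that include zeros and negative values (e.g. cover-change metrics) ahead
#' of linear modelling.
#'
#' @param x Numeric vector.
#' @return Transformed vector.
#' @examples
#' signed_cuberoot(c(-8, 0, 27)) # -2 0 3
#' @export
signed_cuberoot <- function(x) sign(x) * abs(x)^(1 / 3)

#' Centre and scale continuous columns
#'
#' Centres each column to mean zero and scales to unit (n-1) standard
#' deviation, as done for continuous fixed effects prior to modelling.
#'
#' @param df Data frame or tibble of numeric columns.
#' @return Tibble of the same shape, scaled.
#' @export
scale_columns <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) {
    stop("scale_columns expects numeric columns only", call. = FALSE)
  }
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(is.na(sds) | sds == 0)) {
    stop("zero-variance column(s): ",
         paste(names(df)[is.na(sds) | sds == 0], collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(as.data.frame(scale(as.matrix(df))))
}

#' Variance-inflation-factor screening
#'
#' Computes VIF_j = 1 / (1 - R^2_j) from regressing each predictor on the
#' others, then iteratively removes the single highest-VIF predictor
#' exceeding the threshold and recomputes, until all remaining predictors
#' pass. Perfectly collinear predictors have infinite VIF and are removed
#' first. With tied VIFs (e.g. exactly two collinear predictors) the
#' later column in the current ordering is removed, so earlier-listed
#' predictors are preferred.
#'
#' @param df Data frame of numeric predictors (more rows than columns).
#' @param threshold VIF threshold above which a predictor is dropped
#'   (default 2).
#' @return List with `retained` (tibble of surviving columns), `removed`
#'   (character vector, removal order) and `report` (tibble of the VIFs at
#'   each iteration: `iteration`, `predictor`, `vif`, `removed`).
#' @export
vif_screen <- function(df, threshold = 2) {
  stopifnot(ncol(df) >= 2, nrow(df) > ncol(df))
  df <- tibble::as_tibble(df)
  removed <- character()
  report <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    vifs <- vif_values(df)
    worst <- if (any(vifs > threshold)) {
      idx <- which(vifs == max(vifs))
      names(vifs)[max(idx)] # tie-break: drop the later column
    } else NA_character_
    report[[iter]] <- tibble::tibble(iteration = iter,
                                     predictor = names(vifs),
                                     vif = unname(vifs),
                                     removed = names(vifs) %in% worst)
    if (is.na(worst)) break
    removed <- c(removed, worst)
    df <- df[setdiff(names(df), worst)]
    if (ncol(df) < 2) break
  }
  list(retained = df, removed = removed, report = dplyr::bind_rows(report))
}

vif_values <- function(df) {
  x <- as.matrix(df)
  vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |>
    stats::setNames(colnames(x))
}

#' Fit a resilience linear mixed model
#'
#' Random-intercept linear mixed model for a resilience response (resistance
#' or recovery rate) on event- and regime-level predictors, with reef
#' location as the random effect. Preprocessing follows the modelling
#' conventions for these responses: optional signed cube-root transform of
#' the response (they include zeros and negative values), scaling of
#' continuous fixed effects, and VIF screening of the predictors before the
#' fit. Singular fits are reported, not hidden.
#'
#' @param df Tibble holding the response, predictors and grouping factor.
#' @param response Response column name.
#' @param predictors Character vector of fixed-effect column names (numeric).
#' @param group Grouping-factor column name (reef site).
#' @param cuberoot Apply [signed_cuberoot()] to the response (default TRUE).
#' @param scale Scale the predictors (default TRUE).
#' @param vif_threshold Threshold for [vif_screen()]; `Inf` disables
#'   screening. Screening requires >= 2 predictors.
#' @return Object of class `reefstorm_lmm`: list with `fit` (the `lmerMod`),
#'   `spec` (the resolved model description), `vif` (screening report or
#'   `NULL`), `singular` (logical). Has [tidy()] and [glance()] methods.
#' @export
fit_resilience_lmm <- function(df, response, predictors, group,
                               cuberoot = TRUE, scale = TRUE,
                               vif_threshold = 2) {
  stopifnot(response %in% names(df), group %in% names(df),
            all(predictors %in% names(df)))
  if (group %in% predictors) {
    stop("the grouping factor cannot also be a fixed effect", call. = FALSE)
  }
  dat <- df[stats::complete.cases(df[c(response, predictors, group)]), ]
  y <- dat[[response]]
  if (cuberoot) y <- signed_cuberoot(y)

  vif <- NULL
  kept <- predictors
  if (is.finite(vif_threshold) && length(predictors) >= 2) {
    vif <- vif_screen(dat[predictors], threshold = vif_threshold)
    kept <- names(vif$retained)
  }
  x <- dat[kept]
  if (scale) x <- scale_columns(x)

  model_dat <- dplyr::bind_cols(
    tibble::tibble(.response = y, .group = factor(dat[[group]])), x
  )
  form <- stats::as.formula(paste(
    ".response ~", paste(c(kept, "(1 | .group)"), collapse = " + ")
  ))
  fit <- lme4::lmer(
    form, data = model_dat, REML = TRUE,
    # degenerate groupings (one level per row) are reported, not refused
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                check.nobs.vs.rankZ = "ignore")
  )
  structure(
    list(fit = fit,
         spec = list(response = response, predictors = kept,
                     dropped = setdiff(predictors, kept), group = group,
                     cuberoot = cuberoot, scale = scale),
         vif = vif,
         singular = lme4::isSingular(fit)),
    class = "reefstorm_lmm"
  )
}

#' @export
print.reefstorm_lmm <- function(x, ...) {
  cat("Resilience linear mixed model\n")
  cat("  response:  ", x$spec$response,
      if (x$spec$cuberoot) " (signed cube root)" else "", "\n", sep = "")
  cat("  fixed:     ", paste(x$spec$predictors, collapse = ", "), "\n", sep = "")
  if (length(x$spec$dropped)) {
    cat("  dropped:   ", paste(x$spec$dropped, collapse = ", "),
        " (VIF screen)\n", sep = "")
  }
  cat("  random:    (1 | ", x$spec$group, ")\n", sep = "")
  if (x$singular) cat("  NOTE: singular fit\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a resilience mixed model
#'
#' @param x A `reefstorm_lmm` object.
#' @param ... Unused.
#' @return Tibble of fixed effects (`term`, `estimate`, `std_error`,
#'   `t_value`) and variance components (`term`, `estimate` of the variance).
#' @export
tidy.reefstorm_lmm <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  fixed <- tibble::tibble(effect = "fixed", term = rownames(co),
                          estimate = unname(co[, "Estimate"]),
                          std_error = unname(co[, "Std. Error"]),
                          t_value = unname(co[, "t value"]))
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  ran <- tibble::tibble(effect = "variance",
                        term = paste0(vc$grp,
                                      ifelse(is.na(vc$var1), "", paste0(".", vc$var1))),
                        estimate = vc$vcov,
                        std_error = NA_real_, t_value = NA_real_)
  dplyr::bind_rows(fixed, ran)
}

#' @rdname tidy.reefstorm_lmm
#' @return `glance()`: one-row tibble `n_obs`, `n_groups`, `sigma`,
#'   `random_intercept_var`, `singular`, `logLik`, `REMLcrit`.
#' @export
glance.reefstorm_lmm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    n_obs = stats::nobs(x$fit),
    n_groups = lme4::ngrps(x$fit)[[1]],
    sigma = stats::sigma(x$fit),
    random_intercept_var = vc$vcov[vc$grp == ".group"][1],
    singular = x$singular,
    logLik = as.numeric(stats::logLik(x$fit)),
    REMLcrit = lme4::REMLcrit(x$fit)
  )
}

#' Residual diagnostics for a resilience mixed model
#'
#' @param x A `reefstorm_lmm` object.
#' @return Tibble `fitted`, `residual`, `group`, for normality /
#'   homoscedasticity checks (see also [autoplot.reefstorm_lmm()]).
#' @export
lmm_residuals <- function(x) {
  tibble::tibble(
    fitted = stats::fitted(x$fit),
    residual = stats::residuals(x$fit),
    group = x$fit@frame$.group
  )
}
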