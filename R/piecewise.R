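#' Continuous piecewise (segmented) linear regression
#'
#' Fits a continuous segmented linear model with a fixed number of
#' breakpoints by minimising the residual sum of squares over candidate
#' breakpoint locations. For a given breakpoint set the fit is an ordinary
#' least-squares regression on the hinge basis
#' `y ~ x + (x - b1)+ + ... + (x - bk)+`, which is continuous at every
#' breakpoint by construction. Breakpoints are searched on a candidate grid
#' (the observed interior x values by default, or any finer user grid):
#' one breakpoint is located by exhaustive scan; additional breakpoints are
#' added greedily and then refined one at a time (coordinate descent over the
#' grid) until the RSS stops improving. The RSS therefore never exceeds that
#' of the single-line fit and is non-increasing in the number of breakpoints.
#'
#' @param x,y Numeric vectors (the predictor need not be sorted).
#' @param n_breakpoints Number of breakpoints (k >= 1). The fit needs at
#'   least `2 * (k + 1) + k` points.
#' @param grid Optional numeric vector of candidate breakpoint locations;
#'   defaults to the observed x values strictly inside the data range.
#' @param min_seg Minimum number of points per segment (default 2).
#' @return Object of class `piecewise_fit`: list with `breakpoints`,
#'   `segments` (tibble `segment`, `x_lo`, `x_hi`, `intercept`, `slope`),
#'   `rss`, `rss_line` (single-line RSS), `n`, `data` (tibble `x`, `y`,
#'   `fitted`). Has `tidy()`, `glance()`, `predict()`, `autoplot()` methods.
#' @examples
#' x <- seq(0, 10, by = 0.5)
#' y <- ifelse(x < 5, x, 5)
#' fit <- piecewise_fit(x, y, 1)
#' fit$breakpoints # 5
#' @export
piecewise_fit <- function(x, y, n_breakpoints = 1, grid = NULL, min_seg = 2) {
  stopifnot(length(x) == length(y), n_breakpoints >= 1)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  k <- as.integer(n_breakpoints)
  if (length(x) < 2 * (k + 1) + k) {
    stop("need at least ", 2 * (k + 1) + k, " points for ", k,
         " breakpoint(s)", call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("degenerate predictor: all x values equal", call. = FALSE)
  }
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (is.null(grid)) {
    grid <- unique(x)
    grid <- grid[grid > min(x) & grid < max(x)]
  } else {
    grid <- sort(unique(grid[grid > min(x) & grid < max(x)]))
  }
  if (length(grid) == 0) stop("no interior candidate breakpoints", call. = FALSE)

  valid <- function(bps) {
    cuts <- c(-Inf, bps, Inf)
    counts <- tabulate(findInterval(x, cuts, left.open = TRUE),
                       nbins = length(bps) + 1)
    all(counts >= min_seg)
  }
  rss_at <- function(bps) {
    design <- cbind(1, x, vapply(bps, function(b) pmax(x - b, 0),
                                 numeric(length(x))))
    fit <- stats::lm.fit(design, y)
    sum(fit$residuals^2)
  }

  # greedy addition, then coordinate refinement over the grid
  bps <- numeric(0)
  for (j in seq_len(k)) {
    cand <- setdiff(grid, bps)
    scores <- vapply(cand, function(b) {
      trial <- sort(c(bps, b))
      if (!valid(trial)) Inf else rss_at(trial)
    }, numeric(1))
    if (all(!is.finite(scores))) {
      stop("no breakpoint placement leaves >= ", min_seg,
           " points per segment", call. = FALSE)
    }
    bps <- sort(c(bps, cand[which.min(scores)]))
  }
  best <- rss_at(bps)
  repeat {
    improved <- FALSE
    for (j in seq_along(bps)) {
      cand <- setdiff(grid, bps[-j])
      scores <- vapply(cand, function(b) {
        trial <- sort(c(bps[-j], b))
        if (!valid(trial)) Inf else rss_at(trial)
      }, numeric(1))
      if (min(scores) < best - 1e-12) {
        bps <- sort(c(bps[-j], cand[which.min(scores)]))
        best <- min(scores)
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  design <- cbind(1, x, vapply(bps, function(b) pmax(x - b, 0),
                               numeric(length(x))))
  fit <- stats::lm.fit(design, y)
  beta <- fit$coefficients
  slopes <- cumsum(c(beta[2], beta[-(1:2)]))
  intercepts <- numeric(k + 1)
  intercepts[1] <- beta[1]
  for (j in seq_len(k)) {
    intercepts[j + 1] <- intercepts[j] - beta[j + 2] * bps[j]
  }
  line_fit <- stats::lm.fit(cbind(1, x), y)

  structure(
    list(
      breakpoints = bps,
      segments = tibble::tibble(
        segment = seq_len(k + 1),
        x_lo = c(min(x), bps),
        x_hi = c(bps, max(x)),
        intercept = intercepts,
        slope = unname(slopes)
      ),
      rss = sum(fit$residuals^2),
      rss_line = sum(line_fit$residuals^2),
      n = length(x),
      data = tibble::tibble(x = x, y = y, fitted = design %*% beta |> drop())
    ),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Segmented linear fit:", length(x$breakpoints), "breakpoint(s) at",
      paste(signif(x$breakpoints, 6), collapse = ", "), "\n")
  cat("RSS", signif(x$rss, 6), "(single line:", signif(x$rss_line, 6), ")\n")
  print(x$segments)
  invisible(x)
}

#' Tidy a segmented fit
#'
#' @param x A `piecewise_fit`.
#' @param ... Unused.
#' @return `tidy()`: the per-segment tibble (`segment`, `x_lo`, `x_hi`,
#'   `intercept`, `slope`); `glance()`: one-row tibble with `n`,
#'   `n_breakpoints`, `rss`, `rss_line`, `r_squared`.
#' @export
tidy.piecewise_fit <- function(x, ...) x$segments

#' @rdname tidy.piecewise_fit
#' @export
glance.piecewise_fit <- function(x, ...) {
  tss <- sum((x$data$y - mean(x$data$y))^2)
  tibble::tibble(n = x$n, n_breakpoints = length(x$breakpoints),
                 rss = x$rss, rss_line = x$rss_line,
                 r_squared = if (tss > 0) 1 - x$rss / tss else NA_real_)
}

#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$data$x else newdata$x
  hinges <- matrix(vapply(object$breakpoints, function(b) pmax(xs - b, 0),
                          numeric(length(xs))), nrow = length(xs))
  design <- cbind(1, xs, hinges)
  b0 <- object$segments$intercept[1]
  s0 <- object$segments$slope[1]
  gammas <- diff(object$segments$slope)
  drop(design %*% c(b0, s0, gammas))
}
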