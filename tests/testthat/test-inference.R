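# exact two-sided signed-rank p-value by enumerating all sign assignments
enumerate_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
  list(V = v_obs, p = p)
}

test_that("paired Wilcoxon matches exhaustive enumeration and handles degeneracy", {
  pre <- c(21.5, 18.2, 30.0, 12.4, 25.1, 9.8, 16.6, 28.3)
  post <- c(17.0, 18.9, 24.5, 12.9, 20.0, 10.4, 13.2, 23.1)
  got <- paired_wilcoxon(pre, post)
  want <- enumerate_signed_rank(post - pre)
  expect_equal(got$statistic, want$V)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(got$n_used, 8L)

  same <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))

  pre20 <- runif(20, 10, 30)
  shifted <- paired_wilcoxon(pre20, pre20 - 1)
  expect_lt(shifted$p_value, 0.001)
})

test_that("paired Wilcoxon type-I error is nominal under a true null", {
  set.seed(314)
  p <- replicate(400, {
    pre <- rnorm(15, 20, 3); post <- pre + rnorm(15, 0, 2)
    paired_wilcoxon(pre, post)$p_value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("Kruskal-Wallis matches the rank-sum formula and separates groups", {
  vals <- c(3.1, 5.2, 1.4, 8.8, 7.7, 2.2, 9.9, 6.1, 4.4)
  grp <- rep(c("a", "b", "c"), each = 3)
  got <- kruskal_wallis(vals, grp)
  r <- rank(vals)
  n <- length(vals)
  h_hand <- 12 / (n * (n + 1)) *
    sum(tapply(r, grp, sum)^2 / tabulate(factor(grp))) - 3 * (n + 1)
  expect_equal(got$H, h_hand) # no ties, so no correction
  expect_equal(got$df, 2)

  sep <- kruskal_wallis(c(1, 2, 3, 101, 102, 103), rep(c("x", "y"), each = 3))
  expect_lt(sep$p_value, 0.05)

  perm <- kruskal_wallis(1:6, rep(c("x", "y"), 3)) # interleaved ranks
  expect_lt(perm$H, 2) # near-identical group distributions: H near 0

  expect_error(kruskal_wallis(1:5, rep("only", 5)), "two non-empty groups")
})

test_that("bootstrap intervals are seeded, bounded and collapse on constants", {
  const <- bootstrap_ci(rep(7, 10), seed = 1)
  expect_equal(const$lo, 7)
  expect_equal(const$hi, 7)

  x <- rnorm(40)
  a <- bootstrap_ci(x, seed = 99)
  b <- bootstrap_ci(x, seed = 99)
  expect_identical(a, b)
  c2 <- bootstrap_ci(x, seed = 100)
  expect_false(isTRUE(all.equal(a$lo, c2$lo)))

  expect_gte(a$lo, min(x)); expect_lte(a$hi, max(x))
  expect_lte(a$lo, a$hi)
  expect_error(bootstrap_ci(1), "at least two")
})

test_that("bootstrap coverage of the mean is near nominal", {
  set.seed(77)
  hits <- replicate(300, {
    x <- rnorm(60)
    ci <- bootstrap_ci(x, B = 400, seed = sample.int(1e6, 1))
    ci$lo <= 0 && ci$hi >= 0
  })
  expect_gt(mean(hits), 0.88)
  expect_lte(mean(hits), 1.0)
})

test_that("signed cube root is odd, monotone and inverts cubing", {
  expect_equal(signed_cuberoot(-8), -2)
  expect_equal(signed_cuberoot(0), 0)
  expect_equal(signed_cuberoot(27), 3)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(signed_cuberoot(-x), -signed_cuberoot(x))
  expect_true(all(diff(signed_cuberoot(x)) > 0))
  expect_equal(signed_cuberoot(x^3), x)
})

test_that("column scaling centres to unit variance and rejects constants", {
  out <- scale_columns(tibble::tibble(a = c(1, 2, 3)))
  expect_equal(out$a, c(-1, 0, 1))
  again <- scale_columns(out)
  expect_equal(again$a, out$a, tolerance = 1e-12)
  expect_error(scale_columns(tibble::tibble(a = c(1, 1, 1))), "zero-variance")
  expect_error(scale_columns(tibble::tibble(a = letters[1:3])), "numeric")
})

test_that("VIF screening matches 1/(1-R^2) and removes collinear predictors", {
  # orthogonal predictors: all VIF 1, nothing removed
  orth <- tibble::tibble(a = rep(c(1, -1), 8), b = rep(c(1, 1, -1, -1), 4))
  v <- vif_screen(orth)
  expect_equal(v$report$vif, c(1, 1))
  expect_length(v$removed, 0)

  # exact correlation 0.8: VIF = 1/(1-0.64) = 2.778 each, one removed
  x <- rep(c(1, -1), 8); z <- rep(c(1, 1, -1, -1), 4)
  y <- 0.8 * x + 0.6 * z
  v2 <- vif_screen(tibble::tibble(x = x, y = y))
  expect_equal(v2$report$vif[v2$report$iteration == 1],
               rep(1 / (1 - 0.64), 2), tolerance = 1e-9)
  expect_equal(v2$removed, "y") # tie-break keeps the earlier column
  expect_named(v2$retained, "x")

  # duplicated column: infinite VIF, duplicate removed first
  dup <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  dup$c <- dup$a
  v3 <- vif_screen(dup)
  expect_true(is.infinite(v3$report$vif[1]))
  expect_true("c" %in% v3$removed)
  expect_false("b" %in% v3$removed)
})

test_that("VIF values agree with an independent implementation", {
  skip_if_not_installed("car")
  set.seed(15)
  n <- 60
  df <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  df$c <- 0.6 * df$a + 0.5 * df$b + rnorm(n, 0, 0.4)
  y <- rnorm(n)
  ref <- car::vif(lm(y ~ a + b + c, data = df))
  got <- vif_screen(df, threshold = Inf)$report
  expect_equal(got$vif, unname(ref[got$predictor]), tolerance = 1e-9)
})

test_that("VIF screening is order-invariant when VIFs are untied", {
  set.seed(8)
  n <- 80
  a <- rnorm(n); b <- 0.9 * a + rnorm(n, 0, 0.3); c <- rnorm(n)
  d1 <- vif_screen(tibble::tibble(a = a, b = b, c = c))
  d2 <- vif_screen(tibble::tibble(c = c, b = b, a = a))
  expect_setequal(d1$removed, d2$removed)
  expect_setequal(names(d1$retained), names(d2$retained))
})

test_that("mixed model recovers a known fixed effect and reports variance", {
  set.seed(21)
  n_site <- 50; per <- 10
  site <- rep(sprintf("s%02d", 1:n_site), each = per)
  u <- rep(rnorm(n_site, 0, 0.5), each = per)
  x1 <- rnorm(n_site * per)
  x2 <- rnorm(n_site * per)
  resp <- (1 * x1 + 0 * x2 + u + rnorm(n_site * per, 0, 1))^3
  df <- tibble::tibble(resp = resp, x1 = x1, x2 = x2, site = site)
  m <- fit_resilience_lmm(df, "resp", c("x1", "x2"), "site")
  td <- tidy(m)
  est <- td$estimate[td$term == "x1"]
  expect_equal(est, 1, tolerance = 0.15)
  gl <- glance(m)
  expect_gt(gl$random_intercept_var, 0.05)
  expect_equal(gl$n_groups, n_site)
  expect_false(m$singular)
  res <- lmm_residuals(m)
  expect_equal(nrow(res), n_site * per)
})

test_that("degenerate mixed-model groupings are flagged, not hidden", {
  set.seed(4)
  n <- 60
  df <- tibble::tibble(resp = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                       site = sprintf("r%02d", 1:n)) # one level per row
  m <- suppressMessages(
    fit_resilience_lmm(df, "resp", c("x1", "x2"), "site", cuberoot = FALSE))
  expect_true(is.logical(m$singular))
  expect_s4_class(m$fit, "lmerMod")

  # zero between-site variance: random-intercept variance collapses
  site <- rep(sprintf("s%02d", 1:10), each = 20)
  df2 <- tibble::tibble(resp = rnorm(200), x1 = rnorm(200), x2 = rnorm(200),
                        site = site)
  m2 <- fit_resilience_lmm(df2, "resp", c("x1", "x2"), "site",
                           cuberoot = FALSE)
  expect_lt(glance(m2)$random_intercept_var, 0.1)
  expect_error(fit_resilience_lmm(df2, "resp", c("x1", "site"), "site"),
               "grouping factor")
})
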