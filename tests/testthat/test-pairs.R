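# Cross-pair table construction, collinearity screen, weighted logistic
# fits, AICc ranking, matching-permutation test, t-tests.

toy_metrics <- function(f_vals, m_vals, trait = "x", year = "2022") {
  nf <- length(f_vals); nm <- length(m_vals)
  out <- data.frame(
    bird_id = c(paste0("F", seq_len(nf)), paste0("M", seq_len(nm))),
    sex = c(rep("F", nf), rep("M", nm)),
    year = year,
    pair_id = c(paste0("P", seq_len(nf)), paste0("P", seq_len(nm))),
    stringsAsFactors = FALSE)
  out[[trait]] <- c(f_vals, m_vals)
  out
}

test_that("the cross-pair table has n_F x n_M rows with hand-checked differences", {
  pt <- build_pair_table(toy_metrics(c(10, 20), c(12, 30)), "x")
  expect_equal(nrow(pt), 4)
  expect_equal(sort(pt$d_x), sort(c(2, 20, 8, 10)))
  expect_equal(sum(pt$is_real), 2)
  # a pair with equal trait values differences to zero
  pt0 <- build_pair_table(toy_metrics(5, 5), "x")
  expect_equal(pt0$d_x, 0)
})

test_that("pair-table weights balance classes without touching the traits", {
  met <- toy_metrics(1:5, 6:10)
  pt <- build_pair_table(met, "x")
  expect_equal(unique(pt$weight[pt$is_real == 1]), 20 / 5)  # n_rand / n_real
  expect_equal(unique(pt$weight[pt$is_real == 0]), 1)
  pt2 <- build_pair_table(met, "x", weight_real = 7)
  expect_equal(unique(pt2$weight[pt2$is_real == 1]), 7)
  expect_equal(pt$d_x, pt2$d_x)     # weights never touch the differences
})

test_that("a study-sized season crosses 19 females with 19 males", {
  cfg <- sim_config(n_pairs_per_year = c("2022" = 19), seed = 2)
  st <- simulate_pair_study(cfg)
  pt <- build_pair_table(st$metrics, "mean_trip_distance")
  expect_equal(nrow(pt), 361)
  expect_equal(sum(pt$is_real), 19)
})

test_that("standardization and the overlap transform are applied after differencing", {
  met <- toy_metrics(c(1, 5, 9), c(2, 4, 8))
  ba <- expand.grid(female_id = c("F1", "F2", "F3"),
                    male_id = c("M1", "M2", "M3"),
                    stringsAsFactors = FALSE)
  ba$ba <- seq(0, 0.8, length.out = 9)
  pt <- build_pair_table(met, "x", standardize = "x", ba = ba)
  expect_equal(mean(pt$d_x), 0, tolerance = 1e-12)
  expect_equal(sd(pt$d_x), 1, tolerance = 1e-12)
  expect_equal(pt$log1p_BA,
               log1p(ba$ba[match(paste(pt$female_id, pt$male_id),
                                 paste(ba$female_id, ba$male_id))]))
})

test_that("collinearity screening keeps the mean variant and drops its twin", {
  set.seed(10)
  n <- 1000
  base <- rnorm(n)
  x <- data.frame(mean_dive_duration = base + rnorm(n, 0, 0.3),
                  max_dive_duration = base + rnorm(n, 0, 0.3),
                  other = rnorm(n))
  stopifnot(cor(x$mean_dive_duration, x$max_dive_duration) > 0.8)
  cf <- collinearity_filter(x)
  expect_true("mean_dive_duration" %in% cf$retained)
  expect_false("max_dive_duration" %in% cf$retained)
  expect_true("other" %in% cf$retained)
  # duplicated column: exactly one survives
  dup <- data.frame(a = base, b = base)
  expect_length(collinearity_filter(dup)$retained, 1)
  # independent Gaussians all survive
  ind <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  expect_length(collinearity_filter(ind)$retained, 4)
  expect_warning(collinearity_filter(data.frame(a = rnorm(n), c = 1)),
                 "constant")
})

test_that("the intercept-only weighted fit equals the logit of weighted prevalence", {
  set.seed(20)
  y <- rbinom(100, 1, 0.3)
  w <- runif(100, 0.5, 4)
  fit <- fit_weighted_logistic(matrix(1, 100, 1), y, w)
  expect_equal(unname(fit$coefficients),
               qlogis(sum(w * y) / sum(w)), tolerance = 1e-8)
})

test_that("the IRLS slope matches a 1-D grid search on a symmetric toy", {
  X <- cbind(1, rep(c(-1, 1), each = 20))
  y <- rep(c(0, 1, 0, 1), c(15, 5, 5, 15))
  fit <- fit_weighted_logistic(X, y)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) wll(c(0, b), X, y, rep(1, 40)), 0)
  expect_equal(unname(fit$coefficients[2]), grid[which.max(ll)],
               tolerance = 1e-4)
})

test_that("estimates are invariant to rescaling all weights", {
  set.seed(21)
  X <- cbind(1, rnorm(80))
  y <- rbinom(80, 1, plogis(X[, 2]))
  f1 <- fit_weighted_logistic(X, y, rep(2, 80))
  f2 <- fit_weighted_logistic(X, y, rep(14, 80))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-7)
})

test_that("IRLS agrees with glm() and with a derivative-free maximizer", {
  set.seed(22)
  for (r in 1:5) {
    n <- 150
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rbinom(n, 1, plogis(0.3 - 0.8 * X[, 2] + 0.5 * X[, 3]))
    w <- runif(n, 0.5, 3)
    fit <- fit_weighted_logistic(X, y, w)
    gfit <- suppressWarnings(glm.fit(X, y, weights = w,
                                     family = binomial()))
    expect_equal(unname(fit$coefficients), unname(gfit$coefficients),
                 tolerance = 1e-6)
    opt <- optim(rep(0, 3), function(b) -wll(b, X, y, w),
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
  }
})

test_that("degenerate logistic inputs raise explicit errors", {
  X <- cbind(1, rnorm(30))
  expect_error(fit_weighted_logistic(X, rep(1, 30)), "degenerate response")
  y_sep <- as.numeric(X[, 2] > 0)
  expect_error(fit_weighted_logistic(X, y_sep, rep(1, 30)), "separation")
  expect_error(fit_weighted_logistic(X, rbinom(30, 1, 0.5),
                                     rep(-1, 30)), "weights")
})

test_that("wlogit methods behave like a standard model object", {
  set.seed(23)
  d <- data.frame(x = rnorm(60))
  d$y <- rbinom(60, 1, plogis(0.5 * d$x))
  fit <- wlogit(y ~ x, d)
  expect_s3_class(fit, "wlogit")
  expect_named(coef(fit), c("(Intercept)", "x"))
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  p <- predict(fit, data.frame(x = c(-1, 0, 1)))
  expect_true(all(p > 0 & p < 1))
  expect_equal(unname(predict(fit, data.frame(x = 0), type = "link")),
               unname(coef(fit)[1]), tolerance = 1e-12)
  s <- summary(fit)
  expect_true(all(c("Estimate", "Pr(>|z|)") %in%
                    colnames(s$coefficients)))
  expect_length(residuals(fit), 60)
})

test_that("AICc and Akaike weights follow their formulas", {
  expect_equal(aicc(-100, 3, 100), 206.25)
  expect_equal(aicc(-100, 3, 100) - 2 * 3 * 4 / 96, 206)   # plain AIC
  set.seed(24)
  d <- data.frame(x = rnorm(50))
  d$y <- rbinom(50, 1, 0.5)
  f1 <- wlogit(y ~ 1, d); f2 <- wlogit(y ~ 1, d)
  tab <- aicc_rank(list(a = f1, b = f2))
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_equal(tab$deviance, -2 * tab$loglik)
  expect_equal(aicc_rank(list(only = f1))$weight, 1)
  f3 <- wlogit(y ~ 1, d[1:40, ])
  expect_error(aicc_rank(list(f1, f3)), "different numbers of rows")
})

test_that("a 2x2 year enumerates both matchings exhaustively", {
  met <- toy_metrics(c(0, 10), c(0, 10))
  pt <- build_pair_table(met, "x")
  res <- matching_permutation_test(pt, "x", n_perm = 999)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 2)
  # observed matching F1-M1/F2-M2 has mean |d| = 0; the alternative has 10;
  # grand mean is 5, so the two null statistics are -5 and +5
  expect_equal(sort(res$null), c(-5, 5))
  expect_equal(res$statistic, -5)
  expect_equal(res$p_value, 1)   # |T| ties with the only other matching
})

test_that("monte-carlo permutation p-values respect the add-one bound", {
  set.seed(30)
  cfg <- sim_config(n_pairs_per_year = c("2022" = 12),
                    disassortment = c(mean_trip_distance = 30),
                    wing_assortment = 0, seed = 77)
  st <- simulate_pair_study(cfg)
  pt <- build_pair_table(st$metrics, "mean_trip_distance")
  res <- matching_permutation_test(pt, "mean_trip_distance", n_perm = 199,
                                   seed = 4, exhaustive_limit = 10)
  expect_false(res$exhaustive)
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 1)
  expect_warning(matching_permutation_test(pt, "mean_trip_distance",
                                           n_perm = 50, seed = 4,
                                           exhaustive_limit = 10),
                 "coarse")
})

test_that("t-tests match hand computation and reject degenerate input", {
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  res <- ttest_unpaired(x, y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4          # pooled variance, df = 4
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 4), tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # paired
  before <- c(10, 12, 14, 16); after <- c(9, 11, 12, 17)
  pres <- ttest_paired(before, after)
  dif <- before - after
  expect_equal(pres$t, mean(dif) / (sd(dif) / 2), tolerance = 1e-10)
  expect_error(ttest_paired(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(ttest_paired(1:3, 1:4), "length")
  expect_error(ttest_unpaired(1, 1:3), "n >= 2")
})
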