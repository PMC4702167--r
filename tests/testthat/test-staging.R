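test_that("linear stage regression matches closed-form OLS", {
  # exact line
  st <- rep(2:12, each = 3)
  y <- 2 * st + 1
  fit <- suppressWarnings(fit_stage_linear(st, y))  # exact fit
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # noisy data against the closed-form oracle
  dat <- with_seed_restore(5, {
    x <- rep(2:12, each = 15)
    list(x = x, y = log(1500) + 0.38 * (x - 2) + rnorm(length(x), 0, 0.15))
  })
  fit2 <- fit_stage_linear(dat$x, dat$y)
  sxy <- sum((dat$x - mean(dat$x)) * (dat$y - mean(dat$y)))
  sxx <- sum((dat$x - mean(dat$x))^2)
  slope_o <- sxy / sxx
  int_o <- mean(dat$y) - slope_o * mean(dat$x)
  pred <- int_o + slope_o * dat$x
  r2_o <- 1 - sum((dat$y - pred)^2) / sum((dat$y - mean(dat$y))^2)
  expect_equal(fit2$slope, slope_o, tolerance = 1e-10)
  expect_equal(fit2$intercept, int_o, tolerance = 1e-10)
  expect_equal(fit2$r_squared, r2_o, tolerance = 1e-10)
  expect_lt(abs(fit2$slope - 0.38) / 0.38, 0.1)
  expect_gt(fit2$r_squared, 0.9)
  # the CI band brackets the fit
  expect_true(all(fit2$ci_band$lwr <= fit2$ci_band$fit &
                    fit2$ci_band$fit <= fit2$ci_band$upr))

  expect_error(fit_stage_linear(rep(3, 10), rnorm(10)), "distinct")
})

simulate_po <- function(n, beta, alpha, seed) {
  with_seed_restore(seed, {
    x <- runif(n, -2, 2)
    u <- runif(n)
    K <- length(alpha) + 1L
    y <- integer(n)
    for (i in seq_len(n)) {
      p_gt <- plogis(beta * x[i] - alpha)    # P(Y > k)
      cum <- c(1 - p_gt, 1)                  # P(Y <= k), k = 1..K
      y[i] <- findInterval(u[i], c(0, cum[-K])) # smallest k with u <= cum_k
    }
    list(x = x, y = y)
  })
}

test_that("cumulative-logit MLE recovers generating parameters", {
  d <- simulate_po(500, beta = 3, alpha = c(-1, 2), seed = 9)
  m <- fit_ordinal(d$y, d$x, feature_name = "x")
  expect_false(m$penalized)
  expect_lt(abs(m$coefficient - 3) / 3, 0.15)
  expect_lt(max(abs(m$intercepts - c(-1, 2))), 0.3)
  # monotonicity of P(stage > k) in x for every k
  probs <- predict(m, seq(-2, 2, length.out = 50))
  surv <- t(apply(probs, 1, function(p) rev(cumsum(rev(p)))))[, -1]
  expect_true(all(diff(surv[, 1]) >= -1e-9))
  expect_true(all(diff(surv[, 2]) >= -1e-9))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
})

test_that("the in-package MLE agrees with an independent ordinal fitter", {
  skip_if_not_installed("MASS")
  d <- simulate_po(400, beta = 2, alpha = c(-0.5, 0.8, 2), seed = 21)
  m <- fit_ordinal(d$y, d$x, feature_name = "x")
  pol <- MASS::polr(factor(d$y, ordered = TRUE) ~ x,
                    data = data.frame(x = d$x), method = "logistic")
  expect_equal(m$coefficient, unname(coef(pol)), tolerance = 1e-4)
  expect_equal(unname(m$intercepts), unname(pol$zeta), tolerance = 1e-4)
  expect_equal(m$log_lik, as.numeric(logLik(pol)), tolerance = 1e-6)
})

test_that("the fitted log-likelihood is a stationary point", {
  d <- simulate_po(300, beta = 3, alpha = c(-1, 2), seed = 31)
  m <- fit_ordinal(d$y, d$x, feature_name = "x")
  par <- c(m$coefficient, m$intercepts)
  lk <- list(F = plogis, f = dlogis, name = "logit")
  nll <- function(p) {
    y <- d$y; x <- d$x; K <- 3L
    eta_lo <- ifelse(y == 1L, Inf, p[1] * x - p[-1][pmax(y - 1L, 1L)])
    eta_hi <- ifelse(y == K, -Inf, p[1] * x - p[-1][pmin(y, K - 1L)])
    -sum(log(pmax(plogis(eta_lo) - plogis(eta_hi), 1e-12)))
  }
  g <- vapply(seq_along(par), function(i) {
    h <- 1e-6
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (nll(pp) - nll(pm)) / (2 * h)
  }, numeric(1))
  expect_lt(sqrt(sum(g^2)), 1e-4)
})

test_that("stage cutoffs are alpha/beta, ordered, and flag unresolvable pairs", {
  m <- structure(list(feature_name = "x", coefficient = 1,
                      intercepts = setNames(c(3, 5, 5.01),
                                            c("2|3", "3|4", "4|5")),
                      stage_range = 2:5, link = "logit"),
                 class = "stage_model")
  cuts <- stage_cutoffs(m)
  expect_equal(unname(cuts[1]), 3)
  expect_equal(unname(cuts[2]), 5)
  expect_true(is.na(cuts[3]))   # 0.01 gap << median gap: unavailable

  m$coefficient <- 2
  expect_equal(unname(stage_cutoffs(m)[1]), 1.5)
  m$coefficient <- -1
  expect_error(stage_cutoffs(m), "coefficient")

  # recovery: cutoffs of the fitted synthetic model match alpha/beta
  d <- simulate_po(500, beta = 3, alpha = c(-1, 2), seed = 13)
  fit <- fit_ordinal(d$y, d$x, feature_name = "x")
  expect_lt(max(abs(stage_cutoffs(fit) - c(-1, 2) / 3) / abs(c(-1, 2) / 3)),
            0.1)
})

test_that("classification argmax respects cutoffs and stage ordering", {
  d <- simulate_po(500, beta = 3, alpha = c(-1, 2), seed = 51)
  m <- fit_ordinal(d$y, d$x, feature_name = "log_size")
  # at the k-th cutoff the exceedance probability is exactly 1/2: the mass
  # below the boundary equals the mass above it
  x_star <- unname(m$intercepts[1] / m$coefficient)
  p <- predict(m, x_star)[1, ]
  expect_equal(unname(p[1]), 0.5, tolerance = 1e-9)
  expect_equal(sum(p[2:3]), 0.5, tolerance = 1e-9)
  # prediction is monotone in the feature
  grid <- seq(-3, 3, length.out = 200)
  cls <- apply(predict(m, grid), 1, which.max)
  expect_true(all(diff(cls) >= 0))
  pr <- classify_stage(m, list(log_size = 1.5))
  expect_s3_class(pr, "stage_prediction")
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-9)
  expect_equal(pr$stage, m$stage_range[which.max(pr$probabilities)])
  expect_error(classify_stage(structure(list(feature_name = "chamber_ratio"),
                                        class = "stage_model"),
                              list(chamber_ratio = 2)),
               "log_size")
})

test_that("two-sample t-test behaves and matches a permutation oracle", {
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "variance")
  same <- c(1, 2, 3, 4)
  tt <- two_sample_ttest(same, same)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  a <- c(1, 2, 3); b <- a + 10
  tt2 <- two_sample_ttest(a, b)
  expect_lt(tt2$p, 0.001)

  groups <- with_seed_restore(61, list(a = rnorm(30), b = rnorm(30, 0.8)))
  tt3 <- two_sample_ttest(groups$a, groups$b)
  p_perm <- oracle_permutation_p(groups$a, groups$b, n_perm = 1e5, seed = 62)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 1e5)
  expect_lt(abs(tt3$p - p_perm), 0.01 + 4 * mc_se)
})

test_that("the Gaussian intersection rule finds the between-means root", {
  # equal SDs: midpoint
  a <- c(-0.1, 0, 0.1); b <- c(0.9, 1, 1.1)
  gc <- gaussian_intercept_rule(a, b)
  expect_equal(gc$cutoff, 0.5, tolerance = 1e-12)

  # unequal SDs vs the grid-search oracle
  g <- with_seed_restore(71, list(a = rnorm(40, 0, 1), b = rnorm(40, 2, 2)))
  gc2 <- gaussian_intercept_rule(g$a, g$b)
  root <- oracle_gaussian_root(gc2$mean_a, gc2$sd_a, gc2$mean_b, gc2$sd_b)
  expect_lt(abs(gc2$cutoff - root), 1e-4)
  expect_gt(gc2$cutoff, gc2$mean_a)
  expect_lt(gc2$cutoff, gc2$mean_b)

  # between the means, thresholding at the cutoff equals the
  # likelihood-ratio rule between the two fitted Gaussians
  xs <- seq(gc2$mean_a + 1e-6, gc2$mean_b - 1e-6, length.out = 200)
  lr <- dnorm(xs, gc2$mean_b, gc2$sd_b) > dnorm(xs, gc2$mean_a, gc2$sd_a)
  expect_identical(lr, xs > gc2$cutoff)

  expect_error(gaussian_intercept_rule(c(1), c(2, 3)), "at least 2")
})

test_that("the stage-8/9 rule separates generator Delta groups", {
  tabs <- generate_feature_table(20, seed = 81)
  t8 <- tabs$table$delta_to_uniform[tabs$table$stage == 8]
  t9 <- tabs$table$delta_to_uniform[tabs$table$stage == 9]
  gc <- gaussian_intercept_rule(t8, t9)
  expect_lt(gc$p_value, 1e-4)
  # held-out draws classified by the cutoff
  held <- generate_feature_table(30, seed = 82)
  h8 <- held$table$delta_to_uniform[held$table$stage == 8]
  h9 <- held$table$delta_to_uniform[held$table$stage == 9]
  acc <- mean(c(h8 < gc$cutoff, h9 > gc$cutoff))
  expect_gte(acc, 0.9)
})

test_that("stage models round-trip through JSON", {
  d <- simulate_po(300, beta = 3, alpha = c(-1, 2), seed = 91)
  m <- fit_ordinal(d$y, d$x, feature_name = "log_size")
  path <- tempfile(fileext = ".json")
  write_stage_models(list(log_size = m), path)
  back <- read_stage_models(path)
  expect_equal(back$log_size$coefficient, m$coefficient)
  expect_equal(unname(back$log_size$intercepts), unname(m$intercepts))
  expect_equal(back$log_size$stage_range, m$stage_range)
  unlink(path)
})

test_that("stage labels 10A/10B are merged into stage 10 for fitting", {
  expect_equal(eggstage:::merge_stage_labels(c("9", "10A", "10B", "11")),
               c(9, 10, 10, 11))
})
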