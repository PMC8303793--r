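test_that("Wald ratios follow the delta-method arithmetic", {
  r <- wald_ratio(0.2, 0.4, 0.1)
  expect_equal(r$theta_j, 2)
  expect_equal(r$se_j, 0.5)
  expect_equal(wald_ratio(1, 0, 0.1)$theta_j, 0)
  expect_equal(wald_ratio(-0.2, 0.4, 0.1)$theta_j, -2)  # sign equivariance
  expect_error(wald_ratio(0, 0.4, 0.1), "beta_x == 0")
  r2 <- wald_ratio(0.2, 0.4, 0.1, se_x = 0.05, second_order = TRUE)
  expect_gt(r2$se_j, 0.5)
})

test_that("IVW matches the closed-form weighted-least-squares value", {
  h <- make_h(c(0.1, 0.2, 0.15), c(0.05, 0.11, 0.07), c(0.01, 0.02, 0.015))
  e <- mr_ivw(h, "fixed")
  expect_equal(e$theta, 151.6667 / 300, tolerance = 1e-6)
  # each term of the denominator weights w_j * beta_x^2 equals 100
  expect_equal(1 / e$se^2, 300, tolerance = 1e-10)
  expect_error(mr_ivw(make_h(0.1, 0.05, 0.01)), "at least 2")
})

test_that("a perfect proportional fit gives Q = 0 and equal FE/RE errors", {
  bx <- c(0.1, 0.2, 0.3)
  h <- make_h(bx, 0.4 * bx, rep(0.01, 3))
  fe <- mr_ivw(h, "fixed"); re <- mr_ivw(h, "random")
  expect_equal(fe$theta, 0.4)
  expect_equal(fe$Q, 0)
  expect_equal(re$sigma2, 1)
  expect_equal(re$se, fe$se)
})

test_that("IVW equals an independent weighted-regression oracle", {
  set.seed(101)
  for (i in 1:50) {
    J <- sample(3:30, 1)
    h <- make_h(runif(J, -0.3, 0.3) + 0.35, rnorm(J, 0, 0.1),
                runif(J, 0.005, 0.05))
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
              weights = 1 / h$se_outcome^2)
    expect_equal(mr_ivw(h, "fixed")$theta, unname(coef(fit)), tolerance = 1e-12)
  }
})

test_that("Egger recovers an exact affine relation and its intercept", {
  h <- make_h(c(1, 2, 3), 0.5 + 0.3 * c(1, 2, 3), rep(0.1, 3))
  e <- mr_egger(h)
  expect_equal(e$theta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept, 0.5, tolerance = 1e-12)
  expect_error(mr_egger(make_h(c(1, 2), c(1, 2), c(0.1, 0.1))), "at least 3")
  expect_error(mr_egger(make_h(rep(1, 4), 1:4, rep(0.1, 4))), "degenerate")
})

test_that("Egger equals IVW when the data carry no intercept", {
  # exact through-origin data: the stated equivalence of the two methods
  bx <- c(0.12, 0.2, 0.31, 0.4)
  h <- make_h(bx, 0.27 * bx, c(0.01, 0.03, 0.02, 0.015))
  expect_equal(mr_egger(h)$theta, mr_ivw(h, "fixed")$theta, tolerance = 1e-12)
  expect_equal(mr_egger(h)$intercept, 0, tolerance = 1e-12)
})

test_that("Egger coefficients and scaled errors match a weighted lm oracle", {
  set.seed(77)
  for (i in 1:20) {
    J <- sample(10:40, 1)
    bx <- runif(J, 0.05, 0.4)
    by <- 0.1 + 0.3 * bx + rnorm(J, 0, 0.05)  # overdispersed: sigma2 > 1
    se_y <- runif(J, 0.005, 0.02)
    h <- make_h(bx, by, se_y)
    fit <- lm(by ~ bx, weights = 1 / se_y^2)
    e <- mr_egger(h)
    expect_equal(e$theta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    sm <- summary(fit)$coefficients
    if (e$sigma2 > 1) {  # lm scales by the residual sd with no floor
      expect_equal(e$se, unname(sm[2, 2]), tolerance = 1e-10)
      expect_equal(e$intercept_se, unname(sm[1, 2]), tolerance = 1e-10)
      expect_equal(e$pval, unname(sm[2, 4]), tolerance = 1e-10)
    }
  }
})

test_that("median estimators reduce and interpolate correctly", {
  h <- make_h(c(1, 1, 1), c(1, 2, 3), rep(0.1, 3))
  expect_equal(mr_median(h, weighted = FALSE, n_boot = 10, seed = 1)$theta, 2)
  # equal weights collapse the weighted median onto the simple median
  set.seed(5)
  for (i in 1:10) {
    J <- sample(3:15, 1)
    r <- rnorm(J)
    h <- make_h(rep(1, J), r, rep(0.2, J))
    expect_equal(mr_median(h, weighted = TRUE, n_boot = 2, seed = 1)$theta,
                 median(r))
  }
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  h <- sim_h(n_snps = 20, theta = 0.2, seed = 31)
  a <- mr_median(h, n_boot = 100, seed = 99)
  b <- mr_median(h, n_boot = 100, seed = 99)
  expect_identical(a$se, b$se)
  c_ <- mr_median(h, n_boot = 100, seed = 100)
  expect_false(identical(a$se, c_$se))
  m1 <- mr_mode(h, n_boot = 50, seed = 7)
  m2 <- mr_mode(h, n_boot = 50, seed = 7)
  expect_identical(m1$se, m2$se)
})

test_that("the mode estimator finds the dominant ratio cluster", {
  h <- make_h(rep(1, 4), c(2, 2, 2, 7), rep(0.5, 4))
  expect_equal(mr_mode(h, weighted = FALSE, n_boot = 2, seed = 1)$theta, 2,
               tolerance = 0.3)
  # all ratios identical: the mode is that value exactly
  h2 <- make_h(c(1, 2, 4), c(1.5, 3, 6), rep(0.1, 3))
  expect_equal(mr_mode(h2, n_boot = 2, seed = 1)$theta, 1.5, tolerance = 1e-12)
})

test_that("estimators are scale-equivariant in the outcome units", {
  h <- sim_h(n_snps = 30, theta = 0.2, seed = 41)
  cc <- 3.7
  h2 <- h$data
  h2$beta_outcome <- cc * h2$beta_outcome
  h2$se_outcome <- cc * h2$se_outcome
  for (fn in list(
    function(x) mr_ivw(x, "random"),
    function(x) mr_ivw(x, "fixed"),
    mr_egger,
    function(x) mr_median(x, n_boot = 20, seed = 3),
    function(x) mr_mode(x, n_boot = 10, seed = 3)
  )) {
    a <- fn(h$data); b <- fn(h2)
    expect_equal(b$theta, cc * a$theta, tolerance = 1e-8)
    expect_equal(b$se, cc * a$se, tolerance = 1e-8)
  }
})

test_that("jointly negating SNP effect pairs changes nothing", {
  h <- sim_h(n_snps = 30, theta = 0.2, seed = 43)
  set.seed(2)
  idx <- sample(30, 13)
  h2 <- h$data
  h2$beta_exposure[idx] <- -h2$beta_exposure[idx]
  h2$beta_outcome[idx] <- -h2$beta_outcome[idx]
  for (fn in list(
    function(x) mr_ivw(x, "random"),
    mr_egger,
    function(x) mr_median(x, n_boot = 20, seed = 3),
    function(x) mr_mode(x, n_boot = 10, seed = 3)
  )) {
    a <- fn(h$data); b <- fn(h2)
    expect_equal(b$theta, a$theta, tolerance = 1e-10)
    expect_equal(b$se, a$se, tolerance = 1e-10)
  }
})

test_that("random-effects errors never undercut fixed-effects errors", {
  set.seed(303)
  for (i in 1:30) {
    J <- sample(3:40, 1)
    h <- make_h(runif(J, 0.05, 0.3), rnorm(J, 0, 0.05), runif(J, 0.005, 0.05))
    fe <- mr_ivw(h, "fixed"); re <- mr_ivw(h, "random")
    expect_gte(re$se, fe$se)
    if (fe$Q <= J - 1) expect_equal(re$se, fe$se)
  }
})

test_that("mr_all dispatches each requested method once", {
  h <- sim_h(n_snps = 20, theta = 0.2, seed = 51)
  out <- mr_all(h, c("ivw_re", "ivw_fe", "egger", "median_simple",
                     "median_weighted", "mode_simple", "mode_weighted"),
                n_boot = 5, seed = 1)
  expect_named(out, c("ivw_re", "ivw_fe", "egger", "median_simple",
                      "median_weighted", "mode_simple", "mode_weighted"))
  expect_equal(out$ivw_re$theta, out$ivw_fe$theta)
  expect_error(mr_all(h, "presso"), "unknown method")
})
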