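test_that("intercept-only fits give flat curves for every individual", {
  std <- standardization(0.5, 0.25)
  mu <- matrix(c(0.2, 0.1, 0.3), 3L, 1L,
               dimnames = list(NULL, "intercept"))
  B <- array(c(0.2, 0.1, 0.3, -0.1, 0, 0.1), c(3L, 2L, 1L))
  fit <- make_fake_fit(mu, mu * 0 + 0.1, B, std, rsf_formula())
  cur <- individual_response(fit, "b", grid = c(0, 0.25, 0.5, 0.75, 1))
  for (id in unique(cur$level)) {
    m <- cur$mean[cur$level == id]
    expect_equal(diff(range(m)), 0)
  }
})

test_that("a single-draw posterior reproduces the closed-form inverse logit", {
  std <- standardization(0.5, 0.25)
  mu <- matrix(c(0.5, 1.2, -0.8), 1L, 3L,
               dimnames = list(NULL, c("intercept", "b", "b2")))
  B <- array(c(0.4, 1.0, -0.7), c(1L, 1L, 3L))
  # a second individual so the object is structurally typical
  B <- array(c(0.4, 0.6, 1.0, 1.4, -0.7, -0.9), c(1L, 2L, 3L))
  fit <- make_fake_fit(mu, mu * 0 + 0.1, B, std, rsf_formula(c("b", "b2")))
  grid <- c(0.1, 0.5, 0.9)
  cur <- individual_response(fit, "b", grid)
  z <- (grid - 0.5) / 0.25
  p1 <- plogis(0.4 + 1.0 * z - 0.7 * z^2)
  got <- cur[cur$level == fit$individuals[1L], ]
  expect_equal(got$mean, p1, tolerance = 1e-12)
  expect_equal(got$lo80, p1, tolerance = 1e-12)  # single draw: degenerate bounds
})

test_that("a three-draw posterior matches hand-computed pointwise summaries", {
  std <- standardization(0, 1)  # identity standardization
  mu <- matrix(0, 3L, 2L, dimnames = list(NULL, c("intercept", "b")))
  # one individual, three draws of (intercept, slope)
  B <- array(c(0, 0.5, 1,  1, 1, 1), c(3L, 1L, 2L))
  fit <- make_fake_fit(mu, mu * 0 + 0.1, B, std, rsf_formula("b"))
  grid <- c(-1, 0, 2)
  cur <- individual_response(fit, "b", grid)
  probs <- rbind(plogis(0 + 1 * grid), plogis(0.5 + 1 * grid),
                 plogis(1 + 1 * grid))
  expect_equal(cur$mean, colMeans(probs), tolerance = 1e-12)
  expect_equal(cur$lo80, apply(probs, 2L, quantile, 0.1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cur$hi80, apply(probs, 2L, quantile, 0.9), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("curve bounds are ordered probabilities on real fits", {
  tf <- tiny_fitted()
  grid <- seq(0.05, 0.95, length.out = 11L)
  ind <- individual_response(tf$fit, "b", grid)
  marg <- marginal_response(tf$fit, "b", grid, n_new_individuals = 150L,
                            seed = 4, use_draws = 200L)
  for (cur in list(ind, marg)) {
    expect_true(all(cur$lo80 <= cur$mean + 1e-12))
    expect_true(all(cur$mean <= cur$hi80 + 1e-12))
    expect_true(all(cur$lo80 >= 0 & cur$hi80 <= 1))
  }
  expect_identical(nrow(marg), 11L)
  expect_identical(sum(ind$level == tf$fit$individuals[1L]), 11L)
  marg2 <- marginal_response(tf$fit, "b", grid, n_new_individuals = 150L,
                             seed = 4, use_draws = 200L)
  expect_identical(marg$mean, marg2$mean)  # seeded reproducibility
})

test_that("the marginal curve collapses to the population curve as sigma -> 0", {
  std <- standardization(0.5, 0.25)
  mu <- matrix(c(0.3, 1.5, -1.0), 2L, 3L, byrow = TRUE,
               dimnames = list(NULL, c("intercept", "b", "b2")))
  mu[2L, ] <- mu[1L, ]
  B <- array(rep(mu[1L, ], each = 4L), c(2L, 2L, 3L))
  sig <- matrix(1e-8, 2L, 3L)
  fit <- make_fake_fit(mu, sig, B, std, rsf_formula(c("b", "b2")))
  grid <- seq(0.1, 0.9, 0.2)
  marg <- marginal_response(fit, "b", grid, n_new_individuals = 2000L, seed = 2)
  z <- (grid - 0.5) / 0.25
  expect_equal(marg$mean, plogis(0.3 + 1.5 * z - 1.0 * z^2), tolerance = 1e-3)
})

test_that("the quadratic optimum follows the parabola vertex and its flags", {
  std <- standardization(0, 1)  # identity: raw == standardized
  mu <- matrix(c(0, 1, -1), 1L, 3L,
               dimnames = list(NULL, c("intercept", "b", "b2")))
  B <- array(rep(c(0, 1, -1), each = 2L), c(1L, 2L, 3L))
  fit <- make_fake_fit(mu, mu * 0 + 0.1, B, std, rsf_formula(c("b", "b2")))
  opt <- optimum_covariate(fit, "b")
  expect_equal(opt$mean, 0.5, tolerance = 1e-12)  # -beta/(2*gamma) = 0.5
  expect_identical(opt$frac_interior, 1)

  mu_pos <- mu; mu_pos[, "b2"] <- 0.5
  fit_pos <- make_fake_fit(mu_pos, mu * 0 + 0.1, B, std,
                           rsf_formula(c("b", "b2")))
  opt_pos <- optimum_covariate(fit_pos, "b")
  expect_false(opt_pos$defined)
  expect_identical(opt_pos$frac_interior, 0)
  expect_true(is.na(opt_pos$mean))

  fit_lin <- make_fake_fit(mu[, 1:2, drop = FALSE],
                           matrix(0.1, 1L, 2L),
                           B[, , 1:2, drop = FALSE], std, rsf_formula("b"))
  expect_error(optimum_covariate(fit_lin, "b"), class = "formula_mismatch")
})

test_that("optimum back-transforms through the standardization", {
  std <- standardization(0.4, 0.2)
  mu <- matrix(c(0, 2, -2), 1L, 3L,
               dimnames = list(NULL, c("intercept", "b", "b2")))
  B <- array(rep(c(0, 2, -2), each = 1L), c(1L, 1L, 3L))
  fit <- make_fake_fit(mu, mu * 0 + 0.1, B, std, rsf_formula(c("b", "b2")))
  # vertex at z* = 0.5 -> raw 0.4 + 0.2 * 0.5 = 0.5
  expect_equal(optimum_covariate(fit, "b")$mean, 0.5, tolerance = 1e-12)
})
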