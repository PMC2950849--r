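test_that("landscapes hit the target bare fraction and zero bare heights", {
  land <- make_landscape(extent = c(200, 200), bare_fraction = 0.5, seed = 3)
  expect_gte(bare_fraction(land), 0.45)
  expect_lte(bare_fraction(land), 0.55)
  expect_true(all(land$height[land$bare] == 0))
  expect_true(all(land$height >= 0))

  sparse <- make_landscape(extent = c(100, 100), bare_fraction = 0.01, seed = 3)
  expect_lt(bare_fraction(sparse), 0.05)

  expect_error(make_landscape(patch_scale = 0.4, grain = 0.5),
               class = "resolution_error")
  expect_error(make_landscape(bare_fraction = 0), class = "bad_config")
})

test_that("mosaic autocorrelation range grows with patch_scale", {
  # variogram range along rows: first lag where the semivariance of the
  # bare indicator reaches 95% of its sill
  vrange <- function(patch_scale) {
    land <- make_landscape(extent = c(150, 150), grain = 0.5,
                           patch_scale = patch_scale, seed = 11)
    m <- land$bare * 1
    lags <- 1:80
    gamma <- vapply(lags, function(l) {
      d <- m[, seq_len(ncol(m) - l)] - m[, -seq_len(l)]
      mean(d^2) / 2
    }, numeric(1L))
    sill <- mean(gamma[60:80])
    lags[which(gamma >= 0.95 * sill)[1L]]
  }
  r <- vapply(c(2, 8, 32), vrange, numeric(1L))
  expect_true(all(diff(r) > 0))
})

test_that("no selection means used and available covariates match", {
  land <- make_landscape(extent = c(260, 260), seed = 21)
  preset <- list(name = "test", n_individuals = 1L, patch_radius = 1,
                 include_height = TRUE, n_used = 500L)
  sim <- simulate_individual(land, preset,
                             c(intercept = 0, b = 0, b2 = 0),
                             n_used = 500L, seed = 8, hr_span = 200,
                             exclusion_radius = 1)
  used_b <- sim$records$bare[sim$records$y == 1]
  avail_b <- sim$records$bare[sim$records$y == 0]
  ks <- suppressWarnings(ks.test(used_b, avail_b))
  expect_gt(ks$p.value, 0.01)
})

test_that("directional selection shifts the used covariate distribution", {
  land <- make_landscape(extent = c(260, 260), seed = 22)
  preset <- list(name = "test", n_individuals = 1L, patch_radius = 1,
                 include_height = TRUE, n_used = 300L)
  sim <- simulate_individual(land, preset, c(intercept = 0, b = 2),
                             n_used = 300L, seed = 9, hr_span = 200,
                             exclusion_radius = 1)
  expect_gt(mean(sim$records$bare[sim$records$y == 1]),
            mean(sim$records$bare[sim$records$y == 0]))
})

test_that("quadratic selection with optimum 0.5 peaks centrally", {
  land <- make_landscape(extent = c(260, 260), seed = 23)
  preset <- list(name = "test", n_individuals = 1L, patch_radius = 1,
                 include_height = TRUE, n_used = 500L)
  sim <- simulate_individual(land, preset,
                             c(intercept = 0, b = 2, b2 = -2),
                             n_used = 500L, seed = 10, hr_span = 200,
                             exclusion_radius = 1)
  used_b <- sim$records$bare[sim$records$y == 1]
  counts <- table(cut(used_b, breaks = seq(0, 1, 0.1), include.lowest = TRUE))
  mode_bin <- which.max(counts)
  expect_true(mode_bin %in% 4:7)  # central bins around bare = 0.5
})

test_that("study generation matches the field design's structure", {
  sims <- simulate_all_species(seed = 14, n_used = 8L)
  counts <- vapply(sims, function(s) length(unique(s$records$individual_id)),
                   integer(1L))
  expect_identical(unname(counts), c(13L, 8L, 7L, 5L))
  for (s in sims) {
    tab <- table(s$records$individual_id, s$records$y)
    expect_true(all(tab[, "1"] == tab[, "0"]))  # matched counts by design
  }
  expect_true(all(is.na(sims$common_redstart$records$height)))
  expect_true(all(!is.na(sims$hoopoe$records$height)))

  # every generated dataset satisfies the model's design preconditions
  d <- build_design(sims$wryneck$records, rsf_formula(c("b", "b2")))
  expect_s3_class(d, "rsf_design")
})

test_that("generation is reproducible and sigma = 0 collapses individuals", {
  preset <- species_presets("wryneck")
  s1 <- simulate_study(preset, seed = 77, n_used = 6L)
  s2 <- simulate_study(preset, seed = 77, n_used = 6L)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$B, s2$truth$B)
  s3 <- simulate_study(preset, seed = 78, n_used = 6L)
  expect_false(identical(s1$records$bare, s3$records$bare))

  mu <- c(intercept = 0, b = 1)
  s0 <- simulate_study(preset, mu = mu,
                       sigma = c(intercept = 0, b = 0), seed = 5, n_used = 5L)
  expect_true(all(apply(s0$truth$B, 1L, function(r) identical(unname(r), unname(mu)))))
})
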