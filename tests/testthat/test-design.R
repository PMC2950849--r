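test_that("formulas enforce marginality and print canonically", {
  f <- rsf_formula(c("b2", "b"))
  expect_identical(f$terms, c("b", "b2"))
  expect_identical(format(f), "b+b2")
  expect_identical(format(rsf_formula()), "intercept")
  expect_error(rsf_formula("b2"), class = "bad_formula")
  expect_error(rsf_formula(c("h2")), class = "bad_formula")
  expect_error(rsf_formula("x"), class = "bad_formula")
})

test_that("two-point standardization and squared-term convention", {
  recs <- data.frame(individual_id = c("a", "a", "b", "b"),
                     y = c(1, 0, 1, 0),
                     bare = c(0.2, 0.8, 0.2, 0.8),
                     height = c(5, 10, 5, 10))
  d <- build_design(recs, rsf_formula("b"))
  # sd of c(.2,.8,.2,.8) = sqrt(0.12); standardized values +-0.866...
  expect_equal(unname(d$X[, "b"]),
               (recs$bare - 0.5) / sd(recs$bare))
  d2 <- build_design(recs, rsf_formula(c("b", "b2")),
                     std = standardization(0.3, 0.4))
  z <- (recs$bare - 0.3) / 0.4
  expect_equal(unname(d2$X[, "b2"]), z^2)  # square of the standardized value

  # round trip raw -> standardized -> raw
  s <- d2$std
  expect_equal(s$mean[["b"]] + s$sd[["b"]] * z, recs$bare, tolerance = 1e-12)
})

test_that("design matrix equals a hand-computed fixture entry by entry", {
  recs <- data.frame(
    individual_id = rep(c("a", "b"), each = 5L),
    y = rep(c(1, 0, 1, 0, 1), 2L),
    bare = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2, 0.4, 0.5, 0.6, 0.8),
    height = c(4, 8, 12, 16, 20, 6, 10, 12, 14, 18))
  std <- standardization(0.5, 0.25, 12, 5)
  d <- suppressWarnings(
    build_design(recs, rsf_formula(c("b", "b2", "h", "h2")), std = std))
  zb <- (recs$bare - 0.5) / 0.25
  zh <- (recs$height - 12) / 5
  expected <- cbind(intercept = 1, b = zb, b2 = zb^2, h = zh, h2 = zh^2)
  expect_equal(unname(d$X), unname(expected))
  expect_identical(colnames(d$X), c("intercept", "b", "b2", "h", "h2"))
  expect_identical(d$individuals, c("a", "b"))
})

test_that("degenerate designs and imbalance are caught", {
  recs <- make_records(I = 3L)
  solo <- recs[recs$individual_id == "ind_01", ]
  expect_error(build_design(solo, rsf_formula("b")), class = "degenerate_design")

  one_class <- recs
  one_class$y[one_class$individual_id == "ind_02"] <- 0
  expect_error(build_design(one_class, rsf_formula("b")),
               "ind_02", class = "degenerate_design")

  imb <- recs
  extra <- imb[imb$individual_id == "ind_01" & imb$y == 0, ][rep(1, 6), ]
  expect_warning(build_design(rbind(imb, extra), rsf_formula("b")),
                 "imbalance")

  no_h <- recs
  no_h$height <- NA_real_
  expect_error(build_design(no_h, rsf_formula(c("h"))), class = "bad_records")
  expect_silent(build_design(no_h, rsf_formula(c("b", "b2"))))
})

test_that("record validation rejects malformed tables", {
  recs <- make_records(I = 2L)
  bad_y <- recs; bad_y$y[1L] <- 2
  expect_error(validate_use_records(bad_y), class = "bad_records")
  bad_b <- recs; bad_b$bare[1L] <- 1.4
  expect_error(validate_use_records(bad_b), class = "bad_records")
  expect_error(validate_use_records(recs[, -3L]), class = "bad_records")
})
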