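# Independent oracles and fixture builders. Everything here is written
# deliberately differently from the package implementation (loops, textbook
# algorithms) so that agreement is evidence, not tautology.

# Jarvis-march (gift wrapping) convex hull, counter-clockwise vertex order.
gift_wrap_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1L] + 1e-12 * pts[, 2L])  # leftmost, lowest tie-break
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1L] - pts[cur, 1L]) * (pts[j, 2L] - pts[cur, 2L]) -
            (pts[cand, 2L] - pts[cur, 2L]) * (pts[j, 1L] - pts[cur, 1L])
      if (cand == cur || cr > 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) >
                      sum((pts[cand, ] - pts[cur, ])^2))) {
        cand <- j
      }
    }
    cur <- cand
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# Shoelace area by explicit loop.
loop_area <- function(v) {
  s <- 0
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1L] * v[j, 2L] - v[j, 1L] * v[i, 2L]
  }
  unname(abs(s) / 2)
}

# Canonical form of a hull vertex set for comparison: rows sorted.
hull_canonical <- function(v) {
  v <- unclass(v)
  attr(v, "area") <- NULL
  v[order(v[, 1L], v[, 2L]), , drop = FALSE]
}

# Record-by-record Bernoulli log-likelihood, plain log(), no vectorization.
loglik_loop <- function(design, B) {
  total <- 0
  for (r in seq_along(design$y)) {
    i <- design$indiv_index[r]
    eta <- 0
    for (k in seq_len(ncol(design$X))) eta <- eta + design$X[r, k] * B[i, k]
    p <- 1 / (1 + exp(-eta))
    total <- total + design$y[r] * log(p) + (1 - design$y[r]) * log(1 - p)
  }
  unname(total)
}

# Gauss-Hermite nodes/weights via the Golub-Welsch Jacobi eigenproblem
# (weight exp(-x^2)).
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) J[i, i + 1L] <- J[i + 1L, i] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
}

# E[plogis(a + e)], e ~ N(0, s^2), by 20-node Gauss-Hermite quadrature.
gh_logit_normal_mean <- function(a, s, n_nodes = 20L) {
  gh <- gauss_hermite(n_nodes)
  vapply(a, function(ai) {
    sum(gh$weights * stats::plogis(ai + sqrt(2) * s * gh$nodes)) / sqrt(pi)
  }, numeric(1L))
}

# Deterministic small record table: I individuals, n0 random and n1 used
# points each, covariates spread over their ranges.
make_records <- function(I = 3L, n1 = 5L, n0 = 5L, with_height = TRUE) {
  rows <- list()
  for (i in seq_len(I)) {
    n <- n1 + n0
    bare <- round(seq(0.05, 0.95, length.out = n) + 0.01 * i, 4)
    bare <- pmin(pmax(bare, 0), 1)
    height <- if (with_height) round(seq(2, 30, length.out = n) + i, 4) else NA_real_
    rows[[i]] <- data.frame(
      individual_id = sprintf("ind_%02d", i), species = "test",
      y = rep_len(c(1, 0), n), bare = bare, height = height,
      habitat = "meadow")
  }
  do.call(rbind, rows)
}

# Hand-assembled rsf_fit-like object for fixture tests.
make_fake_fit <- function(mu, sigma, B, std, formula, deviance = NULL,
                          individuals = NULL) {
  stopifnot(is.matrix(mu), length(dim(B)) == 3L)
  if (is.null(individuals)) individuals <- sprintf("ind_%02d", seq_len(dim(B)[2L]))
  dimnames(B) <- list(NULL, individuals, colnames(mu))
  structure(list(mu = mu, sigma = sigma, B = B,
                 deviance = deviance %||% rep(1, nrow(mu)),
                 rhat = NULL, ess = NULL, accept = NULL, std = std,
                 formula = formula, individuals = individuals,
                 priors = rsf_priors(),
                 config = mcmc_config(chains = 1L, iterations = nrow(mu) + 1L,
                                      burn_in = 1L),
                 chain = rep(1L, nrow(mu)), warnings = character(0)),
            class = "rsf_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform landscape builder for exact patch-extraction cases.
make_uniform_landscape <- function(nx = 40L, ny = 40L, grain = 0.5,
                                   bare = FALSE, height = 12) {
  bm <- matrix(bare, ny, nx)
  hm <- matrix(ifelse(bm, 0, height), ny, nx)
  structure(list(extent = c(nx * grain, ny * grain), grain = grain,
                 bare = bm, height = hm, bare_fraction = mean(bm),
                 patch_scale = NA_real_, height_mean = height,
                 height_sd = 0, seed = NA_integer_),
            class = "habitat_landscape")
}

# Small fitted model shared across tests (cached per session).
tiny_fit_cache <- new.env(parent = emptyenv())
tiny_fitted <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    recs <- make_records(I = 4L, n1 = 12L, n0 = 12L)
    design <- build_design(recs, rsf_formula(c("b", "b2")))
    fit <- fit_rsf(design, rsf_priors(),
                   mcmc_config(chains = 2L, iterations = 800L, burn_in = 300L,
                               seed = 11L))
    tiny_fit_cache$fit <- fit
    tiny_fit_cache$design <- design
    tiny_fit_cache$records <- recs
  }
  tiny_fit_cache
}
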