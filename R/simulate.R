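# Synthetic use-availability studies with known ground truth.
#
# The generator mirrors the field protocol: an individual's home range is
# the MCP of a point scatter; candidate foraging points are drawn uniformly
# inside it and retained by rejection against the selection weight
# exp(beta' x) evaluated on patch-circle covariates (so selection operates
# at the measurement scale); availability points are drawn uniformly with
# the 10 m exclusion buffer around the retained foraging points.
#
# Truth coefficients are interpreted on a fixed reference standardization
# (bare: mean 0.40, sd 0.20; height: mean 15 cm, sd 10 cm), stored in the
# TruthBundle; with the default truth mu_b = 2, mu_b2 = -2 the raw-scale
# bare-ground optimum sits at exactly 0.5.

#' Reference standardization of the synthetic truth
#'
#' The fixed covariate scale on which generating coefficients are
#' interpreted (and on which recovery studies compare fitted to true
#' population means).
#' @return An `rsf_standardization`.
#' @export
truth_standardization <- function() {
  standardization(bare_mean = 0.4, bare_sd = 0.2,
                  height_mean = 15, height_sd = 10)
}

#' Species presets of the study design
#'
#' The four study species with their number of radio-tracked (or observed)
#' individuals, patch-circle radius and whether vegetation height was
#' measured: hoopoe (13 individuals, 1 m), wryneck (8, 1 m), woodlark
#' (7, 5 m), common redstart (5 individuals, 1 m, no height).
#'
#' @param name One of `"hoopoe"`, `"wryneck"`, `"woodlark"`,
#'   `"common_redstart"`, or `NULL` for the full list.
#' @return A preset (list) or named list of presets. Fields:
#'   `n_individuals`, `patch_radius` (m), `include_height`, `n_used`
#'   (default foraging locations per individual; with matched availability
#'   counts a four-species run totals ~2,900 locations), `habitats` and
#'   `habitat_probs` (dominant habitat mix used to label records).
#' @export
species_presets <- function(name = NULL) {
  presets <- list(
    hoopoe = list(name = "hoopoe", n_individuals = 13L, patch_radius = 1,
                  include_height = TRUE, n_used = 45L,
                  habitats = c("fruit_tree_plantation", "grassland", "other"),
                  habitat_probs = c(0.6, 0.25, 0.15)),
    wryneck = list(name = "wryneck", n_individuals = 8L, patch_radius = 1,
                   include_height = TRUE, n_used = 45L,
                   habitats = c("fruit_tree_plantation", "other"),
                   habitat_probs = c(0.75, 0.25)),
    woodlark = list(name = "woodlark", n_individuals = 7L, patch_radius = 5,
                    include_height = TRUE, n_used = 45L,
                    habitats = "vineyard", habitat_probs = 1),
    common_redstart = list(name = "common_redstart", n_individuals = 5L,
                           patch_radius = 1, include_height = FALSE,
                           n_used = 45L,
                           habitats = "orchard", habitat_probs = 1))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop_patchrsf("unknown species preset '%s'", name, class = "bad_config")
  }
  presets[[name]]
}

#' Default generating truth
#'
#' Population-mean coefficients and random-effect sds used by default for
#' synthetic studies, on the [truth_standardization()] scale: a strong
#' concave bare-ground quadratic (raw optimum 0.5), a mild preference for
#' shorter swards, and between-individual sds of 0.3.
#'
#' @param include_height Include the height terms.
#' @return List with named vectors `mu` and `sigma`.
#' @export
default_truth <- function(include_height = TRUE) {
  mu <- c(intercept = 0, b = 2, b2 = -2, h = -0.5, h2 = -0.5)
  if (!include_height) mu <- mu[c("intercept", "b", "b2")]
  list(mu = mu, sigma = stats::setNames(rep(0.3, length(mu)), names(mu)))
}

# Standardized design row(s) for raw patch covariates under a fixed
# standardization, for the given coefficient names. The generator accepts
# one term the fitted models never do: a cubic bare-ground effect "b3",
# there to build deliberately misspecified truths for goodness-of-fit
# power studies.
truth_design_row <- function(bare, height, terms, std) {
  X <- matrix(0, length(bare), length(terms), dimnames = list(NULL, terms))
  if ("intercept" %in% terms) X[, "intercept"] <- 1
  zb <- std_forward(std, "b", bare)
  if ("b" %in% terms) X[, "b"] <- zb
  if ("b2" %in% terms) X[, "b2"] <- zb^2
  if ("b3" %in% terms) X[, "b3"] <- zb^3
  if (any(c("h", "h2") %in% terms)) {
    zh <- std_forward(std, "h", height)
    if ("h" %in% terms) X[, "h"] <- zh
    if ("h2" %in% terms) X[, "h2"] <- zh^2
  }
  X
}

#' Simulate one individual's used and availability points
#'
#' @param landscape A `habitat_landscape`.
#' @param preset A species preset (see [species_presets()]); only
#'   `patch_radius` and `include_height` are used here.
#' @param coefficients Named coefficient vector (subset of
#'   `intercept, b, b2, h, h2`) on the `std` scale.
#' @param n_used Number of foraging locations to generate.
#' @param n_avail Number of availability points (default `n_used`, matching
#'   the study design).
#' @param seed Seed (sub-seeds derived for scatter, selection, availability).
#' @param std Standardization under which `coefficients` are interpreted
#'   (default [truth_standardization()]).
#' @param hr_span Side (m) of the square within which the home-range scatter
#'   is placed (default 200).
#' @param exclusion_radius Availability exclusion buffer (m, default 10).
#' @return List: `used` and `avail` coordinate matrices, `records` (rows for
#'   used then availability points with covariates), `home_range`
#'   (`mcp_polygon`), `acceptance_rate` of the selection-rejection sampler.
#' @export
simulate_individual <- function(landscape, preset, coefficients, n_used,
                                n_avail = n_used, seed = 1L,
                                std = truth_standardization(),
                                hr_span = 200, exclusion_radius = 10) {
  terms <- names(coefficients)
  stopifnot(!is.null(terms),
            all(terms %in% c("intercept", .rsf_terms, "b3")))
  margin <- preset$patch_radius + landscape$grain
  ext <- landscape$extent
  if (hr_span + 2 * margin > min(ext)) {
    stop_patchrsf("home-range span %.0f m does not fit in the landscape",
                  hr_span, class = "bad_config")
  }
  set.seed(derive_seed(seed, 11L))
  ox <- stats::runif(1, margin, ext[1L] - margin - hr_span)
  oy <- stats::runif(1, margin, ext[2L] - margin - hr_span)
  scatter <- cbind(x = stats::runif(12L, ox, ox + hr_span),
                   y = stats::runif(12L, oy, oy + hr_span))
  hr <- minimum_convex_polygon(scatter)

  # selection-weighted rejection sampling of foraging points
  set.seed(derive_seed(seed, 12L))
  used <- matrix(NA_real_, n_used, 2L, dimnames = list(NULL, c("x", "y")))
  used_cov <- matrix(NA_real_, n_used, 2L,
                     dimnames = list(NULL, c("bare", "height")))
  kept <- 0L
  tried <- 0L
  budget <- max(100000L, 2000L * n_used)
  wmax <- NULL
  xr <- range(hr[, 1L]); yr <- range(hr[, 2L])
  while (kept < n_used && tried < budget) {
    m <- 4L * max(n_used, 64L)
    cand <- cbind(stats::runif(m, xr[1L], xr[2L]), stats::runif(m, yr[1L], yr[2L]))
    cand <- cand[points_in_polygon(cand, hr), , drop = FALSE]
    if (nrow(cand) == 0L) { tried <- tried + m; next }
    covs <- sample_patches(landscape, cand, preset$patch_radius)
    Xc <- truth_design_row(covs[, 1L], covs[, 2L], terms, std)
    w <- exp(drop(Xc %*% coefficients))
    if (is.null(wmax)) {
      # pre-scan: bound the selection weight over the home range
      wmax <- max(w) * 1.05
    }
    acc <- stats::runif(nrow(cand)) < w / wmax
    tried <- tried + m
    if (any(acc)) {
      take <- which(acc)[seq_len(min(sum(acc), n_used - kept))]
      used[kept + seq_along(take), ] <- cand[take, , drop = FALSE]
      used_cov[kept + seq_along(take), ] <- covs[take, , drop = FALSE]
      kept <- kept + length(take)
    }
  }
  if (kept < n_used) {
    stop_patchrsf(paste0("selection sampling infeasible: acceptance rate ",
                         "%.2e below budget for coefficients (%s)"),
                  kept / max(tried, 1L),
                  paste(sprintf("%s=%.1f", terms, coefficients), collapse = ", "),
                  class = "simulation_infeasible")
  }
  avail <- sample_availability(hr, used, n_avail,
                               exclusion_radius = exclusion_radius,
                               seed = derive_seed(seed, 13L))
  avail_cov <- sample_patches(landscape, avail, preset$patch_radius)
  records <- data.frame(
    y = rep(c(1, 0), c(n_used, n_avail)),
    x = c(used[, 1L], avail[, 1L]),
    y_coord = c(used[, 2L], avail[, 2L]),
    bare = c(used_cov[, 1L], avail_cov[, 1L]),
    height = c(used_cov[, 2L], avail_cov[, 2L]))
  if (!preset$include_height) records$height <- NA_real_
  list(used = used, avail = avail, records = records, home_range = hr,
       acceptance_rate = kept / tried)
}

#' Simulate a full single-species study with known truth
#'
#' Draws per-individual coefficients from `Normal(mu, sigma^2)` (independent
#' across terms), simulates each individual's used and availability points
#' on a shared landscape, and returns the combined record table together
#' with the ground truth.
#'
#' @param preset A species preset or preset name (see [species_presets()]).
#' @param mu,sigma Named truth vectors on the [truth_standardization()]
#'   scale; default [default_truth()] for the preset.
#' @param seed Master seed (landscape and every individual use derived
#'   sub-seeds).
#' @param n_used Used points per individual (default `preset$n_used`).
#' @param landscape Optional pre-built `habitat_landscape`; by default one
#'   is generated at the package defaults.
#' @param hr_span,exclusion_radius Passed to [simulate_individual()].
#' @return List: `records` (use-availability table with columns
#'   `individual_id, species, y, x, y_coord, bare, height, habitat`) and
#'   `truth` (a `truth_bundle`: `mu`, `sigma`, `B` realized per-individual
#'   coefficients, `std`, `home_ranges`, `seed`, `preset`).
#' @export
simulate_study <- function(preset = "hoopoe", mu = NULL, sigma = NULL,
                           seed = 1L, n_used = NULL, landscape = NULL,
                           hr_span = 200, exclusion_radius = 10) {
  if (is.character(preset)) preset <- species_presets(preset)
  truth <- default_truth(preset$include_height)
  if (is.null(mu)) mu <- truth$mu
  if (is.null(sigma)) sigma <- truth$sigma
  stopifnot(identical(names(mu), names(sigma)))
  if (is.null(n_used)) n_used <- preset$n_used
  if (is.null(landscape)) {
    landscape <- make_landscape(seed = derive_seed(seed, 1000L))
  }
  std <- truth_standardization()
  I <- preset$n_individuals
  set.seed(derive_seed(seed, 2000L))
  B <- matrix(rep(mu, each = I), I, length(mu),
              dimnames = list(NULL, names(mu))) +
    matrix(stats::rnorm(I * length(mu)), I) * rep(sigma, each = I)
  recs <- vector("list", I)
  hrs <- vector("list", I)
  ids <- sprintf("%s_%02d", preset$name, seq_len(I))
  for (i in seq_len(I)) {
    sim <- simulate_individual(landscape, preset, B[i, ], n_used,
                               seed = derive_seed(seed, 3000L + i),
                               std = std, hr_span = hr_span,
                               exclusion_radius = exclusion_radius)
    r <- sim$records
    r$individual_id <- ids[i]
    recs[[i]] <- r
    hrs[[i]] <- sim$home_range
  }
  records <- do.call(rbind, recs)
  records$species <- preset$name
  set.seed(derive_seed(seed, 4000L))
  records$habitat <- sample(preset$habitats, nrow(records), replace = TRUE,
                            prob = preset$habitat_probs)
  records <- records[, c("individual_id", "species", "y", "x", "y_coord",
                         "bare", "height", "habitat")]
  rownames(records) <- NULL
  names(hrs) <- ids
  truth_bundle <- structure(list(mu = mu, sigma = sigma, B = B, std = std,
                                 home_ranges = hrs, seed = seed,
                                 preset = preset$name,
                                 landscape_seed = landscape$seed),
                            class = "truth_bundle")
  list(records = records, truth = truth_bundle)
}

#' Simulate the four-species study
#'
#' One [simulate_study()] per species preset with the default truth, giving
#' the study's structure: 33 individuals split 13/8/7/5 across hoopoe,
#' wryneck, woodlark and common redstart, used and availability counts
#' matched per individual (~2,900 locations in total at defaults).
#'
#' @param seed Master seed.
#' @param n_used Used points per individual (default: preset values).
#' @return List of per-species [simulate_study()] results, named by species.
#' @export
simulate_all_species <- function(seed = 1L, n_used = NULL) {
  presets <- species_presets()
  out <- lapply(seq_along(presets), function(k) {
    simulate_study(presets[[k]], seed = derive_seed(seed, 500L + k),
                   n_used = n_used)
  })
  stats::setNames(out, names(presets))
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("Truth bundle (%s): %d individuals, terms %s\n", x$preset,
              nrow(x$B), paste(names(x$mu), collapse = ", ")))
  cat("  mu:", paste(sprintf("%.2f", x$mu), collapse = ", "),
      " sigma:", paste(sprintf("%.2f", x$sigma), collapse = ", "), "\n")
  invisible(x)
}
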