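# Selection-probability response curves and the quadratic optimum.
#
# Curves are reported on the raw covariate scale (proportion bare ground,
# vegetation height in cm). Under roughly balanced used:available counts a
# selection probability of 0.5 is neutral: below 0.5 avoidance, above 0.5
# preference.

# Design matrix rows for a covariate grid, other covariate held fixed.
# A covariate absent from the formula has no effect, so the curve against
# it is flat (the intercept-only curve of the balanced design is the 0.5
# neutrality line).
grid_design <- function(fit, covariate, grid, others_at = NULL) {
  covariate <- match.arg(covariate, c("b", "h"))
  other <- setdiff(c("b", "h"), covariate)
  cols <- formula_columns(fit$formula)
  Xg <- matrix(0, length(grid), length(cols), dimnames = list(NULL, cols))
  Xg[, "intercept"] <- 1
  if (covariate %in% cols) {
    z <- std_forward(fit$std, covariate, grid)
    Xg[, covariate] <- z
    sq <- paste0(covariate, "2")
    if (sq %in% cols) Xg[, sq] <- z^2
  }
  if (other %in% cols) {
    at <- if (!is.null(others_at) && !is.null(others_at[[other]])) {
      others_at[[other]]
    } else {
      fit$std$mean[[other]]  # raw-scale mean: standardized 0
    }
    zo <- std_forward(fit$std, other, at)
    Xg[, other] <- zo
    osq <- paste0(other, "2")
    if (osq %in% cols) Xg[, osq] <- zo^2
  }
  Xg
}

response_curve_df <- function(level, covariate, grid, probs) {
  # probs: draws x grid matrix
  data.frame(level = level, covariate = covariate, grid = grid,
             mean = colMeans(probs),
             lo80 = apply(probs, 2L, stats::quantile, 0.1),
             hi80 = apply(probs, 2L, stats::quantile, 0.9),
             row.names = NULL)
}

#' Individual selection-probability response curves
#'
#' The functional response of each individual: posterior selection
#' probability against one covariate, the other held fixed, using that
#' individual's coefficient draws.
#'
#' @param fit An `rsf_fit`.
#' @param covariate `"b"` (bare ground) or `"h"` (height).
#' @param grid Raw-scale covariate values.
#' @param others_at Optional named list of raw-scale values at which to hold
#'   the non-varied covariate (default: its standardization mean).
#' @return An object of class `response_curves`: a data frame with columns
#'   `level` (individual id), `covariate`, `grid`, `mean`, `lo80`, `hi80`
#'   (pointwise posterior mean and equal-tailed 80% credible bounds).
#' @export
individual_response <- function(fit, covariate, grid, others_at = NULL) {
  Xg <- grid_design(fit, covariate, grid, others_at)
  out <- lapply(seq_along(fit$individuals), function(i) {
    Bi <- matrix(fit$B[, i, ], nrow = dim(fit$B)[1L])  # draws x terms
    probs <- stats::plogis(Bi %*% t(Xg))
    response_curve_df(fit$individuals[i], covariate, grid, probs)
  })
  structure(do.call(rbind, out), class = c("response_curves", "data.frame"))
}

#' Marginal (population-level) response curve
#'
#' Averages the selection probability over the population distribution of
#' individuals: for each posterior draw of `(mu, sigma)`, simulates
#' `n_new_individuals` coefficient vectors from `Normal(mu, sigma^2)` and
#' averages their inverse-logit responses over the grid; the reported curve
#' is the pointwise posterior mean and 80% interval of these per-draw
#' marginal curves.
#'
#' @inheritParams individual_response
#' @param n_new_individuals Hypothetical new individuals simulated per draw
#'   (default 500; at least 100).
#' @param seed Seed for the simulated individuals.
#' @param use_draws Optional number of posterior draws to use (evenly
#'   spaced); default all.
#' @return A `response_curves` data frame with `level = "marginal"`.
#' @export
marginal_response <- function(fit, covariate, grid, others_at = NULL,
                              n_new_individuals = 500L, seed = 1L,
                              use_draws = NULL) {
  if (n_new_individuals < 100L) {
    stop_patchrsf("n_new_individuals must be at least 100", class = "bad_config")
  }
  Xg <- grid_design(fit, covariate, grid, others_at)
  n_draw <- nrow(fit$mu)
  dd <- if (is.null(use_draws) || use_draws >= n_draw) seq_len(n_draw) else
    unique(round(seq(1L, n_draw, length.out = use_draws)))
  K <- ncol(fit$mu)
  set.seed(as.integer(seed %% 2147483647))
  curves <- matrix(NA_real_, length(dd), length(grid))
  for (j in seq_along(dd)) {
    d <- dd[j]
    Z <- matrix(stats::rnorm(n_new_individuals * K), n_new_individuals, K)
    Bnew <- sweep(sweep(Z, 2L, fit$sigma[d, ], `*`), 2L, fit$mu[d, ], `+`)
    curves[j, ] <- colMeans(stats::plogis(Bnew %*% t(Xg)))
  }
  structure(response_curve_df("marginal", covariate, grid, curves),
            class = c("response_curves", "data.frame"))
}

#' Posterior summary of the quadratic covariate optimum
#'
#' For a covariate with linear and squared terms, each posterior draw of the
#' population coefficients implies a vertex of the quadratic selection
#' surface; when the curvature is negative the vertex is an interior optimum
#' `x* = -beta_lin / (2 beta_sq)` on the standardized scale, back-transformed
#' to the raw scale. Draws with non-negative curvature have no interior
#' optimum and are flagged, not summarised.
#'
#' @param fit An `rsf_fit` whose formula contains the covariate's linear and
#'   squared terms.
#' @param covariate `"b"` or `"h"`.
#' @return An object of class `optimum_summary`: `mean`, `lo80`, `hi80`
#'   (raw scale, over draws with an interior optimum; `NA` and
#'   `defined = FALSE` when no draw has one), `frac_interior`, and the raw
#'   per-draw optima `draws` (NA where undefined).
#' @export
optimum_covariate <- function(fit, covariate) {
  covariate <- match.arg(covariate, c("b", "h"))
  sq <- paste0(covariate, "2")
  if (!formula_has(fit$formula, covariate) || !formula_has(fit$formula, sq)) {
    stop_patchrsf("formula (%s) lacks %s and/or %s: no quadratic optimum",
                  format(fit$formula), covariate, sq, class = "formula_mismatch")
  }
  b_lin <- fit$mu[, covariate]
  b_sq <- fit$mu[, sq]
  interior <- b_sq < 0
  z_star <- ifelse(interior, -b_lin / (2 * b_sq), NA_real_)
  x_star <- std_backward(fit$std, covariate, z_star)
  frac <- mean(interior)
  ok <- x_star[interior]
  structure(list(
    covariate = covariate,
    mean = if (frac > 0) mean(ok) else NA_real_,
    lo80 = if (frac > 0) unname(stats::quantile(ok, 0.1)) else NA_real_,
    hi80 = if (frac > 0) unname(stats::quantile(ok, 0.9)) else NA_real_,
    frac_interior = frac,
    defined = frac > 0,
    draws = x_star), class = "optimum_summary")
}

#' @export
print.optimum_summary <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("No interior optimum for %s (curvature >= 0 in all draws)\n",
                x$covariate))
  } else {
    cat(sprintf("Optimum %s = %.3f [80%% CI %.3f, %.3f], interior in %.0f%% of draws\n",
                x$covariate, x$mean, x$lo80, x$hi80, 100 * x$frac_interior))
  }
  invisible(x)
}

#' Plot response curves
#'
#' Draws the individual and/or marginal selection-probability curves with a
#' horizontal neutrality reference at 0.5 (below: avoidance; above:
#' preference). Requires ggplot2.
#'
#' @param curves A `response_curves` data frame (individual and marginal
#'   curves may be row-bound together).
#' @param ribbon Show the 80% credible band for the marginal curve
#'   (default TRUE).
#' @return A ggplot object.
#' @export
plot_response_curves <- function(curves, ribbon = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_patchrsf("ggplot2 is required for plotting", class = "missing_suggest")
  }
  marg <- curves[curves$level == "marginal", , drop = FALSE]
  ind <- curves[curves$level != "marginal", , drop = FALSE]
  gg <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$grid, y = .data$mean))
  if (nrow(ind) > 0L) {
    gg <- gg + ggplot2::geom_line(data = ind,
                                  ggplot2::aes(group = .data$level),
                                  colour = "grey60", linewidth = 0.3)
  }
  if (nrow(marg) > 0L) {
    if (ribbon) {
      gg <- gg + ggplot2::geom_ribbon(
        data = marg, ggplot2::aes(ymin = .data$lo80, ymax = .data$hi80),
        alpha = 0.25, fill = "steelblue")
    }
    gg <- gg + ggplot2::geom_line(data = marg, colour = "steelblue",
                                  linewidth = 0.9)
  }
  xlab <- if (curves$covariate[1L] == "b") "Proportion bare ground" else
    "Vegetation height (cm)"
  gg + ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = "Selection probability") +
    ggplot2::theme_minimal()
}
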