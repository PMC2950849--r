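# Deviance information criterion with conditional focus: the deviance is
# conditional on the individual-level coefficients B, and the effective
# number of parameters pD is the posterior-mean deviance minus the deviance
# at the posterior mean of B. This focus is what makes an intercept-only
# hierarchical model cost roughly two effective parameters (grand intercept
# plus the shrunken individual intercepts).

#' Deviance information criterion of a fitted model
#'
#' @param fit An `rsf_fit` with per-draw conditional deviance.
#' @param design The `rsf_design` the model was fitted to.
#' @return An object of class `dic_summary`: `d_bar` (posterior mean
#'   deviance), `p_d` (effective number of parameters, plug-in at the
#'   posterior mean of `B`), and `dic = d_bar + p_d` (exact identity).
#' @details Negative `p_d` is legal for DIC (it signals a poorly behaved
#'   posterior, e.g. strong non-normality); it raises a warning but never an
#'   error.
#' @export
compute_dic <- function(fit, design) {
  stopifnot(inherits(fit, "rsf_fit"), inherits(design, "rsf_design"))
  d_bar <- mean(fit$deviance)
  B_hat <- apply(fit$B, c(2L, 3L), mean)
  d_hat <- deviance_rsf(design, B_hat)
  p_d <- d_bar - d_hat
  if (p_d < 0) {
    warning(sprintf("negative pD (%.2f): posterior of B is poorly summarised by its mean",
                    p_d), call. = FALSE)
  }
  structure(list(d_bar = d_bar, p_d = p_d, dic = d_bar + p_d),
            class = "dic_summary")
}

#' @export
print.dic_summary <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (mean deviance %.2f, pD %.2f)\n",
              x$dic, x$d_bar, x$p_d))
  invisible(x)
}

# Individuals x terms coefficient matrix for one posterior draw.
draw_B <- function(fit, d) {
  matrix(fit$B[d, , ], nrow = dim(fit$B)[2L], ncol = dim(fit$B)[3L],
         dimnames = dimnames(fit$B)[2:3])
}

#' Chi-square discrepancy posterior predictive check
#'
#' For each posterior draw, computes the chi-square discrepancy
#' `T = sum (y - p)^2 / (p (1 - p))` between the observed responses and the
#' draw's fitted selection probabilities, and the same discrepancy for a
#' replicated data set `y* ~ Bernoulli(p)`. The Bayesian P-value is the
#' fraction of draws whose replicated discrepancy is at least the observed
#' one; values near 0.5 indicate adequate fit, values near 0 or 1 misfit.
#'
#' @param fit An `rsf_fit`.
#' @param design The `rsf_design` the model was fitted to (same records).
#' @param seed Seed for the replicate draws.
#' @return An object of class `gof_report`: `t_obs`, `t_rep` (one value per
#'   draw), `bayes_p`, and `n_clamped` (count of record-level probabilities
#'   clamped to `[1e-12, 1 - 1e-12]` — reported, never silent).
#' @export
bayesian_p_value <- function(fit, design, seed = 1L) {
  stopifnot(inherits(fit, "rsf_fit"), inherits(design, "rsf_design"))
  n_draw <- nrow(fit$mu)
  y <- design$y
  X <- design$X
  gi <- design$indiv_index
  set.seed(as.integer(seed %% 2147483647))
  t_obs <- numeric(n_draw)
  t_rep <- numeric(n_draw)
  n_clamped <- 0L
  for (d in seq_len(n_draw)) {
    Bd <- draw_B(fit, d)
    eta <- rowSums(X * Bd[gi, , drop = FALSE])
    p <- stats::plogis(eta)
    n_clamped <- n_clamped + sum(p < 1e-12 | p > 1 - 1e-12)
    p <- clamp_prob(p)
    v <- p * (1 - p)
    t_obs[d] <- sum((y - p)^2 / v)
    yrep <- stats::rbinom(length(p), 1L, p)
    t_rep[d] <- sum((yrep - p)^2 / v)
  }
  if (n_clamped > 0L) {
    message(sprintf("bayesian_p_value: %d record-level probabilities clamped to [1e-12, 1-1e-12]",
                    n_clamped))
  }
  structure(list(t_obs = t_obs, t_rep = t_rep,
                 bayes_p = mean(t_rep >= t_obs), n_clamped = n_clamped),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Posterior predictive check: Bayesian P-value = %.3f (%d draws)\n",
              x$bayes_p, length(x$t_obs)))
  invisible(x)
}
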