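# Building the regression design from use-availability records.
#
# Records are one row per location: y = 1 for an observed foraging location,
# y = 0 for a random (availability) point, with the patch covariates measured
# the same way for both classes.

#' Validate a table of use-availability records
#'
#' @param records Data frame with columns `individual_id`, `y` (0/1),
#'   `bare` (proportion in `[0, 1]`) and `height` (cm, `NA` allowed when the
#'   formula omits height); optional `species`, `habitat`.
#' @return The records, invisibly, after validation.
#' @export
validate_use_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("individual_id", "y", "bare", "height")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop_patchrsf("records missing columns: %s", paste(miss, collapse = ", "),
                  class = "bad_records")
  }
  if (!all(records$y %in% c(0, 1))) {
    stop_patchrsf("y must be 0 (random point) or 1 (foraging location)",
                  class = "bad_records")
  }
  if (any(!is.finite(records$bare)) || any(records$bare < 0 | records$bare > 1)) {
    stop_patchrsf("bare must be a proportion in [0, 1]", class = "bad_records")
  }
  h <- records$height[!is.na(records$height)]
  if (any(h < 0)) {
    stop_patchrsf("height must be non-negative (cm)", class = "bad_records")
  }
  invisible(records)
}

#' Standardization used for the covariates
#'
#' Centring/scaling applied to the raw covariates before sampling. Fits run
#' on the standardized scale; all reporting is back-transformed to the raw
#' proportion / cm scale.
#'
#' @param bare_mean,bare_sd Moments for the bare-ground proportion.
#' @param height_mean,height_sd Moments for vegetation height (cm).
#' @return An object of class `rsf_standardization`.
#' @export
standardization <- function(bare_mean, bare_sd, height_mean = NA_real_,
                            height_sd = NA_real_) {
  if (bare_sd <= 0 || (!is.na(height_sd) && height_sd <= 0)) {
    stop_patchrsf("standardization sds must be positive", class = "bad_standardization")
  }
  structure(list(mean = c(b = bare_mean, h = height_mean),
                 sd = c(b = bare_sd, h = height_sd)),
            class = "rsf_standardization")
}

std_forward <- function(std, covariate, raw) {
  (raw - std$mean[[covariate]]) / std$sd[[covariate]]
}

std_backward <- function(std, covariate, z) {
  std$mean[[covariate]] + std$sd[[covariate]] * z
}

#' Build the regression design for a formula
#'
#' Standardizes the covariates, forms the design matrix in the fixed column
#' order (intercept, b, b2, h, h2) restricted to the formula, and indexes
#' records by individual. Squared terms are squares of the standardized
#' linear term.
#'
#' @param records Use-availability records (see [validate_use_records()]).
#' @param formula An [rsf_formula()].
#' @param std Optional `rsf_standardization` to use instead of the empirical
#'   covariate moments (e.g. a synthetic-truth scale in recovery studies).
#' @param imbalance_warn Used:available ratio beyond which a per-individual
#'   imbalance warning is raised (default 1.25); the 0.5-neutrality reading
#'   of selection probabilities presumes roughly balanced counts.
#' @return A list of class `rsf_design`: `y`, `indiv` (factor), `X`
#'   (n x K design matrix), `std`, `formula`, `individuals`.
#' @export
build_design <- function(records, formula, std = NULL, imbalance_warn = 1.25) {
  validate_use_records(records)
  stopifnot(inherits(formula, "rsf_formula"))
  ids <- factor(records$individual_id)
  if (nlevels(ids) < 2L) {
    stop_patchrsf("need at least 2 individuals, got %d", nlevels(ids),
                  class = "degenerate_design")
  }
  tab <- table(ids, factor(records$y, levels = c(0, 1)))
  one_class <- rownames(tab)[tab[, 1L] == 0L | tab[, 2L] == 0L]
  if (length(one_class) > 0L) {
    stop_patchrsf(paste0("degenerate individual(s) with only one response ",
                         "class: %s"), paste(one_class, collapse = ", "),
                  class = "degenerate_design")
  }
  ratio <- pmax(tab[, 1L], tab[, 2L]) / pmin(tab[, 1L], tab[, 2L])
  if (any(ratio > imbalance_warn)) {
    warning(sprintf(paste0("used:available imbalance above %.2f for: %s; ",
                           "selection probabilities lose their 0.5-neutral ",
                           "reading"), imbalance_warn,
                    paste(rownames(tab)[ratio > imbalance_warn], collapse = ", ")),
            call. = FALSE)
  }
  needs_h <- formula_has(formula, "h")
  if (needs_h && anyNA(records$height)) {
    stop_patchrsf("formula includes height but records have missing heights",
                  class = "bad_records")
  }
  if (is.null(std)) {
    h_ok <- !anyNA(records$height) && stats::sd(records$height) > 0
    std <- standardization(
      bare_mean = mean(records$bare), bare_sd = stats::sd(records$bare),
      height_mean = if (h_ok) mean(records$height) else NA_real_,
      height_sd = if (h_ok) stats::sd(records$height) else NA_real_)
  }
  n <- nrow(records)
  cols <- formula_columns(formula)
  X <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  X[, "intercept"] <- 1
  zb <- std_forward(std, "b", records$bare)
  if ("b" %in% cols) X[, "b"] <- zb
  if ("b2" %in% cols) X[, "b2"] <- zb^2
  if (needs_h) {
    zh <- std_forward(std, "h", records$height)
    X[, "h"] <- zh
    if ("h2" %in% cols) X[, "h2"] <- zh^2
  }
  structure(list(y = as.numeric(records$y), indiv = ids,
                 indiv_index = as.integer(ids), X = X, std = std,
                 formula = formula, individuals = levels(ids)),
            class = "rsf_design")
}

#' Conditional log-likelihood of the use-availability logistic model
#'
#' Bernoulli-logit log-likelihood conditional on the individual-level
#' coefficients: records are independent given each record's
#' individual-specific linear predictor.
#'
#' @param design An `rsf_design`.
#' @param B Individuals x terms coefficient matrix (rows in the order of
#'   `design$individuals`, columns in design-column order).
#' @return The scalar log-likelihood. The conditional deviance is -2 times
#'   this value.
#' @export
log_likelihood <- function(design, B) {
  B <- as.matrix(B)
  if (nrow(B) != nlevels(design$indiv) || ncol(B) != ncol(design$X)) {
    stop_patchrsf("coefficient matrix must be %d individuals x %d terms",
                  nlevels(design$indiv), ncol(design$X), class = "bad_coefficients")
  }
  eta <- rowSums(design$X * B[design$indiv_index, , drop = FALSE])
  if (any(!is.finite(eta))) {
    stop_patchrsf("non-finite linear predictor at record %s",
                  which(!is.finite(eta))[1L], class = "numeric_error")
  }
  # y*eta - log(1 + exp(eta)), computed stably for large |eta|
  sum(design$y * eta - log1pexp(eta))
}

#' Conditional deviance
#' @inheritParams log_likelihood
#' @return `-2 * log_likelihood(design, B)`.
#' @export
deviance_rsf <- function(design, B) -2 * log_likelihood(design, B)

#' @export
print.rsf_design <- function(x, ...) {
  cat(sprintf("rsf design: %d records, %d individuals, formula %s\n",
              length(x$y), nlevels(x$indiv), format(x$formula)))
  invisible(x)
}
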