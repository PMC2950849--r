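# Candidate set and DIC ranking. The candidate set is fixed a priori (it is
# never data-driven): all marginality-respecting combinations of the bare
# ground and height terms, plus the intercept-only model.

#' The fixed candidate set of model formulas
#'
#' @param include_height Whether the vegetation-height terms are available
#'   (`FALSE` for data where height was not measured, as for the common
#'   redstart): the set then reduces to the three bare-ground rows.
#' @return A list of [rsf_formula()] objects, in the canonical row order:
#'   `b+b2+h+h2, b+h+h2, h+h2, b+b2+h, b+b2, b+h, b, h, intercept` (or
#'   `b+b2, b, intercept` without height).
#' @export
candidate_formulas <- function(include_height = TRUE) {
  specs <- if (include_height) {
    list(c("b", "b2", "h", "h2"), c("b", "h", "h2"), c("h", "h2"),
         c("b", "b2", "h"), c("b", "b2"), c("b", "h"), "b", "h", character(0))
  } else {
    list(c("b", "b2"), "b", character(0))
  }
  lapply(specs, rsf_formula)
}

#' Fit and rank the candidate models by DIC
#'
#' Fits every candidate formula to the same records (per-model seed derived
#' deterministically from the base seed, so one integer reproduces the whole
#' table) and ranks by DIC ascending.
#'
#' @param records Use-availability records.
#' @param priors An [rsf_priors()].
#' @param config An [mcmc_config()]; `config$seed` is the base seed.
#' @param include_height `NULL` (default) to detect from the data (heights
#'   all present), or logical.
#' @param std Optional fixed standardization passed to [build_design()].
#' @param keep_fits `"best"` (default), `"all"` or `"none"`: which fitted
#'   models to retain in the result.
#' @return An object of class `rsf_selection`: `table` (data frame with
#'   columns `model`, `deviance`, `pD`, `DIC`, `dDIC`, sorted by DIC; the
#'   best row has `dDIC = 0`), `fits` (named list, per `keep_fits`),
#'   `best` (label of the best model), and `ties` (labels within 1e-8 of the
#'   best DIC, reported but never resolved).
#' @export
run_selection <- function(records, priors = rsf_priors(),
                          config = mcmc_config(), include_height = NULL,
                          std = NULL, keep_fits = c("best", "all", "none")) {
  keep_fits <- match.arg(keep_fits)
  validate_use_records(records)
  if (is.null(include_height)) include_height <- !anyNA(records$height)
  cands <- candidate_formulas(include_height)
  labels <- vapply(cands, format, character(1L))
  rows <- vector("list", length(cands))
  fits <- stats::setNames(vector("list", length(cands)), labels)
  for (k in seq_along(cands)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + k)
    design <- tryCatch(
      build_design(records, cands[[k]], std = std),
      error = function(e) {
        stop_patchrsf("candidate '%s': %s", labels[k], conditionMessage(e),
                      class = "selection_error")
      })
    fit <- fit_rsf(design, priors, cfg)
    dic <- withCallingHandlers(compute_dic(fit, design),
                               warning = function(w) invokeRestart("muffleWarning"))
    rows[[k]] <- data.frame(model = labels[k], deviance = dic$d_bar,
                            pD = dic$p_d, DIC = dic$dic)
    if (keep_fits == "all") fits[[k]] <- fit
    if (keep_fits == "best") fits[[k]] <- fit  # pruned below
  }
  tab <- do.call(rbind, rows)
  tab$dDIC <- tab$DIC - min(tab$DIC)
  tab <- tab[order(tab$DIC), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  best <- tab$model[1L]
  if (keep_fits == "best") fits <- fits[best]
  if (keep_fits == "none") fits <- list()
  structure(list(table = tab, fits = fits, best = best,
                 ties = tab$model[tab$dDIC < 1e-8],
                 include_height = include_height, config = config),
            class = "rsf_selection")
}

#' @export
print.rsf_selection <- function(x, ...) {
  cat("Model selection by DIC", if (!x$include_height) "(height-free set)",
      "\n")
  tab <- x$table
  tab$deviance <- sprintf("%.2f", tab$deviance)
  tab$pD <- sprintf("%.2f", tab$pD)
  tab$DIC <- sprintf("%.2f", tab$DIC)
  tab$dDIC <- sprintf("%.2f", tab$dDIC)
  print(tab, row.names = FALSE)
  if (length(x$ties) > 1L) {
    cat("tied best models:", paste(x$ties, collapse = ", "), "\n")
  }
  invisible(x)
}
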