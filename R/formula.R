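# Candidate model formulas over the two patch covariates:
# b  = proportion bare ground, b2 = its square,
# h  = vegetation height (cm),  h2 = its square.
# Every formula includes an intercept; squared terms obey marginality.

.rsf_terms <- c("b", "b2", "h", "h2")

#' Construct a model formula over the patch covariates
#'
#' @param terms Character vector, a subset of `c("b", "b2", "h", "h2")`. The
#'   intercept is always included. Marginality is enforced: `b2` requires
#'   `b`, `h2` requires `h`.
#' @return An object of class `rsf_formula`.
#' @examples
#' rsf_formula(c("b", "b2"))
#' @export
rsf_formula <- function(terms = character(0)) {
  terms <- unique(as.character(terms))
  bad <- setdiff(terms, .rsf_terms)
  if (length(bad) > 0L) {
    stop_patchrsf("unknown formula terms: %s", paste(bad, collapse = ", "),
                  class = "bad_formula")
  }
  if ("b2" %in% terms && !("b" %in% terms)) {
    stop_patchrsf("marginality violated: b2 requires b", class = "bad_formula")
  }
  if ("h2" %in% terms && !("h" %in% terms)) {
    stop_patchrsf("marginality violated: h2 requires h", class = "bad_formula")
  }
  terms <- .rsf_terms[.rsf_terms %in% terms]
  structure(list(terms = terms), class = "rsf_formula")
}

#' @export
format.rsf_formula <- function(x, ...) {
  if (length(x$terms) == 0L) "intercept" else paste(x$terms, collapse = "+")
}

#' @export
print.rsf_formula <- function(x, ...) {
  cat("rsf formula:", format(x), "\n")
  invisible(x)
}

formula_has <- function(formula, term) term %in% formula$terms

# Names of the design-matrix columns for a formula (fixed order).
formula_columns <- function(formula) c("intercept", formula$terms)
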