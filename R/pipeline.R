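# Pipeline entry points tying the stages together: simulate, select (fit +
# rank + GoF + curves), curves-from-stored-fit. Each command resolves its
# configuration (flags > config file > defaults), logs the resolved config
# including derived seeds to a run manifest, and writes plain-text outputs;
# re-running from the manifest reproduces outputs bit-for-bit. A thin
# command-line wrapper over these functions ships in
# `system.file("scripts", "rsf.R", package = "patchrsf")`.

default_run_config <- function() {
  list(species = "hoopoe", formula = "select", seed = 1L,
       out_dir = ".", records = NULL, filter_habitat = NULL,
       grid_points = 21L,
       priors = list(mu_mean = 0, mu_sd = 10, sigma_upper = 10),
       mcmc = list(chains = 3L, iterations = 6000L, burn_in = 1000L,
                   thin = 1L, adapt_window = 50L),
       n_new_individuals = 500L)
}

#' Resolve a run configuration
#'
#' Precedence: explicit overrides > YAML config file > package defaults.
#'
#' @param config_file Optional YAML file.
#' @param overrides Named list of settings taking highest precedence.
#' @return Resolved configuration list.
#' @export
resolve_config <- function(config_file = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  utils::modifyList(cfg, overrides)
}

config_objects <- function(cfg) {
  list(priors = do.call(rsf_priors, cfg$priors),
       mcmc = do.call(mcmc_config, c(cfg$mcmc, list(seed = cfg$seed))))
}

write_manifest <- function(cfg, out_dir, command, derived = list()) {
  manifest <- c(list(command = command, package_version =
                       as.character(utils::packageVersion("patchrsf"))),
                cfg, list(derived_seeds = derived))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
}

#' Simulate a synthetic study and write its files
#'
#' Writes the use-availability records CSV, the truth bundle JSON, the
#' landscape rasters (bare and height ASCII grids), one GeoJSON home range
#' per individual, and the run manifest; prints per-individual counts.
#'
#' @param config_file Optional YAML config.
#' @param ... Overrides (e.g. `species`, `seed`, `out_dir`, `n_used`).
#' @return The output directory, invisibly.
#' @export
run_simulate_cmd <- function(config_file = NULL, ...) {
  cfg <- resolve_config(config_file, list(...))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) {
    stop_patchrsf("cannot create output directory '%s'", out, class = "io_error")
  }
  landscape_seed <- derive_seed(cfg$seed, 1000L)
  landscape <- make_landscape(seed = landscape_seed)
  sim <- simulate_study(cfg$species, seed = cfg$seed, n_used = cfg$n_used,
                        landscape = landscape)
  write_use_records(sim$records, file.path(out, "records.csv"))
  write_truth_json(sim$truth, file.path(out, "truth.json"))
  write_ascii_grid(landscape, file.path(out, "landscape_bare.asc"), "bare")
  write_ascii_grid(landscape, file.path(out, "landscape_height.asc"), "height")
  for (id in names(sim$truth$home_ranges)) {
    write_geojson_polygon(sim$truth$home_ranges[[id]],
                          file.path(out, paste0("home_range_", id, ".geojson")),
                          id = id)
  }
  write_manifest(cfg, out, "simulate",
                 derived = list(landscape = landscape_seed))
  counts <- table(sim$records$individual_id, sim$records$y)
  cat("Simulated", cfg$species, "study:\n")
  for (id in rownames(counts)) {
    cat(sprintf("  %s: %d used, %d available\n", id, counts[id, "1"],
                counts[id, "0"]))
  }
  invisible(out)
}

apply_habitat_filter <- function(records, filter_habitat) {
  if (is.null(filter_habitat)) return(records)
  if (!filter_habitat %in% records$habitat) {
    stop_patchrsf("habitat filter value '%s' not present in the data",
                  filter_habitat, class = "bad_config")
  }
  records[records$habitat == filter_habitat, , drop = FALSE]
}

#' Run model selection (or a single-formula fit) and write its files
#'
#' Fits the candidate set (or one formula), writes the DIC ranking CSV in
#' the published table layout, the best model's posterior draws, DIC and
#' goodness-of-fit JSON, the individual and marginal response-curve CSVs,
#' and the run manifest. An optional habitat-category filter restricts the
#' records before fitting (the per-habitat refit procedure).
#'
#' @param config_file Optional YAML config.
#' @param ... Overrides; `records` (CSV path) is required, `formula` may be
#'   `"select"` (default) or a formula label like `"b+b2"`.
#' @return List with `selection` (`rsf_selection` or `NULL`), `fit`, `gof`,
#'   `dic`, invisibly.
#' @export
run_select_cmd <- function(config_file = NULL, ...) {
  cfg <- resolve_config(config_file, list(...))
  if (is.null(cfg$records) || !file.exists(cfg$records)) {
    stop_patchrsf("records CSV not found: '%s'", cfg$records %||% "(unset)",
                  class = "io_error")
  }
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  records <- apply_habitat_filter(read_use_records(cfg$records),
                                  cfg$filter_habitat)
  obj <- config_objects(cfg)
  selection <- NULL
  if (identical(cfg$formula, "select")) {
    selection <- run_selection(records, obj$priors, obj$mcmc,
                               keep_fits = "best")
    fit <- selection$fits[[selection$best]]
    write_selection_table(selection, file.path(out, "selection_table.csv"))
  } else {
    terms <- setdiff(strsplit(cfg$formula, "+", fixed = TRUE)[[1L]], "intercept")
    fit <- fit_rsf(build_design(records, rsf_formula(terms)), obj$priors,
                   obj$mcmc)
  }
  design <- build_design(records, fit$formula)
  dic <- compute_dic(fit, design)
  gof <- bayesian_p_value(fit, design, seed = derive_seed(cfg$seed, 77L))
  write_draws(fit, file.path(out, "posterior_draws.csv"))
  write_dic_json(dic, file.path(out, "dic.json"))
  write_gof_json(gof, file.path(out, "gof.json"))
  curves <- export_curves(fit, cfg, records, out)
  write_manifest(cfg, out, "select",
                 derived = list(gof = derive_seed(cfg$seed, 77L),
                                marginal = derive_seed(cfg$seed, 88L)))
  invisible(list(selection = selection, fit = fit, gof = gof, dic = dic,
                 curves = curves))
}

export_curves <- function(fit, cfg, records, out) {
  curves <- list()
  for (cov in c("b", "h")) {
    if (!formula_has(fit$formula, cov)) next
    raw <- if (cov == "b") records$bare else records$height
    grid <- seq(min(raw), max(raw), length.out = cfg$grid_points)
    ind <- individual_response(fit, cov, grid)
    marg <- marginal_response(fit, cov, grid,
                              n_new_individuals = cfg$n_new_individuals,
                              seed = derive_seed(cfg$seed, 88L))
    both <- rbind(ind, marg)
    write_response_curves(both,
                          file.path(out, sprintf("response_%s.csv", cov)))
    curves[[cov]] <- both
  }
  curves
}

#' Export response curves (and optionally a figure) from a stored fit
#'
#' @param fit An `rsf_fit` (e.g. from [run_select_cmd()]'s return value or a
#'   freshly refitted model); a missing fit is an error.
#' @param records The records the fit was built from (for the grid range).
#' @param config_file,... Config and overrides as elsewhere.
#' @param plot_file Optional path for a PDF figure of the curves with the
#'   0.5 neutrality reference (requires ggplot2).
#' @return The list of exported `response_curves`, invisibly.
#' @export
run_curves_cmd <- function(fit, records, config_file = NULL, plot_file = NULL,
                           ...) {
  if (missing(fit) || !inherits(fit, "rsf_fit")) {
    stop_patchrsf("a stored rsf_fit is required", class = "not_found")
  }
  cfg <- resolve_config(config_file, list(...))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  curves <- export_curves(fit, cfg, records, out)
  write_manifest(cfg, out, "curves",
                 derived = list(marginal = derive_seed(cfg$seed, 88L)))
  if (!is.null(plot_file)) {
    gg <- plot_response_curves(curves[[1L]])
    grDevices::pdf(plot_file, width = 6, height = 4)
    print(gg)
    grDevices::dev.off()
  }
  invisible(curves)
}
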