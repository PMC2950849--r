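# File interfaces: use-availability records and telemetry fixes as CSV,
# home ranges as GeoJSON (RFC 7946), landscapes as ESRI ASCII grid rasters,
# summaries as JSON. Plain text throughout, UTF-8, '.' decimal separator.

#' Read use-availability records from CSV
#'
#' Expected columns: `individual_id, species, y, bare, height, habitat`
#' (header required; `height` may be empty when not measured, as for the
#' common redstart).
#'
#' @param path CSV file path.
#' @return A validated records data frame.
#' @export
read_use_records <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_use_records(records)
  records
}

#' Write use-availability records to CSV
#'
#' @param records Records data frame.
#' @param path Output path.
#' @export
write_use_records <- function(records, path) {
  validate_use_records(records)
  cols <- intersect(c("individual_id", "species", "y", "bare", "height",
                      "habitat"), names(records))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
}

#' Read a telemetry track from CSV
#'
#' Columns: `individual_id, species, x, y, t, activity`.
#'
#' @param path CSV file path.
#' @return Data frame of fixes.
#' @export
read_track <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "x", "y", "t", "activity")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0L) {
    stop_patchrsf("track CSV missing columns: %s",
                  paste(miss, collapse = ", "), class = "bad_track")
  }
  tr
}

#' Write a home-range polygon as GeoJSON
#'
#' RFC 7946 Polygon feature; the ring is closed on write.
#'
#' @param polygon An `mcp_polygon`.
#' @param path Output path.
#' @param id Optional feature id (e.g. individual id).
#' @export
write_geojson_polygon <- function(polygon, path, id = NULL) {
  v <- unclass_poly(polygon)
  ring <- rbind(v, v[1L, , drop = FALSE])  # enforce ring closure
  coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
  feat <- list(type = "Feature",
               properties = if (is.null(id)) stats::setNames(list(), character(0)) else
                 list(individual_id = id),
               geometry = list(type = "Polygon", coordinates = list(coords)))
  jsonlite::write_json(feat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Read a GeoJSON polygon home range
#'
#' @param path GeoJSON file (a Polygon geometry or a Feature wrapping one).
#' @return An `mcp_polygon`.
#' @export
read_geojson_polygon <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (identical(gj$type, "Feature")) gj$geometry else gj
  if (!identical(geom$type, "Polygon")) {
    stop_patchrsf("expected a GeoJSON Polygon, got %s",
                  geom$type %||% "nothing", class = "bad_geojson")
  }
  co <- geom$coordinates
  ring <- if (is.array(co) && length(dim(co)) == 3L) {
    matrix(co[1L, , ], dim(co)[2L], 2L)
  } else if (is.list(co)) {
    do.call(rbind, lapply(co[[1L]], as.numeric))
  } else {
    matrix(as.numeric(co), ncol = 2L)
  }
  if (all(ring[1L, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  minimum_convex_polygon(ring)
}

#' Write a landscape as an ESRI ASCII grid
#'
#' Two rasters can be derived from a landscape; `layer` selects bare-ground
#' (0/1) or vegetation height (cm).
#'
#' @param landscape A `habitat_landscape`.
#' @param path Output path.
#' @param layer `"bare"` or `"height"`.
#' @export
write_ascii_grid <- function(landscape, path, layer = c("bare", "height")) {
  layer <- match.arg(layer)
  m <- if (layer == "bare") landscape$bare * 1L else landscape$height
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %g", landscape$grain),
               "NODATA_value -9999"), con)
  # ASCII grid rows run north to south: top matrix row last
  for (r in rev(seq_len(nrow(m)))) {
    writeLines(paste(format(m[r, ], trim = TRUE, digits = 6), collapse = " "),
               con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path Raster path.
#' @return List with `values` (matrix, row 1 = south), `cellsize`, `ncols`,
#'   `nrows`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) as.numeric(sub(paste0("^", key, "\\s+"), "",
                                      hdr[grep(paste0("^", key), hdr, ignore.case = TRUE)]))
  ncols <- val("ncols"); nrows <- val("nrows"); cs <- val("cellsize")
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  list(values = m[rev(seq_len(nrow(m))), , drop = FALSE],
       cellsize = cs, ncols = ncols, nrows = nrows)
}

#' Write posterior draws to CSV
#'
#' One row per retained draw with flattened parameter names
#' (`mu.b`, `sigma.b`, `B.<individual>.<term>`, `deviance`, `chain`).
#'
#' @param fit An `rsf_fit`.
#' @param path Output path.
#' @export
write_draws <- function(fit, path) {
  I <- length(fit$individuals)
  K <- ncol(fit$mu)
  Bflat <- matrix(fit$B, nrow = dim(fit$B)[1L])
  colnames(Bflat) <- paste0("B.", rep(fit$individuals, times = K), ".",
                            rep(colnames(fit$mu), each = I))
  out <- data.frame(chain = fit$chain, fit$mu, fit$sigma, Bflat,
                    deviance = fit$deviance, check.names = FALSE)
  names(out)[2:(1 + K)] <- paste0("mu.", colnames(fit$mu))
  names(out)[(2 + K):(1 + 2 * K)] <- paste0("sigma.", colnames(fit$sigma))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write response curves to CSV
#'
#' Columns `level,covariate,grid,mean,lo80,hi80`.
#'
#' @param curves A `response_curves` data frame.
#' @param path Output path.
#' @export
write_response_curves <- function(curves, path) {
  utils::write.csv(as.data.frame(curves)[, c("level", "covariate", "grid",
                                             "mean", "lo80", "hi80")],
                   path, row.names = FALSE, quote = FALSE)
}

#' Write a model-selection table to CSV
#'
#' Columns `model,deviance,pD,dDIC` (the published table layout).
#'
#' @param selection An `rsf_selection`.
#' @param path Output path.
#' @export
write_selection_table <- function(selection, path) {
  tab <- selection$table[, c("model", "deviance", "pD", "dDIC")]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
}

#' Write a goodness-of-fit report as JSON
#' @param gof A `gof_report`.
#' @param path Output path.
#' @export
write_gof_json <- function(gof, path) {
  jsonlite::write_json(list(bayes_p = gof$bayes_p,
                            n_draws = length(gof$t_obs),
                            n_clamped = gof$n_clamped,
                            mean_t_obs = mean(gof$t_obs),
                            mean_t_rep = mean(gof$t_rep)),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write a DIC summary as JSON
#' @param dic A `dic_summary`.
#' @param path Output path.
#' @export
write_dic_json <- function(dic, path) {
  jsonlite::write_json(list(d_bar = dic$d_bar, p_d = dic$p_d, dic = dic$dic),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write a truth bundle as JSON
#' @param truth A `truth_bundle`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(preset = truth$preset, seed = truth$seed,
         landscape_seed = truth$landscape_seed,
         mu = as.list(truth$mu), sigma = as.list(truth$sigma),
         B = apply(truth$B, 1L, as.list),
         standardization = list(mean = as.list(truth$std$mean),
                                sd = as.list(truth$std$sd))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
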