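# Synthetic grass/bare-ground mosaic landscapes.
#
# The bare-ground mask is a smoothed Gaussian random field thresholded at
# the quantile matching the target bare fraction; vegetation height is a
# second, independent smoothed field truncated at zero and zeroed on bare
# cells. patch_scale controls the spatial autocorrelation range of the
# mosaic (larger values give coarser patches).

#' Generate a synthetic habitat landscape
#'
#' @param extent Length-2 numeric, landscape size in metres (default
#'   `c(400, 400)`).
#' @param grain Cell size in metres (default 0.5).
#' @param bare_fraction Target proportion of bare-ground cells (default 0.4).
#' @param patch_scale Patch autocorrelation scale in metres (> grain;
#'   default 3, a fine-grained mosaic whose patches are on the order of the
#'   foraging-patch scale).
#' @param height_mean,height_sd Mean and sd of vegetation height (cm) on
#'   vegetated cells before truncation at zero (defaults 15 and 5).
#' @param seed Master seed; the bare and height fields use independent
#'   sub-seeds derived from it.
#' @return An object of class `habitat_landscape`: `extent`, `grain`,
#'   `bare` (cells-y x cells-x logical matrix), `height` (cm matrix, 0 on
#'   bare cells), plus the generating parameters.
#' @export
make_landscape <- function(extent = c(400, 400), grain = 0.5,
                           bare_fraction = 0.4, patch_scale = 3,
                           height_mean = 15, height_sd = 5, seed = 1L) {
  stopifnot(length(extent) == 2L, all(extent > 0), grain > 0)
  if (bare_fraction <= 0 || bare_fraction >= 1) {
    stop_patchrsf("bare_fraction must be strictly between 0 and 1",
                  class = "bad_config")
  }
  if (patch_scale <= grain) {
    stop_patchrsf("patch_scale (%.2f m) must exceed the grain (%.2f m)",
                  patch_scale, grain, class = "resolution_error")
  }
  nx <- max(4L, as.integer(round(extent[1L] / grain)))
  ny <- max(4L, as.integer(round(extent[2L] / grain)))
  sd_cells <- patch_scale / grain / 2

  f_bare <- gaussian_field(ny, nx, sd_cells, derive_seed(seed, 1L))
  bare <- f_bare <= stats::quantile(f_bare, bare_fraction)

  f_h <- gaussian_field(ny, nx, sd_cells, derive_seed(seed, 2L))
  height <- height_mean + height_sd * f_h
  height[height < 0] <- 0  # truncate at bare soil level
  height[bare] <- 0

  structure(list(extent = c(nx * grain, ny * grain), grain = grain,
                 bare = bare, height = height,
                 bare_fraction = bare_fraction, patch_scale = patch_scale,
                 height_mean = height_mean, height_sd = height_sd,
                 seed = seed),
            class = "habitat_landscape")
}

# Standardized (mean 0, sd 1) smoothed Gaussian random field on a torus:
# white noise convolved with an isotropic Gaussian kernel via the FFT.
gaussian_field <- function(ny, nx, sd_cells, seed) {
  set.seed(seed)
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  dy <- 0:(ny - 1L); dy <- pmin(dy, ny - dy)
  dx <- 0:(nx - 1L); dx <- pmin(dx, nx - dx)
  kern <- outer(exp(-0.5 * (dy / sd_cells)^2), exp(-0.5 * (dx / sd_cells)^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE))
  (f - mean(f)) / stats::sd(f)
}

#' Realized bare-ground fraction of a landscape
#' @param landscape A `habitat_landscape`.
#' @return Proportion of bare cells.
#' @export
bare_fraction <- function(landscape) mean(landscape$bare)

#' @export
print.habitat_landscape <- function(x, ...) {
  cat(sprintf(paste0("Habitat landscape: %.0f x %.0f m at %.2g m grain, ",
                     "%.0f%% bare, patch scale %.0f m\n"),
              x$extent[1L], x$extent[2L], x$grain, 100 * bare_fraction(x),
              x$patch_scale))
  invisible(x)
}
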