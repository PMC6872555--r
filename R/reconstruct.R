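# High-level reconstruction interface: one entry point from a dataset to a
# classed result object, wrapping preprocessing, delay tables and the
# chosen beamformer.

#' Reconstruct a scattering intensity image from a dataset
#'
#' Runs the full chain on a multistatic dataset: odd/even rotation split and
#' rotation subtraction, frequency-to-time conversion, delay-table
#' computation, and DAS / DMAS / IC-DMAS image formation.
#'
#' `gate = "auto"` applies a focal integration gate of half-width equal to
#' one inverse bandwidth around t = 0 (the width of the band-limited pulse).
#' Gating is what lets the iterative delay correction act: integrated over
#' an unbounded record, a per-voxel delay shift common to all channels
#' cannot change the DMAS integral (see the methods vignette). Pass
#' `gate = NULL` to integrate over the full record.
#'
#' @param ds An `mwi_dataset`.
#' @param grid An `mwi_grid`, or `NULL` for the default 2 mm slice covering
#'   |x|, |y| <= 0.04 m at the antenna plane.
#' @param algorithm `"dmas"` (default), `"das"`, or `"icdmas"`.
#' @param eps_b Background relative permittivity assumed by the delay
#'   computation (default 1, air).
#' @param window,pad_factor Passed to [to_time_domain()].
#' @param gate `"auto"` (default), `NULL`, or a half-width in seconds.
#' @param control [icdmas_control()] settings (IC-DMAS only).
#' @return An object of class `mwi_recon`: `map` (an `mwi_map`), `state`
#'   (IC-DMAS iteration state or `NULL`), `grid`, `algorithm`, `settings`.
#' @examples
#' \donttest{
#' ph <- make_phantom("B", seed = 1)
#' geom <- build_cylindrical_array(4, 4, 0.1, 10, 36)
#' ds <- simulate_scatter_dataset(ph, geom, default_freqs(101))
#' rec <- reconstruct(ds, algorithm = "dmas")
#' print(rec)
#' }
#' @export
reconstruct <- function(ds, grid = NULL,
                        algorithm = c("dmas", "das", "icdmas"),
                        eps_b = 1, window = "hann", pad_factor = 4,
                        gate = "auto", control = icdmas_control()) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ds, "mwi_dataset"))
  if (is.null(grid)) {
    grid <- build_imaging_grid(c(-0.04, 0.04, -0.04, 0.04), 0.002,
                               z_plane = ds$geometry$z_plane,
                               geom = ds$geometry)
  }
  td <- preprocess_dataset(ds, window = window, pad_factor = pad_factor)
  if (identical(gate, "auto")) {
    gate <- 1 / (max(ds$freqs) - min(ds$freqs))
  }
  dist <- compute_distance_tables(grid, ds$geometry)
  delays <- compute_delay_table(dist, eps_b = eps_b)
  state <- NULL
  map <- switch(algorithm,
    das = das_image(td, delays, grid, gate = gate),
    dmas = dmas_image(td, delays, grid, gate = gate),
    icdmas = {
      fit <- icdmas_reconstruct(td, delays, grid, control = control,
                                gate = gate)
      state <- fit$state
      fit$map
    }
  )
  structure(
    list(map = map, state = state, grid = grid, algorithm = algorithm,
         settings = list(eps_b = eps_b, window = window,
                         pad_factor = pad_factor, gate = gate,
                         control = if (algorithm == "icdmas") control),
         meta = ds$meta),
    class = "mwi_recon"
  )
}

#' @export
print.mwi_recon <- function(x, ...) {
  cat(sprintf("mwibeam reconstruction (%s)\n", toupper(x$algorithm)))
  print(x$map)
  if (!is.null(x$state)) {
    cat(sprintf("  iterations: %d (%s), E history: %s\n", x$state$n,
                if (x$state$converged) "converged" else "max_iter reached",
                paste(sprintf("%.3g", x$state$e_history), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.mwi_recon <- function(object, true_positions = NULL,
                              mask_radius = 0.005, ...) {
  v <- object$map$values
  out <- list(algorithm = object$algorithm,
              n_voxels = length(v),
              intensity_range = range(v),
              argmax = object$grid$points[which.max(pmax(v, 0)), ],
              n_iter = object$map$n_iter,
              e_history = object$state$e_history)
  if (!is.null(true_positions)) {
    mask <- tumor_mask_sphere(object$grid, true_positions, mask_radius)
    out$smr_peak_db <- smr(object$map, mask, "peak")$smr_db
    out$smr_region_mean_db <- smr(object$map, mask, "region_mean")$smr_db
    out$localization <- localization_error(object$map, true_positions)
  }
  structure(out, class = "summary.mwi_recon")
}

#' @export
print.summary.mwi_recon <- function(x, ...) {
  cat(sprintf("%s reconstruction over %d voxels\n", toupper(x$algorithm),
              x$n_voxels))
  cat(sprintf("  intensity range [%.3g, %.3g], argmax at (%.3f, %.3f, %.3f) m\n",
              x$intensity_range[1], x$intensity_range[2],
              x$argmax[1], x$argmax[2], x$argmax[3]))
  if (!is.null(x$e_history) && length(x$e_history)) {
    cat(sprintf("  %d iteration(s), final E = %.3g\n", x$n_iter,
                x$e_history[length(x$e_history)]))
  }
  if (!is.null(x$smr_peak_db)) {
    cat(sprintf("  SMR: %.3f dB (peak), %.3f dB (region mean)\n",
                x$smr_peak_db, x$smr_region_mean_db))
    errs <- x$localization$errors
    cat(sprintf("  localization errors (mm): %s; missed: %d\n",
                paste(sprintf("%.2f", errs * 1e3), collapse = ", "),
                x$localization$n_missed))
  }
  invisible(x)
}

#' @export
plot.mwi_recon <- function(x, ...) plot(x$map, ...)
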