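# Image-quality metrics: signal-to-mean ratio and localization error.

#' Spherical tumor mask around ground-truth positions
#'
#' @param grid An `mwi_grid`.
#' @param centers Matrix (k x 3) or single length-3 vector of positions (m).
#' @param radius Mask radius in meters (default 5 mm).
#' @return Logical vector over grid points.
#' @export
tumor_mask_sphere <- function(grid, centers, radius = 0.005) {
  if (is.numeric(centers) && is.null(dim(centers))) {
    centers <- matrix(centers, nrow = 1)
  }
  .mwi_check(ncol(centers) == 3, "mwi_config_error",
             "centers must be k x 3 positions")
  .mwi_check(radius > 0, "mwi_domain_error", "radius must be > 0")
  pts <- grid$points
  mask <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[k, 1])^2 + (pts[, 2] - centers[k, 2])^2 +
      (pts[, 3] - centers[k, 3])^2
    mask <- mask | (d2 <= radius^2)
  }
  mask
}

#' Signal-to-mean ratio of a reconstructed image
#'
#' Ratio of the tumor-region energy to the mean energy of the whole image,
#' in dB. `mode = "peak"` uses the maximum intensity over the tumor mask
#' (the formula variant); `mode = "region_mean"` uses the mean over the
#' mask (the region-mean variant). "Energy" is the intensity value clamped
#' at zero - the DMAS map is already a quadratic (pairwise-product)
#' quantity - unless `squared = TRUE`, which squares the clamped values.
#'
#' @param map An `mwi_map`.
#' @param tumor_mask Logical vector over grid points, or integer indices.
#' @param mode `"peak"` or `"region_mean"`.
#' @param squared Use squared intensity as energy (default FALSE).
#' @return A list of class `mwi_smr`: `smr_db`, `ratio`, `tumor_energy`,
#'   `mean_energy`, `mode`, `n_mask`.
#' @export
smr <- function(map, tumor_mask, mode = c("peak", "region_mean"),
                squared = FALSE) {
  mode <- match.arg(mode)
  v <- if (inherits(map, "mwi_map")) map$values else as.numeric(map)
  if (is.logical(tumor_mask)) {
    .mwi_check(length(tumor_mask) == length(v), "mwi_shape_error",
               "mask length must match map length")
    idx <- which(tumor_mask)
  } else {
    idx <- as.integer(tumor_mask)
    .mwi_check(all(idx >= 1 & idx <= length(v)), "mwi_index_error",
               "mask indices out of range")
  }
  .mwi_check(length(idx) > 0, "mwi_domain_error", "tumor mask is empty")
  energy <- pmax(v, 0)
  if (squared) energy <- energy^2
  mean_energy <- mean(energy)
  .mwi_check(mean_energy > 0, "mwi_domain_error",
             "map has no positive energy; SMR undefined")
  tumor_energy <- if (mode == "peak") max(energy[idx]) else mean(energy[idx])
  ratio <- tumor_energy / mean_energy
  structure(
    list(smr_db = 10 * log10(ratio), ratio = ratio,
         tumor_energy = tumor_energy, mean_energy = mean_energy,
         mode = mode, n_mask = length(idx)),
    class = "mwi_smr"
  )
}

#' @export
print.mwi_smr <- function(x, ...) {
  cat(sprintf("SMR (%s): %.4f dB (tumor %.4g / mean %.4g over %d voxels)\n",
              x$mode, x$smr_db, x$tumor_energy, x$mean_energy, x$n_mask))
  invisible(x)
}

#' Detect peaks and measure localization error against ground truth
#'
#' Greedy peak picking on the clamped map: repeatedly take the strongest
#' remaining voxel and suppress a disk of `min_separation` around it, until
#' `length(true_positions)` peaks are found or no positive intensity
#' remains. Detections are then greedily matched to the nearest unmatched
#' truth (global nearest pair first). Truths left unmatched are reported as
#' missed detections (NA error), not as an exception.
#'
#' @param map An `mwi_map`.
#' @param true_positions Matrix (k x 3) or length-3 vector of true
#'   scatterer positions in meters.
#' @param min_separation Minimum distance between reported peaks, meters
#'   (default 2 grid spacings, suppressing halo-effect double counting).
#' @return A list of class `mwi_localization`: `errors` (meters, one per
#'   truth, NA if missed), `detections` (m x 3 positions, strongest first),
#'   `matched` (truth index per detection), `n_missed`.
#' @export
localization_error <- function(map, true_positions, min_separation = NULL) {
  stopifnot(inherits(map, "mwi_map"))
  if (is.numeric(true_positions) && is.null(dim(true_positions))) {
    true_positions <- matrix(true_positions, nrow = 1)
  }
  .mwi_check(ncol(true_positions) == 3, "mwi_config_error",
             "true_positions must be k x 3")
  grid <- map$grid
  if (is.null(min_separation)) min_separation <- 2 * grid$spacing
  v <- pmax(map$values, 0)
  .mwi_check(any(v > 0), "mwi_domain_error",
             "map has no positive intensity; no peaks to detect")
  k <- nrow(true_positions)
  pts <- grid$points
  det <- matrix(NA_real_, 0, 3)
  strengths <- numeric(0)
  vv <- v
  while (nrow(det) < k) {
    i <- which.max(vv)
    if (vv[i] <= 0) break
    det <- rbind(det, pts[i, ])
    strengths <- c(strengths, vv[i])
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
      (pts[, 3] - pts[i, 3])^2
    vv[d2 <= min_separation^2] <- 0
  }
  # Greedy global-nearest matching between detections and truths.
  errors <- rep(NA_real_, k)
  matched <- rep(NA_integer_, max(nrow(det), 0))
  if (nrow(det) > 0) {
    D <- matrix(NA_real_, nrow(det), k)
    for (m in seq_len(nrow(det))) {
      for (tt in seq_len(k)) {
        D[m, tt] <- sqrt(sum((det[m, ] - true_positions[tt, ])^2))
      }
    }
    free_d <- rep(TRUE, nrow(det)); free_t <- rep(TRUE, k)
    for (step in seq_len(min(nrow(det), k))) {
      Dm <- D
      Dm[!free_d, ] <- Inf
      Dm[, !free_t] <- Inf
      i <- which.min(Dm)
      if (!is.finite(Dm[i])) break
      m <- (i - 1) %% nrow(det) + 1
      tt <- (i - 1) %/% nrow(det) + 1
      errors[tt] <- D[m, tt]
      matched[m] <- tt
      free_d[m] <- FALSE
      free_t[tt] <- FALSE
    }
  }
  structure(
    list(errors = errors, detections = det, strengths = strengths,
         matched = matched, n_missed = sum(is.na(errors))),
    class = "mwi_localization"
  )
}

#' @export
print.mwi_localization <- function(x, ...) {
  cat(sprintf("Localization: %d detection(s), %d missed\n",
              nrow(x$detections), x$n_missed))
  if (length(x$errors)) {
    cat("  errors (mm):", paste(sprintf("%.2f", x$errors * 1e3),
                                collapse = ", "), "\n")
  }
  invisible(x)
}
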