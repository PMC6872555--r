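# DAS and DMAS confocal beamformers.
#
# Channel = one (tx, rx, odd-rotation) triple. For a voxel hypothesis i each
# channel's signal is advanced by its round-trip delay tau(i, channel), so
# that the echo scattered at i lands at t = 0 for every channel; the voxel
# intensity integrates the coherent sum (DAS) or the pairwise products
# (DMAS) of the aligned signals over time.

#' Delay (align) one channel's signal
#'
#' Returns the channel signal advanced by `tau`: `y(t) = Gamma(t + tau)`,
#' evaluated on the record's own time axis with linear interpolation at
#' fractional-sample offsets; samples beyond the record are zero. With this
#' convention the echo of a scatterer whose round-trip delay equals `tau`
#' appears at `t = 0`.
#'
#' @param td An `mwi_timedomain`.
#' @param channel Integer triple `c(tx, rx, odd_rotation_index)`.
#' @param tau Delay in seconds (>= 0).
#' @return Numeric vector of the delayed signal, same length as the record.
#' @export
sample_delayed <- function(td, channel, tau) {
  stopifnot(inherits(td, "mwi_timedomain"))
  .mwi_check(is.numeric(tau) && length(tau) == 1 && tau >= 0,
             "mwi_domain_error", "tau must be >= 0, got %s", format(tau))
  .mwi_check(length(channel) == 3, "mwi_index_error",
             "channel must be c(tx, rx, odd_index)")
  g <- td$gamma[, channel[1], channel[2], channel[3]]
  .mwi_sample_shift(g, tau / td$dt)
}

# Advance a single signal by `shift` samples (linear interpolation,
# zero outside the record).
.mwi_sample_shift <- function(g, shift) {
  n <- length(g)
  p <- seq_len(n) + shift
  i0 <- floor(p)
  frac <- p - i0
  y <- numeric(n)
  v1 <- i0 >= 1 & i0 <= n
  v2 <- i0 + 1 >= 1 & i0 + 1 <= n
  y[v1] <- g[i0[v1]] * (1 - frac[v1])
  y[v2] <- y[v2] + g[i0[v2] + 1] * frac[v2]
  y
}

# Time indices over which the beamformers integrate. `gate` is NULL (full
# record) or a half-width in seconds around t = 0.
.mwi_gate_indices <- function(td, gate) {
  n_t <- dim(td$gamma)[1]
  if (is.null(gate)) return(seq_len(n_t))
  .mwi_check(is.numeric(gate) && length(gate) == 1 && gate > 0,
             "mwi_config_error", "gate must be NULL or a positive half-width")
  t <- td$t0 + (seq_len(n_t) - 1) * td$dt
  idx <- which(abs(t) <= gate)
  .mwi_check(length(idx) > 0, "mwi_config_error",
             "gate excludes every time sample")
  idx
}

# Shared validation + flattening for the beamformers. Returns the signal
# matrix G (n_t x K), per-channel sample shifts (n_pts x K) and gate indices.
.mwi_beamform_setup <- function(td, delays, grid, gate) {
  stopifnot(inherits(td, "mwi_timedomain"), inherits(delays, "mwi_delays"),
            inherits(grid, "mwi_grid"))
  dg <- dim(td$gamma)
  dtau <- dim(delays$tau)
  .mwi_check(length(dg) == 4, "mwi_shape_error",
             "time-domain data must be indexed (t, tx, rx, odd)")
  .mwi_check(all(dg[2:4] == dtau[2:4]), "mwi_shape_error",
             "channel layout of signals (%s) and delays (%s) differ",
             paste(dg[2:4], collapse = "x"),
             paste(dtau[2:4], collapse = "x"))
  .mwi_check(dtau[1] == nrow(grid$points), "mwi_shape_error",
             "delay table has %d voxels but the grid has %d",
             dtau[1], nrow(grid$points))
  if (is.complex(td$gamma))
    .mwi_stop("mwi_config_error",
              "beamformers require the real-valued signal (output = 'real')")
  K <- prod(dg[2:4])
  list(G = matrix(td$gamma, nrow = dg[1], ncol = K),
       shifts = matrix(delays$tau, nrow = dtau[1], ncol = K) / td$dt,
       gate_idx = .mwi_gate_indices(td, gate),
       n_t = dg[1], K = K, n_pts = dtau[1])
}

# Core accumulation: per gate sample, the coherent sum S and (for DMAS) the
# sum of squares Q over channels, blockwise over channels to bound memory.
.mwi_accumulate <- function(setup, need_sq, block = 256L) {
  G <- setup$G; shifts <- setup$shifts
  n_t <- setup$n_t; K <- setup$K; n_pts <- setup$n_pts
  gate_idx <- setup$gate_idx
  n_g <- length(gate_idx)
  S <- matrix(0, n_pts, n_g)
  Q <- if (need_sq) matrix(0, n_pts, n_g) else NULL
  for (start in seq(1L, K, by = block)) {
    chans <- start:min(start + block - 1L, K)
    off <- matrix(rep((chans - 1L) * n_t, each = n_pts),
                  nrow = n_pts)
    tb <- shifts[, chans, drop = FALSE]
    for (gi in seq_len(n_g)) {
      p <- tb + gate_idx[gi]
      i0 <- floor(p)
      frac <- p - i0
      x <- numeric(length(p))
      dim(x) <- dim(p)
      v <- i0 >= 1 & i0 <= n_t
      idx <- i0 + off
      x[v] <- G[idx[v]] * (1 - frac[v])
      v <- i0 + 1 >= 1 & i0 + 1 <= n_t
      x[v] <- x[v] + G[idx[v] + 1] * frac[v]
      S[, gi] <- S[, gi] + rowSums(x)
      if (need_sq) Q[, gi] <- Q[, gi] + rowSums(x * x)
    }
  }
  list(S = S, Q = Q)
}

.mwi_map <- function(values, grid, algorithm, n_iter = 0L, gate = NULL) {
  structure(
    list(values = as.numeric(values), grid = grid, algorithm = algorithm,
         n_iter = as.integer(n_iter), gate = gate),
    class = "mwi_map"
  )
}

#' Delay-and-sum (DAS) image formation
#'
#' Baseline coherent beamformer: per voxel the aligned channel signals are
#' summed and the square of the sum is integrated over time,
#' `DAS(i) = int [sum_k x_k(t)]^2 dt`.
#'
#' @param td An `mwi_timedomain` (real signals indexed t, tx, rx, odd).
#' @param delays An `mwi_delays` table on the same channel layout.
#' @param grid The `mwi_grid` the delay table was computed on.
#' @param gate `NULL` to integrate over the full record (default), or a
#'   half-width in seconds: only `|t| <= gate` contributes (focal gating).
#' @return An `mwi_map` of scattering intensities.
#' @export
das_image <- function(td, delays, grid, gate = NULL) {
  setup <- .mwi_beamform_setup(td, delays, grid, gate)
  acc <- .mwi_accumulate(setup, need_sq = FALSE)
  .mwi_map(rowSums(acc$S^2) * td$dt, grid, "das", gate = gate)
}

#' Delay-multiply-and-sum (DMAS) image formation
#'
#' Per voxel, the aligned channel signals are pairwise multiplied and the
#' products summed over all unordered distinct channel pairs, then
#' integrated over time. The default `pairs = "fast"` uses the algebraic
#' identity `sum_{k<k'} x_k x_k' = ((sum_k x_k)^2 - sum_k x_k^2) / 2`;
#' `pairs = "enumerate"` sums the pairs explicitly (O(K^2), used as an
#' independent oracle in tests); `pairs = "literal"` restricts the second
#' index of each pair to the printed triangular ranges
#' (odd' >= odd, tx' >= tx, rx' >= rx + 1), which drops some cross terms
#' and is retained for comparison only.
#'
#' @inheritParams das_image
#' @param pairs `"fast"`, `"enumerate"` or `"literal"`.
#' @return An `mwi_map` of scattering intensities (signed; clamp at display
#'   time only).
#' @export
dmas_image <- function(td, delays, grid, gate = NULL,
                       pairs = c("fast", "enumerate", "literal")) {
  pairs <- match.arg(pairs)
  setup <- .mwi_beamform_setup(td, delays, grid, gate)
  .mwi_check(setup$K >= 2, "mwi_config_error",
             "DMAS needs at least 2 channels (no pairs with %d)", setup$K)
  if (pairs == "fast") {
    acc <- .mwi_accumulate(setup, need_sq = TRUE)
    values <- rowSums((acc$S^2 - acc$Q) / 2) * td$dt
    return(.mwi_map(values, grid, "dmas", gate = gate))
  }
  # Explicit pair enumeration: sample every channel once, then loop pairs.
  X <- .mwi_sample_all(setup)
  dims <- dim(delays$tau)[2:4]
  pair_list <- .mwi_pair_set(dims, pairs)
  values <- numeric(setup$n_pts)
  for (pr in pair_list) {
    values <- values + rowSums(X[, pr[1], , drop = FALSE] *
                                 X[, pr[2], , drop = FALSE])
  }
  .mwi_map(values * td$dt, grid, "dmas", gate = gate)
}

# Sample every channel at every gate index: (n_pts, K, n_gate) array.
# Only intended for small channel counts (oracle paths).
.mwi_sample_all <- function(setup) {
  G <- setup$G; shifts <- setup$shifts
  n_t <- setup$n_t; K <- setup$K; n_pts <- setup$n_pts
  gate_idx <- setup$gate_idx
  X <- array(0, c(n_pts, K, length(gate_idx)))
  for (k in seq_len(K)) {
    g <- G[, k]
    for (gi in seq_along(gate_idx)) {
      p <- shifts[, k] + gate_idx[gi]
      i0 <- floor(p)
      frac <- p - i0
      x <- numeric(n_pts)
      v <- i0 >= 1 & i0 <= n_t
      x[v] <- g[i0[v]] * (1 - frac[v])
      v <- i0 + 1 >= 1 & i0 + 1 <= n_t
      x[v] <- x[v] + g[i0[v] + 1] * frac[v]
      X[, k, gi] <- x
    }
  }
  X
}

# Channel-pair index sets over the flattened (tx, rx, odd) channel space.
.mwi_pair_set <- function(dims, pairs) {
  n_tx <- dims[1]; n_rx <- dims[2]; n_odd <- dims[3]
  flat <- function(a, b, m) a + n_tx * ((b - 1) + n_rx * (m - 1))
  out <- list()
  if (pairs == "enumerate") {
    K <- n_tx * n_rx * n_odd
    for (k in seq_len(K - 1)) {
      for (k2 in (k + 1):K) out[[length(out) + 1L]] <- c(k, k2)
    }
    return(out)
  }
  # literal printed ranges: odd' >= odd, tx' >= tx, rx' >= rx + 1
  for (m in seq_len(n_odd)) for (a in seq_len(n_tx)) for (b in seq_len(n_rx)) {
    for (m2 in m:n_odd) for (a2 in a:n_tx) {
      if (b + 1 > n_rx) next
      for (b2 in (b + 1):n_rx) {
        out[[length(out) + 1L]] <- c(flat(a, b, m), flat(a2, b2, m2))
      }
    }
  }
  out
}

#' @export
print.mwi_map <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "Scattering intensity map (%s%s): %d voxels, range [%.3g, %.3g]\n",
    x$algorithm, if (x$n_iter > 0) sprintf(", %d iterations", x$n_iter) else "",
    length(v), min(v), max(v)))
  invisible(x)
}

#' Display a scattering intensity map
#'
#' Negative DMAS values are clamped at zero for display; the raw signed map
#' is left untouched.
#'
#' @param x An `mwi_map` on a 2D slice grid.
#' @param ... Passed to [graphics::image()].
#' @export
plot.mwi_map <- function(x, ...) {
  .mwi_check(x$grid$mode == "slice2d", "mwi_config_error",
             "plotting is implemented for slice2d grids")
  z <- matrix(pmax(x$values, 0), nrow = x$grid$shape[1])
  graphics::image(x$grid$x, x$grid$y, z, asp = 1,
                  xlab = "x (m)", ylab = "y (m)",
                  main = toupper(x$algorithm), ...)
  invisible(x)
}
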