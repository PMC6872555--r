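# Rotation-subtraction skin removal and frequency-to-time conversion.

#' Split a dataset into odd and even rotation frames
#'
#' Rotation positions 1, 3, ..., n_phi - 1 form the "original" illumination
#' and 2, 4, ..., n_phi the "offset" illumination of the rotation-subtraction
#' scheme.
#'
#' @param ds An `mwi_dataset`, or a complex array indexed (f, tx, rx, phi).
#' @return List with complex arrays `odd` and `even` (each with n_phi/2
#'   rotation frames) and the index vectors `phi_odd`, `phi_even`.
#' @export
split_even_odd <- function(ds) {
  s <- if (inherits(ds, "mwi_dataset")) ds$s else ds
  .mwi_check(is.array(s) && length(dim(s)) == 4, "mwi_shape_error",
             "expected a (f, tx, rx, phi) array")
  n_phi <- dim(s)[4]
  .mwi_check(n_phi %% 2 == 0, "mwi_shape_error",
             "n_phi must be even, got %d", n_phi)
  phi_odd <- seq(1L, n_phi - 1L, by = 2L)
  phi_even <- seq(2L, n_phi, by = 2L)
  list(odd = s[, , , phi_odd, drop = FALSE],
       even = s[, , , phi_even, drop = FALSE],
       phi_odd = phi_odd, phi_even = phi_even)
}

#' Rotation subtraction (skin-artifact removal)
#'
#' Elementwise difference of paired rotation frames:
#' `S_odd(f, tx, rx, 2k-1) - S_even(f, tx, rx, 2k)`. Any reflection that is
#' identical across rotation positions (the dominant air-skin interface)
#' cancels exactly; localized scatterer responses persist.
#'
#' @param s_odd,s_even Complex arrays of matching shape (the two halves from
#'   [split_even_odd()]).
#' @return Complex array of the same shape as `s_odd`.
#' @export
rotation_subtract <- function(s_odd, s_even) {
  .mwi_check(identical(dim(s_odd), dim(s_even)), "mwi_shape_error",
             "odd and even frame shapes differ")
  s_odd - s_even
}

#' Convert a frequency-domain cube to the time domain
#'
#' Band-limited inverse discrete Fourier transform evaluated with the band
#' at its true position on the frequency axis (a direct shifted-DFT, so the
#' band start need not be commensurate with the frequency spacing). The
#' record spans `1/df` seconds sampled at `dt = 1/(pad_factor * n_f * df)`;
#' the time origin `t0` defaults to minus one eighth of the record so that
#' focal echoes near t = 0 keep a margin on both sides. The real part of the
#' analytic signal is retained as the beamformer input Gamma; the analytic
#' (complex) signal is available via `output = "analytic"` for diagnostics.
#'
#' @param s Complex array whose first dimension indexes frequency (any
#'   further dimensions are treated as channels), or an `mwi_dataset`.
#' @param freqs Frequencies in Hz (uniform spacing required); taken from the
#'   dataset when `s` is an `mwi_dataset`.
#' @param window Spectral window: `"hann"` (default), `"hamming"`, `"none"`.
#' @param pad_factor Time-domain oversampling factor (integer >= 1).
#' @param t0 Time of the first sample in seconds; default `-record/8`.
#' @param output `"real"` (default) or `"analytic"`.
#' @return An object of class `mwi_timedomain`: `gamma` (array with time as
#'   first dimension), `dt`, `t0`, `window`, `pad_factor`.
#' @export
to_time_domain <- function(s, freqs = NULL,
                           window = c("hann", "hamming", "none"),
                           pad_factor = 4, t0 = NULL,
                           output = c("real", "analytic")) {
  window <- match.arg(window)
  output <- match.arg(output)
  if (inherits(s, "mwi_dataset")) {
    if (is.null(freqs)) freqs <- s$freqs
    s <- s$s
  }
  .mwi_check(!is.null(freqs), "mwi_format_error", "freqs must be supplied")
  if (!is.array(s)) s <- array(s, c(length(s), 1L))
  dims <- dim(s)
  n_f <- dims[1]
  .mwi_check(n_f == length(freqs), "mwi_shape_error",
             "first dimension of s (%d) must match length(freqs) (%d)",
             n_f, length(freqs))
  .mwi_check(is.numeric(pad_factor) && length(pad_factor) == 1 &&
               pad_factor >= 1 && pad_factor == round(pad_factor),
             "mwi_config_error", "pad_factor must be an integer >= 1")
  .mwi_check(n_f >= 2, "mwi_format_error", "need at least 2 frequency points")
  df <- diff(freqs)
  .mwi_check(max(abs(df - df[1])) <= abs(df[1]) * 1e-9, "mwi_format_error",
             "frequency grid must be uniform")
  df <- df[1]

  w <- switch(window,
    none = rep(1, n_f),
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n_f) - 1) / (n_f - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(n_f) - 1) / (n_f - 1))
  )

  n_t <- pad_factor * n_f
  dt <- 1 / (pad_factor * n_f * df)
  if (is.null(t0)) t0 <- -(n_t * dt) / 8
  t <- t0 + (seq_len(n_t) - 1) * dt

  # Direct shifted-DFT synthesis: z(t) = (1/n_f) sum_m w_m S_m e^{+i 2 pi f_m t}
  E <- exp(2i * pi * outer(t, freqs))
  s_mat <- matrix(s, nrow = n_f)
  z <- (E %*% (w * s_mat)) / n_f
  gamma <- if (output == "real") Re(z) else z
  dim(gamma) <- c(n_t, dims[-1])

  structure(
    list(gamma = gamma, dt = dt, t0 = t0, freqs = freqs, window = window,
         pad_factor = pad_factor, output = output),
    class = "mwi_timedomain"
  )
}

#' @export
print.mwi_timedomain <- function(x, ...) {
  d <- dim(x$gamma)
  cat(sprintf(
    "Time-domain data: %d samples (dt = %.3g ps, t0 = %.3g ns) x %s channels\n",
    d[1], x$dt * 1e12, x$t0 * 1e9,
    paste(d[-1], collapse = " x ")))
  invisible(x)
}

#' Skin removal + time conversion in one step
#'
#' Convenience wrapper: split the rotation positions, apply rotation
#' subtraction, and convert the differenced cube to the time domain. The
#' result is the beamformer input `Gamma(t, tx, rx, phi_odd)`.
#'
#' @inheritParams to_time_domain
#' @param ds An `mwi_dataset`.
#' @return An `mwi_timedomain` whose `gamma` is indexed (t, tx, rx, odd).
#' @export
preprocess_dataset <- function(ds, window = "hann", pad_factor = 4,
                               t0 = NULL) {
  stopifnot(inherits(ds, "mwi_dataset"))
  halves <- split_even_odd(ds)
  resid <- rotation_subtract(halves$odd, halves$even)
  td <- to_time_domain(resid, ds$freqs, window = window,
                       pad_factor = pad_factor, t0 = t0)
  td$phi_odd <- halves$phi_odd
  td
}
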