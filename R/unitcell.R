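# Closed-form circuit model of the metasurface unit cell (complementary
# split-ring resonator): LC resonance, split-gap capacitance, and microstrip
# inductance with substrate correction factor.

#' Resonant frequency of the unit-cell LC circuit
#'
#' `f = 1 / (pi * sqrt(L * C))`.
#'
#' @param L Lumped inductance in henries (> 0).
#' @param C Lumped capacitance in farads (> 0).
#' @return Resonant frequency in Hz.
#' @examples
#' resonant_frequency(1e-9, 1e-12)  # ~1.0066e10 Hz
#' @export
resonant_frequency <- function(L, C) {
  .mwi_check(is.numeric(L) && all(L > 0), "mwi_domain_error", "L must be > 0")
  .mwi_check(is.numeric(C) && all(C > 0), "mwi_domain_error", "C must be > 0")
  1 / (pi * sqrt(L * C))
}

#' Parallel-plate capacitance of the split gap
#'
#' `C = eps0 * eps_r * A / d`, with `A` the split area and `d` the split
#' length (the gap).
#'
#' @param eps_r Relative permittivity of the medium in the gap (>= 1).
#' @param A Split area in m^2 (> 0).
#' @param d Split length in m (> 0).
#' @return Capacitance in farads.
#' @export
split_capacitance <- function(eps_r, A, d) {
  .mwi_check(is.numeric(eps_r) && all(eps_r >= 1), "mwi_domain_error",
             "eps_r must be >= 1")
  .mwi_check(is.numeric(A) && all(A > 0), "mwi_domain_error", "A must be > 0")
  .mwi_check(is.numeric(d) && all(d > 0), "mwi_domain_error", "d must be > 0")
  .mwi_eps0 * eps_r * A / d
}

#' Microstrip line inductance (transmission-line formula)
#'
#' `L(nH) = 2e-4 * l * [ln(l / (w + t)) + 1.193 + 0.02235 * (w + t) / l] * Kg`
#' with all conductor dimensions in micrometers (the standard convention for
#' this printed formula) and the substrate correction factor
#' `Kg = 0.57 - 0.145 * ln(w' / h')`.
#'
#' The source text defines `w'` as the substrate *thickness* and `h'` as the
#' substrate *width* - reversed relative to the usual literature convention.
#' Both orderings are exposed: `kg_convention = "as_printed"` (default) uses
#' thickness/width, `"literature"` uses width/thickness. Alternatively pass
#' a precomputed `k_g` directly.
#'
#' Degenerate geometries where the bracket term or `Kg` is non-positive
#' yield a warning and the result carries `attr(, "nonphysical") = TRUE`.
#'
#' @param l,w,t Length, width, thickness of the microstrip line, micrometers.
#' @param sub_thickness,sub_width Substrate thickness and width, micrometers
#'   (any common unit; only their ratio enters). Ignored when `k_g` is given.
#' @param k_g Correction factor; overrides the substrate ratio when given.
#' @param kg_convention `"as_printed"` or `"literature"`.
#' @return Inductance in nanohenries.
#' @examples
#' microstrip_inductance(1000, 90, 10, k_g = 1)  # ~0.6996 nH
#' @export
microstrip_inductance <- function(l, w, t, sub_thickness = NULL,
                                  sub_width = NULL, k_g = NULL,
                                  kg_convention = c("as_printed",
                                                    "literature")) {
  kg_convention <- match.arg(kg_convention)
  .mwi_check(is.numeric(l) && all(l > 0), "mwi_domain_error", "l must be > 0")
  .mwi_check(is.numeric(w) && all(w >= 0) && is.numeric(t) && all(t >= 0) &&
               all(w + t > 0),
             "mwi_domain_error", "w and t must be >= 0 with w + t > 0")
  if (is.null(k_g)) {
    .mwi_check(!is.null(sub_thickness) && !is.null(sub_width),
               "mwi_config_error",
               "supply either k_g or sub_thickness and sub_width")
    .mwi_check(all(sub_thickness > 0) && all(sub_width > 0),
               "mwi_domain_error", "substrate dimensions must be > 0")
    ratio <- if (kg_convention == "as_printed") sub_thickness / sub_width
             else sub_width / sub_thickness
    k_g <- 0.57 - 0.145 * log(ratio)
  }
  bracket <- log(l / (w + t)) + 1.193 + 0.02235 * (w + t) / l
  L <- 2e-4 * l * bracket * k_g
  nonphysical <- any(bracket <= 0) || any(k_g <= 0)
  if (nonphysical) {
    warning("non-physical microstrip geometry: bracket term or Kg <= 0",
            call. = FALSE)
    attr(L, "nonphysical") <- TRUE
  }
  L
}
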