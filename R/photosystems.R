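#' Antenna configuration of the two photosystems
#'
#' Describes how chlorophyll is held by the photosystem core complexes and the
#' peripheral light-harvesting complexes (LHCs).  The PSII and PSI cores bind
#' fixed numbers of chlorophyll molecules (37 and 95 respectively); each
#' peripheral LHC unit binds 14.  `n1` is the number of LHC units attached to
#' each photosystem and is the "antenna size" dial of the whole package: the
#' engineering scenario studied here shrinks `n1`, not the number of reaction
#' centres.
#'
#' @param psii_conc PSII concentration, umol m-2 leaf.
#' @param n1 Number of peripheral LHC units per photosystem (dimensionless,
#'   may be fractional).
#' @param psi_psii_ratio Stoichiometric ratio \[PSI\]/\[PSII\] (default 1.4).
#' @param core_chl_psii,core_chl_psi Chlorophylls per PSII / PSI core.
#' @param chl_per_lhc Chlorophylls per LHC unit.
#' @return An object of class `antenna_config`.
#' @examples
#' cfg <- antenna_config(psii_conc = 1, n1 = 9.66)
#' total_chlorophyll(cfg)  # ~ 494.6 umol m-2
#' @export
antenna_config <- function(psii_conc, n1, psi_psii_ratio = 1.4,
                           core_chl_psii = 37, core_chl_psi = 95,
                           chl_per_lhc = 14) {
  stopifnot(is.numeric(psii_conc), psii_conc >= 0,
            is.numeric(n1), n1 >= 0,
            psi_psii_ratio > 0, core_chl_psii > 0, core_chl_psi > 0,
            chl_per_lhc > 0)
  structure(list(psii_conc = psii_conc, n1 = n1,
                 psi_psii_ratio = psi_psii_ratio,
                 core_chl_psii = core_chl_psii,
                 core_chl_psi = core_chl_psi,
                 chl_per_lhc = chl_per_lhc),
            class = "antenna_config")
}

#' @export
print.antenna_config <- function(x, ...) {
  cat("<antenna_config>\n")
  cat(sprintf("  PSII: %.3f umol m-2,  PSI/PSII: %.2f,  n1: %.3f LHC units\n",
              x$psii_conc, x$psi_psii_ratio, x$n1))
  cat(sprintf("  total chlorophyll: %.1f umol m-2\n", total_chlorophyll(x)))
  invisible(x)
}

#' Total chlorophyll held by photosystems and their antennas
#'
#' Chl = PSII * (core_PSII + 14 n1) + PSI * (core_PSI + 14 n1) with
#' PSI = ratio * PSII.  With the shipped stoichiometry (cores 37 and 95,
#' 14 chlorophylls per LHC, PSI/PSII = 1.4) this collapses to
#' `PSII * (170 + 33.6 n1)`.
#'
#' @param cfg An [antenna_config()].
#' @return Total chlorophyll, umol m-2.
#' @export
total_chlorophyll <- function(cfg) {
  stopifnot(inherits(cfg, "antenna_config"))
  per_psii <- (cfg$core_chl_psii + cfg$chl_per_lhc * cfg$n1) +
    cfg$psi_psii_ratio * (cfg$core_chl_psi + cfg$chl_per_lhc * cfg$n1)
  cfg$psii_conc * per_psii
}

#' Chlorophyll-per-PSII coefficients of the antenna model
#'
#' Collects the total-chlorophyll expression into
#' `Chl = PSII * (core_term + lhc_term * n1)` and returns the two
#' coefficients.  With defaults: core_term = 37 + 1.4*95 = 170 chlorophylls
#' per PSII and lhc_term = 14*(1 + 1.4) = 33.6 chlorophylls per PSII per LHC
#' unit.
#'
#' @inheritParams antenna_config
#' @return Named numeric vector `c(core_term =, lhc_term =)`.
#' @export
chl_coefficients <- function(psi_psii_ratio = 1.4, core_chl_psii = 37,
                             core_chl_psi = 95, chl_per_lhc = 14) {
  c(core_term = core_chl_psii + psi_psii_ratio * core_chl_psi,
    lhc_term = chl_per_lhc * (1 + psi_psii_ratio))
}

#' Antenna size needed to reach a target chlorophyll concentration
#'
#' Exact algebraic inverse of [total_chlorophyll()] in `n1` at fixed PSII
#' concentration.  Errors when the target lies below the chlorophyll bound in
#' the cores alone (antenna size cannot be negative).
#'
#' @param target_chl Target total chlorophyll, umol m-2.
#' @param psii_conc PSII concentration, umol m-2.
#' @inheritParams antenna_config
#' @return `n1`, LHC units per photosystem.
#' @export
antenna_size_for_chl <- function(target_chl, psii_conc, psi_psii_ratio = 1.4,
                                 core_chl_psii = 37, core_chl_psi = 95,
                                 chl_per_lhc = 14) {
  stopifnot(target_chl >= 0, psii_conc > 0)
  co <- chl_coefficients(psi_psii_ratio, core_chl_psii, core_chl_psi,
                         chl_per_lhc)
  core_chl <- psii_conc * co[["core_term"]]
  if (target_chl < core_chl - 1e-9) {
    stop(sprintf(paste0("target chlorophyll %.2f umol m-2 is below the ",
                        "core-antenna minimum %.2f umol m-2 at PSII = %.3f"),
                 target_chl, core_chl, psii_conc))
  }
  max(0, (target_chl / psii_conc - co[["core_term"]]) / co[["lhc_term"]])
}

#' Leaf optical properties in the photosynthetically active band
#'
#' @param reflectance,transmittance Broadband PAR reflectance and
#'   transmittance, each in `[0, 1)` with sum `<= 1` (a pigment-free laminar
#'   limit with zero absorbance is representable; the ray tracer itself
#'   requires strictly absorbing facets).
#' @return Object of class `leaf_optics` with fields `reflectance`,
#'   `transmittance`, `absorbance` (= 1 - r - t).
#' @export
leaf_optics <- function(reflectance, transmittance) {
  stopifnot(all(reflectance >= 0), all(reflectance < 1),
            all(transmittance >= 0), all(transmittance < 1),
            all(reflectance + transmittance <= 1))
  structure(list(reflectance = reflectance, transmittance = transmittance,
                 absorbance = 1 - reflectance - transmittance),
            class = "leaf_optics")
}

#' @export
print.leaf_optics <- function(x, ...) {
  cat(sprintf("<leaf_optics> r = %s, t = %s, a = %s\n",
              paste(signif(x$reflectance, 3), collapse = ","),
              paste(signif(x$transmittance, 3), collapse = ","),
              paste(signif(x$absorbance, 3), collapse = ",")))
  invisible(x)
}

#' Broadband PAR optics from spectral curves
#'
#' Solar-spectrum-weighted means of per-wavelength reflectance and
#' transmittance over the photosynthetically active band:
#' r = sum(r_n I_n) / sum(I_n), and likewise for t.
#'
#' @param spectral_r,spectral_t Per-wavelength reflectance / transmittance
#'   (e.g. 1-nm steps over 400-700 nm), values in `[0, 1]`.
#' @param solar_spectrum Per-wavelength photon flux weights, same length,
#'   non-negative, not all zero.
#' @return A [leaf_optics()].
#' @export
broadband_optics <- function(spectral_r, spectral_t, solar_spectrum) {
  n <- length(solar_spectrum)
  if (length(spectral_r) != n || length(spectral_t) != n)
    stop("spectral_r, spectral_t and solar_spectrum must have equal length")
  stopifnot(all(solar_spectrum >= 0), sum(solar_spectrum) > 0,
            all(spectral_r >= 0 & spectral_r <= 1),
            all(spectral_t >= 0 & spectral_t <= 1))
  w <- solar_spectrum / sum(solar_spectrum)
  leaf_optics(sum(spectral_r * w), sum(spectral_t * w))
}

#' Leaf optics as a function of chlorophyll concentration
#'
#' Saturating-exponential absorbance model:
#' `a(chl) = a_max * (1 - exp(-chl / chl0))`, calibrated so that the default
#' parameters give absorbance `abs_at_ref` (0.90) at the reference chlorophyll
#' concentration `chl_ref` (494.7 umol m-2), a typical value for a healthy
#' rice flag leaf.  The unabsorbed fraction is split between reflectance and
#' transmittance by `r_share` (default 0.5: near-symmetric scattering).
#' Absorbance is monotone increasing in chlorophyll and r + t + a = 1 exactly.
#'
#' @param chl Chlorophyll concentration(s), umol m-2 (vectorised).
#' @param a_max Asymptotic absorbance of a chlorophyll-saturated leaf.
#' @param chl_ref,abs_at_ref Calibration point fixing the curvature scale.
#' @param r_share Fraction of unabsorbed light that is reflected.
#' @return A [leaf_optics()] with vector fields parallel to `chl`.
#' @export
optics_from_chl <- function(chl, a_max = 0.96, chl_ref = 494.7,
                            abs_at_ref = 0.90, r_share = 0.5) {
  stopifnot(all(chl >= 0), a_max > 0, a_max <= 1,
            abs_at_ref > 0, abs_at_ref < a_max,
            r_share >= 0, r_share <= 1)
  chl0 <- -chl_ref / log(1 - abs_at_ref / a_max)
  a <- a_max * (1 - exp(-chl / chl0))
  leaf_optics((1 - a) * r_share, (1 - a) * (1 - r_share))
}

#' SPAD reading to chlorophyll concentration (and back)
#'
#' Monotone exponential calibration of the form
#' `chl = c1 * (exp(c2 * spad) - 1)`, anchored at chl(0) = 0, of the family
#' routinely fitted for SPAD-502 meters.  Default coefficients place a SPAD
#' reading of 40 at ~495 umol m-2, matching a healthy rice flag leaf.
#' `chl_to_spad()` is the exact inverse; the pair round-trips to well under
#' 0.1%.  Readings outside 0-60 are outside the meter's documented validity
#' and produce a warning.
#'
#' @param spad SPAD reading(s), >= 0.
#' @param chl Chlorophyll concentration(s), umol m-2.
#' @param c1,c2 Calibration coefficients.
#' @return Chlorophyll in umol m-2 (`spad_to_chl`) or a SPAD reading
#'   (`chl_to_spad`).
#' @export
spad_to_chl <- function(spad, c1 = 125.13, c2 = 0.04) {
  stopifnot(all(spad >= 0))
  if (any(spad > 60)) warning("SPAD readings > 60 are outside the calibrated range")
  c1 * (exp(c2 * spad) - 1)
}

#' @rdname spad_to_chl
#' @export
chl_to_spad <- function(chl, c1 = 125.13, c2 = 0.04) {
  stopifnot(all(chl >= 0))
  log(chl / c1 + 1) / c2
}
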