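#' Nanopore geometry specification
#'
#' A cylindrical solid-state pore described by its diameter, membrane
#' thickness and surface charge density. Defaults follow typical SiNx
#' pores: 20 nm diameter and thickness, -0.02 C/m^2 surface charge.
#'
#' @param diameter_nm Pore diameter in nm (> 0).
#' @param thickness_nm Membrane thickness in nm (> 0).
#' @param surface_charge_C_per_m2 Signed areal charge density in C/m^2.
#' @return An object of class `pore_spec`.
#' @export
pore_spec <- function(diameter_nm = 20, thickness_nm = 20,
                      surface_charge_C_per_m2 = -0.02) {
  if (!is.numeric(diameter_nm) || diameter_nm <= 0)
    stop("pore diameter must be > 0")
  if (!is.numeric(thickness_nm) || thickness_nm <= 0)
    stop("pore thickness must be > 0")
  structure(list(diameter_nm = diameter_nm, thickness_nm = thickness_nm,
                 surface_charge_C_per_m2 = surface_charge_C_per_m2),
            class = "pore_spec")
}

#' Electrolyte specification
#'
#' Defaults describe 100 mM KCl at room temperature: bulk conductivity
#' 1.28 S/m and potassium mobility 7.62e-8 m^2/(V s).
#'
#' @param kcl_mM KCl concentration in mM.
#' @param bulk_conductivity_S_per_m Bulk conductivity in S/m.
#' @param cation_mobility_m2_per_Vs Cation mobility in m^2/(V s).
#' @return An object of class `electrolyte`.
#' @export
electrolyte <- function(kcl_mM = 100, bulk_conductivity_S_per_m = 1.28,
                        cation_mobility_m2_per_Vs = 7.62e-8) {
  vals <- c(kcl_mM, bulk_conductivity_S_per_m, cation_mobility_m2_per_Vs)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all electrolyte fields must be positive")
  structure(list(kcl_mM = kcl_mM,
                 bulk_conductivity_S_per_m = bulk_conductivity_S_per_m,
                 cation_mobility_m2_per_Vs = cation_mobility_m2_per_Vs),
            class = "electrolyte")
}

#' Background-noise power spectral density parameters
#'
#' One-sided PSD with four components, dominant in this order from low to
#' high frequency: flicker (`a_flicker / f^beta`), electrode
#' (`a_electrode / f^gamma`), white thermal (`a_white`) and dielectric
#' (`a_dielectric * f`). Default coefficients place the dominance
#' crossovers near 20 Hz, 200 Hz and 2 kHz inside a [1 Hz, 5 kHz] band and
#' integrate to about 0.02 nA RMS; the absolute level is rescaled per
#' generated trace to hit the requested SNR, so only the spectral shape
#' matters downstream.
#'
#' @param a_flicker,beta Flicker coefficient (nA^2/Hz * Hz^beta) and exponent.
#' @param a_electrode,gamma Electrode coefficient and exponent.
#' @param a_white White (flat) level in nA^2/Hz.
#' @param a_dielectric Dielectric coefficient (nA^2/Hz^2).
#' @param f_min_Hz,f_max_Hz Integration band; `f_min_Hz > 0` keeps the
#'   flicker integral finite.
#' @return An object of class `noise_psd_params`.
#' @export
noise_psd_params <- function(a_flicker = 1.85e-6, beta = 1,
                             a_electrode = 4.1e-7, gamma = 0.5,
                             a_white = 2.9e-8, a_dielectric = 1.46e-11,
                             f_min_Hz = 1, f_max_Hz = 5000) {
  co <- c(a_flicker, a_electrode, a_white, a_dielectric)
  if (any(co < 0)) stop("PSD coefficients must be >= 0")
  if (!(f_min_Hz > 0 && f_max_Hz > f_min_Hz))
    stop("need 0 < f_min_Hz < f_max_Hz")
  structure(list(a_flicker = a_flicker, beta = beta,
                 a_electrode = a_electrode, gamma = gamma,
                 a_white = a_white, a_dielectric = a_dielectric,
                 f_min_Hz = f_min_Hz, f_max_Hz = f_max_Hz),
            class = "noise_psd_params")
}

#' Signal-to-noise specification
#'
#' SNR is the ratio of spike amplitude to the peak-to-peak background
#' noise, with peak-to-peak estimated as `p2p_factor` (default 6) times the
#' noise RMS.
#'
#' @param snr Target SNR (> 0, may be `Inf` for noise-free data).
#' @param p2p_factor RMS-to-peak-to-peak multiplier.
#' @return An object of class `snr_spec`.
#' @export
snr_spec <- function(snr = 4, p2p_factor = 6) {
  if (!(snr > 0)) stop("snr must be > 0")
  if (!(p2p_factor > 0)) stop("p2p_factor must be > 0")
  structure(list(snr = snr, p2p_factor = p2p_factor), class = "snr_spec")
}

#' Effective pore conductivity
#'
#' Bulk conductivity plus a surface-conduction term,
#' `kappa_eff = kappa_bulk + 4 * mu * |sigma| / d`, with `d` the pore
#' diameter. Reduces to the bulk value for an uncharged pore or a very
#' wide pore.
#'
#' @param pore A [pore_spec()].
#' @param elec An [electrolyte()].
#' @return Effective conductivity in S/m.
#' @export
effective_conductivity <- function(pore, elec) {
  stopifnot(inherits(pore, "pore_spec"), inherits(elec, "electrolyte"))
  d_m <- pore$diameter_nm * 1e-9
  elec$bulk_conductivity_S_per_m +
    4 * elec$cation_mobility_m2_per_Vs *
      abs(pore$surface_charge_C_per_m2) / d_m
}

#' Open-pore (baseline) current
#'
#' Series resistance of a cylindrical pore body plus access resistance:
#' `R = (4 L / (pi d^2) + 1 / d) / kappa_eff`; the open-pore current is
#' `I0 = V / R`, linear in the bias voltage.
#'
#' @param pore A [pore_spec()].
#' @param elec An [electrolyte()].
#' @param bias_V Bias voltage in volts.
#' @return Open-pore current in nA.
#' @export
open_pore_current <- function(pore, elec, bias_V = 0.3) {
  stopifnot(is.finite(bias_V))
  kappa <- effective_conductivity(pore, elec)
  if (kappa <= 0) stop("effective conductivity must be > 0")
  d <- pore$diameter_nm * 1e-9
  L <- pore$thickness_nm * 1e-9
  R <- (4 * L / (pi * d^2) + 1 / d) / kappa
  bias_V / R * 1e9
}

#' Steric blockade amplitude
#'
#' Current drop caused by a sphere of diameter `d_np` inside the pore,
#' from the relative resistance change of the partially blocked channel:
#' `dI = I0 * d_np^3 / (d^2 * (L + 0.8 d))` with an effective channel
#' length `L + 0.8 d` accounting for access regions. Strictly increasing
#' in the sphere diameter.
#'
#' @param pore A [pore_spec()].
#' @param d_np_nm Nanosphere diameter in nm, must be smaller than the pore.
#' @param i0_nA Open-pore current in nA.
#' @return Blockade amplitude in nA (positive magnitude).
#' @export
blockade_amplitude <- function(pore, d_np_nm, i0_nA) {
  stopifnot(inherits(pore, "pore_spec"))
  if (any(d_np_nm <= 0)) stop("nanosphere diameter must be > 0")
  if (any(d_np_nm >= pore$diameter_nm))
    stop("nanosphere does not translocate: diameter >= pore diameter")
  d <- pore$diameter_nm
  L <- pore$thickness_nm
  i0_nA * d_np_nm^3 / (d^2 * (L + 0.8 * d))
}

#' Evaluate the noise PSD
#'
#' @param params A [noise_psd_params()].
#' @param f_Hz Frequencies (> 0) in Hz.
#' @return One-sided PSD values in nA^2/Hz.
#' @export
noise_psd <- function(params, f_Hz) {
  stopifnot(inherits(params, "noise_psd_params"))
  if (any(f_Hz <= 0)) stop("frequency must be > 0")
  params$a_flicker / f_Hz^params$beta +
    params$a_electrode / f_Hz^params$gamma +
    params$a_white +
    params$a_dielectric * f_Hz
}

#' Band-integrated noise RMS
#'
#' Square root of the PSD integrated over `[f_min_Hz, f_max_Hz]` by
#' adaptive quadrature.
#'
#' @param params A [noise_psd_params()].
#' @return RMS in nA.
#' @export
noise_rms <- function(params) {
  stopifnot(inherits(params, "noise_psd_params"))
  if (params$beta >= 1 && params$f_min_Hz <= 0)
    stop("flicker integral diverges at f_min = 0")
  v <- stats::integrate(function(f) noise_psd(params, f),
                        params$f_min_Hz, params$f_max_Hz,
                        rel.tol = 1e-10, subdivisions = 1000L)$value
  sqrt(v)
}

#' Noise scale factor for a target SNR
#'
#' Returns the multiplier `s` applied to unit-calibration noise so that
#' `amplitude / (p2p_factor * s * base_rms) = snr`.
#'
#' @param target An [snr_spec()].
#' @param spike_amplitude_nA Blockade amplitude of the generating condition.
#' @param base_rms_nA RMS of the unscaled noise.
#' @return Dimensionless scale factor (0 when `snr = Inf`).
#' @export
snr_noise_scale <- function(target, spike_amplitude_nA, base_rms_nA) {
  stopifnot(inherits(target, "snr_spec"))
  if (base_rms_nA <= 0) stop("base RMS must be > 0")
  if (spike_amplitude_nA <= 0) stop("spike amplitude must be > 0")
  if (is.infinite(target$snr)) return(0)
  spike_amplitude_nA / (target$p2p_factor * target$snr * base_rms_nA)
}
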