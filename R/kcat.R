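# Turnover-number engine: SASA scaling, per-site conversion, temperature.

#' Default turnover-number parameters
#'
#' The mean enzyme turnover rate is 234,000 per day, anchored to a generic
#' bacterial enzyme of 283 residues and 31.09 kDa; enzyme-specific values
#' are scaled from it by solvent-accessible surface area. Rubisco is the
#' exception with measured per-active-site rates: 3.7 s^-1 per site for
#' form I (L8S8) and 6.6 s^-1 per site for form II (L2).
#'
#' @param kcat_mean mean turnover number, day^-1.
#' @param mw_mean molecular weight anchoring the mean, kDa.
#' @param rubisco_I_kcat,rubisco_II_kcat per-active-site rates, s^-1.
#' @return object of class \code{kcat_defaults}.
#' @export
kcat_defaults <- function(kcat_mean = 234000, mw_mean = 31.09,
                          rubisco_I_kcat = 3.7, rubisco_II_kcat = 6.6) {
  stopifnot(kcat_mean > 0, mw_mean > 0,
            rubisco_I_kcat > 0, rubisco_II_kcat > 0)
  structure(
    list(kcat_mean = kcat_mean, mw_mean = mw_mean,
         rubisco_I_kcat = rubisco_I_kcat, rubisco_II_kcat = rubisco_II_kcat),
    class = "kcat_defaults"
  )
}

#' Solvent-accessible surface area proxy
#'
#' SASA is approximated as molecular weight to the 3/4 power. The proxy is
#' only ever used as a ratio, so its absolute units are immaterial.
#'
#' @param mw molecular weight in kDa; must be positive.
#' @return \code{mw^(3/4)}.
#' @examples
#' sasa(16)  # 8
#' @export
sasa <- function(mw) {
  if (any(!is.finite(mw)) || any(mw <= 0)) stop("mw must be positive")
  mw^0.75
}

#' Assign a turnover number from molecular weight
#'
#' \code{kcat = kcat_mean * SASA(mw) / SASA(mw_mean)}: larger complexes
#' expose more catalytic surface and receive proportionally larger
#' turnover numbers. The scaling is exact at the anchor: an enzyme at the
#' mean molecular weight receives exactly the mean kcat, and a 16-fold
#' mass increase yields an 8-fold kcat increase.
#'
#' @param mw molecular weight in kDa.
#' @param defaults a [kcat_defaults()] object.
#' @return turnover number in day^-1 (vectorised over \code{mw}).
#' @examples
#' assign_kcat(31.09)            # 234000
#' assign_kcat(16 * 31.09)       # 8 * 234000
#' @export
assign_kcat <- function(mw, defaults = kcat_defaults()) {
  if (!inherits(defaults, "kcat_defaults")) stop("defaults must be kcat_defaults()")
  defaults$kcat_mean * sasa(mw) / sasa(defaults$mw_mean)
}

#' Convert a per-active-site rate to an enzyme-level daily turnover
#'
#' Multiplies the per-site rate (s^-1) by the number of active sites and
#' by 86,400 s/day. The model couples whole complexes to flux, so a
#' measured per-site rate must be raised to the complex level: form I
#' rubisco carries eight active large subunits, form II two.
#'
#' @param kcat_site per-active-site rate, s^-1; positive.
#' @param active_sites number of active sites; at least 1.
#' @return enzyme-level turnover in day^-1.
#' @examples
#' convert_per_site_kcat(6.6, 2)   # form II rubisco
#' @export
convert_per_site_kcat <- function(kcat_site, active_sites) {
  if (any(kcat_site <= 0)) stop("kcat_site must be positive")
  if (any(active_sites < 1)) stop("active_sites must be >= 1")
  kcat_site * active_sites * 86400
}

#' Temperature scale for Arrhenius adjustment of turnover numbers
#'
#' @param T_ref reference temperature, K.
#' @param activation_energy apparent activation energy, kJ/mol. Not a
#'   measured quantity for these enzymes; the default 50 kJ/mol is a
#'   typical enzymatic value used only for qualitative scans.
#' @param gas_constant kJ/(mol K).
#' @return object of class \code{temperature_scale}.
#' @export
temperature_scale <- function(T_ref = 303, activation_energy = 50,
                              gas_constant = 0.008314) {
  stopifnot(T_ref > 0, activation_energy >= 0, gas_constant > 0)
  structure(list(T_ref = T_ref, activation_energy = activation_energy,
                 gas_constant = gas_constant),
            class = "temperature_scale")
}

#' Arrhenius adjustment of a turnover number
#'
#' \code{kcat(T) = kcat_ref * exp(-(Ea/R) (1/T - 1/T_ref))}; the identity
#' holds at the reference temperature and cooling always lowers kcat.
#' Because the factor is shared, the adjustment is multiplicative and
#' preserves the kcat ordering across enzymes at any fixed temperature.
#'
#' @param kcat_ref turnover at the reference temperature, day^-1.
#' @param T temperature in K; positive.
#' @param scale a [temperature_scale()] object.
#' @return adjusted turnover, day^-1.
#' @export
temperature_scale_kcat <- function(kcat_ref, T, scale = temperature_scale()) {
  if (any(T <= 0)) stop("temperature must be positive (K)")
  kcat_ref * exp(-(scale$activation_energy / scale$gas_constant) *
                   (1 / T - 1 / scale$T_ref))
}
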