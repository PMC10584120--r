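#' Seawater CO2-system equilibrium constants
#'
#' Standard surface-pressure formulations: K1/K2 from the Mehrbach refit of
#' Lueker et al. (2000, total scale), K0 from Weiss (1974), KB from Dickson
#' (1990b), KW from Millero (1995), KS from Dickson (1990a, free scale), KF
#' from Perez & Fraga (1987), and calcite/aragonite solubility products from
#' Mucci (1983). Total boron follows Lee et al. (2010); sulfate, fluoride and
#' calcium are proportional to salinity (Morris & Riley; Riley; Riley &
#' Tongudai). K1, K2, KB and KW are returned on the total hydrogen-ion scale;
#' KS and KF on the free scale.
#'
#' @param temperature Temperature, deg C (valid -2 to 40).
#' @param salinity Salinity, PSU (valid 0 to 45, exclusive).
#' @return List of class \code{"carb_constants"}: \code{K0} (mol/kg/atm),
#'   \code{K1}, \code{K2}, \code{KB}, \code{KW}, \code{KS}, \code{KF}
#'   (mol/kg), \code{Ksp_calcite}, \code{Ksp_aragonite} (mol^2/kg^2), total
#'   boron/sulfate/fluoride/calcium (mol/kg), the CO2 fugacity factor, and
#'   the inputs.
#' @export
equilibrium_constants <- function(temperature, salinity) {
  if (!is.finite(temperature) || temperature < -2 || temperature > 40) {
    stop("'temperature' out of range [-2, 40] degC", call. = FALSE)
  }
  if (!is.finite(salinity) || salinity <= 0 || salinity >= 45) {
    stop("'salinity' out of range (0, 45) PSU", call. = FALSE)
  }
  TK <- temperature + 273.15
  S <- salinity
  lnTK <- log(TK)
  sqS <- sqrt(S)

  # CO2 solubility, mol/kg/atm (Weiss 1974)
  K0 <- exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
              S * (0.023517 - 0.023656 * (TK / 100) +
                     0.0047036 * (TK / 100)^2))

  # carbonic acid, total scale (Lueker et al. 2000)
  pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * lnTK - 0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * lnTK - 0.01781 * S + 0.0001122 * S^2
  K1 <- 10^(-pK1)
  K2 <- 10^(-pK2)

  # boric acid, total scale (Dickson 1990b)
  KB <- exp((-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 -
               0.0996 * S^2) / TK +
              148.0248 + 137.1942 * sqS + 1.62142 * S -
              (24.4344 + 25.085 * sqS + 0.2474 * S) * lnTK +
              0.053105 * sqS * TK)

  # bisulfate, free scale, mol/kg-sw (Dickson 1990a)
  IonS <- 19.924 * S / (1000 - 1.005 * S)
  KS <- exp(-4276.1 / TK + 141.328 - 23.093 * lnTK +
              (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IonS) +
              (35474 / TK - 771.54 + 114.723 * lnTK) * IonS -
              2698 / TK * IonS^1.5 + 1776 / TK * IonS^2 +
              log(1 - 0.001005 * S))

  # totals, mol/kg
  ST <- (0.14 / 96.062) * (S / 1.80655)       # sulfate (Morris & Riley 1966)
  FT <- (0.000067 / 18.998) * (S / 1.80655)   # fluoride (Riley 1965)
  BT <- 0.0004326 * S / 35                    # boron (Lee et al. 2010)
  Ca <- (0.02128 / 40.087) * (S / 1.80655)    # calcium (Riley & Tongudai 1967)

  # hydrogen fluoride (Perez & Fraga 1987; total scale -> free scale)
  KF_total <- exp(874 / TK - 9.68 + 0.111 * sqS)
  free_to_total <- 1 + ST / KS
  KF <- KF_total / free_to_total

  # water, seawater scale (Millero 1995) -> total scale
  KW_sws <- exp(148.9802 - 13847.26 / TK - 23.6521 * lnTK +
                  (-5.977 + 118.67 / TK + 1.0495 * lnTK) * sqS - 0.01615 * S)
  sws_to_total <- free_to_total / (1 + ST / KS + FT / KF)
  KW <- KW_sws * sws_to_total

  # calcium carbonate solubility (Mucci 1983), mol^2/kg^2
  log10Kspc <- -171.9065 - 0.077993 * TK + 2839.319 / TK +
    71.595 * log10(TK) +
    (-0.77712 + 0.0028426 * TK + 178.34 / TK) * sqS -
    0.07711 * S + 0.0041249 * S^1.5
  log10Kspa <- -171.945 - 0.077993 * TK + 2903.293 / TK +
    71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqS -
    0.10018 * S + 0.0059415 * S^1.5

  # CO2 fugacity coefficient at 1 atm total pressure (Weiss 1974)
  delta <- 57.7 - 0.118 * TK
  b_vir <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
  fugfac <- exp((b_vir + 2 * delta) * 1.01325 / (83.14472 * TK))

  structure(list(
    K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS, KF = KF,
    Ksp_calcite = 10^log10Kspc, Ksp_aragonite = 10^log10Kspa,
    BT = BT, ST = ST, FT = FT, Ca = Ca,
    fugacity_factor = fugfac,
    temperature = temperature, salinity = salinity
  ), class = "carb_constants")
}

#' Convert pH between hydrogen-ion concentration scales
#'
#' Free, total (free + bisulfate) and seawater (free + bisulfate + fluoride)
#' scales. The total-scale correction is
#' \code{pH_total = pH_free - log10(1 + ST/KS)}; at open-ocean salinities its
#' magnitude is about 0.1 units.
#'
#' @param ph pH value(s).
#' @param from,to \code{"free"}, \code{"total"}, or \code{"seawater"}.
#' @param constants A [equilibrium_constants()] set.
#' @return Converted pH.
#' @export
ph_scale_convert <- function(ph, from, to, constants) {
  scales <- c("free", "total", "seawater")
  if (!(from %in% scales) || !(to %in% scales)) {
    stop("pH scales must be one of: ", paste(scales, collapse = ", "),
         call. = FALSE)
  }
  fac <- function(scale) {
    switch(scale,
           free = 1,
           total = 1 + constants$ST / constants$KS,
           seawater = 1 + constants$ST / constants$KS +
             constants$FT / constants$KF)
  }
  # H on 'from' scale -> free H -> 'to' scale
  ph - log10(fac(to) / fac(from))
}

# Total alkalinity (mol/kg) from total-scale H and DIC (mol/kg).
total_alkalinity <- function(h_total, dic, k) {
  denom <- 1 + k$K1 / h_total + k$K1 * k$K2 / h_total^2
  co2 <- dic / denom
  hco3 <- co2 * k$K1 / h_total
  co3 <- hco3 * k$K2 / h_total
  h_free <- h_total / (1 + k$ST / k$KS)
  balk <- k$BT * k$KB / (k$KB + h_total)
  oh <- k$KW / h_total
  hso4 <- k$ST * h_free / (k$KS + h_free)
  hf <- k$FT * h_free / (k$KF + h_free)
  hco3 + 2 * co3 + balk + oh - h_free - hso4 - hf
}

build_state <- function(h_total, dic, k) {
  denom <- 1 + k$K1 / h_total + k$K1 * k$K2 / h_total^2
  co2 <- dic / denom
  hco3 <- co2 * k$K1 / h_total
  co3 <- hco3 * k$K2 / h_total
  fco2 <- co2 / k$K0                      # atm
  pco2 <- fco2 / k$fugacity_factor * 1e6  # uatm
  om <- omega(co3 * 1e3, k$salinity, k)
  ph_total <- -log10(h_total)
  structure(list(
    pco2 = pco2, fco2 = fco2 * 1e6,
    co2 = co2 * 1e3, hco3 = hco3 * 1e3, co3 = co3 * 1e3,  # mmol/kg
    dic = dic * 1e3,
    ta = total_alkalinity(h_total, dic, k) * 1e3,
    ph_total = ph_total,
    ph_free = ph_scale_convert(ph_total, "total", "free", k),
    ph_seawater = ph_scale_convert(ph_total, "total", "seawater", k),
    omega_aragonite = om[["aragonite"]], omega_calcite = om[["calcite"]],
    temperature = k$temperature, salinity = k$salinity
  ), class = "carbonate_state")
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf("Carbonate state at T = %.2f degC, S = %.1f\n",
              x$temperature, x$salinity))
  cat(sprintf("  pH: %.3f free / %.3f total;  pCO2 = %.1f uatm\n",
              x$ph_free, x$ph_total, x$pco2))
  cat(sprintf("  DIC = %.3f, HCO3 = %.3f, CO3 = %.4f, TA = %.3f mmol/kg\n",
              x$dic, x$hco3, x$co3, x$ta))
  cat(sprintf("  Omega: aragonite %.2f, calcite %.2f\n",
              x$omega_aragonite, x$omega_calcite))
  invisible(x)
}

#' Solve the CO2 system from free-scale pH and DIC
#'
#' Closed-form speciation: pH is converted to the total scale, the DIC is
#' partitioned into CO2*, bicarbonate and carbonate (so the mass balance
#' \code{CO2* + HCO3 + CO3 = DIC} holds by construction), pCO2 follows from
#' Henry's law with a fugacity correction, total alkalinity from the
#' carbonate, borate, water and minor acid-base species, and saturation
#' states from the carbonate ion and the solubility products.
#'
#' @param ph_free pH on the free scale, in \code{[4, 10]}.
#' @param dic Dissolved inorganic carbon, mmol/kg.
#' @param temperature Temperature, deg C.
#' @param salinity Salinity, PSU (default 32; not reported with the study's
#'   chemistry tables, so it is an explicit, reported assumption).
#' @param constants Optional precomputed [equilibrium_constants()].
#' @return Object of class \code{"carbonate_state"}: \code{pco2} (uatm),
#'   \code{co2}, \code{hco3}, \code{co3}, \code{dic}, \code{ta} (mmol/kg),
#'   pH on the free/total/seawater scales, and \code{omega_aragonite} /
#'   \code{omega_calcite}.
#' @examples
#' solve_from_ph_dic(7.50, dic = 2.15, temperature = 2.05, salinity = 32)
#' @export
solve_from_ph_dic <- function(ph_free, dic, temperature, salinity = 32,
                              constants = NULL) {
  if (!is.finite(ph_free) || ph_free < 4 || ph_free > 10) {
    stop("'ph_free' must be in [4, 10]", call. = FALSE)
  }
  if (dic < 0) stop("'dic' must be >= 0", call. = FALSE)
  k <- constants %||% equilibrium_constants(temperature, salinity)
  ph_total <- ph_scale_convert(ph_free, "free", "total", k)
  build_state(10^(-ph_total), dic * 1e-3, k)
}

#' Solve the CO2 system from total alkalinity and DIC
#'
#' Root-finds the total-scale pH in \code{[4, 10]} at which the modelled
#' alkalinity matches the measured value (to better than 1e-10 mol/kg; TA is
#' strictly increasing in pH at fixed DIC, so the root is unique), then
#' completes the speciation as in [solve_from_ph_dic()].
#'
#' @param ta Total alkalinity, mmol/kg.
#' @param dic Dissolved inorganic carbon, mmol/kg.
#' @inheritParams solve_from_ph_dic
#' @return A \code{"carbonate_state"} object.
#' @export
solve_from_ta_dic <- function(ta, dic, temperature, salinity = 32,
                              constants = NULL) {
  if (ta <= 0 || dic <= 0) stop("'ta' and 'dic' must be > 0", call. = FALSE)
  k <- constants %||% equilibrium_constants(temperature, salinity)
  ta_mol <- ta * 1e-3
  dic_mol <- dic * 1e-3
  f <- function(ph) total_alkalinity(10^(-ph), dic_mol, k) - ta_mol
  lo <- f(4); hi <- f(10)
  if (sign(lo) == sign(hi)) {
    stop(sprintf(paste0("no pH root in [4, 10] for TA = %g, DIC = %g mmol/kg ",
                        "(TA residual %.3g at pH 4, %.3g at pH 10)"),
                 ta, dic, lo, hi), call. = FALSE)
  }
  root <- stats::uniroot(f, c(4, 10), tol = 1e-13)
  ph <- root$root
  # polish with bisection-free Newton steps until |dTA| < 1e-10 mol/kg
  for (i in 1:20) {
    res <- f(ph)
    if (abs(res) < 1e-10) break
    dres <- (f(ph + 1e-6) - res) / 1e-6
    ph <- ph - res / dres
  }
  build_state(10^(-ph), dic_mol, k)
}

#' Calcium carbonate saturation states
#'
#' \eqn{\Omega = [Ca^{2+}][CO_3^{2-}]/K_{sp}} for aragonite and calcite, with
#' calcium proportional to salinity. Calcite is always the more saturated
#' phase (\code{Ksp_calcite < Ksp_aragonite}).
#'
#' @param co3 Carbonate ion concentration, mmol/kg (>= 0).
#' @param salinity Salinity, PSU.
#' @param constants Optional [equilibrium_constants()] set (must match
#'   \code{salinity} if supplied).
#' @param temperature Temperature used if \code{constants} is not supplied.
#' @return Named vector \code{c(aragonite = , calcite = )}.
#' @export
omega <- function(co3, salinity = 32, constants = NULL, temperature = 2) {
  if (any(co3 < 0)) stop("'co3' must be >= 0", call. = FALSE)
  k <- constants %||% equilibrium_constants(temperature, salinity)
  co3_mol <- co3 * 1e-3
  c(aragonite = k$Ca * co3_mol / k$Ksp_aragonite,
    calcite = k$Ca * co3_mol / k$Ksp_calcite)
}

#' Derived water-chemistry table for a monitoring series
#'
#' Summarises a [gen_water_series()]-style record set the way experiment
#' chemistry tables are reported: mean +- SD of the measured daily pH and
#' temperature and weekly DIC, plus derived pCO2, bicarbonate, carbonate,
#' alkalinity and saturation states computed from the mean measured
#' conditions.
#'
#' @param water Data frame as returned by [gen_water_series()].
#' @param salinity Salinity used for the solve.
#' @return One-row data frame with the table's column set.
#' @export
water_chemistry_summary <- function(water, salinity = 32) {
  daily <- water[water$type == "daily", ]
  weekly <- water[water$type == "weekly", ]
  st <- solve_from_ph_dic(mean(daily$ph_free), mean(weekly$dic),
                          mean(daily$temperature), salinity)
  data.frame(
    temperature = mean(daily$temperature), temperature_sd = sd(daily$temperature),
    ph_free = mean(daily$ph_free), ph_free_sd = sd(daily$ph_free),
    pco2 = st$pco2, hco3 = st$hco3, co3 = st$co3,
    dic = mean(weekly$dic), dic_sd = sd(weekly$dic),
    alkalinity = st$ta,
    omega_aragonite = st$omega_aragonite, omega_calcite = st$omega_calcite
  )
}
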