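#' Alveolar oxygen tension (alveolar gas equation)
#'
#' PAO2 = FiO2 * (Pb - PH2O) - PaCO2 / RQ, floored at 1 mmHg.
#'
#' @param fio2 inspired O2 fraction.
#' @param paco2 arterial CO2 tension, mmHg (> 0).
#' @param pb barometric pressure, mmHg.
#' @param ph2o water vapor pressure, mmHg.
#' @param rq respiratory quotient.
#' @return mmHg.
#' @export
#' @examples
#' alveolar_po2(1.0, 80)   # 613
#' alveolar_po2(0.21, 40)  # 99.73
alveolar_po2 <- function(fio2, paco2, pb = 760, ph2o = 47, rq = 0.8) {
  stopifnot(paco2 > 0)
  max(1, fio2 * (pb - ph2o) - paco2 / rq)
}

#' Severinghaus oxyhemoglobin dissociation curve
#'
#' SO2 = 1 / (23400 / (PO2^3 + 150 PO2) + 1). Strictly increasing, bounded
#' in (0, 1), accurate near both asymptotes.
#'
#' @param po2 oxygen tension, mmHg (> 0). Vectorized.
#' @return hemoglobin O2 saturation, fraction.
#' @export
severinghaus_so2 <- function(po2) {
  stopifnot(all(po2 > 0))
  1 / (23400 / (po2^3 + 150 * po2) + 1)
}

#' Arterial oxygen content
#'
#' CxO2 = 1.34 * Hb * SO2(PO2) + 0.003 * PO2, mL O2 / dL.
#'
#' @param po2 mmHg.
#' @param hb hemoglobin, g/dL.
#' @return mL O2/dL.
#' @export
o2_content <- function(po2, hb) {
  1.34 * hb * severinghaus_so2(po2) + 0.003 * po2
}

#' Arterial PO2 under venous admixture (Berggren shunt)
#'
#' Solves the content-mixing balance CaO2 = shunt * CvO2 + (1 - shunt) * CcO2
#' with end-capillary PO2 equal to alveolar PO2 and mixed-venous content from
#' the Fick principle, CvO2 = CaO2 - VO2 / (10 CO). Eliminating CvO2 gives
#' CaO2 = CcO2 - shunt/(1-shunt) * VO2/(10 CO); arterial PO2 is recovered by
#' numerically inverting the content curve (monotone root find, tolerance
#' well below 0.1 mmHg).
#'
#' @param shunt perfusion fraction bypassing ventilated lung, in [0, 1).
#' @param pao2_alv alveolar (= end-capillary) PO2, mmHg.
#' @param hb hemoglobin, g/dL.
#' @param co cardiac output, L/min (> 0).
#' @param vo2 oxygen consumption, mL/min.
#' @return arterial PO2, mmHg.
#' @export
#' @examples
#' shunt_pao2(0, 613, 10, 4, 200)    # no admixture: alveolar PO2
#' shunt_pao2(0.5, 613, 10, 4, 200)  # severe admixture
shunt_pao2 <- function(shunt, pao2_alv, hb, co, vo2) {
  stopifnot(shunt >= 0, shunt < 1, co > 0, pao2_alv > 0)
  if (shunt == 0) return(pao2_alv)
  cc <- o2_content(pao2_alv, hb)
  ca <- cc - shunt / (1 - shunt) * vo2 / (10 * co)
  lo <- 3
  ca <- max(ca, o2_content(lo, hb)) # physiological floor: content cannot go negative
  if (ca >= cc) return(pao2_alv)
  root <- tryCatch(
    uniroot(function(p) o2_content(p, hb) - ca, c(lo, pao2_alv), tol = 1e-4),
    error = function(e) stop("shunt_pao2: content inversion failed (shunt=", shunt,
                             ", PAO2=", pao2_alv, ", CaO2=", signif(ca, 4), "): ",
                             conditionMessage(e))
  )
  root$root
}

#' Arterial CO2 tension from alveolar ventilation
#'
#' PaCO2 = 863 * VCO2 / VA, capped to [10, 200] mmHg.
#'
#' @param vco2 CO2 production, mL/min.
#' @param va alveolar ventilation, mL/min (> 0).
#' @return mmHg.
#' @export
#' @examples
#' paco2_from_ventilation(160, 5800) # 23.8
paco2_from_ventilation <- function(vco2, va) {
  if (!is.numeric(va) || va <= 0) stop("alveolar ventilation must be positive")
  min(200, max(10, 863 * vco2 / va))
}

#' Henderson-Hasselbalch arterial pH
#'
#' pH = 6.1 + log10(HCO3 / (0.03 * PaCO2)). Bicarbonate is held fixed in the
#' simulator (no metabolic compensation on the experiment's time scale), so
#' pH is a deterministic function of PaCO2.
#'
#' @param paco2 mmHg (> 0).
#' @param hco3 mmol/L (> 0).
#' @return pH units.
#' @export
#' @examples
#' ph_from_paco2(40, 24) # 7.40
ph_from_paco2 <- function(paco2, hco3 = 24) {
  stopifnot(paco2 > 0, hco3 > 0)
  6.1 + log10(hco3 / (0.03 * paco2))
}

#' Systemic oxygen delivery
#'
#' DO2 = CaO2 * CO * 10.
#'
#' @param pao2 arterial PO2, mmHg.
#' @param hb hemoglobin, g/dL.
#' @param co cardiac output, L/min.
#' @return mL O2/min.
#' @export
oxygen_delivery <- function(pao2, hb, co) {
  stopifnot(pao2 > 0, hb > 0, co > 0)
  o2_content(pao2, hb) * co * 10
}

#' Blood gas for a realized breath
#'
#' Quasi-steady gas exchange from the breath's aeration bookkeeping.
#' Effective shunt is the hypoxic-vasoconstriction-attenuated perfusion to
#' non-participating units: consolidated and never-opened units count fully,
#' cyclically open units (aerated only during inspiration) at
#' `cyclic_shunt_weight`, consolidated units at `consolidated_shunt_weight`
#' (vascular destruction diverts their perfusion). The physiological
#' dead-space fraction is the airway dead space plus terms growing with
#' derecruitment, consolidation, overdistension (sigmoid factor and excess
#' tidal strain), lavage-induced surfactant dysfunction, and PEEP above
#' `deadspace_peep_onset` (alveolar vessel compression), capped at 0.92.
#'
#' @param pig a `pig` object.
#' @param record breath record from [step_breath()].
#' @return object of class `blood_gas`: pao2, paco2, ph, sao2, spo2,
#'   pf_ratio, co, do2, shunt, vd_frac.
#' @export
blood_gas <- function(pig, record) {
  g <- pig$params$gas
  inj <- pig$params$injury
  # consolidated regions lose perfusion beyond acute HPV (vascular destruction
  # and chronic diversion), so they carry a lower shunt weight than acutely
  # collapsed units
  shunt <- inj$shunt_hpv_factor *
    (inj$consolidated_shunt_weight * record[["frac_consolidated"]] +
       record[["frac_never"]] +
       inj$cyclic_shunt_weight * record[["frac_cyclic"]])
  shunt <- min(shunt, 0.95)
  vt <- record[["vt_ml"]]
  vd_frac <- min(0.92, pig$vd_aw / max(vt, 1) + pig$vd_alv_frac +
                   g$deadspace_gain_aeration * (1 - record[["frac_open_exp"]]) +
                   g$deadspace_gain_consolidation * record[["frac_consolidated"]] +
                   g$deadspace_gain_overdistension * (1 - record[["s_od"]]) +
                   g$deadspace_gain_strain * max(0, record[["strain"]] - 1) +
                   g$deadspace_gain_peep * max(0, record[["peep"]] - g$deadspace_peep_onset))
  vd_frac <- max(vd_frac, pig$vd_aw / max(vt, 1))
  va <- record[["rr"]] * vt * (1 - vd_frac)
  paco2 <- paco2_from_ventilation(pig$vco2, max(va, 1))
  ph <- ph_from_paco2(paco2, pig$hco3)
  pao2_alv <- alveolar_po2(record[["fio2"]], paco2, g$pb, g$ph2o, g$rq)
  co <- cardiac_output(pig, record[["peep"]])
  pao2 <- shunt_pao2(shunt, pao2_alv, pig$hb, co, pig$vo2)
  sao2 <- severinghaus_so2(pao2)
  structure(list(
    pao2 = pao2, paco2 = paco2, ph = ph, sao2 = sao2, spo2 = sao2,
    pf_ratio = pao2 / record[["fio2"]], co = co,
    do2 = oxygen_delivery(pao2, pig$hb, co), shunt = shunt, vd_frac = vd_frac
  ), class = "blood_gas")
}

#' @export
print.blood_gas <- function(x, ...) {
  cat(sprintf(
    "<blood gas> PaO2 %.0f mmHg, PaCO2 %.0f mmHg, pH %.2f, SpO2 %.0f%%, P/F %.0f, CO %.1f L/min, DO2 %.0f mL/min\n",
    x$pao2, x$paco2, x$ph, 100 * x$spo2, x$pf_ratio, x$co, x$do2
  ))
  invisible(x)
}
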