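# Absorbed dose per unit activity: 1 GBq of Y-90 distributed uniformly in
# 1 kg of tissue delivers 49.67 Gy (pure beta emitter, local deposition).
Y90_GY_PER_GBQ_PER_KG <- 49.67

# Intended single-treatment lung mean-dose limit, Gy.
LUNG_DOSE_LIMIT_GY <- 25

#' MIRD lung mean absorbed dose
#'
#' `D_mean = 49.67 * LSF * activity(GBq) / mass(kg)`, the MIRD-formalism
#' lung mean dose for Y-90 microspheres, where 49.67 Gy is the absorbed dose
#' of 1 GBq distributed uniformly through 1 kg of tissue. Masses are
#' accepted in grams at the interface and converted internally. The
#' `within_limit` flag compares against the 25 Gy single-treatment limit
#' (inclusive: exactly 25 Gy passes).
#'
#' Methodology conventions: `"planar"` uses the planar LSF with the standard
#' 1000 g lung mass assumption; `"spectct"` pairs SPECT/CT LSF with SPECT/CT
#' densitovolumetric mass; `"reference"` pairs SPECT/CT LSF with
#' diagnostic-CT densitovolumetric mass. The planar methodology therefore
#' forces `lung_mass_g = 1000`.
#'
#' @param lsf Lung shunt fraction in \[0, 1\].
#' @param activity_gbq Injected activity in GBq (> 0).
#' @param lung_mass_g Lung parenchyma mass in grams (> 0); forced to 1000
#'   for the planar methodology.
#' @param methodology `"planar"`, `"spectct"` or `"reference"`.
#' @param limit_gy Dose limit in Gy (default 25).
#' @return A one-row tibble: `methodology`, `lsf`, `activity_gbq`,
#'   `lung_mass_g`, `d_mean_gy`, `within_limit`.
#' @examples
#' lung_mean_dose(1, 1, 1000)      # the coefficient itself: 49.67 Gy
#' lung_mean_dose(0.0596, 1.65, 822, methodology = "reference")
#' @export
lung_mean_dose <- function(lsf, activity_gbq, lung_mass_g = 1000,
                           methodology = c("spectct", "planar", "reference"),
                           limit_gy = LUNG_DOSE_LIMIT_GY) {
  methodology <- match.arg(methodology)
  if (!is.finite(lsf) || lsf < 0 || lsf > 1) {
    stop("`lsf` must lie in [0, 1]", call. = FALSE)
  }
  if (activity_gbq <= 0) stop("`activity_gbq` must be positive", call. = FALSE)
  if (methodology == "planar") {
    lung_mass_g <- 1000
  }
  if (lung_mass_g <= 0) stop("`lung_mass_g` must be positive", call. = FALSE)
  d <- Y90_GY_PER_GBQ_PER_KG * lsf * activity_gbq / (lung_mass_g / 1000)
  tibble::tibble(
    methodology = methodology,
    lsf = lsf,
    activity_gbq = activity_gbq,
    lung_mass_g = lung_mass_g,
    d_mean_gy = d,
    within_limit = d <= limit_gy
  )
}

#' Maximum injectable activity for a lung dose limit
#'
#' Inverse of the MIRD lung dose formula for treatment planning:
#' `activity = limit * mass(kg) / (49.67 * LSF)`. At the returned activity
#' the lung mean dose equals the limit exactly.
#'
#' @param lsf Lung shunt fraction, strictly positive (with a zero shunt the
#'   lung dose is zero at any activity, so no finite maximum exists — this
#'   is signalled as an error rather than `Inf`).
#' @param lung_mass_g Lung parenchyma mass in grams (> 0).
#' @param limit_gy Lung mean-dose limit in Gy (default 25).
#' @return Activity in GBq.
#' @export
max_activity_for_limit <- function(lsf, lung_mass_g, limit_gy = LUNG_DOSE_LIMIT_GY) {
  if (!is.finite(lsf) || lsf <= 0 || lsf > 1) {
    stop("`lsf` must lie in (0, 1]: with no shunt the lung dose does not ",
         "constrain the activity", call. = FALSE)
  }
  if (lung_mass_g <= 0) stop("`lung_mass_g` must be positive", call. = FALSE)
  limit_gy * (lung_mass_g / 1000) / (Y90_GY_PER_GBQ_PER_KG * lsf)
}

#' Lung dose under the three methodologies
#'
#' Computes the lung mean dose for the same treatment under the planar
#' methodology (planar LSF, standard 1000 g mass), the SPECT/CT methodology
#' (SPECT/CT LSF and SPECT/CT densitovolumetric mass), and the reference
#' combination (SPECT/CT LSF with diagnostic-CT densitovolumetric mass).
#'
#' @param planar_lsf,spect_lsf Shunt fractions in \[0, 1\].
#' @param diag_mass_g Diagnostic-CT lung parenchyma mass, g.
#' @param spect_mass_g SPECT/CT lung parenchyma mass, g.
#' @param activity_gbq Injected activity, GBq.
#' @return A three-row tibble (one per methodology), as [lung_mean_dose()].
#' @export
methodology_comparison <- function(planar_lsf, spect_lsf, diag_mass_g,
                                   spect_mass_g, activity_gbq) {
  rbind(
    lung_mean_dose(planar_lsf, activity_gbq, methodology = "planar"),
    lung_mean_dose(spect_lsf, activity_gbq, spect_mass_g, methodology = "spectct"),
    lung_mean_dose(spect_lsf, activity_gbq, diag_mass_g, methodology = "reference")
  )
}
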