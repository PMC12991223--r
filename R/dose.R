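#' Convert dose-area product to effective dose
#'
#' Chest tomosynthesis systems report exposure as the dose-area product
#' (DAP, Gy cm^2) of the examination; the effective dose in mSv is obtained
#' by multiplying the DAP with a Monte-Carlo-derived conversion coefficient.
#' For the VolumeRAD chest geometry and a standard-sized adult the
#' coefficient is 0.26 mSv per Gy cm^2, the package default.
#'
#' @param dap dose-area product(s), Gy cm^2, non-negative.
#' @param coefficient conversion coefficient, mSv per Gy cm^2, positive.
#' @return Effective dose(s) in mSv, exactly `dap * coefficient`.
#' @examples
#' effective_dose(1.0)        # 0.26 mSv
#' effective_dose(2.53)       # mean DAP of a slim-patient group
#' @export
effective_dose <- function(dap, coefficient = 0.26) {
  if (!is.numeric(dap) || anyNA(dap) || any(dap < 0))
    stopf("`dap` must be non-negative")
  if (!is.numeric(coefficient) || length(coefficient) != 1L || coefficient <= 0)
    stopf("`coefficient` must be a single positive number")
  dap * coefficient
}

#' Effective dose of a reduced protocol as a percentage of the reference
#'
#' @param e_reduced effective dose(s) of the dose-reduced protocol, mSv.
#' @param e_reference effective dose of the reference protocol, mSv, > 0.
#' @return Integer percentage(s), `round(100 * e_reduced / e_reference)`
#'   with halves rounded up.
#' @examples
#' percent_vs_reference(0.39, 0.56)  # 70
#' percent_vs_reference(0.45, 1.01)  # 45
#' @export
percent_vs_reference <- function(e_reduced, e_reference) {
  if (!is.numeric(e_reference) || anyNA(e_reference) || any(e_reference <= 0))
    stopf("`e_reference` must be positive")
  if (!is.numeric(e_reduced) || anyNA(e_reduced))
    stopf("`e_reduced` must be numeric")
  as.integer(round_half_up(100 * e_reduced / e_reference))
}

#' Designed exposure fraction of a dose ratio
#'
#' Tomosynthesis exposure is set by a *dose ratio*: the scout-image tube
#' load is multiplied by the ratio and spread over the projection images.
#' Relative to the vendor default of 10, a ratio of 7 aims at a 30% dose
#' reduction and a ratio of 5 at 50%.
#'
#' @param dose_ratio,reference_ratio positive dose-ratio settings.
#' @return `dose_ratio / reference_ratio`, the nominal exposure fraction.
#' @examples
#' nominal_relative_exposure(7, 10)  # 0.7
#' @export
nominal_relative_exposure <- function(dose_ratio, reference_ratio = 10) {
  if (!is.numeric(dose_ratio) || any(dose_ratio <= 0) ||
      !is.numeric(reference_ratio) || any(reference_ratio <= 0))
    stopf("dose ratios must be positive")
  dose_ratio / reference_ratio
}

#' Assign BMI groups
#'
#' Groups follow the conventional cut points: below 25, 25 to 30 inclusive
#' on both ends, and above 30.
#'
#' @param bmi numeric body-mass-index values, kg/m^2, positive.
#' @return Factor with levels `"<25"`, `"25-30"`, `">30"`.
#' @export
bmi_group <- function(bmi) {
  if (!is.numeric(bmi) || anyNA(bmi) || any(bmi <= 0))
    stopf("`bmi` must be positive")
  factor(ifelse(bmi < 25, "<25", ifelse(bmi <= 30, "25-30", ">30")),
         levels = c("<25", "25-30", ">30"))
}

#' Build per-examination dose records
#'
#' @param df data frame (or CSV path with header
#'   `patient,dap_gycm2,dose_ratio,bmi`) holding one row per patient and
#'   dose-ratio setting.
#' @param coefficient DAP-to-effective-dose conversion coefficient,
#'   mSv per Gy cm^2.
#' @return Data frame of class `dose_records` with the input columns plus
#'   `effective_dose` (mSv) and `bmi_group`.
#' @export
dose_records <- function(df, coefficient = 0.26) {
  if (is.character(df) && length(df) == 1L) {
    if (!file.exists(df)) stopf("dose file not found: %s", df)
    df <- utils::read.csv(df, stringsAsFactors = FALSE)
  }
  needed <- c("patient", "dap_gycm2", "dose_ratio", "bmi")
  if (!is.data.frame(df) || !all(needed %in% names(df)))
    stopf("dose records need columns `%s`", paste(needed, collapse = ","))
  if (nrow(df) == 0L) stopf("dose table is empty")
  out <- data.frame(patient = as.character(df$patient),
                    dap_gycm2 = as.numeric(df$dap_gycm2),
                    dose_ratio = as.integer(df$dose_ratio),
                    bmi = as.numeric(df$bmi),
                    stringsAsFactors = FALSE)
  out$effective_dose <- effective_dose(out$dap_gycm2, coefficient)
  out$bmi_group <- bmi_group(out$bmi)
  structure(out, class = c("dose_records", "data.frame"),
            coefficient = coefficient)
}

#' BMI-stratified dose summary
#'
#' For each BMI group and dose-ratio setting, computes the mean and
#' standard deviation of DAP and effective dose, and expresses each reduced
#' ratio's mean effective dose as an integer percentage of the reference
#' ratio's mean within the same group.  Percentages are ratios of group
#' means (not means of per-patient ratios), rounded half-up.
#'
#' @param records a [dose_records()] data frame.
#' @param reference_ratio the dose ratio treated as full dose (default 10);
#'   every BMI group present must contain records at this ratio.
#' @return Data frame with one row per (bmi_group, dose_ratio): `n`,
#'   `mean_dap`, `sd_dap`, `mean_effective_dose`, `sd_effective_dose` and
#'   `percent_vs_reference` (100 for the reference ratio itself).
#' @export
summarize_by_bmi <- function(records, reference_ratio = 10) {
  stopifnot(inherits(records, "dose_records"))
  groups <- levels(droplevels(records$bmi_group))
  out <- list()
  for (g in groups) {
    rg <- records[records$bmi_group == g, , drop = FALSE]
    if (!any(rg$dose_ratio == reference_ratio))
      stopf("BMI group `%s` has no records at reference ratio %d",
            g, reference_ratio)
    e_ref <- mean(rg$effective_dose[rg$dose_ratio == reference_ratio])
    for (r in sort(unique(rg$dose_ratio), decreasing = TRUE)) {
      rr <- rg[rg$dose_ratio == r, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        bmi_group = g, dose_ratio = r, n = nrow(rr),
        mean_dap = mean(rr$dap_gycm2), sd_dap = stats::sd(rr$dap_gycm2),
        mean_effective_dose = mean(rr$effective_dose),
        sd_effective_dose = stats::sd(rr$effective_dose),
        percent_vs_reference =
          percent_vs_reference(mean(rr$effective_dose), e_ref),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$bmi_group <- factor(res$bmi_group, levels = c("<25", "25-30", ">30"))
  res[order(res$bmi_group, -res$dose_ratio), , drop = FALSE]
}
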