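#' Printed per-subject partition coefficients and hematocrits
#'
#' The study's per-subject summary: for each of the ten volunteers, the
#' mean partition coefficient (with SEM over serial measurements) and the
#' same-day hematocrit for the constant-infusion and bolus sessions.
#' Hematocrits are returned as fractions (the source lists percent).
#'
#' @return data frame with one row per subject: `age`, `sex`,
#'   `infusion_lambda`, `infusion_lambda_sem`, `infusion_hct`,
#'   `bolus_lambda`, `bolus_lambda_sem`, `bolus_hct`.
#' @export
subject_table <- function() {
  data.frame(
    age = c(20, 21, 21, 22, 31, 34, 66, 68, 69, 81),
    sex = c("male", "male", "female", "male", "male", "male",
            "female", "female", "male", "male"),
    infusion_lambda = c(0.452, 0.399, 0.434, 0.398, 0.412, 0.437,
                        0.451, 0.453, 0.473, 0.460),
    infusion_lambda_sem = c(0.002, 0.002, 0.004, 0.002, 0.002, 0.001,
                            0.002, 0.002, 0.006, 0.002),
    infusion_hct = c(47.7, 41.2, 39.6, 41.0, 40.4, 42.7,
                     30.0, 38.0, 44.4, 41.2) / 100,
    bolus_lambda = c(0.424, 0.392, 0.424, 0.401, 0.424, 0.448,
                     0.442, 0.461, 0.474, 0.459),
    bolus_lambda_sem = c(0.007, 0.004, 0.004, 0.003, 0.003, 0.002,
                         0.002, 0.003, 0.009, 0.004),
    bolus_hct = c(46.1, 41.9, 38.9, 42.1, 42.3, 41.5,
                  29.8, 38.9, 44.0, 40.4) / 100
  )
}

#' Per-subject Ve from the printed subject table
#'
#' Applies [ve_from_lambda()] to each subject's session-matched partition
#' coefficient and hematocrit for one technique.
#'
#' @param protocol `"infusion"` or `"bolus"`.
#' @param table a data frame in the [subject_table()] layout.
#' @param constants an [ecv_constants()].
#' @return the table with an added `ve` column (fraction).
#' @examples
#' subject_ve("infusion")
#' @export
subject_ve <- function(protocol = c("infusion", "bolus"), table = subject_table(),
                       constants = ecv_constants()) {
  protocol <- match.arg(protocol)
  lam <- table[[paste0(protocol, "_lambda")]]
  hct <- table[[paste0(protocol, "_hct")]]
  table$ve <- ve_from_lambda(lam, hct, constants)
  table
}

#' Age-group Ve summary from the printed subject table
#'
#' Per-subject Ve by one technique, summarized (mean, SD, in percent) over
#' an age group: the young healthy volunteers (under 35) or the older
#' subjects with comorbidity (66 and over).
#'
#' @param protocol `"infusion"` or `"bolus"`.
#' @param group `"young"` (age < 35) or `"old"` (age >= 66).
#' @param table,constants as in [subject_ve()].
#' @return list with `mean_ve_pct`, `sd_ve_pct`, `n`, and the per-subject
#'   `ve_pct` vector.
#' @examples
#' group_ve_summary("infusion", "young") # mean about 21.1%
#' @export
group_ve_summary <- function(protocol = c("infusion", "bolus"),
                             group = c("young", "old"),
                             table = subject_table(), constants = ecv_constants()) {
  protocol <- match.arg(protocol)
  group <- match.arg(group)
  tab <- subject_ve(protocol, table, constants)
  sel <- if (group == "young") tab$age < 35 else tab$age >= 66
  ve_pct <- 100 * tab$ve[sel]
  list(mean_ve_pct = mean(ve_pct), sd_ve_pct = stats::sd(ve_pct),
       n = sum(sel), ve_pct = ve_pct)
}
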