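#' Early-stage glottic carcinoma effect table (nine studies, 14 risk factors)
#'
#' The curated study-by-factor table of univariate log odds ratios for local
#' recurrence after definitive radiotherapy in early-stage glottic carcinoma,
#' with within-study standard errors. Nine cohorts published between 2000 and
#' 2023 each report a subset of fourteen coded risk-factor contrasts; blank
#' cells are genuinely unreported, while a stored `0.00` (e.g. the Bignardi
#' tumour-grading entry `0.00 (0.02)`) is an observed estimate. Estimates
#' derived from adjusted multivariable regressions are excluded; only
#' univariate contrasts are carried.
#'
#' The same data ship as a long-layout CSV under
#' `system.file("extdata", "glottic_table1.csv", package = "mfmeta")`.
#'
#' Note that the published posterior-summary table lists slightly smaller
#' study counts for a few factors (e.g. 8 rather than 9 for anterior
#' commissure involvement) without naming the excluded entries; this object
#' keeps every printed cell, and [drop_cell()] supports running alternative
#' inclusion variants.
#'
#' @return A validated [effect_table()] with 9 studies and 14 factors.
#' @export
#' @examples
#' tab <- glottic_table1()
#' reporting_counts(tab)
glottic_table1 <- function() {
  defs <- data.frame(
    factor_id = c("aci", "t_substage", "cord_mobility", "subglottic",
                  "rt_technique", "rt_dose", "fraction_size", "ott",
                  "field_size", "gender", "hb_level", "smoking", "age",
                  "tumor_grading"),
    display_name = c("ACI", "T substage", "Vocal cord mobility",
                     "Subglottic extension", "RT technique", "Total RT dose",
                     "Fraction size", "OTT", "Field size", "Gender",
                     "Hb level", "Smoking status", "Age", "Tumor grading"),
    contrast = c("yes vs no", "T1a vs T1b/T1 vs T2",
                 "impaired vs not impaired", "yes vs no",
                 "technique comparison", "<60 Gy vs >=60 Gy",
                 "conventional vs accelerated", "<=40 days vs >40 days",
                 "T vs TN", "male vs female", "normal vs low", "yes vs no",
                 "<65 years vs >=65 years", "low vs intermediate/high"),
    higher_is_risk = TRUE,
    stringsAsFactors = FALSE)

  studies <- data.frame(
    study_id = c("elicin_2019", "gultekin_2012", "yamazaki_2006",
                 "almamgani_2013", "bignardi_2004", "chung_2018",
                 "matsumoto_2016", "raitiola_2000", "deridder_2023"),
    citation_label = c("Elicin et al. (2019)", "Gultekin et al. (2012)",
                       "Yamazaki et al. (2006)", "Al-Mamgani et al. (2013)",
                       "Bignardi et al. (2004)", "Chung et al. (2018)",
                       "Matsumoto et al. (2016)", "Raitiola et al. (2000)",
                       "de Ridder et al. (2023)"),
    stringsAsFactors = FALSE)

  # one row per printed cell: study, factor, log OR, SE
  cells <- list(
    # Elicin et al. (2019)
    c("elicin_2019", "aci",            0.51, 0.16),
    c("elicin_2019", "t_substage",     0.48, 0.21),
    c("elicin_2019", "rt_technique",  -0.17, 0.25),
    c("elicin_2019", "rt_dose",        0.45, 0.16),
    c("elicin_2019", "gender",         1.25, 0.59),
    c("elicin_2019", "age",           -0.04, 0.18),
    # Gultekin et al. (2012)
    c("gultekin_2012", "aci",          0.73, 0.28),
    c("gultekin_2012", "t_substage",   0.64, 0.30),
    c("gultekin_2012", "subglottic",   0.41, 0.35),
    c("gultekin_2012", "rt_technique", 0.30, 0.18),
    c("gultekin_2012", "gender",      -0.92, 1.27),
    c("gultekin_2012", "smoking",      0.97, 1.01),
    c("gultekin_2012", "age",          1.21, 0.30),
    c("gultekin_2012", "tumor_grading", -0.08, 0.18),
    # Yamazaki et al. (2006)
    c("yamazaki_2006", "aci",         -0.20, 0.66),
    c("yamazaki_2006", "t_substage",   0.57, 0.73),
    c("yamazaki_2006", "fraction_size", -1.17, 0.41),
    c("yamazaki_2006", "gender",      -0.62, 1.05),
    c("yamazaki_2006", "hb_level",    -0.21, 0.45),
    c("yamazaki_2006", "smoking",      0.25, 0.72),
    c("yamazaki_2006", "age",         -0.26, 0.44),
    # Al-Mamgani et al. (2013)
    c("almamgani_2013", "aci",         0.10, 0.20),
    c("almamgani_2013", "rt_dose",    -0.11, 0.11),
    c("almamgani_2013", "fraction_size", 0.47, 0.06),
    c("almamgani_2013", "gender",      0.18, 0.56),
    c("almamgani_2013", "hb_level",    0.99, 0.16),
    c("almamgani_2013", "smoking",     1.31, 0.10),
    c("almamgani_2013", "age",         0.00, 0.25),
    # Bignardi et al. (2004)
    c("bignardi_2004", "aci",         -0.73, 0.47),
    c("bignardi_2004", "cord_mobility", -0.07, 0.63),
    c("bignardi_2004", "subglottic",   0.48, 0.75),
    c("bignardi_2004", "rt_technique", 0.34, 0.48),
    c("bignardi_2004", "rt_dose",      0.04, 0.08),
    c("bignardi_2004", "ott",          0.18, 0.20),
    c("bignardi_2004", "field_size",   0.17, 0.57),
    c("bignardi_2004", "tumor_grading", 0.00, 0.02),
    # Chung et al. (2018)
    c("chung_2018", "aci",             0.51, 0.40),
    c("chung_2018", "t_substage",      0.72, 0.47),
    c("chung_2018", "gender",         -0.06, 0.74),
    c("chung_2018", "age",             0.37, 0.39),
    c("chung_2018", "tumor_grading",  -0.13, 0.45),
    # Matsumoto et al. (2016)
    c("matsumoto_2016", "aci",        -1.03, 0.83),
    c("matsumoto_2016", "t_substage",  1.00, 0.68),
    c("matsumoto_2016", "fraction_size", 1.26, 0.58),
    c("matsumoto_2016", "ott",         1.03, 0.69),
    c("matsumoto_2016", "gender",     -0.20, 1.14),
    c("matsumoto_2016", "age",         0.92, 0.63),
    # Raitiola et al. (2000)
    c("raitiola_2000", "aci",          1.34, 0.47),
    c("raitiola_2000", "t_substage",   1.48, 0.46),
    c("raitiola_2000", "cord_mobility", 1.00, 0.64),
    # de Ridder et al. (2023)
    c("deridder_2023", "aci",         -0.36, 0.72),
    c("deridder_2023", "t_substage",   2.08, 0.82),
    c("deridder_2023", "field_size",   0.02, 0.03),
    c("deridder_2023", "gender",      -0.01, 1.07),
    c("deridder_2023", "smoking",      2.22, 0.73),
    c("deridder_2023", "age",         -0.02, 0.04))

  y <- s <- matrix(NA_real_, nrow(studies), nrow(defs),
                   dimnames = list(studies$study_id, defs$factor_id))
  for (cell in cells) {
    y[cell[1], cell[2]] <- as.numeric(cell[3])
    s[cell[1], cell[2]] <- as.numeric(cell[4])
  }
  effect_table(y, s, studies = studies, factors = defs)
}
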