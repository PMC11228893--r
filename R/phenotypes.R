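#' Blood cell composition ratios
#'
#' Systemic-inflammation markers derived from blood counts:
#' NLR = neutrophils / lymphocytes, PLR = platelets / lymphocytes,
#' LMR = lymphocytes / monocytes, SII = neutrophils x platelets /
#' lymphocytes. To avoid infinities, none of the ratios are calculated for
#' individuals with a zero lymphocyte or monocyte count; missing inputs
#' propagate to missing ratios.
#'
#' @param counts data.frame with columns `neutrophils`, `lymphocytes`,
#'   `platelets`, `monocytes` (counts x 10^9/L).
#' @return data.frame with columns `NLR`, `PLR`, `LMR`, `SII`.
#' @export
blood_ratios <- function(counts) {
  need <- c("neutrophils", "lymphocytes", "platelets", "monocytes")
  if (!all(need %in% names(counts)))
    stop_ribocn("counts must have columns ", paste(need, collapse = ", "))
  N <- counts$neutrophils; L <- counts$lymphocytes
  P <- counts$platelets; M <- counts$monocytes
  zero_den <- (!is.na(L) & L == 0) | (!is.na(M) & M == 0)
  out <- data.frame(NLR = N / L, PLR = P / L, LMR = L / M, SII = N * P / L)
  out[zero_den, ] <- NA_real_
  out
}

#' Principal components of nucleated blood cell proportions
#'
#' Unit-variance-scaled PCA of the five nucleated white-cell percentages
#' (lymphocytes, monocytes, neutrophils, eosinophils, basophils), used as
#' covariates controlling for somatic blood-composition differences.
#' Individuals with any nucleated red blood cells recorded (`nrbc_pct > 0`)
#' are excluded before fitting, as are rows with missing percentages.
#' Because the five percentages sum to (approximately) 100, the data are
#' compositional with rank at most four, so the first four components carry
#' essentially all the variance.
#'
#' @param percentages data.frame with columns `lymph_pct`, `mono_pct`,
#'   `neut_pct`, `eos_pct`, `baso_pct` and `nrbc_pct`.
#' @param n_components number of component scores to return (default 4).
#' @return list with `scores` (matrix, retained rows x components),
#'   `explained` (variance fractions for all five components), `loadings`,
#'   and `kept` (logical vector over input rows).
#' @export
blood_composition_pcs <- function(percentages, n_components = 4L) {
  need <- c("lymph_pct", "mono_pct", "neut_pct", "eos_pct", "baso_pct", "nrbc_pct")
  if (!all(need %in% names(percentages)))
    stop_ribocn("percentages must have columns ", paste(need, collapse = ", "))
  mat <- as.matrix(percentages[, c("lymph_pct", "mono_pct", "neut_pct",
                                   "eos_pct", "baso_pct")])
  kept <- !is.na(percentages$nrbc_pct) & percentages$nrbc_pct == 0 &
    rowSums(is.na(mat)) == 0
  if (sum(kept) < 6L)
    stop_ribocn("fewer than 6 usable participants for blood PCA",
                class = "ribocn_insufficient_data")
  fit <- prcomp(mat[kept, , drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  n_components <- min(n_components, ncol(fit$x))
  list(scores = fit$x[, seq_len(n_components), drop = FALSE],
       explained = expl, loadings = fit$rotation, kept = kept)
}

#' Sex-specific eGFR coefficients
#'
#' Coefficients of the race-free CKD-EPI-style piecewise power formulas as
#' used here: `gamma` multipliers per variant, the creatinine knot `kappa`,
#' the below-knot creatinine exponent `alpha_cr`, the fixed exponents and
#' the per-variant age decay bases. All values are configurable; the
#' defaults are the published set for this pipeline (note `alpha_cr`
#' duplicates `kappa` in that set).
#'
#' @param gamma_cr,gamma_cc,gamma_crcc named `c(male=, female=)` multipliers.
#' @param alpha_cr below-knot creatinine exponent, by sex.
#' @param kappa creatinine knot (mg/dL), by sex.
#' @param exp_cr_max,exp_cc_min,exp_cc_max,exp_crcc_cr_max,exp_crcc_cc_min,exp_crcc_cc_max
#'   fixed exponents.
#' @param age_base_cr,age_base_cc,age_base_crcc per-year age decay bases.
#' @return list of coefficients.
#' @export
egfr_coefficients <- function(gamma_cr = c(male = 142, female = 143.704),
                              gamma_cc = c(male = 135, female = 130.035),
                              gamma_crcc = c(male = 133, female = 123.956),
                              alpha_cr = c(male = 0.9, female = 0.7),
                              kappa = c(male = 0.9, female = 0.7),
                              exp_cr_max = -1.2,
                              exp_cc_min = -0.499, exp_cc_max = -1.328,
                              exp_crcc_cr_max = -0.544,
                              exp_crcc_cc_min = -0.323, exp_crcc_cc_max = -0.778,
                              age_base_cr = 0.9938, age_base_cc = 0.996,
                              age_base_crcc = 0.9961) {
  list(gamma_cr = gamma_cr, gamma_cc = gamma_cc, gamma_crcc = gamma_crcc,
       alpha_cr = alpha_cr, kappa = kappa,
       exp_cr_max = exp_cr_max, exp_cc_min = exp_cc_min, exp_cc_max = exp_cc_max,
       exp_crcc_cr_max = exp_crcc_cr_max, exp_crcc_cc_min = exp_crcc_cc_min,
       exp_crcc_cc_max = exp_crcc_cc_max,
       age_base_cr = age_base_cr, age_base_cc = age_base_cc,
       age_base_crcc = age_base_crcc)
}

#' Estimated glomerular filtration rate
#'
#' Piecewise power eGFR formulas from serum creatinine (`cr`), cystatin C
#' (`cc`), or both (`cr_cc`), with sex-specific coefficients:
#' \deqn{eGFR_{cr} = \gamma_{cr} \min(S_{cr}/\kappa,1)^{\alpha_{cr}}
#'       \max(S_{cr}/\kappa,1)^{-1.2} \times 0.9938^{Age}}
#' \deqn{eGFR_{cc} = \gamma_{cc} \min(S_{cc}/0.8,1)^{-0.499}
#'       \max(S_{cc}/0.8,1)^{-1.328} \times 0.996^{Age}}
#' \deqn{eGFR_{cr+cc} = \gamma_{cr+cc} \min(S_{cr}/\kappa,1)^{\alpha_{cr}}
#'       \max(S_{cr}/\kappa,1)^{-0.544} \min(S_{cc}/0.8,1)^{-0.323}
#'       \max(S_{cc}/0.8,1)^{-0.778} \times 0.9961^{Age}}
#' Serum creatinine recorded in umol/L is converted to mg/dL by the
#' `conversion_factor` (default 0.0133 as used in the source pipeline; the
#' conventional factor 1/88.42 differs slightly and can be supplied
#' instead). In the cystatin-only variant the above-knot term is evaluated
#' on cystatin C by default; `strict_as_printed = TRUE` evaluates it on
#' creatinine, reproducing the published formula text verbatim.
#'
#' Missing biomarkers propagate to missing output; non-positive biomarkers
#' are a validation error.
#'
#' @param scr serum creatinine (vectorised; units per `scr_units`).
#' @param scc cystatin C, applied as recorded.
#' @param age age in years.
#' @param sex `"male"`/`"female"` (or 1/0), vectorised.
#' @param variant `"cr"`, `"cc"` or `"cr_cc"`.
#' @param coefficients [egfr_coefficients()].
#' @param scr_units `"umol/L"` (converted) or `"mg/dL"` (used as is).
#' @param conversion_factor umol/L to mg/dL factor (default 0.0133).
#' @param strict_as_printed use creatinine in the cystatin-only max term.
#' @return eGFR in mL/min/1.73m^2.
#' @export
egfr <- function(scr = NULL, scc = NULL, age, sex,
                 variant = c("cr", "cc", "cr_cc"),
                 coefficients = egfr_coefficients(),
                 scr_units = c("umol/L", "mg/dL"),
                 conversion_factor = 0.0133,
                 strict_as_printed = FALSE) {
  variant <- match.arg(variant)
  scr_units <- match.arg(scr_units)
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "male", "female")
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  n <- max(length(scr), length(scc), length(age), length(sex))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  cf <- coefficients
  pick <- function(v) unname(v[sex])
  if (!is.null(scr)) {
    if (any(!is.na(scr) & scr <= 0))
      stop_ribocn("non-positive serum creatinine", class = "ribocn_validation_error")
    if (scr_units == "umol/L") scr <- scr * conversion_factor
    scr <- rep_len(scr, n)
  }
  if (!is.null(scc)) {
    if (any(!is.na(scc) & scc <= 0))
      stop_ribocn("non-positive cystatin C", class = "ribocn_validation_error")
    scc <- rep_len(scc, n)
  }
  need <- switch(variant, cr = "scr", cc = if (strict_as_printed) c("scc", "scr") else "scc",
                 cr_cc = c("scr", "scc"))
  if ("scr" %in% need && is.null(scr)) stop_ribocn("variant '", variant, "' requires scr")
  if ("scc" %in% need && is.null(scc)) stop_ribocn("variant '", variant, "' requires scc")
  kap <- pick(cf$kappa)
  if (variant == "cr") {
    r <- scr / kap
    out <- pick(cf$gamma_cr) * pmin(r, 1)^pick(cf$alpha_cr) *
      pmax(r, 1)^cf$exp_cr_max * cf$age_base_cr^age
  } else if (variant == "cc") {
    rcc <- scc / 0.8
    rmax <- if (strict_as_printed) scr / 0.8 else rcc
    out <- pick(cf$gamma_cc) * pmin(rcc, 1)^cf$exp_cc_min *
      pmax(rmax, 1)^cf$exp_cc_max * cf$age_base_cc^age
  } else {
    rcr <- scr / kap; rcc <- scc / 0.8
    out <- pick(cf$gamma_crcc) * pmin(rcr, 1)^pick(cf$alpha_cr) *
      pmax(rcr, 1)^cf$exp_crcc_cr_max * pmin(rcc, 1)^cf$exp_crcc_cc_min *
      pmax(rcc, 1)^cf$exp_crcc_cc_max * cf$age_base_crcc^age
  }
  unname(out)
}

#' Default renal disease code groupings
#'
#' ICD-10 groupings used for case/control construction: glomerular disease
#' (N00-N08), kidney failure (N17, N18) and urolithiasis (N20-N23).
#'
#' @return named list of code vectors.
#' @export
renal_code_groups <- function() {
  list(glomerular_disease = sprintf("N%02d", 0:8),
       kidney_failure = c("N17", "N18"),
       urolithiasis = paste0("N", 20:23))
}

#' Case/control labels from first-report dates of renal disease codes
#'
#' A participant is a case for a disease group if any member code carries a
#' valid first-report date, and a control only if no member code does. The
#' special-meaning sentinel date `"1903-03-03"` is treated as missing; any
#' other unparseable non-empty date is a validation error naming the record.
#'
#' @param first_report_dates data.frame with an `id` column plus one
#'   character column per disease code ("" or NA when never reported).
#' @param grouping named list mapping group name to code vector (default
#'   [renal_code_groups()]).
#' @return data.frame with `id` and one logical case column per group.
#' @export
renal_disease_groups <- function(first_report_dates, grouping = renal_code_groups()) {
  stopifnot("id" %in% names(first_report_dates))
  codes <- setdiff(names(first_report_dates), "id")
  has_date <- sapply(first_report_dates[codes], function(col) {
    col <- as.character(col)
    col[!is.na(col) & col == "1903-03-03"] <- NA     # UKB special-meaning sentinel
    nonempty <- !is.na(col) & nzchar(col)
    parsed <- as.Date(rep(NA_character_, length(col)))
    parsed[nonempty] <- as.Date(col[nonempty], format = "%Y-%m-%d",
                                optional = TRUE)
    bad <- nonempty & is.na(parsed)
    if (any(bad))
      stop_ribocn("unparseable first-report date(s) for id(s) ",
                  paste(first_report_dates$id[bad], collapse = ", "),
                  class = "ribocn_validation_error")
    !is.na(parsed)
  })
  if (is.null(dim(has_date))) has_date <- matrix(has_date, nrow = 1L,
                                                 dimnames = list(NULL, codes))
  out <- data.frame(id = first_report_dates$id)
  for (g in names(grouping)) {
    members <- intersect(grouping[[g]], codes)
    out[[g]] <- if (length(members))
      rowSums(has_date[, members, drop = FALSE]) > 0 else FALSE
  }
  out
}

#' Cohort filtering rules
#'
#' Thresholds and code lists for the nested quality-control subsets. The
#' disease / medication / congenital code lists are study-specific
#' configuration (placeholders by default); the thresholds are the standard
#' hematology exclusions: leukocytes <= 200 x 10^9/L, hemoglobin <= 20 g/dL,
#' hematocrit <= 60%, platelets <= 1000 x 10^9/L, processing delay <= 36 h,
#' and (for the healthy subset) BMI <= 30 kg/m^2 and non-smoking status.
#' The statin codes are the six standard UKB medication codes.
#'
#' @param blood_cancer_codes,blood_disorder_codes,medication_exclude_codes,congenital_codes
#'   character code vectors.
#' @param statin_codes statin medication codes.
#' @param leukocyte_max,hemoglobin_max,hematocrit_max,platelet_max,delay_max_hours,bmi_max
#'   numeric caps.
#' @return list of rules.
#' @export
cohort_filter_rules <- function(blood_cancer_codes = character(0),
                                blood_disorder_codes = character(0),
                                medication_exclude_codes = character(0),
                                congenital_codes = character(0),
                                statin_codes = c("1140861958", "1140888594",
                                                 "1140888648", "1141146138",
                                                 "1141146234", "1141192410"),
                                leukocyte_max = 200, hemoglobin_max = 20,
                                hematocrit_max = 60, platelet_max = 1000,
                                delay_max_hours = 36, bmi_max = 30) {
  list(blood_cancer_codes = as.character(blood_cancer_codes),
       blood_disorder_codes = as.character(blood_disorder_codes),
       medication_exclude_codes = as.character(medication_exclude_codes),
       congenital_codes = as.character(congenital_codes),
       statin_codes = as.character(statin_codes),
       leukocyte_max = leukocyte_max, hemoglobin_max = hemoglobin_max,
       hematocrit_max = hematocrit_max, platelet_max = platelet_max,
       delay_max_hours = delay_max_hours, bmi_max = bmi_max)
}

has_code <- function(column, codes) {
  if (is.null(column)) return(rep(FALSE, 0L))
  vapply(strsplit(ifelse(is.na(column), "", as.character(column)), ";", fixed = TRUE),
         function(x) any(x %in% codes), logical(1))
}

exceeds <- function(x, cap) !is.na(x) & x > cap

#' Apply nested cohort quality-control filters
#'
#' Adds logical subset-membership flags. `FILTERED` drops blood cancers and
#' disorders, pregnancy, aberrant blood measurements and long processing
#' delays; `FILTERED_UNMEDICATED` further drops listed medications and
#' participants taking other prescription medications;
#' `HEALTHY` further drops any recorded cancer or non-cancer illness,
#' congenital codes, current smokers and BMI above the cap;
#' `FILTERED_UNRELATED` intersects `FILTERED` with a supplied unrelated id
#' set; `STATIN_FREE` flags participants on none of the statin codes. The
#' flags are nested: `HEALTHY` implies `FILTERED_UNMEDICATED` implies
#' `FILTERED`. Missing values never trigger an exclusion on their own.
#'
#' Expected columns (all optional except `id`): `leukocytes`, `hemoglobin`,
#' `hematocrit`, `platelets`, `pregnancy` (0/1/2), `delay_hours`,
#' `cancer_codes`, `noncancer_codes`, `medication_codes` (each a
#' `;`-separated code string), `other_prescriptions` (0/1),
#' `congenital_codes`, `smoking_status` (0/1/2), `bmi`.
#'
#' @param table cohort data.frame with an `id` column.
#' @param rules [cohort_filter_rules()].
#' @param unrelated_ids optional character vector of unrelated participant ids.
#' @return `table` with flag columns appended.
#' @export
apply_cohort_filters <- function(table, rules = cohort_filter_rules(),
                                 unrelated_ids = NULL) {
  stopifnot(is.data.frame(table), "id" %in% names(table))
  need <- c("blood_cancer_codes", "blood_disorder_codes",
            "medication_exclude_codes", "congenital_codes", "statin_codes",
            "leukocyte_max", "hemoglobin_max", "hematocrit_max",
            "platelet_max", "delay_max_hours", "bmi_max")
  if (!all(need %in% names(rules)))
    stop_ribocn("rules missing: ", paste(setdiff(need, names(rules)), collapse = ", "),
                class = "ribocn_config_error")
  n <- nrow(table)
  col <- function(nm) if (nm %in% names(table)) table[[nm]] else rep(NA, n)
  excl_filtered <-
    has_code(col("cancer_codes"), rules$blood_cancer_codes) |
    has_code(col("noncancer_codes"), rules$blood_disorder_codes) |
    (!is.na(col("pregnancy")) & col("pregnancy") %in% c(1, 2)) |
    exceeds(col("leukocytes"), rules$leukocyte_max) |
    exceeds(col("hemoglobin"), rules$hemoglobin_max) |
    exceeds(col("hematocrit"), rules$hematocrit_max) |
    exceeds(col("platelets"), rules$platelet_max) |
    exceeds(col("delay_hours"), rules$delay_max_hours)
  table$FILTERED <- !excl_filtered
  excl_med <-
    has_code(col("medication_codes"), rules$medication_exclude_codes) |
    (!is.na(col("other_prescriptions")) & col("other_prescriptions") == 1)
  table$FILTERED_UNMEDICATED <- table$FILTERED & !excl_med
  any_entry <- function(nm) {
    v <- col(nm)
    !is.na(v) & nzchar(as.character(v))
  }
  smoker <- !is.na(col("smoking_status")) & !(col("smoking_status") %in% c(0, 1))
  excl_healthy <- any_entry("cancer_codes") | any_entry("noncancer_codes") |
    has_code(col("congenital_codes"), rules$congenital_codes) |
    any_entry("congenital_codes") & length(rules$congenital_codes) == 0L |
    smoker | exceeds(col("bmi"), rules$bmi_max)
  table$HEALTHY <- table$FILTERED_UNMEDICATED & !excl_healthy
  if (!is.null(unrelated_ids))
    table$FILTERED_UNRELATED <- table$FILTERED & table$id %in% unrelated_ids
  table$STATIN_FREE <- !has_code(col("medication_codes"), rules$statin_codes)
  table
}
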