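test_that("blood ratios follow the defining formulas and the zero-count rule", {
  counts <- data.frame(neutrophils = 4, lymphocytes = 2, platelets = 250,
                       monocytes = 0.5)
  r <- blood_ratios(counts)
  expect_equal(r$NLR, 2)
  expect_equal(r$PLR, 125)
  expect_equal(r$LMR, 4)
  expect_equal(r$SII, 500)

  zl <- blood_ratios(data.frame(neutrophils = 4, lymphocytes = 0,
                                platelets = 250, monocytes = 0.5))
  expect_true(all(is.na(zl)))
  zm <- blood_ratios(data.frame(neutrophils = 4, lymphocytes = 2,
                                platelets = 250, monocytes = 0))
  expect_true(all(is.na(zm)))
  miss <- blood_ratios(data.frame(neutrophils = NA_real_, lymphocytes = NA_real_,
                                  platelets = NA_real_, monocytes = NA_real_))
  expect_true(all(is.na(miss)))
})

test_that("blood-composition PCA is compositional: four components suffice", {
  set.seed(61)
  n <- 300
  raw <- matrix(stats::rgamma(5 * n, shape = c(30, 8, 55, 3, 1)), ncol = 5,
                byrow = TRUE)
  pct <- 100 * raw / rowSums(raw)   # rows sum exactly to 100
  df <- data.frame(lymph_pct = pct[, 1], mono_pct = pct[, 2],
                   neut_pct = pct[, 3], eos_pct = pct[, 4],
                   baso_pct = pct[, 5], nrbc_pct = 0)
  res <- blood_composition_pcs(df)
  expect_identical(ncol(res$scores), 4L)
  expect_gte(sum(res$explained[1:4]), 0.9999)
  expect_lt(res$explained[5], 1e-4)

  # participants with any nucleated red blood cells are excluded from the fit
  df2 <- df
  df2$nrbc_pct[5] <- 0.1
  res2 <- blood_composition_pcs(df2)
  expect_false(res2$kept[5])
  expect_equal(nrow(res2$scores), n - 1L)

  # duplicating every row leaves the loadings unchanged (up to sign)
  dup <- rbind(df, df)
  res_dup <- blood_composition_pcs(dup)
  agree <- abs(colSums(res_dup$loadings * res$loadings))
  expect_equal(unname(agree), rep(1, 5), tolerance = 1e-8)

  expect_error(blood_composition_pcs(df[1:4, ]),
               class = "ribocn_insufficient_data")
})

test_that("eGFR variants return their sex-specific gamma at the knot", {
  # all kernel terms and the age factor equal 1 at these inputs
  expect_equal(egfr(scr = 0.7, age = 0, sex = "female", variant = "cr",
                    scr_units = "mg/dL"), 143.704)
  expect_equal(egfr(scr = 0.9, age = 0, sex = "male", variant = "cr",
                    scr_units = "mg/dL"), 142)
  expect_equal(egfr(scc = 0.8, scr = 0.72, age = 0, sex = "male",
                    variant = "cc", scr_units = "mg/dL"), 135)
  expect_equal(egfr(scc = 0.8, age = 0, sex = "female", variant = "cc"), 130.035)
  expect_equal(egfr(scr = 0.7, scc = 0.8, age = 0, sex = "female",
                    variant = "cr_cc", scr_units = "mg/dL"), 123.956)
  expect_equal(egfr(scr = 0.9, scc = 0.8, age = 0, sex = "male",
                    variant = "cr_cc", scr_units = "mg/dL"), 133)
})

test_that("eGFR is continuous at the knots and monotone in its inputs", {
  eps <- 1e-9
  for (sx in c("male", "female")) {
    kap <- if (sx == "male") 0.9 else 0.7
    left <- egfr(scr = kap - eps, age = 50, sex = sx, variant = "cr",
                 scr_units = "mg/dL")
    right <- egfr(scr = kap + eps, age = 50, sex = sx, variant = "cr",
                  scr_units = "mg/dL")
    expect_equal(left, right, tolerance = 1e-6)
    lcc <- egfr(scc = 0.8 - eps, age = 50, sex = sx, variant = "cc")
    rcc <- egfr(scc = 0.8 + eps, age = 50, sex = sx, variant = "cc")
    expect_equal(lcc, rcc, tolerance = 1e-6)
  }
  # above the knot the creatinine exponent is negative, so eGFR decreases;
  # below it the configured below-knot exponent (0.7/0.9) is positive, so
  # strict monotonicity holds on the above-knot branch
  scr_grid <- seq(0.7, 3, by = 0.1)
  v <- egfr(scr = scr_grid, age = 50, sex = "female", variant = "cr",
            scr_units = "mg/dL")
  expect_true(all(diff(v) < 0))
  ages <- seq(20, 90, by = 5)
  va <- egfr(scr = 1, age = ages, sex = "male", variant = "cr",
             scr_units = "mg/dL")
  expect_true(all(diff(va) < 0))
  scc_grid <- seq(0.4, 3, by = 0.1)
  vc <- egfr(scc = scc_grid, age = 50, sex = "male", variant = "cc")
  expect_true(all(diff(vc) < 0))
})

test_that("creatinine units, strict-as-printed mode, and missingness behave", {
  # umol/L converted by the configurable published factor
  expect_equal(egfr(scr = 100, age = 40, sex = "male", variant = "cr"),
               egfr(scr = 100 * 0.0133, age = 40, sex = "male", variant = "cr",
                    scr_units = "mg/dL"))
  # strict-as-printed evaluates the cystatin-only max term on creatinine
  strict <- egfr(scc = 1.6, scr = 0.72, age = 0, sex = "male", variant = "cc",
                 scr_units = "mg/dL", strict_as_printed = TRUE)
  expect_equal(strict, 135)          # scr below knot: max term 1 despite high scc
  default <- egfr(scc = 1.6, age = 0, sex = "male", variant = "cc")
  expect_equal(default, 135 * 2^(-1.328))
  # missing biomarker propagates; non-positive is an error
  expect_true(is.na(egfr(scr = NA, age = 40, sex = "male", variant = "cr")))
  expect_error(egfr(scr = -1, age = 40, sex = "male", variant = "cr"),
               class = "ribocn_validation_error")
  expect_error(egfr(scc = 0.8, age = 40, sex = "male", variant = "cr"),
               "requires scr")
})

test_that("renal disease groups honour dates, the sentinel, and code groupings", {
  dates <- data.frame(id = c("p1", "p2", "p3", "p4"),
                      N17 = c("2005-01-01", "", "", ""),
                      N03 = c("", "2010-06-15", "", ""),
                      N21 = c("", "", "1903-03-03", ""),
                      stringsAsFactors = FALSE)
  g <- renal_disease_groups(dates)
  expect_true(g$kidney_failure[g$id == "p1"])
  expect_false(g$glomerular_disease[g$id == "p1"])
  expect_true(g$glomerular_disease[g$id == "p2"])
  # the sentinel date is treated as missing: p3 is a control everywhere
  expect_false(any(unlist(g[g$id == "p3", -1])))
  expect_false(any(unlist(g[g$id == "p4", -1])))
  bad <- dates
  bad$N17[2] <- "not-a-date"
  expect_error(renal_disease_groups(bad), "p2", class = "ribocn_validation_error")
})

test_that("cohort filters implement the exclusion rules and nest", {
  rules <- cohort_filter_rules(blood_cancer_codes = "C91",
                               blood_disorder_codes = "D50",
                               medication_exclude_codes = "M001",
                               congenital_codes = "Q90")
  base <- data.frame(id = sprintf("p%02d", 1:10),
                     leukocytes = 8, hemoglobin = 14, hematocrit = 42,
                     platelets = 260, pregnancy = 0, delay_hours = 10,
                     cancer_codes = "", noncancer_codes = "",
                     medication_codes = "", other_prescriptions = 0,
                     congenital_codes = "", smoking_status = 0, bmi = 24,
                     stringsAsFactors = FALSE)
  tab <- base
  tab$platelets[1] <- 1200          # aberrant platelets
  tab$cancer_codes[2] <- "C91"      # blood cancer
  tab$delay_hours[3] <- 48          # processed too late
  out <- apply_cohort_filters(tab, rules)
  expect_identical(sum(out$FILTERED), 7L)
  expect_false(out$FILTERED[1])

  # BMI over the cap: kept in FILTERED, dropped from HEALTHY
  tab2 <- base
  tab2$bmi[4] <- 32
  out2 <- apply_cohort_filters(tab2, rules)
  expect_true(out2$FILTERED[4])
  expect_true(out2$FILTERED_UNMEDICATED[4])
  expect_false(out2$HEALTHY[4])

  # medication and smoking rules
  tab3 <- base
  tab3$medication_codes[5] <- "M001;X999"
  tab3$other_prescriptions[6] <- 1
  tab3$smoking_status[7] <- 2
  tab3$medication_codes[8] <- "1141146234"   # a statin
  out3 <- apply_cohort_filters(tab3, rules)
  expect_true(out3$FILTERED[5])
  expect_false(out3$FILTERED_UNMEDICATED[5])
  expect_false(out3$FILTERED_UNMEDICATED[6])
  expect_false(out3$HEALTHY[7])
  expect_true(out3$FILTERED_UNMEDICATED[7])
  expect_false(out3$STATIN_FREE[8])
  expect_true(out3$STATIN_FREE[5])

  # unrelated flag intersects with the supplied id set (p01 fails FILTERED)
  out4 <- apply_cohort_filters(tab, rules, unrelated_ids = c("p04", "p05", "p01"))
  expect_identical(out4$id[out4$FILTERED_UNRELATED], c("p04", "p05"))
})

test_that("subset flags nest for arbitrary tables", {
  set.seed(62)
  rules <- cohort_filter_rules(blood_cancer_codes = "C91",
                               medication_exclude_codes = "M001")
  n <- 400
  tab <- data.frame(id = sprintf("r%03d", 1:n),
                    leukocytes = stats::rlnorm(n, 2, 0.8),
                    hemoglobin = rnorm(n, 14, 4),
                    hematocrit = rnorm(n, 42, 12),
                    platelets = rnorm(n, 260, 400),
                    pregnancy = sample(0:2, n, TRUE),
                    delay_hours = stats::rexp(n, 1 / 20),
                    cancer_codes = sample(c("", "C91", "C50"), n, TRUE),
                    noncancer_codes = sample(c("", "J45"), n, TRUE),
                    medication_codes = sample(c("", "M001", "1140861958"), n, TRUE),
                    other_prescriptions = sample(0:1, n, TRUE),
                    congenital_codes = "",
                    smoking_status = sample(0:2, n, TRUE),
                    bmi = rnorm(n, 27, 5), stringsAsFactors = FALSE)
  out <- apply_cohort_filters(tab, rules)
  expect_true(all(out$FILTERED_UNMEDICATED <= out$FILTERED))
  expect_true(all(out$HEALTHY <= out$FILTERED_UNMEDICATED))
})
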