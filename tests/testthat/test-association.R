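test_that("standardized simple regression equals the Pearson correlation", {
  set.seed(71)
  # perfectly collinear response standardizes to beta = 1
  d <- data.frame(x = rnorm(200))
  d$y <- 2 * d$x
  fit <- suppressWarnings(fit_association(d, "y", "x"))  # perfect fit warns
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  expect_lt(fit$p, 1e-100)

  for (i in 1:5) {
    n <- 400
    d <- data.frame(x = rnorm(n))
    d$y <- 0.4 * d$x + rnorm(n)
    fit <- fit_association(d, "y", "x")
    expect_equal(fit$beta, stats::cor(d$x, d$y), tolerance = 1e-10)
  }
})

test_that("null exposures give calibrated p-values", {
  set.seed(72)
  ps <- replicate(200, {
    d <- data.frame(x = rnorm(400), y = rnorm(400))
    fit_association(d, "y", "x")$p
  })
  expect_equal(mean(ps), 0.5, tolerance = 0.08)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps < 0.5), 0.38)
})

test_that("logistic fits recover a known log-odds and report the odds ratio", {
  set.seed(73)
  n <- 60000
  x <- rnorm(n)
  eta <- qlogis(0.1) + 0.0392 * x
  d <- data.frame(x = x, y = rbinom(n, 1, plogis(eta)))
  fit <- fit_association(d, "y", "x", family = "logistic")
  expect_true(fit$ci_low <= 0.0392 && 0.0392 <= fit$ci_high)
  expect_equal(fit$or_value, 1.04, tolerance = 0.03)
  expect_equal(fit$or_value, exp(fit$beta))
  expect_true(fit$ci_low < fit$ci_high)
})

test_that("model pathologies raise informative errors", {
  set.seed(74)
  d <- data.frame(x = rnorm(100), y = rnorm(100))
  d$z <- d$x                        # collinear covariate
  expect_error(fit_association(d, "y", "x", covariates = "z"),
               class = "ribocn_model_error")
  d2 <- data.frame(x = rnorm(100), y = sample(c(1, 2, 3), 100, TRUE))
  expect_error(fit_association(d2, "y", "x", family = "logistic"),
               class = "ribocn_validation_error")
  expect_error(fit_association(d[1:8, ], "y", "x"),
               class = "ribocn_insufficient_data")
  expect_error(fit_association(d, "y", "x", covariates = "x"))
})

test_that("covariate adjustment removes a planted confounder", {
  set.seed(75)
  n <- 5000
  u <- rnorm(n)
  d <- data.frame(x = u + rnorm(n), u_obs = u,
                  center = sample(c("A", "B"), n, TRUE))
  d$y <- u + rnorm(n)               # association only through u
  raw <- fit_association(d, "y", "x", covariates = "center")
  adj <- fit_association(d, "y", "x", covariates = c("u_obs", "center"))
  expect_gt(raw$beta, 0.3)
  expect_lt(abs(adj$beta), 0.05)
})

test_that("phenome screen applies eligibility rules and controls the FDR", {
  set.seed(76)
  n <- 4000
  d <- data.frame(cn = rnorm(n))
  phen <- character(0)
  for (i in 1:40) {                  # null continuous phenotypes
    nm <- sprintf("null%02d", i)
    d[[nm]] <- rnorm(n)
    phen[nm] <- "continuous"
  }
  for (i in 1:3) {                   # strongly associated phenotypes
    nm <- sprintf("hit%02d", i)
    d[[nm]] <- 0.5 * d$cn + rnorm(n)
    phen[nm] <- "continuous"
  }
  d$rare_case <- c(rep(1, 150), rep(0, n - 150))    # below the case floor
  phen["rare_case"] <- "binary"
  d$sparse <- c(rnorm(n / 4), rep(NA, 3 * n / 4))   # under-measured
  phen["sparse"] <- "continuous"

  res <- phenome_screen(d, "cn", phen)
  expect_s3_class(res, "phenome_screen")
  expect_identical(res$reason[res$phenotype == "rare_case"], "min_cases")
  expect_identical(res$reason[res$phenotype == "sparse"], "min_measured_fraction")
  disc <- res$phenotype[!is.na(res$fdr) & res$fdr < 0.01]
  expect_setequal(disc, c("hit01", "hit02", "hit03"))

  # permuted exposure: discoveries vanish
  d$cn_perm <- sample(d$cn)
  res_perm <- phenome_screen(d, "cn_perm", phen)
  expect_lte(sum(res_perm$fdr < 0.01, na.rm = TRUE), 1L)
})

test_that("genomic inflation matches the median chi-square definition", {
  expect_equal(genomic_inflation(rep(0.5, 10)), 1)
  expect_equal(genomic_inflation(0.05),
               qchisq(0.95, 1) / qchisq(0.5, 1))
  expect_equal(genomic_inflation(0.05), 8.4439, tolerance = 1e-4)
  set.seed(77)
  expect_equal(genomic_inflation(runif(2e5)), 1, tolerance = 0.02)
  expect_error(genomic_inflation(numeric(0)))
  expect_error(genomic_inflation(c(0.5, 0)))
  expect_error(genomic_inflation(c(0.5, 1.2)))
})

test_that("standard errors recovered from beta and p invert the Wald test", {
  expect_equal(se_from_beta_p(1, 0.05), 1 / qnorm(0.975))
  expect_equal(se_from_beta_p(1, 0.05), 0.5102, tolerance = 1e-4)
  expect_equal(se_from_beta_p(-2, 0.05), 2 * se_from_beta_p(1, 0.05))
  # round trip: p recomputed from beta/se returns the input p
  for (p in c(0.3, 0.01, 1e-6)) {
    se <- se_from_beta_p(0.7, p)
    expect_equal(2 * pnorm(-abs(0.7 / se)), p, tolerance = 1e-8)
  }
  expect_error(se_from_beta_p(1, 0))
  expect_error(se_from_beta_p(1, 1))
})

test_that("IVW Mendelian randomization reduces correctly and recovers effects", {
  one <- mr_ivw(0.2, 0.06, 0.01)
  expect_equal(one$beta, 0.3)            # single-instrument Wald ratio
  # two equally-weighted instruments average their ratios
  two <- mr_ivw(c(0.2, 0.2), c(0.05, 0.07), c(0.01, 0.01))
  expect_equal(two$beta, (0.25 + 0.35) / 2)
  # a zero-weight instrument leaves the estimate unchanged
  three <- mr_ivw(c(0.2, 0.2, 0), c(0.05, 0.07, 0.4), c(0.01, 0.01, 0.01))
  expect_equal(three$beta, two$beta)
  expect_equal(three$se, two$se)

  set.seed(78)
  bx <- runif(30, 0.05, 0.3)
  se_y <- runif(30, 0.005, 0.02)
  by <- 0.3 * bx + rnorm(30, 0, se_y)
  est <- mr_ivw(bx, by, se_y)
  expect_lt(abs(est$beta - 0.3), 2 * est$se)
  expect_error(mr_ivw(numeric(0), numeric(0), numeric(0)))
  expect_error(mr_ivw(0, 0.1, 0.01))
})

test_that("effect-profile correlation restricts to significant features", {
  set.seed(79)
  feats <- sprintf("prot%03d", 1:200)
  beta_a <- setNames(rnorm(200), feats)
  fdr_a <- setNames(runif(200, 0, 0.2), feats)
  fdr_a[1:50] <- 0.001
  same <- effect_profile_correlation(beta_a, fdr_a, beta_a)
  expect_equal(same$r, 1)
  expect_identical(same$n_features, sum(fdr_a < 0.01))
  noise <- effect_profile_correlation(beta_a, fdr_a,
                                      setNames(rnorm(200), feats))
  expect_lt(abs(noise$r), 0.35)
  shared <- 0.8 * beta_a + rnorm(200, 0, 0.2)
  names(shared) <- feats
  cor_hit <- effect_profile_correlation(beta_a, fdr_a, shared)
  expect_gt(cor_hit$r, 0.9)
  few <- setNames(runif(200), feats); few[] <- 0.5
  expect_error(effect_profile_correlation(beta_a, few, beta_a),
               class = "ribocn_insufficient_data")
})

test_that("quantile trends bin equally and use t-based intervals", {
  d <- data.frame(x = 1:100, y = 1:100)
  qt5 <- quantile_trend(d, "x", "y")
  expect_identical(as.character(qt5$group),
                   c("Low", "Mid-Low", "Mid", "Mid-High", "High"))
  expect_identical(qt5$n, rep(20L, 5))
  expect_true(all(diff(qt5$mean) > 0))

  set.seed(80)
  d2 <- data.frame(x = rnorm(150), y = rnorm(150))
  tr <- quantile_trend(d2, "x", "y")
  expect_identical(sum(tr$n), 150L)
  g1 <- tr[1, ]
  yy <- d2$y[order(d2$x)][1:g1$n]
  expect_equal(g1$ci_high - g1$mean,
               qt(0.975, g1$n - 1) * sd(yy) / sqrt(g1$n), tolerance = 1e-8)

  expect_error(quantile_trend(data.frame(x = rep(1, 50), y = rnorm(50)),
                              "x", "y"), "x")
  expect_error(quantile_trend(d[1:6, ], "x", "y"),
               class = "ribocn_insufficient_data")
})

test_that("rank-based group comparison detects shifts and rejects degenerate input", {
  set.seed(81)
  a <- rnorm(200); b <- rnorm(200) + 2
  res <- group_difference_test(a, b)
  expect_lt(res$p, 1e-10)
  same <- rnorm(50)
  expect_gt(group_difference_test(same, same + rnorm(50, 0, 1e-6),
                                  paired = TRUE)$p, 0.01)
  expect_error(group_difference_test(same, same, paired = TRUE),
               class = "ribocn_degenerate_data")
  expect_error(group_difference_test(rep(1, 10), rep(1, 10)),
               class = "ribocn_degenerate_data")
  expect_error(group_difference_test(1:2, 1:5))
})
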