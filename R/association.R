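standardize_columns <- function(df, cols) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.numeric(v) && length(unique(na.omit(v))) > 2L) {
      s <- sd(v, na.rm = TRUE)
      if (is.finite(s) && s > 0) df[[cl]] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  df
}

prepare_categoricals <- function(df, cols) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- factor(v)
      ## most frequent level as reference
      tab <- sort(table(v), decreasing = TRUE)
      df[[cl]] <- stats::relevel(v, ref = names(tab)[1L])
    }
  }
  df
}

#' Fit a standardized association model
#'
#' The workhorse regression behind every association reported by this
#' package: a linear or logistic model of a response on an exposure plus a
#' covariate stack. When `standardize` is set (the default, matching how
#' effect sizes are reported here), every continuous variable -- including
#' the response in the linear family -- is centered and scaled to unit
#' variance before fitting, so linear effect sizes are standardized betas
#' and logistic ones are log-odds per standard deviation of exposure.
#' Categorical covariates enter as indicator encodings with the most
#' frequent level as reference. Fitting is on complete cases.
#'
#' @param data data.frame.
#' @param response response column name (binary 0/1 for logistic).
#' @param exposure exposure column name; its coefficient is reported.
#' @param covariates character vector of covariate column names.
#' @param family `"linear"` or `"logistic"`.
#' @param standardize center/scale continuous variables before fitting.
#' @param min_extra_cases minimum complete cases beyond the parameter count
#'   (default 10).
#' @param keep_model retain the underlying `lm`/`glm` object.
#' @return Object of class `assoc_fit` with elements `beta`, `se`, `ci_low`,
#'   `ci_high` (95%), `p`, `n`, `or_value` (logistic only), `response`,
#'   `exposure`, `family`.
#' @export
fit_association <- function(data, response, exposure, covariates = character(0),
                            family = c("linear", "logistic"),
                            standardize = TRUE, min_extra_cases = 10L,
                            keep_model = FALSE) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  vars <- c(response, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop_ribocn("columns not in data: ", paste(missing_cols, collapse = ", "))
  if (exposure %in% covariates || response %in% covariates)
    stop_ribocn("exposure/response must not appear among covariates")
  df <- data[, vars, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  df <- prepare_categoricals(df, covariates)
  if (family == "logistic") {
    vals <- unique(df[[response]])
    if (!all(vals %in% c(0, 1, FALSE, TRUE)))
      stop_ribocn("logistic response '", response, "' is not binary 0/1",
                  class = "ribocn_validation_error")
    df[[response]] <- as.numeric(df[[response]])
  }
  std_cols <- c(if (family == "linear") response, exposure,
                covariates[vapply(df[covariates], is.numeric, logical(1))])
  if (standardize) df <- standardize_columns(df, std_cols)
  fml <- stats::reformulate(c(exposure, covariates), response = response)
  n_par <- length(covariates) + 2L
  if (nrow(df) < n_par + min_extra_cases)
    stop_ribocn("too few complete cases (", nrow(df), ") for ", n_par,
                " parameters", class = "ribocn_insufficient_data")
  if (family == "linear") {
    fit <- lm(fml, data = df)
  } else {
    fit <- withCallingHandlers(
      glm(fml, data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          stop_ribocn("separation detected fitting '", response, "'",
                      class = "ribocn_model_error")
        invokeRestart("muffleWarning")
      })
  }
  cf <- coef(fit)
  if (any(is.na(cf))) {
    bad <- names(cf)[is.na(cf)]
    stop_ribocn("rank-deficient fit; offending column(s): ",
                paste(bad, collapse = ", "), class = "ribocn_model_error")
  }
  sm <- summary(fit)$coefficients
  beta <- sm[exposure, 1L]; se <- sm[exposure, 2L]; p <- sm[exposure, 4L]
  if (family == "linear") {
    tq <- qt(0.975, df = fit$df.residual)
    ci <- beta + c(-1, 1) * tq * se
  } else {
    ci <- beta + c(-1, 1) * qnorm(0.975) * se   # Wald on the log-odds scale
  }
  out <- list(beta = unname(beta), se = unname(se),
              ci_low = ci[1L], ci_high = ci[2L], p = unname(p),
              n = nrow(df),
              or_value = if (family == "logistic") exp(unname(beta)) else NULL,
              response = response, exposure = exposure, family = family,
              model = if (keep_model) fit else NULL)
  class(out) <- "assoc_fit"
  out
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("%s association: %s ~ %s\n", x$family, x$response, x$exposure))
  cat(sprintf("  beta = %.4g [%.4g, %.4g], se = %.3g, p = %.3g, n = %d\n",
              x$beta, x$ci_low, x$ci_high, x$se, x$p, x$n))
  if (!is.null(x$or_value)) cat(sprintf("  OR = %.4g\n", x$or_value))
  invisible(x)
}

#' @export
coef.assoc_fit <- function(object, ...) setNames(object$beta, object$exposure)

#' @export
confint.assoc_fit <- function(object, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list(object$exposure, c("2.5 %", "97.5 %")))
  m
}

#' @export
summary.assoc_fit <- function(object, ...) object

#' @export
as.data.frame.assoc_fit <- function(x, ...) {
  data.frame(response = x$response, exposure = x$exposure, family = x$family,
             beta = x$beta, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             p = x$p, n = x$n,
             or_value = if (is.null(x$or_value)) NA_real_ else x$or_value)
}

#' Simplified phenome-wide association screen
#'
#' Fits one association model per phenotype against a common exposure and
#' covariate stack, applying the standard eligibility filters before
#' testing: binary phenotypes need at least `min_cases` cases, and every
#' phenotype must be measured in at least `min_measured_fraction` of the
#' table. Benjamini-Hochberg FDR is computed across the eligible set;
#' ineligible phenotypes are reported with their exclusion reason. Output
#' order is deterministic (input phenotype order).
#'
#' @param data cohort data.frame.
#' @param exposure exposure column name.
#' @param phenotypes named character vector: names are phenotype columns,
#'   values their types (`"continuous"` or `"binary"`); an unnamed vector is
#'   taken as all-continuous column names.
#' @param covariates covariate column names.
#' @param min_cases minimum cases for binary phenotypes (default 200).
#' @param min_measured_fraction minimum measured fraction (default 0.5).
#' @return data.frame of class `phenome_screen` with one row per phenotype:
#'   `phenotype`, `type`, `eligible`, `reason`, `beta`, `se`, `p`, `n`,
#'   `fdr`.
#' @export
phenome_screen <- function(data, exposure, phenotypes, covariates = character(0),
                           min_cases = 200L, min_measured_fraction = 0.5) {
  if (is.null(names(phenotypes)))
    phenotypes <- setNames(rep("continuous", length(phenotypes)), phenotypes)
  total_n <- nrow(data)
  rows <- lapply(names(phenotypes), function(ph) {
    type <- phenotypes[[ph]]
    row <- data.frame(phenotype = ph, type = type, eligible = FALSE,
                      reason = NA_character_, beta = NA_real_, se = NA_real_,
                      p = NA_real_, n = NA_integer_, fdr = NA_real_)
    if (!ph %in% names(data)) { row$reason <- "missing_column"; return(row) }
    v <- data[[ph]]
    measured <- sum(!is.na(v))
    if (measured < min_measured_fraction * total_n) {
      row$reason <- "min_measured_fraction"; return(row)
    }
    if (type == "binary") {
      cases <- sum(v == 1, na.rm = TRUE)
      if (cases < min_cases) { row$reason <- "min_cases"; return(row) }
    }
    fit <- tryCatch(
      fit_association(data, response = ph, exposure = exposure,
                      covariates = covariates,
                      family = if (type == "binary") "logistic" else "linear"),
      ribocn_error = function(e) e)
    if (inherits(fit, "ribocn_error")) {
      row$reason <- conditionMessage(fit); return(row)
    }
    row$eligible <- TRUE
    row$beta <- fit$beta; row$se <- fit$se; row$p <- fit$p; row$n <- fit$n
    row
  })
  out <- do.call(rbind, rows)
  if (!any(out$eligible)) {
    warning("no eligible phenotypes in screen")
  } else {
    out$fdr[out$eligible] <- p.adjust(out$p[out$eligible], method = "BH")
  }
  class(out) <- c("phenome_screen", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' The median association chi-square statistic divided by its null median:
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`. Values
#' near 1 indicate well-calibrated tests.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(pvalues) {
  if (length(pvalues) == 0L) stop_ribocn("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop_ribocn("p-values must lie in (0, 1]")
  median(qchisq(1 - pvalues, df = 1)) / qchisq(0.5, df = 1)
}

#' Standard error recovered from an effect size and p-value
#'
#' `se = |beta| / z` where `z` is the standard-normal quantile at
#' `1 - p/2`, inverting the two-sided Wald test. Used to reconstruct
#' standard errors for summary statistics that report only beta and p.
#'
#' @param beta effect size(s).
#' @param p two-sided p-value(s) in (0, 1).
#' @return standard error(s).
#' @export
se_from_beta_p <- function(beta, p) {
  if (any(!is.finite(beta))) stop_ribocn("beta must be finite")
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1))
    stop_ribocn("p must lie strictly inside (0, 1)")
  abs(beta) / qnorm(1 - p / 2)
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Fixed-effect IVW estimate over pre-harmonized instruments:
#' `beta = sum(bx*by/se_y^2) / sum(bx^2/se_y^2)`,
#' `se = sqrt(1 / sum(bx^2/se_y^2))`, with a Wald p-value. With a single
#' instrument this reduces to the Wald ratio `by/bx`.
#'
#' @param beta_exposure per-instrument exposure effects.
#' @param beta_outcome per-instrument outcome effects.
#' @param se_outcome per-instrument outcome standard errors (> 0).
#' @return list with `beta`, `se`, `p`, `n_instruments` (class `ivw_mr`).
#' @export
mr_ivw <- function(beta_exposure, beta_outcome, se_outcome) {
  n <- length(beta_exposure)
  if (n == 0L) stop_ribocn("zero instruments")
  if (length(beta_outcome) != n || length(se_outcome) != n)
    stop_ribocn("instrument vectors must have equal length")
  if (any(se_outcome <= 0)) stop_ribocn("outcome standard errors must be > 0")
  if (all(beta_exposure == 0)) stop_ribocn("all exposure effects are zero")
  w <- beta_exposure^2 / se_outcome^2
  beta <- sum(beta_exposure * beta_outcome / se_outcome^2) / sum(w)
  se <- sqrt(1 / sum(w))
  p <- 2 * pnorm(-abs(beta / se))
  structure(list(beta = beta, se = se, p = p, n_instruments = n),
            class = "ivw_mr")
}

#' @export
print.ivw_mr <- function(x, ...) {
  cat(sprintf("IVW MR estimate: beta = %.4g (se %.3g, p %.3g) from %d instrument(s)\n",
              x$beta, x$se, x$p, x$n_instruments))
  invisible(x)
}

#' Correlation between two effect-size profiles
#'
#' Pearson correlation between the effect sizes of profile A's
#' FDR-significant features and the matching effect sizes in profile B,
#' as used to compare trait-associated proteomic profiles.
#'
#' @param beta_a named effect sizes (profile A).
#' @param fdr_a named FDR values aligned with `beta_a`.
#' @param beta_b named effect sizes (profile B, shared feature namespace).
#' @param fdr_threshold FDR cutoff applied to profile A (default 0.01).
#' @return list with `r`, `p`, `n_features`.
#' @export
effect_profile_correlation <- function(beta_a, fdr_a, beta_b, fdr_threshold = 0.01) {
  if (is.null(names(beta_a)) || is.null(names(beta_b)))
    stop_ribocn("effect profiles must be named by feature")
  sig <- names(beta_a)[!is.na(fdr_a) & fdr_a < fdr_threshold]
  shared <- intersect(sig, names(beta_b))
  shared <- shared[is.finite(beta_a[shared]) & is.finite(beta_b[shared])]
  if (length(shared) < 3L)
    stop_ribocn("fewer than 3 shared FDR-significant features",
                class = "ribocn_insufficient_data")
  ct <- cor.test(beta_a[shared], beta_b[shared], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_features = length(shared))
}

#' Quantile-group trend summary
#'
#' Splits a grouping variable into equal-count quantile groups (default
#' five: Low, Mid-Low, Mid, Mid-High, High) and summarises an outcome per
#' group with its mean and t-based 95% confidence interval
#' `mean +/- t(0.975, n-1) * s / sqrt(n)`.
#'
#' @param data data.frame.
#' @param grouping_variable column to bin.
#' @param outcome column to summarise.
#' @param n_groups number of quantile groups (default 5).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame of class `quantile_trend` with columns `group`, `n`,
#'   `mean`, `ci_low`, `ci_high`.
#' @export
quantile_trend <- function(data, grouping_variable, outcome, n_groups = 5L,
                           conf_level = 0.95) {
  x <- data[[grouping_variable]]; y <- data[[outcome]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < n_groups * 2L)
    stop_ribocn("too few complete cases for ", n_groups, " quantile groups",
                class = "ribocn_insufficient_data")
  breaks <- quantile(x, probs = seq(0, 1, length.out = n_groups + 1L))
  if (anyDuplicated(breaks))
    stop_ribocn("ties in '", grouping_variable,
                "' prevent ", n_groups, " distinct quantile groups")
  labels <- if (n_groups == 5L) c("Low", "Mid-Low", "Mid", "Mid-High", "High")
  else paste0("Q", seq_len(n_groups))
  grp <- cut(x, breaks = breaks, include.lowest = TRUE, labels = labels)
  alpha <- 1 - conf_level
  res <- lapply(levels(grp), function(g) {
    yy <- y[grp == g]
    n <- length(yy); m <- mean(yy)
    half <- qt(1 - alpha / 2, df = n - 1L) * sd(yy) / sqrt(n)
    data.frame(group = g, n = n, mean = m, ci_low = m - half, ci_high = m + half)
  })
  out <- do.call(rbind, res)
  out$group <- factor(out$group, levels = labels)
  class(out) <- c("quantile_trend", "data.frame")
  out
}

#' Rank-based two-group difference test
#'
#' Wilcoxon rank-sum (or signed-rank when `paired`) test for a difference
#' in location, as used for sequencing-center mean comparisons.
#'
#' @param values_a,values_b numeric samples (at least 3 each).
#' @param paired paired signed-rank test.
#' @return list with `statistic` and `p`.
#' @export
group_difference_test <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop_ribocn("need at least 3 observations per group")
  if (paired && all(values_a == values_b) ||
      (!paired && length(unique(c(values_a, values_b))) == 1L))
    stop_ribocn("degenerate all-tied input", class = "ribocn_degenerate_data")
  wt <- suppressWarnings(wilcox.test(values_a, values_b, paired = paired))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
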