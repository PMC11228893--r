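#' Load and validate a sample manifest
#'
#' A manifest is a TSV with header and columns `sample_id`, `path` (the
#' alignment file) and `center` (sequencing-center batch label). Duplicate
#' sample ids and empty center labels are rejected.
#'
#' @param source path to a TSV file, or a data.frame.
#' @return validated data.frame.
#' @export
load_manifest <- function(source) {
  df <- if (is.data.frame(source)) source else read_tsv(source)
  need <- c("sample_id", "path", "center")
  if (!all(need %in% names(df)))
    stop_ribocn("manifest must have columns ", paste(need, collapse = ", "),
                class = "ribocn_schema_error")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop_ribocn("duplicate sample id(s): ", paste(dup, collapse = ", "),
                class = "ribocn_validation_error")
  if (any(is.na(df$center) | !nzchar(as.character(df$center))))
    stop_ribocn("empty center label(s) in manifest",
                class = "ribocn_validation_error")
  df
}

#' Infer the sequencing-center batch from an alignment header
#'
#' Optional helper implementing the read-group heuristic used for the first
#' UK Biobank WGS release: records whose RG line contains `CN:SC` are
#' Sanger (further split into `"Sanger Vanguard"` when `Main Phase` is
#' absent), all others deCODE. Manifest labels are authoritative; this is a
#' convenience for compatible files.
#'
#' @param bam path to an alignment file.
#' @return center label.
#' @export
sniff_center <- function(bam) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$text
  rg <- hdr[names(hdr) == "@RG"]
  rg <- unlist(rg, use.names = FALSE)
  if (!length(rg)) return("deCODE")
  txt <- paste(rg, collapse = " ")
  if (grepl("CN:SC", txt, fixed = TRUE)) {
    if (grepl("Main Phase", txt, fixed = TRUE)) "Sanger" else "Sanger Vanguard"
  } else "deCODE"
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(summary, name, out_dir, fun) {
  res <- tryCatch(fun(), error = function(e) e)
  if (inherits(res, "error")) {
    summary$stages[[name]] <- list(status = "failed",
                                   error = conditionMessage(res))
    summary$status <- "failed"
  } else {
    summary$stages[[name]] <- c(list(status = "ok"), res$info)
    summary$value[[name]] <- res$value
  }
  summary
}

#' Run the estimation-to-association pipeline
#'
#' Executes the stages in order -- `estimate` (18S Ratios over a manifest),
#' `adjust` (sequencing-center adjustment), `derive` (blood ratios and eGFR
#' where the cohort table carries the needed columns) and `associate`
#' (configured model fits) -- writing one TSV per stage plus a JSON run
#' summary. Stages without configured inputs are skipped. A stage failure
#' retains earlier outputs, records the error in the summary, and signals
#' an error after writing it. Re-running with an identical config
#' reproduces identical outputs.
#'
#' @param config named list: `manifest` (path or data.frame), `regions`
#'   (BED path or GRanges), `reference_center`, `cohort` (path or
#'   data.frame), `models` (list of lists with response / exposure /
#'   covariates / family), `constants`, `egfr_variants`, `seed`.
#' @param out_dir artifact directory (created).
#' @return the run summary, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  constants <- config$constants %||% conversion_constants()
  summary <- list(tool = "ribocn",
                  version = as.character(packageVersion("ribocn")),
                  config_hash = config_hash(config),
                  seed = config$seed, status = "ok",
                  stages = list(), value = list())
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ..., "\n",
                            file = log_path, append = TRUE)

  if (!is.null(config$manifest)) {
    summary <- run_stage(summary, "estimate", out_dir, function() {
      logf("stage estimate")
      manifest <- load_manifest(config$manifest)
      regions <- if (is.character(config$regions)) read_region_bed(config$regions)
                 else config$regions
      est <- estimate_ratios(manifest, regions, constants = constants)
      write_tsv(as.data.frame(est), file.path(out_dir, "estimates.tsv"))
      list(value = est, info = list(n_samples = nrow(est)))
    })
    if (summary$status == "ok" && !is.null(config$reference_center)) {
      summary <- run_stage(summary, "adjust", out_dir, function() {
        logf("stage adjust")
        adj <- center_adjust(summary$value$estimate, config$reference_center)
        write_tsv(as.data.frame(adj), file.path(out_dir, "estimates_adjusted.tsv"))
        list(value = adj, info = list(reference_center = config$reference_center))
      })
    }
  }
  cohort <- NULL
  if (summary$status == "ok" && !is.null(config$cohort)) {
    summary <- run_stage(summary, "derive", out_dir, function() {
      logf("stage derive")
      cohort <- if (is.data.frame(config$cohort)) config$cohort
                else read_tsv(config$cohort)
      blood_cols <- c("neutrophils", "lymphocytes", "platelets", "monocytes")
      if (all(blood_cols %in% names(cohort)))
        cohort <- cbind(cohort, blood_ratios(cohort))
      if (all(c("scr", "age", "sex") %in% names(cohort)))
        for (v in (config$egfr_variants %||% "cr"))
          cohort[[paste0("egfr_", v)]] <-
            egfr(scr = cohort$scr, scc = cohort$scc, age = cohort$age,
                 sex = cohort$sex, variant = v)
      write_tsv(cohort, file.path(out_dir, "cohort_derived.tsv"))
      list(value = cohort, info = list(n_participants = nrow(cohort)))
    })
    cohort <- summary$value$derive
  }
  if (summary$status == "ok" && !is.null(config$models) && !is.null(cohort)) {
    summary <- run_stage(summary, "associate", out_dir, function() {
      logf("stage associate")
      res <- do.call(rbind, lapply(config$models, function(m)
        as.data.frame(fit_association(
          cohort, response = m$response, exposure = m$exposure,
          covariates = m$covariates %||% character(0),
          family = m$family %||% "linear"))))
      write_tsv(res, file.path(out_dir, "associations.tsv"))
      list(value = res, info = list(n_models = nrow(res)))
    })
  }
  out <- summary[setdiff(names(summary), "value")]
  jsonlite::write_json(out, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("status", out$status)
  if (out$status == "failed") {
    failed <- names(Filter(function(s) identical(s$status, "failed"), out$stages))
    stop_ribocn("pipeline stage failed: ", paste(failed, collapse = ", "),
                class = "ribocn_pipeline_error")
  }
  invisible(summary)
}
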