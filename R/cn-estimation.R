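#' Conversion constants for copy-number equivalents
#'
#' `genome_bases` is the total length of the numbered (1-22) chromosomes in
#' Hg38 (2,875,001,522 bases) and `subunit_bases` the size of the 18S subunit
#' used as the per-copy yardstick (1,871 bases as conventionally quoted; note
#' the 18S query spans 1,869 bases, positions 3658-5526 of the unit -- the
#' two-base difference is a documented quirk of the published constant, kept
#' configurable here).
#'
#' @param genome_bases total numbered-chromosome bases.
#' @param subunit_bases 18S subunit size in bases.
#' @return list of validated constants.
#' @export
conversion_constants <- function(genome_bases = 2875001522, subunit_bases = 1871) {
  assert_scalar_number(genome_bases, "genome_bases", positive = TRUE)
  assert_scalar_number(subunit_bases, "subunit_bases", positive = TRUE)
  list(genome_bases = genome_bases, subunit_bases = subunit_bases)
}

numbered_chromosome_pattern <- "^(chr)?([1-9]|1[0-9]|2[0-2])$"

check_bam_index <- function(bam) {
  if (!file.exists(bam)) stop_ribocn("alignment file not found: ", bam)
  idx <- paste0(bam, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam)
  if (!file.exists(idx) && !file.exists(idx2) &&
      !file.exists(paste0(bam, ".crai")))
    stop_ribocn("missing index for ", bam)
  invisible(bam)
}

#' Count reads overlapping the 18S analogue regions
#'
#' Counts each alignment record that overlaps any analogue region by at least
#' one base exactly once, even when it overlaps several regions
#' (count-once-across-regions semantics, equivalent to a multi-region
#' `samtools view -c -M -L` call). The default policy counts every mapped
#' record, mirroring a plain counting command; `policy = "primary_only"`
#' additionally drops secondary, supplementary and duplicate records.
#'
#' @param bam path to an indexed BAM (or CRAM) file.
#' @param regions [GenomicRanges::GRanges] of analogue regions.
#' @param policy `"all"` (default) or `"primary_only"`.
#' @return Non-negative integer count.
#' @export
count_region_reads <- function(bam, regions, policy = c("all", "primary_only")) {
  policy <- match.arg(policy)
  check_bam_index(bam)
  stopifnot(is(regions, "GRanges"))
  if (length(regions) == 0L) return(0L)
  targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(regions))),
                     names(targets))
  if (length(missing))
    stop_ribocn("region contig(s) absent from alignment header: ",
                paste(missing, collapse = ", "))
  red <- GenomicRanges::reduce(regions)
  flags <- if (policy == "primary_only")
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE, isDuplicate = FALSE)
  else Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(which = red, flag = flags,
                                   what = c("qname", "flag", "rname", "pos", "cigar"))
  res <- Rsamtools::scanBam(bam, param = param)
  keys <- unlist(lapply(res, function(r)
    paste(r$qname, r$flag, r$rname, r$pos, r$cigar, sep = "\r")), use.names = FALSE)
  length(unique(keys))
}

#' Per-contig mapped read counts
#'
#' Mapped record counts per contig from the alignment index (the `samtools
#' idxstats` numbers); unmapped records are excluded.
#'
#' @param bam path to an indexed BAM file.
#' @return Named integer vector of mapped-record counts, one per contig.
#' @export
count_chromosome_reads <- function(bam) {
  check_bam_index(bam)
  st <- Rsamtools::idxstatsBam(bam)
  setNames(as.integer(st$mapped), as.character(st$seqnames))
}

#' Sum of reads mapped to numbered chromosomes
#'
#' Recognises both naming dialects (`"chr1"` and `"1"`) for chromosomes 1-22.
#'
#' @param contig_counts named vector from [count_chromosome_reads()].
#' @return Total mapped reads on numbered chromosomes.
#' @export
numbered_chromosome_sum <- function(contig_counts) {
  if (is.null(names(contig_counts))) stop_ribocn("contig_counts must be named")
  sel <- grepl(numbered_chromosome_pattern, names(contig_counts))
  if (!any(sel))
    stop_ribocn("no numbered chromosome (chr1-chr22 or 1-22) found among contigs")
  sum(as.numeric(contig_counts[sel]))
}

#' Compute the 18S Ratio
#'
#' The rDNA copy-number proxy: reads overlapping 18S analogue regions divided
#' by the total reads mapped to numbered chromosomes.
#'
#' @param region_reads non-negative integer from [count_region_reads()].
#' @param contig_counts named per-contig counts, or a single positive number
#'   already summed over numbered chromosomes.
#' @return Dimensionless ratio.
#' @export
compute_18s_ratio <- function(region_reads, contig_counts) {
  assert_scalar_number(region_reads, "region_reads", nonneg = TRUE)
  total <- if (length(contig_counts) == 1L && is.null(names(contig_counts)))
    as.numeric(contig_counts) else numbered_chromosome_sum(contig_counts)
  if (total <= 0)
    stop_ribocn("zero numbered-chromosome baseline",
                class = "ribocn_estimation_error")
  region_reads / total
}

#' Convert an 18S Ratio to a total rDNA copy-number equivalent
#'
#' `ratio * genome_bases / subunit_bases`: the ratio rescaled so one diploid
#' genome's worth of numbered-chromosome reads corresponds to the genome
#' size, and each 18S subunit length of analogue reads to one rDNA copy.
#'
#' @param ratio 18S Ratio (vectorised).
#' @param constants [conversion_constants()].
#' @return Copy-number equivalents (copies per diploid genome).
#' @export
ratio_to_cn_equivalent <- function(ratio, constants = conversion_constants()) {
  if (any(!is.na(ratio) & ratio < 0)) stop_ribocn("ratio must be >= 0")
  ratio * constants$genome_bases / constants$subunit_bases
}

#' Tailored-assembly copy-number estimate
#'
#' The prior published estimator used for cross-validation: twice the ratio
#' of mean per-base read depth over the 18S subunit (from a tailored
#' whole-genome alignment) to mean depth over a filtered exome baseline. The
#' factor two reflects the diploid baseline.
#'
#' @param depth_18s mean 18S read depth (vectorised).
#' @param depth_exome mean exome read depth (vectorised, must be > 0).
#' @return Copy-number estimate(s).
#' @export
tailored_cn_estimate <- function(depth_18s, depth_exome) {
  if (any(!is.na(depth_18s) & depth_18s < 0)) stop_ribocn("depth_18s must be >= 0")
  if (any(!is.na(depth_exome) & depth_exome <= 0))
    stop_ribocn("zero or negative exome depth", class = "ribocn_estimation_error")
  2 * depth_18s / depth_exome
}

#' Estimate 18S Ratios for a manifest of alignments
#'
#' Runs region and baseline counting for every sample in a manifest and
#' assembles the per-sample estimate table. Samples with an invalid baseline
#' are flagged with a machine-readable reason rather than dropped.
#'
#' @param manifest data.frame from [load_manifest()] with columns
#'   `sample_id`, `path`, `center`.
#' @param regions [GenomicRanges::GRanges] of 18S analogue regions.
#' @param constants [conversion_constants()].
#' @param policy record-inclusion policy, see [count_region_reads()].
#' @return An object of class `rdna_ratio_set`: a data.frame with columns
#'   `sample_id`, `region_reads`, `numbered_reads`, `ratio`, `cn_equivalent`,
#'   `center`, `flag`.
#' @export
estimate_ratios <- function(manifest, regions, constants = conversion_constants(),
                            policy = "all") {
  stopifnot(is.data.frame(manifest))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    bam <- manifest$path[i]
    rr <- count_region_reads(bam, regions, policy = policy)
    cc <- count_chromosome_reads(bam)
    out <- data.frame(sample_id = manifest$sample_id[i],
                      region_reads = rr, numbered_reads = NA_real_,
                      ratio = NA_real_, cn_equivalent = NA_real_,
                      center = manifest$center[i], flag = NA_character_)
    ratio <- tryCatch({
      out$numbered_reads <- numbered_chromosome_sum(cc)
      compute_18s_ratio(rr, cc)
    }, ribocn_error = function(e) {
      out$flag <<- conditionMessage(e)
      NA_real_
    })
    out$ratio <- ratio
    out$cn_equivalent <- ratio_to_cn_equivalent(ratio, constants)
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("rdna_ratio_set", "data.frame")
  res
}

new_ratio_set <- function(df) {
  class(df) <- c("rdna_ratio_set", "data.frame")
  df
}

#' @export
print.rdna_ratio_set <- function(x, ...) {
  cat(sprintf("18S Ratio estimates for %d sample(s) across %d center(s)\n",
              nrow(x), length(unique(x$center))))
  print.data.frame(head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.rdna_ratio_set <- function(object, ...) {
  ok <- is.finite(object$ratio)
  by_center <- tapply(object$ratio[ok], object$center[ok], mean)
  out <- list(n = nrow(object), n_flagged = sum(!is.na(object$flag)),
              mean_ratio = mean(object$ratio[ok]),
              mean_cn = mean(object$cn_equivalent[ok]),
              center_means = by_center)
  class(out) <- "summary.rdna_ratio_set"
  out
}

#' @export
print.summary.rdna_ratio_set <- function(x, ...) {
  cat(sprintf("%d samples (%d flagged); mean 18S Ratio %.4g, mean CN equivalent %.1f\n",
              x$n, x$n_flagged, x$mean_ratio, x$mean_cn))
  cat("per-center mean ratios:\n"); print(x$center_means)
  invisible(x)
}

#' @export
plot.rdna_ratio_set <- function(x, which = c("cn", "ratio"), ...) {
  which <- match.arg(which)
  v <- if (which == "cn") x$cn_equivalent else x$ratio
  graphics::hist(v[is.finite(v)], breaks = 30,
                 main = "rDNA copy-number equivalents",
                 xlab = if (which == "cn") "CN equivalent (copies)" else "18S Ratio")
  invisible(x)
}

#' Sequencing-center batch adjustment
#'
#' Fits `ratio ~ center` (one categorical predictor) on all supplied samples
#' and subtracts each non-reference center's coefficient from its samples'
#' ratios, so every center mean equals the reference-center mean. Applying
#' the adjustment twice is a no-op.
#'
#' @param estimates an `rdna_ratio_set` or data.frame with `ratio` and
#'   `center` columns.
#' @param reference_center the center whose mean is preserved (default
#'   `"deCODE"`).
#' @return The input with an `adjusted_ratio` column.
#' @export
center_adjust <- function(estimates, reference_center = "deCODE") {
  stopifnot(is.data.frame(estimates), all(c("ratio", "center") %in% names(estimates)))
  centers <- unique(as.character(estimates$center))
  if (!reference_center %in% centers)
    stop_ribocn("reference center '", reference_center, "' not present")
  if (length(centers) < 2L) {
    warning("single-center input: adjustment is the identity")
    estimates$adjusted_ratio <- estimates$ratio
    return(estimates)
  }
  cf <- factor(estimates$center, levels = c(reference_center,
                                            setdiff(centers, reference_center)))
  fit <- lm(ratio ~ cf, data = data.frame(ratio = estimates$ratio, cf = cf))
  shift <- c(0, coef(fit)[-1L])[as.integer(cf)]
  estimates$adjusted_ratio <- estimates$ratio - shift
  estimates
}

#' Familial correlation of copy-number estimates
#'
#' Pearson correlation between the two members' estimates across relative
#' pairs (member ordering as given in the pair records), as used to quantify
#' the heritable signal in MZ-twin through third-degree pairs.
#'
#' @param values named numeric vector of per-individual estimates (ratios or
#'   CN equivalents), names are participant ids.
#' @param pairs data.frame with columns `id1`, `id2` and optionally
#'   `category`.
#' @param category if given, restrict to pairs of this relationship category.
#' @return list with `r`, `p` and `n_pairs` (class `familial_correlation`).
#' @export
familial_correlation <- function(values, pairs, category = NULL) {
  stopifnot(is.data.frame(pairs), all(c("id1", "id2") %in% names(pairs)))
  if (!is.null(category)) {
    if (!"category" %in% names(pairs)) stop_ribocn("pairs lack a category column")
    pairs <- pairs[pairs$category == category, , drop = FALSE]
  }
  v1 <- values[as.character(pairs$id1)]
  v2 <- values[as.character(pairs$id2)]
  ok <- is.finite(v1) & is.finite(v2)
  if (sum(ok) < 3L)
    stop_ribocn("fewer than 3 estimated pairs", class = "ribocn_insufficient_data")
  ct <- cor.test(v1[ok], v2[ok], method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok)),
            class = "familial_correlation")
}

#' @export
print.familial_correlation <- function(x, ...) {
  cat(sprintf("Pearson R = %.3f (p = %.3g) over %d pairs\n", x$r, x$p, x$n_pairs))
  invisible(x)
}
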