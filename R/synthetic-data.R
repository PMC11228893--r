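#' Configuration for synthetic read-placement simulation
#'
#' Describes a toy genome for the read-count estimator: numbered background
#' contigs, 18S-analogue intervals placed on them, a toy rDNA subunit length
#' `unit_length` (the per-copy yardstick), a true copy number, and the read
#' geometry. Each simulated read falls in the rDNA compartment with
#' probability `true_cn * unit_length / (true_cn * unit_length + G)` where
#' `G` is the total background size, and is then placed uniformly within an
#' analogue region; otherwise it is placed uniformly on the background.
#' Defaults use large header-declared contigs (no sequence needed for
#' counting), so the analogue self-contribution to the numbered baseline is
#' negligible, as in the real genome.
#'
#' @param background_genome named vector of contig lengths (numbered
#'   dialect).
#' @param analogue_regions [GenomicRanges::GRanges] on those contigs; NULL
#'   places four 600-base regions on the first contig.
#' @param unit_length toy 18S subunit length in bases.
#' @param true_cn true copy number (copies per diploid genome).
#' @param read_length read length in bases.
#' @param n_reads number of reads to simulate.
#' @param seed integer seed.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(background_genome = c(chr1 = 1e8, chr2 = 1e8),
                            analogue_regions = NULL,
                            unit_length = 2000, true_cn = 300,
                            read_length = 150, n_reads = 2e5, seed = 1L) {
  if (is.null(names(background_genome)) || any(!nzchar(names(background_genome))))
    stop_ribocn("background_genome must be a named length vector",
                class = "ribocn_config_error")
  if (is.null(analogue_regions)) {
    first <- names(background_genome)[1L]
    starts <- seq(10001, by = 5000, length.out = 4L)
    analogue_regions <- GenomicRanges::GRanges(
      first, IRanges::IRanges(starts, width = 600))
  }
  stopifnot(is(analogue_regions, "GRanges"))
  ctg <- as.character(GenomicRanges::seqnames(analogue_regions))
  if (!all(ctg %in% names(background_genome)))
    stop_ribocn("analogue regions name unknown contigs", class = "ribocn_config_error")
  if (any(GenomicRanges::end(analogue_regions) > background_genome[ctg]))
    stop_ribocn("analogue region extends past its contig", class = "ribocn_config_error")
  if (any(GenomicRanges::width(analogue_regions) < read_length))
    stop_ribocn("analogue regions must be at least one read long",
                class = "ribocn_config_error")
  assert_scalar_number(unit_length, "unit_length", positive = TRUE)
  assert_scalar_number(true_cn, "true_cn", nonneg = TRUE)
  assert_scalar_number(n_reads, "n_reads", positive = TRUE)
  structure(list(background_genome = background_genome,
                 analogue_regions = analogue_regions,
                 unit_length = unit_length, true_cn = true_cn,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Probability that a read falls in the rDNA compartment
#' @param config [read_sim_config()].
#' @return scalar probability.
#' @export
rdna_compartment_probability <- function(config) {
  G <- sum(config$background_genome)
  with(config, true_cn * unit_length / (true_cn * unit_length + G))
}

#' Write a toy reference genome and matching analogue BED
#'
#' Generates random background contigs with copies of a toy 18S query
#' planted at the configured analogue coordinates, and writes the matching
#' BED. Intended for exercising discovery and BED round-trips at small
#' scale; read counting itself never needs the sequence.
#'
#' @param config [read_sim_config()] with a total genome below 5e7 bases.
#' @param dir output directory.
#' @return list with paths `fasta`, `bed`, and the planted `query` sequence
#'   (character).
#' @export
simulate_reference <- function(config, dir = tempfile("ref")) {
  stopifnot(inherits(config, "read_sim_config"))
  if (sum(config$background_genome) > 5e7)
    stop_ribocn("reference too large to write; use counting-level simulation",
                class = "ribocn_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  qlen <- max(GenomicRanges::width(config$analogue_regions))
  query <- paste(sample(bases, qlen, replace = TRUE), collapse = "")
  contigs <- lapply(config$background_genome, function(len)
    paste(sample(bases, len, replace = TRUE), collapse = ""))
  for (i in seq_along(config$analogue_regions)) {
    r <- config$analogue_regions[i]
    ctg <- as.character(GenomicRanges::seqnames(r))
    w <- GenomicRanges::width(r)
    substr(contigs[[ctg]], GenomicRanges::start(r), GenomicRanges::end(r)) <-
      substr(query, 1L, w)
  }
  seqs <- Biostrings::DNAStringSet(unlist(contigs))
  names(seqs) <- names(config$background_genome)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(seqs, fasta)
  bed <- file.path(dir, "analogues.bed")
  write_region_bed(config$analogue_regions, bed)
  list(fasta = fasta, bed = bed, query = query)
}

#' Simulate a sorted, indexed alignment with known true copy number
#'
#' Placement-only simulation: each read is assigned to the rDNA compartment
#' with the configured probability and placed uniformly within an analogue
#' region (region chosen proportional to width), otherwise uniformly on the
#' background contigs. Records carry no base calls (the estimator consumes
#' placements). The SAM text is converted, coordinate-sorted and indexed.
#'
#' @param config [read_sim_config()].
#' @param dir output directory.
#' @return list with `bam` path and `truth` (true_cn, expected compartment
#'   probability, realized region read count).
#' @export
simulate_alignment <- function(config, dir = tempfile("aln")) {
  stopifnot(inherits(config, "read_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_reads; rl <- config$read_length
  regions <- config$analogue_regions
  glens <- config$background_genome
  p <- rdna_compartment_probability(config)
  in_region <- runif(n) < p
  n_reg <- sum(in_region); n_bg <- n - n_reg
  rname <- character(n); pos <- integer(n)
  if (n_reg > 0L) {
    w <- GenomicRanges::width(regions) - rl + 1L
    ridx <- sample.int(length(regions), n_reg, replace = TRUE, prob = w)
    pos[in_region] <- GenomicRanges::start(regions)[ridx] +
      floor(runif(n_reg) * w[ridx])
    rname[in_region] <- as.character(GenomicRanges::seqnames(regions))[ridx]
  }
  if (n_bg > 0L) {
    cidx <- sample.int(length(glens), n_bg, replace = TRUE, prob = glens)
    bpos <- 1L + floor(runif(n_bg) * (glens[cidx] - rl))
    bname <- names(glens)[cidx]
    ## the background compartment excludes the analogue intervals: resample
    ## placements that would overlap a region
    repeat {
      bgr <- GenomicRanges::GRanges(bname, IRanges::IRanges(bpos, width = rl))
      bad <- IRanges::overlapsAny(bgr, regions)
      if (!any(bad)) break
      nb <- sum(bad)
      ci <- sample.int(length(glens), nb, replace = TRUE, prob = glens)
      bpos[bad] <- 1L + floor(runif(nb) * (glens[ci] - rl))
      bname[bad] <- names(glens)[ci]
    }
    pos[!in_region] <- bpos
    rname[!in_region] <- bname
  }
  sam <- file.path(dir, "sim.sam")
  con <- file(sam, open = "wt")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(glens), as.integer(glens))), con)
  writeLines(sprintf("r%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                     seq_len(n), rname, pos, rl), con)
  close(con)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "sim_unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "sim"))
  Rsamtools::indexBam(bam)
  unlink(c(sam, bam0))
  list(bam = bam,
       truth = list(true_cn = config$true_cn, p_region = p,
                    region_reads = n_reg, n_reads = n))
}

#' Counting-level simulation of proxy estimates for many samples
#'
#' Draws per-sample region read counts directly from the binomial
#' compartment model at full genome scale (no alignment files), returning
#' the same per-sample table [estimate_ratios()] would produce. The
#' numbered-chromosome baseline is the non-region remainder, mirroring
#' analogue regions hosted on unplaced scaffolds.
#'
#' @param true_cn vector of true copy numbers, one per sample.
#' @param n_reads mapped reads per sample (default 6e8, about 30x).
#' @param constants [conversion_constants()]; also defines the genome and
#'   subunit sizes of the generative model.
#' @param center center label(s) recycled across samples.
#' @param seed integer seed.
#' @return `rdna_ratio_set` data.frame with a `true_cn` column.
#' @export
simulate_sample_counts <- function(true_cn, n_reads = 6e8,
                                   constants = conversion_constants(),
                                   center = "deCODE", seed = 1L) {
  set.seed(seed)
  ns <- length(true_cn)
  G <- constants$genome_bases; L <- constants$subunit_bases
  p <- true_cn * L / (true_cn * L + G)
  region <- rbinom(ns, size = as.integer(n_reads), prob = p)
  numbered <- n_reads - region
  ratio <- region / numbered
  df <- data.frame(sample_id = sprintf("S%04d", seq_len(ns)),
                   true_cn = true_cn,
                   region_reads = region, numbered_reads = numbered,
                   ratio = ratio,
                   cn_equivalent = ratio_to_cn_equivalent(ratio, constants),
                   center = rep_len(center, ns), flag = NA_character_)
  new_ratio_set(df)
}

#' Simulate 18S/exome depth pairs for the tailored estimator
#'
#' Mean 18S depth is `true_cn * exome_depth / 2` with Poisson-scale noise
#' (total bases over the subunit are Poisson), so the tailored estimator
#' recovers `true_cn` in expectation; with `noise = FALSE` it recovers it
#' exactly.
#'
#' @param true_cn vector of true copy numbers.
#' @param exome_depth mean exome depth (default 30).
#' @param subunit_bases subunit length over which 18S depth is averaged.
#' @param exome_bases effective baseline size over which exome depth is
#'   averaged.
#' @param noise add Poisson sampling noise.
#' @param seed integer seed.
#' @return data.frame with `true_cn`, `depth_18s`, `depth_exome`.
#' @export
simulate_depth_pairs <- function(true_cn, exome_depth = 30,
                                 subunit_bases = 1871, exome_bases = 1e6,
                                 noise = TRUE, seed = 1L) {
  set.seed(seed)
  assert_scalar_number(exome_depth, "exome_depth", positive = TRUE)
  mu18 <- true_cn * exome_depth / 2
  if (noise) {
    d18 <- rpois(length(true_cn), mu18 * subunit_bases) / subunit_bases
    dex <- rpois(length(true_cn), exome_depth * exome_bases) / exome_bases
  } else {
    d18 <- mu18; dex <- rep(exome_depth, length(true_cn))
  }
  data.frame(true_cn = true_cn, depth_18s = d18, depth_exome = dex)
}

#' Simulate a kinship table with known family structure
#'
#' Families are chains of relative pairs with kinship drawn inside the
#' requested category band, IBS0 consistent with the parental/fraternal
#' rule, and birth years consistent with the 10-year parental gap. Filler
#' pairs between unrelated individuals carry kinship below the third-degree
#' band.
#'
#' @param family_sizes integer vector, one entry per family (each >= 2).
#' @param categories category per family (`"MZ"`, `"FIRST"`, `"SECOND"`,
#'   `"THIRD"`), recycled.
#' @param first_subtype for FIRST-degree families: `"PARENTAL"` or
#'   `"FRATERNAL"`, recycled.
#' @param n_unrelated_pairs filler unrelated pairs to append.
#' @param thresholds [kinship_thresholds()].
#' @param seed integer seed.
#' @return list with `pairs` (id1, id2, kinship, ibs0, birth_year1,
#'   birth_year2, category) and `truth` (family membership data.frame,
#'   `birth_years` named vector).
#' @export
simulate_kinship <- function(family_sizes = c(3L, 2L, 2L),
                             categories = "FIRST",
                             first_subtype = "FRATERNAL",
                             n_unrelated_pairs = 0L,
                             thresholds = kinship_thresholds(), seed = 1L) {
  set.seed(seed)
  stopifnot(all(family_sizes >= 2L))
  categories <- rep_len(categories, length(family_sizes))
  first_subtype <- rep_len(first_subtype, length(family_sizes))
  t <- thresholds
  band <- function(cat) switch(cat,
    MZ = c(t$mz + 0.01, 0.5),
    FIRST = c(t$first_low, t$first_high),
    SECOND = c(t$boundary_23, t$first_low - 1e-4),
    THIRD = c(t$third_low, t$boundary_23 - 1e-4),
    stop_ribocn("unknown category ", cat))
  pairs <- list(); truth_fam <- list(); byrs <- c()
  for (f in seq_along(family_sizes)) {
    m <- family_sizes[f]
    ids <- sprintf("F%02dI%02d", f, seq_len(m))
    parental <- categories[f] == "FIRST" && first_subtype[f] == "PARENTAL"
    yr <- if (parental) 1940 + 25 * (seq_len(m) - 1L)
          else 1950 + sample.int(8, m, replace = TRUE) - 1L
    names(yr) <- ids
    byrs <- c(byrs, yr)
    truth_fam[[f]] <- data.frame(id = ids, family = f)
    b <- band(categories[f])
    for (i in seq_len(m - 1L)) {
      k <- runif(1, b[1L], b[2L])
      ibs0 <- if (categories[f] != "FIRST") runif(1, 0.002, 0.01)
              else if (parental) runif(1, 0, 0.0011) else runif(1, 0.002, 0.01)
      pairs[[length(pairs) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[i + 1L], kinship = k, ibs0 = ibs0,
        birth_year1 = yr[i], birth_year2 = yr[i + 1L],
        category = categories[f])
    }
  }
  if (n_unrelated_pairs > 0L) {
    for (u in seq_len(n_unrelated_pairs)) {
      ids <- sprintf("U%03d%s", u, c("A", "B"))
      yr <- 1950 + sample.int(30, 2, replace = TRUE)
      byrs <- c(byrs, setNames(yr, ids))
      pairs[[length(pairs) + 1L]] <- data.frame(
        id1 = ids[1L], id2 = ids[2L],
        kinship = runif(1, 0, t$third_low - 1e-4),
        ibs0 = runif(1, 0.005, 0.02),
        birth_year1 = yr[1L], birth_year2 = yr[2L],
        category = "UNRELATED")
    }
  }
  list(pairs = do.call(rbind, pairs),
       truth = list(families = do.call(rbind, truth_fam), birth_years = byrs))
}

#' Configuration for cohort simulation
#'
#' Generative model for a synthetic cohort with known effect sizes. True
#' copy number is Gaussian (truncated to `cn_range`) with optional family
#' blocks sharing a latent component: within a family,
#' `cn = sqrt(rho) * family_effect + sqrt(1 - rho) * individual_effect`,
#' giving intra-family correlation `rho`. The observed ratio is
#' `cn * L / G` plus a per-center offset and measurement noise. Continuous
#' traits are `beta * z(cn) + small covariate effects + Gaussian noise`
#' scaled so the standardized effect equals `beta`; binary traits use a
#' logistic link with the given log-odds per SD of copy number. Defaults
#' anchor to the population range of roughly 100-600 copies (mean 315,
#' sd 80) and exercise a positive Sanger-vs-deCODE offset.
#'
#' @param n participants.
#' @param cn_mean,cn_sd,cn_range copy-number distribution (copies).
#' @param effects named standardized betas for continuous traits.
#' @param binary_effects named log-odds (per SD of CN) for binary traits.
#' @param binary_prevalence baseline prevalence for binary traits.
#' @param center_levels,center_probs,center_offsets sequencing-center
#'   labels, sampling proportions and additive ratio offsets.
#' @param ratio_noise_sd measurement noise on the ratio scale.
#' @param family_sizes,rho optional family block sizes and intra-family CN
#'   correlation.
#' @param covariate_sd standardized effect of each nuisance covariate on
#'   every trait.
#' @param constants [conversion_constants()].
#' @param seed integer seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 20000L, cn_mean = 315, cn_sd = 80,
                              cn_range = c(50, 800),
                              effects = c(neutrophils = 0.0273),
                              binary_effects = c(kidney_failure = log(1.04)),
                              binary_prevalence = 0.08,
                              center_levels = c("deCODE", "Sanger"),
                              center_probs = c(0.5, 0.5),
                              center_offsets = c(deCODE = 0, Sanger = 1e-5),
                              ratio_noise_sd = 2e-6,
                              family_sizes = NULL, rho = 0,
                              covariate_sd = 0.05,
                              constants = conversion_constants(), seed = 1L) {
  stopifnot(abs(rho) <= 1, cn_sd > 0, n > 0)
  structure(list(n = as.integer(n), cn_mean = cn_mean, cn_sd = cn_sd,
                 cn_range = cn_range, effects = effects,
                 binary_effects = binary_effects,
                 binary_prevalence = binary_prevalence,
                 center_levels = center_levels, center_probs = center_probs,
                 center_offsets = center_offsets,
                 ratio_noise_sd = ratio_noise_sd,
                 family_sizes = family_sizes, rho = rho,
                 covariate_sd = covariate_sd, constants = constants,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a cohort table with known ground truth
#'
#' @param config [cohort_sim_config()].
#' @return list with `table` (data.frame: id, family, true_cn, ratio,
#'   cn_equivalent, center, sex, age, age_sq, assessment_center, pc1, pc2,
#'   telomere, month, hour, one column per trait) and `truth` (the config's
#'   effect maps plus the drawn family assignment).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n
  ## family blocks with shared latent component
  if (!is.null(config$family_sizes) && length(config$family_sizes)) {
    fam_of <- integer(0)
    for (f in seq_along(config$family_sizes))
      fam_of <- c(fam_of, rep(f, config$family_sizes[f]))
    if (length(fam_of) > n) stop_ribocn("family blocks exceed cohort size",
                                        class = "ribocn_config_error")
    fam_of <- c(fam_of, seq(length(config$family_sizes) + 1L,
                            length.out = n - length(fam_of)))
  } else fam_of <- seq_len(n)
  z_fam <- rnorm(max(fam_of))[fam_of]
  z_ind <- rnorm(n)
  rho <- config$rho
  z_cn <- sqrt(rho) * z_fam + sqrt(1 - rho) * z_ind
  cn <- pmin(pmax(config$cn_mean + config$cn_sd * z_cn, config$cn_range[1L]),
             config$cn_range[2L])
  G <- config$constants$genome_bases; L <- config$constants$subunit_bases
  center <- sample(config$center_levels, n, replace = TRUE,
                   prob = config$center_probs)
  ratio <- cn * L / G + config$center_offsets[center] +
    rnorm(n, 0, config$ratio_noise_sd)
  zx <- as.numeric(scale(cn))
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 40, 70)
  assessment_center <- sample(c("AC1", "AC2", "AC3"), n, replace = TRUE)
  pc1 <- rnorm(n); pc2 <- rnorm(n); telomere <- rnorm(n)
  month <- sample.int(12L, n, replace = TRUE)
  hour <- sample(8:19, n, replace = TRUE)
  g <- config$covariate_sd
  cov_part <- g * (as.numeric(scale(age)) + pc1 + telomere)
  tab <- data.frame(id = sprintf("P%06d", seq_len(n)), family = fam_of,
                    true_cn = cn, ratio = unname(ratio),
                    cn_equivalent = ratio_to_cn_equivalent(unname(ratio),
                                                           config$constants),
                    center = center, sex = sex, age = age, age_sq = age^2,
                    assessment_center = assessment_center,
                    pc1 = pc1, pc2 = pc2, telomere = telomere,
                    month = month, hour = hour)
  for (tr in names(config$effects)) {
    b <- config$effects[[tr]]
    resid_sd <- sqrt(max(1 - b^2 - 3 * g^2, 0.01))
    tab[[tr]] <- b * zx + cov_part + rnorm(n, 0, resid_sd)
  }
  ## a trait with seasonal structure the copy number does not share,
  ## for reverse-causality null checks
  tab$seasonal_trait <- 0.2 * sin(2 * pi * tab$month / 12) + cov_part + rnorm(n)
  for (tr in names(config$binary_effects)) {
    eta <- qlogis(config$binary_prevalence) + config$binary_effects[[tr]] * zx
    tab[[tr]] <- rbinom(n, 1, plogis(eta))
  }
  list(table = tab,
       truth = list(effects = config$effects,
                    binary_effects = config$binary_effects,
                    rho = rho, family = fam_of,
                    center_offsets = config$center_offsets))
}
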