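#' Construct an rDNA unit sequence
#'
#' Container for a single 47S rDNA repeat-unit reference sequence (for human
#' work typically the GenBank KY962518.1 unit), together with the 1-based
#' position of the transcription start site (TSS) within the unit. The looped
#' reference and the 18S query are both derived from this object.
#'
#' @param id character identifier.
#' @param residues the nucleotide sequence: a [Biostrings::DNAString], a
#'   character scalar, or a length-1 [Biostrings::DNAStringSet].
#' @param tss_offset 1-based position of the TSS within the unit. KY962518.1
#'   begins at the TSS, so the default is 1.
#' @return An object of class `rdna_unit` with fields `id`, `residues`
#'   (DNAString) and `tss_offset`.
#' @export
rdna_unit <- function(id, residues, tss_offset = 1L) {
  if (is(residues, "DNAStringSet")) {
    if (length(residues) != 1L) stop_ribocn("residues must be a single sequence")
    residues <- residues[[1L]]
  }
  if (is.character(residues)) {
    residues <- tryCatch(Biostrings::DNAString(residues),
                         error = function(e) stop_ribocn("residues contain non-IUPAC characters"))
  }
  if (!is(residues, "DNAString")) stop_ribocn("residues must be a DNAString or character")
  len <- length(residues)
  if (len < 1L) stop_ribocn("empty unit sequence")
  tss_offset <- as.integer(tss_offset)
  if (is.na(tss_offset) || tss_offset < 1L || tss_offset > len)
    stop_ribocn("tss_offset must lie within 1..", len)
  structure(list(id = as.character(id), residues = residues,
                 tss_offset = tss_offset),
            class = "rdna_unit")
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat(sprintf("rDNA unit '%s': %d bp, TSS at position %d\n",
              x$id, length(x$residues), x$tss_offset))
  invisible(x)
}

#' @export
length.rdna_unit <- function(x) length(x$residues)

#' Read an rDNA unit from a FASTA file
#'
#' @param path FASTA file containing a single record.
#' @param tss_offset 1-based TSS position (see [rdna_unit()]).
#' @return An `rdna_unit`.
#' @export
read_rdna_unit <- function(path, tss_offset = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 1L) stop_ribocn("no sequences in ", path)
  rdna_unit(sub("\\s.*$", "", names(seqs)[1L]), seqs[[1L]], tss_offset)
}

#' Extract the 18S query subsequence from an rDNA unit
#'
#' The 18S subunit of the human KY962518.1 unit spans positions 3658 to 5526
#' (1-based inclusive, 1869 bases). The extracted query is what gets searched
#' against the assembly to locate 18S analogue regions.
#'
#' @param unit an [rdna_unit()].
#' @param start_1based,end_1based 1-based inclusive coordinates within the
#'   unit; defaults are the human 18S subunit bounds.
#' @return A [Biostrings::DNAString] of length `end - start + 1`.
#' @export
extract_18s_query <- function(unit, start_1based = 3658L, end_1based = 5526L) {
  stopifnot(inherits(unit, "rdna_unit"))
  len <- length(unit$residues)
  start_1based <- as.integer(start_1based); end_1based <- as.integer(end_1based)
  if (is.na(start_1based) || start_1based < 1L)
    stop_ribocn("start coordinate ", start_1based, " out of bounds (must be >= 1)",
                class = "ribocn_coordinate_error")
  if (is.na(end_1based) || end_1based > len)
    stop_ribocn("end coordinate ", end_1based, " out of bounds (unit length ", len, ")",
                class = "ribocn_coordinate_error")
  if (start_1based > end_1based)
    stop_ribocn("start coordinate ", start_1based, " exceeds end coordinate ", end_1based,
                class = "ribocn_coordinate_error")
  Biostrings::subseq(unit$residues, start_1based, end_1based)
}

#' Build the looped rDNA reference
#'
#' Rotates the unit so the sequence begins at a breakpoint a fixed distance
#' upstream of the TSS: the segment from the breakpoint to the end of the
#' (TSS-first) unit is prepended to the segment from the TSS up to the
#' breakpoint. This moves the unit's artificial start/end away from the
#' promoter so read coverage is not lost at the junction. Length and residue
#' content are preserved.
#'
#' @param unit an [rdna_unit()].
#' @param breakpoint_upstream_of_tss bases upstream of the TSS at which to
#'   break the circularised unit (default 2120, the midpoint of the
#'   repetitive element closest to the 3' end of the human unit).
#' @return A [Biostrings::DNAString]: the rotated unit.
#' @export
loop_rdna_reference <- function(unit, breakpoint_upstream_of_tss = 2120L) {
  stopifnot(inherits(unit, "rdna_unit"))
  k <- as.integer(breakpoint_upstream_of_tss)
  len <- length(unit$residues)
  if (is.na(k) || k < 0L || k >= len)
    stop_ribocn("breakpoint ", k, " bases upstream of the TSS falls outside the ",
                len, "-base unit", class = "ribocn_coordinate_error")
  ## rotate so the TSS is first, then break k bases before its (circular) end
  s <- unit$residues
  if (unit$tss_offset > 1L)
    s <- Biostrings::xscat(Biostrings::subseq(s, unit$tss_offset, len),
                           Biostrings::subseq(s, 1L, unit$tss_offset - 1L))
  if (k == 0L) return(Biostrings::DNAString(s))
  Biostrings::DNAString(Biostrings::xscat(Biostrings::subseq(s, len - k + 1L, len),
                                          Biostrings::subseq(s, 1L, len - k)))
}

## exhaustive ungapped segment finder along one diagonal.
## match is a logical vector; returns maximal positive-score segments under
## +1/match, -penalty/mismatch scoring, so every segment kept has identity
## >= min_identity over its own span.
max_score_segments <- function(match, min_identity, min_length) {
  penalty <- min_identity / (1 - min_identity + 1e-12)
  sc <- ifelse(match, 1, -penalty)
  n <- length(sc)
  out <- list()
  i <- 1L
  while (i <= n) {
    ## skip leading mismatches
    while (i <= n && !match[i]) i <- i + 1L
    if (i > n) break
    ## greedy max-scoring extension from i (Kadane-style restart)
    best <- 0; best_end <- i - 1L; run <- 0
    j <- i
    while (j <= n) {
      run <- run + sc[j]
      if (run > best) { best <- run; best_end <- j }
      if (run < 0) break
      j <- j + 1L
    }
    seg_start <- i; seg_end <- best_end
    if (seg_end >= seg_start) {
      w <- seg_end - seg_start + 1L
      ident <- sum(match[seg_start:seg_end]) / w
      if (w >= min_length && ident >= min_identity)
        out[[length(out) + 1L]] <- c(seg_start, seg_end)
    }
    i <- max(seg_end, seg_start) + 1L
  }
  out
}

diagonal_hits <- function(qraw, sraw, diags, min_identity, min_length) {
  qn <- length(qraw); sn <- length(sraw)
  res <- list()
  for (d in diags) {
    qlo <- max(1L, 1L - d); qhi <- min(qn, sn - d)
    if (qhi - qlo + 1L < min_length) next
    qi <- qlo:qhi
    match <- qraw[qi] == sraw[qi + d]
    for (seg in max_score_segments(match, min_identity, min_length)) {
      res[[length(res) + 1L]] <- c(qlo + seg[1L] - 1L + d, qlo + seg[2L] - 1L + d)
    }
  }
  res
}

seed_diagonals <- function(qchar, schar, word_size) {
  qn <- nchar(qchar); sn <- nchar(schar)
  if (qn < word_size || sn < word_size) return(integer(0))
  qk <- substring(qchar, seq_len(qn - word_size + 1L),
                  seq_len(qn - word_size + 1L) + word_size - 1L)
  sk <- substring(schar, seq_len(sn - word_size + 1L),
                  seq_len(sn - word_size + 1L) + word_size - 1L)
  hit <- match(sk, qk)                     # first query position per subject kmer
  spos <- which(!is.na(hit))
  if (!length(spos)) return(integer(0))
  ## all query positions sharing that kmer: expand via split
  qidx <- split(seq_along(qk), qk)
  diags <- unlist(lapply(spos, function(sp) sp - qidx[[sk[sp]]]), use.names = FALSE)
  sort(unique(diags))
}

#' Locate 18S analogue regions by local similarity search
#'
#' Self-contained ungapped seed-and-extend search: exact k-mer seeds anchor
#' diagonals, along which maximal segments with identity at least
#' `min_identity` over at least `min_length` aligned bases are reported. Both
#' strands are searched; matches are reported as forward-strand intervals
#' (read counting is strand-agnostic). Overlapping intervals within a contig
#' are merged. Output is deterministic: sorted by contig then start.
#'
#' @param query the query sequence (e.g. the 18S subunit from
#'   [extract_18s_query()]): DNAString or character.
#' @param subjects named [Biostrings::DNAStringSet] or named character vector
#'   of subject sequences (assembly contigs/scaffolds).
#' @param min_identity minimum identity fraction over the reported segment
#'   (default 0.90).
#' @param min_length minimum aligned length in bases (default 100).
#' @param word_size exact seed length (default 11).
#' @return A [GenomicRanges::GRanges] of merged analogue intervals with the
#'   query length recorded in `metadata(x)$query_length`.
#' @export
find_analogue_regions <- function(query, subjects, min_identity = 0.90,
                                  min_length = 100L, word_size = 11L) {
  if (is(query, "DNAString") || is(query, "XString")) query <- as.character(query)
  if (!is.character(query) || length(query) != 1L || nchar(query) == 0L)
    stop_ribocn("query must be a single non-empty sequence")
  if (grepl("^N+$", query))
    stop_ribocn("degenerate all-N query", class = "ribocn_validation_error")
  if (min_identity <= 0 || min_identity > 1) stop_ribocn("min_identity must be in (0, 1]")
  if (min_length < 1) stop_ribocn("min_length must be >= 1")
  if (is(subjects, "DNAStringSet")) subjects <- setNames(as.character(subjects), names(subjects))
  if (length(subjects) == 0L) {
    warning("empty subject set: returning no analogue regions")
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$query_length <- nchar(query)
    return(gr)
  }
  if (is.null(names(subjects)) || any(!nzchar(names(subjects))))
    stop_ribocn("subjects must be named")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  hits <- list()
  for (contig in names(subjects)) {
    schar <- subjects[[contig]]
    sraw <- charToRaw(schar)
    for (q in c(query, rc)) {
      diags <- seed_diagonals(q, schar, word_size)
      if (!length(diags)) next
      segs <- diagonal_hits(charToRaw(q), sraw, diags, min_identity, min_length)
      for (seg in segs)
        hits[[length(hits) + 1L]] <- data.frame(contig = contig,
                                                start = seg[1L], end = seg[2L])
    }
  }
  if (!length(hits)) {
    gr <- GenomicRanges::GRanges()
  } else {
    df <- do.call(rbind, hits)
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      df$contig, IRanges::IRanges(df$start, df$end)))
    gr <- GenomicRanges::sort(gr)
  }
  S4Vectors::metadata(gr)$query_length <- nchar(query)
  gr
}

#' Write analogue regions as a BED file
#'
#' BED output is 0-based half-open, tab-separated, no header.
#'
#' @param regions a [GenomicRanges::GRanges] (1-based closed, the native R
#'   convention; conversion happens here at the boundary).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  stopifnot(is(regions, "GRanges"))
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,     # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(regions))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of analogue regions
#'
#' Accepts 3+ column BED (0-based half-open); extra columns are ignored.
#' Malformed lines raise a parse error naming the line number.
#'
#' @param path BED file.
#' @return A [GenomicRanges::GRanges] (1-based closed coordinates).
#' @export
read_region_bed <- function(path) {
  if (!file.exists(path)) stop_ribocn("BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  if (!length(keep)) return(GenomicRanges::GRanges())
  recs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_ribocn("BED parse error at line ", ln, ": fewer than 3 columns",
                  class = "ribocn_parse_error")
    s <- suppressWarnings(as.numeric(f[2L])); e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e))
      stop_ribocn("BED parse error at line ", ln, ": non-numeric coordinates",
                  class = "ribocn_parse_error")
    if (s < 0 || e <= s)
      stop_ribocn("BED parse error at line ", ln, ": end <= start",
                  class = "ribocn_parse_error")
    if (!nzchar(f[1L]))
      stop_ribocn("BED parse error at line ", ln, ": empty contig",
                  class = "ribocn_parse_error")
    recs[[i]] <- data.frame(contig = f[1L], start = s, end = e)
  }
  df <- do.call(rbind, recs)
  GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start + 1L, df$end))
}
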