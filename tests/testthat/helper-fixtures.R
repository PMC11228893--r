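# shared fixture builders and independent oracles

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# plant `query` into `subject` at 1-based position, with a given number of
# substitutions at random positions
plant_query <- function(subject, query, at, n_subs = 0L) {
  q <- strsplit(query, "")[[1L]]
  if (n_subs > 0L) {
    idx <- sample(seq_along(q), n_subs)
    for (i in idx) q[i] <- sample(setdiff(c("A", "C", "G", "T"), q[i]), 1L)
  }
  mutated <- paste(q, collapse = "")
  substr(subject, at, at + nchar(query) - 1L) <- mutated
  subject
}

# independent oracle for analogue discovery: exhaustive sliding-window
# identity scan of the full query against every subject offset
window_scan_oracle <- function(query, subject, min_identity) {
  q <- charToRaw(query); s <- charToRaw(subject)
  qn <- length(q); sn <- length(s)
  hits <- integer(0)
  for (off in 0:(sn - qn)) {
    ident <- sum(q == s[(off + 1):(off + qn)]) / qn
    if (ident >= min_identity) hits <- c(hits, off + 1L)
  }
  hits
}

# independent union-find oracle for family clustering
union_find_families <- function(pairs) {
  ids <- sort(unique(c(as.character(pairs$id1), as.character(pairs$id2))))
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(match(as.character(pairs$id1[k]), ids))
    b <- find(match(as.character(pairs$id2[k]), ids))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  # canonical labels: number components by smallest member id
  comp <- split(ids, roots)
  comp <- comp[order(vapply(comp, min, character(1)))]
  out <- data.frame(id = unlist(comp, use.names = FALSE),
                    family_id = rep(seq_along(comp), lengths(comp)))
  out[order(out$id), , drop = FALSE]
}

# hand-built SAM -> sorted+indexed BAM for counting tests
write_toy_bam <- function(reads, contigs, dir = tempfile("toybam")) {
  # reads: data.frame(qname, flag, rname, pos, cigar)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sam <- file.path(dir, "toy.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  reads$qname, reads$flag, reads$rname, reads$pos, reads$cigar)
  writeLines(c(hdr, body), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "toy_unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "toy"))
  Rsamtools::indexBam(bam)
  bam
}

gr <- function(contig, start, end) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
}
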