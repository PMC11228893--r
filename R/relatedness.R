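#' KING kinship classification thresholds
#'
#' Band edges for relative classification from KING kinship estimates.
#' Monozygotic (MZ) twins are kinship > 0.4; first-degree relatives
#' 0.177-0.354; second-degree from `boundary_23` up to 0.177; third-degree
#' from 0.0442 up to `boundary_23`. The published second/third-degree bands
#' overlap in print (0.0844 vs 0.0884); the default boundary is 0.0884, the
#' canonical KING cutoff 2^-3.5, and is configurable.
#'
#' @param mz MZ threshold (exclusive lower bound).
#' @param first_low,first_high first-degree band (inclusive both ends).
#' @param boundary_23 boundary between second and third degree.
#' @param third_low lower bound of the third-degree band.
#' @return list of thresholds.
#' @export
kinship_thresholds <- function(mz = 0.4, first_low = 0.177, first_high = 0.354,
                               boundary_23 = 0.0884, third_low = 0.0442) {
  stopifnot(third_low < boundary_23, boundary_23 < first_low,
            first_low < first_high, first_high < mz)
  list(mz = mz, first_low = first_low, first_high = first_high,
       boundary_23 = boundary_23, third_low = third_low)
}

relationship_levels <- c("MZ", "FIRST", "SECOND", "THIRD", "UNRELATED")

#' Classify relative pairs from KING kinship estimates
#'
#' Total classification: every finite kinship maps to exactly one category.
#' Lower band edges are inclusive and upper edges exclusive, except the MZ
#' cut which is strictly greater than the threshold.
#'
#' @param kinship numeric vector of KING kinship estimates.
#' @param thresholds [kinship_thresholds()].
#' @return factor with levels MZ, FIRST, SECOND, THIRD, UNRELATED.
#' @export
classify_relationship <- function(kinship, thresholds = kinship_thresholds()) {
  if (any(!is.finite(kinship))) stop_ribocn("kinship values must be finite")
  t <- thresholds
  out <- ifelse(kinship > t$mz, "MZ",
         ifelse(kinship >= t$first_low & kinship <= t$first_high, "FIRST",
         ifelse(kinship >= t$boundary_23 & kinship < t$first_low, "SECOND",
         ifelse(kinship >= t$third_low & kinship < t$boundary_23, "THIRD",
                "UNRELATED"))))
  factor(out, levels = relationship_levels)
}

#' Split first-degree relatives into parental and fraternal pairs
#'
#' Parent-offspring pairs share one allele at essentially every marker, so
#' their IBS0 (no shared alleles) fraction is near zero: pairs with IBS0
#' below the threshold are `PARENTAL`, the rest `FRATERNAL`. Out of caution,
#' putatively parental pairs whose birth years are less than `min_gap_years`
#' apart are `DISCARDED` (a parent-child age gap below 10 years is not
#' credible), as are putatively parental pairs with missing birth years
#' (reason `"unverifiable"`).
#'
#' @param ibs0 numeric vector of IBS0 fractions.
#' @param birth_year1,birth_year2 birth years of the two members (NA allowed).
#' @param ibs0_threshold parental IBS0 cutoff (default 0.0012).
#' @param min_gap_years minimum credible parent-child age gap (default 10).
#' @return data.frame with columns `subtype` (factor PARENTAL / FRATERNAL /
#'   DISCARDED) and `reason`.
#' @export
classify_first_degree <- function(ibs0, birth_year1 = NA, birth_year2 = NA,
                                  ibs0_threshold = 0.0012, min_gap_years = 10) {
  n <- length(ibs0)
  birth_year1 <- rep_len(birth_year1, n); birth_year2 <- rep_len(birth_year2, n)
  subtype <- rep("FRATERNAL", n); reason <- rep(NA_character_, n)
  par <- ibs0 < ibs0_threshold
  gap <- abs(birth_year1 - birth_year2)
  unverifiable <- par & (is.na(birth_year1) | is.na(birth_year2))
  close_births <- par & !unverifiable & gap < min_gap_years
  subtype[par] <- "PARENTAL"
  subtype[close_births] <- "DISCARDED"
  reason[close_births] <- "birth gap below minimum"
  subtype[unverifiable] <- "DISCARDED"
  reason[unverifiable] <- "unverifiable"
  data.frame(subtype = factor(subtype, levels = c("PARENTAL", "FRATERNAL", "DISCARDED")),
             reason = reason)
}

#' Cluster related individuals into families
#'
#' Families are the connected components of the graph whose vertices are
#' individuals and whose edges are the relative pairs. Family ids are
#' assigned deterministically: families are numbered by their
#' lexicographically smallest member id.
#'
#' @param pairs data.frame with columns `id1`, `id2`.
#' @return data.frame with columns `id`, `family_id`, sorted by id.
#' @export
build_families <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(id = character(0), family_id = integer(0)))
  stopifnot(all(c("id1", "id2") %in% names(pairs)))
  edges <- cbind(as.character(pairs$id1), as.character(pairs$id2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  ids <- names(membership)
  ## renumber components by smallest member id
  min_id <- tapply(ids, membership, min)
  rank <- match(membership, as.integer(names(sort(min_id))))
  out <- data.frame(id = ids, family_id = rank)
  out[order(out$id), , drop = FALSE]
}

#' Select a maximal unrelated subset
#'
#' Keeps every individual without an entry in the relatedness table plus
#' exactly one member per family: the oldest (smallest birth year), with
#' ties (and all-missing birth years, which are flagged) broken by
#' lexicographically smallest id.
#'
#' @param individuals data.frame with columns `id` and `birth_year`.
#' @param assignment family assignment from [build_families()].
#' @return character vector of retained ids (attribute `flagged` lists
#'   families resolved without any birth year).
#' @export
select_unrelated <- function(individuals, assignment) {
  stopifnot(all(c("id", "birth_year") %in% names(individuals)))
  ids <- as.character(individuals$id)
  if (anyDuplicated(ids)) stop_ribocn("duplicate individual ids")
  by <- setNames(individuals$birth_year, ids)
  singletons <- setdiff(ids, assignment$id)
  reps <- character(0); flagged <- character(0)
  if (nrow(assignment)) {
    for (fam in split(assignment$id, assignment$family_id)) {
      fam <- sort(as.character(fam))
      yrs <- by[fam]
      if (all(is.na(yrs))) {
        pick <- fam[1L]
        flagged <- c(flagged, pick)
      } else {
        oldest <- min(yrs, na.rm = TRUE)
        pick <- sort(fam[!is.na(yrs) & yrs == oldest])[1L]
      }
      reps <- c(reps, pick)
    }
  }
  out <- sort(unique(c(singletons, reps)))
  attr(out, "flagged") <- flagged
  out
}

#' Read a pairwise kinship table
#'
#' Expects tab-separated columns ID1, ID2, Kinship, IBS0 (case-insensitive).
#'
#' @param path TSV file.
#' @return data.frame with columns `id1`, `id2`, `kinship`, `ibs0`.
#' @export
read_kinship_table <- function(path) {
  df <- read_tsv(path)
  names(df) <- tolower(names(df))
  need <- c("id1", "id2", "kinship", "ibs0")
  if (!all(need %in% names(df)))
    stop_ribocn("kinship table must have columns ID1, ID2, Kinship, IBS0")
  df[, c(need, setdiff(names(df), need)), drop = FALSE]
}
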