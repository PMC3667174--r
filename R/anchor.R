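#' Anchor markers to assembly scaffolds by unique exact tag match
#'
#' Each marker's parent-A (reference) tag is searched, full length and exact,
#' against all scaffolds on both strands. A marker anchors only when there is
#' exactly one hit site on exactly one scaffold; markers with zero hits or
#' multiple hit sites (same or different scaffolds) are rejected with a
#' reason code. For SNP markers the recorded position is the 1-based
#' forward-strand scaffold coordinate of the SNP site; for indel markers it
#' is the coordinate of the tag start.
#'
#' @param markers Marker definitions from [call_parental_markers()].
#' @param scaffolds A named `DNAStringSet` (or named character vector) of
#'   scaffold sequences.
#' @return List with `anchors` (data.frame `marker, scaffold, position,
#'   strand`) and `rejected` (data.frame `marker, reason` with reasons
#'   `no_hit` / `ambiguous`).
#' @export
locate_tags <- function(markers, scaffolds) {
  if (!inherits(scaffolds, "DNAStringSet"))
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (is.null(names(scaffolds))) stop("scaffolds must be named")
  anchors <- list()
  rejected <- list()
  tag_len <- nchar(markers$tag_A[1])
  for (i in seq_len(nrow(markers))) {
    tag <- Biostrings::DNAString(markers$tag_A[i])
    fwd <- Biostrings::vmatchPattern(tag, scaffolds)
    rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(tag),
                                     scaffolds)
    nf <- S4Vectors::elementNROWS(fwd)
    nr <- S4Vectors::elementNROWS(rev)
    total <- sum(nf) + sum(nr)
    if (total == 0L) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(marker = markers$marker_id[i], reason = "no_hit",
                   stringsAsFactors = FALSE)
      next
    }
    if (total > 1L) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(marker = markers$marker_id[i], reason = "ambiguous",
                   stringsAsFactors = FALSE)
      next
    }
    on_fwd <- sum(nf) == 1L
    sc_idx <- which((if (on_fwd) nf else nr) == 1L)
    hit <- if (on_fwd) fwd[[sc_idx]] else rev[[sc_idx]]
    st <- BiocGenerics::start(hit)[1]
    off <- markers$offset[i]
    pos <- if (is.na(off)) {
      st                                  # indel: tag start coordinate
    } else if (on_fwd) {
      st + off - 1L                       # SNP site, forward match
    } else {
      st + (tag_len - off)                # SNP site, reverse-complement match
    }
    anchors[[length(anchors) + 1L]] <- data.frame(
      marker = markers$marker_id[i], scaffold = names(scaffolds)[sc_idx],
      position = pos, strand = if (on_fwd) "+" else "-",
      stringsAsFactors = FALSE)
  }
  empty_a <- data.frame(marker = character(0), scaffold = character(0),
                        position = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  empty_r <- data.frame(marker = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  list(anchors = if (length(anchors)) do.call(rbind, anchors) else empty_a,
       rejected = if (length(rejected)) do.call(rbind, rejected) else empty_r)
}

#' Integrate anchored scaffolds onto a linkage map
#'
#' Attaches each anchored scaffold to the locus of its marker and summarises
#' per linkage group the count of distinct scaffolds and their summed length
#' span. A scaffold whose markers map to two or more groups is reported as a
#' conflict and excluded from the counts.
#'
#' @param anchors Anchor data.frame from [locate_tags()] (`$anchors`).
#' @param map A `ril_map`.
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp.
#' @return List: `table` (marker, scaffold, position, group, locus, cM),
#'   `per_group` (group, scaffolds, span_bp), `totals`, `conflicts`
#'   (scaffold, groups).
#' @export
integrate_anchors <- function(anchors, map, scaffold_lengths) {
  mt <- map_table(map)
  tab <- merge(anchors, mt, by = "marker", sort = FALSE)
  names(tab)[names(tab) == "position.x"] <- "position"
  names(tab)[names(tab) == "position.y"] <- "cM"
  ## conflicts: scaffold attached to >= 2 groups
  gps <- tapply(tab$group, tab$scaffold, function(g) unique(g))
  conflict_sc <- names(gps)[lengths(gps) >= 2L]
  conflicts <- data.frame(
    scaffold = conflict_sc,
    groups = vapply(gps[conflict_sc], paste, "", collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
  keep <- !tab$scaffold %in% conflict_sc
  tt <- tab[keep, , drop = FALSE]
  per_group <- do.call(rbind, lapply(split(tt, tt$group), function(d) {
    sc <- unique(d$scaffold)
    data.frame(group = d$group[1], scaffolds = length(sc),
               span_bp = sum(scaffold_lengths[sc]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  if (is.null(per_group))
    per_group <- data.frame(group = character(0), scaffolds = integer(0),
                            span_bp = numeric(0))
  list(table = tab, per_group = per_group,
       totals = list(scaffolds = sum(per_group$scaffolds),
                     span_bp = sum(per_group$span_bp)),
       conflicts = conflicts)
}

#' Map-anchored fractions of the assembly and of the genome
#'
#' @param integrated_span_bp Summed length of scaffolds anchored on the map.
#' @param assembly_span_bp Total assembly span.
#' @param genome_size_bp Estimated genome size.
#' @return List with `pct_of_assembly` and `pct_of_genome` (percentages).
#' @examples
#' coverage_fractions(71751603, 598e6, 1.153e9)
#' @export
coverage_fractions <- function(integrated_span_bp, assembly_span_bp,
                               genome_size_bp) {
  stopifnot(integrated_span_bp > 0, assembly_span_bp > 0, genome_size_bp > 0)
  list(pct_of_assembly = 100 * integrated_span_bp / assembly_span_bp,
       pct_of_genome = 100 * integrated_span_bp / genome_size_bp)
}
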