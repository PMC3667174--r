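#' Genotype matrix constructor
#'
#' A markers x samples character matrix of codes `A` (homozygous for the
#' founder-A allele), `B`, `H` (heterozygous) and `NA` (missing), with the
#' parent columns recorded.
#'
#' @param codes Character matrix (rownames = markers, colnames = samples),
#'   entries in `A`, `B`, `H` or `NA`.
#' @param parents Character vector of length 2 naming the founder-A and
#'   founder-B sample columns (may be `NULL` for parent-free matrices).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, parents = NULL) {
  stopifnot(is.matrix(codes), is.character(codes))
  bad <- !is.na(codes) & !codes %in% c("A", "B", "H")
  if (any(bad)) stop("genotype codes must be A, B, H or NA")
  if (!is.null(parents)) stopifnot(all(parents %in% colnames(codes)))
  structure(codes, parents = parents, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(unclass(x)))))
  invisible(x)
}

#' Samples of a genotype matrix that are RILs (non-parent columns)
#' @param gm A `genotype_matrix`.
#' @return Character vector of RIL sample names.
#' @export
ril_samples <- function(gm) {
  setdiff(colnames(gm), attr(gm, "parents"))
}

#' Demultiplex barcoded RAD reads into per-sample tag sets
#'
#' Reads are assigned by exact match of their leading barcode; the barcode is
#' removed and the remaining tag retained. Reads matching no barcode
#' (including reads with any barcode sequencing error) go to an unassigned
#' sink.
#'
#' @param reads Character vector of full-length reads (barcode + tag).
#' @param barcode_map data.frame with columns `sample`, `barcode`; barcodes
#'   must be unique and of equal length.
#' @return List with `samples` (named list of tag character vectors, barcode
#'   removed), `unassigned` (count) and `n_input`.
#' @export
demultiplex <- function(reads, barcode_map) {
  stopifnot(all(c("sample", "barcode") %in% names(barcode_map)))
  if (anyDuplicated(barcode_map$barcode))
    stop("duplicate barcodes in barcode map")
  blen <- unique(nchar(barcode_map$barcode))
  if (length(blen) != 1L) stop("barcodes must share one length")
  bc <- substr(reads, 1L, blen)
  idx <- match(bc, barcode_map$barcode)
  tags <- substring(reads, blen + 1L)
  samples <- lapply(seq_len(nrow(barcode_map)), function(i)
    unname(tags[!is.na(idx) & idx == i]))
  names(samples) <- barcode_map$sample
  list(samples = samples, unassigned = sum(is.na(idx)),
       n_input = length(reads))
}

#' Cluster identical reads into tags
#'
#' Identity clustering: one tag per distinct sequence per sample, with
#' read_count equal to its multiplicity. Sequencing errors therefore stay in
#' separate (typically singleton) tags.
#'
#' @param reads Character vector of trimmed tag-length reads for one sample.
#' @return data.frame with columns `sequence`, `count`, sorted by decreasing
#'   count then sequence.
#' @export
cluster_tags <- function(reads) {
  if (!length(reads))
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(reads)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), ]
  rownames(out) <- NULL
  out
}

#' Remove over-deep (repetitive) tags
#'
#' Tags backed by more than `max_reads` reads are treated as collapsed
#' repeats and removed so that paralogous copies are not mistaken for
#' alleles.
#'
#' @param tags data.frame from [cluster_tags()].
#' @param max_reads Depth ceiling (default 100; a tag with exactly 100 reads
#'   is kept, 101 is removed).
#' @return Filtered data.frame; the number removed is in attribute
#'   `"n_removed"`.
#' @export
filter_repetitive <- function(tags, max_reads = 100L) {
  keep <- tags$count <= max_reads
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

## Hamming mismatch counts of one sequence against a pre-split matrix
## (characters x sequences). Returns integer vector.
mismatch_counts <- function(seq, mat) {
  v <- strsplit(seq, "")[[1]]
  colSums(mat != v)
}

## Single-gap, zero-mismatch alignment of two equal-length tags.
## Returns list(gap, pos, inserted_in) or NULL. `pos` is the 1-based length
## of the matching prefix; `inserted_in` is "A" or "B" (which tag carries the
## insertion relative to the other).
single_gap_align <- function(a, b, max_gap = 10L) {
  if (a == b) return(NULL)
  n <- nchar(a)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  diffs <- which(av != bv)
  p <- diffs[1] - 1L  # common prefix length
  for (g in seq_len(max_gap)) {
    # insertion in b: a[p+1 .. n-g] == b[p+g+1 .. n]
    if (p + 1L <= n - g &&
        all(av[(p + 1L):(n - g)] == bv[(p + g + 1L):n]))
      return(list(gap = g, pos = p, inserted_in = "B"))
    if (p + 1L <= n - g &&
        all(bv[(p + 1L):(n - g)] == av[(p + g + 1L):n]))
      return(list(gap = g, pos = p, inserted_in = "A"))
  }
  NULL
}

#' Call SNP and indel markers polymorphic between the two parents
#'
#' Tags identical across the parents are monomorphic and discarded. A SNP
#' marker is emitted for a cross-parent tag pair at Hamming distance exactly
#' 1 that pairs uniquely in both directions; an indel marker for a unique
#' pair aligning with a single 1-10 bp gap and no mismatches. Tags with two
#' or more candidate partners are discarded as ambiguous (paralog
#' protection). SNP markers are named `DAFWA<n>`, indel markers `iDAFWA<n>`.
#'
#' @param tags_A,tags_B Repeat-filtered tag data.frames from
#'   [cluster_tags()] for parents A and B.
#' @param min_depth Minimum read count each parental tag must have
#'   (default 3).
#' @param max_gap Maximum indel gap length (default 10).
#' @return data.frame of marker definitions: `marker_id, type, tag_A, tag_B,
#'   offset` (1-based SNP offset within the tag; NA for indels), `allele_A,
#'   allele_B`. Rejection counts by reason are in attribute `"rejected"`.
#' @export
call_parental_markers <- function(tags_A, tags_B, min_depth = 3L,
                                  max_gap = 10L) {
  rejected <- c(low_depth = 0L, monomorphic = 0L, ambiguous = 0L,
                unpaired = 0L)
  a <- tags_A[tags_A$count >= min_depth, , drop = FALSE]
  b <- tags_B[tags_B$count >= min_depth, , drop = FALSE]
  rejected["low_depth"] <- (nrow(tags_A) - nrow(a)) + (nrow(tags_B) - nrow(b))
  mono <- intersect(a$sequence, b$sequence)
  rejected["monomorphic"] <- length(mono)
  a <- a[!a$sequence %in% mono, , drop = FALSE]
  b <- b[!b$sequence %in% mono, , drop = FALSE]
  empty <- data.frame(marker_id = character(0), type = character(0),
                      tag_A = character(0), tag_B = character(0),
                      offset = integer(0), allele_A = character(0),
                      allele_B = character(0), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) {
    attr(empty, "rejected") <- rejected
    return(empty)
  }
  bmat <- do.call(cbind, strsplit(b$sequence, ""))
  ## candidate partners at Hamming distance 1 in both directions
  cand <- lapply(a$sequence, function(s) which(mismatch_counts(s, bmat) == 1L))
  n_cand_b <- integer(nrow(b))
  for (idx in cand) n_cand_b[idx] <- n_cand_b[idx] + 1L
  snp <- list()
  used_a <- used_b <- integer(0)
  for (i in seq_along(cand)) {
    js <- cand[[i]]
    if (length(js) == 1L && n_cand_b[js] == 1L) {
      used_a <- c(used_a, i); used_b <- c(used_b, js)
      sa <- a$sequence[i]; sb <- b$sequence[js]
      off <- which(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
      snp[[length(snp) + 1L]] <- data.frame(
        type = "SNP", tag_A = sa, tag_B = sb, offset = off,
        allele_A = substring(sa, off, off),
        allele_B = substring(sb, off, off), stringsAsFactors = FALSE)
    } else if (length(js) >= 2L) {
      rejected["ambiguous"] <- rejected["ambiguous"] + 1L
    }
  }
  rejected["ambiguous"] <- rejected["ambiguous"] +
    sum(n_cand_b >= 2L)
  ## indel pairing among tags not consumed by SNP pairs
  a2 <- setdiff(seq_len(nrow(a)), used_a)
  b2 <- setdiff(seq_len(nrow(b)), used_b)
  indel <- list()
  if (length(a2) && length(b2)) {
    hits <- list()
    for (i in a2) {
      for (j in b2) {
        al <- single_gap_align(a$sequence[i], b$sequence[j], max_gap)
        if (!is.null(al))
          hits[[length(hits) + 1L]] <- c(i = i, j = j, gap = al$gap,
                                         pos = al$pos,
                                         ins_b = al$inserted_in == "B")
      }
    }
    if (length(hits)) {
      hm <- do.call(rbind, hits)
      ok <- !(duplicated(hm[, "i"]) | duplicated(hm[, "i"], fromLast = TRUE) |
                duplicated(hm[, "j"]) | duplicated(hm[, "j"], fromLast = TRUE))
      rejected["ambiguous"] <- rejected["ambiguous"] + sum(!ok)
      hm <- hm[ok, , drop = FALSE]
      for (r in seq_len(nrow(hm))) {
        i <- hm[r, "i"]; j <- hm[r, "j"]
        g <- hm[r, "gap"]; p <- hm[r, "pos"]
        sa <- a$sequence[i]; sb <- b$sequence[j]
        gap_seq <- if (hm[r, "ins_b"] == 1)
          substring(sb, p + 1L, p + g) else substring(sa, p + 1L, p + g)
        indel[[length(indel) + 1L]] <- data.frame(
          type = "indel", tag_A = sa, tag_B = sb, offset = NA_integer_,
          allele_A = if (hm[r, "ins_b"] == 1) "-" else gap_seq,
          allele_B = if (hm[r, "ins_b"] == 1) gap_seq else "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(do.call(rbind, snp), do.call(rbind, indel))
  if (is.null(out)) out <- empty[, -1]
  rejected["unpaired"] <- (nrow(a) - length(used_a)) +
    (nrow(b) - length(used_b)) - 2L * nrow(out[out$type == "indel", ])
  if (nrow(out)) {
    is_snp <- out$type == "SNP"
    ids <- character(nrow(out))
    ids[is_snp] <- sprintf("DAFWA%d", seq_len(sum(is_snp)))
    ids[!is_snp] <- sprintf("iDAFWA%d", seq_len(sum(!is_snp)))
    out <- cbind(marker_id = ids, out, stringsAsFactors = FALSE)
  } else out <- empty
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Genotype RIL samples at called markers
#'
#' Per RIL and marker: code `A` when only the parent-A tag is observed at
#' depth >= `min_depth`, `B` symmetrically, `H` when both tags reach
#' `min_depth`, and missing otherwise.
#'
#' @param markers Marker definitions from [call_parental_markers()].
#' @param sample_tags Named list of repeat-filtered tag data.frames, one per
#'   sample (parents first if present).
#' @param min_depth Minimum read count per tag to accept an allele
#'   (default 3).
#' @param parents Optional length-2 character vector naming the parent
#'   samples within `sample_tags`.
#' @return A [genotype_matrix()].
#' @export
genotype_rils <- function(markers, sample_tags, min_depth = 3L,
                          parents = NULL) {
  samples <- names(sample_tags)
  codes <- matrix(NA_character_, nrow = nrow(markers), ncol = length(samples),
                  dimnames = list(markers$marker_id, samples))
  for (sm in samples) {
    tg <- sample_tags[[sm]]
    cnt_a <- tg$count[match(markers$tag_A, tg$sequence)]
    cnt_b <- tg$count[match(markers$tag_B, tg$sequence)]
    cnt_a[is.na(cnt_a)] <- 0L
    cnt_b[is.na(cnt_b)] <- 0L
    has_a <- cnt_a >= min_depth
    has_b <- cnt_b >= min_depth
    codes[has_a & !has_b, sm] <- "A"
    codes[!has_a & has_b, sm] <- "B"
    codes[has_a & has_b, sm] <- "H"
  }
  genotype_matrix(codes, parents = parents)
}

#' Per-marker quality report of a genotype matrix
#'
#' Missing rate, founder-A allele frequency and a 1:1 segregation chi-square
#' over the A/B calls of the RIL samples. Markers exceeding the missing-rate
#' cutoff are flagged, not removed.
#'
#' @param gm A `genotype_matrix`.
#' @param max_missing Missing-rate flag threshold (default 0.2).
#' @return data.frame with one row per marker: `marker, n_A, n_B, n_H,
#'   n_missing, missing_rate, freq_A, chisq, flagged`.
#' @export
qc_matrix <- function(gm, max_missing = 0.2) {
  rl <- ril_samples(gm)
  sub <- unclass(gm)[, rl, drop = FALSE]
  n_A <- rowSums(sub == "A", na.rm = TRUE)
  n_B <- rowSums(sub == "B", na.rm = TRUE)
  n_H <- rowSums(sub == "H", na.rm = TRUE)
  n_missing <- rowSums(is.na(sub))
  n_calls <- n_A + n_B
  chisq <- ifelse(n_calls > 0, (n_A - n_B)^2 / n_calls, NA_real_)
  missing_rate <- n_missing / length(rl)
  data.frame(marker = rownames(gm), n_A = n_A, n_B = n_B, n_H = n_H,
             n_missing = n_missing, missing_rate = missing_rate,
             freq_A = ifelse(n_calls > 0, n_A / n_calls, NA_real_),
             chisq = chisq, flagged = missing_rate > max_missing,
             row.names = NULL, stringsAsFactors = FALSE)
}
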