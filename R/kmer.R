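#' Build a canonical k-mer depth histogram from reads
#'
#' Counts canonical k-mers (the lexicographically smaller of each k-mer and
#' its reverse complement, in 2-bit encoding) across a read collection and
#' tabulates how many distinct k-mers occur at each depth. k-mers containing
#' a non-ACGT character are skipped. The histogram's volume (total number of
#' k-mer instances, the survey's "K-number") drives genome-size estimation.
#'
#' @param reads Character vector or `DNAStringSet` of reads (uppercased).
#' @param k Odd integer k-mer size, 1 < k <= 31 (default 17).
#' @return Object of class `kmer_histogram`: list with `k`, `depth`, `count`
#'   (parallel vectors, depth ascending), and `volume` = sum(depth * count).
#' @examples
#' h <- count_kmers(c("ACGTACG"), k = 7)
#' h$volume
#' @export
count_kmers <- function(reads, k = 17L) {
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  k <- as.integer(k)
  if (k %% 2L == 0L || k <= 1L || k > 31L)
    stop("k must be odd and in (1, 31]")
  res <- .kmer_histogram_cpp(toupper(reads), k)
  if (res$n_short > 0)
    warning(sprintf("%d read(s) shorter than k = %d contributed nothing",
                    res$n_short, k))
  kmer_histogram(res$depth, res$count, k = k)
}

#' Construct a k-mer histogram from depth/count vectors
#'
#' @param depth Integer vector of depths (>= 1).
#' @param count Numeric vector: number of distinct k-mers at each depth.
#' @param k The k-mer size the histogram was built with.
#' @return A `kmer_histogram`.
#' @export
kmer_histogram <- function(depth, count, k = 17L) {
  stopifnot(length(depth) == length(count))
  if (length(depth) && any(depth < 1)) stop("all depths must be >= 1")
  o <- order(depth)
  structure(list(k = as.integer(k), depth = as.integer(depth[o]),
                 count = as.numeric(count[o]),
                 volume = sum(as.numeric(depth[o]) * as.numeric(count[o]))),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %d): %d depth classes, volume %.0f\n",
              x$k, length(x$depth), x$volume))
  if (length(x$depth)) {
    p <- tryCatch(find_peak(x), error = function(e) NA)
    if (!is.na(p)) cat(sprintf("  main peak at depth %d\n", p))
  }
  invisible(x)
}

#' @export
plot.kmer_histogram <- function(x, log = "y", ...) {
  graphics::plot(x$depth, x$count, type = "h", log = log,
                 xlab = "k-mer depth", ylab = "distinct k-mers", ...)
  invisible(x)
}

#' Locate the main peak of a k-mer histogram
#'
#' Returns the modal depth after excluding the low-depth region dominated by
#' sequencing errors. Ties between depths are broken toward the smaller
#' depth.
#'
#' @param hist A `kmer_histogram`.
#' @param min_peak_depth Depths below this are excluded (default 4).
#' @return Integer peak depth.
#' @export
find_peak <- function(hist, min_peak_depth = 4L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  sel <- hist$depth >= min_peak_depth
  if (!any(sel))
    stop(sprintf("no k-mer depth >= %d; cannot locate a peak", min_peak_depth))
  d <- hist$depth[sel]; c_d <- hist$count[sel]
  d[which.max(c_d)]  # depths ascending, which.max takes the first maximum
}

#' Estimate genome size from a k-mer histogram
#'
#' Uses the survey model G = K-number / peak depth, where the K-number is the
#' total k-mer volume of the histogram and the peak depth is the modal k-mer
#' depth of the single-copy component.
#'
#' @param hist A `kmer_histogram`, or a single numeric k-mer volume.
#' @param peak Peak depth; computed with [find_peak()] when missing and
#'   `hist` is a histogram.
#' @param min_peak_depth Passed to [find_peak()].
#' @return Estimated genome size in bp (numeric).
#' @examples
#' estimate_genome_size(25376847185, peak = 22)  # ~1.153e9
#' @export
estimate_genome_size <- function(hist, peak = NULL, min_peak_depth = 4L) {
  if (is.numeric(hist)) {
    volume <- as.numeric(hist)
    if (is.null(peak)) stop("peak must be supplied with a raw volume")
  } else {
    stopifnot(inherits(hist, "kmer_histogram"))
    volume <- hist$volume
    if (is.null(peak)) peak <- find_peak(hist, min_peak_depth)
  }
  if (peak <= 0) stop("peak depth must be positive")
  volume / peak
}

#' Sequencing coverage implied by a genome-size estimate
#'
#' @param total_sequenced_bp Total base pairs sequenced.
#' @param genome_size Genome size in bp.
#' @return Fold coverage (numeric; conventionally reported at 1 decimal).
#' @export
estimate_coverage <- function(total_sequenced_bp, genome_size) {
  stopifnot(total_sequenced_bp > 0, genome_size > 0)
  total_sequenced_bp / genome_size
}

#' Share of k-mer volume at and above a repeat-depth threshold
#'
#' Reports which fraction of the k-mer volume sits at depth >= threshold
#' (default twice the peak depth, i.e. k-mers occurring at least twice per
#' genome copy) and its complement. This is a k-mer-volume statistic, not a
#' direct genome-fraction estimate of repeat content.
#'
#' @param hist A `kmer_histogram`.
#' @param threshold Depth threshold; defaults to `2 * find_peak(hist)`.
#' @param min_peak_depth Passed to [find_peak()] for the default threshold.
#' @return List with `threshold`, `above` and `below` (fractions of volume).
#' @export
repeat_volume_fraction <- function(hist, threshold = NULL,
                                   min_peak_depth = 4L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (is.null(threshold))
    threshold <- 2L * find_peak(hist, min_peak_depth)
  vol <- hist$volume
  if (vol == 0) return(list(threshold = threshold, above = 0, below = 0))
  above <- sum(as.numeric(hist$depth[hist$depth >= threshold]) *
                 hist$count[hist$depth >= threshold]) / vol
  list(threshold = threshold, above = above, below = 1 - above)
}

#' Read / write a k-mer histogram as two-column CSV
#'
#' @param path File path; CSV with header `depth,count`.
#' @param hist A `kmer_histogram`.
#' @param k k-mer size recorded when reading (default 17).
#' @return `read_kmer_histogram` returns a `kmer_histogram`;
#'   `write_kmer_histogram` returns `path` invisibly.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  df <- utils::read.csv(path)
  if (!all(c("depth", "count") %in% names(df)))
    stop("histogram CSV must have columns depth,count")
  kmer_histogram(df$depth, df$count, k = k)
}

#' @rdname read_kmer_histogram
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.csv(data.frame(depth = hist$depth, count = hist$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
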