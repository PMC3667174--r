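#' Simulate a pair of homozygous founder genomes
#'
#' Generates two fully homozygous founder genomes ("A" and "B") that differ by
#' a configured number of SNPs and short (1-10 bp) indels, emulating a
#' domesticated x domesticated biparental cross. Founder A is the reference
#' coordinate system; founder B is obtained by applying the variant truth
#' table to A. By default variants are kept at least 92 bp apart so that each
#' RAD tag window carries at most one variant; set `min_spacing = 0` to allow
#' multi-variant tags (used to exercise the marker caller's rejection path).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param genetic_lengths Numeric vector of genetic lengths in cM, one per
#'   chromosome (recycled). Default 100 cM each, a typical plant chromosome.
#' @param n_variants Total number of variants to place, allocated across
#'   chromosomes proportionally to physical length.
#' @param indel_fraction Fraction of variants that are indels rather than
#'   SNPs (default 0.08, roughly the published SNP/indel marker ratio).
#' @param min_spacing Minimum distance in bp between variants (default 92,
#'   one tag window).
#' @param margin Distance in bp kept variant-free at each chromosome end so
#'   tags and indels never run off the sequence.
#' @param seed Optional integer seed; when supplied the generator is fully
#'   deterministic.
#' @param variant_windows Optional data.frame (`chrom, start, end`)
#'   restricting variant placement to the given windows (e.g. the cut-site
#'   flanks from [cut_site_flanks()], so every variant is RAD-genotypeable).
#' @return An object of class `founder_genome`: list with `seq_A`, `seq_B`
#'   (named character vectors of chromosome sequences), `lengths_bp`,
#'   `genetic_lengths` and `variants`, a data.frame with columns
#'   `id, chrom, pos, type, allele_A, allele_B, gpos_cM` (positions 1-based on
#'   founder A; `gpos_cM` the genetic coordinate used by the meiosis model).
#' @examples
#' fg <- make_founders(c(chr1 = 2e4), n_variants = 10, seed = 1)
#' nrow(fg$variants)
#' @export
make_founders <- function(chrom_lengths, genetic_lengths = 100,
                          n_variants = 0, indel_fraction = 0.08,
                          min_spacing = 92, margin = 150, seed = NULL,
                          variant_windows = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chrom_lengths))
  chrom_lengths <- as.integer(chrom_lengths)
  names(chrom_lengths) <- nm
  genetic_lengths <- rep_len(as.numeric(genetic_lengths),
                             length(chrom_lengths))
  names(genetic_lengths) <- names(chrom_lengths)
  ## candidate positions per chromosome (away from ends, within windows)
  allowed_list <- lapply(seq_along(chrom_lengths), function(ci) {
    lo <- margin + 1L
    hi <- chrom_lengths[ci] - margin
    if (hi < lo) return(integer(0))
    pos <- lo:hi
    if (!is.null(variant_windows)) {
      w <- variant_windows[variant_windows$chrom == nm[ci], , drop = FALSE]
      if (!nrow(w)) return(integer(0))
      keep <- rep(FALSE, length(pos))
      for (r in seq_len(nrow(w)))
        keep <- keep | (pos >= w$start[r] & pos <= w$end[r])
      pos <- pos[keep]
    }
    pos
  })
  usable <- lengths(allowed_list)
  if (n_variants > 0 && sum(usable) <= 0)
    stop("chromosomes too short to host variants away from their ends")

  ## proportional allocation of variant counts across chromosomes
  alloc <- if (n_variants > 0) {
    a <- floor(n_variants * usable / sum(usable))
    rem <- n_variants - sum(a)
    if (rem > 0) {
      ord <- order(usable, decreasing = TRUE)
      a[ord[seq_len(rem)]] <- a[ord[seq_len(rem)]] + 1L
    }
    a
  } else rep(0L, length(chrom_lengths))

  bases <- c("A", "C", "G", "T")
  seq_A <- vapply(chrom_lengths, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), "")
  names(seq_A) <- names(chrom_lengths)

  var_list <- list()
  for (ci in seq_along(chrom_lengths)) {
    nv <- alloc[ci]
    if (nv == 0) next
    allowed <- allowed_list[[ci]]
    # feasibility: spaced variants need roughly nv * min_spacing of room
    if (length(allowed) < nv ||
        (is.null(variant_windows) &&
         (max(allowed) - min(allowed)) < (nv - 1L) * max(min_spacing, 1L)))
      stop(sprintf("variant density infeasible on %s: cannot place %d variants",
                   names(chrom_lengths)[ci], nv))
    ## accumulate uniform draws, keeping an earliest-first maximal spaced
    ## subset each round, until nv spaced positions are available
    sp <- max(min_spacing, 1L)
    pos <- integer(0)
    tries <- 0L
    while (length(pos) < nv) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("variant placement failed; density too high for min_spacing")
      need <- nv - length(pos)
      cand <- sample(allowed, min(need, length(allowed)), replace = FALSE)
      all_pos <- sort(unique(c(pos, cand)))
      keep <- integer(0)
      last <- -Inf
      for (p in all_pos) {
        if (p - last >= sp) { keep <- c(keep, p); last <- p }
      }
      pos <- keep
    }
    if (length(pos) > nv) pos <- sort(sample(pos, nv))
    type <- ifelse(stats::runif(nv) < indel_fraction, "indel", "SNP")
    ## an indel at the edge of a tag window leaves no aligned suffix inside
    ## the tag and cannot be recognised as a single gap; keep indels at
    ## least 12 bp inside their window (gap <= 10 plus anchor)
    if (!is.null(variant_windows) && any(type == "indel")) {
      w <- variant_windows[variant_windows$chrom == nm[ci], , drop = FALSE]
      edge_dist <- vapply(pos, function(p) {
        inw <- w$start <= p & w$end >= p
        if (!any(inw)) return(Inf)
        max(pmin(p - w$start[inw], w$end[inw] - p))
      }, 0)
      type[type == "indel" & edge_dist < 12] <- "SNP"
    }
    chrom_seq <- seq_A[ci]
    ref <- substring(chrom_seq, pos, pos)
    allele_A <- character(nv)
    allele_B <- character(nv)
    for (i in seq_len(nv)) {
      if (type[i] == "SNP") {
        allele_A[i] <- ref[i]
        allele_B[i] <- sample(setdiff(bases, ref[i]), 1L)
      } else {
        len <- sample.int(10L, 1L)
        if (stats::runif(1) < 0.5) {  # insertion in B
          allele_A[i] <- ref[i]
          allele_B[i] <- paste0(ref[i], paste(sample(bases, len, replace = TRUE),
                                              collapse = ""))
        } else {                      # deletion in B
          allele_A[i] <- substring(chrom_seq, pos[i], pos[i] + len)
          allele_B[i] <- ref[i]
        }
      }
    }
    var_list[[names(chrom_lengths)[ci]]] <- data.frame(
      chrom = names(chrom_lengths)[ci], pos = pos, type = type,
      allele_A = allele_A, allele_B = allele_B,
      stringsAsFactors = FALSE)
  }
  variants <- if (length(var_list)) do.call(rbind, var_list) else
    data.frame(chrom = character(0), pos = integer(0), type = character(0),
               allele_A = character(0), allele_B = character(0),
               stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  if (nrow(variants)) {
    variants$id <- sprintf("V%04d", seq_len(nrow(variants)))
    variants <- variants[, c("id", "chrom", "pos", "type",
                             "allele_A", "allele_B")]
    variants$gpos_cM <- variants$pos / chrom_lengths[variants$chrom] *
      genetic_lengths[variants$chrom]
  } else {
    variants$id <- character(0)
    variants$gpos_cM <- numeric(0)
  }

  seq_B <- seq_A
  if (nrow(variants)) {
    for (cn in unique(variants$chrom)) {
      v <- variants[variants$chrom == cn, ]
      v <- v[order(v$pos, decreasing = TRUE), ]  # apply right-to-left
      s <- seq_B[cn]
      for (i in seq_len(nrow(v))) {
        end_a <- v$pos[i] + nchar(v$allele_A[i]) - 1L
        s <- paste0(substring(s, 1L, v$pos[i] - 1L), v$allele_B[i],
                    substring(s, end_a + 1L))
      }
      seq_B[cn] <- s
    }
  }

  structure(list(seq_A = seq_A, seq_B = seq_B,
                 lengths_bp = chrom_lengths,
                 genetic_lengths = genetic_lengths,
                 variants = variants),
            class = "founder_genome")
}

#' @export
print.founder_genome <- function(x, ...) {
  cat("Founder genome pair:", length(x$seq_A), "chromosome(s),",
      sum(x$lengths_bp), "bp,", nrow(x$variants), "variants (",
      sum(x$variants$type == "SNP"), "SNP /",
      sum(x$variants$type == "indel"), "indel )\n")
  invisible(x)
}

## ---- pedigree machinery ----------------------------------------------------
## A haplotype is a data.frame(founder, start, end) of segments in genetic
## coordinates (cM) exactly tiling [0, L]. An individual is, per chromosome,
## a list of two haplotypes.

new_haplotype <- function(founder, L) {
  data.frame(founder = founder, start = 0, end = L, stringsAsFactors = FALSE)
}

#' Construct the F1 individual of a biparental cross
#'
#' @param founders A `founder_genome`.
#' @return An `ril_genome` individual: per chromosome, haplotype 1 entirely
#'   founder A and haplotype 2 entirely founder B.
#' @export
make_f1 <- function(founders) {
  chroms <- names(founders$genetic_lengths)
  ind <- lapply(chroms, function(cn) {
    L <- founders$genetic_lengths[[cn]]
    list(h1 = new_haplotype("A", L), h2 = new_haplotype("B", L))
  })
  names(ind) <- chroms
  structure(list(chromosomes = ind,
                 genetic_lengths = founders$genetic_lengths,
                 generation = 1L),
            class = "ril_genome")
}

## sub-segments of haplotype `hap` within [a, b), shifted to absolute coords
extract_interval <- function(hap, a, b) {
  sel <- hap$end > a & hap$start < b
  seg <- hap[sel, , drop = FALSE]
  if (!nrow(seg)) return(seg)
  seg$start <- pmax(seg$start, a)
  seg$end <- pmin(seg$end, b)
  seg
}

merge_segments <- function(seg) {
  if (nrow(seg) <= 1L) return(seg)
  keep <- logical(nrow(seg))
  keep[1] <- TRUE
  out <- seg
  j <- 1L
  for (i in 2:nrow(seg)) {
    if (seg$founder[i] == out$founder[j] &&
        abs(seg$start[i] - out$end[j]) < 1e-12) {
      out$end[j] <- seg$end[i]
    } else {
      j <- j + 1L
      out[j, ] <- seg[i, ]
    }
  }
  out[seq_len(j), , drop = FALSE]
}

#' Simulate one gamete from an individual
#'
#' Meiosis under the Haldane model: per chromosome the crossover count is
#' Poisson with mean (genetic length)/100 and breakpoints are uniform in
#' genetic coordinates; there is no interference. The gamete alternates
#' between the two parental haplotypes at each breakpoint, starting from a
#' randomly chosen haplotype.
#'
#' @param individual An `ril_genome` individual.
#' @return A list of haplotypes (one per chromosome), each a segment
#'   data.frame tiling `[0, L]` cM.
#' @export
simulate_gamete <- function(individual) {
  lens <- individual$genetic_lengths
  out <- lapply(names(lens), function(cn) {
    L <- lens[[cn]]
    haps <- individual$chromosomes[[cn]]
    phase <- sample(1:2, 1L)
    if (L <= 0) return(haps[[phase]])
    n_co <- stats::rpois(1L, L / 100)
    if (n_co == 0L) return(haps[[phase]])
    bp <- sort(stats::runif(n_co, 0, L))
    bounds <- c(0, bp, L)
    pieces <- vector("list", length(bounds) - 1L)
    for (i in seq_len(length(bounds) - 1L)) {
      src <- if ((i + phase) %% 2L == 0L) haps[[1L]] else haps[[2L]]
      pieces[[i]] <- extract_interval(src, bounds[i], bounds[i + 1L])
    }
    merge_segments(do.call(rbind, pieces))
  })
  names(out) <- names(lens)
  out
}

self_offspring <- function(individual) {
  g1 <- simulate_gamete(individual)
  g2 <- simulate_gamete(individual)
  chroms <- lapply(names(individual$genetic_lengths), function(cn)
    list(h1 = g1[[cn]], h2 = g2[[cn]]))
  names(chroms) <- names(individual$genetic_lengths)
  structure(list(chromosomes = chroms,
                 genetic_lengths = individual$genetic_lengths,
                 generation = individual$generation + 1L),
            class = "ril_genome")
}

#' Advance an F1 individual to an inbred generation by single seed descent
#'
#' Repeated selfing with one offspring retained per generation: generation g
#' requires g - 1 rounds of selfing from the F1, so an F8 RIL has undergone 7
#' meioses and its expected per-site heterozygosity is (1/2)^7.
#'
#' @param f1 An `ril_genome` (typically from [make_f1()]).
#' @param generations Target generation number (default 8; must be >= 2).
#' @return The generation-`generations` individual.
#' @export
advance_ssd <- function(f1, generations = 8L) {
  if (generations < 2L) stop("generations must be >= 2")
  ind <- f1
  for (g in seq_len(generations - f1$generation)) ind <- self_offspring(ind)
  ind
}

#' Simulate a RIL population
#'
#' @param founders A `founder_genome`.
#' @param n_rils Number of recombinant inbred lines.
#' @param generations Final selfing generation (default 8).
#' @param seed Optional integer seed.
#' @return A named list of `ril_genome` individuals (`RIL001`, ...).
#' @export
simulate_rils <- function(founders, n_rils, generations = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_rils < 1L) stop("n_rils must be >= 1")
  f1 <- make_f1(founders)
  rils <- lapply(seq_len(n_rils), function(i) advance_ssd(f1, generations))
  names(rils) <- sprintf("RIL%03d", seq_len(n_rils))
  rils
}

## founder label carried by haplotype `hap` at genetic position g
hap_founder_at <- function(hap, g) {
  i <- findInterval(g, hap$start, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(hap))
  hap$founder[i]
}

#' True genotypes of simulated individuals at the founder variants
#'
#' Reads genotypes straight off the simulated segment maps (no sequencing),
#' giving the ground truth that the RAD genotyper is later compared against.
#'
#' @param founders A `founder_genome`.
#' @param individuals Named list of `ril_genome` individuals.
#' @param include_parents Prepend ideal homozygous parent columns `P_A`, `P_B`.
#' @return A [genotype_matrix()]-classed character matrix (variants x samples)
#'   with codes `A`, `B`, `H`.
#' @export
truth_genotypes <- function(founders, individuals, include_parents = TRUE) {
  v <- founders$variants
  codes <- vapply(individuals, function(ind) {
    vapply(seq_len(nrow(v)), function(i) {
      haps <- ind$chromosomes[[v$chrom[i]]]
      f1 <- hap_founder_at(haps$h1, v$gpos_cM[i])
      f2 <- hap_founder_at(haps$h2, v$gpos_cM[i])
      if (f1 == f2) f1 else "H"
    }, "")
  }, character(nrow(v)))
  codes <- matrix(codes, nrow = nrow(v),
                  dimnames = list(v$id, names(individuals)))
  if (include_parents)
    codes <- cbind(P_A = rep("A", nrow(v)), P_B = rep("B", nrow(v)), codes)
  genotype_matrix(codes, parents = if (include_parents) c("P_A", "P_B"))
}

## ---- RAD library simulation ------------------------------------------------

#' RAD library configuration
#'
#' @param recognition_site Restriction recognition sequence; default EcoRI
#'   `GAATTC`, cut after the first base (`G/AATTC`).
#' @param read_length Total read length including barcode (default 100).
#' @param barcode_length Inline barcode length (default 8); the analysed tag
#'   is `read_length - barcode_length` = 92 bp.
#' @param mean_depth Mean read depth per (site, flank) (default 20).
#' @param depth_distribution `"poisson"` or `"fixed"`.
#' @param error_rate Per-base substitution error rate in `[0, 0.05]`.
#' @param barcode_error_rate Per-base substitution rate inside the barcode
#'   (default 0; exact demultiplexing assumes error-free barcodes, the
#'   non-zero setting exists to exercise the unassigned-read path).
#' @return A list of class `rad_config`.
#' @export
rad_config <- function(recognition_site = "GAATTC", read_length = 100L,
                       barcode_length = 8L, mean_depth = 20,
                       depth_distribution = c("poisson", "fixed"),
                       error_rate = 0, barcode_error_rate = 0) {
  depth_distribution <- match.arg(depth_distribution)
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  tag_len <- read_length - barcode_length
  structure(list(recognition_site = recognition_site,
                 read_length = as.integer(read_length),
                 barcode_length = as.integer(barcode_length),
                 tag_length = as.integer(tag_len),
                 mean_depth = mean_depth,
                 depth_distribution = depth_distribution,
                 error_rate = error_rate,
                 barcode_error_rate = barcode_error_rate),
            class = "rad_config")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## RAD tag catalog of one founder sequence set: for each occurrence of the
## recognition site, the two flanking tags starting at the cut site.
founder_tag_catalog <- function(seqs, genetic_lengths, config) {
  site <- config$recognition_site
  tl <- config$tag_length
  out <- list()
  for (cn in names(seqs)) {
    s <- seqs[[cn]]
    L <- nchar(s)
    hits <- gregexpr(site, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    cut <- as.integer(hits)  # cut between cut and cut+1 (after the leading G)
    right_ok <- cut + tl <= L
    left_ok <- cut - tl >= 0L
    right <- data.frame(chrom = cn, site = cut, flank = "R",
                        tag = substring(s, cut + 1L, cut + tl),
                        stringsAsFactors = FALSE)[right_ok, , drop = FALSE]
    lf <- data.frame(chrom = cn, site = cut, flank = "L",
                     tag = NA_character_, stringsAsFactors = FALSE)
    lf <- lf[left_ok, , drop = FALSE]
    if (nrow(lf))
      lf$tag <- revcomp_chr(substring(s, lf$site - tl + 1L, lf$site))
    out[[cn]] <- rbind(right, lf)
  }
  cat <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), site = integer(0), flank = character(0),
               tag = character(0), stringsAsFactors = FALSE)
  if (nrow(cat)) {
    lens_bp <- vapply(seqs, nchar, 1L)
    cat$gpos_cM <- cat$site / lens_bp[cat$chrom] * genetic_lengths[cat$chrom]
    cat$key <- paste(cat$chrom, cat$flank, round(cat$gpos_cM, 9), sep = ":")
  } else {
    cat$gpos_cM <- numeric(0); cat$key <- character(0)
  }
  rownames(cat) <- NULL
  cat
}

apply_errors <- function(reads, rate, from = 1L, to = NULL) {
  if (rate <= 0 || !length(reads)) return(reads)
  n <- nchar(reads[1])
  if (is.null(to)) to <- n
  span <- to - from + 1L
  n_err <- stats::rpois(1L, rate * span * length(reads))
  if (n_err == 0L) return(reads)
  idx_read <- sample.int(length(reads), n_err, replace = TRUE)
  idx_pos <- sample(from:to, n_err, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_err)) {
    old <- substring(reads[idx_read[i]], idx_pos[i], idx_pos[i])
    new <- sample(setdiff(bases, old), 1L)
    substring(reads[idx_read[i]], idx_pos[i], idx_pos[i]) <- new
  }
  reads
}

#' Generate default sample barcodes
#'
#' @param samples Character vector of sample names.
#' @param length Barcode length (default 8).
#' @return data.frame with columns `sample`, `barcode` (unique).
#' @export
make_barcodes <- function(samples, length = 8L) {
  n <- length(samples)
  bases <- c("A", "C", "G", "T")
  bc <- character(0)
  while (length(bc) < n) {
    cand <- vapply(seq_len(n * 2L), function(i)
      paste(sample(bases, length, replace = TRUE), collapse = ""), "")
    bc <- unique(c(bc, cand))
  }
  data.frame(sample = samples, barcode = bc[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' In-silico restriction digest and RAD sequencing of simulated individuals
#'
#' For every occurrence of the recognition site in the locally inherited
#' founder sequence, reads are emitted from both flanks starting at the cut
#' site: an 8-nt sample barcode followed by the 92-bp tag (100 bp total).
#' Depth is drawn per (site, flank); reads are allocated uniformly to the two
#' haplotypes, and a haplotype lacking the site (e.g. the recognition site is
#' destroyed by a variant on that founder) contributes nothing. Substitution
#' errors are applied to the tag portion at the configured rate.
#'
#' @param founders A `founder_genome`.
#' @param individuals Named list: each element either an `ril_genome` or one
#'   of the strings `"A"`/`"B"` denoting a pure founder sample (parents).
#' @param barcodes data.frame(sample, barcode); defaults to random unique
#'   barcodes for all individuals.
#' @param config A [rad_config()].
#' @param seed Optional integer seed.
#' @return List with `reads` (named list per sample of 100-bp read strings),
#'   `barcodes`, `origins` (truth table: sample, chrom, site, flank,
#'   haplotype founder, read count), and `config`.
#' @export
digest_and_sequence <- function(founders, individuals, barcodes = NULL,
                                config = rad_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(barcodes)) barcodes <- make_barcodes(names(individuals))
  if (anyDuplicated(barcodes$barcode)) stop("duplicate barcodes")
  cat_A <- founder_tag_catalog(founders$seq_A, founders$genetic_lengths, config)
  cat_B <- founder_tag_catalog(founders$seq_B, founders$genetic_lengths, config)
  catalogs <- list(A = cat_A, B = cat_B)
  all_keys <- unique(c(cat_A$key, cat_B$key))

  draw_depth <- function(n) {
    if (config$depth_distribution == "fixed") rep(round(config$mean_depth), n)
    else stats::rpois(n, config$mean_depth)
  }

  reads_out <- list()
  origins <- list()
  for (sm in names(individuals)) {
    ind <- individuals[[sm]]
    bc <- barcodes$barcode[match(sm, barcodes$sample)]
    ## tags present on each haplotype, keyed by (chrom, flank, gpos)
    hap_tags <- lapply(1:2, function(h) {
      res <- list()
      for (fo in c("A", "B")) {
        ct <- catalogs[[fo]]
        if (!nrow(ct)) next
        if (is.character(ind)) {
          keep <- rep(ind == fo, nrow(ct))
        } else {
          keep <- vapply(seq_len(nrow(ct)), function(i) {
            haps <- ind$chromosomes[[ct$chrom[i]]]
            hap_founder_at(haps[[h]], ct$gpos_cM[i]) == fo
          }, TRUE)
        }
        res[[fo]] <- ct[keep, , drop = FALSE]
      }
      do.call(rbind, res)
    })
    keys <- unique(c(hap_tags[[1]]$key, hap_tags[[2]]$key))
    if (!length(keys)) { reads_out[[sm]] <- character(0); next }
    depth <- draw_depth(length(keys))
    sm_reads <- character(0)
    sm_org <- list()
    for (i in seq_along(keys)) {
      d <- depth[i]
      if (d <= 0) next
      hap_choice <- sample(1:2, d, replace = TRUE)
      for (h in 1:2) {
        dh <- sum(hap_choice == h)
        if (dh == 0) next
        row <- hap_tags[[h]][hap_tags[[h]]$key == keys[i], , drop = FALSE]
        if (!nrow(row)) next  # haplotype lacks the site
        tags <- rep(row$tag[1], dh)
        tags <- apply_errors(tags, config$error_rate)
        sm_reads <- c(sm_reads, paste0(bc, tags))
        sm_org[[length(sm_org) + 1L]] <- data.frame(
          sample = sm, chrom = row$chrom[1], site = row$site[1],
          flank = row$flank[1], haplotype = h,
          founder = if (is.character(ind)) ind else
            hap_founder_at(ind$chromosomes[[row$chrom[1]]][[h]],
                           row$gpos_cM[1]),
          n_reads = dh, stringsAsFactors = FALSE)
      }
    }
    if (config$barcode_error_rate > 0)
      sm_reads <- apply_errors(sm_reads, config$barcode_error_rate,
                               from = 1L, to = config$barcode_length)
    reads_out[[sm]] <- sm_reads
    origins[[sm]] <- if (length(sm_org)) do.call(rbind, sm_org) else NULL
  }
  origins <- do.call(rbind, origins[!vapply(origins, is.null, TRUE)])
  rownames(origins) <- NULL
  list(reads = reads_out, barcodes = barcodes, origins = origins,
       config = config, n_sites = length(all_keys))
}

#' Cut-site flank windows of a sequence set
#'
#' Returns, for every occurrence of the recognition site, the two tag
#' windows sequenced from the cut site (the regions a RAD tag can observe).
#' Useful for placing simulated variants where the genotyper can see them,
#' and for restricting a truth set to RAD-visible variants. Windows are
#' trimmed to exclude the recognition site itself (a variant inside the site
#' destroys it rather than appearing in a tag).
#'
#' @param seqs Named character vector of chromosome/scaffold sequences.
#' @param site Recognition sequence (default `GAATTC`, cut after base 1).
#' @param tag_length Tag length in bp (default 92).
#' @return data.frame: `chrom, start, end, site_pos, flank` (1-based,
#'   inclusive).
#' @export
cut_site_flanks <- function(seqs, site = "GAATTC", tag_length = 92L) {
  out <- list()
  slen <- nchar(site)
  for (cn in names(seqs)) {
    s <- seqs[[cn]]
    L <- nchar(s)
    hits <- gregexpr(site, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    cut <- as.integer(hits)  # cut after position `cut` (the leading G)
    right <- data.frame(chrom = cn, start = cut + slen,
                        end = pmin(cut + tag_length, L),
                        site_pos = cut, flank = "R",
                        stringsAsFactors = FALSE)
    left <- data.frame(chrom = cn, start = pmax(cut - tag_length + 1L, 1L),
                       end = cut - 1L, site_pos = cut, flank = "L",
                       stringsAsFactors = FALSE)
    keep_r <- cut + tag_length <= L
    keep_l <- cut - tag_length >= 0L
    out[[cn]] <- rbind(right[keep_r, , drop = FALSE],
                       left[keep_l, , drop = FALSE])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), site_pos = integer(0),
                      flank = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pool per-sample reads into one barcoded FASTQ-style read vector
#'
#' @param sim Result of [digest_and_sequence()].
#' @return Named character vector of reads (names are read ids).
#' @export
pool_reads <- function(sim) {
  out <- unlist(lapply(names(sim$reads), function(sm) {
    r <- sim$reads[[sm]]
    if (!length(r)) return(NULL)
    names(r) <- sprintf("%s_read%06d", sm, seq_along(r))
    r
  }))
  if (is.null(out)) character(0) else out
}
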