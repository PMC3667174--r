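# Shared fixtures and independent oracles used across the test files.

# all permutations of 1..n as a matrix (n! x n); used as the brute-force
# ordering oracle
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# brute-force minimum COUNT over all marker orders (independent of the
# greedy/ripple search path)
exhaustive_min_count <- function(kmat) {
  n <- nrow(kmat)
  P <- all_perms(n)
  tot <- Reduce(`+`, lapply(seq_len(n - 1L), function(i)
    kmat[cbind(P[, i], P[, i + 1L])]))
  min(tot)
}

# random symmetric recombination-count matrix with named markers
random_kmat <- function(n, max_k = 10L) {
  m <- matrix(sample(0:max_k, n * n, replace = TRUE), n, n)
  m <- m + t(m)
  diag(m) <- 0
  dimnames(m) <- list(sprintf("m%02d", seq_len(n)), sprintf("m%02d", seq_len(n)))
  m
}

# small deterministic genotype matrix: `pattern` rows of A/B codes for RILs
toy_genotypes <- function(patterns, parents = TRUE) {
  mk <- names(patterns)
  n <- unique(nchar(unname(unlist(patterns))))
  stopifnot(length(n) == 1L)
  codes <- do.call(rbind, lapply(patterns, function(p) strsplit(p, "")[[1]]))
  codes[codes == "-"] <- NA_character_
  colnames(codes) <- sprintf("RIL%03d", seq_len(n))
  rownames(codes) <- mk
  if (parents) {
    codes <- cbind(P_A = rep("A", nrow(codes)), P_B = rep("B", nrow(codes)),
                   codes)
    genotype_matrix(codes, parents = c("P_A", "P_B"))
  } else genotype_matrix(codes)
}

# founder pair + RIL panel + truth genotypes in one call
sim_panel <- function(n_chrom = 2, len_bp = 6e5, len_cM = 100,
                      n_variants = 60, n_rils = 94, seed = 1,
                      generations = 8) {
  lens <- rep(len_bp, n_chrom)
  names(lens) <- paste0("chr", seq_len(n_chrom))
  fg <- make_founders(lens, len_cM, n_variants = n_variants, seed = seed)
  set.seed(seed + 1000L)
  rils <- simulate_rils(fg, n_rils, generations)
  list(founders = fg, rils = rils,
       genotypes = truth_genotypes(fg, rils))
}
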