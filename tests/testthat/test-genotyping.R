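tag92 <- function(seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 92, TRUE), collapse = "")
}

mutate_at <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

test_that("demultiplexing is exact-prefix and partitions the input", {
  bm <- data.frame(sample = c("s1", "s2"),
                   barcode = c("AAAAAAAA", "CCCCCCCC"))
  t1 <- tag92(1)
  reads <- c(paste0("AAAAAAAA", t1), paste0("CCCCCCCC", t1),
             paste0("AAAAAAAG", t1),  # one barcode mismatch -> unassigned
             paste0("GGGGGGGG", t1))
  dm <- demultiplex(reads, bm)
  expect_equal(dm$samples$s1, t1)
  expect_equal(dm$samples$s2, t1)
  expect_equal(dm$unassigned, 2)
  expect_equal(length(dm$samples$s1) + length(dm$samples$s2) + dm$unassigned,
               length(reads))
  expect_true(all(nchar(unlist(dm$samples)) == 92))

  expect_error(
    demultiplex(reads, data.frame(sample = c("a", "b"),
                                  barcode = c("AAAAAAAA", "AAAAAAAA"))),
    "duplicate")
})

test_that("error-free simulated library demultiplexes 100% to truth counts", {
  fg <- make_founders(c(chr1 = 3e4), n_variants = 5, seed = 2)
  set.seed(2)
  rils <- simulate_rils(fg, 4, 8)
  sim <- digest_and_sequence(fg, c(list(P_A = "A", P_B = "B"), rils),
                             config = rad_config(error_rate = 0), seed = 3)
  reads <- pool_reads(sim)
  dm <- demultiplex(unname(reads), sim$barcodes)
  expect_equal(dm$unassigned, 0)
  truth_counts <- tapply(sim$origins$n_reads, sim$origins$sample, sum)
  got <- vapply(dm$samples, length, 1L)
  expect_equal(unname(got[names(truth_counts)]),
               as.vector(truth_counts))
})

test_that("tag clustering is identity-based with multiplicities", {
  t1 <- tag92(4)
  t2 <- mutate_at(t1, 10, if (substr(t1, 10, 10) == "A") "C" else "A")
  tags <- cluster_tags(c(rep(t1, 5), rep(t2, 2)))
  expect_equal(nrow(tags), 2)
  expect_equal(tags$count[tags$sequence == t1], 5)
  expect_equal(tags$count[tags$sequence == t2], 2)
  expect_equal(nrow(cluster_tags(character(0))), 0)
})

test_that("repeat filter removes tags with more than 100 reads", {
  tags <- data.frame(sequence = c("AA", "CC", "GG"),
                     count = c(100L, 101L, 1L))
  out <- filter_repetitive(tags)
  expect_setequal(out$sequence, c("AA", "GG"))  # 100 kept, 101 removed
  expect_equal(attr(out, "n_removed"), 1)
  empty <- filter_repetitive(cluster_tags(character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("a collapsed repeat exceeds the depth ceiling and is removed", {
  # 10 identical copies of one tag region at 20x: ~200 reads on one tag
  set.seed(5)
  unit <- paste0("G", paste(sample(c("A", "C", "T"), 250, TRUE),
                            collapse = ""))
  unit <- sub("^G", "GAATTC", unit)          # one cut site per copy
  genome <- paste(rep(unit, 10), collapse = "")
  fg <- make_founders(c(chr1 = nchar(genome)), n_variants = 0, seed = 1)
  fg$seq_A["chr1"] <- fg$seq_B["chr1"] <- genome
  fg$lengths_bp["chr1"] <- nchar(genome)
  sim <- digest_and_sequence(fg, list(S = "A"),
                             config = rad_config(mean_depth = 20,
                                                 error_rate = 0), seed = 6)
  tags <- cluster_tags(substring(sim$reads$S, 9))
  expect_true(any(tags$count > 100))
  kept <- filter_repetitive(tags)
  expect_gt(attr(kept, "n_removed"), 0)
  expect_true(all(kept$count <= 100))
})

test_that("parental marker calling pairs uniquely and rejects ambiguity", {
  base <- tag92(7)
  snp_b <- mutate_at(base, 31, if (substr(base, 31, 31) == "C") "T" else "C")
  other <- tag92(8)
  tags_A <- data.frame(sequence = c(base, other), count = c(10L, 10L))
  tags_B <- data.frame(sequence = c(snp_b, other), count = c(10L, 10L))
  mk <- call_parental_markers(tags_A, tags_B)
  # the shared tag is monomorphic and excluded; one SNP marker at offset 31
  expect_equal(nrow(mk), 1)
  expect_equal(mk$type, "SNP")
  expect_equal(mk$offset, 31L)
  expect_identical(sort(c(mk$allele_A, mk$allele_B)),
                   sort(c(substr(base, 31, 31), substr(snp_b, 31, 31))))
  expect_match(mk$marker_id, "^DAFWA")
  expect_equal(attr(mk, "rejected")[["monomorphic"]], 1)

  # identical tag sets -> no markers
  mk0 <- call_parental_markers(tags_A, tags_A)
  expect_equal(nrow(mk0), 0)

  # three mutually close tags: ambiguous pairing discards all.
  # Independent oracle: exhaustive pairwise Hamming comparison.
  b2 <- mutate_at(base, 50, if (substr(base, 50, 50) == "A") "G" else "A")
  tA <- data.frame(sequence = base, count = 10L)
  tB <- data.frame(sequence = c(snp_b, b2), count = c(10L, 10L))
  ham <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  n_partners <- sum(vapply(tB$sequence, function(y) ham(base, y) == 1, TRUE))
  expect_equal(n_partners, 2)  # oracle confirms the ambiguity
  mk2 <- call_parental_markers(tA, tB)
  expect_equal(nrow(mk2), 0)
  expect_gt(attr(mk2, "rejected")[["ambiguous"]], 0)

  # depth below min_depth suppresses the pair
  tags_lo <- data.frame(sequence = base, count = 2L)
  mk3 <- call_parental_markers(tags_lo,
                               data.frame(sequence = snp_b, count = 10L))
  expect_equal(nrow(mk3), 0)
})

test_that("indel markers align with a single gap and no mismatches", {
  base <- tag92(9)
  # founder B inserted 4 bp at position 40; its 92-bp tag shifts accordingly
  ins <- "TGCA"
  shifted <- paste0(substr(base, 1, 40), ins, substr(base, 41, 88))
  expect_equal(nchar(shifted), 92)
  tags_A <- data.frame(sequence = base, count = 10L)
  tags_B <- data.frame(sequence = shifted, count = 10L)
  mk <- call_parental_markers(tags_A, tags_B)
  expect_equal(nrow(mk), 1)
  expect_equal(mk$type, "indel")
  expect_match(mk$marker_id, "^iDAFWA")
  expect_true(is.na(mk$offset))
  expect_equal(sort(c(mk$allele_A, mk$allele_B))[2], ins)
})

test_that("RIL genotype codes follow the depth rules", {
  base <- tag92(10)
  alt <- mutate_at(base, 20, if (substr(base, 20, 20) == "G") "T" else "G")
  mk <- call_parental_markers(data.frame(sequence = base, count = 10L),
                              data.frame(sequence = alt, count = 10L))
  st <- list(
    P_A = data.frame(sequence = base, count = 10L),
    P_B = data.frame(sequence = alt, count = 10L),
    R1 = data.frame(sequence = base, count = 10L),
    R2 = data.frame(sequence = base, count = 2L),          # below min_depth
    R3 = data.frame(sequence = c(base, alt), count = c(5L, 4L)),  # het
    R4 = data.frame(sequence = "X", count = 1L)[0, ])      # nothing seen
  gm <- genotype_rils(mk, st, parents = c("P_A", "P_B"))
  x <- unclass(gm)[1, ]
  expect_equal(unname(x[c("P_A", "P_B", "R1", "R2", "R3", "R4")]),
               c("A", "B", "A", NA, "H", NA))
})

test_that("simulated panel genotypes match truth at >= 99%", {
  fg0 <- make_founders(c(chr1 = 8e4, chr2 = 8e4), n_variants = 0, seed = 12)
  fl <- cut_site_flanks(fg0$seq_A)
  fg <- make_founders(c(chr1 = 8e4, chr2 = 8e4), n_variants = 24, seed = 12,
                      variant_windows = fl)
  set.seed(13)
  rils <- simulate_rils(fg, 48, 8)
  sim <- digest_and_sequence(fg, c(list(P_A = "A", P_B = "B"), rils),
                             config = rad_config(mean_depth = 20,
                                                 error_rate = 0.001),
                             seed = 14)
  dm <- demultiplex(unname(pool_reads(sim)), sim$barcodes)
  tags <- lapply(dm$samples, function(r) filter_repetitive(cluster_tags(r)))
  mk <- call_parental_markers(tags$P_A, tags$P_B)
  expect_gt(nrow(mk), 10)
  gm <- genotype_rils(mk, tags, parents = c("P_A", "P_B"))
  truth <- truth_genotypes(fg, rils)

  # match each marker to its truth variant through the variant position:
  # anchor tag_A in founder A and read off the truth genotype row
  loc <- locate_tags(mk, fg$seq_A)
  anch <- loc$anchors
  v <- fg$variants
  agree <- 0L; total <- 0L
  for (i in seq_len(nrow(anch))) {
    pos <- anch$position[i]
    hit <- which(v$chrom == anch$scaffold[i] & abs(v$pos - pos) <= 92)
    if (length(hit) != 1) next
    truth_row <- unclass(truth)[v$id[hit], ril_samples(gm)]
    got_row <- unclass(gm)[anch$marker[i], ril_samples(gm)]
    use <- !is.na(got_row)
    agree <- agree + sum(got_row[use] == truth_row[use])
    total <- total + sum(use)
  }
  expect_gt(total, 200)
  expect_gte(agree / total, 0.99)
})

test_that("genotype codes are symmetric under swapping parent labels", {
  base <- tag92(15)
  alt <- mutate_at(base, 60, if (substr(base, 60, 60) == "A") "C" else "A")
  st <- list(P_A = data.frame(sequence = base, count = 10L),
             P_B = data.frame(sequence = alt, count = 10L),
             R1 = data.frame(sequence = base, count = 8L),
             R2 = data.frame(sequence = alt, count = 8L))
  mk <- call_parental_markers(st$P_A, st$P_B)
  gm <- genotype_rils(mk, st, parents = c("P_A", "P_B"))
  mk_sw <- call_parental_markers(st$P_B, st$P_A)
  gm_sw <- genotype_rils(mk_sw, st[c(2, 1, 3, 4)], parents = c("P_B", "P_A"))
  flip <- c(A = "B", B = "A", H = "H")
  expect_equal(unname(flip[unclass(gm)[1, c("R1", "R2")]]),
               unname(unclass(gm_sw)[1, c("R1", "R2")]))
})

test_that("qc reports closed-form segregation chi-square", {
  gm <- toy_genotypes(list(
    m1 = paste(c(rep("A", 47), rep("B", 47)), collapse = ""),
    m2 = paste(rep("A", 94), collapse = "")))
  qc <- qc_matrix(gm)
  expect_equal(qc$chisq[qc$marker == "m1"], 0)
  expect_equal(qc$chisq[qc$marker == "m2"], 94)   # (94-47)^2/47 * 2
  expect_equal(qc$missing_rate, c(0, 0))

  # simulated panel: few markers beyond the chi-square 99.9% critical value
  p <- sim_panel(n_chrom = 2, len_bp = 4e5, n_variants = 50, n_rils = 94,
                 seed = 21)
  qc2 <- qc_matrix(p$genotypes)
  crit <- qchisq(0.999, df = 1)
  expect_lt(mean(qc2$chisq > crit), 0.05)
})
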