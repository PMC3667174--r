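test_that("founder generation honours variant counts, spacing and determinism", {
  fg0 <- make_founders(c(chr1 = 2e4), n_variants = 0, seed = 1)
  expect_identical(fg0$seq_A, fg0$seq_B)

  fg <- make_founders(c(chr1 = 1e5), n_variants = 50, seed = 1)
  expect_equal(nrow(fg$variants), 50)
  expect_true(all(diff(sort(fg$variants$pos)) >= 92))
  expect_true(all(fg$variants$pos > 92 &
                    fg$variants$pos < 1e5 - 92))
  snp <- fg$variants[fg$variants$type == "SNP", ]
  expect_true(all(nchar(snp$allele_A) == 1 & nchar(snp$allele_B) == 1 &
                    snp$allele_A != snp$allele_B))
  ind <- fg$variants[fg$variants$type == "indel", ]
  if (nrow(ind)) {
    gap <- abs(nchar(ind$allele_A) - nchar(ind$allele_B))
    expect_true(all(gap >= 1 & gap <= 10))
  }
  # byte-identical regeneration under the same seed
  fg2 <- make_founders(c(chr1 = 1e5), n_variants = 50, seed = 1)
  expect_identical(fg, fg2)
})

test_that("infeasible variant density errors instead of silently truncating", {
  expect_error(make_founders(c(chr1 = 2000), n_variants = 50, seed = 1),
               "infeasible|too short")
})

test_that("founder B sequence carries exactly the truth variants", {
  fg <- make_founders(c(chr1 = 5e4), n_variants = 20, seed = 3,
                      indel_fraction = 0)
  a <- strsplit(fg$seq_A[["chr1"]], "")[[1]]
  b <- strsplit(fg$seq_B[["chr1"]], "")[[1]]
  diff_pos <- which(a != b)
  expect_identical(diff_pos, sort(fg$variants$pos))
  expect_identical(a[diff_pos],
                   fg$variants$allele_A[order(fg$variants$pos)])
  expect_identical(b[diff_pos],
                   fg$variants$allele_B[order(fg$variants$pos)])
})

test_that("gametes follow the Poisson/Haldane meiosis model", {
  fg <- make_founders(c(chr1 = 1e4), genetic_lengths = 0, n_variants = 0,
                      seed = 1)
  f1 <- make_f1(fg)
  set.seed(1)
  g <- simulate_gamete(f1)[["chr1"]]
  expect_equal(nrow(g), 1)  # 0 cM: intact parental haplotype

  fg2 <- make_founders(c(chr1 = 1e4), genetic_lengths = 100, n_variants = 0,
                       seed = 1)
  f1b <- make_f1(fg2)
  set.seed(2)
  n_co <- replicate(10000, {
    g <- simulate_gamete(f1b)[["chr1"]]
    nrow(g) - 1L   # junction count = crossovers retained in the mosaic
  })
  # mean crossover count 1.0 within 3 SE (Poisson sd 1)
  expect_lt(abs(mean(n_co) - 1), 3 / sqrt(10000))

  # recombinant fraction between positions 10 cM apart matches Haldane
  set.seed(3)
  rec <- replicate(8000, {
    g <- simulate_gamete(f1b)[["chr1"]]
    rilmap:::hap_founder_at(g, 45) != rilmap:::hap_founder_at(g, 55)
  })
  r_hald <- (1 - exp(-0.2)) / 2        # 0.0906
  se <- sqrt(r_hald * (1 - r_hald) / 8000)
  expect_lt(abs(mean(rec) - r_hald), 3 * se)
})

test_that("single seed descent reaches the expected residual heterozygosity", {
  # 50 one-variant chromosomes give near-independent sites
  lens <- rep(3000L, 50)
  names(lens) <- paste0("c", 1:50)
  fg <- make_founders(lens, genetic_lengths = 50, n_variants = 50, seed = 5)
  set.seed(6)
  rils <- simulate_rils(fg, 200, 8)
  tg <- truth_genotypes(fg, rils, include_parents = FALSE)
  n_sites <- length(tg)
  h <- sum(unclass(tg) == "H")
  p <- (1 / 2)^7
  # binomial 99% bounds around the Mendelian halving expectation
  bounds <- qbinom(c(0.005, 0.995), n_sites, p)
  expect_gte(h, bounds[1])
  expect_lte(h, bounds[2])

  # F2: heterozygosity 0.5 expectation, one meiosis pair from F1
  f1 <- make_f1(fg)
  set.seed(7)
  f2h <- replicate(1500, {
    ind <- rilmap:::self_offspring(f1)
    haps <- ind$chromosomes[[1]]
    rilmap:::hap_founder_at(haps$h1, 25) != rilmap:::hap_founder_at(haps$h2, 25)
  })
  expect_lt(abs(mean(f2h) - 0.5), 3 * sqrt(0.25 / 1500))

  # unlinked loci segregate independently across RILs
  g1 <- unclass(tg)[1, ]
  g2 <- unclass(tg)[30, ]
  use <- g1 %in% c("A", "B") & g2 %in% c("A", "B")
  co <- cor(g1[use] == "A", g2[use] == "A")
  expect_lt(abs(co), 3 / sqrt(sum(use)))
})

test_that("haplotype segments tile each chromosome exactly", {
  fg <- make_founders(c(chr1 = 2e4, chr2 = 2e4), genetic_lengths = c(80, 120),
                      n_variants = 0, seed = 2)
  set.seed(2)
  rils <- simulate_rils(fg, 20, 8)
  for (ind in rils) {
    for (cn in names(ind$chromosomes)) {
      L <- ind$genetic_lengths[[cn]]
      for (h in ind$chromosomes[[cn]]) {
        expect_equal(h$start[1], 0)
        expect_equal(h$end[nrow(h)], L)
        if (nrow(h) > 1)
          expect_equal(h$start[-1], h$end[-nrow(h)])
      }
    }
  }
})

test_that("marker segregation across RILs is balanced", {
  p <- sim_panel(n_chrom = 2, len_bp = 4e5, n_variants = 40, n_rils = 96,
                 seed = 11)
  tg <- unclass(p$genotypes)[, ril_samples(p$genotypes)]
  freq <- rowMeans(tg == "A") /
    rowMeans(matrix(tg %in% c("A", "B"), nrow(tg)))
  se <- sqrt(0.25 / 96)
  expect_true(all(freq > 0.5 - 3 * se - 0.05 & freq < 0.5 + 3 * se + 0.05))
  # population mean allele frequency tightly around 0.5
  expect_lt(abs(mean(freq) - 0.5), 0.05)
})

test_that("RAD digest emits correct reads from both flanks", {
  # no recognition site -> no reads
  fg <- make_founders(c(chr1 = 300), n_variants = 0, seed = 1)
  fg$seq_A["chr1"] <- fg$seq_B["chr1"] <-
    paste(rep("AC", 150), collapse = "")
  sim <- digest_and_sequence(fg, list(S1 = "A"),
                             config = rad_config(mean_depth = 5,
                                                 depth_distribution = "fixed"),
                             seed = 1)
  expect_length(sim$reads$S1, 0)

  # single central site, fixed depth 5, error-free: 2 flanks x 5 = 10 reads
  set.seed(42)
  flank <- function(n) paste(sample(c("A", "C", "T"), n, TRUE), collapse = "")
  left <- flank(120)
  right <- flank(120)
  s <- paste0(left, "GAATTC", right)
  fg$seq_A["chr1"] <- fg$seq_B["chr1"] <- s
  fg$lengths_bp["chr1"] <- nchar(s)
  sim <- digest_and_sequence(fg, list(S1 = "A"),
                             barcodes = data.frame(sample = "S1",
                                                   barcode = "AAGGTTCC"),
                             config = rad_config(mean_depth = 5,
                                                 depth_distribution = "fixed",
                                                 error_rate = 0),
                             seed = 1)
  reads <- sim$reads$S1
  expect_length(reads, 10)
  expect_true(all(nchar(reads) == 100))
  expect_true(all(substr(reads, 1, 8) == "AAGGTTCC"))
  cut <- nchar(left) + 1L  # position of the G; cut after it
  tag_right <- substr(s, cut + 1, cut + 92)
  tag_left <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, cut - 91, cut))))
  expect_setequal(unique(substring(reads, 9)), c(tag_right, tag_left))
})

test_that("a SNP near the cut site separates parental tags at the true offset", {
  set.seed(9)
  flank <- function(n) paste(sample(c("A", "C", "T"), n, TRUE), collapse = "")
  left <- flank(120); right <- flank(120)
  s_a <- paste0(left, "GAATTC", right)
  cut <- nchar(left) + 1L
  snp_pos <- cut + 30L    # offset 30 within the right-flank tag
  s_b <- s_a
  substr(s_b, snp_pos, snp_pos) <- "G"
  stopifnot(substr(s_a, snp_pos, snp_pos) != "G")
  fg <- make_founders(c(chr1 = nchar(s_a)), n_variants = 0, seed = 1)
  fg$seq_A["chr1"] <- s_a
  fg$seq_B["chr1"] <- s_b
  fg$lengths_bp["chr1"] <- nchar(s_a)
  sim <- digest_and_sequence(fg, list(PA = "A", PB = "B"),
                             config = rad_config(mean_depth = 5,
                                                 depth_distribution = "fixed",
                                                 error_rate = 0),
                             seed = 2)
  tag_a <- unique(substring(sim$reads$PA, 9))
  tag_b <- unique(substring(sim$reads$PB, 9))
  shared <- intersect(tag_a, tag_b)
  diff_a <- setdiff(tag_a, shared)
  diff_b <- setdiff(tag_b, shared)
  expect_length(diff_a, 1)
  expect_length(diff_b, 1)
  mism <- which(strsplit(diff_a, "")[[1]] != strsplit(diff_b, "")[[1]])
  expect_equal(mism, 30L)
})

test_that("identical configuration and seed give byte-identical output", {
  run <- function() {
    fg <- make_founders(c(chr1 = 3e4), n_variants = 10, seed = 4)
    set.seed(5)
    rils <- simulate_rils(fg, 5, 8)
    digest_and_sequence(fg, c(list(P_A = "A", P_B = "B"), rils),
                        config = rad_config(error_rate = 0.001), seed = 6)
  }
  expect_identical(pool_reads(run()), pool_reads(run()))
})

test_that("RIL recombinant fractions follow the Haldane-Waddington curve", {
  # variants at known genetic positions; compare observed R with 2r/(1+2r)
  fg <- make_founders(c(chr1 = 1e5), genetic_lengths = 100, n_variants = 0,
                      seed = 1)
  fg$variants <- data.frame(
    id = c("V1", "V2", "V3"), chrom = "chr1",
    pos = c(30000, 40000, 70000), type = "SNP",
    allele_A = "A", allele_B = "C", gpos_cM = c(30, 40, 70),
    stringsAsFactors = FALSE)
  set.seed(8)
  rils <- simulate_rils(fg, 600, 8)
  gm <- truth_genotypes(fg, rils)
  for (pair in list(c("V1", "V2", 10), c("V2", "V3", 30))) {
    d <- as.numeric(pair[3])
    r <- (1 - exp(-2 * d / 100)) / 2
    R_exp <- 2 * r / (1 + 2 * r)
    tp <- two_point(gm, pair[1], pair[2])
    se <- sqrt(R_exp * (1 - R_exp) / tp$n)
    # F8 sits slightly below the RIL-infinity limit; allow 3 SE + 1.5% model gap
    expect_lt(abs(tp$R - R_exp), 3 * se + 0.015)
  }
})
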