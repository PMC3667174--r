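#' Default pipeline configuration
#'
#' All tunable stage parameters of the end-to-end run with their defaults.
#' Every source of randomness flows from the single `seed`.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    ## simulate
    n_chromosomes = 2, chrom_length_bp = 1e5, genetic_length_cM = 100,
    n_variants = 40, indel_fraction = 0.08, n_rils = 24, generations = 8,
    variants_in_flanks = TRUE,
    mean_depth = 20, depth_distribution = "poisson", error_rate = 0.001,
    ## kmer
    k = 17,
    ## genotyping
    min_depth = 3, max_tag_reads = 100,
    ## map
    lod_start = 6, target_groups = 2, lod_floor = 3,
    mapping_function = "kosambi", n_starts = 10,
    ## traits
    trait_variant = 1, window_cM = 5,
    ## scaffolds: founder A chopped into pieces of this size
    scaffold_size_bp = 10000)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

## chop founder A into a synthetic scaffold set (named character vector)
founder_scaffolds <- function(founders, size) {
  out <- character(0)
  i <- 0L
  for (cn in names(founders$seq_A)) {
    s <- founders$seq_A[[cn]]
    starts <- seq(1L, nchar(s), by = size)
    for (st in starts) {
      i <- i + 1L
      out[sprintf("scaffold%05d", i)] <- substring(s, st, min(st + size - 1L,
                                                              nchar(s)))
    }
  }
  out
}

#' Run the full simulate -> survey -> genotype -> map -> anchor -> trait scan
#' pipeline
#'
#' Executes every stage on a simulated dataset defined by the configuration,
#' writes the stage outputs as headered CSV (plus FASTQ for reads) into
#' `out_dir`, and a flat-text run manifest with the seed, parameters and
#' per-stage counts. The simulated trait is the genotype at one chosen
#' founder variant, so the scan's expected answer (the scaffold carrying
#' that variant) is known.
#'
#' @param config List from [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run (a prefix of the full
#'   sequence).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "kmerprof", "genotype",
                                    "map", "anchor", "traitscan")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  res <- list(config = config)
  counts <- list()

  full <- c("simulate", "kmerprof", "genotype", "map", "anchor", "traitscan")
  stages <- full[full %in% stages]

  ## simulate
  stage_log("simulate", "founders + %d F%d RILs", config$n_rils,
            config$generations)
  lens <- rep(config$chrom_length_bp, config$n_chromosomes)
  names(lens) <- paste0("chr", seq_len(config$n_chromosomes))
  windows <- NULL
  if (isTRUE(config$variants_in_flanks)) {
    ## same seed re-draws the identical founder sequence, so the flank
    ## windows computed from the variant-free draw stay valid
    bare <- make_founders(lens, config$genetic_length_cM, n_variants = 0,
                          seed = config$seed)
    windows <- cut_site_flanks(bare$seq_A)
  }
  founders <- make_founders(lens, config$genetic_length_cM,
                            n_variants = config$n_variants,
                            indel_fraction = config$indel_fraction,
                            seed = config$seed, variant_windows = windows)
  rils <- simulate_rils(founders, config$n_rils, config$generations)
  individuals <- c(list(P_A = "A", P_B = "B"), rils)
  rcfg <- rad_config(mean_depth = config$mean_depth,
                     depth_distribution = config$depth_distribution,
                     error_rate = config$error_rate)
  sim <- digest_and_sequence(founders, individuals, config = rcfg)
  reads <- pool_reads(sim)
  res$founders <- founders
  res$ril_individuals <- rils
  res$sim <- sim
  counts$simulate <- c(variants = nrow(founders$variants),
                       rils = config$n_rils, reads = length(reads))
  utils::write.csv(founders$variants, file.path(out_dir, "truth_variants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$origins, file.path(out_dir, "truth_read_origins.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$barcodes, file.path(out_dir, "barcodes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_fastq(reads, file.path(out_dir, "reads.fastq"))
  if (!"kmerprof" %in% stages && length(stages) == 1L)
    return(finish_run(res, counts, config, out_dir))

  if ("kmerprof" %in% stages) {
    stage_log("kmerprof", "k = %d histogram over %d reads", config$k,
              length(reads))
    tags_only <- substring(reads, 9L)
    hist <- count_kmers(tags_only, k = config$k)
    write_kmer_histogram(hist, file.path(out_dir, "kmer_histogram.csv"))
    res$kmer <- hist
    counts$kmerprof <- c(volume = hist$volume,
                         peak = tryCatch(find_peak(hist),
                                         error = function(e) NA))
  }

  if ("genotype" %in% stages) {
    stage_log("genotype", "demultiplex + tag clustering + marker calling")
    dm <- demultiplex(unname(reads), sim$barcodes)
    sample_tags <- lapply(dm$samples, function(rr)
      filter_repetitive(cluster_tags(rr), config$max_tag_reads))
    markers <- call_parental_markers(sample_tags$P_A, sample_tags$P_B,
                                     min_depth = config$min_depth)
    gm <- genotype_rils(markers, sample_tags, min_depth = config$min_depth,
                        parents = c("P_A", "P_B"))
    res$markers <- markers
    res$genotypes <- gm
    counts$genotype <- c(assigned = dm$n_input - dm$unassigned,
                         unassigned = dm$unassigned, markers = nrow(markers))
    utils::write.csv(markers, file.path(out_dir, "markers.csv"),
                     row.names = FALSE, quote = FALSE)
    write_genotype_matrix(gm, file.path(out_dir, "genotypes.csv"))
    utils::write.csv(qc_matrix(gm), file.path(out_dir, "genotype_qc.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("map" %in% stages) {
    stage_log("map", "linkage map from %d markers", nrow(res$genotypes))
    map <- ril_map(res$genotypes, lod_start = config$lod_start,
                   target_groups = config$target_groups,
                   lod_floor = config$lod_floor,
                   mapping_function = config$mapping_function,
                   n_starts = config$n_starts, seed = config$seed)
    res$map <- map
    counts$map <- c(groups = length(map$groups),
                    loci = sum(vapply(map$groups,
                                      function(g) length(g$loci), 0L)))
    utils::write.csv(map_table(map), file.path(out_dir, "map.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("anchor" %in% stages) {
    stage_log("anchor", "exact tag match against synthetic scaffolds")
    scaffolds <- founder_scaffolds(founders, config$scaffold_size_bp)
    loc <- locate_tags(res$markers, scaffolds)
    integ <- integrate_anchors(loc$anchors, res$map, nchar(scaffolds))
    res$scaffolds <- scaffolds
    res$anchors <- loc
    res$integration <- integ
    counts$anchor <- c(anchored = nrow(loc$anchors),
                       rejected = nrow(loc$rejected),
                       conflicts = nrow(integ$conflicts))
    write_fasta(scaffolds, file.path(out_dir, "scaffolds.fasta"))
    utils::write.csv(loc$anchors, file.path(out_dir, "anchors.csv"),
                     row.names = FALSE, quote = FALSE)
    summ <- summary(res$map, anchors = integ)
    utils::write.csv(summ$per_group, file.path(out_dir, "map_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("traitscan" %in% stages) {
    stage_log("traitscan", "co-segregation scan for the simulated trait")
    v <- founders$variants[config$trait_variant, ]
    pheno <- trait_phenotype_from_variant(founders, res, config)
    scan <- trait_scan(res$genotypes, pheno, res$map,
                       anchors = res$anchors$anchors,
                       scaffold_lengths = nchar(res$scaffolds),
                       window = config$window_cM, donor_class = "R",
                       trait_name = sprintf("variant_%s", v$id))
    res$trait <- scan
    counts$traitscan <- c(linked = nrow(scan$linked),
                          cosegregating = length(scan$cosegregating),
                          candidates = if (is.null(scan$candidates)) 0L
                          else nrow(scan$candidates))
    if (!is.null(scan$candidates))
      utils::write.csv(scan$candidates,
                       file.path(out_dir, "trait_candidates.csv"),
                       row.names = FALSE, quote = FALSE)
  }

  finish_run(res, counts, config, out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## phenotype for the configured causal variant: R where the RIL carries the
## founder-A allele, S otherwise (H -> donor class, a dominant-style call)
trait_phenotype_from_variant <- function(founders, res, config) {
  v <- founders$variants[config$trait_variant, ]
  rl <- ril_samples(res$genotypes)
  inds <- res$ril_individuals
  if (is.null(inds))
    stop("internal: RIL individuals unavailable for trait simulation")
  codes <- vapply(rl, function(sm) {
    ind <- inds[[sm]]
    haps <- ind$chromosomes[[v$chrom]]
    f1 <- hap_founder_at(haps$h1, v$gpos_cM)
    f2 <- hap_founder_at(haps$h2, v$gpos_cM)
    if (f1 == "A" || f2 == "A") "R" else "S"
  }, "")
  names(codes) <- rl
  codes
}

finish_run <- function(res, counts, config, out_dir) {
  manifest <- c(
    sprintf("rilmap_version = %s",
            as.character(utils::packageVersion("rilmap"))),
    sprintf("seed = %s", format(config$seed)),
    vapply(names(config), function(k)
      sprintf("param.%s = %s", k, format(config[[k]])), ""),
    unlist(lapply(names(counts), function(st)
      sprintf("count.%s.%s = %s", st, names(counts[[st]]),
              format(unname(counts[[st]]))))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  res$counts <- counts
  invisible(res)
}
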