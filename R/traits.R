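#' Convert a binary phenotype to a pseudo-marker genotype vector
#'
#' The trait is treated as one extra two-class marker: samples carrying the
#' donor parent's phenotype class are coded with that parent's allele. In an
#' F8 population phenotypes report (near-)homozygous classes, so the mapping
#' is direct.
#'
#' @param phenotype Named character vector (sample -> class, e.g. `R`/`S`).
#' @param donor_class Phenotype class carried by founder A (default the
#'   class of the first parent if `parents` given, else the first class
#'   alphabetically).
#' @param samples Sample order for the output (default names of
#'   `phenotype`).
#' @return Named character vector of `A`/`B` codes (NA where phenotype
#'   missing).
#' @export
phenotype_as_marker <- function(phenotype, donor_class = NULL,
                                samples = names(phenotype)) {
  classes <- sort(unique(stats::na.omit(unname(phenotype))))
  if (length(classes) != 2L)
    stop("phenotype must have exactly two classes among scored samples")
  if (is.null(donor_class)) donor_class <- classes[1]
  out <- ifelse(phenotype[samples] == donor_class, "A", "B")
  names(out) <- samples
  out
}

#' Two-point linkage of a trait against every marker
#'
#' @param gm A `genotype_matrix`.
#' @param trait Named `A`/`B` vector from [phenotype_as_marker()], indexed
#'   by RIL sample names.
#' @param mapping_function For the per-marker cM distance.
#' @return data.frame: `marker, n, k, R, r, distance_cM, lod`.
#' @export
trait_linkage <- function(gm, trait,
                          mapping_function = c("kosambi", "haldane")) {
  mapping_function <- match.arg(mapping_function)
  rl <- ril_samples(gm)
  s <- geno_signed(gm)[, rl, drop = FALSE]
  tv <- rep(NA_real_, length(rl))
  tv[trait[rl] == "A"] <- -1
  tv[trait[rl] == "B"] <- 1
  inf <- !is.na(s) & matrix(rep(!is.na(tv), each = nrow(s)), nrow = nrow(s))
  n <- rowSums(inf)
  tmat <- matrix(rep(tv, each = nrow(s)), nrow = nrow(s))
  k <- rowSums(inf & s != tmat, na.rm = TRUE)
  R <- ifelse(n > 0, k / n, NA_real_)
  r <- ril_to_meiotic(pmin(R, 0.5))
  lod <- as.vector(lod_from_kn(matrix(k, ncol = 1), matrix(n, ncol = 1)))
  data.frame(marker = rownames(gm), n = n, k = k, R = pmin(R, 0.5), r = r,
             distance_cM = map_distance(r, mapping_function), lod = lod,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Place a binary trait on a linkage map
#'
#' The trait is assigned to the group of the marker with the highest LOD
#' against it, positioned at the locus of its nearest marker (by
#' recombination distance). If no marker reaches `lod_floor` the trait is
#' reported unplaced.
#'
#' @param gm A `genotype_matrix`.
#' @param trait Named `A`/`B` vector (see [phenotype_as_marker()]).
#' @param map A `ril_map`.
#' @param lod_floor Minimum LOD to call the trait linked (default 3).
#' @return List: `placed` (logical), `group`, `position`, `nearest_marker`,
#'   `linkage` (the full [trait_linkage()] table with map coordinates
#'   merged).
#' @export
map_trait <- function(gm, trait, map, lod_floor = 3) {
  tl <- trait_linkage(gm, trait, map$mapping_function)
  mt <- map_table(map)
  tl <- merge(tl, mt, by = "marker", sort = FALSE)
  names(tl)[names(tl) == "position"] <- "cM"
  if (!nrow(tl) || all(is.na(tl$lod)) || max(tl$lod, na.rm = TRUE) < lod_floor)
    return(list(placed = FALSE, group = NA_character_, position = NA_real_,
                nearest_marker = NA_character_, linkage = tl))
  best <- tl[which.max(tl$lod), ]
  list(placed = TRUE, group = best$group,
       position = best$cM, nearest_marker = best$marker, linkage = tl)
}

#' Markers linked to a trait within a cM window
#'
#' @param linkage A [trait_linkage()] table (or the `linkage` element of
#'   [map_trait()]).
#' @param window Maximum recombination distance in cM (default 5).
#' @return The linked subset, sorted by distance then marker id.
#' @export
linked_markers <- function(linkage, window = 5) {
  sel <- !is.na(linkage$distance_cM) & linkage$distance_cM <= window
  out <- linkage[sel, , drop = FALSE]
  out <- out[order(out$distance_cM, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Markers co-segregating with a trait
#'
#' Markers with zero observed recombinants against the phenotype over the
#' informative RILs (reported as 0 cM).
#'
#' @param gm A `genotype_matrix`.
#' @param trait Named `A`/`B` vector.
#' @param min_informative Minimum informative individuals (default 10).
#' @return Character vector of marker ids.
#' @export
cosegregating_markers <- function(gm, trait, min_informative = 10L) {
  tl <- trait_linkage(gm, trait)
  tl$marker[tl$k == 0 & tl$n >= min_informative]
}

#' Candidate scaffolds for a trait
#'
#' Distinct scaffolds carrying at least one marker co-segregating with the
#' trait, with their member markers and lengths.
#'
#' @param cosegregating Character vector of co-segregating marker ids.
#' @param anchors Anchor data.frame from [locate_tags()] (`$anchors`).
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @return data.frame: `scaffold, size_bp, markers` (comma-joined),
#'   `n_markers`, plus an empty `annotation` slot column.
#' @export
candidate_scaffolds <- function(cosegregating, anchors,
                                scaffold_lengths = NULL) {
  hit <- anchors[anchors$marker %in% cosegregating, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(scaffold = character(0), size_bp = numeric(0),
                      markers = character(0), n_markers = integer(0),
                      annotation = character(0), stringsAsFactors = FALSE))
  sp <- split(hit$marker, hit$scaffold)
  out <- data.frame(
    scaffold = names(sp),
    size_bp = if (is.null(scaffold_lengths)) NA_real_ else
      as.numeric(scaffold_lengths[names(sp)]),
    markers = vapply(sp, paste, "", collapse = ","),
    n_markers = lengths(sp), annotation = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_markers, out$scaffold), , drop = FALSE]
}

#' Full trait scan: placement, linked set, co-segregating set, candidates
#'
#' @param gm A `genotype_matrix`.
#' @param phenotype Named phenotype class vector (two classes).
#' @param map A `ril_map`.
#' @param anchors Anchor data.frame from [locate_tags()] (`$anchors`);
#'   optional.
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @param window Linked-marker window in cM (default 5).
#' @param donor_class Phenotype class of founder A (see
#'   [phenotype_as_marker()]).
#' @param trait_name Label used in printing.
#' @return Object of class `trait_scan`: list with `trait`, `placement`,
#'   `linked`, `cosegregating`, `candidates`.
#' @export
trait_scan <- function(gm, phenotype, map, anchors = NULL,
                       scaffold_lengths = NULL, window = 5,
                       donor_class = NULL, trait_name = "trait") {
  trait <- phenotype_as_marker(phenotype, donor_class)
  placement <- map_trait(gm, trait, map)
  linked <- linked_markers(placement$linkage, window)
  coseg <- cosegregating_markers(gm, trait)
  cands <- if (!is.null(anchors))
    candidate_scaffolds(coseg, anchors, scaffold_lengths) else NULL
  structure(list(trait = trait_name, placement = placement, linked = linked,
                 cosegregating = coseg, candidates = cands, window = window),
            class = "trait_scan")
}

#' @export
print.trait_scan <- function(x, ...) {
  cat(sprintf("Trait scan: %s\n", x$trait))
  if (x$placement$placed)
    cat(sprintf("  placed on %s at %.1f cM (nearest marker %s)\n",
                x$placement$group, x$placement$position,
                x$placement$nearest_marker))
  else cat("  unplaced (no marker linked above the LOD floor)\n")
  cat(sprintf("  %d markers within %.1f cM; %d co-segregating (0 cM)\n",
              nrow(x$linked), x$window, length(x$cosegregating)))
  if (!is.null(x$candidates))
    cat(sprintf("  %d candidate scaffold(s)\n", nrow(x$candidates)))
  invisible(x)
}

#' Validate a marker on an external genotype-phenotype panel
#'
#' Cross-tabulates marker genotype classes against the known binary
#' phenotype and reports the overall consistent fraction. Samples with a
#' missing genotype are excluded and counted.
#'
#' @param panel data.frame with columns `sample, genotype, phenotype`
#'   (genotype NA = missing).
#' @param genotype_for Named character vector mapping each genotype class to
#'   the phenotype class it predicts (e.g. `c("A:A" = "R", "G:G" = "S")`).
#' @return List: `n_scored`, `n_excluded`, `n_consistent`,
#'   `consistent_fraction`, `table` (per-sample concordance).
#' @export
validate_panel <- function(panel, genotype_for) {
  stopifnot(all(c("sample", "genotype", "phenotype") %in% names(panel)))
  miss <- is.na(panel$genotype) | panel$genotype == ""
  sc <- panel[!miss, , drop = FALSE]
  if (!nrow(sc)) stop("panel has no scored samples")
  pred <- unname(genotype_for[sc$genotype])
  sc$predicted <- pred
  sc$consistent <- !is.na(pred) & pred == sc$phenotype
  list(n_scored = nrow(sc), n_excluded = sum(miss),
       n_consistent = sum(sc$consistent),
       consistent_fraction = mean(sc$consistent),
       table = sc)
}
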