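## Two-point linkage machinery for selfing-RIL populations.
##
## Observed RIL recombinant fraction R accumulates recombination over the
## repeated selfing generations; at the RIL-infinity limit for selfers,
## R = 2r / (1 + 2r) (Haldane-Waddington), inverted as r = R / (2 (1 - R)).
## H (heterozygous) codes are treated as missing: the F8 analysis is
## two-class and the recombinant status of a residual heterozygote is
## ambiguous.

#' Haldane-Waddington correction for selfing RILs
#'
#' Converts between the meiotic recombination fraction `r` and the observed
#' RIL recombinant fraction `R = 2r / (1 + 2r)`.
#'
#' @param R Observed RIL recombinant fraction(s) in `[0, 0.5]`.
#' @param r Meiotic recombination fraction(s) in `[0, 0.5]`.
#' @return The corrected fraction(s).
#' @examples
#' ril_to_meiotic(2 * 0.1 / (1 + 2 * 0.1))  # 0.1
#' @export
ril_to_meiotic <- function(R) {
  R <- pmin(pmax(R, 0), 0.5)
  pmin(R / (2 * (1 - R)), 0.5)
}

#' @rdname ril_to_meiotic
#' @export
meiotic_to_ril <- function(r) {
  r <- pmin(pmax(r, 0), 0.5)
  2 * r / (1 + 2 * r)
}

#' Map distance from recombination fraction
#'
#' Haldane: `d = -50 ln(1 - 2r)`; Kosambi: `d = 25 ln((1 + 2r) / (1 - 2r))`.
#'
#' @param r Meiotic recombination fraction(s).
#' @param method `"kosambi"` (default) or `"haldane"`.
#' @return Distance(s) in cM (`Inf` at r = 0.5).
#' @examples
#' map_distance(0.1, "haldane")  # 11.157
#' map_distance(0.1, "kosambi")  # 10.137
#' @export
map_distance <- function(r, method = c("kosambi", "haldane")) {
  method <- match.arg(method)
  r <- pmin(pmax(r, 0), 0.5)
  if (method == "haldane") -50 * log(1 - 2 * r)
  else 25 * log((1 + 2 * r) / (1 - 2 * r))
}

## numeric recoding: A = -1, B = +1, H / missing = NA
geno_signed <- function(gm) {
  x <- unclass(gm)
  s <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  s[x == "A"] <- -1
  s[x == "B"] <- 1
  s
}

lod_from_kn <- function(k, n) {
  lod <- matrix(0, nrow(k), ncol(k), dimnames = dimnames(k))
  Rh <- ifelse(n > 0, k / n, NA_real_)
  Rc <- pmin(Rh, 0.5)
  pos <- !is.na(Rh) & k > 0 & Rc < 0.5
  lod[pos] <- k[pos] * log10(Rc[pos] / 0.5) +
    (n[pos] - k[pos]) * log10((1 - Rc[pos]) / 0.5)
  zero <- !is.na(Rh) & k == 0 & n > 0
  lod[zero] <- n[zero] * log10(2)  # k = 0 limit of the likelihood ratio
  lod[is.na(Rh)] <- NA_real_
  lod
}

#' All pairwise two-point estimates for a genotype matrix
#'
#' For every marker pair, counts informative RILs (both calls in `A`/`B`),
#' recombinants `k` (discordant codes), the observed fraction `R = k/n`
#' (clamped to 0.5), the Haldane-Waddington corrected meiotic fraction `r`,
#' and the two-point LOD score
#' `k log10(R/0.5) + (n - k) log10((1 - R)/0.5)` (its `k = 0` limit is
#' `n log10 2`). Pairs with fewer than `min_informative` RILs are marked
#' uninformative (`lod = NA`) and excluded from grouping.
#'
#' @param gm A `genotype_matrix` (RIL columns are used; parents excluded).
#' @param min_informative Minimum informative individuals per pair
#'   (default 10).
#' @return List of marker x marker matrices: `n`, `k`, `R`, `r`, `lod`.
#' @export
pairwise_linkage <- function(gm, min_informative = 10L) {
  s <- geno_signed(gm)[, ril_samples(gm), drop = FALSE]
  inf <- !is.na(s)
  s0 <- s
  s0[!inf] <- 0
  n <- tcrossprod(inf * 1)           # informative counts
  agree <- tcrossprod(s0)            # agreements - disagreements
  k <- (n - agree) / 2
  R <- ifelse(n > 0, k / n, NA_real_)
  lod <- lod_from_kn(k, n)
  lod[n < min_informative] <- NA_real_
  r <- ril_to_meiotic(pmin(R, 0.5))
  r[is.na(R)] <- NA_real_
  list(n = n, k = k, R = pmin(R, 0.5), r = r, lod = lod)
}

#' Two-point estimate for one marker pair
#'
#' @param gm A `genotype_matrix`.
#' @param i,j Marker names or indices.
#' @param min_informative Minimum informative individuals (default 10).
#' @return data.frame row: `n, k, R, r, lod` (lod `NA` when uninformative).
#' @export
two_point <- function(gm, i, j, min_informative = 10L) {
  s <- geno_signed(gm)[, ril_samples(gm), drop = FALSE]
  a <- s[i, ]; b <- s[j, ]
  use <- !is.na(a) & !is.na(b)
  n <- sum(use)
  k <- sum(a[use] != b[use])
  R <- if (n > 0) k / n else NA_real_
  lod <- if (n > 0) lod_from_kn(matrix(k), matrix(n))[1, 1] else NA_real_
  if (n < min_informative) lod <- NA_real_
  data.frame(n = n, k = k, R = min(R, 0.5), r = ril_to_meiotic(R), lod = lod)
}

## ---- grouping --------------------------------------------------------------

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Group markers into linkage groups by LOD threshold with stepwise relaxation
#'
#' Markers are first joined by single linkage at `lod > lod_start`. While the
#' group count exceeds `target_groups`, the threshold is lowered in steps of
#' 0.5 down to `lod_floor`, and at each step only merges that attach a small
#' group (fewer than `small_frac` of all markers) to another group are
#' allowed — large established groups are never fused during relaxation.
#'
#' @param est Pairwise estimates from [pairwise_linkage()] (uses `$lod`).
#' @param lod_start Initial stringent threshold (default 6).
#' @param target_groups Stop once the group count reaches this (default 20,
#'   the haploid chromosome number of narrow-leafed lupin).
#' @param lod_floor Lowest threshold tried (default 3).
#' @param small_frac Small-group definition as a fraction of all markers
#'   (default 0.05).
#' @return List: `groups` (integer vector, names = markers), `n_groups`,
#'   `trace` (data.frame threshold / group count), `reached_target`,
#'   `singletons` (marker names left unlinked).
#' @export
build_groups <- function(est, lod_start = 6, target_groups = 20L,
                         lod_floor = 3, small_frac = 0.05) {
  lod <- est$lod
  n <- nrow(lod)
  markers <- rownames(lod)
  link <- !is.na(lod) & lod > lod_start
  diag(link) <- FALSE
  comp <- components_from_adjacency(link)
  trace <- data.frame(lod = lod_start, n_groups = length(unique(comp)))
  thr <- lod_start
  small_n <- max(1L, ceiling(small_frac * n) - 1L)
  while (length(unique(comp)) > target_groups && thr - 0.5 >= lod_floor) {
    thr <- thr - 0.5
    repeat {
      sizes <- table(comp)
      merged <- FALSE
      cand <- which(!is.na(lod) & lod > thr, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      for (rix in seq_len(nrow(cand))) {
        ci <- comp[cand[rix, 1]]
        cj <- comp[cand[rix, 2]]
        if (ci == cj) next
        if (sizes[as.character(ci)] <= small_n ||
            sizes[as.character(cj)] <= small_n) {
          comp[comp == cj] <- ci
          merged <- TRUE
          break
        }
      }
      if (!merged) break
      if (length(unique(comp)) <= target_groups) break
    }
    trace <- rbind(trace,
                   data.frame(lod = thr, n_groups = length(unique(comp))))
  }
  comp <- as.integer(factor(comp))
  names(comp) <- markers
  sizes <- table(comp)
  list(groups = comp, n_groups = length(sizes), trace = trace,
       reached_target = length(sizes) <= target_groups,
       singletons = markers[comp %in% as.integer(names(sizes)[sizes == 1L])])
}

## ---- RECORD-style ordering -------------------------------------------------

order_count <- function(ord, kmat) {
  if (length(ord) < 2L) return(0)
  sum(kmat[cbind(ord[-length(ord)], ord[-1L])])
}

greedy_insertion <- function(ord_in, kmat) {
  ord <- ord_in[1L]
  for (m in ord_in[-1L]) {
    L <- length(ord)
    # cost of inserting m into each of the L+1 gaps
    cost <- numeric(L + 1L)
    cost[1L] <- kmat[m, ord[1L]]
    cost[L + 1L] <- kmat[ord[L], m]
    if (L > 1L) {
      prev <- ord[-L]; nxt <- ord[-1L]
      cost[2:L] <- kmat[cbind(prev, m)] + kmat[cbind(m, nxt)] -
        kmat[cbind(prev, nxt)]
    }
    p <- which.min(cost)
    ord <- append(ord, m, after = p - 1L)
  }
  ord
}

## 2-opt segment reversals and single-marker relocations; with a symmetric
## count matrix only the segment-boundary edges change, so deltas are O(1)
local_search <- function(ord, kmat, max_pass = 200L) {
  n <- length(ord)
  if (n < 3L) return(ord)
  edge <- function(a, b) if (a == 0L || b > n) 0 else kmat[ord[a], ord[b]]
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    ## segment reversal
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        delta <- (if (i > 1L) kmat[ord[i - 1L], ord[j]] else 0) +
          (if (j < n) kmat[ord[i], ord[j + 1L]] else 0) -
          (if (i > 1L) kmat[ord[i - 1L], ord[i]] else 0) -
          (if (j < n) kmat[ord[j], ord[j + 1L]] else 0)
        if (delta < -1e-9) {
          ord[i:j] <- ord[j:i]
          improved <- TRUE
        }
      }
    }
    ## single-marker relocation (remove marker i, reinsert at best gap)
    for (i in seq_len(n)) {
      m <- ord[i]
      removal <- -edge(i - 1L, i) - edge(i, i + 1L) +
        (if (i > 1L && i < n) kmat[ord[i - 1L], ord[i + 1L]] else 0)
      base <- ord[-i]
      nb <- n - 1L
      add <- numeric(nb + 1L)
      add[1L] <- kmat[m, base[1L]]
      add[nb + 1L] <- kmat[base[nb], m]
      if (nb > 1L) {
        prev <- base[-nb]; nxt <- base[-1L]
        add[2:nb] <- kmat[cbind(prev, m)] + kmat[cbind(m, nxt)] -
          kmat[cbind(prev, nxt)]
      }
      p <- which.min(add)
      if (removal + add[p] < -1e-9) {
        ord <- append(base, m, after = p - 1L)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ord
}

window_ripple <- function(ord, kmat, windows = c(2L, 3L), max_pass = 50L) {
  perms2 <- matrix(c(1, 2, 2, 1), ncol = 2, byrow = TRUE)
  perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
  best <- order_count(ord, kmat)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (w in windows) {
      perms <- if (w == 2L) perms2 else perms3
      for (s in seq_len(length(ord) - w + 1L)) {
        window <- ord[s:(s + w - 1L)]
        for (p in seq_len(nrow(perms))[-1L]) {
          cand <- ord
          cand[s:(s + w - 1L)] <- window[perms[p, ]]
          cc <- order_count(cand, kmat)
          if (cc < best - 1e-9) {
            ord <- cand; best <- cc; improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  list(order = ord, count = best)
}

#' Order markers within a linkage group by recombination-count minimisation
#'
#' Minimises COUNT, the sum of observed recombination events between adjacent
#' markers along the order (pairs with no informative individuals contribute
#' zero). The search is randomised greedy insertion followed by a window
#' ripple of sizes 2 and 3, a 2-opt/relocation polish, and a final ripple,
#' repeated over `n_starts` seeded restarts; the best order found is
#' returned. The orientation is
#' normalised so that the lexicographically smaller terminal marker id comes
#' first (an order and its reversal have equal COUNT).
#'
#' @param est Pairwise estimates from [pairwise_linkage()] (uses `$k`).
#' @param markers Character vector of marker ids in the group.
#' @param n_starts Number of randomised restarts (default 10).
#' @param seed Optional seed for the restarts.
#' @return List: `order` (character vector), `count` (its COUNT).
#' @export
order_group <- function(est, markers, n_starts = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(markers) < 2L)
    return(list(order = markers, count = 0))
  kmat <- est$k[markers, markers, drop = FALSE]
  kmat[is.na(kmat)] <- 0  # uninformative pairs impute as non-recombinant
  idx <- seq_along(markers)
  ## small groups are cheap to search, so give them extra restarts
  ns <- if (length(idx) <= 10L) max(n_starts, 25L) else n_starts
  best <- NULL
  for (s in seq_len(ns)) {
    start <- if (s == 1L) idx else sample(idx)
    ord <- if (s %% 3L == 0L) start else greedy_insertion(start, kmat)
    rp <- window_ripple(ord, kmat)
    ord2 <- local_search(rp$order, kmat)
    rp2 <- window_ripple(ord2, kmat)
    if (is.null(best) || rp2$count < best$count - 1e-9) best <- rp2
  }
  ord <- markers[best$order]
  if (ord[1L] > ord[length(ord)]) ord <- rev(ord)
  list(order = ord, count = best$count)
}

#' Collapse consecutive co-segregating markers into loci
#'
#' Adjacent markers in the given order with zero observed recombinants over
#' informative individuals are merged into a single locus; the locus id is
#' its first member marker.
#'
#' @param ordered_markers Character vector (output of [order_group()]).
#' @param est Pairwise estimates from [pairwise_linkage()].
#' @return List of character vectors, one per locus in map order.
#' @export
collapse_loci <- function(ordered_markers, est) {
  if (!length(ordered_markers)) return(list())
  loci <- list(ordered_markers[1L])
  if (length(ordered_markers) > 1L) {
    for (i in 2:length(ordered_markers)) {
      prev <- ordered_markers[i - 1L]
      cur <- ordered_markers[i]
      merge <- est$n[prev, cur] > 0 && est$k[prev, cur] == 0
      if (merge) loci[[length(loci)]] <- c(loci[[length(loci)]], cur)
      else loci[[length(loci) + 1L]] <- cur
    }
  }
  names(loci) <- vapply(loci, `[`, "", 1L)
  loci
}

#' Assign cM positions to ordered loci
#'
#' Positions are the cumulative sum of the mapping-function distances between
#' adjacent loci, computed from the Haldane-Waddington corrected `r` of their
#' first member markers; the first locus sits at 0 cM. An adjacent pair at
#' r = 0.5 yields an infinite distance and is capped at `d_max` and
#' flagged.
#'
#' @param loci List of loci from [collapse_loci()].
#' @param est Pairwise estimates from [pairwise_linkage()].
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param d_max Cap for undefined/huge adjacent distances in cM (default 50).
#' @return data.frame: `locus, position, n_markers, capped`.
#' @export
position_loci <- function(loci, est,
                          mapping_function = c("kosambi", "haldane"),
                          d_max = 50) {
  mapping_function <- match.arg(mapping_function)
  nl <- length(loci)
  pos <- numeric(nl)
  capped <- logical(nl)
  if (nl > 1L) {
    for (i in 2:nl) {
      ra <- est$r[names(loci)[i - 1L], names(loci)[i]]
      d <- if (is.na(ra)) d_max else map_distance(ra, mapping_function)
      if (!is.finite(d) || d > d_max) { d <- d_max; capped[i] <- TRUE }
      pos[i] <- pos[i - 1L] + d
    }
  }
  data.frame(locus = names(loci), position = pos,
             n_markers = lengths(loci), capped = capped,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Find marker gaps in a positioned map
#'
#' @param map A `ril_map`.
#' @param threshold Minimum adjacent-locus interval in cM to report
#'   (default 20).
#' @return data.frame: `group, locus_left, locus_right, gap_cM`.
#' @export
find_gaps <- function(map, threshold = 20) {
  out <- list()
  for (g in names(map$groups)) {
    p <- map$groups[[g]]$positions
    if (nrow(p) < 2L) next
    d <- diff(p$position)
    hit <- which(d > threshold)
    if (length(hit))
      out[[g]] <- data.frame(group = g, locus_left = p$locus[hit],
                             locus_right = p$locus[hit + 1L], gap_cM = d[hit],
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group = character(0), locus_left = character(0),
                      locus_right = character(0), gap_cM = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- the map itself --------------------------------------------------------

#' Build a sequence-defined genetic linkage map from a genotype matrix
#'
#' The central estimator of the package: computes all pairwise two-point
#' estimates (with the Haldane-Waddington selfing-RIL correction), partitions
#' markers into linkage groups by stringent LOD-threshold single linkage with
#' stepwise relaxation towards the expected chromosome number, orders each
#' group by recombination-count (RECORD-style) minimisation, collapses
#' zero-recombinant runs into loci, and positions loci in cM with the chosen
#' mapping function. Groups are named `SLG-1`, `SLG-2`, ... in decreasing
#' order of genetic length.
#'
#' @param gm A `genotype_matrix` (parents + RILs).
#' @param lod_start,target_groups,lod_floor,small_frac See [build_groups()].
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param n_starts Ordering restarts per group (default 10).
#' @param min_informative Minimum informative individuals per pair.
#' @param d_max Adjacent-distance cap in cM (default 50).
#' @param seed Seed for the ordering restarts (default 1; the estimator is
#'   deterministic given the seed).
#' @return Object of class `ril_map`: list with `groups` (per group: `order`,
#'   `loci`, `positions`, `count`, `length_cM`), `membership` (marker ->
#'   group name), `est` (pairwise matrices), `grouping` (threshold trace),
#'   `mapping_function`, `call`.
#' @seealso [summary.ril_map()], [find_gaps()], [locate_tags()],
#'   [trait_scan()]
#' @export
ril_map <- function(gm, lod_start = 6, target_groups = 20L, lod_floor = 3,
                    small_frac = 0.05,
                    mapping_function = c("kosambi", "haldane"),
                    n_starts = 10L, min_informative = 10L, d_max = 50,
                    seed = 1L) {
  mapping_function <- match.arg(mapping_function)
  est <- pairwise_linkage(gm, min_informative)
  grouping <- build_groups(est, lod_start, target_groups, lod_floor,
                           small_frac)
  set.seed(seed)
  ids <- sort(unique(grouping$groups))
  built <- lapply(ids, function(gid) {
    mk <- names(grouping$groups)[grouping$groups == gid]
    og <- order_group(est, mk, n_starts = n_starts)
    loci <- collapse_loci(og$order, est)
    pos <- position_loci(loci, est, mapping_function, d_max)
    list(order = og$order, count = og$count, loci = loci, positions = pos,
         length_cM = max(pos$position))
  })
  lens <- vapply(built, `[[`, 0, "length_cM")
  o <- order(lens, decreasing = TRUE)
  built <- built[o]
  names(built) <- sprintf("SLG-%d", seq_along(built))
  membership <- character(0)
  for (g in names(built)) {
    mk <- built[[g]]$order
    membership[mk] <- g
  }
  structure(list(groups = built, membership = membership, est = est,
                 grouping = grouping, mapping_function = mapping_function,
                 n_rils = length(ril_samples(gm)),
                 call = match.call()),
            class = "ril_map")
}

#' @export
print.ril_map <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "Sequence-defined linkage map: %d markers on %d loci in %d groups\n",
    s$totals$markers, s$totals$loci, nrow(s$per_group)))
  cat(sprintf("  total length %.1f cM (%s), %.1f markers/cM, %.1f markers/locus\n",
              s$totals$length_cM, x$mapping_function, s$density,
              s$markers_per_locus))
  invisible(x)
}

#' Per-group marker-level table of a linkage map
#'
#' @param map A `ril_map`.
#' @return data.frame: `group, locus, position, marker`.
#' @export
map_table <- function(map) {
  out <- list()
  for (g in names(map$groups)) {
    gr <- map$groups[[g]]
    for (i in seq_along(gr$loci)) {
      out[[length(out) + 1L]] <- data.frame(
        group = g, locus = names(gr$loci)[i],
        position = gr$positions$position[i], marker = gr$loci[[i]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise a linkage map (per-group counts, lengths, density)
#'
#' @param object A `ril_map`.
#' @param anchors Optional anchor table from [locate_tags()] together with
#'   scaffold lengths, as returned by [integrate_anchors()]; adds per-group
#'   anchored-scaffold counts and length spans.
#' @param ... Unused.
#' @return Object of class `ril_map_summary` (see [map_summary()]).
#' @export
summary.ril_map <- function(object, anchors = NULL, ...) {
  per_group <- data.frame(
    group = names(object$groups),
    markers = vapply(object$groups, function(g) length(g$order), 0L),
    loci = vapply(object$groups, function(g) length(g$loci), 0L),
    length_cM = vapply(object$groups, `[[`, 0, "length_cM"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(anchors)) {
    per_group$scaffolds <-
      anchors$per_group$scaffolds[match(per_group$group,
                                        anchors$per_group$group)]
    per_group$span_bp <-
      anchors$per_group$span_bp[match(per_group$group,
                                      anchors$per_group$group)]
    per_group$scaffolds[is.na(per_group$scaffolds)] <- 0L
    per_group$span_bp[is.na(per_group$span_bp)] <- 0
  }
  map_summary(per_group)
}

#' Summary arithmetic over a per-group map table
#'
#' Computes the totals row and derived statistics (marker density per cM,
#' markers per locus) from a per-linkage-group summary table. Used both for
#' maps built by [ril_map()] and for externally supplied per-group tables.
#'
#' @param per_group data.frame with columns `group, markers, loci, length_cM`
#'   and optionally `scaffolds, span_bp`.
#' @return Object of class `ril_map_summary`: list with `per_group`, `totals`
#'   (named list of column sums), `density` (markers per cM) and
#'   `markers_per_locus`.
#' @export
map_summary <- function(per_group) {
  stopifnot(all(c("group", "markers", "loci", "length_cM") %in%
                  names(per_group)))
  totals <- list(markers = sum(per_group$markers),
                 loci = sum(per_group$loci),
                 length_cM = sum(per_group$length_cM))
  if ("scaffolds" %in% names(per_group))
    totals$scaffolds <- sum(per_group$scaffolds)
  if ("span_bp" %in% names(per_group))
    totals$span_bp <- sum(per_group$span_bp)
  structure(list(per_group = per_group, totals = totals,
                 density = if (totals$length_cM > 0)
                   totals$markers / totals$length_cM else 0,
                 markers_per_locus = if (totals$loci > 0)
                   totals$markers / totals$loci else 0),
            class = "ril_map_summary")
}

#' @export
print.ril_map_summary <- function(x, ...) {
  df <- x$per_group
  print(df, row.names = FALSE)
  cat(sprintf("Totals: %d markers, %d loci, %.1f cM",
              x$totals$markers, x$totals$loci, x$totals$length_cM))
  if (!is.null(x$totals$scaffolds))
    cat(sprintf(", %d scaffolds, %.0f bp span",
                x$totals$scaffolds, x$totals$span_bp))
  cat(sprintf("\nDensity %.1f markers/cM; %.1f markers/locus\n",
              x$density, x$markers_per_locus))
  invisible(x)
}

#' Plot a linkage map
#'
#' Draws each linkage group as a vertical bar with locus positions as ticks.
#'
#' @param x A `ril_map`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ril_map <- function(x, ...) {
  ng <- length(x$groups)
  maxlen <- max(vapply(x$groups, `[[`, 0, "length_cM"))
  graphics::plot(NA, xlim = c(0.5, ng + 0.5), ylim = c(maxlen * 1.05, 0),
                 xlab = "", ylab = "position (cM)", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(ng), labels = names(x$groups), las = 2,
                 cex.axis = 0.7)
  for (i in seq_len(ng)) {
    g <- x$groups[[i]]
    graphics::segments(i, 0, i, g$length_cM, lwd = 3, col = "grey60")
    graphics::segments(i - 0.18, g$positions$position, i + 0.18,
                       g$positions$position, lwd = 0.8)
  }
  invisible(x)
}
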