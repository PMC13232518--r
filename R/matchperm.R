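# Matched-background permutation frameworks:
#  (1) chromosome-stratified variant-in-CRE enrichment, matching sampled
#      background peaks on length and distance-to-TSS bins with hierarchical
#      relaxation to adjacent bins;
#  (2) eQTL variant-gene concordance, additionally matching on CRE class and
#      number of predicted target genes, with each sampled peak keeping its
#      own predicted target set.

#' Count unique variants overlapping at least one CRE
#'
#' Variants are deduplicated by (chrom, pos0, id); a variant inside several
#' CREs counts once.
#'
#' @param variants data.frame `chrom`, `pos0` (0-based), `id`.
#' @param cres data.frame with `chrom`, `start`, `end`.
#' @return integer count.
#' @export
observed_variant_overlap <- function(variants, cres) {
  if (nrow(variants) == 0 || nrow(cres) == 0) return(0L)
  v <- variants[!duplicated(variants[, c("chrom", "pos0", "id")]), , drop = FALSE]
  sum(points_in_intervals(v$chrom, v$pos0, cres))
}

#' Build a matched-sampling index over the candidate peak universe
#'
#' Assigns every candidate peak to a (chromosome, length-bin,
#' distance-to-TSS-bin) cell; distance is measured from the peak midpoint to
#' the nearest annotated TSS. Default bin edges are deciles of the candidate
#' length and distance distributions. Bins are half-open on the left edge
#' (a value equal to an interior edge falls in the right-hand bin); values
#' outside the outermost edges are assigned to the boundary bins.
#'
#' For eQTL-mode matching, per-peak `class` and `n_targets` (number of
#' predicted target genes) are attached when supplied.
#'
#' @param peaks candidate peak data.frame (`peak_id` or `cre_id`, `chrom`,
#'   `start`, `end`).
#' @param genes gene annotation (for nearest-TSS distances).
#' @param len_edges,dist_edges optional explicit strictly-increasing bin
#'   edges; defaults to deciles.
#' @param n_bins number of default quantile bins per axis.
#' @param cre_class optional named vector `id -> class`.
#' @param n_targets optional named vector `id -> predicted target count`.
#' @return object of class `eg_match_index`: peak table with `len_bin`,
#'   `dist_bin` (+ `class`, `n_targets`), plus the edges used.
#' @export
build_match_index <- function(peaks, genes, len_edges = NULL, dist_edges = NULL,
                              n_bins = 10L, cre_class = NULL, n_targets = NULL) {
  stopifnot(nrow(peaks) >= 1)
  id_col <- if ("cre_id" %in% names(peaks)) "cre_id" else "peak_id"
  len <- peaks$end - peaks$start
  mid <- interval_midpoint(peaks$start, peaks$end)
  dist <- nearest_tss_distance(peaks$chrom, mid, genes)
  if (is.null(len_edges)) {
    len_edges <- unique(quantile(len, probs = seq(0, 1, length.out = n_bins + 1)))
  }
  if (is.null(dist_edges)) {
    dist_edges <- unique(quantile(dist, probs = seq(0, 1, length.out = n_bins + 1)))
  }
  if (any(diff(len_edges) <= 0) || any(diff(dist_edges) <= 0)) {
    stop("bin edges must be strictly increasing")
  }
  tab <- data.frame(
    id = peaks[[id_col]], chrom = peaks$chrom,
    start = peaks$start, end = peaks$end,
    length = len, dist = dist,
    len_bin = .bin_assign(len, len_edges),
    dist_bin = .bin_assign(dist, dist_edges),
    stringsAsFactors = FALSE
  )
  if (!is.null(cre_class)) tab$class <- unname(cre_class[tab$id])
  if (!is.null(n_targets)) {
    nt <- unname(n_targets[tab$id])
    nt[is.na(nt)] <- 0L
    tab$n_targets <- nt
  }
  structure(list(peaks = tab, len_edges = len_edges, dist_edges = dist_edges),
            class = "eg_match_index")
}

# half-open bin assignment; out-of-range values go to the boundary bins
.bin_assign <- function(x, edges) {
  b <- findInterval(x, edges)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

#' Matched sampling pools with hierarchical relaxation
#'
#' For each query CRE, the pool of candidate peaks it may be replaced by:
#' peaks on the same chromosome in the same (length, distance) bin; when the
#' exact cell is empty, the search expands to cells at increasing Chebyshev
#' distance in (len_bin, dist_bin) space until a non-empty set is found. In
#' eQTL mode (`use_class = TRUE`) candidates must share the query's class,
#' and the predicted-target count is matched exactly first, then relaxed to
#' +/-1, +/-2, ... jointly with the bin relaxation (level L allows Chebyshev
#' bin distance <= L and count difference <= L); the class constraint is
#' dropped only as a last resort (counted as a relaxation event).
#'
#' @param index an `eg_match_index` over the candidate universe.
#' @param queries data.frame of query CREs (`chrom`, `start`, `end`; for
#'   class/target matching also matching `class` / `n_targets` columns or
#'   ids resolvable in the index).
#' @param genes gene annotation (query distances recomputed with the index's
#'   edges).
#' @param use_class,use_targets enable the eQTL-mode matching keys.
#' @return list `pools` (list of integer index vectors into `index$peaks`),
#'   `relaxation` (integer per query).
#' @export
matched_pools <- function(index, queries, genes, use_class = FALSE,
                          use_targets = FALSE) {
  tab <- index$peaks
  absent <- setdiff(unique(queries$chrom), unique(tab$chrom))
  if (length(absent)) {
    stop("no candidate peak on chromosome ", paste(absent, collapse = ", "))
  }
  qlen <- queries$end - queries$start
  qmid <- interval_midpoint(queries$start, queries$end)
  qdist <- nearest_tss_distance(queries$chrom, qmid, genes)
  qlb <- .bin_assign(qlen, index$len_edges)
  qdb <- .bin_assign(qdist, index$dist_edges)
  qcls <- if (use_class) queries$class else NULL
  qnt <- if (use_targets) queries$n_targets else NULL
  max_lev <- max(length(index$len_edges), length(index$dist_edges),
                 if (use_targets) max(tab$n_targets) + 1L else 0L)
  pools <- vector("list", nrow(queries))
  relax <- integer(nrow(queries))
  chrom_idx <- split(seq_len(nrow(tab)), tab$chrom)
  for (i in seq_len(nrow(queries))) {
    cand0 <- chrom_idx[[queries$chrom[i]]]
    if (is.null(cand0) || length(cand0) == 0) {
      stop("no candidate peak on chromosome ", queries$chrom[i])
    }
    cand <- cand0
    dropped_class <- FALSE
    if (use_class) {
      same_cls <- cand[tab$class[cand] == qcls[i]]
      if (length(same_cls) == 0) dropped_class <- TRUE else cand <- same_cls
    }
    found <- integer()
    lev_used <- NA_integer_
    for (lev in 0:max_lev) {
      ok <- abs(tab$len_bin[cand] - qlb[i]) <= lev &
        abs(tab$dist_bin[cand] - qdb[i]) <= lev
      if (use_targets) ok <- ok & abs(tab$n_targets[cand] - qnt[i]) <= lev
      if (any(ok)) { found <- cand[ok]; lev_used <- lev; break }
    }
    if (length(found) == 0) { found <- cand; lev_used <- max_lev }
    pools[[i]] <- found
    relax[i] <- lev_used + if (dropped_class) 1L else 0L
  }
  list(pools = pools, relaxation = relax)
}

#' Sample one matched background peak for a query CRE
#'
#' Uniform draw from the query's matched pool (exact cell, or the first
#' non-empty relaxation level); see [matched_pools()].
#'
#' @param index an `eg_match_index`.
#' @param query single-row data.frame describing the query CRE.
#' @param genes gene annotation.
#' @param use_class,use_targets matching mode flags.
#' @return list `peak` (single-row data.frame from the index), `relaxation`.
#' @export
sample_matched <- function(index, query, genes, use_class = FALSE,
                           use_targets = FALSE) {
  mp <- matched_pools(index, query, genes, use_class, use_targets)
  pool <- mp$pools[[1]]
  pick <- pool[sample.int(length(pool), 1L)]
  list(peak = index$peaks[pick, , drop = FALSE], relaxation = mp$relaxation[1])
}

# draw one pool member per query, vectorised over queries
.sample_pools <- function(pools) {
  k <- lengths(pools)
  flat <- unlist(pools, use.names = FALSE)
  off <- cumsum(c(0L, k[-length(k)]))
  flat[off + 1L + floor(runif(length(k)) * k) * (k > 0)]
}

#' Chromosome-stratified permutation test for variant enrichment in network CREs
#'
#' Observed statistic: unique variants overlapping at least one CRE of the
#' E-G network. Null: each network CRE is replaced (with replacement) by a
#' matched candidate peak from [matched_pools()]; the overlap count is
#' recomputed on each sampled set for `n_perm` permutations. Empirical
#' p-value uses the +1 correction in numerator and denominator; fold
#' enrichment is observed / mean(null).
#'
#' @param variants data.frame `chrom`, `pos0`, `id` (see [read_variants()]).
#' @param network_cres data.frame of network CRE regions (`chrom`, `start`,
#'   `end`).
#' @param all_peaks candidate peak universe data.frame.
#' @param genes gene annotation.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param len_edges,dist_edges,n_bins binning controls (see
#'   [build_match_index()]).
#' @return object of class `eg_permutation`: `observed`, `null_values`,
#'   `p_empirical`, `fold_enrichment`, `n_perm`, `seed`,
#'   `relaxation_events` (queries needing relaxation level > 0).
#' @export
permutation_test_variants <- function(variants, network_cres, all_peaks, genes,
                                      n_perm = 1000L, seed = 1L,
                                      len_edges = NULL, dist_edges = NULL,
                                      n_bins = 10L) {
  stopifnot(n_perm >= 1)
  v <- variants[!duplicated(variants[, c("chrom", "pos0", "id")]), , drop = FALSE]
  observed <- observed_variant_overlap(v, network_cres)
  index <- build_match_index(all_peaks, genes, len_edges, dist_edges, n_bins)
  mp <- matched_pools(index, network_cres, genes)
  var_sets <- .peak_variant_sets(index$peaks, v)
  null_values <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      sampled <- .sample_pools(mp$pools)
      length(unique(unlist(var_sets[sampled], use.names = FALSE)))
    }, integer(1))
  })
  .perm_result(observed, null_values, n_perm, seed, sum(mp$relaxation > 0))
}

# per-peak integer sets of overlapping (deduplicated) variant row ids
.peak_variant_sets <- function(peak_tab, variants) {
  sets <- vector("list", nrow(peak_tab))
  if (nrow(variants) == 0) return(sets)
  for (ch in intersect(unique(peak_tab$chrom), unique(variants$chrom))) {
    pi <- which(peak_tab$chrom == ch)
    vi <- which(variants$chrom == ch)
    ir_p <- IRanges::IRanges(peak_tab$start[pi] + 1L, peak_tab$end[pi])
    ir_v <- IRanges::IRanges(variants$pos0[vi] + 1L, variants$pos0[vi] + 1L)
    hits <- IRanges::findOverlaps(ir_v, ir_p)
    byp <- split(vi[S4Vectors::queryHits(hits)], S4Vectors::subjectHits(hits))
    for (j in names(byp)) sets[[pi[as.integer(j)]]] <- byp[[j]]
  }
  sets
}

.perm_result <- function(observed, null_values, n_perm, seed, relaxation_events) {
  p <- (sum(null_values >= observed) + 1) / (n_perm + 1)
  fe <- if (mean(null_values) > 0) observed / mean(null_values) else NA_real_
  structure(list(observed = observed, null_values = null_values,
                 p_empirical = p, fold_enrichment = fe,
                 n_perm = n_perm, seed = seed,
                 relaxation_events = relaxation_events),
            class = "eg_permutation")
}

#' @export
print.eg_permutation <- function(x, ...) {
  cat(sprintf("observed %d vs null mean %.2f: p = %.3g, fold enrichment = %.3f (%d permutations)\n",
              x$observed, mean(x$null_values), x$p_empirical,
              x$fold_enrichment, x$n_perm))
  invisible(x)
}

#' Count eQTL variant-gene pairs concordant with a predicted E-G network
#'
#' A unique (variant, gene) pair is concordant when the variant overlaps a
#' network CRE and that CRE has a network edge to the pair's target gene.
#'
#' @param eqtls data.frame `chrom`, `pos0`, `id`, `gene_id`.
#' @param network an `eg_network` (edges must carry CRE coordinates).
#' @return integer count.
#' @export
observed_eqtl_concordance <- function(eqtls, network) {
  e <- network$edges
  if (nrow(eqtls) == 0 || nrow(e) == 0) return(0L)
  cres <- unique(e[, c("cre_id", "cre_chrom", "cre_start", "cre_end")])
  names(cres) <- c("id", "chrom", "start", "end")
  q <- eqtls[!duplicated(eqtls[, c("chrom", "pos0", "id", "gene_id")]), , drop = FALSE]
  sets <- .peak_variant_sets(cres, q)
  edge_key <- paste(e$cre_id, e$gene_id, sep = "\r")
  hit_pairs <- unlist(lapply(seq_len(nrow(cres)), function(j) {
    rows <- sets[[j]]
    if (is.null(rows)) return(integer())
    ok <- paste(cres$id[j], q$gene_id[rows], sep = "\r") %in% edge_key
    rows[ok]
  }), use.names = FALSE)
  length(unique(hit_pairs))
}

#' Matched permutation test for eQTL concordance with predicted E-G links
#'
#' Each CRE of the observed network is replaced, with replacement, by a
#' candidate peak matched on chromosome, class, length bin, distance-to-TSS
#' bin, and predicted-target count (see [matched_pools()]). Every sampled
#' peak keeps its own model-predicted target genes, reconstructed with the
#' same score threshold and the promoter-self-edge rule used for the
#' observed network; the null statistic is the concordant-pair count on that
#' reconstructed network.
#'
#' @param eqtls data.frame `chrom`, `pos0`, `id`, `gene_id`.
#' @param network the observed `eg_network`.
#' @param all_peaks candidate peak universe (data.frame with ids and
#'   coordinates).
#' @param genes gene annotation.
#' @param predicted data.frame `cre_id`, `gene_id`, `score`: model
#'   predictions over the candidate universe (used to reconstruct each
#'   sampled peak's own edges).
#' @param cre_class named vector `cre_id -> class` over the universe.
#' @param owner_gene optional named vector `cre_id -> own gene` for
#'   promoter-class peaks (defaults to ids of the form `prom_<gene>`).
#' @param n_perm,seed,len_edges,dist_edges,n_bins as in
#'   [permutation_test_variants()].
#' @return an `eg_permutation`.
#' @export
permutation_test_eqtl <- function(eqtls, network, all_peaks, genes, predicted,
                                  cre_class, owner_gene = NULL,
                                  n_perm = 1000L, seed = 1L,
                                  len_edges = NULL, dist_edges = NULL,
                                  n_bins = 10L) {
  stopifnot(n_perm >= 1)
  q <- eqtls[!duplicated(eqtls[, c("chrom", "pos0", "id", "gene_id")]), , drop = FALSE]
  observed <- observed_eqtl_concordance(q, network)
  threshold <- network$threshold
  id_col <- if ("cre_id" %in% names(all_peaks)) "cre_id" else "peak_id"
  ids <- all_peaks[[id_col]]
  if (is.null(owner_gene)) {
    owner_gene <- setNames(ifelse(startsWith(ids, "prom_"), sub("^prom_", "", ids),
                                  NA_character_), ids)
  }
  # each candidate peak's own above-threshold target set (promoters: self only)
  pred <- predicted[predicted$score > threshold, , drop = FALSE]
  is_prom <- !is.na(cre_class[pred$cre_id]) & cre_class[pred$cre_id] == "promoter"
  own <- owner_gene[pred$cre_id]
  keep <- !is_prom | (!is.na(own) & own == pred$gene_id)
  pred <- pred[keep, , drop = FALSE]
  targets_by_peak <- split(pred$gene_id, pred$cre_id)
  n_targets <- setNames(integer(length(ids)), ids)
  n_targets[names(targets_by_peak)] <- lengths(targets_by_peak)
  index <- build_match_index(all_peaks, genes, len_edges, dist_edges, n_bins,
                             cre_class = cre_class, n_targets = n_targets)
  # query CREs: unique network CREs with their class and observed target count
  e <- network$edges
  qcre <- unique(e[, c("cre_id", "cre_chrom", "cre_start", "cre_end")])
  queries <- data.frame(chrom = qcre$cre_chrom, start = qcre$cre_start,
                        end = qcre$cre_end,
                        class = unname(cre_class[qcre$cre_id]),
                        n_targets = unname(n_targets[qcre$cre_id]),
                        stringsAsFactors = FALSE)
  queries$n_targets[is.na(queries$n_targets)] <- 0L
  mp <- matched_pools(index, queries, genes, use_class = TRUE, use_targets = TRUE)
  # per-peak precomputed concordant eQTL row sets
  var_sets <- .peak_variant_sets(
    data.frame(id = index$peaks$id, chrom = index$peaks$chrom,
               start = index$peaks$start, end = index$peaks$end,
               stringsAsFactors = FALSE), q)
  conc_sets <- lapply(seq_len(nrow(index$peaks)), function(j) {
    rows <- var_sets[[j]]
    if (is.null(rows)) return(integer())
    tg <- targets_by_peak[[index$peaks$id[j]]]
    if (is.null(tg)) return(integer())
    rows[q$gene_id[rows] %in% tg]
  })
  null_values <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      sampled <- .sample_pools(mp$pools)
      length(unique(unlist(conc_sets[sampled], use.names = FALSE)))
    }, integer(1))
  })
  .perm_result(observed, null_values, n_perm, seed, sum(mp$relaxation > 0))
}
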