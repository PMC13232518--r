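# Thresholded bipartite E-G networks, Louvain community detection, and
# redundant / non-redundant substructure classification.

#' Named score-threshold presets for network construction
#'
#' Operating thresholds at the 70%-recall point of the trained classifier:
#' `standard` = 0.283 (standard Hi-C contact), `megamap` = 0.234 (megamap
#' Hi-C contact).
#' @export
eg_thresholds <- c(standard = 0.283, megamap = 0.234)

#' Build a thresholded bipartite E-G network
#'
#' Retains edges with score strictly greater than `threshold`. Promoter-class
#' CREs keep only the self edge to their own gene; edges are deduplicated by
#' (cre_id, gene_id).
#'
#' @param scored_pairs data.frame `cre_id`, `gene_id`, `score` (in `[0,1]`).
#' @param threshold edge score cutoff (or a name of [eg_thresholds]).
#' @param cres optional candidate-CRE data.frame supplying `chrom`, `start`,
#'   `end`, `owner_gene` per `cre_id`.
#' @param cre_class optional named character vector `cre_id` -> class
#'   (`promoter` / `genic_enhancer` / `intergenic_enhancer`). Promoter
#'   self-edge filtering needs `owner_gene` in `cres` or promoter ids of the
#'   form `prom_<gene_id>`.
#' @return object of class `eg_network`: list with `edges` (data.frame
#'   `cre_id`, `cre_chrom`, `cre_start`, `cre_end`, `cre_class`, `gene_id`,
#'   `score`) and `threshold`.
#' @export
build_eg_network <- function(scored_pairs, threshold = eg_thresholds["standard"],
                             cres = NULL, cre_class = NULL) {
  if (is.character(threshold)) threshold <- eg_thresholds[[threshold]]
  stopifnot(all(c("cre_id", "gene_id", "score") %in% names(scored_pairs)))
  if (nrow(scored_pairs) && (min(scored_pairs$score) < 0 || max(scored_pairs$score) > 1)) {
    stop("scores must lie in [0, 1]")
  }
  e <- scored_pairs[scored_pairs$score > threshold, , drop = FALSE]
  e <- e[!duplicated(e[, c("cre_id", "gene_id")]), , drop = FALSE]
  cls <- if (!is.null(cre_class)) unname(cre_class[e$cre_id]) else rep(NA_character_, nrow(e))
  owner <- rep(NA_character_, nrow(e))
  if (!is.null(cres) && "owner_gene" %in% names(cres)) {
    owner <- cres$owner_gene[match(e$cre_id, cres$cre_id)]
  }
  fallback <- is.na(owner) & startsWith(e$cre_id, "prom_")
  owner[fallback] <- sub("^prom_", "", e$cre_id[fallback])
  is_prom <- !is.na(cls) & cls == "promoter"
  drop <- is_prom & (!is.na(owner)) & owner != e$gene_id
  e <- e[!drop, , drop = FALSE]
  cls <- cls[!drop]
  edge <- data.frame(
    cre_id = e$cre_id,
    cre_chrom = rep(NA_character_, nrow(e)),
    cre_start = rep(NA_integer_, nrow(e)),
    cre_end = rep(NA_integer_, nrow(e)),
    cre_class = cls, gene_id = e$gene_id, score = e$score,
    stringsAsFactors = FALSE
  )
  if (!is.null(cres)) {
    idx <- match(edge$cre_id, cres$cre_id)
    edge$cre_chrom <- cres$chrom[idx]
    edge$cre_start <- cres$start[idx]
    edge$cre_end <- cres$end[idx]
  }
  rownames(edge) <- NULL
  structure(list(edges = edge, threshold = unname(threshold)), class = "eg_network")
}

#' @export
print.eg_network <- function(x, ...) {
  cat("E-G network:", nrow(x$edges), "edges,",
      length(unique(x$edges$cre_id)), "CREs,",
      length(unique(x$edges$gene_id)), "genes (threshold ",
      x$threshold, ")\n")
  invisible(x)
}

.network_graph <- function(network, weighted = FALSE) {
  e <- network$edges
  # bipartite: prefix node names to keep CRE and gene namespaces disjoint
  el <- data.frame(from = paste0("C:", e$cre_id),
                   to = paste0("G:", e$gene_id),
                   stringsAsFactors = FALSE)
  if (weighted) el$weight <- e$score
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(weight = "max", "ignore"))
}

#' Detect regulatory substructures by multi-level modularity optimisation
#'
#' Runs the Louvain method on the bipartite E-G graph treated as a simple
#' undirected graph (unweighted by default; `weighted = TRUE` uses edge
#' scores as modularity weights). Deterministic for a fixed seed.
#'
#' @param network an `eg_network` with at least one edge.
#' @param seed integer seed (controls node-visit order).
#' @param resolution Louvain resolution parameter.
#' @param weighted use edge scores as weights.
#' @return list `membership` (named integer vector over node names
#'   `C:<cre_id>` / `G:<gene_id>`), `modularity` (achieved value),
#'   `n_communities`, `seed`, `resolution`.
#' @export
detect_communities <- function(network, seed = 1L, resolution = 1.0,
                               weighted = FALSE) {
  if (nrow(network$edges) == 0) stop("cannot detect communities in an empty network")
  g <- .network_graph(network, weighted = weighted)
  cl <- .with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  list(membership = setNames(as.integer(memb), names(memb)),
       modularity = max(cl$modularity),
       n_communities = length(unique(as.integer(memb))),
       seed = seed, resolution = resolution)
}

#' Classify communities as redundant / non-redundant substructures
#'
#' A substructure is non-redundant (NR) iff it contains exactly one CRE (one
#' enhancer node serving one or more genes); substructures with multiple CREs
#' are redundant (R). Communities without any CRE (isolated genes) are
#' labelled `not_applicable` and excluded from the %NR denominator.
#'
#' @param network an `eg_network`.
#' @param partition result of [detect_communities()] (or a named membership
#'   vector).
#' @return data.frame `community_id`, `type` (`R`/`NR`/`not_applicable`),
#'   `n_cres`, `n_genes`, `n_edges`, `cres`, `genes` (comma-separated
#'   member lists).
#' @export
classify_substructures <- function(network, partition) {
  memb <- if (is.list(partition)) partition$membership else partition
  nodes <- names(memb)
  if (!all(c(paste0("C:", network$edges$cre_id),
             paste0("G:", network$edges$gene_id)) %in% nodes)) {
    stop("partition does not cover all network nodes")
  }
  is_cre <- startsWith(nodes, "C:")
  comm <- sort(unique(as.integer(memb)))
  e_comm <- memb[paste0("C:", network$edges$cre_id)]
  out <- lapply(comm, function(cid) {
    members <- nodes[memb == cid]
    cres <- sub("^C:", "", members[startsWith(members, "C:")])
    genes <- sub("^G:", "", members[startsWith(members, "G:")])
    n_edges <- sum(e_comm == cid &
                     memb[paste0("G:", network$edges$gene_id)] == cid)
    type <- if (length(cres) == 0) "not_applicable"
            else if (length(cres) == 1) "NR" else "R"
    data.frame(community_id = cid, type = type,
               n_cres = length(cres), n_genes = length(genes),
               n_edges = n_edges,
               cres = paste(sort(cres), collapse = ","),
               genes = paste(sort(genes), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarise an E-G network and its substructures
#'
#' @param network an `eg_network`.
#' @param substructures optional output of [classify_substructures()]; when
#'   supplied, `pct_nr` = 100 * #NR / #(communities with >= 1 CRE) and the
#'   achieved modularity can be attached via `modularity`.
#' @param modularity optional achieved modularity to record.
#' @return list `n_unique_cres`, `n_unique_genes`, `n_pairs`, `pct_nr`,
#'   `n_communities`, `modularity`.
#' @export
summarize_network <- function(network, substructures = NULL, modularity = NA_real_) {
  e <- network$edges
  pct_nr <- NA_real_
  n_comm <- NA_integer_
  if (!is.null(substructures)) {
    with_cre <- substructures[substructures$type != "not_applicable", , drop = FALSE]
    n_comm <- nrow(with_cre)
    pct_nr <- if (n_comm > 0) 100 * sum(with_cre$type == "NR") / n_comm else NA_real_
  }
  list(n_unique_cres = length(unique(e$cre_id)),
       n_unique_genes = length(unique(e$gene_id)),
       n_pairs = nrow(e),
       pct_nr = pct_nr,
       n_communities = n_comm,
       modularity = modularity)
}
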