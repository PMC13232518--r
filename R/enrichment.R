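# Condition-specific motif enrichment (merged regions, one-sided Fisher
# tests, continuity-corrected log2 odds ratios, BH FDR) and hypergeometric
# gene-set enrichment.

#' Build merged regions across condition-specific CRE sets
#'
#' CREs from every condition's network are merged by >= 1 bp overlap on the
#' same chromosome; each merged region records which conditions contributed
#' and is `condition_specific` iff exactly one condition is present.
#'
#' @param cre_sets named list: condition -> data.frame (`chrom`, `start`,
#'   `end`).
#' @return data.frame `region_id`, `chrom`, `start`, `end`, `conditions`
#'   (comma-separated), `specificity`.
#' @export
build_merged_regions <- function(cre_sets) {
  stopifnot(length(cre_sets) >= 1, !is.null(names(cre_sets)))
  all_int <- do.call(rbind, lapply(names(cre_sets), function(cn) {
    x <- cre_sets[[cn]][, c("chrom", "start", "end")]
    x$condition <- cn
    x
  }))
  merged <- merge_labeled(all_int[, c("chrom", "start", "end")], all_int$condition)
  conds <- vapply(merged$labels, paste, "", collapse = ",")
  n_cond <- lengths(merged$labels)
  data.frame(
    region_id = paste0(merged$chrom, ":", merged$start, "-", merged$end),
    chrom = merged$chrom, start = merged$start, end = merged$end,
    conditions = conds,
    specificity = ifelse(n_cond == 1, "condition_specific", "condition_agnostic"),
    stringsAsFactors = FALSE
  )
}

#' Motif presence per merged region
#'
#' A merged region is TFBM-present for a TF iff at least one scanner hit,
#' keyed to a CRE of the given condition's network, falls within the region.
#' Hits are keyed by `sequence_name`, which must resolve to a CRE id of
#' `condition_cres` (unknown ids error).
#'
#' @param regions merged regions from [build_merged_regions()].
#' @param hits motif hit data.frame from [read_fimo()].
#' @param condition_cres data.frame of the condition's network CREs
#'   (`cre_id`, `chrom`, `start`, `end`).
#' @return logical matrix, regions x TFs.
#' @export
tf_presence <- function(regions, hits, condition_cres) {
  tfs <- sort(unique(hits$tf_name))
  out <- matrix(FALSE, nrow = nrow(regions), ncol = length(tfs),
                dimnames = list(regions$region_id, tfs))
  if (nrow(hits) == 0) return(out)
  unknown <- setdiff(unique(hits$sequence_name), condition_cres$cre_id)
  if (length(unknown)) {
    stop("motif hits reference unknown CRE ids: ",
         paste(head(unknown), collapse = ", "))
  }
  idx <- match(hits$sequence_name, condition_cres$cre_id)
  hit_pts <- data.frame(chrom = condition_cres$chrom[idx],
                        pos = interval_midpoint(condition_cres$start[idx],
                                                condition_cres$end[idx]))
  # map each hit's CRE to the merged region containing it (CRE midpoint)
  region_of <- rep(NA_integer_, nrow(hits))
  for (ch in intersect(unique(hit_pts$chrom), unique(regions$chrom))) {
    hi <- which(hit_pts$chrom == ch)
    ri <- which(regions$chrom == ch)
    ir_h <- IRanges::IRanges(hit_pts$pos[hi] + 1L, hit_pts$pos[hi] + 1L)
    ir_r <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
    ov <- IRanges::findOverlaps(ir_h, ir_r, select = "first")
    region_of[hi] <- ri[ov]
  }
  ok <- !is.na(region_of)
  out[cbind(region_of[ok], match(hits$tf_name[ok], tfs))] <- TRUE
  out
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Tests enrichment of TFBM presence among condition-specific regions
#' (alternative: greater). Cells: `a` present & specific, `b` present &
#' agnostic, `c` absent & specific, `d` absent & agnostic. The p-value is
#' the hypergeometric upper tail of `a` given the table margins; the empty
#' table returns 1.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return one-sided p-value.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) return(1.0)
  # population a+b+c+d; specific column a+c; present row draws a+b
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Continuity-corrected log2 odds ratio
#'
#' `log2(((a+cc)(d+cc)) / ((b+cc)(c+cc)))`; the 0.5 pseudo-count keeps the
#' value finite for empty cells.
#'
#' @param a,b,c,d cell counts as in [fisher_one_sided()].
#' @param cc continuity correction (> 0).
#' @return log2 odds ratio.
#' @export
log2_or_cc <- function(a, b, c, d, cc = 0.5) {
  stopifnot(cc > 0)
  log2(((a + cc) * (d + cc)) / ((b + cc) * (c + cc)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, returned in input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted values (same order).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-TF motif enrichment in condition-specific regions
#'
#' For one condition: builds the 2x2 of TFBM presence vs region specificity
#' over all merged regions, computes the one-sided Fisher p, raw and
#' continuity-corrected odds ratios, and BH FDR across TFs (within the
#' condition, never pooled across conditions).
#'
#' @param regions merged regions (all conditions).
#' @param hits motif hits for this condition's network CREs.
#' @param condition_cres the condition's network CRE table.
#' @return data.frame `tf_name`, `a`, `b`, `c`, `d`, `odds_ratio` (raw
#'   `ad/bc`, `Inf` when `bc == 0`), `log2_or_cc`, `p_one_sided`, `fdr`,
#'   sorted by ascending FDR then p.
#' @export
motif_enrichment <- function(regions, hits, condition_cres) {
  pres <- tf_presence(regions, hits, condition_cres)
  spec <- regions$specificity == "condition_specific"
  recs <- lapply(colnames(pres), function(tf) {
    p_tf <- pres[, tf]
    a <- sum(p_tf & spec); b <- sum(p_tf & !spec)
    c_ <- sum(!p_tf & spec); d <- sum(!p_tf & !spec)
    data.frame(tf_name = tf, a = a, b = b, c = c_, d = d,
               odds_ratio = if (b * c_ == 0) Inf else (a * d) / (b * c_),
               log2_or_cc = log2_or_cc(a, b, c_, d),
               p_one_sided = fisher_one_sided(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$fdr <- bh_fdr(out$p_one_sided)
  out <- out[order(out$fdr, out$p_one_sided, out$tf_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment (survival function)
#'
#' `P(X >= x)` for `X ~ Hypergeometric(M, n, k)`: population `M` background
#' genes of which `n` belong to the set, `k` genes drawn (the network's
#' genes), `x` observed in the set. Equivalent to `sf(x - 1)` of the
#' hypergeometric distribution.
#'
#' @param M background size; @param n set members in the background;
#' @param k network gene count; @param x overlap count.
#' @return enrichment p-value.
#' @export
hypergeom_gene_enrichment <- function(M, n, k, x) {
  stopifnot(n <= M, k <= M)
  if (x > min(n, k)) stop("overlap x exceeds min(n, k)")
  phyper(x - 1, n, M - n, k, lower.tail = FALSE)
}

#' Gene-set enrichment of a network's genes
#'
#' Convenience wrapper: intersects the gene set with the background before
#' testing, per standard practice.
#'
#' @param network_genes character vector of the network's genes.
#' @param gene_set character vector (the curated set).
#' @param background character vector: union of genes across all networks.
#' @return list `M`, `n`, `k`, `x`, `p`.
#' @export
gene_set_enrichment <- function(network_genes, gene_set, background) {
  background <- unique(background)
  gene_set <- intersect(unique(gene_set), background)
  network_genes <- intersect(unique(network_genes), background)
  M <- length(background); n <- length(gene_set)
  k <- length(network_genes)
  x <- length(intersect(network_genes, gene_set))
  list(M = M, n = n, k = k, x = x,
       p = hypergeom_gene_enrichment(M, n, k, x))
}

#' Read a gene set (GMT or one gene per line)
#' @param path file path; `.gmt` files may contain several sets (a named
#'   list is returned), plain files one set (character vector).
#' @param set_name for GMT input, the set to extract (default: all).
#' @return character vector or named list.
#' @export
read_gene_set <- function(path, set_name = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    sets <- setNames(lapply(f, function(x) x[-(1:2)]), vapply(f, `[`, "", 1L))
    if (!is.null(set_name)) {
      if (!set_name %in% names(sets)) stop("gene set not found: ", set_name)
      return(sets[[set_name]])
    }
    return(sets)
  }
  trimws(lines)
}
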