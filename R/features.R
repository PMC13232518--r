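# Candidate-CRE selection, E-G pair enumeration, activity-by-contact scoring
# and feature-matrix assembly.

#' Select candidate CREs from DNase peaks plus gene promoters
#'
#' Peaks are resized to `cre_len` bp about their midpoints, ranked by read
#' count (ties broken by chrom, start ascending) and the top `n_top` kept.
#' One promoter CRE per gene is appended (id `prom_<gene_id>`, carrying its
#' owner gene), and candidates with identical coordinates are collapsed
#' (first occurrence kept, peak before promoter).
#'
#' @param peaks data.frame as from [read_narrowpeak()].
#' @param genes gene annotation data.frame.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_top number of top peaks to retain (150000 for genome-scale runs).
#' @param cre_len scoring-element width in bp.
#' @param promoter_flank promoter half-width when not annotated.
#' @return data.frame `cre_id`, `chrom`, `start`, `end`, `summit`,
#'   `read_count`, `source` (`dnase_peak`/`promoter`), `owner_gene` (NA for
#'   peak CREs).
#' @export
select_candidates <- function(peaks, genes, chrom_sizes, n_top = 150000L,
                              cre_len = 500L, promoter_flank = 500L) {
  if (nrow(peaks) == 0) stop("no peaks supplied")
  res <- resize_center(peaks[, c("chrom", "start", "end")], cre_len, chrom_sizes)
  cand <- data.frame(
    cre_id = peaks$peak_id, chrom = res$chrom, start = res$start, end = res$end,
    summit = peaks$summit, read_count = peaks$read_count,
    source = "dnase_peak", owner_gene = NA_character_,
    stringsAsFactors = FALSE
  )
  ord <- order(-cand$read_count, cand$chrom, cand$start)
  cand <- cand[ord[seq_len(min(n_top, nrow(cand)))], , drop = FALSE]
  prom <- promoter_intervals(genes, flank = promoter_flank)
  promc <- data.frame(
    cre_id = paste0("prom_", prom$gene_id), chrom = prom$chrom,
    start = prom$start, end = prom$end,
    summit = interval_midpoint(prom$start, prom$end),
    read_count = NA_real_, source = "promoter", owner_gene = prom$gene_id,
    stringsAsFactors = FALSE
  )
  out <- rbind(cand, promc)
  out <- out[!duplicated(out[, c("chrom", "start", "end")]), , drop = FALSE]
  if (any(duplicated(out$cre_id))) stop("duplicated cre_id in candidate set")
  rownames(out) <- NULL
  out
}

#' Enumerate candidate E-G pairs within a distance window
#'
#' All (CRE, gene) pairs on the same chromosome with |CRE midpoint - TSS|
#' <= `window` (boundary inclusive).
#'
#' @param cres candidate CRE data.frame (from [select_candidates()]).
#' @param genes gene annotation data.frame.
#' @param window maximum midpoint-to-TSS distance in bp (default 5 Mb).
#' @return data.frame `cre_id`, `gene_id`, `distance`.
#' @export
enumerate_pairs <- function(cres, genes, window = 5e6) {
  if (nrow(cres) == 0 || nrow(genes) == 0) {
    return(data.frame(cre_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  mid <- interval_midpoint(cres$start, cres$end)
  cre_dt <- data.table::data.table(cre_id = cres$cre_id, chrom = cres$chrom, mid = mid)
  gene_dt <- data.table::data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                                    tss = genes$tss)
  j <- cre_dt[gene_dt, on = "chrom", allow.cartesian = TRUE, nomatch = NULL]
  j[, distance := abs(mid - tss)]
  j <- j[distance <= window]
  out <- as.data.frame(j[, list(cre_id, gene_id, distance)])
  out$distance <- as.integer(out$distance)
  out[!duplicated(out[, c("cre_id", "gene_id")]), , drop = FALSE]
}

#' Activity-by-contact score for candidate pairs
#'
#' For pair (e, g): `A_e * C_eg / sum over e' in g's candidate set of
#' A_e' * C_e'g`, where the activity `A = sqrt(dnase * h3k27ac)` (geometric
#' mean of the two chromatin signals) and `C` is the pair's 3D contact value
#' with `pseudocount` added to zero contacts. Per-gene scores sum to 1;
#' a gene whose candidates all have `A * C = 0` gets all-zero scores with a
#' warning.
#'
#' @param pairs data.frame `cre_id`, `gene_id` (one row per candidate pair).
#' @param activity data.frame `cre_id`, `dnase`, `h3k27ac`.
#' @param contact data.frame `cre_id`, `gene_id`, `contact`; pairs absent
#'   from the table get contact 0 (then the pseudocount).
#' @param pseudocount added to zero contact values.
#' @return numeric vector of scores aligned with `pairs` rows.
#' @export
abc_score <- function(pairs, activity, contact, pseudocount = 1e-6) {
  if (nrow(pairs) == 0) return(numeric())
  a <- activity[match(pairs$cre_id, activity$cre_id), , drop = FALSE]
  if (anyNA(a$cre_id)) {
    stop("activity missing for CREs: ",
         paste(head(unique(pairs$cre_id[is.na(a$cre_id)])), collapse = ", "))
  }
  A <- sqrt(a$dnase * a$h3k27ac)
  key <- paste(pairs$cre_id, pairs$gene_id, sep = "\r")
  ckey <- paste(contact$cre_id, contact$gene_id, sep = "\r")
  C <- contact$contact[match(key, ckey)]
  C[is.na(C)] <- 0
  C[C == 0] <- pseudocount
  prod <- A * C
  denom <- ave(prod, pairs$gene_id, FUN = sum)
  score <- ifelse(denom > 0, prod / denom, 0)
  if (any(denom == 0)) {
    warning("gene(s) with zero total activity*contact: ",
            paste(unique(pairs$gene_id[denom == 0]), collapse = ", "),
            "; their pair scores set to 0")
  }
  score
}

#' Average forward and reverse-complement orientation scores
#'
#' @param fwd,rev finite numeric vectors of orientation-specific activity
#'   scores.
#' @return element-wise arithmetic mean.
#' @export
average_orientations <- function(fwd, rev) {
  if (any(!is.finite(fwd)) || any(!is.finite(rev))) {
    stop("non-finite orientation score")
  }
  (fwd + rev) / 2
}

#' Ensemble-average replicate model predictions per CRE
#'
#' Averages the per-model predictions for each CRE (10 replicate models
#' expected; fewer are accepted with a warning).
#'
#' @param scores data.frame `cre_id`, `value` (one row per model replicate).
#' @param n_expected expected replicate count.
#' @return data.frame `cre_id`, `value` with one row per CRE.
#' @export
ensemble_mean <- function(scores, n_expected = 10L) {
  if (nrow(scores) == 0) stop("no predictions to ensemble")
  n <- table(scores$cre_id)
  if (any(n < n_expected)) {
    warning(sum(n < n_expected), " CRE(s) with fewer than ", n_expected,
            " model predictions; averaging what is present")
  }
  out <- aggregate(value ~ cre_id, data = scores, FUN = mean)
  out[order(out$cre_id), , drop = FALSE]
}

#' Collapse duplicate feature columns by averaging
#'
#' When several input columns map to the same chromatin feature (e.g.
#' several model outputs for one histone mark), they are replaced by their
#' row-wise arithmetic mean, named by the feature.
#'
#' @param x numeric data.frame / matrix.
#' @param groups character vector, one feature name per column of `x`.
#' @return data.frame with one column per unique feature name (order of
#'   first appearance).
#' @export
collapse_duplicate_columns <- function(x, groups) {
  x <- as.data.frame(x)
  stopifnot(length(groups) == ncol(x))
  feats <- unique(groups)
  out <- lapply(feats, function(f) rowMeans(x[, groups == f, drop = FALSE]))
  names(out) <- feats
  as.data.frame(out, check.names = FALSE)
}

#' Assemble the per-pair feature matrix
#'
#' Left-joins pair-level features (keyed by `cre_id`, `gene_id`) and
#' CRE-level features (keyed by `cre_id`) onto the candidate pair list, adds
#' the ABC score and distance, imputes missing values with per-column
#' training medians (adding a 0/1 missingness indicator column per affected
#' source), and records per-column provenance in a manifest.
#'
#' Rows are canonically sorted by (`gene_id`, `cre_id`).
#'
#' @param pairs data.frame `cre_id`, `gene_id`, `distance`.
#' @param re2g optional pair-level feature table keyed by (`cre_id`,
#'   `gene_id`); all other columns are numeric features.
#' @param mpra optional per-CRE table `cre_id`, `value` (ensembled,
#'   orientation-averaged activity).
#' @param sei optional per-CRE wide table: `cre_id` plus one numeric column
#'   per chromatin feature.
#' @param abc optional numeric vector of ABC scores aligned with `pairs`.
#' @param check_keys error on feature rows whose keys are absent from
#'   `pairs` (default TRUE).
#' @return object of class `eg_features`: list with `matrix` (data.frame:
#'   `cre_id`, `gene_id`, then numeric features) and `manifest` (named
#'   character vector column -> provenance tag).
#' @export
assemble_features <- function(pairs, re2g = NULL, mpra = NULL, sei = NULL,
                              abc = NULL, check_keys = TRUE) {
  stopifnot(all(c("cre_id", "gene_id", "distance") %in% names(pairs)))
  key <- paste(pairs$cre_id, pairs$gene_id, sep = "\r")
  if (any(duplicated(key))) stop("duplicated (cre_id, gene_id) in pairs")
  X <- data.frame(cre_id = pairs$cre_id, gene_id = pairs$gene_id,
                  distance = as.numeric(pairs$distance),
                  stringsAsFactors = FALSE)
  manifest <- c(distance = "re2g")
  if (!is.null(abc)) {
    stopifnot(length(abc) == nrow(pairs))
    X$abc_score <- as.numeric(abc)
    manifest["abc_score"] <- "abc"
  }
  if (!is.null(re2g)) {
    stopifnot(all(c("cre_id", "gene_id") %in% names(re2g)))
    rkey <- paste(re2g$cre_id, re2g$gene_id, sep = "\r")
    if (check_keys) {
      bad <- setdiff(rkey, key)
      if (length(bad)) {
        stop("pair-feature rows with unknown keys: ",
             paste(head(gsub("\r", "/", bad)), collapse = ", "))
      }
    }
    idx <- match(key, rkey)
    for (cn in setdiff(names(re2g), c("cre_id", "gene_id"))) {
      X[[cn]] <- as.numeric(re2g[[cn]])[idx]
      manifest[cn] <- "re2g"
    }
  }
  if (!is.null(mpra)) {
    stopifnot(all(c("cre_id", "value") %in% names(mpra)))
    if (check_keys) {
      bad <- setdiff(mpra$cre_id, pairs$cre_id)
      if (length(bad)) stop("mpra rows with unknown cre_id: ", paste(head(bad), collapse = ", "))
    }
    X$mpra_activity <- mpra$value[match(pairs$cre_id, mpra$cre_id)]
    manifest["mpra_activity"] <- "mpralegnet"
  }
  if (!is.null(sei)) {
    stopifnot("cre_id" %in% names(sei))
    if (check_keys) {
      bad <- setdiff(sei$cre_id, pairs$cre_id)
      if (length(bad)) stop("sei rows with unknown cre_id: ", paste(head(bad), collapse = ", "))
    }
    idx <- match(pairs$cre_id, sei$cre_id)
    for (cn in setdiff(names(sei), "cre_id")) {
      nm <- paste0("sei_", cn)
      X[[nm]] <- as.numeric(sei[[cn]])[idx]
      manifest[nm] <- "sei"
    }
  }
  # median imputation + per-source missingness indicators (flags reflect the
  # pre-imputation NA pattern)
  feat_cols <- setdiff(names(X), c("cre_id", "gene_id"))
  na_by_source <- list()
  for (cn in feat_cols) {
    nas <- is.na(X[[cn]])
    if (any(nas)) {
      src <- manifest[[cn]]
      prev <- na_by_source[[src]]
      na_by_source[[src]] <- if (is.null(prev)) nas else (prev | nas)
      med <- median(X[[cn]], na.rm = TRUE)
      if (is.na(med)) med <- 0
      X[[cn]][nas] <- med
    }
  }
  for (src in names(na_by_source)) {
    flag <- paste0("missing_", src)
    X[[flag]] <- as.numeric(na_by_source[[src]])
    manifest[flag] <- src
  }
  ord <- order(X$gene_id, X$cre_id)
  X <- X[ord, , drop = FALSE]
  rownames(X) <- NULL
  if (any(!vapply(X[setdiff(names(X), c("cre_id", "gene_id"))], function(v) all(is.finite(v)), TRUE))) {
    stop("non-finite feature values after imputation")
  }
  structure(list(matrix = X, manifest = manifest), class = "eg_features")
}

#' Write / read a feature matrix with its provenance manifest
#'
#' The matrix is written as a TSV; the manifest as a JSON file alongside
#' (`<path>.manifest.json`).
#'
#' @param features an `eg_features` object.
#' @param path TSV output path.
#' @return `write_features`: the path invisibly; `read_features`: an
#'   `eg_features`.
#' @export
write_features <- function(features, path) {
  .write_tsv(features$matrix, path)
  jsonlite::write_json(as.list(features$manifest), paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  m <- .read_tsv(path, required = c("cre_id", "gene_id"), what = path)
  man_path <- paste0(path, ".manifest.json")
  manifest <- if (file.exists(man_path)) {
    unlist(jsonlite::read_json(man_path))
  } else {
    setNames(rep("re2g", ncol(m) - 2L), setdiff(names(m), c("cre_id", "gene_id")))
  }
  structure(list(matrix = m, manifest = manifest), class = "eg_features")
}
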