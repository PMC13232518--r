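# File dialects. All tables are tab-separated; lines starting with '#' are
# metadata/comments and are skipped on read. 1-based formats (VCF POS, FIMO
# start/stop) are converted to 0-based half-open exactly once, here.

.read_tsv <- function(path, col_names, required = col_names, what = path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE, quote = ""),
    error = function(e) stop("malformed table ", what, ": ", conditionMessage(e))
  )
  miss <- setdiff(required, names(x))
  if (length(miss)) stop(what, ": missing required columns: ", paste(miss, collapse = ", "))
  x
}

.write_tsv <- function(x, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", names(meta), "=", unlist(meta)), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MACS2 narrowPeak file
#'
#' Standard 10-column narrowPeak (BED6+4, no header): chrom, start, end, name,
#' score, strand, signalValue, pValue, qValue, summit offset. The summit is
#' `start + column 10`. The per-peak read count is taken from `signalValue`
#' by default (configurable to the `score` column).
#'
#' @param path file path.
#' @param read_count_from `"signalValue"` or `"score"`.
#' @return data.frame `peak_id`, `chrom`, `start`, `end`, `summit`,
#'   `read_count`.
#' @export
read_narrowpeak <- function(path, read_count_from = c("signalValue", "score")) {
  read_count_from <- match.arg(read_count_from)
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, quote = "")
  if (ncol(x) < 10) stop("narrowPeak file ", path, " has ", ncol(x), " columns; 10 required")
  names(x)[1:10] <- c("chrom", "start", "end", "name", "score", "strand",
                      "signalValue", "pValue", "qValue", "peak_offset")
  bad <- which(x$end <= x$start | x$start < 0)
  if (length(bad)) stop("narrowPeak ", path, ": invalid interval at line ", bad[1])
  out <- data.frame(
    peak_id = ifelse(x$name == "." | x$name == "", paste0("peak_", seq_len(nrow(x))), x$name),
    chrom = x$chrom, start = as.integer(x$start), end = as.integer(x$end),
    summit = as.integer(x$start + x$peak_offset),
    read_count = as.numeric(x[[read_count_from]]),
    stringsAsFactors = FALSE
  )
  bad <- which(out$summit < out$start | out$summit >= out$end)
  if (length(bad)) stop("narrowPeak ", path, ": summit outside peak at line ", bad[1])
  check_intervals(out, "peaks")
  out
}

#' Write peaks as narrowPeak
#' @param peaks data.frame as from [read_narrowpeak()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  x <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                  rep(0L, n), rep(".", n), peaks$read_count, rep(-1, n),
                  rep(-1, n), peaks$summit - peaks$start)
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` (+ `name`, `score`, `strand`
#'   when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, quote = "")
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cn[seq_len(min(ncol(x), 6))]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  check_intervals(x, path)
  x
}

#' Write intervals as BED
#' @param x data.frame with `chrom`, `start`, `end` (+ optional BED6 columns).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  write.table(x[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with header; required columns `gene_id`, `chrom`, `strand`, `tss`;
#' optional `promoter_start`, `promoter_end`, `gene_start`, `gene_end`.
#'
#' @param path file path.
#' @return gene annotation data.frame.
#' @export
read_genes <- function(path) {
  x <- .read_tsv(path, required = c("gene_id", "chrom", "strand", "tss"), what = path)
  if (any(duplicated(x$gene_id))) stop(path, ": duplicated gene_id")
  if (!all(x$strand %in% c("+", "-"))) stop(path, ": strand must be '+' or '-'")
  x$tss <- as.integer(x$tss)
  x
}

#' Read gene annotations from a minimal GTF subset
#'
#' Parses `gene` feature lines of a GTF: TSS is the start for `+` strand and
#' the end for `-` strand genes (converted to 0-based).
#'
#' @param path GTF file path.
#' @return gene annotation data.frame with gene bodies.
#' @export
read_genes_gtf <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, quote = "")
  x <- x[x[[3]] == "gene", , drop = FALSE]
  if (nrow(x) == 0) stop(path, ": no 'gene' features")
  gid <- sub('.*gene_id[ ="]+([^";]+).*', "\\1", x[[9]])
  start0 <- as.integer(x[[4]]) - 1L
  end0 <- as.integer(x[[5]])
  data.frame(
    gene_id = gid, chrom = x[[1]], strand = x[[7]],
    tss = ifelse(x[[7]] == "+", start0, end0 - 1L),
    gene_start = start0, gene_end = end0,
    stringsAsFactors = FALSE
  )
}

#' Read per-CRE activity signals
#' @param path TSV with columns `cre_id`, `dnase`, `h3k27ac`.
#' @return data.frame.
#' @export
read_activity <- function(path) {
  x <- .read_tsv(path, required = c("cre_id", "dnase", "h3k27ac"), what = path)
  if (any(x$dnase < 0 | x$h3k27ac < 0)) stop(path, ": negative activity signal")
  x
}

#' Read per-pair 3D contact values
#' @param path TSV with columns `cre_id`, `gene_id`, `contact`.
#' @return data.frame.
#' @export
read_contact <- function(path) {
  x <- .read_tsv(path, required = c("cre_id", "gene_id", "contact"), what = path)
  if (any(x$contact < 0)) stop(path, ": negative contact value")
  x
}

#' Read per-CRE reporter-activity model scores
#'
#' One row per (CRE, model replicate): columns `cre_id`, `model_index`,
#' `fwd`, `rev` holding forward / reverse-complement orientation scores
#' (log2 RNA/DNA scale).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_mpra_scores <- function(path) {
  .read_tsv(path, required = c("cre_id", "model_index", "fwd", "rev"), what = path)
}

#' Read per-CRE chromatin-probability scores
#'
#' Long format: columns `cre_id`, `output_name`, `feature`, `probability`;
#' several `output_name`s may map to the same `feature` and are averaged
#' downstream.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sei_scores <- function(path) {
  .read_tsv(path, required = c("cre_id", "output_name", "feature", "probability"), what = path)
}

#' Read CRISPRi labels for E-G pairs
#' @param path TSV with `cre_id`, `gene_id`, `label` (0/1) and optional
#'   `effect_size` (percent change in expression).
#' @return data.frame.
#' @export
read_labels <- function(path) {
  x <- .read_tsv(path, required = c("cre_id", "gene_id", "label"), what = path)
  if (!all(x$label %in% c(0L, 1L))) stop(path, ": labels must be 0/1")
  x
}

#' Read a variant table (TSV or sites-only VCF)
#'
#' TSV dialect: header columns `chrom`, `pos` (1-based), `id`, optional
#' `p_value`. VCF: standard CHROM/POS/ID columns of a sites-only file.
#' Positions are converted to 0-based (`pos0`); duplicates by
#' (chrom, pos, id) are collapsed; when a `p_value` column exists, variants
#' are filtered to `p_value < p_max`.
#'
#' @param path file path.
#' @param p_max association p-value cutoff applied when a p-value column is
#'   present (default 0.01).
#' @return data.frame `chrom`, `pos0`, `id` (+ `p_value` when present).
#' @export
read_variants <- function(path, p_max = 0.01) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || startsWith(first, "#CHROM")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0) {
      x <- data.frame(chrom = character(), pos = integer(), id = character())
    } else {
      f <- strsplit(lines, "\t", fixed = TRUE)
      x <- data.frame(chrom = vapply(f, `[`, "", 1L),
                      pos = as.integer(vapply(f, `[`, "", 2L)),
                      id = vapply(f, `[`, "", 3L),
                      stringsAsFactors = FALSE)
    }
  } else {
    x <- .read_tsv(path, required = c("chrom", "pos", "id"), what = path)
    x$pos <- as.integer(x$pos)
  }
  if (nrow(x) && any(x$pos < 1)) stop(path, ": VCF/TSV positions are 1-based, found pos < 1")
  if ("p_value" %in% names(x)) x <- x[x$p_value < p_max, , drop = FALSE]
  x$pos0 <- x$pos - 1L
  x$pos <- NULL
  x[!duplicated(x[, c("chrom", "pos0", "id")]), , drop = FALSE]
}

#' Read an eQTL variant-gene table
#' @param path TSV with `chrom`, `pos` (1-based), `id`, `gene_id`.
#' @return data.frame `chrom`, `pos0`, `id`, `gene_id`, deduplicated by
#'   (variant, gene).
#' @export
read_eqtls <- function(path) {
  x <- .read_tsv(path, required = c("chrom", "pos", "id", "gene_id"), what = path)
  x$pos0 <- as.integer(x$pos) - 1L
  x$pos <- NULL
  x[!duplicated(x[, c("chrom", "pos0", "id", "gene_id")]), , drop = FALSE]
}

#' Read motif hits in the FIMO output dialect
#'
#' Tab-separated with header `motif_id`, `motif_alt_id`, `sequence_name`,
#' `start`, `stop`, `strand`, `score`, `p-value`, `q-value`,
#' `matched_sequence`; comment lines and trailing blank lines tolerated.
#' `sequence_name` keys hits either to CRE ids or to region coordinates,
#' resolved by the caller. Coordinates are 1-based inclusive within the
#' scanned sequence and are kept as-is (hits are used for presence only).
#'
#' @param path file path.
#' @param p_max scanner p-value cutoff (default 1e-5).
#' @return data.frame `tf_name`, `sequence_name`, `start`, `stop`, `strand`,
#'   `score`, `p_value`.
#' @export
read_fimo <- function(path, p_max = 1e-5) {
  x <- .read_tsv(path, required = c("motif_id", "sequence_name", "start", "stop",
                                    "strand", "score", "p-value"), what = path)
  out <- data.frame(
    tf_name = if ("motif_alt_id" %in% names(x) && !all(x$motif_alt_id %in% c("", ".")))
      x$motif_alt_id else x$motif_id,
    sequence_name = x$sequence_name,
    start = as.integer(x$start), stop = as.integer(x$stop),
    strand = x$strand, score = as.numeric(x$score),
    p_value = as.numeric(x[["p-value"]]),
    stringsAsFactors = FALSE
  )
  out[out$p_value <= p_max, , drop = FALSE]
}

#' Write / read an E-G network table
#'
#' Columns: `cre_id`, `cre_chrom`, `cre_start`, `cre_end`, `cre_class`,
#' `gene_id`, `score`.
#'
#' @param network an `eg_network` (see [build_eg_network()]).
#' @param path file path.
#' @return `write_network`: the path invisibly; `read_network`: an
#'   `eg_network`.
#' @export
write_network <- function(network, path) {
  .write_tsv(network$edges, path, meta = list(threshold = network$threshold))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- .read_tsv(path, required = c("cre_id", "cre_chrom", "cre_start", "cre_end",
                                    "cre_class", "gene_id", "score"), what = path)
  structure(list(edges = x, threshold = NA_real_), class = "eg_network")
}

#' Write a scalar-result list as JSON
#' @param x list of scalars / vectors.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
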