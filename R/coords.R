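#' @importFrom stats median quantile rbinom rgamma rlnorm rnorm runif sd cor
#'   p.adjust phyper plogis qlogis rpois complete.cases setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

# All coordinates inside the package are 0-based half-open (BED convention).
# 1-based inputs (VCF POS, FIMO start/stop) are converted at the I/O boundary.

#' Validate a data frame of genomic intervals
#'
#' Intervals are 0-based half-open: a row covers bases `[start, end)` and
#' must satisfy `0 <= start < end`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
check_intervals <- function(x, what = "intervals") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) > 0) {
    if (any(x$start < 0)) stop(what, ": negative start coordinate")
    if (any(x$end <= x$start)) stop(what, ": empty or inverted interval (end <= start)")
  }
  invisible(x)
}

#' Interval midpoint
#'
#' Deterministic midpoint convention: `floor((start + end) / 2)`, so the
#' midpoint of an even-length interval is the left of the two central bases.
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return integer vector of midpoints.
#' @export
interval_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

#' Resize intervals about their midpoints
#'
#' Each interval is replaced by a window of length `target_len` centred on its
#' midpoint. Windows falling off a chromosome end are shifted inward so the
#' length is always preserved (never truncated); this is the behaviour wanted
#' for fixed-width candidate-CRE windows such as the 500-bp scoring element or
#' the 200-bp reporter-assay element.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param target_len positive integer window size.
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @return the input data.frame with `start`/`end` replaced.
#' @export
resize_center <- function(intervals, target_len, chrom_sizes) {
  check_intervals(intervals)
  stopifnot(length(target_len) == 1, target_len >= 1)
  if (nrow(intervals) == 0) return(intervals)
  miss <- setdiff(unique(intervals$chrom), names(chrom_sizes))
  if (length(miss)) stop("chromosomes missing from sizes: ", paste(miss, collapse = ", "))
  len <- unname(chrom_sizes[intervals$chrom])
  if (any(len < target_len)) {
    stop("chromosome shorter than target length ", target_len)
  }
  mid <- interval_midpoint(intervals$start, intervals$end)
  half <- floor(target_len / 2)
  start <- mid - half
  end <- start + target_len
  # shift inward at chromosome ends, preserving length
  shift_r <- pmax(0L, -start)
  start <- start + shift_r
  end <- end + shift_r
  shift_l <- pmax(0, end - len)
  start <- as.integer(start - shift_l)
  end <- as.integer(end - shift_l)
  intervals$start <- start
  intervals$end <- end
  intervals
}

#' Resize peaks to fixed windows centred on their summits
#'
#' Builds a `target_len` window centred on each peak summit (summit at offset
#' `floor(target_len / 2)` from the window start). Where the window exits the
#' chromosome the interval is truncated to valid coordinates and the
#' out-of-bounds amount is reported as `left_pad` / `right_pad`; a sequence
#' consumer pads with Ns. The invariant `(end - start) + left_pad + right_pad
#' == target_len` always holds. This is the geometry used for fixed-length
#' sequence-model inputs (e.g. 4096-bp chromatin-profile windows).
#'
#' @param peaks data.frame with `chrom`, `summit` (absolute bp).
#' @param target_len positive integer window size.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return data.frame `chrom`, `start`, `end`, `left_pad`, `right_pad`.
#' @export
resize_on_summit <- function(peaks, target_len, chrom_sizes) {
  stopifnot(is.data.frame(peaks), all(c("chrom", "summit") %in% names(peaks)),
            length(target_len) == 1, target_len >= 1)
  len <- unname(chrom_sizes[peaks$chrom])
  if (nrow(peaks) > 0 && anyNA(len)) stop("chromosome missing from sizes")
  half <- floor(target_len / 2)
  raw_start <- peaks$summit - half
  raw_end <- raw_start + target_len
  start <- pmax(0, raw_start)
  end <- pmin(len, raw_end)
  data.frame(
    chrom = peaks$chrom,
    start = as.integer(start),
    end = as.integer(end),
    left_pad = as.integer(start - raw_start),
    right_pad = as.integer(raw_end - end),
    stringsAsFactors = FALSE
  )
}

.as_iranges <- function(intervals) {
  # 0-based half-open -> IRanges 1-based closed
  IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
}

#' Merge overlapping labelled intervals
#'
#' Groups intervals into merged regions by chains of >= 1 bp overlap on the
#' same chromosome. Half-open abutment (`end == start`) is a 0-bp overlap and
#' does not merge. Each merged region carries the union of the labels of its
#' contributing intervals.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param labels character vector, one label per interval (recycled if length 1).
#' @return data.frame `chrom`, `start`, `end`, plus a list-column `labels`
#'   (sorted unique contributing labels) and `n_members`.
#' @export
merge_labeled <- function(intervals, labels = rep("x", nrow(intervals))) {
  check_intervals(intervals)
  labels <- rep_len(as.character(labels), nrow(intervals))
  if (nrow(intervals) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_members = integer())[, , drop = FALSE])
  }
  out <- lapply(split(seq_len(nrow(intervals)), intervals$chrom), function(idx) {
    ir <- .as_iranges(intervals[idx, , drop = FALSE])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    lab_by_region <- split(labels[idx][S4Vectors::queryHits(hit)],
                           S4Vectors::subjectHits(hit))
    members <- tabulate(S4Vectors::subjectHits(hit), nbins = length(red))
    data.frame(
      chrom = intervals$chrom[idx[1]],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      n_members = members,
      labels = I(unname(lapply(lab_by_region, function(l) sort(unique(l))))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Distance to the nearest transcription start site
#'
#' For each query point, the minimum absolute distance to any TSS on the same
#' chromosome. Errors if a query chromosome carries no annotated gene.
#'
#' @param chrom,pos vectors of query chromosome names and bp positions.
#' @param genes data.frame with `chrom`, `tss`.
#' @return integer vector of distances (0 if the point is a TSS).
#' @export
nearest_tss_distance <- function(chrom, pos, genes) {
  stopifnot(length(chrom) == length(pos))
  out <- integer(length(pos))
  tss_by_chrom <- split(genes$tss, genes$chrom)
  for (ch in unique(chrom)) {
    tss <- tss_by_chrom[[ch]]
    if (is.null(tss) || length(tss) == 0) stop("no annotated TSS on chromosome ", ch)
    sel <- which(chrom == ch)
    tss <- sort(tss)
    # nearest via findInterval on the sorted TSS vector
    i <- findInterval(pos[sel], tss)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(tss))
    d <- pmin(abs(pos[sel] - tss[lo]), abs(pos[sel] - tss[hi]))
    out[sel] <- as.integer(d)
  }
  out
}

#' Promoter intervals for a gene annotation
#'
#' Uses annotated `promoter_start` / `promoter_end` when present and finite;
#' otherwise defaults to TSS +/- `flank` bp (clamped at 0). The +/- 500 bp
#' default is a package convention, configurable everywhere it is consumed.
#'
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `tss`, ...).
#' @param flank default promoter half-width in bp.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_intervals <- function(genes, flank = 500L) {
  ps <- if ("promoter_start" %in% names(genes)) genes$promoter_start else rep(NA_real_, nrow(genes))
  pe <- if ("promoter_end" %in% names(genes)) genes$promoter_end else rep(NA_real_, nrow(genes))
  use_default <- is.na(ps) | is.na(pe)
  ps[use_default] <- pmax(0, genes$tss[use_default] - flank)
  pe[use_default] <- genes$tss[use_default] + flank
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(ps), end = as.integer(pe),
             stringsAsFactors = FALSE)
}

#' Classify CREs as promoter / genic enhancer / intergenic enhancer
#'
#' Fixed priority: an interval overlapping any gene promoter is `promoter`;
#' otherwise one overlapping any gene body (`gene_start`/`gene_end` columns,
#' when annotated) is `genic_enhancer`; everything else is
#' `intergenic_enhancer`.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param genes gene annotation; optional columns `promoter_start`,
#'   `promoter_end`, `gene_start`, `gene_end`.
#' @param promoter_flank default promoter half-width when not annotated.
#' @return character vector of classes, one per interval.
#' @export
classify_cre <- function(intervals, genes, promoter_flank = 500L) {
  check_intervals(intervals)
  if (nrow(intervals) == 0) return(character())
  prom <- promoter_intervals(genes, flank = promoter_flank)
  hit_prom <- .overlaps_any(intervals, prom)
  hit_body <- rep(FALSE, nrow(intervals))
  if (all(c("gene_start", "gene_end") %in% names(genes))) {
    body <- data.frame(chrom = genes$chrom, start = genes$gene_start,
                       end = genes$gene_end, stringsAsFactors = FALSE)
    body <- body[!is.na(body$start) & !is.na(body$end) & body$end > body$start, , drop = FALSE]
    if (nrow(body)) hit_body <- .overlaps_any(intervals, body)
  }
  ifelse(hit_prom, "promoter", ifelse(hit_body, "genic_enhancer", "intergenic_enhancer"))
}

# TRUE for each query interval overlapping (>= 1 bp) any subject on same chrom
.overlaps_any <- function(query, subject) {
  out <- rep(FALSE, nrow(query))
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::overlapsAny(.as_iranges(query[qi, , drop = FALSE]),
                                 .as_iranges(subject[si, , drop = FALSE]),
                                 minoverlap = 1L)
    out[qi] <- hits
  }
  out
}

#' Which points fall inside at least one interval
#'
#' @param chrom,pos 0-based point positions.
#' @param intervals data.frame with `chrom`, `start`, `end` (half-open).
#' @return logical vector.
#' @export
points_in_intervals <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  q <- data.frame(chrom = chrom, start = pos, end = pos + 1L, stringsAsFactors = FALSE)
  .overlaps_any(q, intervals)
}
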