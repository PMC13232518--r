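# Shared synthetic fixtures, built once per test run.

tiny_sizes <- c(chr1 = 1e6, chr2 = 1e6)

tiny_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "-", "+", "+"),
    tss = c(100000L, 600000L, 200000L, 700000L),
    gene_start = c(100000L, 580000L, 200000L, 700000L),
    gene_end = c(130000L, 600001L, 240000L, 725000L),
    stringsAsFactors = FALSE
  )
}

tiny_peaks <- function() {
  data.frame(
    peak_id = paste0("p", 1:6),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(95000L, 150000L, 590000L, 190000L, 400000L, 710000L),
    end = c(95600L, 150400L, 590700L, 190500L, 400800L, 710300L),
    summit = c(95300L, 150200L, 590350L, 190250L, 400400L, 710150L),
    read_count = c(50, 120, 80, 200, 10, 65),
    stringsAsFactors = FALSE
  )
}

# moderately sized simulated study shared by several test files
shared_cfg <- sim_config(seed = 101L, n_peaks = 300L, n_genes = 30L)
shared_world <- sim_world(shared_cfg)
shared_pd <- sim_pair_data(shared_world, shared_cfg)

# brute-force AUPRC: iterate every distinct threshold explicitly
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_r <- 0
  area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    p <- tp / (tp + fp)
    r <- tp / n_pos
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# union-find merge oracle over pairwise >= 1 bp overlap tests
oracle_merge <- function(intervals) {
  n <- nrow(intervals)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && intervals$chrom[i] == intervals$chrom[j] &&
        max(intervals$start[i], intervals$start[j]) <
        min(intervals$end[i], intervals$end[j])) {
      parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  split(seq_len(n), comp)
}

# exhaustive one-sided Fisher p by fixed-margin table enumeration
oracle_fisher <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1.0)
  p <- 0
  for (aa in max(0, row1 + col1 - n):min(row1, col1)) {
    if (aa >= a) {
      p <- p + choose(col1, aa) * choose(n - col1, row1 - aa) / choose(n, row1)
    }
  }
  p
}

# all set partitions of n elements, as membership vectors (restricted
# growth strings); n <= 10 only
partitions_of <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in 1:(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(1L, 1L)
  out
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}
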