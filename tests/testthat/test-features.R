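test_that("select_candidates keeps top peaks plus one promoter per gene", {
  genes <- tiny_genes()
  out <- select_candidates(tiny_peaks(), genes, tiny_sizes, n_top = 3)
  expect_equal(sum(out$source == "dnase_peak"), 3)
  expect_equal(sum(out$source == "promoter"), 4)
  # retained peaks dominate discarded ones by read count
  expect_setequal(out$cre_id[out$source == "dnase_peak"], c("p4", "p2", "p3"))
  # all peak CREs are 500 bp
  expect_true(all(out$end[out$source == "dnase_peak"] -
                    out$start[out$source == "dnase_peak"] == 500))
})

test_that("candidate ranking breaks read-count ties by (chrom, start)", {
  pk <- tiny_peaks()
  pk$read_count <- 7  # all tied
  out <- select_candidates(pk, tiny_genes(), tiny_sizes, n_top = 2)
  kept <- out$cre_id[out$source == "dnase_peak"]
  expect_equal(kept, c("p1", "p2"))  # chr1 ascending start
})

test_that("top-n selection matches a sort oracle on random peaks", {
  set.seed(9)
  n <- 1000
  pk <- data.frame(peak_id = paste0("q", 1:n), chrom = "chr1",
                   start = seq(1000, by = 900, length.out = n))
  pk$end <- pk$start + 600L
  pk$summit <- pk$start + 300L
  pk$read_count <- round(runif(n, 0, 1e4), 1)
  out <- select_candidates(pk, tiny_genes()[1, ], c(chr1 = 1e6 + n * 900), n_top = 150)
  kept <- out$read_count[out$source == "dnase_peak"]
  discarded <- setdiff(pk$read_count, kept)
  expect_equal(length(kept), 150)
  expect_true(min(kept) >= max(discarded))
})

test_that("enumerate_pairs applies the inclusive same-chromosome window", {
  cres <- data.frame(cre_id = c("c1", "c2"), chrom = c("chr1", "chr2"),
                     start = c(0L, 0L), end = c(500L, 500L))
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr1"),
                      strand = "+", tss = c(5000250L, 5000251L))
  p <- enumerate_pairs(cres, genes, window = 5e6)
  # c1 midpoint 250: distance to g1 exactly 5,000,000 (included), g2 excluded
  expect_equal(p$gene_id, "g1")
  expect_equal(p$distance, 5000000L)
  # cross-chromosome pairs never appear
  expect_false("c2" %in% p$cre_id)
})

test_that("enumerate_pairs matches all-pairs brute force and is window-monotone", {
  cres <- shared_pd$cres
  genes <- shared_world$genes
  for (w in c(2e5, 8e5)) {
    got <- enumerate_pairs(cres, genes, window = w)
    mid <- interval_midpoint(cres$start, cres$end)
    want <- 0L
    for (i in seq_len(nrow(cres))) for (j in seq_len(nrow(genes))) {
      if (cres$chrom[i] == genes$chrom[j] && abs(mid[i] - genes$tss[j]) <= w)
        want <- want + 1L
    }
    expect_equal(nrow(got), want)
  }
  n_small <- nrow(enumerate_pairs(cres, genes, window = 1e5))
  n_big <- nrow(enumerate_pairs(cres, genes, window = 1e6))
  expect_lte(n_small, n_big)
})

test_that("abc_score normalises per gene and matches an explicit loop", {
  pairs <- data.frame(cre_id = c("a", "b", "c"), gene_id = c("g", "g", "h"))
  act <- data.frame(cre_id = c("a", "b", "c"), dnase = c(9, 1, 4), h3k27ac = c(1, 1, 4))
  ct <- data.frame(cre_id = c("a", "b", "c"), gene_id = c("g", "g", "h"),
                   contact = c(1, 1, 2))
  s <- abc_score(pairs, act, ct)
  # A = {3, 1, 4}; gene g: {3,1}/4 -> 0.75/0.25; gene h alone -> 1
  expect_equal(s, c(0.75, 0.25, 1))
  # random instance vs loop oracle; per-gene sums are 1
  set.seed(21)
  pairs <- expand.grid(cre_id = paste0("e", 1:20), gene_id = paste0("g", 1:3),
                       stringsAsFactors = FALSE)
  act <- data.frame(cre_id = paste0("e", 1:20), dnase = runif(20, 1, 50),
                    h3k27ac = runif(20, 1, 50))
  ct <- data.frame(cre_id = pairs$cre_id, gene_id = pairs$gene_id,
                   contact = runif(60, 0.01, 2))
  s <- abc_score(pairs, act, ct)
  A <- sqrt(act$dnase * act$h3k27ac)[match(pairs$cre_id, act$cre_id)]
  for (g in unique(pairs$gene_id)) {
    idx <- which(pairs$gene_id == g)
    prod <- A[idx] * ct$contact[match(paste(pairs$cre_id[idx], g),
                                      paste(ct$cre_id, ct$gene_id))]
    expect_equal(s[idx], prod / sum(prod))
    expect_equal(sum(s[idx]), 1)
  }
  # invariance to uniform per-gene contact rescaling
  ct2 <- ct; ct2$contact <- ct2$contact * 13
  expect_equal(abc_score(pairs, act, ct2), s)
})

test_that("abc_score zero-activity genes score 0 with a warning", {
  pairs <- data.frame(cre_id = "a", gene_id = "g")
  act <- data.frame(cre_id = "a", dnase = 0, h3k27ac = 5)
  ct <- data.frame(cre_id = "a", gene_id = "g", contact = 1)
  expect_warning(s <- abc_score(pairs, act, ct), "zero total")
  expect_equal(s, 0)
})

test_that("orientation averaging and ensembling behave as arithmetic means", {
  expect_equal(average_orientations(0.4, 0.6), 0.5)
  expect_equal(average_orientations(1.3, 1.3), 1.3)
  expect_error(average_orientations(Inf, 1), "non-finite")
  set.seed(3)
  f <- rnorm(100); r <- rnorm(100)
  expect_equal(average_orientations(f, r), vapply(1:100, function(i) mean(c(f[i], r[i])), 1))
  # ensemble mean equals explicit sum/10 and warns on short ensembles
  sc <- data.frame(cre_id = rep(c("x", "y"), each = 10), value = rnorm(20))
  em <- ensemble_mean(sc)
  expect_equal(em$value, c(sum(sc$value[1:10]) / 10, sum(sc$value[11:20]) / 10))
  expect_warning(em2 <- ensemble_mean(data.frame(cre_id = "z", value = c(0, 1))),
                 "fewer than")
  expect_equal(em2$value, 0.5)
  expect_error(ensemble_mean(data.frame(cre_id = character(), value = numeric())),
               "no predictions")
})

test_that("duplicate feature columns collapse to row means", {
  x <- data.frame(a1 = c(0.2, 1), a2 = c(0.4, 3), b = c(5, 6))
  out <- collapse_duplicate_columns(x, c("A", "A", "B"))
  expect_equal(names(out), c("A", "B"))
  expect_equal(out$A, c(0.3, 2))
  expect_equal(out$B, x$b)
  # identity for singleton groups; loop oracle at scale
  set.seed(8)
  m <- as.data.frame(matrix(runif(5000), ncol = 5))
  gr <- c("f", "f", "g", "g", "g")
  got <- collapse_duplicate_columns(m, gr)
  expect_equal(got$f, apply(m[, 1:2], 1, mean))
  expect_equal(got$g, apply(m[, 3:5], 1, mean))
})

test_that("assemble_features joins, imputes medians and flags missingness", {
  pairs <- data.frame(cre_id = c("a", "b", "c"), gene_id = "g",
                      distance = c(100L, 200L, 300L))
  mpra <- data.frame(cre_id = c("a", "b"), value = c(1.5, 0.5))  # c missing
  sei <- data.frame(cre_id = c("a", "b", "c"), k27 = c(0.1, 0.2, 0.9))
  fx <- assemble_features(pairs, mpra = mpra, sei = sei, check_keys = FALSE)
  X <- fx$matrix
  expect_equal(X$mpra_activity[X$cre_id == "c"], 1.0)  # median of {1.5, 0.5}
  expect_equal(X$missing_mpralegnet, c(0, 0, 1))
  expect_equal(unname(fx$manifest["sei_k27"]), "sei")
  expect_true(all(is.finite(as.matrix(X[, -(1:2)]))))
  # unknown keys error with offenders listed
  expect_error(assemble_features(pairs, mpra = data.frame(cre_id = "zz", value = 1)),
               "zz")
  # order invariance after canonical sort
  perm <- c(3, 1, 2)
  fx2 <- assemble_features(pairs[perm, ], mpra = mpra, sei = sei, check_keys = FALSE)
  expect_identical(fx2$matrix, fx$matrix)
})

test_that("feature matrices round-trip with their manifest", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features(shared_pd$features, f)
  back <- read_features(f)
  expect_equal(back$matrix$abc_score, shared_pd$features$matrix$abc_score)
  expect_equal(back$manifest, shared_pd$features$manifest)
})
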