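test_that("merged regions record condition membership and specificity", {
  sets <- list(
    K = data.frame(chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1400L)),
    H = data.frame(chrom = "chr1", start = 400L, end = 900L)
  )
  r <- build_merged_regions(sets)
  expect_equal(nrow(r), 2)
  agn <- r[r$start == 0, ]
  expect_equal(agn$specificity, "condition_agnostic")
  expect_equal(agn$conditions, "H,K")
  expect_equal(r$specificity[r$start == 1000], "condition_specific")
  # labels match the union-find oracle on random CREs
  set.seed(50)
  sets <- lapply(1:3, function(i) {
    d <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                    start = sample(0:50000, 200))
    d$end <- d$start + sample(100:800, 200, TRUE)
    d
  })
  names(sets) <- c("A", "B", "C")
  r <- build_merged_regions(sets)
  allint <- do.call(rbind, lapply(names(sets), function(n) {
    cbind(sets[[n]], cond = n)
  }))
  comps <- oracle_merge(allint)
  want_lab <- sort(unname(vapply(comps, function(idx)
    paste(sort(unique(allint$cond[idx])), collapse = ","), "")))
  expect_equal(sort(r$conditions), want_lab)
  expect_equal(r$specificity == "condition_specific", !grepl(",", r$conditions))
})

test_that("TF presence is idempotent and restricted to network CREs", {
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(0L, 1000L), end = c(500L, 1500L),
                        conditions = "K",
                        specificity = c("condition_specific", "condition_agnostic"))
  cres <- data.frame(cre_id = c("c1", "c2"), chrom = "chr1",
                     start = c(100L, 1100L), end = c(300L, 1300L))
  hits <- data.frame(tf_name = c("GATA1", "GATA1", "TAL1"),
                     sequence_name = c("c1", "c1", "c2"),
                     start = 1L, stop = 10L, strand = "+", score = 15,
                     p_value = 1e-6)
  pres <- tf_presence(regions, hits, cres)
  expect_true(pres["r1", "GATA1"])   # two hits, still one presence
  expect_false(pres["r1", "TAL1"])
  expect_true(pres["r2", "TAL1"])
  # hit keyed to an unknown CRE errors
  bad <- hits; bad$sequence_name[1] <- "zz"
  expect_error(tf_presence(regions, bad, cres), "zz")
})

test_that("one-sided Fisher p equals exhaustive fixed-margin enumeration", {
  expect_equal(fisher_one_sided(3, 1, 1, 3), 17 / 70)
  expect_equal(fisher_one_sided(0, 0, 0, 0), 1.0)
  # a at its maximum given margins -> probability of the single extreme table
  expect_equal(fisher_one_sided(4, 0, 0, 4), 1 / choose(8, 4))
  set.seed(52)
  for (i in 1:120) {
    tot <- sample(4:40, 1)
    cells <- as.vector(rmultinom(1, tot, runif(4)))
    expect_equal(fisher_one_sided(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  # agrees with fisher.test as an independent implementation
  expect_equal(fisher_one_sided(7, 2, 3, 8),
               fisher.test(matrix(c(7, 3, 2, 8), 2), alternative = "greater")$p.value)
})

test_that("continuity-corrected log2 odds ratio is finite and monotone in its cells", {
  expect_equal(log2_or_cc(5, 5, 5, 5), 0)
  expect_equal(log2_or_cc(1, 0, 0, 1), log2(9))
  for (a in 0:4) for (b in 0:4) for (c_ in 0:4) for (d in 0:4) {
    v <- log2_or_cc(a, b, c_, d)
    expect_true(is.finite(v))
    # strictly increasing in the concordant cells, decreasing in discordant
    expect_gt(log2_or_cc(a + 1, b, c_, d), v)
    expect_gt(log2_or_cc(a, b, c_, d + 1), v)
    expect_lt(log2_or_cc(a, b + 1, c_, d), v)
    expect_lt(log2_or_cc(a, b, c_ + 1, d), v)
  }
  # balanced tables with a common odds ratio recover its log2 approximately
  expect_equal(log2_or_cc(40, 10, 10, 40), log2(16), tolerance = 0.05)
})

test_that("BH adjustment matches the textbook step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(53)
  for (i in 1:30) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  # sorted output is monotone non-decreasing
  p <- runif(40)
  f <- bh_fdr(p)
  expect_true(all(diff(f[order(p)]) >= -1e-12))
})

test_that("hypergeometric enrichment equals combinatorial enumeration", {
  expect_equal(hypergeom_gene_enrichment(10, 5, 4, 0), 1.0)
  expect_equal(hypergeom_gene_enrichment(10, 5, 4, 3), 55 / 210)
  # x at its maximum: single most-extreme term
  expect_equal(hypergeom_gene_enrichment(10, 5, 4, 4),
               choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_error(hypergeom_gene_enrichment(10, 5, 4, 5), "exceeds")
  # point masses over the support sum to one
  M <- 30; n <- 12; k <- 9
  mass <- sum(vapply(0:min(n, k), function(x)
    choose(n, x) * choose(M - n, k - x) / choose(M, k), 1))
  expect_equal(mass, 1, tolerance = 1e-12)
  # the survival function agrees with direct tail summation on random cases
  set.seed(54)
  for (i in 1:50) {
    M <- sample(10:60, 1); n <- sample(1:M, 1); k <- sample(1:M, 1)
    x <- sample(0:min(n, k), 1)
    tail <- sum(vapply(x:min(n, k), function(xx)
      choose(n, xx) * choose(M - n, k - xx) / choose(M, k), 1))
    expect_equal(hypergeom_gene_enrichment(M, n, k, x), tail, tolerance = 1e-10)
  }
})

test_that("gene_set_enrichment intersects sets with the background", {
  bg <- paste0("g", 1:50)
  gs <- c(paste0("g", 1:10), "not_in_background")
  net_genes <- paste0("g", c(1:8, 20:30))
  r <- gene_set_enrichment(net_genes, gs, bg)
  expect_equal(r$M, 50); expect_equal(r$n, 10)
  expect_equal(r$k, 19); expect_equal(r$x, 8)
  expect_equal(r$p, hypergeom_gene_enrichment(50, 10, 19, 8))
})

test_that("planted motif odds ratios are recovered by the enrichment table", {
  set.seed(56)
  regions <- data.frame(
    region_id = paste0("r", 1:600), chrom = "chr1",
    start = seq(0, by = 1000, length.out = 600))
  regions$end <- regions$start + 500L
  regions$conditions <- "K"
  regions$specificity <- sample(c("condition_specific", "condition_agnostic"),
                                600, TRUE)
  hits <- sim_motif_hits(regions, paste0("TF", 1:8),
                         planted_or = c(TF1 = 8), background_rate = 0.2,
                         seed = 57)
  cres <- data.frame(cre_id = regions$region_id, chrom = regions$chrom,
                     start = regions$start, end = regions$end)
  enr <- motif_enrichment(regions, hits, cres)
  expect_equal(enr$tf_name[1], "TF1")   # planted TF ranks first by FDR
  expect_lt(enr$fdr[1], 0.01)
  # its continuity-corrected effect size is near log2(8)
  expect_equal(enr$log2_or_cc[enr$tf_name == "TF1"], log2(8), tolerance = 0.8)
  # counts are a true partition of the region set
  expect_true(all(enr$a + enr$b + enr$c + enr$d == 600))
})
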