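test_that("observed variant overlap counts unique variants once", {
  cres <- data.frame(chrom = "chr1", start = c(100L, 150L), end = c(200L, 250L))
  # 1-based pos 101 = 0-based 100 = CRE start: counts
  v <- data.frame(chrom = "chr1", pos0 = 100L, id = "rs1")
  expect_equal(observed_variant_overlap(v, cres), 1L)
  # one variant inside two overlapping CREs counts once
  v2 <- data.frame(chrom = "chr1", pos0 = 180L, id = "rs2")
  expect_equal(observed_variant_overlap(v2, cres), 1L)
  # brute-force double loop on random data
  set.seed(40)
  cres <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                     start = sample(0:9e4, 100))
  cres$end <- cres$start + sample(50:500, 100, TRUE)
  v <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                  pos0 = sample(0:1e5, 1000, TRUE),
                  id = paste0("rs", 1:1000))
  want <- 0L
  for (i in 1:1000) {
    hit <- any(cres$chrom == v$chrom[i] & cres$start <= v$pos0[i] &
                 v$pos0[i] < cres$end)
    want <- want + hit
  }
  expect_equal(observed_variant_overlap(v, cres), want)
})

test_that("match-index binning is half-open with boundary-bin clamping", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 0L)
  pk <- data.frame(peak_id = c("a", "b", "c"), chrom = "chr1",
                   start = c(0L, 100L, 1000L), end = c(50L, 200L, 1500L))
  idx <- build_match_index(pk, genes, len_edges = c(0, 100, 600),
                           dist_edges = c(0, 500, 2000))
  # length exactly on the interior edge (100) falls in the right-hand bin
  expect_equal(idx$peaks$len_bin, c(1L, 2L, 2L))
  # out-of-range value clamps to boundary bin rather than erroring
  pk2 <- data.frame(peak_id = "z", chrom = "chr1", start = 0L, end = 10000L)
  idx2 <- build_match_index(pk2, genes, len_edges = c(0, 100, 600),
                            dist_edges = c(0, 500, 2000))
  expect_equal(idx2$peaks$len_bin, 2L)
  expect_error(build_match_index(pk, genes, len_edges = c(5, 5, 6)),
               "strictly increasing")
})

test_that("matched sampling uses the exact bin, then Chebyshev relaxation", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 0L)
  pk <- data.frame(peak_id = c("near_small", "far_big"), chrom = "chr1",
                   start = c(100L, 50000L), end = c(200L, 50400L))
  idx <- build_match_index(pk, genes, len_edges = c(0, 150, 600),
                           dist_edges = c(0, 1000, 100000))
  # query in near_small's bin: relaxation 0, that peak returned
  q <- data.frame(chrom = "chr1", start = 120L, end = 230L)
  s <- sample_matched(idx, q, genes)
  expect_equal(s$peak$id, "near_small")
  expect_equal(s$relaxation, 0L)
  # query whose exact bin is empty (small length, far away): relaxed
  q2 <- data.frame(chrom = "chr1", start = 60000L, end = 60100L)
  s2 <- sample_matched(idx, q2, genes)
  expect_gte(s2$relaxation, 1L)
  # unknown chromosome errors
  expect_error(matched_pools(idx, data.frame(chrom = "chrZ", start = 1L, end = 2L),
                             genes), "no candidate peak")
})

test_that("draws within a pool are uniform", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+", tss = 0L)
  pk <- data.frame(peak_id = c("a", "b", "c"), chrom = "chr1",
                   start = c(100L, 300L, 500L), end = c(200L, 400L, 600L))
  idx <- build_match_index(pk, genes, len_edges = c(0, 1000),
                           dist_edges = c(0, 10000))
  q <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  mp <- matched_pools(idx, q, genes)
  expect_equal(sort(mp$pools[[1]]), 1:3)
  set.seed(55)
  draws <- replicate(9000, sample_matched(idx, q, genes)$peak$id)
  counts <- table(draws)
  # binomial 4-sigma band around 3000
  expect_true(all(abs(counts - 3000) < 4 * sqrt(9000 * (1 / 3) * (2 / 3))))
})

test_that("empirical p-values follow the +1-corrected counting rule", {
  # null {1,2,3,4}, observed 3 -> (2 + 1) / 5
  r <- egnet:::.perm_result(3L, c(1L, 2L, 3L, 4L), 4L, 1L, 0L)
  expect_equal(r$p_empirical, 0.6)
  expect_equal(r$fold_enrichment, 3 / 2.5)
  # observed above every null value at n_perm = 1000 -> floor 1/1001
  r2 <- egnet:::.perm_result(50L, rep(1L, 1000), 1000L, 1L, 0L)
  expect_equal(r2$p_empirical, 1 / 1001)
  # every null >= observed -> p = 1
  r3 <- egnet:::.perm_result(1L, rep(5L, 100), 100L, 1L, 0L)
  expect_equal(r3$p_empirical, 1.0)
})

test_that("the variant permutation test is seed-stable and well-formed", {
  w <- shared_world
  set.seed(61)
  net_ids <- sample(w$peaks$peak_id, 60)
  net_cres <- w$peaks[w$peaks$peak_id %in% net_ids, c("chrom", "start", "end")]
  v <- sim_variants(w, net_ids, planted_fe = 2, n_variants = 250, seed = 62)
  r1 <- permutation_test_variants(v, net_cres, w$peaks, w$genes,
                                  n_perm = 100, seed = 9)
  r2 <- permutation_test_variants(v, net_cres, w$peaks, w$genes,
                                  n_perm = 100, seed = 9)
  expect_identical(r1, r2)
  expect_true(r1$p_empirical >= 1 / 101 && r1$p_empirical <= 1)
  expect_equal(length(r1$null_values), 100)
  expect_gt(r1$fold_enrichment, 1)  # planted enrichment detected
})

test_that("eQTL concordance counts unique pairs supported by network edges", {
  edges <- data.frame(cre_id = c("e1", "e2"), cre_chrom = "chr1",
                      cre_start = c(100L, 500L), cre_end = c(200L, 600L),
                      cre_class = "intergenic_enhancer",
                      gene_id = c("gX", "gY"), score = 0.9)
  net <- structure(list(edges = edges, threshold = 0.5), class = "eg_network")
  # variant in e1 but target gene not linked by e1 -> not counted
  e <- data.frame(chrom = "chr1", pos0 = 150L, id = "rs1", gene_id = "gY")
  expect_equal(observed_eqtl_concordance(e, net), 0L)
  # pair supported via two CREs counts once
  edges2 <- rbind(edges,
                  data.frame(cre_id = "e3", cre_chrom = "chr1", cre_start = 120L,
                             cre_end = 260L, cre_class = "intergenic_enhancer",
                             gene_id = "gX", score = 0.8))
  net2 <- structure(list(edges = edges2, threshold = 0.5), class = "eg_network")
  e2 <- data.frame(chrom = "chr1", pos0 = 150L, id = "rs1", gene_id = "gX")
  expect_equal(observed_eqtl_concordance(e2, net2), 1L)
  # brute-force triple loop on random data
  set.seed(45)
  edges3 <- data.frame(cre_id = paste0("e", 1:30), cre_chrom = "chr1",
                       cre_start = sample(seq(0, 29000, by = 1000), 30))
  edges3$cre_end <- edges3$cre_start + 400L
  edges3$cre_class <- "intergenic_enhancer"
  edges3$gene_id <- sample(paste0("g", 1:10), 30, TRUE)
  edges3$score <- 0.9
  net3 <- structure(list(edges = edges3, threshold = 0.5), class = "eg_network")
  eq <- data.frame(chrom = "chr1", pos0 = sample(0:30000, 200, TRUE),
                   id = paste0("rs", 1:200),
                   gene_id = sample(paste0("g", 1:10), 200, TRUE))
  want <- 0L
  for (i in 1:200) {
    hit <- FALSE
    for (j in 1:30) {
      if (edges3$cre_start[j] <= eq$pos0[i] && eq$pos0[i] < edges3$cre_end[j] &&
          edges3$gene_id[j] == eq$gene_id[i]) hit <- TRUE
    }
    want <- want + hit
  }
  expect_equal(observed_eqtl_concordance(eq, net3), want)
})

test_that("identity sampling makes the eQTL permutation degenerate at p = 1", {
  # universe where every (chrom, class, bins, n_targets) cell is a singleton:
  # each sampled CRE is itself, so every null equals the observed statistic
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      tss = c(0L, 90000L), gene_start = NA, gene_end = NA)
  cres <- data.frame(cre_id = c("e1", "e2"), chrom = "chr1",
                     start = c(1000L, 50000L), end = c(1400L, 50900L))
  pred <- data.frame(cre_id = c("e1", "e2"), gene_id = c("g1", "g2"),
                     score = c(0.9, 0.8))
  cls <- c(e1 = "intergenic_enhancer", e2 = "intergenic_enhancer")
  net <- build_eg_network(pred, threshold = 0.5,
                          cres = cbind(cres, owner_gene = NA), cre_class = cls)
  eq <- data.frame(chrom = "chr1", pos0 = c(1100L, 50100L), id = c("r1", "r2"),
                   gene_id = c("g1", "g2"))
  r <- permutation_test_eqtl(eq, net, cres, genes, predicted = pred,
                             cre_class = cls, n_perm = 50, seed = 3,
                             len_edges = c(0, 600, 2000),
                             dist_edges = c(0, 10000, 100000))
  expect_true(all(r$null_values == r$observed))
  expect_equal(r$p_empirical, 1.0)
})

test_that("planted eQTL concordance is detected against the matched null", {
  cfg <- sim_config(seed = 71L, n_peaks = 300L, n_genes = 30L,
                    concordance_rate = 0.4)
  w <- sim_world(cfg)
  pd <- sim_pair_data(w, cfg)
  m <- train_eg_model(pd$features, pd$labels, C = 1)
  s <- predict(m, pd$features)
  scored <- data.frame(cre_id = pd$features$matrix$cre_id,
                       gene_id = pd$features$matrix$gene_id, score = s)
  cls <- setNames(classify_cre(pd$cres, w$genes), pd$cres$cre_id)
  net <- build_eg_network(scored, threshold = 0.5, cres = pd$cres,
                          cre_class = cls)
  eq <- sim_eqtls(w, net, concordance_rate = cfg$concordance_rate,
                  n_eqtls = 250, config = cfg)
  r <- permutation_test_eqtl(eq, net, pd$cres, w$genes, predicted = scored,
                             cre_class = cls, n_perm = 100, seed = 5,
                             n_bins = 3)
  expect_gt(r$fold_enrichment, 1)
  expect_lte(r$p_empirical, 0.05)
  # a sampled CRE with zero above-threshold targets contributes no pairs:
  # reflected in null values never exceeding the eQTL count
  expect_true(all(r$null_values <= nrow(eq)))
})
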