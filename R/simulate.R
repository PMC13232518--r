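# Seeded synthetic-data generators. Every pipeline input can be produced
# with planted, parameterised statistical structure: a known logistic model
# behind the CRISPRi labels, a known fold enrichment behind the variant
# sets, a known concordance rate behind the eQTLs, and a known odds ratio
# behind the motif hits. All randomness flows from one top-level seed via
# fixed stream offsets (world +0, pair data +1, variants +2, eQTLs +3,
# motif hits +4), so individual generators are reproducible in isolation.

#' Fixture configuration
#'
#' @param seed top-level integer seed.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes,n_peaks counts over the whole genome.
#' @param peak_meanlog,peak_sdlog log-normal peak-length parameters.
#' @param read_shape,read_scale gamma read-count parameters.
#' @param gamma contact distance-decay exponent (> 0; 0 gives flat contact).
#' @param d0 contact distance offset in bp.
#' @param contact_noise sd of multiplicative log-normal contact noise.
#' @param beta named numeric vector of planted logistic coefficients over
#'   feature columns (defaults plant signal on `mpra_activity`, two
#'   pair-level features `f1`, `f2`, and one chromatin column
#'   `sei_planted`).
#' @param intercept logistic intercept (controls link prevalence).
#' @param label_noise probability a true-link label is flipped.
#' @param n_variants variant count; @param planted_fe planted variant fold
#'   enrichment; @param concordance_rate fraction of eQTLs concordant with
#'   planted links.
#' @param motif_or planted motif odds ratio; @param motif_background
#'   background motif presence rate.
#' @return list of class `eg_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 2e6,
                       n_genes = 40L, n_peaks = 400L,
                       peak_meanlog = log(350), peak_sdlog = 0.3,
                       read_shape = 2, read_scale = 50,
                       gamma = 1, d0 = 5000, contact_noise = 0.3,
                       beta = c(mpra_activity = 0.9, f1 = 0.8, f2 = -0.6,
                                sei_planted = 0.7),
                       intercept = -2.5, label_noise = 0.05,
                       n_variants = 300L, planted_fe = 1,
                       concordance_rate = 0.3,
                       motif_or = 8, motif_background = 0.15) {
  cfg <- as.list(environment())
  stopifnot(cfg$gamma >= 0, cfg$label_noise >= 0, cfg$label_noise <= 1,
            cfg$planted_fe >= 1, cfg$concordance_rate >= 0,
            cfg$concordance_rate <= 1, cfg$motif_or > 0)
  structure(cfg, class = "eg_sim_config")
}

#' Simulate chromosome sizes, genes and DNase peaks
#'
#' Genes get uniform-random TSSs with gene bodies extending 5-50 kb
#' downstream; peaks get log-normal lengths and gamma read counts, placed in
#' disjoint slots along each chromosome so peaks never overlap (planted
#' overlap structure stays exact).
#'
#' @param config an `eg_sim_config`.
#' @return list `chrom_sizes` (named vector), `genes`, `peaks`
#'   (data.frames).
#' @export
sim_world <- function(config) {
  cfg <- config
  .with_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    chrom_sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
    per_chrom_g <- rep_len(ceiling(cfg$n_genes / cfg$n_chroms), cfg$n_chroms)
    genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      ng <- per_chrom_g[ci]
      tss <- sort(sample.int(cfg$chrom_length - 60000L, ng) + 5000L)
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      blen <- sample(5000:50000, ng, replace = TRUE)
      gs <- ifelse(strand == "+", tss, pmax(0, tss - blen))
      ge <- ifelse(strand == "+", pmin(cfg$chrom_length, tss + blen), tss + 1L)
      data.frame(gene_id = sprintf("g%s_%03d", ci, seq_len(ng)),
                 chrom = chroms[ci], strand = strand, tss = tss,
                 gene_start = as.integer(gs), gene_end = as.integer(ge),
                 stringsAsFactors = FALSE)
    }))
    empty_peaks <- data.frame(peak_id = character(), chrom = character(),
                              start = integer(), end = integer(),
                              summit = integer(), read_count = numeric(),
                              stringsAsFactors = FALSE)
    per_chrom_p <- rep_len(ceiling(cfg$n_peaks / cfg$n_chroms), cfg$n_chroms)
    peaks <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      np <- per_chrom_p[ci]
      if (np == 0) return(NULL)
      slot <- floor(cfg$chrom_length / np)
      len <- pmin(pmax(round(rlnorm(np, cfg$peak_meanlog, cfg$peak_sdlog)), 50L),
                  slot - 2L)
      if (any(len < 1)) stop("infeasible geometry: peaks longer than slots")
      off <- floor(runif(np) * (slot - len - 1))
      start <- (seq_len(np) - 1L) * slot + as.integer(off)
      end <- start + as.integer(len)
      summit <- start + as.integer(floor(runif(np) * len))
      data.frame(peak_id = sprintf("p%s_%04d", ci, seq_len(np)),
                 chrom = chroms[ci], start = start, end = end,
                 summit = summit,
                 read_count = round(rgamma(np, cfg$read_shape, scale = cfg$read_scale), 2),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(peaks)) peaks <- empty_peaks
    rownames(genes) <- rownames(peaks) <- NULL
    list(chrom_sizes = chrom_sizes, genes = genes, peaks = peaks)
  })
}

#' Simulate per-pair data with a planted logistic link model
#'
#' Builds candidate CREs and pairs from the world, then generates: activity
#' signals (gamma), contact values decaying as `(d + d0)^-gamma` with
#' log-normal noise, a per-CRE reporter-activity score (emitted as 10
#' replicate models x 2 orientations around the planted value), chromatin
#' probability columns (one planted informative column `planted`, the rest
#' noise), and two pair-level feature columns `f1`, `f2`. True links are
#' drawn from the logistic model `logit(p) = intercept + beta . x` over the
#' named planted columns; labels flip with probability `label_noise`;
#' effect sizes are negative for links (percent expression change) and near
#' zero otherwise.
#'
#' @param world from [sim_world()].
#' @param config an `eg_sim_config`.
#' @param n_top candidate-selection cap (defaults to all peaks).
#' @return list: `cres`, `pairs`, `activity`, `contact`, `mpra_long` (model
#'   replicate rows), `mpra` (ensembled per-CRE), `sei` (wide per-CRE),
#'   `re2g` (pair-level features), `features` (`eg_features`), `truth`
#'   (data.frame with `cre_id`, `gene_id`, `link_prob`, `true_link`),
#'   `labels` (with `effect_size`).
#' @export
sim_pair_data <- function(world, config, n_top = NULL) {
  cfg <- config
  if (is.null(n_top)) n_top <- nrow(world$peaks)
  cres <- select_candidates(world$peaks, world$genes, world$chrom_sizes,
                            n_top = n_top)
  pairs <- enumerate_pairs(cres, world$genes)
  .with_seed(cfg$seed + 1L, {
    n_cre <- nrow(cres); n_pair <- nrow(pairs)
    activity <- data.frame(
      cre_id = cres$cre_id,
      dnase = round(rgamma(n_cre, 2, scale = 30) + 1, 3),
      h3k27ac = round(rgamma(n_cre, 2, scale = 30) + 1, 3),
      stringsAsFactors = FALSE
    )
    contact <- data.frame(
      cre_id = pairs$cre_id, gene_id = pairs$gene_id,
      contact = (pairs$distance + cfg$d0)^(-cfg$gamma) *
        exp(rnorm(n_pair, 0, cfg$contact_noise)),
      stringsAsFactors = FALSE
    )
    mpra_true <- setNames(rnorm(n_cre), cres$cre_id)
    mpra_long <- do.call(rbind, lapply(1:10, function(m) {
      data.frame(cre_id = cres$cre_id, model_index = m,
                 fwd = mpra_true + rnorm(n_cre, 0, 0.05),
                 rev = mpra_true + rnorm(n_cre, 0, 0.05),
                 stringsAsFactors = FALSE)
    }))
    sei <- data.frame(
      cre_id = cres$cre_id,
      planted = rnorm(n_cre),
      dnase_prob = runif(n_cre), h3k27ac_prob = runif(n_cre),
      h3k4me1_prob = runif(n_cre),
      stringsAsFactors = FALSE
    )
    re2g <- data.frame(
      cre_id = pairs$cre_id, gene_id = pairs$gene_id,
      f1 = rnorm(n_pair), f2 = rnorm(n_pair), nuis1 = rnorm(n_pair),
      stringsAsFactors = FALSE
    )
    abc <- abc_score(pairs, activity, contact)
    mpra_ens <- data.frame(
      cre_id = mpra_long$cre_id,
      value = average_orientations(mpra_long$fwd, mpra_long$rev)
    )
    mpra <- ensemble_mean(mpra_ens)
    feats <- assemble_features(pairs, re2g = re2g, mpra = mpra, sei = sei,
                               abc = abc)
    X <- feats$matrix
    eta <- rep(cfg$intercept, nrow(X))
    for (nm in names(cfg$beta)) {
      if (!nm %in% names(X)) stop("planted coefficient for unknown column: ", nm)
      eta <- eta + cfg$beta[[nm]] * X[[nm]]
    }
    link_prob <- plogis(eta)
    true_link <- rbinom(nrow(X), 1, link_prob)
    flip <- rbinom(nrow(X), 1, cfg$label_noise) == 1
    label <- ifelse(flip, 1L - true_link, true_link)
    effect <- ifelse(true_link == 1, rnorm(nrow(X), -30, 10), rnorm(nrow(X), 0, 5))
    truth <- data.frame(cre_id = X$cre_id, gene_id = X$gene_id,
                        link_prob = link_prob, true_link = true_link,
                        stringsAsFactors = FALSE)
    labels <- data.frame(cre_id = X$cre_id, gene_id = X$gene_id,
                         label = as.integer(label),
                         effect_size = round(effect, 3),
                         stringsAsFactors = FALSE)
    list(cres = cres, pairs = pairs, activity = activity, contact = contact,
         mpra_long = mpra_long, mpra = mpra, sei = sei, re2g = re2g,
         abc = abc, features = feats, truth = truth, labels = labels)
  })
}

#' Simulate variants with a planted in-network fold enrichment
#'
#' Each variant is placed uniformly inside a candidate peak: a network peak
#' with probability `planted_fe * m / N` (`m` network peaks of `N` total),
#' otherwise a non-network peak. With `planted_fe = 1` variants are uniform
#' over the peak universe, so the matched permutation test is calibrated;
#' larger values plant the stated expected fold enrichment.
#'
#' @param world from [sim_world()].
#' @param network_peak_ids character vector of in-network peak ids.
#' @param planted_fe target fold enrichment (>= 1).
#' @param n_variants variant count.
#' @param seed integer seed (default: world stream offset +2).
#' @param config the `eg_sim_config` (for the default seed).
#' @return data.frame `chrom`, `pos0`, `id`.
#' @export
sim_variants <- function(world, network_peak_ids, planted_fe = 1,
                         n_variants = 300L, config = NULL, seed = NULL) {
  if (is.null(seed)) seed <- (if (!is.null(config)) config$seed else 0L) + 2L
  peaks <- world$peaks
  in_net <- peaks$peak_id %in% network_peak_ids
  m <- sum(in_net); N <- nrow(peaks)
  if (m == 0) stop("no network peaks")
  q <- planted_fe * m / N
  if (q > 1) {
    stop(sprintf("planted fold enrichment %.2f unachievable; maximum feasible is %.3f",
                 planted_fe, N / m))
  }
  .with_seed(seed, {
    pick_net <- runif(n_variants) < q
    idx <- integer(n_variants)
    idx[pick_net] <- sample(which(in_net), sum(pick_net), replace = TRUE)
    if (any(!pick_net)) {
      idx[!pick_net] <- sample(which(!in_net), sum(!pick_net), replace = TRUE)
    }
    pos <- peaks$start[idx] +
      floor(runif(n_variants) * (peaks$end[idx] - peaks$start[idx]))
    data.frame(chrom = peaks$chrom[idx], pos0 = as.integer(pos),
               id = sprintf("rs%06d", seq_len(n_variants)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate eQTL variant-gene pairs with a planted concordance rate
#'
#' With probability `concordance_rate` an eQTL is drawn from a network edge
#' (variant inside the edge's CRE, target = the edge's gene); otherwise the
#' variant lands in a random candidate peak and the target gene is random.
#'
#' @param world from [sim_world()].
#' @param network an `eg_network`.
#' @param concordance_rate in `[0, 1]`.
#' @param n_eqtls pair count.
#' @param config,seed as in [sim_variants()] (default stream offset +3).
#' @return data.frame `chrom`, `pos0`, `id`, `gene_id`.
#' @export
sim_eqtls <- function(world, network, concordance_rate = 0.3, n_eqtls = 300L,
                      config = NULL, seed = NULL) {
  if (is.null(seed)) seed <- (if (!is.null(config)) config$seed else 0L) + 3L
  e <- network$edges
  if (nrow(e) == 0) stop("empty network")
  .with_seed(seed, {
    conc <- runif(n_eqtls) < concordance_rate
    out <- data.frame(chrom = character(n_eqtls), pos0 = integer(n_eqtls),
                      id = sprintf("rs%06d", 500000L + seq_len(n_eqtls)),
                      gene_id = character(n_eqtls), stringsAsFactors = FALSE)
    ei <- sample.int(nrow(e), n_eqtls, replace = TRUE)
    pos_in_cre <- e$cre_start[ei] +
      floor(runif(n_eqtls) * (e$cre_end[ei] - e$cre_start[ei]))
    out$chrom <- e$cre_chrom[ei]
    out$pos0 <- as.integer(pos_in_cre)
    out$gene_id <- e$gene_id[ei]
    if (any(!conc)) {
      n_bg <- sum(!conc)
      pk <- sample.int(nrow(world$peaks), n_bg, replace = TRUE)
      out$chrom[!conc] <- world$peaks$chrom[pk]
      out$pos0[!conc] <- as.integer(world$peaks$start[pk] +
        floor(runif(n_bg) * (world$peaks$end[pk] - world$peaks$start[pk])))
      out$gene_id[!conc] <- sample(world$genes$gene_id, n_bg, replace = TRUE)
    }
    out
  })
}

#' Simulate motif hits with a planted condition-specific odds ratio
#'
#' For each TF and merged region, presence is Bernoulli: background rate
#' `background_rate` in condition-agnostic regions; in condition-specific
#' regions the log-odds is shifted by `log(planted_or[tf])` (planted TFs)
#' so the population odds ratio equals the planted value. Present
#' (region, TF) combinations emit one scanner-dialect hit row keyed to the
#' region id.
#'
#' @param regions merged regions from [build_merged_regions()].
#' @param tfs character vector of TF names.
#' @param planted_or named numeric vector of odds ratios for planted TFs
#'   (others get 1).
#' @param background_rate background presence probability.
#' @param seed integer seed.
#' @return data.frame in the columns produced by [read_fimo()].
#' @export
sim_motif_hits <- function(regions, tfs, planted_or = c(), background_rate = 0.15,
                           seed = 5L) {
  spec <- regions$specificity == "condition_specific"
  .with_seed(seed, {
    rows <- lapply(tfs, function(tf) {
      or_tf <- if (tf %in% names(planted_or)) planted_or[[tf]] else 1
      p <- ifelse(spec, plogis(qlogis(background_rate) + log(or_tf)),
                  background_rate)
      present <- runif(nrow(regions)) < p
      if (!any(present)) return(NULL)
      w <- regions$end[present] - regions$start[present]
      data.frame(
        tf_name = tf, sequence_name = regions$region_id[present],
        start = pmax(1L, as.integer(floor(runif(sum(present)) * pmax(1, w - 10)))) ,
        stop = NA_integer_, strand = sample(c("+", "-"), sum(present), TRUE),
        score = round(runif(sum(present), 10, 25), 3),
        p_value = 10^runif(sum(present), -9, -5.01),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(tf_name = character(), sequence_name = character(),
                        start = integer(), stop = integer(),
                        strand = character(), score = numeric(),
                        p_value = numeric(), stringsAsFactors = FALSE)
    } else {
      out$stop <- out$start + 9L
    }
    out
  })
}

#' Write a complete fixture directory
#'
#' Emits every input file the pipeline consumes (peaks.narrowPeak,
#' genes.tsv, activity.tsv, contact.tsv, mpra.tsv, sei.tsv, labels.tsv,
#' variants.tsv, eqtls.tsv, fimo.tsv) plus truth.json recording the planted
#' parameters.
#'
#' @param config an `eg_sim_config`.
#' @param dir output directory (created if needed).
#' @param threshold network score threshold used for the variant/eQTL
#'   fixtures.
#' @return the directory path, invisibly; the generated objects as an
#'   attribute `"objects"`.
#' @export
write_fixture_dir <- function(config, dir, threshold = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- sim_world(config)
  pd <- sim_pair_data(world, config)
  model <- train_eg_model(pd$features, pd$labels, C = 1, seed = config$seed)
  scores <- predict(model, pd$features)
  scored <- data.frame(cre_id = pd$features$matrix$cre_id,
                       gene_id = pd$features$matrix$gene_id, score = scores)
  cls <- setNames(classify_cre(pd$cres, world$genes), pd$cres$cre_id)
  net <- build_eg_network(scored, threshold = threshold, cres = pd$cres,
                          cre_class = cls)
  net_peaks <- intersect(unique(net$edges$cre_id), world$peaks$peak_id)
  variants <- sim_variants(world, net_peaks, planted_fe = config$planted_fe,
                           n_variants = config$n_variants, config = config)
  eqtls <- sim_eqtls(world, net, concordance_rate = config$concordance_rate,
                     n_eqtls = config$n_variants, config = config)
  write_narrowpeak(world$peaks, file.path(dir, "peaks.narrowPeak"))
  .write_tsv(world$genes, file.path(dir, "genes.tsv"))
  .write_tsv(pd$activity, file.path(dir, "activity.tsv"))
  .write_tsv(pd$contact, file.path(dir, "contact.tsv"))
  .write_tsv(pd$mpra_long, file.path(dir, "mpra.tsv"))
  sei_long <- data.frame(cre_id = rep(pd$sei$cre_id, 4),
                         output_name = rep(paste0("out_", names(pd$sei)[-1]),
                                           each = nrow(pd$sei)),
                         feature = rep(names(pd$sei)[-1], each = nrow(pd$sei)),
                         probability = unlist(pd$sei[-1], use.names = FALSE))
  .write_tsv(sei_long, file.path(dir, "sei.tsv"))
  .write_tsv(pd$re2g, file.path(dir, "re2g.tsv"))
  .write_tsv(pd$labels, file.path(dir, "labels.tsv"))
  v_out <- data.frame(chrom = variants$chrom, pos = variants$pos0 + 1L,
                      id = variants$id)
  .write_tsv(v_out, file.path(dir, "variants.tsv"))
  e_out <- data.frame(chrom = eqtls$chrom, pos = eqtls$pos0 + 1L,
                      id = eqtls$id, gene_id = eqtls$gene_id)
  .write_tsv(e_out, file.path(dir, "eqtls.tsv"))
  regions <- build_merged_regions(list(sim = pd$cres[, c("chrom", "start", "end")]))
  hits <- sim_motif_hits(regions, tfs = paste0("TF", 1:10),
                         planted_or = c(TF1 = config$motif_or),
                         background_rate = config$motif_background,
                         seed = config$seed + 4L)
  fimo <- data.frame(motif_id = hits$tf_name, motif_alt_id = hits$tf_name,
                     sequence_name = hits$sequence_name, start = hits$start,
                     stop = hits$stop, strand = hits$strand,
                     score = hits$score, `p-value` = hits$p_value,
                     `q-value` = NA, matched_sequence = ".",
                     check.names = FALSE)
  .write_tsv(fimo, file.path(dir, "fimo.tsv"))
  write_result_json(list(seed = config$seed, intercept = config$intercept,
                         beta = as.list(config$beta),
                         label_noise = config$label_noise,
                         planted_fe = config$planted_fe,
                         concordance_rate = config$concordance_rate,
                         motif_or = config$motif_or,
                         threshold = threshold),
                    file.path(dir, "truth.json"))
  out <- invisible(dir)
  attr(out, "objects") <- list(world = world, pair_data = pd, model = model,
                               network = net, variants = variants,
                               eqtls = eqtls, regions = regions, hits = hits)
  out
}
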