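# Run configuration and end-to-end orchestration.

#' Read a run configuration
#'
#' Plain `key = value` (or `key: value`) text file; one entry per line,
#' `#` comments allowed. Recognised keys: input paths (`peaks`, `genes`,
#' `activity`, `contact`, `mpra`, `sei`, `re2g`, `labels`, `variants`,
#' `eqtls`, `fimo`), `out_dir`, and numeric settings `threshold`,
#' `target_recall`, `fimo_p`, `variant_p`, `n_perm`, `n_boot`, `n_top`,
#' `window`, `seed`, `C`. CLI-style overrides can be supplied via `...`.
#'
#' @param path config file path (optional).
#' @param ... overrides (name = value).
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path = NULL, ...) {
  cfg <- list(threshold = unname(eg_thresholds["standard"]), target_recall = 0.70,
              fimo_p = 1e-5, variant_p = 0.01, n_perm = 1000L, n_boot = 10000L,
              n_top = 150000L, window = 5e6, seed = 1L, C = 1.0,
              out_dir = "egnet_out")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
      if (length(kv) < 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  for (k in c("n_perm", "n_boot", "n_top", "seed")) cfg[[k]] <- as.integer(cfg[[k]])
  stopifnot(cfg$threshold >= 0, cfg$threshold <= 1,
            cfg$target_recall > 0, cfg$target_recall <= 1)
  cfg
}

#' Run the full E-G pipeline
#'
#' Stages, in dependency order: read inputs; select candidate CREs;
#' enumerate pairs; compute ABC scores; assemble features; train the
#' classifier on the CRISPRi labels; score all pairs; benchmark; build the
#' thresholded network; detect and classify substructures; optional
#' variant / eQTL permutation tests and motif enrichment. Artifacts are
#' written under `config$out_dir`, each stamped with the seed and package
#' version; no input file is modified.
#'
#' @param config list from [read_run_config()]. Required paths: `peaks`,
#'   `genes`, `activity`, `contact`, `labels`; optional: `mpra`, `sei`,
#'   `re2g`, `variants`, `eqtls`, `fimo`, `chrom_sizes` (TSV chrom, size).
#' @return invisible list of in-memory artifacts.
#' @export
run_pipeline <- function(config) {
  need <- c("peaks", "genes", "activity", "contact", "labels")
  miss <- need[!vapply(need, function(k) !is.null(config[[k]]) && file.exists(config[[k]]), TRUE)]
  if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  peaks <- stage("read_peaks", read_narrowpeak(config$peaks))
  genes <- stage("read_genes", read_genes(config$genes))
  chrom_sizes <- if (!is.null(config$chrom_sizes) && file.exists(config$chrom_sizes)) {
    cs <- read.table(config$chrom_sizes, header = FALSE, sep = "\t")
    setNames(cs[[2]], cs[[1]])
  } else {
    # infer from the data, padded
    vals <- c(peaks$end, genes$tss + 1)
    grp <- c(peaks$chrom, genes$chrom)
    tapply(vals, grp, max) + 10000
  }
  cres <- stage("select_candidates",
                select_candidates(peaks, genes, chrom_sizes, n_top = config$n_top))
  pairs <- stage("enumerate_pairs", enumerate_pairs(cres, genes, window = config$window))
  activity <- stage("read_activity", read_activity(config$activity))
  contact <- stage("read_contact", read_contact(config$contact))
  abc <- stage("abc_score", abc_score(pairs, activity, contact))
  mpra <- NULL
  if (!is.null(config$mpra) && file.exists(config$mpra)) {
    raw <- read_mpra_scores(config$mpra)
    raw$value <- average_orientations(raw$fwd, raw$rev)
    mpra <- ensemble_mean(raw[, c("cre_id", "value")])
  }
  sei <- NULL
  if (!is.null(config$sei) && file.exists(config$sei)) {
    long <- read_sei_scores(config$sei)
    wide <- data.table::dcast(data.table::as.data.table(long),
                              cre_id ~ output_name, value.var = "probability",
                              fun.aggregate = mean)
    groups <- long$feature[match(setdiff(names(wide), "cre_id"), long$output_name)]
    coll <- collapse_duplicate_columns(as.data.frame(wide)[, -1, drop = FALSE], groups)
    sei <- cbind(data.frame(cre_id = wide$cre_id), coll)
  }
  re2g <- if (!is.null(config$re2g) && file.exists(config$re2g)) {
    .read_tsv(config$re2g, required = c("cre_id", "gene_id"))
  } else NULL
  feats <- stage("assemble_features",
                 assemble_features(pairs, re2g = re2g, mpra = mpra, sei = sei,
                                   abc = abc, check_keys = FALSE))
  write_features(feats, file.path(config$out_dir, "features.tsv"))
  labels <- stage("read_labels", read_labels(config$labels))
  model <- stage("train", train_eg_model(feats, labels, C = config$C,
                                         seed = config$seed))
  write_model(model, file.path(config$out_dir, "model.json"))
  scores <- stage("score", predict(model, feats))
  scored <- data.frame(cre_id = feats$matrix$cre_id,
                       gene_id = feats$matrix$gene_id, score = scores,
                       stringsAsFactors = FALSE)
  .write_tsv(scored, file.path(config$out_dir, "scores.tsv"),
             meta = list(seed = config$seed,
                         version = as.character(utils::packageVersion("egnet"))))
  lkey <- paste(labels$cre_id, labels$gene_id, sep = "\r")
  skey <- paste(scored$cre_id, scored$gene_id, sep = "\r")
  idx <- match(lkey, skey)
  bench <- stage("benchmark", benchmark_predictions(
    scored$score[idx[!is.na(idx)]], labels$label[!is.na(idx)],
    effects = if ("effect_size" %in% names(labels)) labels$effect_size[!is.na(idx)] else NULL,
    n_boot = config$n_boot, target_recall = config$target_recall,
    seed = config$seed))
  write_result_json(unclass(bench)[setdiff(names(unclass(bench)), "replicates")],
                    file.path(config$out_dir, "benchmark.json"))
  cls <- setNames(classify_cre(cres, genes), cres$cre_id)
  net <- stage("network", build_eg_network(scored, threshold = config$threshold,
                                           cres = cres, cre_class = cls))
  write_network(net, file.path(config$out_dir, "network.tsv"))
  if (nrow(net$edges) > 0) {
    part <- stage("communities", detect_communities(net, seed = config$seed))
    subs <- stage("substructures", classify_substructures(net, part))
  } else {
    warning("no edges above threshold ", config$threshold,
            "; skipping community detection")
    part <- list(membership = integer(), modularity = NA_real_)
    subs <- data.frame(community_id = integer(), type = character(),
                       n_cres = integer(), n_genes = integer(),
                       n_edges = integer(), cres = character(),
                       genes = character())
  }
  .write_tsv(subs, file.path(config$out_dir, "substructures.tsv"))
  summ <- summarize_network(net, subs, modularity = part$modularity)
  write_result_json(summ, file.path(config$out_dir, "network_summary.json"))
  out <- list(cres = cres, pairs = pairs, features = feats, model = model,
              scores = scored, benchmark = bench, network = net,
              partition = part, substructures = subs, summary = summ)
  if (!is.null(config$variants) && file.exists(config$variants)) {
    variants <- read_variants(config$variants, p_max = config$variant_p)
    net_cres <- unique(net$edges[, c("cre_chrom", "cre_start", "cre_end")])
    names(net_cres) <- c("chrom", "start", "end")
    pv <- stage("variant_permutation", permutation_test_variants(
      variants, net_cres, peaks, genes, n_perm = config$n_perm,
      seed = config$seed))
    write_result_json(unclass(pv)[c("observed", "p_empirical", "fold_enrichment",
                                    "n_perm", "seed", "relaxation_events")],
                      file.path(config$out_dir, "variant_enrichment.json"))
    out$variant_perm <- pv
  }
  if (!is.null(config$eqtls) && file.exists(config$eqtls)) {
    eqtls <- read_eqtls(config$eqtls)
    pe <- stage("eqtl_permutation", permutation_test_eqtl(
      eqtls, net, cres, genes, predicted = scored, cre_class = cls,
      n_perm = config$n_perm, seed = config$seed))
    write_result_json(unclass(pe)[c("observed", "p_empirical", "fold_enrichment",
                                    "n_perm", "seed", "relaxation_events")],
                      file.path(config$out_dir, "eqtl_concordance.json"))
    out$eqtl_perm <- pe
  }
  invisible(out)
}
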