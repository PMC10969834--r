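#' Configuration of the full circular-comparison pipeline
#'
#' Collects the simulation settings and the analysis thresholds actually used
#' by the study design: adjusted p < 0.01 with a 2-fold cutoff for the main
#' differential expression call, adjusted p < 0.05 for the pairwise line
#' comparisons, |delta-beta| > 0.2 for differential methylation, and a 10 Mb /
#' 1 Mb window scan on chrX.
#'
#' @param simulate A [synthetic_config()] describing the dataset to generate.
#' @param alpha Adjusted-p significance level of the main DE call.
#' @param fold Fold-change cutoff (linear scale) of the main DE call.
#' @param pairwise_alpha Per-gene adjusted-p level of the pairwise comparisons.
#' @param delta_beta Delta-beta cutoff of the DM call.
#' @param window_bp,step_bp Window width and step of the positional scan.
#' @param k Number of NMF components of the score models.
#' @param reference List of reference-cohort sizes for score training
#'   (n_pluripotent, n_brain, n_other, n_mixture, n_genes).
#' @param seed Root seed; every stage derives its own stream from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = synthetic_config(),
                            alpha = 0.01, fold = 2.0, pairwise_alpha = 0.05,
                            delta_beta = 0.2, window_bp = 1e7, step_bp = 1e6,
                            k = 8,
                            reference = list(n_pluripotent = 98, n_brain = 34,
                                             n_other = 200, n_mixture = 12,
                                             n_genes = 2000),
                            seed = 1L) {
  stopifnot(inherits(simulate, "synthetic_config"),
            alpha > 0, alpha < 1, fold >= 1,
            delta_beta > 0, delta_beta < 1,
            pairwise_alpha > 0, pairwise_alpha < 1,
            window_bp >= step_bp, step_bp > 0, k >= 1)
  seed <- as.integer(seed)
  simulate$seed <- seed
  structure(list(simulate = simulate, alpha = alpha, fold = fold,
                 pairwise_alpha = pairwise_alpha, delta_beta = delta_beta,
                 window_bp = window_bp, step_bp = step_bp, k = k,
                 reference = reference, seed = seed),
            class = "pipeline_config")
}

#' Run the full circular-reprogramming comparison pipeline
#'
#' Executes every stage on a seeded synthetic dataset: simulation, SVA-adjusted
#' differential expression of iPSC-NSC vs ESC-NSC with BH and fold-change
#' filtering, chromosome enrichment with direction split, pairwise line
#' comparisons, expression similarity summaries, delta-beta differential
#' methylation with chromosome enrichment and methylome similarity, chrX window
#' scans for both modalities with co-localization, clustering / subset PCA /
#' silhouette separations, and NMF-based pluripotency + neurality scoring of a
#' held-out reference split.  All tables are written as TSV/BED under `outdir`
#' together with a machine-readable `summary.json` and a `manifest.json`
#' recording config, seed and package version.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The report (contents of `summary.json` plus the intermediate
#'   objects), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("circlex_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$simulate
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[circlex +%.1fs] %s",
                                         as.numeric(Sys.time() - t0, "secs"), msg))

  stage("simulate")
  ann <- generate_annotation(sc)
  expr <- generate_expression(sc, ann)
  meth <- generate_methylation(sc, ann)

  stage("differential expression (SVA)")
  nsc <- expr$samples$origin %in% c("ESC-NSC", "iPSC-NSC")
  Y <- expr$values[, nsc, drop = FALSE]
  smp <- expr$samples[nsc, , drop = FALSE]
  groups <- factor(smp$origin, levels = c("ESC-NSC", "iPSC-NSC"))
  svs <- estimate_surrogate_variables(Y, groups, seed = sc$seed + 10L)
  de <- test_differential_expression(Y, groups, svs)
  sets <- filter_significant(de, config$alpha, config$fold)

  stage("enrichment")
  dir_sig <- factor(de$direction[match(sets$significant, de$gene_id)],
                    levels = c("up", "down"))
  chrom_expr <- chromosome_enrichment(sets$significant, ann$genes, dir_sig)
  x_row <- chrom_expr$chromosome == "chrX"
  sim_expr <- expression_similarities(expr, ann, smp, groups)

  stage("pairwise comparisons")
  pairs <- matched_pairs(smp)
  pw <- pairwise_compare(Y, pairs, ann$genes, alpha = config$pairwise_alpha)

  stage("differential methylation")
  mgroups <- factor(meth$samples$origin, levels = c("ESC-NSC", "iPSC-NSC"))
  dm <- delta_beta(meth$values, mgroups)
  calls <- call_dmcg(dm, config$delta_beta)
  dir_dm <- factor(ifelse(calls$called %in% calls$hyper, "hyper", "hypo"),
                   levels = c("hyper", "hypo"))
  chrom_meth <- chromosome_enrichment(calls$called, ann$cpgs, dir_dm)
  mx_row <- chrom_meth$chromosome == "chrX"
  sim_meth <- methylation_similarities(meth, ann, mgroups)

  stage("positional scan + co-localization")
  xg <- ann$genes[ann$genes$chromosome == "chrX", ]
  xc <- ann$cpgs[ann$cpgs$chromosome == "chrX", ]
  hits_expr <- intersect(sets$significant, xg$feature_id)
  hits_meth <- intersect(calls$called, xc$feature_id)
  win_expr <- window_scan(xg$position[xg$feature_id %in% hits_expr],
                          xg$position, "chrX",
                          window_bp = config$window_bp, step_bp = config$step_bp)
  win_meth <- window_scan(xc$position[xc$feature_id %in% hits_meth],
                          xc$position, "chrX",
                          window_bp = config$window_bp, step_bp = config$step_bp)
  coloc <- colocalize(win_expr, win_meth)

  stage("clustering / PCA / separation")
  pca_x <- pca_subset(Y, ann$genes, "chrX")
  pca_auto <- pca_subset(Y, ann$genes, "autosomal")
  sep <- list(
    x_origin = separation_score(pca_x$scores, smp$origin),
    autosomal_origin = separation_score(pca_auto$scores, smp$origin),
    autosomal_background = separation_score(pca_auto$scores, smp$background))
  hc_expr <- correlation_cluster(Y)
  meth_x <- meth$values[rownames(meth$values) %in% xc$feature_id, , drop = FALSE]
  hc_meth_x <- correlation_cluster(meth_x)

  stage("score models")
  scores <- score_stage(config)

  report <- list(
    n_samples = ncol(expr$values), n_nsc_samples = ncol(Y),
    n_genes = nrow(Y), n_cpgs = nrow(meth$values),
    n_sv = svs$n_sv,
    n_de_genes = length(sets$significant),
    n_de_fold = length(sets$fold),
    n_de_chrx = sum(ann$genes$chromosome[match(sets$significant,
                                               ann$genes$feature_id)] == "chrX"),
    chrx_expression_p = chrom_expr$p[x_row],
    chrx_expression_adjusted_p = chrom_expr$adjusted_p[x_row],
    chrx_hits_up = if (is.null(chrom_expr$k_up)) 0 else chrom_expr$k_up[x_row],
    chrx_hits_down = if (is.null(chrom_expr$k_down)) 0 else chrom_expr$k_down[x_row],
    pairwise_x_enrichment_p = vapply(pw, `[[`, numeric(1), "x_enrichment_p"),
    expression_similarity = sim_expr,
    n_dm_cpgs = length(calls$called),
    n_dm_chrx = sum(ann$cpgs$chromosome[match(calls$called,
                                              ann$cpgs$feature_id)] == "chrX"),
    chrx_methylation_p = chrom_meth$p[mx_row],
    chrx_methylation_adjusted_p = chrom_meth$adjusted_p[mx_row],
    methylation_similarity = sim_meth,
    n_enriched_windows_expression = sum(win_expr$enriched),
    n_enriched_windows_methylation = sum(win_meth$enriched),
    n_coloc_regions = nrow(coloc$merged),
    separation = sep,
    scores = scores$summary)

  stage("write outputs")
  files <- write_outputs(outdir, ann, expr, meth, de, dm, chrom_expr,
                         chrom_meth, win_expr, win_meth, coloc, pca_x,
                         pca_auto, hc_expr, hc_meth_x, scores)
  report$files <- files
  jsonlite::write_json(report, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "circlex",
                   version = as.character(utils::packageVersion("circlex")),
                   seed = config$seed, created = format(Sys.time()),
                   config = unclass_config(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(c(report, list(de = de, dm = dm, windows_expression = win_expr,
                           windows_methylation = win_meth, coloc = coloc,
                           annotation = ann, svs = svs, outdir = outdir)))
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$simulate <- unclass(out$simulate)
  out
}

expression_similarities <- function(expr, ann, smp, groups) {
  esc <- smp$sample_id[groups == "ESC-NSC"]
  ipsc <- smp$sample_id[groups == "iPSC-NSC"]
  g <- ann$genes
  list(all = group_similarity(expr$values, esc, ipsc),
       autosomal = group_similarity(expr$values, esc, ipsc,
                                    g$feature_id[g$chromosome != "chrX"]),
       chrX = group_similarity(expr$values, esc, ipsc,
                               g$feature_id[g$chromosome == "chrX"]))
}

methylation_similarities <- function(meth, ann, mgroups) {
  esc <- meth$samples$sample_id[mgroups == "ESC-NSC"]
  ipsc <- meth$samples$sample_id[mgroups == "iPSC-NSC"]
  cg <- ann$cpgs
  list(all = methylome_similarity(meth$values, esc, ipsc),
       autosomal = methylome_similarity(meth$values, esc, ipsc,
                                        cg$feature_id[cg$chromosome != "chrX"]),
       chrX = methylome_similarity(meth$values, esc, ipsc,
                                   cg$feature_id[cg$chromosome == "chrX"]))
}

## each iPSC-NSC line paired with the ESC-NSC line of its background
matched_pairs <- function(smp) {
  pairs <- list()
  for (ln in unique(smp$line[smp$origin == "iPSC-NSC"])) {
    bg <- smp$background[smp$line == ln][1]
    esc_line <- unique(smp$line[smp$origin == "ESC-NSC" & smp$background == bg])[1]
    pairs[[ln]] <- list(ipsc = smp$sample_id[smp$line == ln],
                        esc = smp$sample_id[smp$line == esc_line])
  }
  pairs
}

## train pluripotency + neurality models on an 80% reference split sharing one
## NMF basis; report held-out AUROCs and the mixture-sample score placement
score_stage <- function(config) {
  rc <- config$reference
  ref <- generate_reference(n_pluripotent = rc$n_pluripotent,
                            n_brain = rc$n_brain, n_other = rc$n_other,
                            n_mixture = rc$n_mixture,
                            k_signatures = config$k,
                            n_genes = rc$n_genes,
                            seed = config$seed + 20L)
  core <- which(ref$labels != "mixture")
  set.seed(config$seed + 21L)
  test_idx <- sort(sample(core, round(0.2 * length(core))))
  train_idx <- setdiff(core, test_idx)

  values <- log2(ref$values + 1)   # compress to a log2-like expression scale
  train <- values[, train_idx, drop = FALSE]
  labels <- ref$labels[train_idx]
  shift <- min(train)
  nmf <- fit_nmf(train - shift, k = config$k, seed = config$seed + 22L)
  model_pluri <- fit_tissue_score_model(train, labels, "pluripotent",
                                        nmf = nmf, shift = shift)
  model_neural <- fit_tissue_score_model(train, labels, "brain",
                                         nmf = nmf, shift = shift)

  test <- values[, test_idx, drop = FALSE]
  test_labels <- ref$labels[test_idx]
  st <- score_samples(test, model_pluri, model_neural)
  st$class <- test_labels
  mix <- NULL
  if (any(ref$labels == "mixture")) {
    mix <- score_samples(values[, ref$labels == "mixture", drop = FALSE],
                         model_pluri, model_neural)
    mix$class <- "mixture"
  }
  summary <- list(
    heldout_pluripotent_auroc = auroc(st$pluripotency_score,
                                      test_labels == "pluripotent"),
    heldout_brain_auroc = auroc(st$neurality_score, test_labels == "brain"),
    n_train = length(train_idx), n_test = length(test_idx),
    nmf_iterations = nmf$iterations)
  if (!is.null(mix)) {
    summary$mixture_median_pluripotency <- stats::median(mix$pluripotency_score)
    summary$mixture_median_neurality <- stats::median(mix$neurality_score)
  }
  list(summary = summary, model_pluri = model_pluri,
       model_neural = model_neural,
       score_table = rbind(st, mix))
}

write_outputs <- function(outdir, ann, expr, meth, de, dm, chrom_expr,
                          chrom_meth, win_expr, win_meth, coloc, pca_x,
                          pca_auto, hc_expr, hc_meth_x, scores) {
  p <- function(f) file.path(outdir, f)
  wt <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  gene_pos <- ann$genes[match(de$gene_id, ann$genes$feature_id),
                        c("chromosome", "position")]
  de_out <- cbind(de[, "gene_id", drop = FALSE], gene_pos,
                  de[, setdiff(names(de), "gene_id")])
  files <- c(
    expression_matrix = { write_matrix_tsv(expr$values, p("expression.tsv")); "expression.tsv" },
    methylation_matrix = { write_matrix_tsv(meth$values, p("methylation.tsv")); "methylation.tsv" },
    gene_annotation = { write_annotation_tsv(ann$genes, p("genes.tsv")); "genes.tsv" },
    cpg_annotation = { write_annotation_tsv(ann$cpgs, p("cpgs.tsv")); "cpgs.tsv" },
    sample_metadata = wt(expr$samples, "samples.tsv"),
    de_table = wt(de_out, "de_table.tsv"),
    dm_table = wt(dm, "dm_table.tsv"),
    chromosome_enrichment_expression = wt(chrom_expr, "chrom_enrichment_expression.tsv"),
    chromosome_enrichment_methylation = wt(chrom_meth, "chrom_enrichment_methylation.tsv"),
    windows_expression = wt(win_expr, "windows_expression.tsv"),
    windows_methylation = wt(win_meth, "windows_methylation.tsv"),
    windows_expression_bed = { windows_to_bed(win_expr, p("windows_expression.bed")); "windows_expression.bed" },
    windows_methylation_bed = { windows_to_bed(win_meth, p("windows_methylation.bed")); "windows_methylation.bed" },
    colocalization = wt(coloc$merged, "colocalization.tsv"),
    pca_chrx = wt(data.frame(sample_id = rownames(pca_x$scores),
                             pca_x$scores[, 1:2]), "pca_chrx.tsv"),
    pca_autosomal = wt(data.frame(sample_id = rownames(pca_auto$scores),
                                  pca_auto$scores[, 1:2]), "pca_autosomal.tsv"),
    dendrogram_expression = { export_newick(hc_expr, p("dendrogram_expression.nwk")); "dendrogram_expression.nwk" },
    dendrogram_methylation_chrx = { export_newick(hc_meth_x, p("dendrogram_methylation_chrx.nwk")); "dendrogram_methylation_chrx.nwk" },
    score_table = wt(scores$score_table, "scores.tsv"),
    ground_truth = {
      jsonlite::write_json(
        list(affected_x_genes = ann$affected_x_genes,
             dm_x_cpgs = ann$dm_x_cpgs,
             x_clusters = ann$x_clusters),
        p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
      "ground_truth.json"
    })
  as.list(files)
}
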