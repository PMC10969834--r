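test_that("generators are bit-identical under the same config and seed", {
  cfg <- small_config(seed = 7)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  expect_identical(generate_expression(cfg, a1), generate_expression(cfg, a2))
  expect_identical(generate_methylation(cfg, a1), generate_methylation(cfg, a2))
  expect_identical(generate_reference(seed = 3), generate_reference(seed = 3))
  expect_false(identical(generate_annotation(small_config(seed = 8)), a1))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_genes_autosomal = 0), "positive count")
  expect_error(synthetic_config(noise_sd = -1), ">= 0")
  expect_error(synthetic_config(frac_x_affected = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(n_x_clusters = 20, cluster_width = 1e7),
               "exceed")
})

test_that("annotation respects the planted cluster ground truth", {
  cfg <- small_config()
  ann <- generate_annotation(cfg)
  expect_false(any(duplicated(c(ann$genes$feature_id, ann$cpgs$feature_id))))
  expect_true(all(ann$genes$position >= 1))
  expect_true(all(ann$genes$chromosome %in% names(circlex_chromosomes())))

  # genes inside the recorded intervals are exactly the planted affected genes
  xg <- ann$genes[ann$genes$chromosome == "chrX", ]
  in_cluster <- vapply(xg$position, function(p)
    any(p >= ann$x_clusters$start & p < ann$x_clusters$end), logical(1))
  expect_equal(sum(in_cluster), length(ann$affected_x_genes))
  expect_setequal(xg$feature_id[in_cluster], ann$affected_x_genes)

  # no X genes at all when n_genes_x = 0
  ann0 <- generate_annotation(small_config(n_genes_x = 0))
  expect_equal(sum(ann0$genes$chromosome == "chrX"), 0)
})

test_that("expression generator plants the configured X effect exactly", {
  # noiseless limit: balanced design cancels batch/background in group means
  cfg <- small_config(noise_sd = 0, effect_x_log2 = 1)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(cfg, ann)
  d <- nsc_subset(expr)
  diff <- rowMeans(d$values[, d$groups == "iPSC-NSC"]) -
    rowMeans(d$values[, d$groups == "ESC-NSC"])
  aff <- rownames(d$values) %in% expr$affected_genes
  expect_equal(unname(diff[aff]), rep(1, sum(aff)), tolerance = 1e-12)
  expect_equal(unname(diff[!aff]), rep(0, sum(!aff)), tolerance = 1e-12)
})

test_that("null expression model shows no systematic group difference", {
  cfg <- small_config(effect_x_log2 = 0, batch_sd = 0, background_sd = 0)
  ann <- generate_annotation(cfg)
  d <- nsc_subset(generate_expression(cfg, ann))
  diff <- rowMeans(d$values[, d$groups == "iPSC-NSC"]) -
    rowMeans(d$values[, d$groups == "ESC-NSC"])
  n_eff <- 1 / (1 / sum(d$groups == "iPSC-NSC") + 1 / sum(d$groups == "ESC-NSC"))
  bound <- 4 * cfg$noise_sd / sqrt(n_eff)
  expect_gt(mean(abs(diff) < bound), 0.999)
  expect_lt(abs(mean(diff)), 0.01)
})

test_that("realized affected-gene effects average to the configured shift", {
  reals <- vapply(1:10, function(s) {
    cfg <- small_config(seed = s)
    ann <- generate_annotation(cfg)
    d <- nsc_subset(generate_expression(cfg, ann))
    aff <- rownames(d$values) %in% ann$affected_x_genes
    mean(rowMeans(d$values[aff, d$groups == "iPSC-NSC"]) -
           rowMeans(d$values[aff, d$groups == "ESC-NSC"]))
  }, numeric(1))
  expect_lt(abs(mean(reals) - 1.0), 0.1)
})

test_that("methylation generator plants delta-beta and stays in [0, 1]", {
  cfg0 <- small_config(beta_noise_sd = 0)
  ann0 <- generate_annotation(cfg0)
  meth0 <- generate_methylation(cfg0, ann0)
  g <- factor(meth0$samples$origin, levels = c("ESC-NSC", "iPSC-NSC"))
  dm <- delta_beta(meth0$values, g)
  hyper <- meth0$dm_truth$cpg_id[meth0$dm_truth$direction == "hyper"]
  hypo <- meth0$dm_truth$cpg_id[meth0$dm_truth$direction == "hypo"]
  expect_equal(dm$delta_beta[match(hyper, dm$cpg_id)], rep(0.3, length(hyper)))
  expect_equal(dm$delta_beta[match(hypo, dm$cpg_id)], rep(-0.3, length(hypo)))

  for (s in 1:3) {
    ds <- small_dataset(seed = s)
    expect_true(all(ds$meth$values >= 0 & ds$meth$values <= 1))
  }

  # non-DM CpGs have no systematic group difference
  ds <- small_dataset()
  gm <- factor(ds$meth$samples$origin, levels = c("ESC-NSC", "iPSC-NSC"))
  dmv <- delta_beta(ds$meth$values, gm)
  nondm <- !(dmv$cpg_id %in% ds$meth$dm_truth$cpg_id)
  expect_lt(mean(abs(dmv$delta_beta[nondm])), 0.05)
})

test_that("reference cohort has the constructed low-rank structure", {
  ref <- generate_reference(n_pluripotent = 10, n_brain = 10, n_other = 10,
                            k_signatures = 3, n_genes = 100,
                            mix_noise_sd = 0, seed = 2)
  expect_true(all(ref$values >= 0))
  expect_equal(qr(ref$values)$rank, 3)
  expect_equal(sort(unique(ref$labels)), c("brain", "other", "pluripotent"))

  ref2 <- generate_reference(n_pluripotent = 10, n_brain = 5, n_other = 5,
                             n_mixture = 4, seed = 2)
  expect_equal(sum(ref2$labels == "mixture"), 4)
  expect_equal(ncol(ref2$values), 24)
})
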