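test_that("surrogate variable analysis recovers a planted batch", {
  set.seed(42)
  g <- 2000; n <- 20
  batch <- rep(c(0, 1), each = n / 2)
  group <- rep(c(0, 1), times = n / 2)        # orthogonal to batch
  Y <- matrix(rnorm(g * n), g, n)
  affected <- seq_len(0.3 * g)
  Y[affected, ] <- Y[affected, ] + outer(rnorm(length(affected), 0, 1), batch)
  colnames(Y) <- paste0("s", 1:n)
  svs <- estimate_surrogate_variables(Y, factor(group), seed = 1)
  expect_gte(svs$n_sv, 1)
  expect_gte(abs(cor(svs$sv[, 1], batch)), 0.9)
  expect_equal(sqrt(colSums(svs$sv^2)), rep(1, svs$n_sv), tolerance = 1e-8)
})

test_that("surrogate variable analysis finds nothing in pure noise", {
  n_sv <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Y <- matrix(rnorm(1000 * 15), 1000, 15)
    estimate_surrogate_variables(Y, factor(rep(1:3, each = 5)),
                                 seed = s)$n_sv
  }, numeric(1))
  expect_gte(mean(n_sv == 0), 0.8)
})

test_that("surrogate variable analysis validates its inputs", {
  Y <- matrix(rnorm(100 * 10), 100, 10)
  expect_error(estimate_surrogate_variables(Y, factor(rep(1:2, each = 5)),
                                            n_permutations = 0), "permutations")
  X <- cbind(1, rep(1:0, each = 5), rep(1:0, each = 5))  # collinear
  expect_error(estimate_surrogate_variables(Y, X), "rank deficient")
  X4 <- cbind(1, c(0, 0, 1, 1), c(0, 1, 0, 1))           # 4 samples, 3 columns
  expect_error(estimate_surrogate_variables(Y[, 1:4], X4), "samples")
})

test_that("differential expression matches the two-sample t-test without SVs", {
  set.seed(5)
  Y <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:10)))
  groups <- factor(rep(c("A", "B"), each = 5))
  de <- test_differential_expression(Y, groups)
  ref <- t(apply(Y, 1, function(y) {
    tt <- t.test(y[6:10], y[1:5], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }))
  expect_lt(max(abs(de$t_statistic - ref[, 1])), 1e-10)
  expect_lt(max(abs(de$p_value - ref[, 2])), 1e-10)
  expect_equal(de$log2_fold_change,
               unname(rowMeans(Y[, 6:10]) - rowMeans(Y[, 1:5])))
  expect_true(all(de$adjusted_p >= de$p_value))
})

test_that("degenerate genes are flagged with t = 0 and p = 1", {
  Y <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  Y[1, ] <- 3.7
  de <- test_differential_expression(Y, factor(rep(c("A", "B"), each = 4)))
  expect_equal(de$t_statistic[1], 0)
  expect_equal(de$p_value[1], 1)
  expect_true(de$zero_variance[1])
  expect_error(test_differential_expression(Y, factor(rep("A", 8))), "two groups")
  expect_error(test_differential_expression(Y[, 1:3],
                                            factor(c("A", "A", "B"))), ">= 2")
})

test_that("planted X genes are recovered with surrogate adjustment", {
  ds <- small_dataset()
  d <- nsc_subset(ds$expr)
  svs <- estimate_surrogate_variables(d$values, d$groups, seed = 2)
  de <- test_differential_expression(d$values, d$groups, svs)
  aff <- de$gene_id %in% ds$annotation$affected_x_genes
  expect_gte(mean(de$adjusted_p[aff] < 0.01), 0.8)
  expect_true(all(de$direction[aff & de$adjusted_p < 0.01] == "up"))
})

test_that("Benjamini-Hochberg matches the independent step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  p <- runif(1000)
  expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  # invariant under permutation of input order
  perm <- sample.int(1000)
  adj <- benjamini_hochberg(p)
  expect_equal(benjamini_hochberg(p[perm])[order(perm)], adj)
})

test_that("significance filtering nests the fold set inside the significant set", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   log2_fold_change = c(1.32, 0.5, 3),
                   adjusted_p = c(0.005, 0.005, 0.02))
  out <- filter_significant(de, alpha = 0.01, fold_change = 2)
  expect_setequal(out$significant, c("a", "b"))
  expect_equal(out$fold, "a")
  expect_error(filter_significant(de, fold_change = 0.5), ">= 1")

  set.seed(3)
  de2 <- data.frame(gene_id = paste0("g", 1:500),
                    log2_fold_change = rnorm(500, 0, 1.5),
                    adjusted_p = runif(500))
  out2 <- filter_significant(de2)
  expect_true(all(out2$fold %in% out2$significant))
})

test_that("pairwise comparisons behave on degenerate and planted inputs", {
  set.seed(9)
  Y <- matrix(rnorm(300 * 12), 300, 12,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:12)))
  same <- list(p1 = list(ipsc = paste0("s", 1:4), esc = paste0("s", 1:4)))
  res <- pairwise_compare(Y, same)
  expect_equal(res$p1$n_significant, 0)
  expect_true(all(res$p1$de$p_value == 1 | res$p1$de$t_statistic == 0 |
                    res$p1$de$p_value > 0))
  expect_error(pairwise_compare(Y, list(p = list(ipsc = "s1", esc = c("s2", "s3")))),
               ">= 2")
  expect_error(pairwise_compare(Y, list(p = list(ipsc = c("s1", "zz"),
                                                 esc = c("s2", "s3")))),
               "unmatched")

  # planted recovery at higher replication: 40 chrX genes of 300 shifted by 1
  ann <- data.frame(feature_id = paste0("g", 1:300),
                    chromosome = c(rep("chrX", 60), rep("chr1", 240)))
  Y2 <- matrix(rnorm(300 * 16, 0, 0.25), 300, 16,
               dimnames = list(paste0("g", 1:300), paste0("s", 1:16)))
  Y2[1:40, 9:16] <- Y2[1:40, 9:16] + 1
  pr <- pairwise_compare(Y2, list(p = list(ipsc = paste0("s", 9:16),
                                           esc = paste0("s", 1:8))), ann)
  expect_gt(pr$p$n_significant, 20)
  expect_lt(pr$p$x_enrichment_p, 1e-5)
})

test_that("group similarity is scale-invariant and subsettable", {
  set.seed(2)
  Y <- matrix(rnorm(200 * 8, 7, 1.5), 200, 8,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  a <- paste0("s", 1:4); b <- paste0("s", 5:8)
  expect_equal(group_similarity(Y, a, a), 1.0)
  Yshift <- Y; Yshift[, 5:8] <- Y[, 1:4] + 2
  expect_equal(group_similarity(Yshift, a, b), 1.0)
  expect_error(group_similarity(Y, character(0), b), "non-empty")
  flat <- matrix(1, 5, 8, dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  expect_error(group_similarity(flat, a, b), "zero variance")

  # planted X effect lowers the X similarity below the autosomal one
  ds <- small_dataset()
  d <- nsc_subset(ds$expr)
  esc <- d$samples$sample_id[d$groups == "ESC-NSC"]
  ipsc <- d$samples$sample_id[d$groups == "iPSC-NSC"]
  g <- ds$annotation$genes
  sim_auto <- group_similarity(d$values, esc, ipsc,
                               g$feature_id[g$chromosome != "chrX"])
  sim_x <- group_similarity(d$values, esc, ipsc,
                            g$feature_id[g$chromosome == "chrX"])
  expect_gt(sim_auto, sim_x)
})
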