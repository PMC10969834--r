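test_that("NMF recovers exact low-rank structure and decreases its objective", {
  set.seed(10)
  w0 <- abs(rnorm(60)); h0 <- abs(rnorm(15))
  X1 <- outer(w0, h0)
  fit1 <- fit_nmf(X1, k = 1, seed = 1)
  expect_lt(sqrt(sum((X1 - fit1$W %*% fit1$H)^2)) / sqrt(sum(X1^2)), 1e-6)

  X <- matrix(abs(rnorm(80 * 20)), 80, 20)
  for (s in 1:3) {
    fit <- fit_nmf(X, k = 4, seed = s, max_iter = 200)
    expect_true(all(fit$W >= 0))
    expect_true(all(fit$H >= 0))
    expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
  }
  expect_error(fit_nmf(X - 10, k = 2), "non-negative")
  expect_error(fit_nmf(X, k = 50), "min\\(dim")
})

test_that("NMF at the generative rank reconstructs the reference cohort", {
  ref <- generate_reference(n_pluripotent = 30, n_brain = 15, n_other = 40,
                            k_signatures = 8, n_genes = 400, seed = 4)
  fit <- fit_nmf(ref$values, k = 8, seed = 1)
  rel <- sqrt(sum((ref$values - fit$W %*% fit$H)^2)) / sqrt(sum(ref$values^2))
  expect_lt(rel, ref$mix_noise_sd)
})

test_that("component AUROC matches brute-force pair counting", {
  expect_equal(unname(rank_components(
    rbind(c(5, 6, 1, 2)), c("t", "t", "o", "o"), "t")$component_auroc), 1.0)
  expect_equal(unname(rank_components(
    rbind(c(2, 1, 3)), c("t", "o", "o"), "t")$component_auroc), 0.5)
  expect_error(rank_components(rbind(1:3), rep("t", 3), "t"), "both classes")

  set.seed(12)
  x <- sample(round(rnorm(200), 1))          # ties on purpose
  pos <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  H <- rbind(x)
  expect_lt(abs(rank_components(H, ifelse(pos, "t", "o"), "t")$component_auroc -
                  auroc_oracle(x, pos)), 1e-12)
})

test_that("non-negative logistic keeps weights at the KKT boundary", {
  set.seed(13)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  good <- ifelse(y, 3, 1) + rnorm(n, 0, 0.2)        # separates positively
  bad <- ifelse(y, 1, 3) + rnorm(n, 0, 0.2)         # separates negatively
  H <- rbind(good = good, bad = bad)
  fit <- fit_nonneg_logistic(H, ifelse(y, "t", "o"), "t")
  expect_true(all(fit$w >= 0))
  expect_gt(fit$w[["good"]], 0)
  expect_lt(fit$w[["bad"]], 1e-6)
  pred <- drop(fit$w %*% H) + fit$b > 0
  expect_equal(unname(pred), y)

  # grid search over the negatively oriented coordinate confirms the optimum
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  yy <- ifelse(y, 1, -1)
  obj <- function(wb) {
    eta <- drop(t(H) %*% wb[1:2]) + wb[3]
    sum(softplus(-yy * eta)) + 0.5 * 1e-3 * sum(wb[1:2]^2)
  }
  base <- obj(c(fit$w, fit$b))
  for (g in c(0.05, 0.2, 0.5))
    expect_gt(obj(c(fit$w[["good"]], g, fit$b)), base)
})

test_that("non-negative logistic has no signal under label shuffling", {
  set.seed(14)
  H <- matrix(abs(rnorm(8 * 60)), 8, 60)
  aucs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    labs <- sample(rep(c("t", "o"), each = 30))
    fit <- fit_nonneg_logistic(H, labs, "t")
    scores <- drop(fit$w %*% H) + fit$b
    r <- rank(scores)
    pos <- labs == "t"
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, numeric(1))
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.65)
})

test_that("NNLS projection recovers known mixtures", {
  set.seed(15)
  W <- matrix(abs(rnorm(100 * 5)), 100, 5,
              dimnames = list(sprintf("g%03d", 1:100), paste0("C", 1:5)))
  h0 <- c(2, 0, 1, 0.5, 0)
  x <- drop(W %*% h0)
  names(x) <- rownames(W)
  h <- project_sample(x, W)
  expect_lt(max(abs(h - h0)), 1e-6)
  expect_equal(unname(project_sample(rep(0, 100), W)), rep(0, 5))

  # optimality: no sampled non-negative h' does better
  res <- sqrt(sum((x - W %*% h)^2))
  for (i in 1:50) {
    hp <- abs(h0 + rnorm(5, 0, 0.3))
    expect_lte(res, sqrt(sum((x - W %*% hp)^2)) + 1e-9)
  }
  expect_error(project_sample(x[1:50], W), "missing basis genes|dimension")
})

test_that("score models order reference classes and are deterministic", {
  ref <- generate_reference(n_pluripotent = 30, n_brain = 20, n_other = 40,
                            n_mixture = 8, n_genes = 400, seed = 5)
  core <- ref$labels != "mixture"
  vals <- log2(ref$values + 1)
  train <- vals[, core, drop = FALSE]
  shift <- min(train)
  nmf <- fit_nmf(train - shift, k = 8, seed = 2)
  mp <- fit_tissue_score_model(train, ref$labels[core], "pluripotent",
                               nmf = nmf, shift = shift)
  mn <- fit_tissue_score_model(train, ref$labels[core], "brain",
                               nmf = nmf, shift = shift)
  st <- score_samples(vals, mp, mn)
  st$class <- ref$labels
  med <- function(col, cl) median(st[[col]][st$class == cl])
  expect_gt(med("pluripotency_score", "pluripotent"), med("pluripotency_score", "brain"))
  expect_gt(med("neurality_score", "brain"), med("neurality_score", "pluripotent"))
  # mixtures land between the class medians on both axes
  expect_gt(med("pluripotency_score", "mixture"), med("pluripotency_score", "brain"))
  expect_lt(med("pluripotency_score", "mixture"), med("pluripotency_score", "pluripotent"))
  expect_gt(med("neurality_score", "mixture"), med("neurality_score", "pluripotent"))
  expect_lt(med("neurality_score", "mixture"), med("neurality_score", "brain"))

  # duplicated sample scores identically
  dup <- vals[, c(1, 1)]
  colnames(dup) <- c("a", "b")
  sd2 <- score_samples(dup, mp, mn)
  expect_equal(sd2$pluripotency_score[1], sd2$pluripotency_score[2])
  expect_equal(sd2$neurality_score[1], sd2$neurality_score[2])
})

test_that("score models survive a save/load round trip", {
  ref <- generate_reference(n_pluripotent = 15, n_brain = 10, n_other = 20,
                            n_genes = 200, seed = 6)
  vals <- log2(ref$values + 1)
  m <- fit_tissue_score_model(vals, ref$labels, "pluripotent", k = 4, seed = 1)
  dir <- tempfile("model_")
  save_score_model(m, dir)
  m2 <- load_score_model(dir)
  expect_equal(predict(m2, vals[, 1:5]), predict(m, vals[, 1:5]), tolerance = 1e-8)
  expect_equal(m2$target_class, "pluripotent")
})
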