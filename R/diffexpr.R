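#' Estimate surrogate variables by residual SVD with parallel analysis
#'
#' Two-step procedure: (1) fit the primary design to every gene by least
#' squares and form the residual matrix; (2) take the SVD of the residuals and
#' retain the leading right singular vectors whose variance fraction exceeds
#' the `1 - alpha` quantile of the corresponding variance fraction obtained
#' from `n_permutations` copies of the residual matrix with every row permuted
#' independently (parallel analysis).  The retained vectors — surrogate
#' variables — capture structured unmodeled heterogeneity such as batch.
#'
#' @param values Genes x samples numeric matrix (log2 scale).
#' @param design Primary design: a factor/vector over samples (expanded via
#'   `model.matrix(~ design)`) or a full-rank design matrix including the
#'   intercept.
#' @param n_permutations Number of row-permuted null matrices (>= 1).
#' @param alpha Retention level for the permutation quantile.
#' @param seed Integer seed for the permutations.
#' @return A list of class `circlex_sva`: `sv` (samples x n_sv, unit-norm
#'   columns), `n_sv`, `var_frac` (observed variance fractions of retained
#'   components), `threshold` (permutation quantile per component), `alpha`,
#'   `n_permutations`.
#' @export
estimate_surrogate_variables <- function(values, design, n_permutations = 20,
                                         alpha = 0.05, seed = 1L) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  X <- design_matrix(design, nrow = ncol(values))
  n <- ncol(values); p <- ncol(X)
  if (qr(X)$rank < p) stop("primary design is rank deficient")
  if (n < p + 2) stop("need at least ", p + 2, " samples for ", p,
                      " design columns")
  set.seed(as.integer(seed))

  ## residuals of the per-gene least-squares fits (projection in sample space)
  Q <- qr.Q(qr(X))
  R <- values - (values %*% Q) %*% t(Q)

  obs <- svd_var_frac(R)
  perm <- matrix(0, n_permutations, length(obs))
  g <- nrow(R)
  for (b in seq_len(n_permutations)) {
    ## permute every row of R independently (row-grouped random order), then
    ## re-project onto the residual subspace so the null spectrum has the same
    ## rank n - p as the observed one
    j <- order(rep(seq_len(g), times = n), runif(g * n))
    Rp <- matrix(R[j], nrow = g, ncol = n, byrow = TRUE)
    Rp <- Rp - (Rp %*% Q) %*% t(Q)
    perm[b, ] <- svd_var_frac(Rp)
  }
  thr <- apply(perm, 2, quantile, probs = 1 - alpha, names = FALSE)
  keep <- which(cumsum(obs > thr) == seq_along(obs))  # leading run only

  sv <- svd(R, nu = 0)$v[, keep, drop = FALSE]
  rownames(sv) <- colnames(values)
  structure(list(sv = sv, n_sv = length(keep), var_frac = obs[keep],
                 threshold = thr, alpha = alpha,
                 n_permutations = n_permutations),
            class = "circlex_sva")
}

#' @export
print.circlex_sva <- function(x, ...) {
  cat("surrogate variables: n_sv =", x$n_sv)
  if (x$n_sv > 0)
    cat(" (variance fractions ", paste(signif(x$var_frac, 3), collapse = ", "),
        ")", sep = "")
  cat("\n")
  invisible(x)
}

design_matrix <- function(design, nrow) {
  if (is.matrix(design)) {
    if (nrow(design) != nrow) stop("design rows must match sample count")
    design
  } else {
    if (length(design) != nrow) stop("design length must match sample count")
    model.matrix(~ factor(design))
  }
}

svd_var_frac <- function(M) {
  ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

#' Per-gene differential expression with surrogate variable adjustment
#'
#' Ordinary least squares of each gene on \[intercept, group, surrogate
#' variables\]; t statistic and two-sided p value for the group coefficient
#' with `n - p` residual degrees of freedom; Benjamini-Hochberg adjustment
#' across all genes.  The reported log2 fold change is the raw difference of
#' group means (non-reference minus reference group), following the microarray
#' convention used for fold-change filtering.
#'
#' @param values Genes x samples log2 matrix.
#' @param groups Factor (or coercible) with exactly two levels over samples;
#'   the first level is the reference (ESC-derived) group.
#' @param svs Optional `circlex_sva` object (or samples x k matrix) of
#'   surrogate variables to adjust for.
#' @param ref Reference level; defaults to the first factor level.
#' @return Data frame of class `circlex_de`: gene_id, log2_fold_change,
#'   t_statistic, p_value, adjusted_p, direction ("up"/"down"), zero_variance.
#' @export
test_differential_expression <- function(values, groups, svs = NULL, ref = NULL) {
  groups <- factor(groups)
  if (!is.null(ref)) groups <- stats::relevel(groups, ref)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  if (length(groups) != ncol(values)) stop("group labels must cover every sample")

  S <- if (is.null(svs)) NULL else if (inherits(svs, "circlex_sva")) svs$sv else svs
  g01 <- as.numeric(groups == levels(groups)[2])
  X <- cbind(`(Intercept)` = 1, group = g01, S)
  n <- ncol(values); p <- ncol(X)
  df <- n - p
  if (df <= 0) stop("non-positive residual degrees of freedom")

  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- values %*% X %*% XtXinv                    # genes x p coefficients
  E <- values - B %*% t(X)
  s2 <- rowSums(E^2) / df
  se <- sqrt(s2 * XtXinv[2, 2])

  beta <- B[, 2]
  t_stat <- beta / se
  zero_var <- s2 < 1e-12
  ## degenerate genes: flat genes get t = 0, p = 1; a perfect nonzero fit
  ## keeps an infinite statistic and p = 0
  t_stat[zero_var & abs(beta) < 1e-12] <- 0
  p <- 2 * pt(-abs(t_stat), df)
  p[zero_var & abs(beta) < 1e-12] <- 1

  lfc <- rowMeans(values[, groups == levels(groups)[2], drop = FALSE]) -
    rowMeans(values[, groups == levels(groups)[1], drop = FALSE])
  out <- data.frame(gene_id = rownames(values),
                    log2_fold_change = lfc,
                    t_statistic = t_stat,
                    p_value = p,
                    adjusted_p = benjamini_hochberg(p),
                    direction = ifelse(lfc >= 0, "up", "down"),
                    zero_variance = zero_var,
                    row.names = NULL)
  class(out) <- c("circlex_de", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1, and stable
#' under permutation of the input order.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in input order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must be finite and in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Filter a differential expression result by significance and fold change
#'
#' @param de A `circlex_de` data frame.
#' @param alpha Significance level on the adjusted p value (strict `<`).
#' @param fold_change Fold-change cutoff on the linear scale (>= 1); the fold
#'   set additionally requires `|log2FC| >= log2(fold_change)`.
#' @return List with `significant` and `fold` gene-id vectors
#'   (`fold` is always a subset of `significant`).
#' @export
filter_significant <- function(de, alpha = 0.01, fold_change = 2.0) {
  if (fold_change < 1) stop("'fold_change' must be >= 1")
  sig <- de$adjusted_p < alpha
  fold <- sig & abs(de$log2_fold_change) >= log2(fold_change)
  list(significant = de$gene_id[sig], fold = de$gene_id[fold])
}

#' Pairwise line-level comparisons with X-chromosome enrichment
#'
#' For each (iPSC-derived line, matched ESC-derived line) pair: per-gene
#' two-sample equal-variance t test, Benjamini-Hochberg adjustment,
#' significance at `alpha`, and (if an annotation is supplied) the chrX
#' hypergeometric enrichment p value of the significant set.  Genes with zero
#' pooled variance are flagged and assigned p = 1.
#'
#' @param values Genes x samples log2 matrix.
#' @param pairs Named list; each element is a list with character vectors
#'   `ipsc` and `esc` of sample ids (>= 2 each).
#' @param annotation Optional gene annotation data frame (feature_id,
#'   chromosome) for the chrX enrichment.
#' @param alpha Per-gene significance level on the adjusted p value.
#' @return Named list per pair: `de` (data frame), `n_significant`,
#'   `significant` (gene ids), `x_enrichment_p` (NA without annotation).
#' @export
pairwise_compare <- function(values, pairs, annotation = NULL, alpha = 0.05) {
  lapply(pairs, function(pr) {
    miss <- setdiff(c(pr$ipsc, pr$esc), colnames(values))
    if (length(miss) > 0)
      stop("unmatched sample ids: ", paste(miss, collapse = ", "))
    if (length(pr$ipsc) < 2 || length(pr$esc) < 2)
      stop("each side of a pair needs >= 2 samples")
    A <- values[, pr$esc, drop = FALSE]
    B <- values[, pr$ipsc, drop = FALSE]
    nA <- ncol(A); nB <- ncol(B)
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- rowSums((A - mA)^2) / (nA - 1)
    vB <- rowSums((B - mB)^2) / (nB - 1)
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    t_stat <- (mB - mA) / se
    zero_var <- sp2 < 1e-12
    t_stat[zero_var] <- 0
    p <- 2 * pt(-abs(t_stat), nA + nB - 2)
    p[zero_var] <- 1
    adj <- benjamini_hochberg(p)
    de <- data.frame(gene_id = rownames(values), log2_fold_change = mB - mA,
                     t_statistic = t_stat, p_value = p, adjusted_p = adj,
                     direction = ifelse(mB - mA >= 0, "up", "down"),
                     zero_variance = zero_var, row.names = NULL)
    sig <- de$gene_id[adj < alpha]
    xp <- NA_real_
    if (!is.null(annotation)) {
      ce <- chromosome_enrichment(sig, annotation)
      xp <- ce$p[ce$chromosome == "chrX"]
    }
    list(de = de, n_significant = length(sig), significant = sig,
         x_enrichment_p = xp)
  })
}

#' Pearson similarity of group-mean expression profiles
#'
#' Correlation of the mean log2 profiles of two sample groups over an optional
#' feature subset; used for the "how similar are ESC- and iPSC-derived NSCs"
#' summaries (all genes / autosomal / chrX).
#'
#' @param values Features x samples matrix.
#' @param samples_a,samples_b Character vectors of sample ids (non-empty).
#' @param features Optional feature-id subset.
#' @return Pearson correlation of the two group-mean vectors.
#' @export
group_similarity <- function(values, samples_a, samples_b, features = NULL) {
  if (length(samples_a) == 0 || length(samples_b) == 0)
    stop("both groups must be non-empty")
  if (!is.null(features)) values <- values[features, , drop = FALSE]
  ma <- rowMeans(values[, samples_a, drop = FALSE])
  mb <- rowMeans(values[, samples_b, drop = FALSE])
  if (sd(ma) < 1e-12 || sd(mb) < 1e-12)
    stop("group-mean profile has zero variance; correlation undefined")
  cor(ma, mb)
}
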