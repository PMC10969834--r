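#' Per-CpG difference of group-mean beta values
#'
#' For every CpG, the difference of the group-mean beta values with the sign
#' convention non-reference minus reference (iPSC-derived minus ESC-derived),
#' so positive delta-beta means hypermethylation in iPSC-derived cells.
#' Missing values are averaged over the present samples per group; CpGs with an
#' entirely missing group are flagged (delta NA).
#'
#' @param values CpGs x samples beta matrix (values in \[0, 1\]).
#' @param groups Factor (or coercible) with exactly two levels; the first
#'   level is the reference (ESC-derived) group.
#' @param ref Optional reference level.
#' @return Data frame of class `circlex_dm`: cpg_id, mean_ref, mean_alt,
#'   delta_beta, direction ("hyper"/"hypo"), group_missing.
#' @export
delta_beta <- function(values, groups, ref = NULL) {
  groups <- factor(groups)
  if (!is.null(ref)) groups <- stats::relevel(groups, ref)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (length(groups) != ncol(values)) stop("group labels must cover every sample")
  A <- values[, groups == levels(groups)[1], drop = FALSE]
  B <- values[, groups == levels(groups)[2], drop = FALSE]
  mA <- rowMeans(A, na.rm = TRUE)
  mB <- rowMeans(B, na.rm = TRUE)
  missing <- !is.finite(mA) | !is.finite(mB)
  d <- mB - mA
  d[missing] <- NA_real_
  out <- data.frame(cpg_id = rownames(values), mean_ref = mA, mean_alt = mB,
                    delta_beta = d,
                    direction = ifelse(d >= 0, "hyper", "hypo"),
                    group_missing = missing, row.names = NULL)
  class(out) <- c("circlex_dm", "data.frame")
  out
}

#' Call differentially methylated CpGs by the delta-beta criterion
#'
#' A CpG is called when `|delta_beta| > threshold` (strict inequality at the
#' boundary).  No variance-based test is involved: the absolute difference of
#' group means is the entire criterion.
#'
#' @param dm A `circlex_dm` data frame from [delta_beta()].
#' @param threshold Beta-difference cutoff in (0, 1); default 0.2.
#' @return List: `called` (all called CpG ids), `hyper`, `hypo` (disjoint
#'   subsets partitioning `called`), `threshold`.
#' @export
call_dmcg <- function(dm, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  ok <- !is.na(dm$delta_beta)
  called <- ok & abs(dm$delta_beta) > threshold
  list(called = dm$cpg_id[called],
       hyper = dm$cpg_id[called & dm$delta_beta > 0],
       hypo = dm$cpg_id[called & dm$delta_beta < 0],
       threshold = threshold)
}

#' Pearson similarity of group-mean methylomes
#'
#' Correlation of the mean beta profiles of two sample groups over an optional
#' CpG subset (all / autosomal / chrX).
#'
#' @inheritParams group_similarity
#' @return Pearson correlation of the two group-mean beta vectors.
#' @export
methylome_similarity <- function(values, samples_a, samples_b, features = NULL) {
  group_similarity(values, samples_a, samples_b, features)
}
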