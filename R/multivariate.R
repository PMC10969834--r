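#' Hierarchical clustering of samples by correlation distance
#'
#' Average-linkage (UPGMA) clustering with distance `1 - Pearson r` between
#' sample profiles.  `1 - r` (not `1 - |r|`) is used so that anticorrelated
#' samples are maximally dissimilar.  Samples are ordered lexicographically
#' before clustering so equal-distance merges break ties deterministically.
#'
#' @param values Features x samples matrix (samples are clustered).
#' @return An `hclust` object with attributes `metric` and `linkage`.
#' @export
correlation_cluster <- function(values) {
  if (ncol(values) < 2) stop("need at least two samples")
  vars <- apply(values, 2, var)
  if (any(vars < 1e-12))
    stop("zero-variance sample(s): ",
         paste(colnames(values)[vars < 1e-12], collapse = ", "))
  o <- order(colnames(values))
  v <- values[, o, drop = FALSE]
  d <- 1 - cor(v)
  hc <- hclust(as.dist(d), method = "average")
  attr(hc, "metric") <- "1 - pearson"
  attr(hc, "linkage") <- "average"
  hc
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths.
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal component analysis of samples over a feature subset
#'
#' Centred (not scaled) PCA of the sample profiles via SVD, over all features,
#' autosomal features, or chrX features.  Component signs are fixed by making
#' the largest-magnitude loading of each component positive, so scores are
#' reproducible across platforms.
#'
#' @param values Features x samples matrix.
#' @param annotation Optional annotation data frame (feature_id, chromosome);
#'   required for the chromosome subsets.
#' @param subset One of "all", "autosomal", "chrX".
#' @return List of class `circlex_pca`: `scores` (samples x PC), `var_frac`
#'   (summing to 1), `loadings`, `subset`.
#' @export
pca_subset <- function(values, annotation = NULL,
                       subset = c("all", "autosomal", "chrX")) {
  subset <- match.arg(subset)
  if (subset != "all") {
    if (is.null(annotation)) stop("annotation required for subset '", subset, "'")
    chr <- annotation$chromosome[match(rownames(values), annotation$feature_id)]
    sel <- if (subset == "chrX") chr == "chrX" else chr != "chrX" & !is.na(chr)
    sel[is.na(sel)] <- FALSE
    if (!any(sel)) stop("feature subset '", subset, "' is empty")
    values <- values[sel, , drop = FALSE]
  }
  if (ncol(values) < 2) stop("need at least two samples")
  pr <- prcomp(t(values), center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(scores = pr$x,
                 var_frac = pr$sdev^2 / sum(pr$sdev^2),
                 loadings = pr$rotation, subset = subset),
            class = "circlex_pca")
}

#' Mean silhouette separation of labeled samples in a score space
#'
#' Quantifies how well a labeling (origin, genetic background, ...) separates
#' samples in a Euclidean score space (e.g. PCA scores): positive values mean
#' the classes form distinct clouds, values near zero mean no separation.
#' Singleton classes are excluded with a warning.
#'
#' @param scores Samples x dimensions numeric matrix.
#' @param labels Class labels over samples (>= 2 classes with >= 2 samples).
#' @return Mean silhouette width.
#' @export
separation_score <- function(scores, labels) {
  f <- factor(labels)
  keep <- f %in% names(which(table(f) >= 2))
  if (!all(keep)) {
    warning("excluding singleton class(es): ",
            paste(setdiff(levels(f), names(which(table(f) >= 2))), collapse = ", "))
    scores <- scores[keep, , drop = FALSE]
    f <- droplevels(f[keep])
  }
  if (nlevels(f) < 2) stop("need at least two classes with >= 2 samples")
  sil <- cluster::silhouette(as.integer(f), dist(scores))
  mean(sil[, "sil_width"])
}
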