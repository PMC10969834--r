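#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error `0.5 * ||X - W H||^2` over
#' non-negative factors with the classical multiplicative updates, which make
#' the objective non-increasing at every iteration.  Initialization is a
#' deterministic non-negative double-SVD split of the leading singular vectors;
#' zero entries of the initial factors are filled with small seeded uniform
#' values so no factor entry is stuck at an exact zero from the start.
#'
#' @param X Non-negative numeric matrix (features x samples).
#' @param k Number of components (`k <= min(dim(X))`).
#' @param seed Seed for the zero-fill of the initialization.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative objective improvement below which iteration stops.
#' @return A list of class `circlex_nmf`: `W` (features x k), `H`
#'   (k x samples), `objective` (per-iteration values), `iterations`,
#'   `converged`.
#' @export
fit_nmf <- function(X, k = 8, seed = 1L, max_iter = 500, tol = 1e-4) {
  if (any(X < 0)) stop("input matrix must be non-negative")
  if (k < 1 || k > min(dim(X))) stop("'k' must be in 1..min(dim(X))")
  n <- nrow(X); m <- ncol(X)

  ## non-negative double-SVD initialization
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn && nup * nvp > 0) {
      sig <- sqrt(s$d[j] * nup * nvp)
      W[, j] <- sig * up / nup; H[j, ] <- sig * vp / nvp
    } else if (nun * nvn > 0) {
      sig <- sqrt(s$d[j] * nun * nvn)
      W[, j] <- sig * un / nun; H[j, ] <- sig * vn / nvn
    }
  }
  set.seed(as.integer(seed))
  floor_val <- mean(X) * 1e-4 + 1e-12
  W[W < floor_val] <- floor_val * runif(sum(W < floor_val))
  H[H < floor_val] <- floor_val * runif(sum(H < floor_val))

  eps <- .Machine$double.eps
  obj <- numeric(max_iter)
  prev <- 0.5 * sum((X - W %*% H)^2)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj[it] <- 0.5 * sum((X - W %*% H)^2)
    if (prev - obj[it] < tol * max(prev, eps)) { converged <- TRUE }
    done <- converged
    prev <- obj[it]
    if (done) break
  }
  dimnames(W) <- list(rownames(X), paste0("C", seq_len(k)))
  dimnames(H) <- list(paste0("C", seq_len(k)), colnames(X))
  structure(list(W = W, H = H, objective = obj[seq_len(it)], iterations = it,
                 converged = converged, k = k, seed = as.integer(seed)),
            class = "circlex_nmf")
}

#' @export
print.circlex_nmf <- function(x, ...) {
  cat("NMF: k =", x$k, "|", x$iterations, "iterations | final objective",
      signif(x$objective[length(x$objective)], 6), "\n")
  invisible(x)
}

## Mann-Whitney AUROC with midrank tie handling
auroc <- function(x, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(x)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Rank NMF components by class-discrimination AUROC
#'
#' Computes, for every component, the area under the receiver operating
#' characteristic of its mixing-weight row for classifying the target class
#' against the rest (midrank tie handling), and ranks the components in
#' decreasing order.
#'
#' @param H Components x samples mixing-weight matrix.
#' @param class_labels Character/factor vector over samples.
#' @param target_class Label of the positive class.
#' @return List: `component_auroc` (named, in component order), `ranking`
#'   (component indices sorted by decreasing AUROC).
#' @export
rank_components <- function(H, class_labels, target_class) {
  pos <- class_labels == target_class
  if (all(pos) || !any(pos)) stop("both classes must be present")
  a <- apply(H, 1, auroc, positive = pos)
  list(component_auroc = a, ranking = order(a, decreasing = TRUE))
}

#' Ridge-penalized logistic regression with non-negative weights
#'
#' Minimizes the logistic loss plus a small ridge penalty on the weights,
#' subject to elementwise non-negativity (the intercept is free and
#' unpenalized).  The objective is strictly convex, so the constrained optimum
#' is unique; it is found by a box-constrained quasi-Newton search from the
#' fixed start `w = 0, b = log-odds`, which in the small-ridge limit maximizes
#' the margin for separable data.
#'
#' @param H Components x samples matrix of non-negative features.
#' @param class_labels Labels over samples.
#' @param target_class Positive class label.
#' @param ridge Ridge penalty on the weights.
#' @param max_iter Iteration cap.
#' @return List: `w` (non-negative weights, one per component), `b`
#'   (intercept), `objective` (at the optimum), `converged`.
#' @export
fit_nonneg_logistic <- function(H, class_labels, target_class, ridge = 1e-3,
                                max_iter = 1000) {
  pos <- class_labels == target_class
  if (all(pos) || !any(pos)) stop("both classes must be present")
  X <- t(H)
  y <- ifelse(pos, 1, -1)
  k <- ncol(X)
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
  fn <- function(th) {
    eta <- drop(X %*% th[1:k]) + th[k + 1]
    sum(softplus(-y * eta)) + 0.5 * ridge * sum(th[1:k]^2)
  }
  gr <- function(th) {
    eta <- drop(X %*% th[1:k]) + th[k + 1]
    s <- plogis(-y * eta)
    c(-drop(crossprod(X, y * s)) + ridge * th[1:k], -sum(y * s))
  }
  p0 <- mean(pos)
  th0 <- c(rep(0, k), log(p0 / (1 - p0)))
  fit <- optim(th0, fn, gr, method = "L-BFGS-B",
               lower = c(rep(0, k), -Inf),
               control = list(maxit = max_iter, factr = 1e4))
  if (fit$convergence != 0)
    stop("non-negative logistic fit did not converge (code ",
         fit$convergence, "): ", fit$message)
  w <- fit$par[1:k]
  names(w) <- rownames(H)
  list(w = w, b = fit$par[k + 1], objective = fit$value, converged = TRUE)
}

#' Project a sample onto a non-negative basis by NNLS
#'
#' Non-negative least squares solution of `min ||x - W h||^2, h >= 0` for a
#' single profile or the columns of a matrix, used to express new samples in
#' the reference component space.
#'
#' @param x Numeric vector (genes) or genes x samples matrix, aligned to the
#'   rows of `W`.
#' @param W Genes x k non-negative basis.
#' @return Non-negative weight vector (or k x samples matrix).
#' @export
project_sample <- function(x, W) {
  if (is.matrix(x)) {
    if (!is.null(rownames(x)) && !is.null(rownames(W))) {
      miss <- setdiff(rownames(W), rownames(x))
      if (length(miss) > 0)
        stop("sample profile is missing basis genes: ",
             paste(head(miss, 5), collapse = ", "))
      x <- x[rownames(W), , drop = FALSE]
    }
    if (nrow(x) != nrow(W)) stop("gene dimension mismatch")
    out <- apply(x, 2, function(col) pracma::lsqnonneg(W, col)$x)
    rownames(out) <- colnames(W)
    return(out)
  }
  if (!is.null(names(x)) && !is.null(rownames(W))) {
    miss <- setdiff(rownames(W), names(x))
    if (length(miss) > 0)
      stop("sample profile is missing basis genes: ",
           paste(head(miss, 5), collapse = ", "))
    x <- x[rownames(W)]
  }
  if (length(x) != nrow(W)) stop("gene dimension mismatch")
  h <- pracma::lsqnonneg(W, as.numeric(x))$x
  names(h) <- colnames(W)
  h
}

#' Fit a reference-based tissue score model
#'
#' PluriTest-style construction, applied to any target tissue: shift the
#' reference expression matrix to non-negativity, factorize it with NMF
#' (`k` components), rank the components by target-vs-rest AUROC, and fit a
#' non-negative logistic combination of the mixing weights.  The same basis
#' may be shared between models for different target classes (e.g. a
#' pluripotency and a neurality score) via the `nmf` argument.
#'
#' @param values Genes x samples reference expression matrix (log2 scale).
#' @param labels Class labels over samples.
#' @param target_class Positive class ("pluripotent", "brain", ...).
#' @param k Number of NMF components.
#' @param seed Seed for the NMF initialization.
#' @param nmf Optional pre-computed `circlex_nmf` fit of the shifted reference
#'   (to share one basis between score axes).
#' @param shift Non-negativity shift; defaults to the global minimum of
#'   `values`, recorded in the model and reapplied at projection.
#' @param ridge Ridge penalty of the logistic combination.
#' @param ... Further arguments to [fit_nmf()].
#' @return An object of class `tissue_score_model`.
#' @export
fit_tissue_score_model <- function(values, labels, target_class, k = 8,
                                   seed = 1L, nmf = NULL, shift = NULL,
                                   ridge = 1e-3, ...) {
  if (is.null(shift)) shift <- min(values)
  if (is.null(nmf)) nmf <- fit_nmf(values - shift, k = k, seed = seed, ...)
  ranking <- rank_components(nmf$H, labels, target_class)
  lg <- fit_nonneg_logistic(nmf$H, labels, target_class, ridge = ridge)
  structure(list(W = nmf$W, shift = shift, k = nmf$k, seed = nmf$seed,
                 component_auroc = ranking$component_auroc,
                 ranking = ranking$ranking, w = lg$w, b = lg$b,
                 target_class = target_class, gene_ids = rownames(values)),
            class = "tissue_score_model")
}

#' @export
print.tissue_score_model <- function(x, ...) {
  cat("tissue score model: target =", x$target_class, "| k =", x$k, "\n")
  cat("  component AUROC:",
      paste(signif(x$component_auroc[x$ranking], 3), collapse = ", "), "\n")
  cat("  positive weights:", sum(x$w > 1e-8), "of", x$k,
      "| intercept", signif(x$b, 4), "\n")
  invisible(x)
}

#' Score samples with a tissue score model
#'
#' Applies the recorded non-negativity shift, projects each sample onto the
#' model basis by NNLS, and returns the logit-scale score `w . h + b`.  Genes
#' absent from the new data are dropped from the basis with a warning
#' (intersection projection).
#'
#' @param object A `tissue_score_model`.
#' @param newdata Genes x samples expression matrix (log2 scale).
#' @param ... Unused.
#' @return Named numeric vector of scores, one per sample.
#' @export
predict.tissue_score_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  common <- intersect(rownames(newdata), object$gene_ids)
  if (length(common) == 0) stop("no genes shared with the model basis")
  if (length(common) < length(object$gene_ids))
    warning(length(object$gene_ids) - length(common),
            " basis genes absent from the data; projecting on the intersection")
  W <- object$W[match(common, object$gene_ids), , drop = FALSE]
  Xs <- newdata[common, , drop = FALSE] - object$shift
  Hn <- apply(Xs, 2, function(col) pracma::lsqnonneg(W, col)$x)
  scores <- drop(object$w %*% Hn) + object$b
  names(scores) <- colnames(newdata)
  scores
}

#' Pluripotency and neurality score pairs
#'
#' Scores every sample with a pluripotency model and a neurality model trained
#' on the same reference basis, yielding the two-axis representation on which
#' pluripotent cells, neural tissue and intermediate NSC-like populations
#' separate.
#'
#' @param values Genes x samples expression matrix.
#' @param model_pluri,model_neural `tissue_score_model` objects.
#' @return Data frame: sample_id, pluripotency_score, neurality_score (in
#'   input sample order).
#' @export
score_samples <- function(values, model_pluri, model_neural) {
  data.frame(sample_id = colnames(values),
             pluripotency_score = unname(predict(model_pluri, values)),
             neurality_score = unname(predict(model_neural, values)),
             row.names = NULL)
}
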