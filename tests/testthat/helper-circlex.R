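# shared fixtures and independent oracles

small_config <- function(seed = 1L, ...) {
  args <- list(n_genes_autosomal = 1200, n_genes_x = 300,
               n_cpgs_autosomal = 1200, n_cpgs_x = 400, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

small_dataset <- function(seed = 1L, ...) {
  cfg <- small_config(seed = seed, ...)
  ann <- generate_annotation(cfg)
  list(config = cfg, annotation = ann,
       expr = generate_expression(cfg, ann),
       meth = generate_methylation(cfg, ann))
}

nsc_subset <- function(expr) {
  keep <- expr$samples$origin %in% c("ESC-NSC", "iPSC-NSC")
  list(values = expr$values[, keep, drop = FALSE],
       samples = expr$samples[keep, , drop = FALSE],
       groups = factor(expr$samples$origin[keep],
                       levels = c("ESC-NSC", "iPSC-NSC")))
}

# independent BH step-up: sort ascending, p_(i) * n / i, running min from the
# top, cap at 1, restore input order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force hypergeometric upper tail by enumerating every draw of n from N
# (category = elements 1..K)
enum_hyper_upper <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# closed-form hypergeometric upper tail from binomial coefficients (for
# universes too large to enumerate draws)
choose_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force AUROC by counting pairs (ties count 1/2)
auroc_oracle <- function(x, positive) {
  xp <- x[positive]; xn <- x[!positive]
  wins <- outer(xp, xn, ">")
  ties <- outer(xp, xn, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(xp) * length(xn))
}
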