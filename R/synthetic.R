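#' Configuration for the synthetic circular-reprogramming dataset
#'
#' Bundles every knob of the seeded generators.  The defaults encode the study
#' conditions the pipeline is designed for: roughly 10,500 expression probes and
#' 20,000 CpGs over 24 arrays, two female genetic backgrounds, three independent
#' experiments (batches), biological triplicates per line, an X-chromosomal
#' upregulation planted in iPSC-derived samples and concentrated in a few
#' genomic clusters, and X-CpGs whose beta value sits near 0.5 in ESC-derived
#' NSCs but splits to hyper-/hypomethylation in iPSC-derived NSCs.
#'
#' @param n_genes_autosomal,n_genes_x Number of autosomal / X-chromosomal gene
#'   probes.
#' @param n_cpgs_autosomal,n_cpgs_x Number of autosomal / X-chromosomal CpGs.
#' @param n_backgrounds Number of genetic backgrounds (cell lines of origin).
#' @param n_batches Number of independent experiments (batches).
#' @param replicates_per_line Biological replicates per expression line.
#' @param meth_replicates Biological replicates per line on the methylation
#'   array (the study used duplicates).
#' @param effect_x_log2 log2 expression shift planted on affected X genes in
#'   iPSC-derived samples.
#' @param frac_x_affected Fraction of X genes carrying the planted upregulation.
#' @param n_x_clusters Number of genomic clusters holding the affected X genes.
#' @param cluster_width Width of each planted cluster in bp.
#' @param batch_sd,background_sd,lineage_sd,noise_sd log2-scale standard
#'   deviations of the per-gene batch, background and lineage (pluripotent vs
#'   NSC) effects, and of the residual noise.
#' @param beta_noise_sd Beta-scale noise standard deviation for methylation.
#' @param dm_hyper_target,dm_hypo_target iPSC-NSC beta means at planted
#'   hyper-/hypomethylated X-CpGs (ESC-NSC mean is 0.5 at those CpGs).
#' @param frac_x_dm Fraction of X CpGs planted as differentially methylated.
#' @param dm_cluster_frac Fraction of planted DM CpGs placed inside expression
#'   clusters (co-localization ground truth).
#' @param n_dm_clusters Number of leading expression clusters that receive the
#'   in-cluster DM CpGs.
#' @param seed Integer seed; equal (config, seed) gives bit-identical output.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes_autosomal = 500, n_genes_x = 100,
#'                         n_cpgs_autosomal = 500, n_cpgs_x = 200, seed = 1)
synthetic_config <- function(n_genes_autosomal = 10000, n_genes_x = 500,
                             n_cpgs_autosomal = 19000, n_cpgs_x = 1000,
                             n_backgrounds = 2, n_batches = 3,
                             replicates_per_line = 3, meth_replicates = 2,
                             effect_x_log2 = 1.0, frac_x_affected = 0.12,
                             n_x_clusters = 3, cluster_width = 1e7,
                             batch_sd = 0.5, background_sd = 0.7,
                             lineage_sd = 2.0, noise_sd = 0.25,
                             beta_noise_sd = 0.05,
                             dm_hyper_target = 0.8, dm_hypo_target = 0.2,
                             frac_x_dm = 0.10, dm_cluster_frac = 0.8,
                             n_dm_clusters = 2, seed = 1L) {
  cfg <- list(n_genes_autosomal = n_genes_autosomal, n_genes_x = n_genes_x,
              n_cpgs_autosomal = n_cpgs_autosomal, n_cpgs_x = n_cpgs_x,
              n_backgrounds = n_backgrounds, n_batches = n_batches,
              replicates_per_line = replicates_per_line,
              meth_replicates = meth_replicates,
              effect_x_log2 = effect_x_log2, frac_x_affected = frac_x_affected,
              n_x_clusters = n_x_clusters, cluster_width = cluster_width,
              batch_sd = batch_sd, background_sd = background_sd,
              lineage_sd = lineage_sd, noise_sd = noise_sd,
              beta_noise_sd = beta_noise_sd,
              dm_hyper_target = dm_hyper_target, dm_hypo_target = dm_hypo_target,
              frac_x_dm = frac_x_dm, dm_cluster_frac = dm_cluster_frac,
              n_dm_clusters = n_dm_clusters, seed = as.integer(seed))
  counts <- c("n_genes_autosomal", "n_cpgs_autosomal", "n_backgrounds",
              "n_batches", "replicates_per_line", "meth_replicates",
              "n_x_clusters")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) || cfg[[nm]] < 1)
      stop("'", nm, "' must be a positive count")
  if (cfg$n_genes_x < 0 || cfg$n_cpgs_x < 0)
    stop("feature counts must be non-negative")
  sds <- c("batch_sd", "background_sd", "lineage_sd", "noise_sd", "beta_noise_sd")
  for (nm in sds)
    if (cfg[[nm]] < 0) stop("'", nm, "' must be >= 0")
  for (nm in c("frac_x_affected", "frac_x_dm", "dm_cluster_frac",
               "dm_hyper_target", "dm_hypo_target"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop("'", nm, "' must be in [0, 1]")
  if (cfg$cluster_width <= 0) stop("'cluster_width' must be > 0")
  if (is.na(cfg$seed)) stop("'seed' must be an integer")
  Lx <- circlex_chromosomes()[["chrX"]]
  if (cfg$n_x_clusters * cfg$cluster_width > Lx)
    stop("planted clusters (", cfg$n_x_clusters, " x ", cfg$cluster_width,
         " bp) exceed the chrX length of ", Lx, " bp")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:",
      x$n_genes_autosomal + x$n_genes_x, "genes,",
      x$n_cpgs_autosomal + x$n_cpgs_x, "CpGs,",
      x$n_backgrounds, "backgrounds,", x$n_batches, "batches, seed", x$seed, "\n")
  invisible(x)
}

## Draw n positions uniformly on [1, L] excluding the given [start, end)
## intervals (assumed disjoint); used so that unaffected X genes never fall
## inside a planted cluster, keeping the cluster ground truth exact.
positions_outside <- function(n, L, intervals) {
  if (n == 0) return(numeric(0))
  if (nrow(intervals) == 0) return(1 + floor(runif(n, 0, L)))
  iv <- intervals[order(intervals$start), , drop = FALSE]
  gap_start <- c(1, iv$end)
  gap_len <- pmax(c(iv$start, L + 1) - gap_start, 0)
  free <- sum(gap_len)
  u <- 1 + floor(runif(n, 0, free))       # 1..free
  cum <- cumsum(c(0, gap_len))
  j <- findInterval(u - 0.5, cum)
  gap_start[j] + (u - cum[j]) - 1
}

## map each CpG to the nearest gene on its chromosome (symbol or NA)
nearest_gene_symbol <- function(chr, pos, genes) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chr)) {
    g <- genes[genes$chromosome == ch, , drop = FALSE]
    sel <- which(chr == ch)
    if (nrow(g) == 0) next
    o <- order(g$position)
    gp <- g$position[o]; gs <- g$gene_symbol[o]
    i <- findInterval(pos[sel], gp)
    lo <- pmax(i, 1); hi <- pmin(i + 1, length(gp))
    left <- abs(pos[sel] - gp[lo]) <= abs(gp[hi] - pos[sel])
    out[sel] <- ifelse(left, gs[lo], gs[hi])
  }
  out
}

#' Generate the synthetic gene and CpG annotation
#'
#' Lays out gene probes and CpGs on a human-like genome.  Affected X genes are
#' placed inside `n_x_clusters` disjoint intervals (one per equal-width chrX
#' segment); all other X genes are placed outside those intervals, so the
#' recorded cluster intervals are exact ground truth.  A fraction of the planted
#' DM CpGs is placed inside the leading clusters to create co-localization
#' ground truth.  Each CpG is annotated with the symbol of its nearest gene.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `circlex_annotation` with elements `genes` and
#'   `cpgs` (data frames: feature_id, chromosome, position, gene_symbol),
#'   `x_clusters` (cluster, start, end, half-open), `affected_x_genes`,
#'   `dm_x_cpgs` (feature ids) and `chrom_lengths`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lens <- circlex_chromosomes()
  Lx <- lens[["chrX"]]

  ## disjoint clusters: one uniform placement per equal chrX segment
  k <- config$n_x_clusters
  seg <- floor(Lx / k)
  if (config$cluster_width > seg)
    stop("cluster_width exceeds the chrX segment length available per cluster")
  starts <- (seq_len(k) - 1) * seg + 1 +
    floor(runif(k, 0, seg - config$cluster_width))
  x_clusters <- data.frame(cluster = seq_len(k), start = starts,
                           end = starts + config$cluster_width)

  ## genes
  n_a <- config$n_genes_autosomal
  n_x <- config$n_genes_x
  n_aff <- round(config$frac_x_affected * n_x)
  a_chr <- sample(AUTOSOMES, n_a, replace = TRUE,
                  prob = lens[AUTOSOMES] / sum(lens[AUTOSOMES]))
  a_pos <- 1 + floor(runif(n_a, 0, lens[a_chr]))
  aff_cluster <- if (n_aff > 0) sample(seq_len(k), n_aff, replace = TRUE) else integer(0)
  aff_pos <- x_clusters$start[aff_cluster] +
    floor(runif(n_aff, 0, config$cluster_width))
  other_pos <- positions_outside(n_x - n_aff, Lx, x_clusters)
  gene_id <- sprintf("gene_%05d", seq_len(n_a + n_x))
  genes <- data.frame(
    feature_id = gene_id,
    chromosome = c(a_chr, rep("chrX", n_x)),
    position = c(a_pos, aff_pos, other_pos),
    gene_symbol = toupper(gene_id))
  affected_x_genes <- gene_id[n_a + seq_len(n_aff)]

  ## CpGs
  n_ca <- config$n_cpgs_autosomal
  n_cx <- config$n_cpgs_x
  n_dm <- round(config$frac_x_dm * n_cx)
  n_in <- round(config$dm_cluster_frac * n_dm)
  ca_chr <- sample(AUTOSOMES, n_ca, replace = TRUE,
                   prob = lens[AUTOSOMES] / sum(lens[AUTOSOMES]))
  ca_pos <- 1 + floor(runif(n_ca, 0, lens[ca_chr]))
  dm_clusters <- seq_len(min(config$n_dm_clusters, k))
  in_cluster <- if (n_in > 0) sample(dm_clusters, n_in, replace = TRUE) else integer(0)
  dm_pos <- c(x_clusters$start[in_cluster] +
                floor(runif(n_in, 0, config$cluster_width)),
              1 + floor(runif(n_dm - n_in, 0, Lx)))
  cx_pos <- c(dm_pos, 1 + floor(runif(n_cx - n_dm, 0, Lx)))
  cpg_id <- sprintf("cg%07d", seq_len(n_ca + n_cx))
  cpgs <- data.frame(
    feature_id = cpg_id,
    chromosome = c(ca_chr, rep("chrX", n_cx)),
    position = c(ca_pos, cx_pos),
    gene_symbol = NA_character_)
  cpgs$gene_symbol <- nearest_gene_symbol(cpgs$chromosome, cpgs$position, genes)
  dm_x_cpgs <- cpg_id[n_ca + seq_len(n_dm)]

  structure(list(genes = genes, cpgs = cpgs, x_clusters = x_clusters,
                 affected_x_genes = affected_x_genes, dm_x_cpgs = dm_x_cpgs,
                 chrom_lengths = lens),
            class = "circlex_annotation")
}

## sample sheet shared by the generators: per background one ESC-NSC line and
## two iPSC-NSC lines; background 1 additionally contributes the parental ESC
## line and one iPSC line.  Replicates rotate through batches (experiment =
## batch, crossing lines as in the study design).
build_sample_sheet <- function(config, nsc_only = FALSE,
                               replicates = config$replicates_per_line) {
  lines <- list()
  for (b in seq_len(config$n_backgrounds)) {
    lines[[length(lines) + 1]] <- c(sprintf("ESC-NSC_bg%d", b), "ESC-NSC", b)
    for (j in 1:2)
      lines[[length(lines) + 1]] <- c(sprintf("iPSC-NSC_bg%d_%d", b, j), "iPSC-NSC", b)
  }
  if (!nsc_only) {
    lines[[length(lines) + 1]] <- c("ESC_bg1", "ESC", 1)
    lines[[length(lines) + 1]] <- c("iPSC_bg1", "iPSC", 1)
  }
  df <- do.call(rbind, lapply(lines, function(l) {
    data.frame(line = l[1], origin = l[2], background = as.integer(l[3]))
  }))
  df <- df[rep(seq_len(nrow(df)), each = replicates), ]
  df$replicate <- rep(seq_len(replicates), length(lines))
  df$batch <- ((df$replicate - 1) %% config$n_batches) + 1L
  df$sample_id <- sprintf("%s_r%d", df$line, df$replicate)
  rownames(df) <- NULL
  df[, c("sample_id", "line", "origin", "background", "batch", "replicate")]
}

#' Generate the synthetic expression matrix
#'
#' Per gene g and sample i the log2 intensity is
#' `mu_g + bg_g * background_i + batch_g * batch_i + lin_g * lineage_i +
#' delta * [i iPSC-derived and g affected-X] + noise`, with per-gene effect
#' coefficients drawn from centred normals with the configured sds (integer
#' 0-based covariate coding), `mu_g ~ N(7, 1.5)` and `delta = effect_x_log2`.
#' The heterogeneous per-gene background/batch coefficients give surrogate
#' variable analysis realistic confounding to remove.
#'
#' @param config A [synthetic_config()].
#' @param annotation Output of [generate_annotation()] for the same config.
#' @return A list of class `circlex_expression`: `values` (genes x samples
#'   log2 matrix), `samples` (metadata data frame), `affected_genes`, `config`.
#' @export
generate_expression <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(annotation, "circlex_annotation"))
  set.seed(config$seed + 1L)
  smp <- build_sample_sheet(config)
  genes <- annotation$genes
  G <- nrow(genes); S <- nrow(smp)

  mu <- rnorm(G, 7, 1.5)
  bg_g <- rnorm(G, 0, config$background_sd)
  batch_g <- rnorm(G, 0, config$batch_sd)
  lin_g <- rnorm(G, 0, config$lineage_sd)

  bg_i <- smp$background - 1
  batch_i <- smp$batch - 1
  lin_i <- as.numeric(smp$origin %in% c("ESC", "iPSC"))
  ipsc_i <- smp$origin %in% c("iPSC", "iPSC-NSC")

  Y <- mu + outer(bg_g, bg_i) + outer(batch_g, batch_i) + outer(lin_g, lin_i)
  aff <- genes$feature_id %in% annotation$affected_x_genes
  if (any(aff) && any(ipsc_i))
    Y[aff, ipsc_i] <- Y[aff, ipsc_i] + config$effect_x_log2
  Y <- Y + matrix(rnorm(G * S, 0, config$noise_sd), G, S)
  dimnames(Y) <- list(genes$feature_id, smp$sample_id)

  structure(list(values = Y, samples = smp,
                 affected_genes = annotation$affected_x_genes, config = config),
            class = "circlex_expression")
}

#' Generate the synthetic methylation (beta-value) matrix
#'
#' NSC lines only, `meth_replicates` biological replicates each.  Non-DM CpGs
#' draw a per-CpG baseline mean from \{0.1, 0.5, 0.9\} shared by both groups.
#' Planted DM X-CpGs have ESC-NSC mean 0.5 and iPSC-NSC mean `dm_hyper_target`
#' or `dm_hypo_target` (half each).  Gaussian beta-scale noise is added and
#' values are clipped to \[0, 1\].
#'
#' @param config A [synthetic_config()].
#' @param annotation Output of [generate_annotation()] for the same config.
#' @return A list of class `circlex_methylation`: `values` (CpGs x samples beta
#'   matrix), `samples`, `dm_truth` (data frame cpg_id, direction), `config`.
#' @export
generate_methylation <- function(config, annotation) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(annotation, "circlex_annotation"))
  set.seed(config$seed + 2L)
  smp <- build_sample_sheet(config, nsc_only = TRUE,
                            replicates = config$meth_replicates)
  cpgs <- annotation$cpgs
  C <- nrow(cpgs); S <- nrow(smp)

  base <- sample(c(0.1, 0.5, 0.9), C, replace = TRUE)
  M <- matrix(base, C, S)
  dm <- cpgs$feature_id %in% annotation$dm_x_cpgs
  n_dm <- sum(dm)
  dirs <- character(0)
  if (n_dm > 0) {
    dirs <- sample(rep(c("hyper", "hypo"), length.out = n_dm))
    ipsc_i <- smp$origin == "iPSC-NSC"
    M[dm, ] <- 0.5
    target <- ifelse(dirs == "hyper", config$dm_hyper_target, config$dm_hypo_target)
    M[dm, ipsc_i] <- matrix(target, n_dm, sum(ipsc_i))
  }
  M <- M + matrix(rnorm(C * S, 0, config$beta_noise_sd), C, S)
  M <- pmin(pmax(M, 0), 1)
  dimnames(M) <- list(cpgs$feature_id, smp$sample_id)

  structure(list(values = M, samples = smp,
                 dm_truth = data.frame(cpg_id = cpgs$feature_id[dm],
                                       direction = dirs),
                 config = config),
            class = "circlex_methylation")
}

#' Generate a labeled reference cohort for score training
#'
#' Samples are non-negative mixtures of `k_signatures` non-negative gene
#' signatures.  Class-specific mixing-weight means (pluripotent samples load on
#' signature 1, brain samples on signature 2, other tissues on the remaining
#' signatures) make the classes linearly separable in component space; all
#' sample-level noise enters through the mixing weights.  Optional `n_mixture`
#' "NSC-like" samples mix the pluripotent and brain weight means equally.  The
#' default class sizes 98/34/200 mirror the proportions of a public
#' pluripotency reference compendium at reduced scale.
#'
#' @param n_pluripotent,n_brain,n_other,n_mixture Class sizes.
#' @param k_signatures Number of gene signatures (>= 3).
#' @param n_genes Number of genes.
#' @param mix_noise_sd Standard deviation of the mixing-weight noise.
#' @param seed Integer seed.
#' @return A list of class `circlex_reference`: `values` (genes x samples,
#'   non-negative), `labels` (pluripotent/brain/other/mixture), `samples`,
#'   `signatures` (true W), `weights` (true H), `mix_noise_sd`.
#' @export
generate_reference <- function(n_pluripotent = 98, n_brain = 34, n_other = 200,
                               n_mixture = 0, k_signatures = 8, n_genes = 2000,
                               mix_noise_sd = 0.3, seed = 1L) {
  stopifnot(n_pluripotent > 0, n_brain > 0, n_other > 0, n_mixture >= 0,
            k_signatures >= 3, n_genes >= k_signatures, mix_noise_sd >= 0)
  set.seed(as.integer(seed))
  k <- k_signatures
  W <- matrix(abs(rnorm(n_genes * k)), n_genes, k)

  mean_for <- function(class) {
    m <- rep(0.5, k)
    if (class == "pluripotent") m[1] <- m[1] + 3.5
    if (class == "brain") m[2] <- m[2] + 3.5
    if (class == "other") m[3:k] <- m[3:k] + 1.5
    if (class == "mixture")
      m <- (mean_for("pluripotent") + mean_for("brain")) / 2
    m
  }
  labels <- rep(c("pluripotent", "brain", "other", "mixture"),
                c(n_pluripotent, n_brain, n_other, n_mixture))
  Hmean <- vapply(labels, mean_for, numeric(k))
  H <- pmax(Hmean + matrix(rnorm(k * length(labels), 0, mix_noise_sd),
                           k, length(labels)), 0)
  X <- W %*% H
  ids <- sprintf("ref_%s_%03d", labels, stats::ave(seq_along(labels), labels,
                                                   FUN = seq_along))
  dimnames(X) <- list(sprintf("refgene_%05d", seq_len(n_genes)), ids)
  colnames(H) <- ids

  structure(list(values = X, labels = labels,
                 samples = data.frame(sample_id = ids, class = labels),
                 signatures = W, weights = H, mix_noise_sd = mix_noise_sd),
            class = "circlex_reference")
}
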