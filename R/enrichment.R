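#' Upper-tail hypergeometric p value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at least
#' `k` category members in a draw of `n` features from a universe of `N` that
#' contains `K` category members.  This one-sided overrepresentation test
#' backs every enrichment call in the package.
#'
#' @param k Observed hits.
#' @param K Category size in the universe.
#' @param n Query (draw) size.
#' @param N Universe size.
#' @return The upper-tail p value.
#' @export
#' @examples
#' hypergeometric_upper(5, 10, 10, 100)
hypergeometric_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-chromosome enrichment of a feature set
#'
#' Hypergeometric overrepresentation of a query feature set on every
#' chromosome of the annotation, with the measured features as universe.
#' If per-feature directions are supplied (e.g. up/down or hyper/hypo), each
#' directional subset is additionally tested as its own query.  BH adjustment
#' is applied across chromosomes within each test family.
#'
#' @param query Character vector of feature ids (subset of the annotation).
#' @param annotation Data frame with columns `feature_id` and `chromosome`
#'   covering all measured features (the universe).
#' @param directions Optional character or factor vector of directions aligned
#'   with `query`; factor levels force a test family even for an empty subset.
#' @return Data frame per chromosome: chromosome, K, n, N, k, p, adjusted_p,
#'   plus `k_<dir>`, `p_<dir>`, `adjusted_p_<dir>` per direction.
#' @export
chromosome_enrichment <- function(query, annotation, directions = NULL) {
  query <- unique(query)
  missing <- setdiff(query, annotation$feature_id)
  if (length(missing) > 0)
    stop("query features missing from annotation: ",
         paste(head(missing, 5), collapse = ", "))
  if (!is.null(directions) && length(directions) != length(query))
    stop("'directions' must align with the (deduplicated) query")

  chroms <- unique(annotation$chromosome)
  N <- nrow(annotation)
  n <- length(query)
  chr_of <- annotation$chromosome[match(query, annotation$feature_id)]

  test_family <- function(q_chr, n_q) {
    vapply(chroms, function(ch) {
      K <- sum(annotation$chromosome == ch)
      k <- sum(q_chr == ch)
      hypergeometric_upper(k, K, n_q, N)
    }, numeric(1))
  }

  out <- data.frame(chromosome = chroms,
                    K = vapply(chroms, function(ch)
                      sum(annotation$chromosome == ch), numeric(1)),
                    n = n, N = N,
                    k = vapply(chroms, function(ch) sum(chr_of == ch), numeric(1)))
  out$p <- test_family(chr_of, n)
  out$adjusted_p <- benjamini_hochberg(out$p)
  if (!is.null(directions)) {
    dir_levels <- if (is.factor(directions)) levels(directions)
      else sort(unique(directions))
    directions <- as.character(directions)
    for (d in dir_levels) {
      sel <- directions == d
      out[[paste0("k_", d)]] <- vapply(chroms, function(ch)
        sum(chr_of[sel] == ch), numeric(1))
      out[[paste0("p_", d)]] <- test_family(chr_of[sel], sum(sel))
      out[[paste0("adjusted_p_", d)]] <-
        benjamini_hochberg(out[[paste0("p_", d)]])
    }
  }
  rownames(out) <- NULL
  out
}

#' Overlap of a query gene set with curated gene sets
#'
#' Case-insensitive hypergeometric overlap of a query gene list with one or
#' several curated sets (e.g. from a GMT file), BH-adjusted across sets.
#'
#' @param query Character vector of gene symbols.
#' @param gene_sets A character vector (single set) or named list of character
#'   vectors.
#' @param universe Character vector of all measured gene symbols.
#' @return Data frame per set: set, k, K, n, N, p, adjusted_p; the overlapping
#'   symbols are attached as the list attribute `overlap`.
#' @export
geneset_overlap <- function(query, gene_sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  uni <- unique(toupper(universe))
  q <- intersect(unique(toupper(query)), uni)
  N <- length(uni); n <- length(q)
  res <- lapply(gene_sets, function(gs) {
    gs <- intersect(unique(toupper(gs)), uni)
    ov <- intersect(q, gs)
    list(k = length(ov), K = length(gs), p = hypergeometric_upper(
      length(ov), length(gs), n, N), overlap = ov)
  })
  out <- data.frame(set = names(gene_sets),
                    k = vapply(res, `[[`, numeric(1), "k"),
                    K = vapply(res, `[[`, numeric(1), "K"),
                    n = n, N = N,
                    p = vapply(res, `[[`, numeric(1), "p"),
                    row.names = NULL)
  out$adjusted_p <- benjamini_hochberg(out$p)
  attr(out, "overlap") <- lapply(res, `[[`, "overlap")
  out
}

#' Imprinted-gene enrichment among genes with a differentially methylated CpG
#'
#' Maps the called CpGs to genes through the annotation, deduplicates (a gene
#' counts once regardless of how many DM CpGs it holds), and tests the
#' gene-level overlap with an imprinted-gene list against the universe of all
#' genes covered by a measured CpG.
#'
#' @param dm_cpg_ids Character vector of called CpG ids.
#' @param cpg_annotation Data frame with `feature_id` and `gene_symbol`.
#' @param imprinted_genes Character vector of imprinted gene symbols.
#' @param universe_genes Optional gene universe; defaults to all genes with a
#'   measured CpG in the annotation.
#' @return List: p, k, K, n, N, genes (the overlapping imprinted genes).
#' @export
imprinted_enrichment <- function(dm_cpg_ids, cpg_annotation, imprinted_genes,
                                 universe_genes = NULL) {
  sym <- cpg_annotation$gene_symbol[match(dm_cpg_ids, cpg_annotation$feature_id)]
  if (anyNA(sym) && length(dm_cpg_ids) > 0 &&
      anyNA(match(dm_cpg_ids, cpg_annotation$feature_id)))
    stop("called CpGs missing from the annotation")
  if (is.null(universe_genes))
    universe_genes <- cpg_annotation$gene_symbol
  uni <- unique(toupper(universe_genes[!is.na(universe_genes)]))
  q <- unique(toupper(sym[!is.na(sym)]))
  imp <- intersect(unique(toupper(imprinted_genes)), uni)
  ov <- intersect(q, imp)
  p <- hypergeometric_upper(length(ov), length(imp), length(q), length(uni))
  list(p = p, k = length(ov), K = length(imp), n = length(q), N = length(uni),
       genes = ov)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then member gene symbols, all
#' tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}
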