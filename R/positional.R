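#' Sliding-window positional enrichment scan
#'
#' Tiles a chromosome with half-open windows `[start, start + window_bp)` every
#' `step_bp` and tests, per window, whether its hit count among the local
#' features exceeds the chromosome-wide hit rate by a one-sided binomial test.
#' BH adjustment is applied across windows; a window is flagged enriched when
#' its adjusted p value is below `alpha` and it holds at least `min_hits`
#' hits (guarding against single-feature windows on sparse chromosomes).
#'
#' @param hit_positions 1-based positions of the hit features (subset of
#'   `all_positions`).
#' @param all_positions 1-based positions of all measured features on the
#'   chromosome (the local universe).
#' @param chromosome Chromosome name (bookkeeping; also used to look up the
#'   default length).
#' @param chrom_length Chromosome length in bp; defaults to the packaged
#'   length for `chromosome`.
#' @param window_bp,step_bp Window width and step in bp (`window_bp >=
#'   step_bp > 0`).
#' @param alpha Enrichment level on the adjusted p value.
#' @param min_hits Minimum hit count for an enriched call.
#' @return Data frame of class `circlex_windows`: chromosome, start, end
#'   (half-open), m (features), k (hits), p, adjusted_p, enriched.
#' @export
window_scan <- function(hit_positions, all_positions, chromosome = "chrX",
                        chrom_length = NULL, window_bp = 1e7, step_bp = 1e6,
                        alpha = 0.05, min_hits = 3) {
  if (length(all_positions) == 0)
    stop("empty feature universe on ", chromosome)
  if (!(window_bp >= step_bp && step_bp > 0))
    stop("need window_bp >= step_bp > 0")
  if (!all(hit_positions %in% all_positions))
    stop("hit positions must be a subset of the feature universe positions")
  if (is.null(chrom_length)) {
    lens <- circlex_chromosomes()
    chrom_length <- if (chromosome %in% names(lens)) lens[[chromosome]]
      else max(all_positions)
  }

  starts <- seq(1, chrom_length, by = step_bp)
  ends <- starts + window_bp
  sa <- sort(all_positions)
  sh <- sort(hit_positions)
  count_in <- function(sorted, s, e)  # features with s <= pos < e
    findInterval(e - 1, sorted) - findInterval(s - 1, sorted)
  m <- count_in(sa, starts, ends)
  k <- count_in(sh, starts, ends)
  rho <- length(hit_positions) / length(all_positions)
  p <- ifelse(m == 0, 1, pbinom(k - 1, m, rho, lower.tail = FALSE))
  adj <- benjamini_hochberg(p)
  out <- data.frame(chromosome = chromosome, start = starts, end = ends,
                    m = m, k = k, p = p, adjusted_p = adj,
                    enriched = adj < alpha & k >= min_hits)
  class(out) <- c("circlex_windows", "data.frame")
  out
}

#' Co-localization of enriched windows across two modalities
#'
#' Pairs every enriched window of one scan (e.g. differentially expressed
#' genes) with every overlapping enriched window of another (e.g.
#' differentially methylated CpGs) on the same chromosome, and merges the
#' windows participating in pairs into maximal union intervals (connected
#' components of the overlap graph).
#'
#' @param windows_a,windows_b `circlex_windows` data frames on the same
#'   chromosome.
#' @return List of class `circlex_coloc`: `pairs` (one row per overlapping
#'   enriched pair with the overlap interval) and `merged` (union intervals).
#' @export
colocalize <- function(windows_a, windows_b) {
  chr <- unique(c(windows_a$chromosome, windows_b$chromosome))
  if (length(chr) != 1)
    stop("both window sets must be on the same chromosome")
  ea <- windows_a[windows_a$enriched, , drop = FALSE]
  eb <- windows_b[windows_b$enriched, , drop = FALSE]
  pairs <- data.frame(chromosome = character(0), a_start = numeric(0),
                      a_end = numeric(0), b_start = numeric(0),
                      b_end = numeric(0), overlap_start = numeric(0),
                      overlap_end = numeric(0))
  if (nrow(ea) > 0 && nrow(eb) > 0) {
    idx <- expand.grid(i = seq_len(nrow(ea)), j = seq_len(nrow(eb)))
    ov <- ea$start[idx$i] < eb$end[idx$j] & eb$start[idx$j] < ea$end[idx$i]
    idx <- idx[ov, , drop = FALSE]
    if (nrow(idx) > 0)
      pairs <- data.frame(
        chromosome = chr,
        a_start = ea$start[idx$i], a_end = ea$end[idx$i],
        b_start = eb$start[idx$j], b_end = eb$end[idx$j],
        overlap_start = pmax(ea$start[idx$i], eb$start[idx$j]),
        overlap_end = pmin(ea$end[idx$i], eb$end[idx$j]))
  }
  merged <- data.frame(chromosome = character(0), start = numeric(0),
                       end = numeric(0))
  if (nrow(pairs) > 0) {
    iv <- unique(rbind(data.frame(start = pairs$a_start, end = pairs$a_end),
                       data.frame(start = pairs$b_start, end = pairs$b_end)))
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    ms <- iv$start[1]; me <- iv$end[1]
    starts <- numeric(0); ends <- numeric(0)
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv$start[r] < me) me <- max(me, iv$end[r])
      else { starts <- c(starts, ms); ends <- c(ends, me)
             ms <- iv$start[r]; me <- iv$end[r] }
    }
    merged <- data.frame(chromosome = chr, start = c(starts, ms),
                         end = c(ends, me))
  }
  structure(list(pairs = pairs, merged = merged), class = "circlex_coloc")
}

#' @export
print.circlex_coloc <- function(x, ...) {
  cat("co-localization:", nrow(x$pairs), "overlapping window pairs,",
      nrow(x$merged), "merged regions\n")
  invisible(x)
}
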