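#' Chromosome lengths used by the synthetic genome
#'
#' Human-like chromosome lengths (hg19 magnitudes, rounded to the Mb) for
#' chr1..chr22 and chrX.  Only the relative magnitudes matter for the
#' statistics; positions are drawn uniformly within these lengths.
#'
#' @return Named numeric vector of basepair lengths.
#' @export
#' @examples
#' circlex_chromosomes()[["chrX"]]
circlex_chromosomes <- function() {
  c(chr1 = 249e6, chr2 = 243e6, chr3 = 198e6, chr4 = 191e6, chr5 = 181e6,
    chr6 = 171e6, chr7 = 159e6, chr8 = 146e6, chr9 = 141e6, chr10 = 136e6,
    chr11 = 135e6, chr12 = 134e6, chr13 = 115e6, chr14 = 107e6, chr15 = 103e6,
    chr16 = 90e6, chr17 = 81e6, chr18 = 78e6, chr19 = 59e6, chr20 = 63e6,
    chr21 = 48e6, chr22 = 51e6, chrX = 155e6)
}

AUTOSOMES <- paste0("chr", 1:22)
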