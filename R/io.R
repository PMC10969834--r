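#' Write a features x samples matrix as TSV
#'
#' First column `feature_id`, then one column per sample (header row of sample
#' ids).
#'
#' @param values Numeric matrix with row and column names.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(values, path) {
  df <- data.frame(feature_id = rownames(values), values,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features x samples TSV matrix
#'
#' @param path TSV written by [write_matrix_tsv()] (or equivalent layout).
#' @return Numeric matrix with feature ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a feature annotation as 4-column TSV
#'
#' Columns feature_id, chromosome, position (1-based), gene_symbol.
#'
#' @param annotation Annotation data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation[, c("feature_id", "chromosome", "position", "gene_symbol")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation TSV
#'
#' @param path TSV with columns feature_id, chromosome, position, gene_symbol.
#' @return Annotation data frame.
#' @export
read_annotation_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             colClasses = c("character", "character", "numeric", "character"))
}

#' Write genomic windows as BED
#'
#' Converts the 1-based half-open window intervals to 0-based half-open BED
#' coordinates (start - 1, end - 1); the score column carries -log10 of the
#' adjusted p value.
#'
#' @param windows A `circlex_windows` data frame.
#' @param path Output file.
#' @param enriched_only Write only enriched windows (default TRUE).
#' @return The path, invisibly.
#' @export
windows_to_bed <- function(windows, path, enriched_only = TRUE) {
  w <- if (enriched_only) windows[windows$enriched, , drop = FALSE] else windows
  bed <- data.frame(chrom = w$chromosome,
                    start = w$start - 1,
                    end = w$end - 1,
                    name = sprintf("window_%d", seq_len(nrow(w))),
                    score = round(-log10(pmax(w$adjusted_p, 1e-300)), 3))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Save / load a tissue score model as a JSON + TSV bundle
#'
#' The scalar parts (weights, intercept, shift, AUROCs, target class) go into
#' `model.json`; the basis matrix goes into `basis.tsv`.
#'
#' @param model A `tissue_score_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_score_model`: the directory, invisibly;
#'   `load_score_model`: the restored model.
#' @export
save_score_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(target_class = model$target_class, k = model$k,
               seed = model$seed, shift = model$shift,
               component_auroc = unname(model$component_auroc),
               ranking = model$ranking, w = unname(model$w), b = model$b)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_matrix_tsv(model$W, file.path(dir, "basis.tsv"))
  invisible(dir)
}

#' @rdname save_score_model
#' @export
load_score_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  W <- read_matrix_tsv(file.path(dir, "basis.tsv"))
  w <- meta$w
  names(w) <- colnames(W)
  structure(list(W = W, shift = meta$shift, k = meta$k, seed = meta$seed,
                 component_auroc = meta$component_auroc,
                 ranking = meta$ranking, w = w, b = meta$b,
                 target_class = meta$target_class, gene_ids = rownames(W)),
            class = "tissue_score_model")
}
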