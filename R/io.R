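## Plain-text interchange formats. Genomic coordinates are 0-based with
## half-open [start, end) intervals everywhere, BED-compatible natively.

#' Write / read the probe annotation table (TSV)
#'
#' Columns: probe_id, chrom, pos (0-based), gene, cross_reactive,
#' snp_overlap.
#'
#' @param annotation annotation `data.frame`.
#' @param path file path.
#' @return `read_annotation` returns the annotation `data.frame`.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(
    annotation[c("probe_id", "chrom", "pos", "gene", "cross_reactive",
                 "snp_overlap")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos", "gene", "cross_reactive",
            "snp_overlap")
  missing <- setdiff(need, names(ann))
  stop_if_not(length(missing) == 0, "annotation file lacks column(s): ",
              paste(missing, collapse = ", "))
  bad <- which(!is.finite(ann$pos))
  stop_if_not(length(bad) == 0,
              "non-numeric position at line ", bad[1] + 1L)
  ann$cross_reactive <- as.logical(ann$cross_reactive)
  ann$snp_overlap <- as.logical(ann$snp_overlap)
  ann
}

#' Write / read a numeric matrix as TSV (probe rows, sample columns)
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stop_if_not(names(df)[1] == "probe_id", "first column must be probe_id")
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    stop("non-numeric value at line ", bad[1, 1] + 1L, ", column ",
         colnames(m)[bad[1, 2]], call. = FALSE)
  }
  rownames(m) <- df$probe_id
  m
}

#' Write / read the phenotype table (CSV)
#'
#' @param pheno phenotype `data.frame`.
#' @param path file path.
#' @return `read_pheno` returns the `data.frame`.
#' @export
write_pheno <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the simulation ground truth (JSON)
#'
#' @param truth truth list from [simulate_cohorts()].
#' @param path file path.
#' @return `read_truth` returns the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$planted_regions <- as.data.frame(raw$planted_regions,
                                       stringsAsFactors = FALSE)
  raw$contaminant_probes <- as.data.frame(raw$contaminant_probes,
                                          stringsAsFactors = FALSE)
  raw
}

#' Export bump tables
#'
#' `write_bumps_tsv` writes the full-detail table; `write_bumps_bed`
#' writes a BED6-compatible file (chrom, start, end,
#' name = cluster/rank, score = -log10 p, strand = effect sign).
#'
#' @param bumps the `bumps` element of a [bump_hunt()] fit.
#' @param path file path.
#' @export
write_bumps_tsv <- function(bumps, path) {
  utils::write.table(bumps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bumps_tsv
#' @export
write_bumps_bed <- function(bumps, path) {
  bed <- data.frame(chrom = bumps$chrom, start = bumps$start,
                    end = bumps$end,
                    name = paste0("cluster", bumps$cluster_id, "_rank",
                                  seq_len(nrow(bumps))),
                    score = round(-log10(bumps$p_value), 4),
                    strand = ifelse(bumps$sign > 0, "+", "-"),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a JSON summary
#'
#' @param x a list of scalars / vectors / data.frames.
#' @param path file path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
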