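## Plain-text interchange formats: expression/annotation TSV and the
## GCT-like perturbation-catalog layout (version line, dimension line, then
## id/description columns ahead of one column per perturbagen).

#' Write an expression matrix as TSV
#'
#' Genes as rows, samples as columns, first column `gene_id`.
#'
#' @param values numeric matrix with gene rownames.
#' @param path output path.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression TSV written by [write_expression_tsv()]
#'
#' @param path input path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a sample annotation table as TSV
#'
#' @param annotation data.frame with a `sample_id` column.
#' @param path output path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a sample annotation TSV
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a perturbation catalog in GCT-like text
#'
#' Layout: `#1.2`-style header line, a dimension line, then a table whose
#' first two columns are the gene id and a description, one column per
#' perturbagen. Perturbagen metadata (type, perturbed gene, declared drug
#' target) are stored as three comment lines after the header.
#'
#' @param catalog a `perturbation_catalog`.
#' @param path output path.
#' @export
write_gct <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(catalog$values), ncol(catalog$values)), con)
  writeLines(paste(c("#type", catalog$meta$type), collapse = "\t"), con)
  writeLines(paste(c("#gene", ifelse(is.na(catalog$meta$gene), "NA",
                                     catalog$meta$gene)), collapse = "\t"), con)
  writeLines(paste(c("#target", ifelse(is.na(catalog$meta$target), "NA",
                                       catalog$meta$target)), collapse = "\t"), con)
  df <- data.frame(id = rownames(catalog$values), description = "na",
                   catalog$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GCT-like perturbation catalog written by [write_gct()]
#'
#' @param path input path.
#' @return A list of class `perturbation_catalog` with `values` and `meta`.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#") & !startsWith(lines, "#1.")]
  parse_meta <- function(tag) {
    l <- meta_lines[startsWith(meta_lines, paste0("#", tag))]
    v <- strsplit(l, "\t", fixed = TRUE)[[1]][-1]
    ifelse(v == "NA", NA_character_, v)
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # dimension line
  tc <- textConnection(body)
  on.exit(close(tc))
  df <- utils::read.table(tc, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df[[1]]
  meta <- data.frame(perturbagen = colnames(values),
                     type = parse_meta("type"),
                     gene = parse_meta("gene"),
                     target = parse_meta("target"),
                     stringsAsFactors = FALSE)
  structure(list(values = values, meta = meta), class = "perturbation_catalog")
}
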