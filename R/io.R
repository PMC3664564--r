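# Readers and writers for every on-disk artifact: expression matrices and
# sample sheets, FASTA sequence sets, prediction tables, GO mappings and
# result tables. All tables are TSV with a header row, UTF-8, LF endings;
# floats are written with a format that round-trips doubles exactly.
# Genomic coordinates and UTR site offsets are 0-based, half-open.

#' Read an expression matrix and sample sheet
#'
#' @param matrix_path TSV; first column feature ids, remaining columns one
#'   per sample, numeric.
#' @param sample_sheet_path TSV with columns `sample_id` and `group`
#'   (`case`/`control`).
#' @param scale `"linear"` (stored as-is) or `"log2"` (exponentiated on
#'   read; internal storage is always linear).
#' @param feature_meta_path optional TSV of feature metadata (column `id`
#'   plus any of `symbol`, `kind`, `chrom`, `position`).
#' @param kind default feature kind if no metadata is given.
#' @return an [expression_dataset].
#' @export
read_expression <- function(matrix_path, sample_sheet_path,
                            scale = c("linear", "log2"),
                            feature_meta_path = NULL, kind = "mRNA") {
  scale <- match.arg(scale)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", matrix_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v))
      stop("non-numeric cell(s) in column '", names(vals)[j], "' of ",
           matrix_path)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (scale == "log2") m <- 2^m

  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs columns sample_id and group")
  sm <- data.frame(id = as.character(sheet$sample_id), group = sheet$group,
                   stringsAsFactors = FALSE)

  fm <- NULL
  if (!is.null(feature_meta_path)) {
    fm <- utils::read.delim(feature_meta_path, stringsAsFactors = FALSE)
  }
  expression_dataset(m, sm, feature_meta = fm, kind = kind)
}

#' Write an expression dataset to a matrix TSV and sample sheet TSV
#'
#' @param dataset an [expression_dataset].
#' @param matrix_path,sample_sheet_path output paths.
#' @param feature_meta_path optional path for the feature metadata table.
#' @return invisibly, the matrix path.
#' @export
write_expression <- function(dataset, matrix_path, sample_sheet_path,
                             feature_meta_path = NULL) {
  df <- data.frame(feature_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_canonical(df, matrix_path)
  write_tsv_canonical(data.frame(sample_id = dataset$sample_meta$id,
                                 group = dataset$sample_meta$group),
                      sample_sheet_path)
  if (!is.null(feature_meta_path))
    write_tsv_canonical(dataset$feature_meta, feature_meta_path)
  invisible(matrix_path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @param alphabet `"DNA"` or `"RNA"`; U/T are normalized to the requested
#'   alphabet after reading.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- if (alphabet == "DNA") as_dna(seqs) else as_rna(seqs)
  ok_chars <- if (alphabet == "DNA") "^[ACGTN]*$" else "^[ACGUN]*$"
  bad <- !grepl(ok_chars, seqs)
  if (any(bad))
    stop("sequence(s) with characters outside the ", alphabet, " alphabet: ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a miRNA target prediction table
#'
#' External prediction tables (for example from a structure-aware predictor)
#' are interchangeable with tables produced by [predict_table()].
#'
#' @param path TSV with columns `mirna_id`, `transcript_id`, and optionally
#'   `score`, `best_site_type`, `n_sites`.
#' @return data.frame of predictions with attribute `source = "external"`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "transcript_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("prediction table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_real_
  attr(df, "source") <- "external"
  df
}

#' Read a flat GO mapping
#'
#' @param gene2term_path 2-column TSV (`gene_id`, `term_id`).
#' @param term_table_path optional TSV (`term_id`, `name`, and optionally
#'   `category`, `level`).
#' @return list with elements `gene2term` (data.frame) and `terms`
#'   (data.frame or NULL), class `go_mapping`.
#' @export
read_go_mapping <- function(gene2term_path, term_table_path = NULL) {
  g2t <- utils::read.delim(gene2term_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(g2t)))
    stop("gene2term table needs columns gene_id and term_id")
  terms <- NULL
  if (!is.null(term_table_path)) {
    terms <- utils::read.delim(term_table_path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "name") %in% names(terms)))
      stop("term table needs columns term_id and name")
    unknown <- setdiff(g2t$term_id, terms$term_id)
    if (length(unknown))
      stop("term(s) referenced by genes but absent from term table: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(gene2term = g2t, terms = terms), class = "go_mapping")
}

#' Write a result table as canonical TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_result_table <- function(df, path) write_tsv_canonical(df, path)
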