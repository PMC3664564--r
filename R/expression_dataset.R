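#' Construct an expression dataset
#'
#' Container for a features x samples matrix of positive relative-expression
#' values (linear scale) with per-feature and per-sample metadata. This is
#' the common currency of the pipeline: the differential-expression,
#' structure and validation stages all consume it.
#'
#' @param values numeric matrix, features in rows, samples in columns. All
#'   values must be finite and strictly positive (linear scale).
#' @param sample_meta data.frame with columns `id` (unique, matching
#'   `colnames(values)`) and `group` (each sample either `"case"` or
#'   `"control"`).
#' @param feature_meta optional data.frame with columns `id` (unique,
#'   matching `rownames(values)`) and optionally `symbol`, `kind`
#'   (`"mRNA"` or `"miRNA"`), `chrom`, `position` (0-based bp).
#' @param kind default feature kind used when `feature_meta` lacks a
#'   `kind` column.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `feature_meta`, `sample_meta`.
#' @export
#' @examples
#' m <- matrix(2^rnorm(12, 7), 3, 4,
#'             dimnames = list(paste0("F", 1:3), paste0("S", 1:4)))
#' sm <- data.frame(id = paste0("S", 1:4),
#'                  group = rep(c("case", "control"), each = 2))
#' expression_dataset(m, sm)
expression_dataset <- function(values, sample_meta, feature_meta = NULL,
                               kind = "mRNA") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("expression values must be finite and > 0 on the linear scale")

  sample_meta <- as.data.frame(sample_meta)
  if (!all(c("id", "group") %in% names(sample_meta)))
    stop("sample_meta needs columns `id` and `group`")
  if (anyDuplicated(sample_meta$id)) stop("duplicate sample id in sample sheet")
  if (!all(sample_meta$group %in% c("case", "control")))
    stop("sample group labels must be 'case' or 'control'; offending: ",
         paste(setdiff(unique(sample_meta$group), c("case", "control")),
               collapse = ", "))
  missing_cols <- setdiff(sample_meta$id, colnames(values))
  if (length(missing_cols))
    stop("samples in sheet but not in matrix: ",
         paste(missing_cols, collapse = ", "))
  # order matrix columns to the sheet
  values <- values[, sample_meta$id, drop = FALSE]

  if (is.null(feature_meta)) {
    feature_meta <- data.frame(id = rownames(values), stringsAsFactors = FALSE)
  }
  feature_meta <- as.data.frame(feature_meta)
  if (!"id" %in% names(feature_meta)) stop("feature_meta needs column `id`")
  if (anyDuplicated(feature_meta$id)) stop("duplicate feature id in metadata")
  if (!setequal(feature_meta$id, rownames(values)))
    stop("feature_meta ids must match matrix rownames")
  feature_meta <- feature_meta[match(rownames(values), feature_meta$id), ,
                               drop = FALSE]
  rownames(feature_meta) <- NULL
  if (!"kind" %in% names(feature_meta)) feature_meta$kind <- kind
  if (!all(feature_meta$kind %in% c("mRNA", "miRNA")))
    stop("feature kind must be 'mRNA' or 'miRNA'")

  structure(list(values = values, feature_meta = feature_meta,
                 sample_meta = sample_meta),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples (%d case / %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_meta$group == "case"),
              sum(x$sample_meta$group == "control")))
  cat("kinds:", paste(sprintf("%s=%d", names(table(x$feature_meta$kind)),
                              table(x$feature_meta$kind)), collapse = ", "), "\n")
  invisible(x)
}

#' Sample ids of one group
#' @param dataset an `expression_dataset`.
#' @param group `"case"` or `"control"`.
#' @return character vector of sample ids.
#' @export
group_samples <- function(dataset, group = c("case", "control")) {
  group <- match.arg(group)
  dataset$sample_meta$id[dataset$sample_meta$group == group]
}

# Split values into case and control submatrices (linear scale).
split_groups <- function(dataset) {
  list(case = dataset$values[, group_samples(dataset, "case"), drop = FALSE],
       control = dataset$values[, group_samples(dataset, "control"), drop = FALSE])
}
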