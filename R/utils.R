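# Internal helpers: scoped RNG, sequence alphabet utilities, float formatting.

#' Evaluate code under a fixed RNG seed without touching global RNG state
#'
#' The caller's `.Random.seed` is saved and restored, so library code never
#' perturbs (or depends on) the session RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# DNA complement / reverse complement on plain character strings.
dna_complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Normalize a sequence to DNA (U -> T) or RNA (T -> U), uppercase.
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# Canonical float formatting for all text-table writers: %.17g always
# round-trips an IEEE double, so write -> read -> write is byte-stable.
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Write a data.frame as TSV with canonical number formatting (LF, UTF-8).
write_tsv_canonical <- function(df, path, row_names = FALSE) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- format_num(df2[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  utils::write.table(df2, con, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE, eol = "\n",
                     fileEncoding = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
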