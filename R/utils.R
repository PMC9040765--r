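#' Round half away from zero
#'
#' Percentage arithmetic in reports uses commercial (half-up) rounding, not
#' banker's rounding, so that e.g. 340/516 prints as 65.89 and 149/516 as 28.9.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shared TSV conventions: UTF-8, tab-delimited, "." decimal separator,
# header row, no quoting. All loaders and writers in the package go
# through these two helpers so outputs are byte-stable across runs.
read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv_plain <- function(df, path, provenance = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
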