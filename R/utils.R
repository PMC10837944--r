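# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setDT setorder rbindlist fwrite fread :=
#' @importFrom stats runif rnorm pchisq setNames
#' @importFrom utils head
NULL

# data.table NSE variables
utils::globalVariables(c(
  "id", "time_hours", "scr_mg_dl", "volume_ml", "code", "icd_version",
  "item_a", "item_b", "n_a", "n_b", "n_ab", "N", "sup", "kulc", "lift",
  "importance", "stage", "organ", "score", ".N", "."
))

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Lexicographic comparison of uppercase alphanumeric code strings.
# Categories are letter + 2 alphanumerics, so base string comparison is
# adequate; we force the C collation to be locale-independent.
code_between <- function(x, lo, hi) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  x >= lo & x <= hi
}

# Canonical unordered pair key "A|B" with A <= B.
pair_key <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "|")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
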