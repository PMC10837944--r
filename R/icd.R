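# ICD code normalisation and itemset construction.
#
# Diagnosis codes arrive as dotted or undotted ICD-9/ICD-10 strings; they
# are canonicalised (undotted, uppercase), ICD-9 codes are mapped to
# ICD-10 through a GEM-style two-column table, external-cause (V01-Y98)
# and health-status (Z00-Z99) categories are removed, codes are truncated
# to the requested prefix level, and each patient becomes one
# deduplicated itemset, optionally carrying the "AKI" pseudo-item derived
# from the KDIGO label.

AKI_ITEM <- "AKI"

#' Canonicalise ICD codes
#'
#' Uppercases and strips dots/whitespace: `"s52.01"` becomes `"S5201"`.
#'
#' @param x Character vector of raw codes.
#' @return Canonical undotted uppercase codes.
#' @export
icd_canonical <- function(x) {
  gsub("[. ]", "", toupper(trimws(as.character(x))))
}

#' Map ICD-9 codes to ICD-10
#'
#' ICD-10 input passes through unchanged; ICD-9 codes are expanded to all
#' of their ICD-10 targets in a GEM-style two-column mapping table.
#' Unmapped ICD-9 codes are dropped and counted.
#'
#' @param codes Character vector of canonical codes.
#' @param versions Integer vector (9 or 10), recycled if length 1.
#' @param mapping `data.frame` with columns `icd9`, `icd10`; may be `NULL`
#'   if all codes are ICD-10.
#' @return Character vector of canonical ICD-10 codes, with attribute
#'   `n_dropped` giving the number of unmapped ICD-9 codes.
#' @export
map_icd9_to_icd10 <- function(codes, versions = 10L, mapping = NULL) {
  codes <- icd_canonical(codes)
  versions <- rep_len(as.integer(versions), length(codes))
  out <- as.list(codes)
  dropped <- 0L
  nine <- which(versions == 9L)
  if (length(nine)) {
    if (is.null(mapping)) {
      dropped <- length(nine)
      out[nine] <- list(character(0))
    } else {
      m9 <- icd_canonical(mapping$icd9)
      m10 <- icd_canonical(mapping$icd10)
      for (i in nine) {
        hits <- m10[m9 == codes[i]]
        if (!length(hits)) dropped <- dropped + 1L
        out[[i]] <- hits
      }
    }
  }
  res <- unlist(out, use.names = FALSE)
  if (dropped > 0)
    warning(sprintf("%d ICD-9 code(s) had no ICD-10 mapping and were dropped",
                    dropped))
  attr(res, "n_dropped") <- dropped
  res
}

#' Remove external-cause and health-status codes
#'
#' Drops every code whose 3-character category falls in V01-Y98 (external
#' causes of morbidity and mortality) or Z00-Z99 (factors influencing
#' health status), both ranges inclusive.
#'
#' @param codes Character vector of canonical ICD-10 codes.
#' @return The retained codes.
#' @export
filter_codes <- function(codes) {
  codes <- icd_canonical(codes)
  cat3 <- substr(codes, 1, 3)
  excl <- code_between(cat3, "V01", "Y98") | code_between(cat3, "Z00", "Z99")
  codes[!excl]
}

#' Truncate a code to a prefix level
#'
#' ID-3 is the 3-character category, ID-4 the 4-character subcategory and
#' ID-5 the full (>= 5 character) detail code. Codes shorter than the
#' requested level are returned unchanged.
#'
#' @param codes Character vector of canonical ICD-10 codes.
#' @param level `"ID3"`, `"ID4"` or `"ID5"`.
#' @return Truncated codes.
#' @export
truncate_icd <- function(codes, level = c("ID3", "ID4", "ID5")) {
  level <- match.arg(level)
  codes <- icd_canonical(codes)
  if (level == "ID5") return(codes)
  n <- if (level == "ID3") 3L else 4L
  ifelse(nchar(codes) <= n, codes, substr(codes, 1, n))
}

.chapter_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "icd10_chapters.csv",
                          package = "akicomorbid")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' ICD-10 chapter lookup table
#'
#' @return `data.frame` with columns `start`, `end`, `chapter`, `label`
#'   covering the 22 WHO ICD-10 chapters.
#' @export
icd10_chapters <- function() .chapter_table()

#' Chapter of an ICD-10 category
#'
#' @param category Character vector of 3-character categories (longer
#'   codes are truncated first).
#' @return Chapter numerals (`"I"`..`"XXII"`), `"unknown"` when a code
#'   matches no chapter range.
#' @export
chapter_of <- function(category) {
  cat3 <- truncate_icd(category, "ID3")
  ch <- .chapter_table()
  out <- rep("unknown", length(cat3))
  for (i in seq_len(nrow(ch))) {
    hit <- out == "unknown" & code_between(cat3, ch$start[i], ch$end[i])
    out[hit] <- ch$chapter[i]
  }
  out
}

#' Build per-patient transaction itemsets
#'
#' Turns raw diagnoses into the mining input: per patient the codes are
#' mapped to ICD-10, filtered of V01-Y98/Z00-Z99 blocks, truncated to the
#' requested prefix level and deduplicated; patients with fewer than
#' `min_codes` distinct disease items are dropped; finally the `"AKI"`
#' pseudo-item is granted according to the KDIGO label. Raw N17 codes are
#' removed when the pseudo-item is in use so the mined AKI item reflects
#' KDIGO labelling rather than coding practice.
#'
#' @param cohort A `cohort_bundle` or a diagnoses `data.frame`
#'   (`id`, `icd_version`, `code`).
#' @param labels Output of [stage_cohort()] (columns `id`, `stage`).
#' @param mapping Optional ICD-9 to ICD-10 mapping table.
#' @param min_codes Minimum number of distinct disease items a patient
#'   must retain (default 2).
#' @param level Truncation level for ordinary codes (default `"ID3"`).
#' @param aki_stage Which stages receive the pseudo-item: `"any"` grants
#'   it to stage >= 1; an integer `s` grants it to stage exactly `s`
#'   (used for stage-stratified mining).
#' @param use_pseudo_item If `FALSE`, keep raw N17 codes and add no
#'   pseudo-item.
#' @param expand Named character vector mapping a category to `"ID4"` or
#'   `"ID5"`: codes in that category are truncated at the finer level
#'   instead (the fallback-verification replacement step).
#' @return A `transaction_set`: list with `items` (named list of
#'   character vectors), `N`, and `ids`.
#' @export
build_transactions <- function(cohort, labels, mapping = NULL,
                               min_codes = 2L, level = "ID3",
                               aki_stage = "any", use_pseudo_item = TRUE,
                               expand = NULL) {
  diag <- if (inherits(cohort, "cohort_bundle")) cohort$diagnoses else cohort
  diag <- as.data.table(diag)
  labels <- as.data.frame(labels)
  stage_of <- setNames(labels$stage, labels$id)

  items <- list()
  if (nrow(diag) > 0) {
    mapped <- map_icd9_to_icd10(diag$code, diag$icd_version %||% 10L, mapping)
    # map_icd9_to_icd10 may expand/drop codes; rebuild the id vector
    versions <- rep_len(as.integer(diag$icd_version %||% 10L), nrow(diag))
    reps <- integer(nrow(diag))
    if (is.null(mapping)) {
      reps <- ifelse(versions == 9L, 0L, 1L)
    } else {
      m9 <- icd_canonical(mapping$icd9)
      canon <- icd_canonical(diag$code)
      for (i in seq_len(nrow(diag)))
        reps[i] <- if (versions[i] == 9L) sum(m9 == canon[i]) else 1L
    }
    ids_long <- rep(diag$id, reps)
    codes <- mapped
    # filter blocks
    cat3 <- substr(codes, 1, 3)
    drop <- code_between(cat3, "V01", "Y98") | code_between(cat3, "Z00", "Z99")
    if (use_pseudo_item) drop <- drop | cat3 == "N17"
    codes <- codes[!drop]
    ids_long <- ids_long[!drop]
    # truncate, honouring per-category expansions
    lev <- rep(level, length(codes))
    if (!is.null(expand) && length(expand)) {
      cat3 <- substr(codes, 1, 3)
      hit <- cat3 %in% names(expand)
      lev[hit] <- expand[cat3[hit]]
    }
    trunc <- codes
    for (lv in unique(lev)) {
      sel <- lev == lv
      trunc[sel] <- truncate_icd(codes[sel], lv)
    }
    items <- lapply(split(trunc, ids_long), function(x) sort(unique(x)))
  }

  items <- items[lengths(items) >= min_codes]
  # patients with diagnoses but no label are excluded
  items <- items[names(items) %in% labels$id]

  if (use_pseudo_item && length(items)) {
    st <- stage_of[names(items)]
    grant <- if (identical(aki_stage, "any")) st >= 1 else st == as.integer(aki_stage)
    grant[is.na(grant)] <- FALSE
    items[grant] <- lapply(items[grant], function(x) c(AKI_ITEM, x))
  }

  structure(list(items = items, N = length(items), ids = names(items)),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("<transaction_set> %d patients, %d distinct items, %d with %s\n",
              x$N, length(unique(unlist(x$items))),
              sum(vapply(x$items, function(s) AKI_ITEM %in% s, logical(1))),
              AKI_ITEM))
  invisible(x)
}
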