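# Stage-stratified risk-factor mining and organ-crosstalk scoring.
#
# The crosstalk score of an organ class u is
#   score_u = sum over partners j in u of sup(AKI, j) * kulc(AKI, j),
# so it grows with the frequency, the reliability and the number of the
# class's comorbidities.

#' Organ classification table
#'
#' Loads a category-range to organ-class mapping. The bundled default is
#' a transparent stand-in covering the organ diseases most often named in
#' AKI crosstalk work (heart: I05-I52 excluding the hypertensive block
#' I10-I15; lung: J00-J99; liver: K70-K77; brain: G00-G99 and I60-I69;
#' gut: K20-K63); replace it with your own range table for real
#' analyses. Ranges must not overlap, so each category maps to exactly
#' one class.
#'
#' @param path Optional CSV with columns `range_start`, `range_end`,
#'   `organ`; default: the bundled table.
#' @return `organ_map` object (a validated `data.frame`).
#' @export
organ_classes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "organ_classes_default.csv",
                        package = "akicomorbid")
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("range_start", "range_end", "organ")
  if (!all(need %in% names(map)))
    stop_config("organ map needs columns %s", paste(need, collapse = ", "))
  map$range_start <- icd_canonical(map$range_start)
  map$range_end <- icd_canonical(map$range_end)
  # overlapping ranges would make the class of a category ambiguous
  for (i in seq_len(nrow(map))) for (j in seq_len(nrow(map))) {
    if (i < j &&
        map$range_start[i] <= map$range_end[j] &&
        map$range_start[j] <= map$range_end[i])
      stop_config("organ ranges %s-%s and %s-%s overlap",
                  map$range_start[i], map$range_end[i],
                  map$range_start[j], map$range_end[j])
  }
  class(map) <- c("organ_map", "data.frame")
  map
}

#' Organ class of ICD-10 categories
#'
#' @param category Character vector of categories.
#' @param organ_map An [organ_classes()] table.
#' @return Character vector of organ classes; `"other"` for categories
#'   outside every range.
#' @export
organ_of <- function(category, organ_map = organ_classes()) {
  cat3 <- truncate_icd(category, "ID3")
  out <- rep("other", length(cat3))
  for (i in seq_len(nrow(organ_map))) {
    hit <- code_between(cat3, organ_map$range_start[i], organ_map$range_end[i])
    out[hit] <- organ_map$organ[i]
  }
  out
}

#' Organ-crosstalk scores from AKI comorbidity pairs
#'
#' Partitions partner codes by organ class and computes
#' `score_u = sum(sup * kulc)` per class, with the top three
#' contributing pairs of each class listed by `sup * kulc`.
#'
#' @param pairs AKI-centred `pair_rules` table.
#' @param organ_map An [organ_classes()] table.
#' @return `crosstalk_report`: list with `scores` (`organ`, `score`,
#'   `n_pairs`, ranked by score), `top_pairs` (named list of up to three
#'   pairs per class) and `pairs` (the input annotated with `organ`).
#' @export
crosstalk_scores <- function(pairs, organ_map = organ_classes()) {
  pairs <- as.data.frame(pairs)
  partner <- if (nrow(pairs))
    ifelse(pairs$item_a == AKI_ITEM, pairs$item_b, pairs$item_a)
    else character(0)
  pairs$organ <- organ_of(partner, organ_map)
  pairs$weight <- pairs$sup * pairs$kulc
  classes <- unique(c(organ_map$organ, "other"))
  scores <- data.frame(
    organ = classes,
    score = vapply(classes, function(u)
      sum(pairs$weight[pairs$organ == u]), numeric(1)),
    n_pairs = vapply(classes, function(u)
      sum(pairs$organ == u), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  scores <- scores[order(-scores$score, scores$organ), , drop = FALSE]
  rownames(scores) <- NULL
  top_pairs <- lapply(setNames(classes, classes), function(u) {
    p <- pairs[pairs$organ == u, , drop = FALSE]
    p <- p[order(-p$weight, p$item_b), , drop = FALSE]
    head(p[, c("item_a", "item_b", "sup", "kulc", "weight")], 3)
  })
  structure(list(scores = scores, top_pairs = top_pairs, pairs = pairs),
            class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat("<crosstalk_report>\n")
  print(x$scores)
  invisible(x)
}

#' Stage-stratified comorbidity mining
#'
#' Re-runs transaction building and mining once per AKI stage, granting
#' the AKI pseudo-item only to patients at exactly that stage (stage-s
#' patients vs everyone else), so the three pair lists are comparable
#' set-wise.
#'
#' @param cohort,labels,mapping As in [build_transactions()].
#' @param thresholds A [mining_thresholds()].
#' @param ... Forwarded to [build_transactions()].
#' @return Named list `stage1`, `stage2`, `stage3` of `pair_rules`.
#' @export
stage_specific_pairs <- function(cohort, labels, mapping = NULL,
                                 thresholds = mining_thresholds(), ...) {
  labels <- as.data.frame(labels)
  out <- list()
  for (s in 1:3) {
    if (!any(labels$stage == s)) {
      warning(sprintf("no stage-%d patients; empty pair list", s))
      ts <- build_transactions(cohort, labels, mapping = mapping,
                               aki_stage = s, ...)
      out[[paste0("stage", s)]] <- suppressWarnings(
        mine_comorbidities(ts, thresholds))
      next
    }
    ts <- build_transactions(cohort, labels, mapping = mapping,
                             aki_stage = s, ...)
    out[[paste0("stage", s)]] <- mine_comorbidities(ts, thresholds)
  }
  out
}

#' Risk factors unique to severe (stage 3) AKI
#'
#' @param stage_lists Output of [stage_specific_pairs()].
#' @return Character vector of partner codes present in the stage-3 list
#'   but absent from both the stage-1 and stage-2 lists.
#' @export
severe_risk_factors <- function(stage_lists) {
  p <- lapply(stage_lists, function(x) {
    x <- as.data.frame(x)
    if (!nrow(x)) return(character(0))
    ifelse(x$item_a == AKI_ITEM, x$item_b, x$item_a)
  })
  sort(setdiff(p$stage3, union(p$stage1, p$stage2)))
}
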