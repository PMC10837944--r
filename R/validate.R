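# Verification of mined comorbidity pairs against reference datasets.
#
# Two mechanisms mirror the original study design:
#  * membership in an externally mined pair list (eICU-style), and
#  * a chi-square test on a local 2x2 co-occurrence table keyed by a
#    concept-mapping table (COHD-style, replayed offline).
# Partner codes whose category (ID-3) cannot be concept-mapped are
# retried by re-mining with the category replaced by each patient's
# observed 4-character subcategories (ID-4) and, failing that, the full
# detail codes (ID-5): confirming any finer-level pair confirms the
# category pair.

#' Reference pair set
#'
#' A named set of unordered code pairs mined from an external dataset,
#' stored canonically (sorted code order).
#'
#' @param source Name of the reference dataset.
#' @param pairs `data.frame` with columns `code_a`, `code_b`.
#' @return `reference_pairs` object.
#' @export
reference_pairs <- function(source, pairs) {
  pairs <- as.data.frame(pairs)
  keys <- if (nrow(pairs))
    pair_key(icd_canonical(pairs$code_a), icd_canonical(pairs$code_b))
    else character(0)
  structure(list(source = source, keys = unique(keys)),
            class = "reference_pairs")
}

#' Confirm pairs by reference membership
#'
#' @param pairs `data.frame` with columns `item_a`, `item_b` (a
#'   `pair_rules` table works directly).
#' @param reference A [reference_pairs()] set.
#' @return Logical vector: `TRUE` where the unordered pair is present in
#'   the reference.
#' @export
confirm_by_membership <- function(pairs, reference) {
  stopifnot(inherits(reference, "reference_pairs"))
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) return(logical(0))
  pair_key(icd_canonical(pairs$item_a), icd_canonical(pairs$item_b)) %in%
    reference$keys
}

#' Pearson chi-square on a 2x2 co-occurrence table
#'
#' No continuity correction; 1 degree of freedom. The closed form is
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` for cells
#' a = both, b = A only, c = B only, d = neither.
#'
#' @param n_ab,n_a_only,n_b_only,n_neither Non-negative cell counts.
#' @return `list(statistic, p_value)`; both `NA` when a marginal is zero
#'   (the statistic is undefined and the pair cannot be confirmed).
#' @export
chi_square_2x2 <- function(n_ab, n_a_only, n_b_only, n_neither) {
  a <- n_ab; b <- n_a_only; cc <- n_b_only; d <- n_neither
  if (any(c(a, b, cc, d) < 0)) stop_config("cell counts must be >= 0")
  n <- a + b + cc + d
  if (n <= 0) stop_config("total count must be > 0")
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0))
    return(list(statistic = NA_real_, p_value = NA_real_))
  stat <- n * (a * d - b * cc)^2 / prod(margins)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Offline co-occurrence reference (COHD-style)
#'
#' Wraps a concept-mapping table and a 2x2 co-occurrence count table so
#' that pairs can be chi-square-verified without live database access.
#'
#' @param concept_map `data.frame` with columns `icd10`, `concept_id`:
#'   the codes (at any prefix level) that map into the reference's
#'   concept space.
#' @param cooccurrence `data.frame` with columns `code_a`, `code_b`,
#'   `n_ab`, `n_a_only`, `n_b_only`, `n_neither`.
#' @param alpha Significance level for confirmation (default 0.05).
#' @return `cohd_reference` object.
#' @export
cohd_reference <- function(concept_map, cooccurrence, alpha = 0.05) {
  concept_map <- as.data.frame(concept_map)
  cooccurrence <- as.data.frame(cooccurrence)
  cooccurrence$key <- pair_key(icd_canonical(cooccurrence$code_a),
                               icd_canonical(cooccurrence$code_b))
  structure(list(mapped_codes = unique(icd_canonical(concept_map$icd10)),
                 cooc = cooccurrence, alpha = alpha),
            class = "cohd_reference")
}

#' Chi-square confirmation of one pair against a co-occurrence reference
#'
#' @param reference A [cohd_reference()].
#' @param code_a,code_b The two codes (the AKI pseudo-item is looked up
#'   as-is).
#' @return List with `mapped` (both codes concept-mapped), `present`
#'   (co-occurrence counts available), `statistic`, `p_value`,
#'   `confirmed` (`p < alpha`).
#' @export
cohd_confirm <- function(reference, code_a, code_b) {
  stopifnot(inherits(reference, "cohd_reference"))
  ca <- icd_canonical(code_a); cb <- icd_canonical(code_b)
  mapped <- all(c(ca, cb) %in% reference$mapped_codes)
  out <- list(mapped = mapped, present = FALSE, statistic = NA_real_,
              p_value = NA_real_, confirmed = FALSE)
  if (!mapped) return(out)
  row <- reference$cooc[reference$cooc$key == pair_key(ca, cb), , drop = FALSE]
  if (!nrow(row)) return(out)
  cs <- chi_square_2x2(row$n_ab[1], row$n_a_only[1], row$n_b_only[1],
                       row$n_neither[1])
  out$present <- TRUE
  out$statistic <- cs$statistic
  out$p_value <- cs$p_value
  out$confirmed <- !is.na(cs$p_value) && cs$p_value < reference$alpha
  out
}

#' Fallback verification of a category pair at finer code levels
#'
#' Implements the ID-3 -> ID-4 -> ID-5 replacement algorithm. When the
#' partner category fails concept mapping, transactions are rebuilt with
#' that category replaced by each patient's observed subcategories,
#' mining is repeated with the same thresholds, and every resulting
#' finer-level AKI pair that maps is chi-square-checked: one confirmed
#' subcategory confirms the category. Subcategories that still fail
#' mapping trigger the same step at the detail (ID-5) level.
#'
#' @param pair Character vector of the two items, one being `"AKI"`.
#' @param cohort,labels,mapping,thresholds As in [build_transactions()]
#'   and [mine_comorbidities()]; `...` is forwarded to
#'   [build_transactions()].
#' @param reference A [cohd_reference()].
#' @param ... Extra arguments for [build_transactions()] (e.g.
#'   `min_codes`).
#' @return `list(pair, confirmed, matched_level, statistic, p_value)`
#'   with `matched_level` in `{"ID3","ID4","ID5","none"}`.
#' @export
fallback_match <- function(pair, cohort, labels, reference,
                           mapping = NULL, thresholds = mining_thresholds(),
                           ...) {
  partner <- setdiff(pair, AKI_ITEM)
  if (length(partner) != 1L)
    stop_config("pair must contain the AKI item and one partner code")
  partner <- icd_canonical(partner)
  res <- list(pair = c(AKI_ITEM, partner), confirmed = FALSE,
              matched_level = "none", statistic = NA_real_,
              p_value = NA_real_)

  # guard: a partner that maps at ID-3 is checked directly, never replaced
  direct <- cohd_confirm(reference, AKI_ITEM, partner)
  if (direct$mapped) {
    res$confirmed <- direct$confirmed
    res$matched_level <- if (direct$confirmed) "ID3" else "none"
    res$statistic <- direct$statistic
    res$p_value <- direct$p_value
    return(res)
  }

  try_level <- function(level) {
    ts <- build_transactions(cohort, labels, mapping = mapping,
                             expand = setNames(level, partner), ...)
    mined <- suppressWarnings(mine_comorbidities(ts, thresholds))
    cands <- mined$partner[substr(mined$partner, 1, 3) == partner &
                             nchar(mined$partner) > 3]
    list(cands = cands)
  }

  lv4 <- try_level("ID4")
  unmapped4 <- character(0)
  for (cand in lv4$cands) {
    chk <- cohd_confirm(reference, AKI_ITEM, cand)
    if (!chk$mapped) { unmapped4 <- c(unmapped4, cand); next }
    if (chk$confirmed) {
      res$confirmed <- TRUE
      res$matched_level <- "ID4"
      res$statistic <- chk$statistic
      res$p_value <- chk$p_value
      return(res)
    }
  }

  if (length(unmapped4) || length(lv4$cands) == 0) {
    lv5 <- try_level("ID5")
    for (cand in lv5$cands) {
      if (nchar(cand) < 5) next
      chk <- cohd_confirm(reference, AKI_ITEM, cand)
      if (!chk$mapped || !chk$confirmed) next
      res$confirmed <- TRUE
      res$matched_level <- "ID5"
      res$statistic <- chk$statistic
      res$p_value <- chk$p_value
      return(res)
    }
  }
  res
}

#' Validate a table of mined pairs against all references
#'
#' @param pairs `pair_rules` table of AKI-centred pairs.
#' @param eicu Optional [reference_pairs()] set.
#' @param cohd Optional [cohd_reference()]; when given, `cohort`,
#'   `labels` (and `mapping`) enable the fallback re-mining.
#' @param cohort,labels,mapping,thresholds Inputs for [fallback_match()].
#' @param literature Optional `data.frame` (`code`, `confirmed`) flagging
#'   literature-confirmed partners; never computed, only joined.
#' @return `data.frame` of verdicts: per-source flags, `matched_level`,
#'   `chi_square`, `p_value`, `literature`, and `final`
#'   (`"confirmed"`/`"unconfirmed"`, confirmed iff any source confirms).
#' @export
validate_pairs <- function(pairs, eicu = NULL, cohd = NULL, cohort = NULL,
                           labels = NULL, mapping = NULL,
                           thresholds = mining_thresholds(),
                           literature = NULL) {
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  v <- data.frame(item_a = pairs$item_a, item_b = pairs$item_b,
                  eicu = FALSE, cohd = FALSE,
                  matched_level = "none", chi_square = NA_real_,
                  p_value = NA_real_, literature = FALSE,
                  stringsAsFactors = FALSE)
  if (n == 0) {
    v$final <- character(0)
    return(v)
  }
  if (!is.null(eicu)) v$eicu <- confirm_by_membership(pairs, eicu)
  if (!is.null(cohd)) {
    for (i in seq_len(n)) {
      pr <- c(pairs$item_a[i], pairs$item_b[i])
      fb <- if (is.null(cohort)) {
        d <- cohd_confirm(cohd, pr[1], pr[2])
        list(confirmed = d$confirmed,
             matched_level = if (d$confirmed) "ID3" else "none",
             statistic = d$statistic, p_value = d$p_value)
      } else {
        fallback_match(pr, cohort, labels, cohd, mapping = mapping,
                       thresholds = thresholds)
      }
      v$cohd[i] <- fb$confirmed
      v$matched_level[i] <- fb$matched_level
      v$chi_square[i] <- fb$statistic
      v$p_value[i] <- fb$p_value
    }
  }
  if (!is.null(literature)) {
    lit <- as.data.frame(literature)
    lit_codes <- icd_canonical(lit$code[as.logical(lit$confirmed)])
    partner <- ifelse(pairs$item_a == AKI_ITEM, pairs$item_b, pairs$item_a)
    v$literature <- icd_canonical(partner) %in% lit_codes
  }
  v$final <- ifelse(v$eicu | v$cohd | v$literature, "confirmed", "unconfirmed")
  v
}

#' Cross-tabulate verification outcomes
#'
#' Summarises verdicts into the confirmed-by-eICU x confirmed-by-COHD
#' 2x2, with the doubly-unconfirmed residual split by the literature
#' flag.
#'
#' @param verdicts Output of [validate_pairs()].
#' @return List with `table` (2x2 matrix), `residual` (named vector:
#'   literature-confirmed vs unconfirmed among pairs confirmed by
#'   neither source) and `total`.
#' @export
consistency_table <- function(verdicts) {
  verdicts <- as.data.frame(verdicts)
  e <- factor(verdicts$eicu, levels = c(TRUE, FALSE))
  c2 <- factor(verdicts$cohd, levels = c(TRUE, FALSE))
  tab <- table(eicu = e, cohd = c2)
  neither <- !verdicts$eicu & !verdicts$cohd
  residual <- c(literature = sum(neither & verdicts$literature),
                unconfirmed = sum(neither & !verdicts$literature))
  list(table = unclass(tab), residual = residual, total = nrow(verdicts))
}
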