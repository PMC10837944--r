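# Apriori frequent-itemset mining and the three interestingness measures.
#
# For an item pair (A, B) over N patient transactions:
#   sup  = P(A and B)                         joint occurrence
#   kulc = (P(A|B) + P(B|A)) / 2              symmetric reliability
#   lift = P(A and B) / (P(A) P(B))           1 = independence
# Counting is per patient (transaction), never per diagnosis row.

#' Mining thresholds
#'
#' The headline configuration `(sup: 8; kulc: 0; lift: 1)` is read as
#' min_sup = 0.08 (8%, compared inclusively) with kulc and lift compared
#' strictly (`> 0`, `> 1`). All of this is configurable because the
#' printed form does not pin down units or strictness.
#'
#' @param min_sup Minimum support fraction in `[0,1]`.
#' @param min_kulc Minimum kulczynski.
#' @param min_lift Minimum lift (`>= 0`).
#' @param sup_inclusive,kulc_strict,lift_strict Comparison conventions.
#' @return `mining_thresholds` object.
#' @export
mining_thresholds <- function(min_sup = 0.08, min_kulc = 0, min_lift = 1,
                              sup_inclusive = TRUE, kulc_strict = TRUE,
                              lift_strict = TRUE) {
  if (min_sup < 0 || min_sup > 1) stop_config("min_sup must be in [0,1]")
  if (min_lift < 0) stop_config("min_lift must be >= 0")
  structure(list(min_sup = min_sup, min_kulc = min_kulc, min_lift = min_lift,
                 sup_inclusive = sup_inclusive, kulc_strict = kulc_strict,
                 lift_strict = lift_strict),
            class = "mining_thresholds")
}

#' Frequent 1-itemsets
#'
#' @param transactions A `transaction_set`.
#' @param min_sup Minimum support fraction; an item is frequent when
#'   `count / N >= min_sup`.
#' @return `data.frame` with columns `item`, `count`, `support`, sorted
#'   by decreasing count then item.
#' @export
frequent_items <- function(transactions, min_sup = 0) {
  stopifnot(inherits(transactions, "transaction_set"))
  N <- transactions$N
  if (N == 0) return(data.frame(item = character(), count = integer(),
                                support = numeric()))
  tab <- table(unlist(transactions$items, use.names = FALSE))
  df <- data.frame(item = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$support <- df$count / N
  df <- df[df$count >= min_sup * N - 1e-9, , drop = FALSE]
  df[order(-df$count, df$item), , drop = FALSE]
}

# Sparse patient x item incidence over a fixed item universe.
incidence_matrix <- function(transactions, universe) {
  items <- transactions$items
  j <- match(unlist(items, use.names = FALSE), universe)
  i <- rep(seq_along(items), lengths(items))
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep],
                       dims = c(length(items), length(universe)),
                       dimnames = list(NULL, universe), x = 1)
}

#' Frequent 2-itemsets with sup, kulc and lift
#'
#' Apriori pruning: candidate pairs are generated only from frequent
#' 1-itemsets, then counted exactly; the result is identical to
#' brute-force enumeration over all pairs.
#'
#' @inheritParams frequent_items
#' @return `pair_rules` `data.frame`: `item_a < item_b` lexicographically,
#'   counts `n_a`, `n_b`, `n_ab`, `N`, and `sup`, `kulc`, `lift`.
#' @export
frequent_pairs <- function(transactions, min_sup = 0) {
  stopifnot(inherits(transactions, "transaction_set"))
  N <- transactions$N
  empty <- data.frame(item_a = character(), item_b = character(),
                      n_a = integer(), n_b = integer(), n_ab = integer(),
                      N = integer(), sup = numeric(), kulc = numeric(),
                      lift = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("pair_rules", "data.frame")
  if (N == 0) return(empty)
  f1 <- frequent_items(transactions, min_sup)
  if (nrow(f1) < 2) return(empty)
  universe <- sort(f1$item)
  M <- incidence_matrix(transactions, universe)
  co <- as.matrix(Matrix::crossprod(M))   # item x item co-occurrence counts
  counts <- setNames(as.integer(diag(co)), universe)
  ut <- which(upper.tri(co), arr.ind = TRUE)
  n_ab <- co[ut]
  keep <- n_ab >= min_sup * N - 1e-9
  ut <- ut[keep, , drop = FALSE]
  n_ab <- as.integer(n_ab[keep])
  a <- universe[ut[, 1]]
  b <- universe[ut[, 2]]
  n_a <- counts[a]
  n_b <- counts[b]
  sup <- n_ab / N
  pa <- n_a / N
  pb <- n_b / N
  out <- data.frame(item_a = a, item_b = b, n_a = unname(n_a),
                    n_b = unname(n_b), n_ab = n_ab, N = N, sup = sup,
                    kulc = (sup / pb + sup / pa) / 2,
                    lift = sup / (pa * pb),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$item_a, out$item_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_rules", "data.frame")
  out
}

#' Mine AKI-centred comorbidity pairs
#'
#' Restricts the frequent 2-itemsets to pairs containing the AKI
#' pseudo-item, applies the kulczynski and lift thresholds, and orders by
#' `sup * kulc` descending with a lexicographic tie-break on the partner
#' code.
#'
#' @param transactions A `transaction_set` containing the AKI item.
#' @param thresholds A [mining_thresholds()].
#' @return `pair_rules` with `item_a = "AKI"`, plus a `partner` column.
#' @export
mine_comorbidities <- function(transactions, thresholds = mining_thresholds()) {
  stopifnot(inherits(thresholds, "mining_thresholds"))
  has_aki <- any(vapply(transactions$items, function(s) AKI_ITEM %in% s,
                        logical(1)))
  fp <- frequent_pairs(transactions, thresholds$min_sup)
  if (!has_aki) {
    warning("no transaction contains the AKI item; returning no pairs")
    fp <- fp[0, , drop = FALSE]
  }
  keep <- fp$item_a == AKI_ITEM | fp$item_b == AKI_ITEM
  fp <- fp[keep, , drop = FALSE]
  if (nrow(fp)) {
    # present AKI first, partner second
    swap <- fp$item_b == AKI_ITEM
    tmp <- fp[swap, ]
    fp[swap, c("item_a", "item_b")] <- tmp[, c("item_b", "item_a")]
    fp[swap, c("n_a", "n_b")] <- tmp[, c("n_b", "n_a")]
    ok_kulc <- if (thresholds$kulc_strict) fp$kulc > thresholds$min_kulc
               else fp$kulc >= thresholds$min_kulc
    ok_lift <- if (thresholds$lift_strict) fp$lift > thresholds$min_lift
               else fp$lift >= thresholds$min_lift
    fp <- fp[ok_kulc & ok_lift, , drop = FALSE]
  }
  fp$partner <- fp$item_b
  fp <- fp[order(-(fp$sup * fp$kulc), fp$partner), , drop = FALSE]
  rownames(fp) <- NULL
  class(fp) <- c("pair_rules", "data.frame")
  fp
}

#' @export
print.pair_rules <- function(x, ...) {
  cat(sprintf("<pair_rules> %d pairs over N = %s patients\n", nrow(x),
              if (nrow(x)) x$N[1] else "?"))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10))
  invisible(x)
}
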