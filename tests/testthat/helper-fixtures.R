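# Shared fixtures and independent oracles.

# Stage mix with P(AKI) = 0.45 and the within-AKI stage proportions of a
# large adult ICU cohort; used whenever pairs are planted at lift 2.0,
# which needs lift * P(AKI) <= 1 to keep the 2x2 feasible.
aki45_mix <- c(0.55, 0.3177, 0.1125, 0.0198)

scr_series <- function(times, values) {
  data.frame(time_hours = times, scr_mg_dl = values)
}

uo_series <- function(times, volumes) {
  data.frame(time_hours = times, volume_ml = volumes)
}

# Hourly urine series: rate (ml/kg/h) per hour 1..length(rates).
uo_hourly <- function(rates, weight) {
  uo_series(seq_along(rates), rates * weight)
}

make_patient <- function(id = "P1", weight = 80, scr = NULL, uo = NULL) {
  list(id = id, weight_kg = weight,
       scr_series = scr %||% scr_series(numeric(0), numeric(0)),
       uo_series = uo %||% uo_series(numeric(0), numeric(0)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Transaction set directly from a list of character itemsets.
ts_from_list <- function(items) {
  names(items) <- names(items) %||% sprintf("P%03d", seq_along(items))
  structure(list(items = lapply(items, function(x) sort(unique(x))),
                 N = length(items), ids = names(items)),
            class = "transaction_set")
}

# Independent brute-force oracle: double loop over all distinct item
# pairs, counting transactions that contain both. No Apriori pruning, no
# shared code with frequent_pairs().
brute_force_pairs <- function(items, min_sup = 0) {
  N <- length(items)
  universe <- sort(unique(unlist(items)))
  rows <- list()
  for (i in seq_along(universe)) {
    for (j in seq_along(universe)) {
      if (j <= i) next
      a <- universe[i]; b <- universe[j]
      n_a <- sum(vapply(items, function(s) a %in% s, logical(1)))
      n_b <- sum(vapply(items, function(s) b %in% s, logical(1)))
      n_ab <- sum(vapply(items, function(s) a %in% s && b %in% s, logical(1)))
      if (n_ab < min_sup * N - 1e-9) next
      sup <- n_ab / N
      rows[[length(rows) + 1L]] <- data.frame(
        item_a = a, item_b = b, n_a = n_a, n_b = n_b, n_ab = n_ab, N = N,
        sup = sup,
        kulc = (sup / (n_b / N) + sup / (n_a / N)) / 2,
        lift = sup / ((n_a / N) * (n_b / N)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(item_a = character(), item_b = character()))
  out <- do.call(rbind, rows)
  out[order(out$item_a, out$item_b), , drop = FALSE]
}

# Empirical lift of a pair counted directly on a generated cohort, where
# "AKI" means truth stage >= 1.
empirical_lift <- function(bundle, item_a, item_b) {
  ids <- bundle$truth_labels$id
  has <- function(item) {
    if (item == "AKI") return(ids %in% bundle$truth_labels$id[bundle$truth_labels$stage >= 1])
    ids %in% bundle$diagnoses$id[bundle$diagnoses$code == item]
  }
  a <- has(item_a); b <- has(item_b)
  n <- length(ids)
  (sum(a & b) / n) / ((sum(a) / n) * (sum(b) / n))
}

# Random transaction sets for property-style tests.
random_transactions <- function(n, codes, p = 0.2, aki_p = 0.4) {
  items <- lapply(seq_len(n), function(i) {
    s <- codes[runif(length(codes)) < p]
    if (runif(1) < aki_p) s <- c("AKI", s)
    s
  })
  ts_from_list(items)
}
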