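# Synthetic ICU cohort generator.
#
# Produces MIMIC-shaped tables (patients, creatinine events, urine-output
# events, diagnoses) with known ground truth: every patient is assigned an
# AKI stage 0-3 and receives creatinine/urine-output trajectories built so
# that the KDIGO staging module recovers that stage exactly, and diagnosis
# itemsets are drawn so that selected item pairs attain a target lift in
# expectation while all other pairs are independent.

#' Simulation configuration
#'
#' Describes a synthetic ICU cohort: its size, the marginal mix of AKI
#' stages, the diagnosis code catalogue with per-code prevalences, and the
#' pairwise associations to plant at a known lift.
#'
#' @param n_patients Number of ICU stays to generate.
#' @param seed Integer root seed; all randomness derives from it.
#' @param stage_mix Length-4 vector of proportions of patients at AKI
#'   stages 0-3. Must sum to 1. The default mirrors a large adult ICU
#'   population in which roughly 57% of stays develop AKI, with stage 1
#'   the most common and stage 3 rare.
#' @param code_catalog `data.frame` with columns `code` (ICD-10 category)
#'   and `prevalence` in (0,1). See [default_code_catalog()].
#' @param planted_pairs Optional `data.frame` with columns `item_a`,
#'   `item_b`, `lift` (each `lift >= 0`). `item_a` may be the `"AKI"`
#'   pseudo-item, whose marginal prevalence is `1 - stage_mix[1]`. All
#'   other items must appear in `code_catalog`.
#' @param weight_range Body-weight interval in kg.
#' @param scr_noise_sd Standard deviation (mg/dl) of measurement noise on
#'   post-onset creatinine values. Noise is truncated at two standard
#'   deviations so that staged trajectories stay inside their KDIGO band;
#'   values above 0.05 void the stage-recovery guarantee.
#' @param horizon ICU stay length in hours (>= 36 so a stage-3 oliguria
#'   episode fits).
#' @param uo_fraction Fraction of staged patients whose stage is expressed
#'   through the urine-output criterion instead of creatinine.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       stage_mix = c(0.435, 0.399, 0.141, 0.025),
                       code_catalog = default_code_catalog(),
                       planted_pairs = NULL,
                       weight_range = c(50, 120),
                       scr_noise_sd = 0.05,
                       horizon = 72,
                       uo_fraction = 0.3) {
  if (!is_count(n_patients) || n_patients < 0)
    stop_config("n_patients must be a non-negative integer")
  if (length(stage_mix) != 4L || any(stage_mix < 0))
    stop_config("stage_mix must be 4 non-negative proportions")
  if (abs(sum(stage_mix) - 1) > 1e-9)
    stop_config("stage_mix must sum to 1 (got %.12f)", sum(stage_mix))
  code_catalog <- as.data.frame(code_catalog)
  if (!all(c("code", "prevalence") %in% names(code_catalog)))
    stop_config("code_catalog needs columns 'code' and 'prevalence'")
  if (anyDuplicated(code_catalog$code))
    stop_config("code_catalog codes must be unique")
  if (any(code_catalog$prevalence <= 0 | code_catalog$prevalence >= 1))
    stop_config("code prevalences must lie strictly in (0,1)")
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    if (!all(c("item_a", "item_b", "lift") %in% names(planted_pairs)))
      stop_config("planted_pairs needs columns item_a, item_b, lift")
    if (any(planted_pairs$lift < 0))
      stop_config("planted target lift must be >= 0")
    items <- c(planted_pairs$item_a, planted_pairs$item_b)
    unknown <- setdiff(items, c("AKI", code_catalog$code))
    if (length(unknown))
      stop_config("planted items not in catalogue: %s",
                  paste(unknown, collapse = ", "))
    if (any(planted_pairs$item_a == planted_pairs$item_b))
      stop_config("planted pairs must have distinct items")
  }
  if (horizon < 36) stop_config("horizon must be >= 36 hours")
  if (scr_noise_sd < 0) stop_config("scr_noise_sd must be >= 0")
  if (scr_noise_sd > 0.1)
    warning("scr_noise_sd > 0.1 mg/dl can break exact stage recovery")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    stage_mix = stage_mix, code_catalog = code_catalog,
    planted_pairs = planted_pairs, weight_range = weight_range,
    scr_noise_sd = scr_noise_sd, horizon = horizon,
    uo_fraction = uo_fraction
  ), class = "sim_config")
}

#' Default diagnosis-code catalogue
#'
#' Builds a deterministic catalogue of ICD-10-like category codes with
#' prevalences evenly spaced over a range. Codes use chapters A-N only, so
#' none fall in the external-cause (V01-Y98) or health-status (Z00-Z99)
#' blocks that the preprocessing step removes, and N17 (the raw AKI code)
#' is never emitted.
#'
#' @param n_codes Number of category codes.
#' @param prevalence_range Low/high marginal prevalence; codes get evenly
#'   spaced prevalences across it.
#' @return `data.frame` with columns `code`, `prevalence`.
#' @export
default_code_catalog <- function(n_codes = 100, prevalence_range = c(0.05, 0.30)) {
  lets <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M", "N")
  k <- ceiling(n_codes / length(lets)) + 1L
  codes <- as.vector(outer(lets, 10:(9 + k), function(l, n) sprintf("%s%02d", l, n)))
  codes <- setdiff(codes, "N17")[seq_len(n_codes)]
  data.frame(
    code = codes,
    prevalence = seq(prevalence_range[1], prevalence_range[2],
                     length.out = n_codes),
    stringsAsFactors = FALSE
  )
}

# Feasibility of a 2x2 with marginals pa, pb and joint lift*pa*pb.
check_planting <- function(pa, pb, lift, label) {
  pab <- lift * pa * pb
  cells <- c(pab, pa - pab, pb - pab, 1 - pa - pb + pab)
  if (any(cells < -1e-12) || any(cells > 1 + 1e-12))
    stop_config(
      "infeasible planting for pair %s: lift %.3f with marginals %.3f/%.3f puts a 2x2 cell outside [0,1]",
      label, lift, pa, pb)
  pab
}

# Per-stage creatinine fold multipliers: mid-interval of each KDIGO band.
# Urine-output episodes are (rate ml/kg/h, duration h): stage 1 = 0.35 for
# 8h (oliguric 6-12h), stage 2 = 0.35 for 14h (>=12h), stage 3 = 0.20 for
# 26h (<0.3 ml/kg/h for >=24h).
.scr_mult <- c(`1` = 1.7, `2` = 2.5, `3` = 3.5)

#' Generate a synthetic cohort
#'
#' Draws a full cohort under a [sim_config()]: demographics, staged
#' creatinine and urine-output trajectories, and diagnosis itemsets with
#' planted pairwise associations. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `cohort_bundle`: list with `patients`, `scr_events`,
#'   `uo_events`, `diagnoses` tables, plus `truth_labels` (id, stage),
#'   `truth_pairs` (the planted associations) and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  horizon <- config$horizon

  ids <- sprintf("P%06d", seq_len(max(n, 1L)))[seq_len(n)]
  stages <- if (n > 0)
    sample(0:3, n, replace = TRUE, prob = config$stage_mix) else integer(0)

  patients <- data.table(
    id = ids,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.56, 0.44)),
    age_years = sample(18:95, n, replace = TRUE),
    ethnicity = sample(c("White", "Black", "Asian", "Hispanic", "Other"),
                       n, replace = TRUE, prob = c(0.62, 0.11, 0.04, 0.07, 0.16)),
    weight_kg = round(runif(n, config$weight_range[1], config$weight_range[2]), 1)
  )

  uo_route <- stages > 0 & runif(n) < config$uo_fraction

  # --- creatinine events: charted every 6 hours -------------------------
  scr_times <- seq(0, horizon, by = 6)
  baseline <- runif(n, 0.6, 1.2)
  onset_choices <- scr_times[scr_times >= 18 & scr_times <= horizon - 12]
  scr_onset <- sample(onset_choices, max(n, 1L), replace = TRUE)[seq_len(n)]
  sd <- config$scr_noise_sd
  scr_events <- if (n > 0) {
    long <- data.table(
      id = rep(ids, each = length(scr_times)),
      time_hours = rep(scr_times, times = n),
      base = rep(baseline, each = length(scr_times)),
      stage = rep(stages, each = length(scr_times)),
      uo_route = rep(uo_route, each = length(scr_times)),
      onset = rep(scr_onset, each = length(scr_times))
    )
    post <- long$stage > 0 & !long$uo_route & long$time_hours >= long$onset
    mult <- ifelse(post, unname(.scr_mult)[pmax(long$stage, 1L)], 1)
    eps <- pmin(pmax(rnorm(nrow(long), 0, sd), -2 * sd), 2 * sd)
    # pre-onset values are charted noise-free so the rolling-minimum
    # baseline equals the constructed baseline exactly
    val <- ifelse(post, long$base * mult + eps, long$base)
    data.table(id = long$id, time_hours = long$time_hours,
               scr_mg_dl = round(val, 3))
  } else {
    data.table(id = character(), time_hours = numeric(), scr_mg_dl = numeric())
  }

  # --- urine output: hourly volumes ------------------------------------
  uo_times <- seq_len(horizon)
  uo_onset <- sample(4:6, max(n, 1L), replace = TRUE)[seq_len(n)]
  uo_events <- if (n > 0) {
    long <- data.table(
      id = rep(ids, each = horizon),
      time_hours = rep(uo_times, times = n),
      w = rep(patients$weight_kg, each = horizon),
      stage = rep(stages, each = horizon),
      uo_route = rep(uo_route, each = horizon),
      onset = rep(uo_onset, each = horizon)
    )
    rate <- rep(1.0, nrow(long))  # normal output 1 ml/kg/h
    ep <- long$uo_route
    if (any(ep)) {
      ep_rate <- c(0.35, 0.35, 0.20)[pmax(long$stage, 1L)]
      ep_dur <- c(8, 14, 26)[pmax(long$stage, 1L)]
      inside <- ep & long$time_hours > long$onset &
        long$time_hours <= long$onset + ep_dur
      rate[inside] <- ep_rate[inside]
    }
    data.table(id = long$id, time_hours = long$time_hours,
               volume_ml = round(rate * long$w, 1))
  } else {
    data.table(id = character(), time_hours = numeric(), volume_ml = numeric())
  }

  # --- diagnoses with planted associations -----------------------------
  cat <- config$code_catalog
  prev <- setNames(cat$prevalence, cat$code)
  p_aki <- 1 - config$stage_mix[1]
  member <- matrix(FALSE, nrow = n, ncol = nrow(cat),
                   dimnames = list(NULL, cat$code))
  realized <- list(AKI = stages > 0)
  marg <- function(item) if (item == "AKI") p_aki else unname(prev[item])

  pp <- config$planted_pairs
  if (!is.null(pp) && nrow(pp) > 0 && n > 0) {
    for (k in seq_len(nrow(pp))) {
      a <- pp$item_a[k]; b <- pp$item_b[k]; lf <- pp$lift[k]
      label <- sprintf("(%s,%s)", a, b)
      if (b == "AKI") { tmp <- a; a <- b; b <- tmp }  # AKI is never redrawn
      if (!is.null(realized[[a]]) && !is.null(realized[[b]]))
        stop_config("infeasible planting for pair %s: both items already constrained by earlier pairs", label)
      if (is.null(realized[[a]]) && !is.null(realized[[b]])) {
        tmp <- a; a <- b; b <- tmp
      }
      pa <- marg(a); pb <- marg(b)
      check_planting(pa, pb, lf, label)
      p_b_given_a <- lf * pb
      p_b_given_not_a <- pb * (1 - lf * pa) / (1 - pa)
      if (is.null(realized[[a]])) {
        realized[[a]] <- runif(n) < pa
        member[, a] <- realized[[a]]
      }
      av <- realized[[a]]
      bv <- ifelse(av, runif(n) < p_b_given_a, runif(n) < p_b_given_not_a)
      realized[[b]] <- bv
      member[, b] <- bv
    }
  }
  free <- setdiff(cat$code, names(realized))
  if (length(free) && n > 0) {
    u <- matrix(runif(n * length(free)), nrow = n)
    member[, free] <- u < rep(prev[free], each = n)
  }

  diagnoses <- if (n > 0) {
    idx <- which(member, arr.ind = TRUE)
    data.table(id = ids[idx[, 1]], icd_version = 10L,
               code = colnames(member)[idx[, 2]])[order(id, code)]
  } else {
    data.table(id = character(), icd_version = integer(), code = character())
  }

  truth_pairs <- if (is.null(pp)) {
    data.frame(item_a = character(), item_b = character(), lift = numeric())
  } else pp[, c("item_a", "item_b", "lift")]

  structure(list(
    patients = patients,
    scr_events = scr_events[order(id, time_hours)],
    uo_events = uo_events[order(id, time_hours)],
    diagnoses = diagnoses,
    truth_labels = data.frame(id = ids, stage = stages,
                              stringsAsFactors = FALSE),
    truth_pairs = truth_pairs,
    config = config
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d patients, %d scr events, %d uo events, %d diagnosis rows\n",
              nrow(x$patients), nrow(x$scr_events), nrow(x$uo_events),
              nrow(x$diagnoses)))
  cat("stage mix (truth):\n")
  print(table(factor(x$truth_labels$stage, levels = 0:3)))
  invisible(x)
}

#' Write a cohort to MIMIC-shaped CSV tables
#'
#' Emits `patients.csv`, `scr_events.csv`, `uo_events.csv` and
#' `diagnoses.csv` into a directory, plus `truth_labels.csv` and
#' `truth_pairs.csv` carrying the simulation ground truth.
#'
#' @param bundle A `cohort_bundle`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- c(patients = "patients.csv", scr_events = "scr_events.csv",
             uo_events = "uo_events.csv", diagnoses = "diagnoses.csv",
             truth_labels = "truth_labels.csv", truth_pairs = "truth_pairs.csv")
  for (nm in names(files)) {
    path <- file.path(directory, files[[nm]])
    fwrite(as.data.table(bundle[[nm]]), path)
  }
  invisible(file.path(directory, unname(files)))
}

#' Read a cohort from MIMIC-shaped CSV tables
#'
#' Inverse of [write_cohort()]; also accepts directories holding only the
#' four clinical tables (no ground truth).
#'
#' @param directory Directory containing the CSV tables.
#' @return A `cohort_bundle` (with `truth_labels`/`truth_pairs` `NULL`
#'   when not present on disk).
#' @export
read_cohort <- function(directory) {
  if (!dir.exists(directory))
    stop_config("cohort directory not found: %s", directory)
  need <- c("patients.csv", "scr_events.csv", "uo_events.csv", "diagnoses.csv")
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing))
    stop_config("cohort directory %s lacks: %s", directory,
                paste(missing, collapse = ", "))
  rd <- function(f, cls = NULL) {
    p <- file.path(directory, f)
    if (!file.exists(p)) return(NULL)
    fread(p, colClasses = cls)
  }
  structure(list(
    patients = rd("patients.csv", c(id = "character")),
    scr_events = rd("scr_events.csv", c(id = "character")),
    uo_events = rd("uo_events.csv", c(id = "character")),
    diagnoses = rd("diagnoses.csv", c(id = "character", code = "character")),
    truth_labels = {
      x <- rd("truth_labels.csv", c(id = "character"))
      if (is.null(x)) NULL else as.data.frame(x)
    },
    truth_pairs = {
      x <- rd("truth_pairs.csv")
      if (is.null(x)) NULL else as.data.frame(x)
    },
    config = NULL
  ), class = "cohort_bundle")
}
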