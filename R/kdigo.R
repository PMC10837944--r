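# KDIGO detection and staging of acute kidney injury from serum
# creatinine (Scr, mg/dl) and urine output (Uo, ml) streams.
#
# Staging bands:
#   stage 1: Scr 1.5-1.9x baseline, or >=0.3 mg/dl rise within 48 h;
#            Uo < 0.5 ml/kg/h for 6-12 h
#   stage 2: Scr 2.0-2.9x baseline; Uo < 0.5 ml/kg/h for >= 12 h
#   stage 3: Scr >= 3.0x baseline, or Scr reaching >= 4.0 mg/dl after a
#            qualifying rise; Uo < 0.3 ml/kg/h for >= 24 h, or anuria for
#            >= 12 h
# Baseline creatinine is the rolling minimum over the preceding 7 days.

SCR_BASELINE_WINDOW_H <- 168   # 7 days
SCR_ABS_RISE_MGDL <- 0.3
SCR_ABS_RISE_WINDOW_H <- 48
UO_GAP_MAX_H <- 2              # charting gap that breaks a low-output run
UMOL_PER_MGDL <- 88.4          # creatinine unit conversion

#' Convert serum creatinine from micromol/l to mg/dl
#'
#' The staging functions work in mg/dl only; apply this to series charted
#' in SI units before staging (1 mg/dl = 88.4 micromol/l). No unit
#' auto-detection is attempted.
#'
#' @param x Creatinine values in micromol/l.
#' @return Values in mg/dl.
#' @export
scr_umol_to_mgdl <- function(x) x / UMOL_PER_MGDL

#' Baseline serum creatinine at a time point
#'
#' The baseline is the minimum creatinine observed in the 7-day window
#' `(t - 168, t]`, the rolling-minimum reading of "known or presumed to
#' have occurred within the prior 7 days".
#'
#' @param scr_series `data.frame` with columns `time_hours`, `scr_mg_dl`
#'   (times non-decreasing, values > 0).
#' @param t Time in hours at which the baseline is needed.
#' @return Baseline in mg/dl, or `NA_real_` when no measurement falls in
#'   the window (the Scr criterion is then undefined at `t`).
#' @export
baseline_scr <- function(scr_series, t) {
  s <- as.data.frame(scr_series)
  keep <- s$time_hours > t - SCR_BASELINE_WINDOW_H & s$time_hours <= t
  if (!any(keep)) return(NA_real_)
  min(s$scr_mg_dl[keep])
}

#' Stage AKI from the creatinine criterion
#'
#' Scans a creatinine series; each measurement is compared against its
#' 7-day rolling-minimum baseline (fold change) and against the minimum
#' value of the preceding 48 hours (absolute rise). The returned stage is
#' the highest band attained anywhere in the stay and the onset is the
#' first time any band was entered.
#'
#' @inheritParams baseline_scr
#' @return `list(stage = 0..3, onset_hours = <hours or NA>)`.
#' @export
scr_stage <- function(scr_series) {
  s <- as.data.frame(scr_series)
  if (nrow(s) == 0) return(list(stage = 0L, onset_hours = NA_real_))
  tt <- s$time_hours
  vv <- s$scr_mg_dl
  stages <- integer(nrow(s))
  for (i in seq_len(nrow(s))) {
    base_win <- tt > tt[i] - SCR_BASELINE_WINDOW_H & tt <= tt[i]
    b <- min(vv[base_win])
    ratio <- vv[i] / b
    prior48 <- tt >= tt[i] - SCR_ABS_RISE_WINDOW_H & tt < tt[i]
    rise48 <- if (any(prior48)) vv[i] - min(vv[prior48]) else -Inf
    qualifies <- ratio >= 1.5 || rise48 >= SCR_ABS_RISE_MGDL
    stages[i] <-
      if (qualifies && (ratio >= 3.0 || vv[i] >= 4.0)) 3L
      else if (ratio >= 2.0) 2L
      else if (qualifies) 1L
      else 0L
  }
  stage <- max(stages)
  onset <- if (stage > 0) tt[which(stages > 0)[1]] else NA_real_
  list(stage = stage, onset_hours = onset)
}

# Hourly low-output runs. Volumes are bucketed into clock hours
# (hour = ceiling(time)); a run of qualifying hours tolerates internal
# charting gaps of at most UO_GAP_MAX_H hours (bridged hours count toward
# the duration) but is broken by any charted non-qualifying hour or by a
# longer gap. Returns the first time the duration threshold is met, or NA.
uo_runs <- function(hours, qualify, min_hours) {
  best <- NA_real_
  run_start <- NA_real_
  prev_q <- NA_real_
  close_run <- function() {
    if (!is.na(run_start) && prev_q - run_start + 1 >= min_hours) {
      onset <- run_start - 1 + min_hours
      if (is.na(best) || onset < best) best <<- onset
    }
    run_start <<- NA_real_
  }
  for (i in seq_along(hours)) {
    h <- hours[i]
    if (qualify[i]) {
      if (!is.na(run_start) && h - prev_q > UO_GAP_MAX_H) close_run()
      if (is.na(run_start)) run_start <- h
      prev_q <- h
    } else {
      close_run()
    }
  }
  close_run()
  best
}

#' Stage AKI from the urine-output criterion
#'
#' Buckets charted urine volumes into clock hours, converts to
#' ml/kg/h, and searches for sustained low-output runs: `< 0.5` ml/kg/h
#' for 6-12 h (stage 1) or `>= 12` h (stage 2); `< 0.3` ml/kg/h for
#' `>= 24` h or anuria for `>= 12` h (stage 3). Runs are broken by
#' charting gaps longer than 2 h.
#'
#' @param uo_series `data.frame` with columns `time_hours`, `volume_ml`.
#' @param weight_kg Body weight in kg; if missing or non-positive the
#'   criterion is skipped with a warning and stage 0 is returned.
#' @return `list(stage = 0..3, onset_hours = <hours or NA>)`; the onset is
#'   the first time the patient qualifies as AKI by urine output (the 6-h
#'   rule), or the first time the stage-3 criterion is met if only that
#'   one fires.
#' @export
uo_stage <- function(uo_series, weight_kg) {
  u <- as.data.frame(uo_series)
  if (nrow(u) == 0) return(list(stage = 0L, onset_hours = NA_real_))
  if (is.null(weight_kg) || is.na(weight_kg) || weight_kg <= 0) {
    warning("missing or non-positive weight: urine-output criterion skipped")
    return(list(stage = 0L, onset_hours = NA_real_))
  }
  hour <- ceiling(pmax(u$time_hours, 1e-9))
  vol <- tapply(u$volume_ml, hour, sum)
  hours <- as.numeric(names(vol))
  o <- order(hours)
  hours <- hours[o]
  vol <- as.numeric(vol)[o]
  rate <- vol / weight_kg  # ml/kg/h over 1-h buckets

  on1 <- uo_runs(hours, rate < 0.5, 6)    # AKI / stage 1
  on2 <- uo_runs(hours, rate < 0.5, 12)   # stage 2
  on3a <- uo_runs(hours, rate < 0.3, 24)  # stage 3 oliguria
  on3b <- uo_runs(hours, vol <= 0, 12)    # stage 3 anuria
  on3 <- suppressWarnings(min(on3a, on3b, na.rm = TRUE))
  if (!is.finite(on3)) on3 <- NA_real_

  stage <- if (!is.na(on3)) 3L else if (!is.na(on2)) 2L else if (!is.na(on1)) 1L else 0L
  onset <- if (stage == 0L) NA_real_ else {
    cand <- c(on1, on2, on3)
    min(cand[!is.na(cand)])
  }
  list(stage = stage, onset_hours = onset)
}

#' Detect and stage AKI for one patient
#'
#' Applies both KDIGO criteria and combines them by taking the worse
#' (maximum) stage; onset is the earliest qualifying time across criteria
#' and `criterion` records which stream(s) attained the final stage.
#'
#' @param patient List-like record with `id`, `weight_kg`, `scr_series`
#'   (`time_hours`, `scr_mg_dl`) and `uo_series` (`time_hours`,
#'   `volume_ml`).
#' @return `aki_label`: list with `id`, `has_aki`, `stage`, `onset_hours`,
#'   `criterion` (`"scr"`, `"uo"`, `"both"` or `NA`).
#' @export
stage_patient <- function(patient) {
  scr <- patient$scr_series %||% data.frame(time_hours = numeric(),
                                            scr_mg_dl = numeric())
  uo <- patient$uo_series %||% data.frame(time_hours = numeric(),
                                          volume_ml = numeric())
  if (nrow(as.data.frame(scr)) == 0 && nrow(as.data.frame(uo)) == 0)
    warning(sprintf("patient %s: no creatinine or urine-output data; stage 0",
                    patient$id %||% "?"))
  s <- scr_stage(scr)
  u <- if (nrow(as.data.frame(uo)) > 0)
    uo_stage(uo, patient$weight_kg) else list(stage = 0L, onset_hours = NA_real_)
  stage <- max(s$stage, u$stage)
  criterion <- if (stage == 0L) NA_character_
    else if (s$stage == stage && u$stage == stage) "both"
    else if (s$stage == stage) "scr" else "uo"
  onset <- if (stage == 0L) NA_real_ else {
    cand <- c(s$onset_hours, u$onset_hours)
    min(cand[!is.na(cand)])
  }
  structure(list(id = patient$id, has_aki = stage > 0L, stage = stage,
                 onset_hours = onset, criterion = criterion),
            class = "aki_label")
}

#' Stage every patient in a cohort
#'
#' @param cohort A `cohort_bundle` (or list with `patients`, `scr_events`,
#'   `uo_events` tables).
#' @return `data.frame` with columns `id`, `has_aki`, `stage`,
#'   `onset_hours`, `criterion`.
#' @export
stage_cohort <- function(cohort) {
  pts <- as.data.frame(cohort$patients)
  scr <- as.data.table(cohort$scr_events)
  uo <- as.data.table(cohort$uo_events)
  scr_by <- split(scr[, .(time_hours, scr_mg_dl)], scr$id)
  uo_by <- split(uo[, .(time_hours, volume_ml)], uo$id)
  out <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    pid <- pts$id[i]
    lab <- stage_patient(list(
      id = pid, weight_kg = pts$weight_kg[i],
      scr_series = scr_by[[pid]], uo_series = uo_by[[pid]]
    ))
    out[[i]] <- data.frame(id = pid, has_aki = lab$has_aki, stage = lab$stage,
                           onset_hours = lab$onset_hours,
                           criterion = lab$criterion %||% NA_character_,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id = character(), has_aki = logical(), stage = integer(),
                      onset_hours = numeric(), criterion = character()))
  do.call(rbind, out)
}
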