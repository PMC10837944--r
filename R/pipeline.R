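# End-to-end orchestration: simulate -> stage -> transactions -> mine ->
# validate -> network -> risk factors -> crosstalk, with a reproducibility
# manifest.

#' Pipeline run configuration
#'
#' Defaults mirror the headline analysis settings: patients need at
#' least two valid ICD-10 codes, mining works on 3-character categories,
#' thresholds are `(sup >= 0.08, kulc > 0, lift > 1)`, and the network
#' keeps the top 284 pairs.
#'
#' @param cohort_dir Directory of MIMIC-shaped CSVs; `NULL` to simulate.
#' @param sim A [sim_config()] used when `cohort_dir` is `NULL`.
#' @param seed Root seed (overrides `sim$seed` when simulating).
#' @param thresholds A [mining_thresholds()].
#' @param min_codes,level As in [build_transactions()].
#' @param top_k Network size.
#' @param organ_map_path Optional organ-class CSV.
#' @param mapping_path Optional ICD-9 to ICD-10 CSV (`icd9`, `icd10`).
#' @param eicu_pairs_path Optional reference pair CSV (`code_a`,
#'   `code_b`).
#' @param cohd_map_path,cohd_cooc_path Optional concept-map and
#'   co-occurrence CSVs enabling chi-square verification.
#' @return `run_config` object.
#' @export
run_config <- function(cohort_dir = NULL,
                       sim = sim_config(n_patients = 500),
                       seed = NULL,
                       thresholds = mining_thresholds(),
                       min_codes = 2L,
                       level = "ID3",
                       top_k = 284,
                       organ_map_path = NULL,
                       mapping_path = NULL,
                       eicu_pairs_path = NULL,
                       cohd_map_path = NULL,
                       cohd_cooc_path = NULL) {
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(cohort_dir = cohort_dir, sim = sim, seed = seed,
                 thresholds = thresholds, min_codes = min_codes,
                 level = level, top_k = top_k,
                 organ_map_path = organ_map_path,
                 mapping_path = mapping_path,
                 eicu_pairs_path = eicu_pairs_path,
                 cohd_map_path = cohd_map_path,
                 cohd_cooc_path = cohd_cooc_path),
            class = "run_config")
}

#' Run the full comorbidity pipeline
#'
#' Executes every stage in order, writes all intermediate artifacts under
#' `out_dir`, and returns a manifest (config hash, seed, per-stage
#' counts, file list) sufficient to reproduce the run.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The manifest, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_config("pipeline stage '%s' failed: %s (partial outputs in %s)",
                  name, conditionMessage(e), out_dir))
  }

  cohort <- step("cohort", {
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else generate_cohort(config$sim)
  })
  cohort_dir <- file.path(out_dir, "cohort")
  if (is.null(config$cohort_dir)) step("cohort", write_cohort(cohort, cohort_dir))

  labels <- step("stage", stage_cohort(cohort))
  fwrite(as.data.table(labels), file.path(out_dir, "labels.csv"))

  mapping <- if (!is.null(config$mapping_path))
    fread(config$mapping_path, colClasses = "character") else NULL

  transactions <- step("transactions", build_transactions(
    cohort, labels, mapping = mapping, min_codes = config$min_codes,
    level = config$level))
  jsonlite::write_json(transactions$items,
                       file.path(out_dir, "transactions.json"))

  pairs <- step("mine", mine_comorbidities(transactions, config$thresholds))
  fwrite(as.data.table(as.data.frame(pairs)),
         file.path(out_dir, "comorbidities.csv"))

  eicu <- if (!is.null(config$eicu_pairs_path))
    reference_pairs("eicu", fread(config$eicu_pairs_path)) else NULL
  cohd <- if (!is.null(config$cohd_map_path) && !is.null(config$cohd_cooc_path))
    cohd_reference(fread(config$cohd_map_path), fread(config$cohd_cooc_path))
    else NULL
  verdicts <- if (!is.null(eicu) || !is.null(cohd)) {
    step("validate", validate_pairs(pairs, eicu = eicu, cohd = cohd,
                                    cohort = cohort, labels = labels,
                                    mapping = mapping,
                                    thresholds = config$thresholds))
  } else NULL
  if (!is.null(verdicts))
    fwrite(as.data.table(verdicts), file.path(out_dir, "verdicts.csv"))

  graph <- step("network", build_network(pairs, verdicts, config$top_k))
  export_graph(graph, file.path(out_dir, "network.graphml"), "graphml")
  export_graph(graph, file.path(out_dir, "network.json"), "json")

  stage_lists <- step("risk", suppressWarnings(stage_specific_pairs(
    cohort, labels, mapping = mapping, thresholds = config$thresholds,
    min_codes = config$min_codes, level = config$level)))
  risk <- severe_risk_factors(stage_lists)
  fwrite(data.table(code = risk), file.path(out_dir, "risk_factors.csv"))

  omap <- if (!is.null(config$organ_map_path))
    organ_classes(config$organ_map_path) else organ_classes()
  xt <- step("crosstalk", crosstalk_scores(pairs, omap))
  jsonlite::write_json(list(scores = xt$scores,
                            top_pairs = lapply(xt$top_pairs, as.data.frame)),
                       file.path(out_dir, "crosstalk.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_canon <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                                auto_unbox = TRUE, digits = NA, null = "null",
                                force = TRUE)
  manifest <- list(
    package = "akicomorbid",
    version = as.character(utils::packageVersion("akicomorbid")),
    config_hash = rlang::hash(as.character(cfg_canon)),
    seed = config$seed %||% config$sim$seed %||% NA,
    counts = list(
      n_patients = nrow(cohort$patients),
      n_aki = sum(labels$stage >= 1),
      stage_counts = as.list(table(factor(labels$stage, levels = 0:3))),
      n_transactions = transactions$N,
      n_pairs = nrow(pairs),
      n_network_nodes = igraph::vcount(graph),
      n_network_edges = igraph::ecount(graph),
      n_risk_factors = length(risk),
      n_verdicts = if (is.null(verdicts)) 0L else nrow(verdicts)
    ),
    crosstalk_scores = setNames(as.list(xt$scores$score), xt$scores$organ),
    files = sort(list.files(out_dir, recursive = TRUE))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
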