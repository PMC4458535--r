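#' Pipeline run configuration
#'
#' Bundles every knob of a full staging run. The defaults are the
#' reference analysis settings: 50 selection repetitions with add/remove
#' R-squared thresholds 0.1/0.05 and a 75% retention cutoff, then 2-fold
#' cross-validation repeated 20 times, over all six diagnostic pairs.
#'
#' @param cohort Path to a cohort CSV, or `NULL` to simulate with
#'   `sim_spec`.
#' @param sim_spec Simulation specification as returned by
#'   [default_cohort_specs()] or [read_cohort_spec()].
#' @param pairs List of length-2 label vectors; default all six pairs.
#' @param select_reps,retention_threshold,add_threshold,remove_threshold
#'   Stability-selection parameters.
#' @param eval_reps Cross-validation repetitions (2 folds each).
#' @param seed Master seed; every stage and pair derives an independent
#'   named stream from it, so adding a pair never perturbs another pair.
#' @param outdir Output directory for [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = NULL, sim_spec = default_cohort_specs(),
                       pairs = all_pairs(), select_reps = 50L,
                       retention_threshold = 0.75, add_threshold = 0.1,
                       remove_threshold = 0.05, eval_reps = 20L, seed = 1L,
                       outdir = "adstager_run") {
  structure(list(cohort = cohort, sim_spec = sim_spec, pairs = pairs,
                 select_reps = as.integer(select_reps),
                 retention_threshold = retention_threshold,
                 add_threshold = add_threshold,
                 remove_threshold = remove_threshold,
                 eval_reps = as.integer(eval_reps), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

# Named substream derivation: a stable polynomial hash of "stage:tag"
# folded into the master seed, kept below 2^31.
derive_seed <- function(master, stage, tag = "") {
  s <- paste0(stage, ":", tag)
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 131 + cc) %% 1048573
  as.integer(((as.numeric(master) %% 1e6) * 1048573 + h) %% 2147483646) + 1L
}

#' Run the full staging pipeline
#'
#' simulate (or load) -> TIV-normalize -> stability selection -> incremental
#' LDA evaluation -> model comparison, for every configured diagnostic
#' pair. Writes, under `config$outdir`: per-pair selection JSON
#' (`selection_<pair>.json`), per-pair incremental accuracy curves
#' (`incremental_<pair>.csv`), an optimal-accuracy summary
#' (`optimal_accuracy.csv`: best feature count and mean ± SD of all five
#' metrics per pair), the model-comparison table
#' (`model_comparison.csv`) and a `manifest.json` recording the
#' configuration, derived seeds and package version, from which the whole
#' run can be reproduced. A failing pair is recorded in the manifest and
#' does not abort the others.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `table3` (optimal-accuracy data.frame),
#'   `table4` (comparison data.frame), `selections`, `incrementals`,
#'   `comparisons`, `errors`, and `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$cohort)) {
    tab <- load_cohort(config$cohort)
    cohort_src <- list(type = "file", path = config$cohort)
  } else {
    sim_seed <- derive_seed(config$seed, "simulate")
    tab <- generate_cohort(config$sim_spec$groups, config$sim_spec$atrophy,
                           seed = sim_seed)
    cohort_src <- list(type = "simulated", seed = sim_seed)
  }
  if (!tab$normalized) tab <- normalize_volumes(tab)

  selections <- list(); incrementals <- list(); comparisons <- list()
  errors <- list(); t3 <- list()
  for (pair in config$pairs) {
    pname <- pair_name(pair)
    res <- tryCatch({
      sel_seed <- derive_seed(config$seed, "select", pname)
      sel <- run_stability(tab, pair, n_reps = config$select_reps,
                           retention_threshold = config$retention_threshold,
                           seed = sel_seed,
                           add_threshold = config$add_threshold,
                           remove_threshold = config$remove_threshold)
      write_stability(sel, file.path(config$outdir,
                                     paste0("selection_", pname, ".json")))
      ranked <- sel$ranked
      if (length(ranked) == 0L) {
        fallback <- pick_best(sel$frequencies)
        message(sprintf("run_pipeline [%s]: empty retained set; using highest-frequency feature '%s'",
                        pname, fallback))
        ranked <- fallback
      }
      eval_seed <- derive_seed(config$seed, "evaluate", pname)
      inc <- incremental_analysis(tab, pair, ranked,
                                  n_reps = config$eval_reps, seed = eval_seed)
      curve <- data.frame(
        k = seq_along(inc$accuracy), feature = ranked,
        accuracy = inc$accuracy,
        accuracy_sd = vapply(inc$reports, function(r)
          r$summary$sd[r$summary$metric == "accuracy"], numeric(1)))
      utils::write.csv(curve,
                       file.path(config$outdir,
                                 paste0("incremental_", pname, ".csv")),
                       row.names = FALSE)
      cmp <- compare_models(tab, pair, select_reps = config$select_reps,
                            retention_threshold = config$retention_threshold,
                            add_threshold = config$add_threshold,
                            remove_threshold = config$remove_threshold,
                            eval_reps = config$eval_reps, seed = config$seed)
      s <- inc$best$summary
      row <- data.frame(pair = paste(pair, collapse = " versus "),
                        n_features_max_accuracy = inc$best_k,
                        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(s))) {
        row[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
        row[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
      }
      list(sel = sel, inc = inc, cmp = cmp, row = row)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[pname]] <- conditionMessage(res)
      message(sprintf("run_pipeline [%s]: FAILED: %s", pname,
                      conditionMessage(res)))
    } else {
      selections[[pname]] <- res$sel
      incrementals[[pname]] <- res$inc
      comparisons[[pname]] <- res$cmp
      t3[[pname]] <- res$row
    }
  }

  table3 <- if (length(t3) > 0L) do.call(rbind, t3) else NULL
  if (!is.null(table3)) {
    rownames(table3) <- NULL
    out3 <- table3
    num <- vapply(out3, is.numeric, logical(1))
    out3[num] <- lapply(out3[num], round, digits = 3)
    utils::write.csv(out3, file.path(config$outdir, "optimal_accuracy.csv"),
                     row.names = FALSE)
  }
  table4 <- if (length(comparisons) > 0L) comparison_table(comparisons) else NULL
  if (!is.null(table4)) {
    utils::write.csv(table4, file.path(config$outdir, "model_comparison.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "adstager",
    version = as.character(utils::packageVersion("adstager")),
    seed = config$seed,
    cohort = cohort_src,
    pairs = vapply(config$pairs, pair_name, character(1)),
    parameters = list(select_reps = config$select_reps,
                      retention_threshold = config$retention_threshold,
                      add_threshold = config$add_threshold,
                      remove_threshold = config$remove_threshold,
                      eval_reps = config$eval_reps, n_folds = 2L),
    derived_seeds = c(
      if (is.null(config$cohort)) list(simulate = derive_seed(config$seed, "simulate")),
      stats::setNames(lapply(config$pairs, function(p)
        list(select = derive_seed(config$seed, "select", pair_name(p)),
             evaluate = derive_seed(config$seed, "evaluate", pair_name(p)))),
        vapply(config$pairs, pair_name, character(1)))),
    errors = errors
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(table3 = table3, table4 = table4, selections = selections,
                 incrementals = incrementals, comparisons = comparisons,
                 errors = errors, outdir = config$outdir))
}
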