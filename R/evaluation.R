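#' Confusion counts for a binary staging decision
#'
#' The positive class is the more severe diagnosis, so sensitivity is
#' detection of the diseased group.
#'
#' @param truth,predicted 0/1 vectors (1 = more severe class).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  c(tp = sum(truth == 1L & predicted == 1L),
    fp = sum(truth == 0L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fn = sum(truth == 1L & predicted == 0L))
}

#' Metric suite from confusion counts
#'
#' @param cc Named vector with `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector: accuracy, sensitivity, specificity,
#'   precision, f_measure. Ratios with a zero denominator are `NA`.
#' @export
confusion_metrics <- function(cc) {
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]; fn <- cc[["fn"]]
  n <- tp + fp + tn + fn
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  c(accuracy = ratio(tp + tn, n), sensitivity = sens, specificity = spec,
    precision = prec, f_measure = f)
}

#' Cross-validated classifier evaluation for one diagnostic pair
#'
#' 2-fold cross-validation repeated `n_reps` times (default 20): per
#' repetition the subjects are split into two stratified halves with fixed
#' per-group counts, each half serves once as training and once as test
#' set for the linear discriminant classifier, and both folds' test
#' predictions are pooled into one confusion table. The summary reports the
#' mean and SD of accuracy, sensitivity, specificity, precision and
#' F-measure over the repetitions (F is computed per repetition, then
#' averaged). Subjects are processed in subject-id order and repetitions
#' use seed-derived independent streams, so results are reproducible and
#' row-order invariant.
#'
#' @param table A `feature_table`.
#' @param pair Length-2 character vector of diagnostic labels.
#' @param features Ordered character vector of feature names to use.
#' @param n_reps Number of repetitions of the 2-fold procedure.
#' @param seed Master integer seed.
#' @param prior Length-2 class priors (less severe, more severe).
#' @return An object of class `eval_report`: `pair`, `features`, `n_reps`,
#'   `n_folds = 2`, `per_rep` (data.frame of confusion counts and metrics
#'   per repetition) and `summary` (mean/sd per metric).
#' @export
crossval_evaluate <- function(table, pair, features, n_reps = 20L, seed = 1L,
                              prior = c(0.5, 0.5)) {
  stopifnot(inherits(table, "feature_table"), length(pair) == 2L, n_reps >= 1L)
  sp <- subset_pair(table, pair[1L], pair[2L])
  missing_f <- setdiff(features, colnames(sp$table$features))
  if (length(missing_f) > 0L) {
    stop("feature(s) not in table: ", paste(missing_f, collapse = ", "))
  }
  ord <- order(sp$table$subject_id)
  X <- sp$table$features[ord, features, drop = FALSE]
  y <- sp$y[ord]
  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  f0 <- ceiling(length(idx0) / 2); f1 <- ceiling(length(idx1) / 2)
  m <- length(features)
  min_fold <- min(f0 + f1, length(idx0) - f0 + length(idx1) - f1)
  if (min(f0, f1, length(idx0) - f0, length(idx1) - f1) < 2L) {
    stop(sprintf("fold too small: %d test subjects for %d feature(s)", min_fold, m))
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seed(seed, r))
    foldA <- c(idx0[sample.int(length(idx0), f0)],
               idx1[sample.int(length(idx1), f1)])
    foldB <- setdiff(seq_along(y), foldA)
    pred <- integer(length(y))
    for (fold in list(list(tr = foldA, te = foldB),
                      list(tr = foldB, te = foldA))) {
      model <- fit_lda(X[fold$tr, , drop = FALSE], y[fold$tr], prior = prior,
                       class_labels = sp$pair)
      cl <- score_and_classify(model, X[fold$te, , drop = FALSE])
      pred[fold$te] <- as.integer(cl$assigned == sp$pair[2L])
    }
    cc <- confusion_counts(y, pred)
    per_rep[[r]] <- c(cc, confusion_metrics(cc))
  }
  per_rep <- as.data.frame(do.call(rbind, per_rep))
  metric_names <- c("accuracy", "sensitivity", "specificity",
                    "precision", "f_measure")
  summ <- data.frame(
    metric = metric_names,
    mean = vapply(per_rep[metric_names], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per_rep[metric_names], stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL)
  structure(list(pair = sp$pair, features = features,
                 n_reps = as.integer(n_reps), n_folds = 2L,
                 per_rep = per_rep, summary = summ),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s vs %s: %d feature(s), %d-fold x %d\n",
              x$pair[1], x$pair[2], length(x$features), x$n_folds, x$n_reps))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f ± %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

report_mean <- function(report, metric = "accuracy") {
  report$summary$mean[report$summary$metric == metric]
}

#' Incremental top-k feature evaluation
#'
#' Evaluates the classifier on the top-1, top-2, ..., top-K prefixes of a
#' ranked feature list and reports the feature count maximizing mean
#' cross-validated accuracy (ties broken toward fewer features). This is
#' the accuracy-saturation analysis: past some k, adding features stops
#' helping.
#'
#' @param table A `feature_table`.
#' @param pair Diagnostic pair.
#' @param ranked_features Ranked feature names (best first), e.g. the
#'   `ranked` field of a [run_stability()] result.
#' @param n_reps,seed,prior Passed to [crossval_evaluate()] (the same seed
#'   is used for every k so prefixes face identical splits).
#' @return An object of class `incremental_report`: `reports` (one
#'   `eval_report` per prefix), `accuracy` (mean per k), `best_k`,
#'   `best` (the best prefix's `eval_report`), `pair`, `ranked_features`.
#' @export
incremental_analysis <- function(table, pair, ranked_features, n_reps = 20L,
                                 seed = 1L, prior = c(0.5, 0.5)) {
  stopifnot(length(ranked_features) >= 1L)
  reports <- lapply(seq_along(ranked_features), function(k) {
    crossval_evaluate(table, pair, ranked_features[seq_len(k)],
                      n_reps = n_reps, seed = seed, prior = prior)
  })
  acc <- vapply(reports, report_mean, numeric(1))
  best_k <- which.max(acc)   # first maximum: ties go to smaller k
  structure(list(pair = reports[[1L]]$pair, ranked_features = ranked_features,
                 reports = reports, accuracy = acc,
                 best_k = best_k, best = reports[[best_k]]),
            class = "incremental_report")
}

#' @export
print.incremental_report <- function(x, ...) {
  cat(sprintf("<incremental_report> %s vs %s: k = 1..%d, best k = %d (accuracy %.3f)\n",
              x$pair[1], x$pair[2], length(x$accuracy), x$best_k,
              x$accuracy[x$best_k]))
  invisible(x)
}

#' Relative improvement of the combined model
#'
#' `(combined - single) / single * 100`, in percent.
#'
#' @param combined,single Accuracy fractions; `single` must be positive.
#' @return Percent relative improvement.
#' @export
#' @examples
#' improvement(0.939, 0.922)  # 1.844
improvement <- function(combined, single) {
  if (any(single <= 0)) stop("single-modality accuracy must be positive")
  (combined - single) / single * 100
}

#' Neuropsychological / MRI / combined model comparison for one pair
#'
#' Runs the full selection-plus-evaluation pipeline three times with
#' restricted candidate pools: neuropsychological + demographic features,
#' volumetric + demographic features, and all features (demographics enter
#' every pool, to absorb age/gender/education-related variability). Each
#' variant's reported accuracy is the maximum of its incremental top-k
#' accuracies; the combined model's relative improvement over each
#' single-modality model is computed with [improvement()]. If a pool
#' retains no feature at the consensus threshold, the variant falls back to
#' that pool's single highest-frequency feature (with a message).
#'
#' @param table A `feature_table` containing all three feature categories.
#' @param pair Diagnostic pair.
#' @param select_reps,retention_threshold,add_threshold,remove_threshold
#'   Passed to [run_stability()].
#' @param eval_reps Passed to [crossval_evaluate()].
#' @param seed Master seed; each variant gets a derived stream.
#' @return An object of class `model_comparison_row`: accuracies
#'   `neuropsychological`, `mri`, `combined`, improvements
#'   `improvement_over_neuro`, `improvement_over_mri`, and `details`
#'   (per-variant selection and incremental reports).
#' @export
compare_models <- function(table, pair, select_reps = 50L,
                           retention_threshold = 0.75, add_threshold = 0.1,
                           remove_threshold = 0.05, eval_reps = 20L,
                           seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  cats <- table$categories
  if (!all(c("demographic", "neuropsychological", "volumetric") %in% cats)) {
    stop("table must contain demographic, neuropsychological and volumetric features")
  }
  pools <- list(
    neuropsychological = names(cats)[cats %in% c("neuropsychological", "demographic")],
    mri = names(cats)[cats %in% c("volumetric", "demographic")],
    combined = names(cats)
  )
  details <- list()
  acc <- c(neuropsychological = NA_real_, mri = NA_real_, combined = NA_real_)
  for (variant in names(pools)) {
    vseed <- derive_seed(seed, "compare", paste(pair_name(pair), variant))
    sel <- run_stability(table, pair, n_reps = select_reps,
                         retention_threshold = retention_threshold,
                         seed = vseed, add_threshold = add_threshold,
                         remove_threshold = remove_threshold,
                         candidates = pools[[variant]])
    ranked <- sel$ranked
    if (length(ranked) == 0L) {
      fallback <- pick_best(sel$frequencies)
      message(sprintf("compare_models [%s, %s]: empty retained set; falling back to highest-frequency feature '%s'",
                      pair_name(pair), variant, fallback))
      ranked <- fallback
    }
    inc <- incremental_analysis(table, pair, ranked, n_reps = eval_reps,
                                seed = vseed)
    acc[variant] <- max(inc$accuracy)
    details[[variant]] <- list(selection = sel, incremental = inc)
  }
  structure(list(
    pair = pair,
    neuropsychological = unname(acc["neuropsychological"]),
    mri = unname(acc["mri"]),
    combined = unname(acc["combined"]),
    improvement_over_neuro = improvement(acc[["combined"]], acc[["neuropsychological"]]),
    improvement_over_mri = improvement(acc[["combined"]], acc[["mri"]]),
    details = details
  ), class = "model_comparison_row")
}

#' Assemble a model-comparison table with averages
#'
#' Stacks per-pair comparison rows into the standard layout (accuracy of
#' the neuropsychological, MRI and combined models, percent improvement of
#' the combined model over each) and appends the arithmetic column means.
#'
#' @param rows List of `model_comparison_row` objects (or a data.frame with
#'   the accuracy columns, from which improvements are recomputed).
#' @param digits Rounding for the assembled table (default 3, half-even).
#' @return A data.frame with one row per pair plus an `Average` row.
#' @export
comparison_table <- function(rows, digits = 3) {
  if (is.data.frame(rows)) {
    df <- data.frame(
      pair = rows$pair,
      neuropsychological = rows$neuropsychological,
      mri = rows$mri,
      combined = rows$combined,
      improvement_over_neuro = improvement(rows$combined, rows$neuropsychological),
      improvement_over_mri = improvement(rows$combined, rows$mri),
      stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      data.frame(pair = paste(r$pair, collapse = " versus "),
                 neuropsychological = r$neuropsychological, mri = r$mri,
                 combined = r$combined,
                 improvement_over_neuro = r$improvement_over_neuro,
                 improvement_over_mri = r$improvement_over_mri,
                 stringsAsFactors = FALSE)
    }))
  }
  avg <- data.frame(pair = "Average",
                    neuropsychological = mean(df$neuropsychological),
                    mri = mean(df$mri), combined = mean(df$combined),
                    improvement_over_neuro = mean(df$improvement_over_neuro),
                    improvement_over_mri = mean(df$improvement_over_mri),
                    stringsAsFactors = FALSE)
  out <- rbind(df, avg)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  rownames(out) <- NULL
  out
}
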