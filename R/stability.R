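#' Resampling-consensus feature selection for one diagnostic pair
#'
#' The stabilization wrapper around [stepwise_select()]: the subjects of a
#' diagnostic pair are repeatedly (default 50 times) split at random into
#' two halves, stratified by label; the stepwise regression runs on the
#' training half only (the other half is discarded for selection purposes),
#' and a feature is retained if it appears in the final stepwise model in
#' more than `retention_threshold` (default 75%) of the repetitions.
#' Retained features are ranked by aggregated coefficient p-value (median
#' over the repetitions that selected them), ties broken by higher
#' selection frequency, then feature name.
#'
#' Subjects are processed in subject-id order, so results do not depend on
#' the row order of the input table. One master seed derives an independent
#' per-repetition stream, making each repetition reproducible on its own.
#'
#' @param table A `feature_table` (normalize volumes first).
#' @param pair Length-2 character vector of diagnostic labels.
#' @param n_reps Number of resampling repetitions.
#' @param retention_threshold Retention frequency cutoff (strict `>`).
#' @param seed Master integer seed.
#' @param add_threshold,remove_threshold Stepwise R-squared increment rules.
#' @param candidates Optional character vector restricting the candidate
#'   feature pool (default: every feature in the table).
#' @param refit_all If `TRUE`, additionally refit an OLS model with the
#'   retained features on ALL subjects of the pair and report its p-values
#'   (reporting aid only; ranking always uses the aggregated values).
#' @return An object of class `stability_result`: `pair`, `n_reps`,
#'   `frequencies` (named, over candidates), `retained`, `ranked`,
#'   `aggregated_pvalues`, `history` (per-repetition selected sets and
#'   p-values), `retention_threshold`, and optionally `refit`.
#' @export
run_stability <- function(table, pair, n_reps = 50L, retention_threshold = 0.75,
                          seed = 1L, add_threshold = 0.1,
                          remove_threshold = 0.05, candidates = NULL,
                          refit_all = FALSE) {
  stopifnot(inherits(table, "feature_table"), length(pair) == 2L,
            n_reps >= 1L, retention_threshold > 0, retention_threshold < 1)
  sp <- subset_pair(table, pair[1L], pair[2L])
  ord <- order(sp$table$subject_id)
  X <- sp$table$features[ord, , drop = FALSE]
  y <- sp$y[ord]
  if (is.null(candidates)) candidates <- colnames(X)
  stopifnot(all(candidates %in% colnames(X)))
  X <- X[, candidates, drop = FALSE]

  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  n_tr0 <- ceiling(length(idx0) / 2); n_tr1 <- ceiling(length(idx1) / 2)
  if (n_tr0 + n_tr1 <= 3L) stop("training half too small for a 1-feature OLS fit")

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  history <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seed(seed, r))
    tr <- c(idx0[sample.int(length(idx0), n_tr0)],
            idx1[sample.int(length(idx1), n_tr1)])
    fit <- stepwise_select(X[tr, , drop = FALSE], y[tr],
                           add_threshold = add_threshold,
                           remove_threshold = remove_threshold)
    history[[r]] <- list(selected = fit$selected, pvalues = fit$pvalues)
  }

  counts <- table(factor(unlist(lapply(history, `[[`, "selected")),
                         levels = candidates))
  frequencies <- as.numeric(counts) / n_reps
  names(frequencies) <- candidates
  rk <- rank_features(history, retention_threshold = retention_threshold,
                      frequencies = frequencies)
  out <- structure(list(
    pair = sp$pair, n_reps = as.integer(n_reps),
    frequencies = frequencies,
    retained = rk$retained, ranked = rk$ranked,
    aggregated_pvalues = rk$aggregated_pvalues,
    history = history, retention_threshold = retention_threshold
  ), class = "stability_result")
  if (refit_all && length(rk$retained) > 0L) {
    out$refit <- fit_ols(X[, rk$ranked, drop = FALSE], y)
  }
  out
}

# independent per-repetition stream from one master seed
rep_seed <- function(master, r) {
  as.integer(((as.numeric(master) %% 1e6) * 2048 + 104729 * r) %% 2147483646) + 1L
}

#' Rank retained features by aggregated p-value
#'
#' Given the per-repetition selection history, computes each feature's
#' selection frequency, applies the retention cutoff, aggregates its
#' coefficient p-values (median over the repetitions in which it was
#' selected) and ranks retained features by aggregated p-value ascending,
#' ties broken by higher frequency, then by name.
#'
#' @param history List, one element per repetition, each with `selected`
#'   (character) and `pvalues` (named numeric over the selected features).
#' @param retention_threshold Frequency cutoff (strict `>`).
#' @param frequencies Optional precomputed named frequency vector; computed
#'   from `history` when omitted.
#' @return A list with `retained` (unordered), `ranked` (ordered) and
#'   `aggregated_pvalues` (named, in ranked order).
#' @export
rank_features <- function(history, retention_threshold = 0.75,
                          frequencies = NULL) {
  n_reps <- length(history)
  all_sel <- unlist(lapply(history, `[[`, "selected"))
  if (is.null(frequencies)) {
    counts <- table(all_sel)
    frequencies <- as.numeric(counts) / n_reps
    names(frequencies) <- names(counts)
  }
  retained <- names(frequencies)[frequencies > retention_threshold]
  if (length(retained) == 0L) {
    return(list(retained = character(), ranked = character(),
                aggregated_pvalues = stats::setNames(numeric(0), character(0))))
  }
  agg <- vapply(retained, function(f) {
    ps <- unlist(lapply(history, function(h) h$pvalues[f]))
    stats::median(ps, na.rm = TRUE)
  }, numeric(1))
  ord <- order(agg, -frequencies[retained], retained)
  ranked <- retained[ord]
  list(retained = retained, ranked = ranked,
       aggregated_pvalues = agg[ord])
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %s vs %s: %d repetitions, %d feature(s) retained (> %g%%)\n",
              x$pair[1], x$pair[2], x$n_reps, length(x$retained),
              100 * x$retention_threshold))
  if (length(x$ranked) > 0L) {
    print(data.frame(rank = seq_along(x$ranked), feature = x$ranked,
                     frequency = unname(x$frequencies[x$ranked]),
                     aggregated_p = unname(x$aggregated_pvalues),
                     row.names = NULL))
  }
  invisible(x)
}

#' Write a stability-selection result to JSON
#'
#' @param result A `stability_result`.
#' @param path Output path.
#' @param traces Include the full per-repetition selection history.
#' @return `path`, invisibly.
#' @export
write_stability <- function(result, path, traces = TRUE) {
  stopifnot(inherits(result, "stability_result"))
  obj <- list(
    pair = result$pair, n_reps = result$n_reps,
    retention_threshold = result$retention_threshold,
    frequencies = as.list(result$frequencies[result$frequencies > 0]),
    retained = result$retained, ranked = result$ranked,
    aggregated_pvalues = as.list(result$aggregated_pvalues)
  )
  if (traces) {
    obj$history <- lapply(result$history, function(h)
      list(selected = h$selected, pvalues = as.list(h$pvalues)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
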