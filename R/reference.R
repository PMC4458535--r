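#' Published per-pair model accuracies
#'
#' The published cross-validated accuracies of the neuropsychological-only,
#' MRI-only and combined models for each of the six diagnostic pairs, as
#' shipped in `inst/extdata/published_model_accuracies.csv`. These are
#' inputs for the relative-improvement arithmetic ([improvement()],
#' [comparison_table()]); the package's own synthetic-cohort runs produce
#' their own accuracies.
#'
#' @return A data.frame with columns `pair`, `neuropsychological`, `mri`,
#'   `combined`.
#' @export
#' @examples
#' acc <- published_model_accuracies()
#' comparison_table(acc)
published_model_accuracies <- function() {
  utils::read.csv(system.file("extdata", "published_model_accuracies.csv",
                              package = "adstager", mustWork = TRUE),
                  check.names = FALSE, stringsAsFactors = FALSE)
}
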