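#' Diagnostic stages, ordered by severity
#'
#' The four diagnostic labels handled by the package, in increasing order of
#' disease severity: cognitively normal (CN), early and late mild cognitive
#' impairment (EMCI, LMCI), and Alzheimer's disease (AD). All pairwise
#' classification code derives its 0/1 response coding from this ordering
#' (the more severe group is the positive class).
#'
#' @return Character vector `c("CN", "EMCI", "LMCI", "AD")`.
#' @export
#' @examples
#' diagnostic_levels()
diagnostic_levels <- function() c("CN", "EMCI", "LMCI", "AD")

#' Severity rank of a diagnostic label
#'
#' @param label Character vector of diagnostic labels.
#' @return Integer vector: 0 for CN, 1 for EMCI, 2 for LMCI, 3 for AD.
#' @export
severity_order <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), diagnostic_levels())
  if (length(bad) > 0L) {
    stop("unknown diagnostic label(s): ", paste(bad, collapse = ", "))
  }
  match(label, diagnostic_levels()) - 1L
}

feature_categories <- c("demographic", "neuropsychological", "volumetric")

#' Construct a feature table
#'
#' The central data container: one row per subject, one column per candidate
#' model feature, with each feature tagged as demographic, neuropsychological
#' or volumetric. Total intracranial volume (TIV) is carried separately so
#' that volumetric features can be converted to volume/TIV ratios by
#' [normalize_volumes()]. Non-feature per-subject variables (e.g. CDRSb,
#' which belongs to the diagnostic index, not the feature set) live in
#' `metadata`.
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param diagnosis Character or factor; one of CN/EMCI/LMCI/AD per subject.
#' @param features Numeric matrix, subjects x features, with column names.
#' @param categories Named character vector mapping every feature name to one
#'   of `"demographic"`, `"neuropsychological"`, `"volumetric"`.
#' @param tiv Numeric vector of total intracranial volumes (mL), required
#'   (and strictly positive) whenever any volumetric feature is present.
#' @param metadata Optional data.frame of per-subject non-feature variables.
#' @param normalized Logical; `TRUE` once volumetric features are
#'   volume/TIV ratios.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(subject_id, diagnosis, features, categories,
                          tiv = NULL, metadata = NULL, normalized = FALSE) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) {
    stop("duplicate subject ids: ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  }
  diagnosis <- factor(as.character(diagnosis), levels = diagnostic_levels())
  if (anyNA(diagnosis)) stop("unknown diagnostic label in 'diagnosis'")
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- length(subject_id)
  if (nrow(features) != n || length(diagnosis) != n) {
    stop("subject_id, diagnosis and features disagree on the number of subjects")
  }
  fn <- colnames(features)
  if (is.null(fn) || anyDuplicated(fn)) {
    stop("features must have unique column names")
  }
  if (anyNA(features)) stop("feature matrix contains missing values")
  if (!all(fn %in% names(categories))) {
    stop("every feature needs a category; missing: ",
         paste(setdiff(fn, names(categories)), collapse = ", "))
  }
  categories <- categories[fn]
  if (!all(categories %in% feature_categories)) {
    stop("categories must be one of: ", paste(feature_categories, collapse = ", "))
  }
  has_vol <- any(categories == "volumetric")
  if (has_vol) {
    if (is.null(tiv)) stop("TIV is required when volumetric features are present")
    tiv <- as.numeric(tiv)
    if (length(tiv) != n || anyNA(tiv) || any(tiv <= 0)) {
      stop("TIV must be positive and present for every subject")
    }
    if (!normalized && any(features[, categories == "volumetric", drop = FALSE] <= 0)) {
      stop("raw volumetric features must be strictly positive")
    }
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != n) stop("metadata must have one row per subject")
  }
  structure(list(
    subject_id = subject_id,
    diagnosis = diagnosis,
    features = features,
    categories = categories,
    tiv = tiv,
    metadata = metadata,
    normalized = isTRUE(normalized)
  ), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$diagnosis)
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              length(x$subject_id), ncol(x$features),
              if (x$normalized) "TIV-normalized" else "raw volumes"))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  ct <- table(factor(x$categories, levels = feature_categories))
  cat("  features:", paste(sprintf("%s=%d", names(ct), ct), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Default CSV column schema
#'
#' Maps CSV columns to roles: `subject_id` and `diagnosis` are required;
#' `TIV_mL` holds total intracranial volume; `age`, `gender`, `education`
#' are demographic features; `MMSE` and `RAVLT` neuropsychological; any
#' column prefixed `vol_` a volumetric feature; `CDRSb`, if present, is
#' carried as metadata only (it is part of the diagnostic index, not a
#' classifier feature).
#'
#' @return A list with entries `subject_id`, `diagnosis`, `tiv`,
#'   `demographic`, `neuropsychological`, `volumetric_prefix`, `metadata`.
#' @export
default_schema <- function() {
  list(
    subject_id = "subject_id",
    diagnosis = "diagnosis",
    tiv = "TIV_mL",
    demographic = c("age", "gender", "education"),
    neuropsychological = c("MMSE", "RAVLT"),
    volumetric_prefix = "vol_",
    metadata = "CDRSb"
  )
}

#' Read a column schema from a YAML file
#'
#' @param path Path to a YAML file with the same keys as [default_schema()];
#'   missing keys fall back to the defaults.
#' @return A schema list.
#' @export
read_schema <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_schema(), user)
}

#' Load a subject-level cohort from CSV
#'
#' Reads a per-subject table (comma-separated, header row, '.' decimal),
#' validates it against a column schema, and returns a [feature_table()].
#' Rows with missing values in any required column are dropped and counted
#' in a message; the loader never imputes.
#'
#' @param path CSV file path.
#' @param schema Column-role mapping, see [default_schema()].
#' @return A `feature_table` with `normalized = FALSE`. The number of dropped
#'   rows is attached as attribute `"n_dropped"`.
#' @export
load_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c(schema$subject_id, schema$diagnosis)
  if (!all(req %in% names(df))) {
    stop("missing required column(s): ", paste(setdiff(req, names(df)), collapse = ", "))
  }
  vol_cols <- grep(paste0("^", schema$volumetric_prefix), names(df), value = TRUE)
  demo_cols <- intersect(schema$demographic, names(df))
  neuro_cols <- intersect(schema$neuropsychological, names(df))
  feat_cols <- c(demo_cols, neuro_cols, vol_cols)
  if (length(feat_cols) == 0L) stop("schema matched no feature columns")
  if (length(vol_cols) > 0L && !(schema$tiv %in% names(df))) {
    stop("TIV column '", schema$tiv, "' required when volumetric columns are present")
  }
  need <- c(req, feat_cols, if (length(vol_cols) > 0L) schema$tiv)
  for (cc in setdiff(need, req)) {
    if (!is.numeric(df[[cc]])) {
      suppressWarnings(num <- as.numeric(df[[cc]]))
      if (sum(is.na(num) & !is.na(df[[cc]]) & df[[cc]] != "") > 0L) {
        stop("non-numeric value in feature column '", cc, "'")
      }
      df[[cc]] <- num
    }
  }
  keep <- stats::complete.cases(df[, need, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("load_cohort: dropped %d row(s) with missing required values", n_dropped))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete rows left after dropping missing values")
  categories <- c(
    stats::setNames(rep("demographic", length(demo_cols)), demo_cols),
    stats::setNames(rep("neuropsychological", length(neuro_cols)), neuro_cols),
    stats::setNames(rep("volumetric", length(vol_cols)), vol_cols)
  )
  meta_cols <- intersect(schema$metadata, names(df))
  tab <- feature_table(
    subject_id = df[[schema$subject_id]],
    diagnosis = df[[schema$diagnosis]],
    features = as.matrix(df[, feat_cols, drop = FALSE]),
    categories = categories,
    tiv = if (length(vol_cols) > 0L) df[[schema$tiv]] else
      if (schema$tiv %in% names(df)) df[[schema$tiv]] else NULL,
    metadata = if (length(meta_cols) > 0L) df[, meta_cols, drop = FALSE] else NULL
  )
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()] under the default schema: writes
#' `subject_id`, `diagnosis`, `TIV_mL`, metadata columns, then all feature
#' columns, at full double precision (round-trip stable).
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject_id = table$subject_id,
                   diagnosis = as.character(table$diagnosis),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$tiv)) df$TIV_mL <- table$tiv
  if (!is.null(table$metadata)) df <- cbind(df, table$metadata)
  df <- cbind(df, as.data.frame(table$features, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert volumetric features to volume/TIV ratios
#'
#' Divides every volumetric feature by the subject's total intracranial
#' volume, removing head-size variation. Demographic and neuropsychological
#' features are untouched. The operation is guarded: applying it twice is an
#' error, never a silent rescale.
#'
#' @param table A `feature_table` with `normalized = FALSE`.
#' @return The table with volumetric columns replaced by ratios and
#'   `normalized = TRUE`.
#' @export
normalize_volumes <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$normalized) stop("volumes already normalized (refusing to rescale twice)")
  vol <- which(table$categories == "volumetric")
  if (length(vol) > 0L) {
    if (is.null(table$tiv) || any(table$tiv <= 0)) {
      stop("TIV must be present and positive for every subject")
    }
    table$features[, vol] <- table$features[, vol, drop = FALSE] / table$tiv
  }
  table$normalized <- TRUE
  table
}

#' Restrict a cohort to one diagnostic pair
#'
#' Keeps only subjects carrying the two requested labels (subject order
#' preserved) and builds the binary response for pairwise modelling:
#' y = 0 for the less severe group, 1 for the more severe group, so the
#' positive class always aligns with disease progression.
#'
#' @param table A `feature_table`.
#' @param group_a,group_b Two distinct diagnostic labels.
#' @return A list with elements `table` (the subset `feature_table`), `y`
#'   (integer 0/1 response) and `pair` (labels ordered less-severe first).
#' @export
subset_pair <- function(table, group_a, group_b) {
  stopifnot(inherits(table, "feature_table"))
  sev <- severity_order(c(group_a, group_b))
  if (group_a == group_b) stop("group_a and group_b must differ")
  pair <- c(group_a, group_b)[order(sev)]
  keep <- which(table$diagnosis %in% pair)
  sub <- table
  sub$subject_id <- table$subject_id[keep]
  sub$diagnosis <- droplevels(table$diagnosis[keep])
  sub$features <- table$features[keep, , drop = FALSE]
  if (!is.null(table$tiv)) sub$tiv <- table$tiv[keep]
  if (!is.null(table$metadata)) sub$metadata <- table$metadata[keep, , drop = FALSE]
  y <- as.integer(as.character(sub$diagnosis) == pair[2L])
  if (sum(y == 0L) == 0L || sum(y == 1L) == 0L) {
    stop("one of the groups is empty after subsetting: ", paste(pair, collapse = " vs "))
  }
  list(table = sub, y = y, pair = pair)
}

#' The six diagnostic classification pairs
#'
#' @return A list of six length-2 character vectors, less severe label first.
#' @export
all_pairs <- function() {
  lv <- diagnostic_levels()
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) out[[length(out) + 1L]] <- c(lv[i], lv[j])
  out
}

pair_name <- function(pair) paste(pair, collapse = "_vs_")
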