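#' Group-level simulation parameters
#'
#' Describes one diagnostic group of a simulated cohort: its size and the
#' mean/SD of each demographic, neuropsychological and head-size variable.
#' Gender is specified as an exact male count (assigned deterministically,
#' not sampled) so published gender tables reproduce exactly.
#'
#' @param label Diagnostic label, one of CN/EMCI/LMCI/AD.
#' @param n Number of subjects (>= 2).
#' @param age,education,mmse,ravlt,cdrsb,tiv Length-2 numeric vectors
#'   `c(mean, sd)`; units are years, years, score points, score points,
#'   score points and mL respectively.
#' @param gender_male Integer count of male subjects (coded 0; females 1).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, n, age, education, gender_male,
                       mmse, ravlt, cdrsb, tiv) {
  stopifnot(label %in% diagnostic_levels(), n >= 2,
            gender_male >= 0, gender_male <= n)
  for (v in list(age, education, mmse, ravlt, cdrsb, tiv)) {
    stopifnot(length(v) == 2L, v[2] >= 0)
  }
  if (mmse[1] < 0 || mmse[1] > 30) stop("MMSE mean outside the 0-30 instrument range")
  structure(list(label = label, n = as.integer(n),
                 age = age, education = education,
                 gender_male = as.integer(gender_male),
                 mmse = mmse, ravlt = ravlt, cdrsb = cdrsb, tiv = tiv),
            class = "group_spec")
}

#' Regional-volume simulation parameters
#'
#' Describes the 115 volumetric features: each region's typical volume as a
#' fraction of TIV, which regions carry group-discriminating atrophy, how
#' strongly each region loads on a shared subject-level atrophy factor, and
#' the multiplicative measurement noise. For an informative region the
#' group multipliers must be monotone along the severity order CN -> EMCI ->
#' LMCI -> AD, with a fixed direction per region: shrinking (multiplier
#' decreasing from 1) for atrophying tissue, growing (increasing from 1) for
#' ventricular/CSF spaces that enlarge with disease.
#'
#' @param region_names Character vector of volumetric feature names
#'   (without the `vol_` column prefix).
#' @param base_fraction Named numeric vector: per-region mean volume as a
#'   fraction of TIV.
#' @param multipliers Numeric matrix, informative regions x 4 labels
#'   (columns CN, EMCI, LMCI, AD), of group multipliers; rownames identify
#'   the informative regions. Regions absent from it are non-informative
#'   (multiplier exactly 1 in every group).
#' @param latent_loading Loadings of each region on shared standard-normal
#'   latent factors: a scalar (recycled; one global atrophy factor), a named
#'   vector (per-region loading on the one global factor), or a matrix with
#'   one row per region (rownames) and one column per factor. The default is
#'   a single global factor; extra columns model additional shared anatomical
#'   variation, which is what makes multi-feature decisional spaces (several
#'   regions each contributing independently to the staging model) possible.
#' @param noise_cv Per-region coefficient of variation of multiplicative
#'   measurement noise (scalar recycled, or named vector).
#' @return An object of class `atrophy_spec`.
#' @export
atrophy_spec <- function(region_names, base_fraction, multipliers = NULL,
                         latent_loading = 0.06, noise_cv = 0.08) {
  region_names <- as.character(region_names)
  stopifnot(length(region_names) > 0L, !anyDuplicated(region_names))
  stopifnot(all(region_names %in% names(base_fraction)))
  base_fraction <- base_fraction[region_names]
  stopifnot(all(base_fraction > 0))
  if (is.null(multipliers)) {
    multipliers <- matrix(numeric(0), 0, 4,
                          dimnames = list(NULL, diagnostic_levels()))
  }
  stopifnot(is.matrix(multipliers), ncol(multipliers) == 4L)
  colnames(multipliers) <- diagnostic_levels()
  if (nrow(multipliers) > 0L) {
    stopifnot(all(rownames(multipliers) %in% region_names),
              all(multipliers > 0))
    d <- t(apply(multipliers, 1L, diff))
    monotone <- apply(d, 1L, function(r) all(r <= 0) || all(r >= 0))
    if (!all(monotone)) {
      stop("group multipliers must be monotone along the severity order for: ",
           paste(rownames(multipliers)[!monotone], collapse = ", "))
    }
  }
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      return(stats::setNames(rep(as.numeric(x), length(region_names)), region_names))
    }
    stopifnot(all(region_names %in% names(x)))
    stats::setNames(as.numeric(x[region_names]), region_names)
  }
  if (is.matrix(latent_loading)) {
    stopifnot(!is.null(rownames(latent_loading)),
              all(rownames(latent_loading) %in% region_names))
    L <- matrix(0, length(region_names), ncol(latent_loading),
                dimnames = list(region_names, NULL))
    L[rownames(latent_loading), ] <- latent_loading
  } else {
    L <- cbind(expand(latent_loading))
    rownames(L) <- region_names
  }
  structure(list(
    region_names = region_names,
    base_fraction = base_fraction,
    informative_regions = rownames(multipliers),
    multipliers = multipliers,
    latent_loading = L,
    noise_cv = expand(noise_cv)
  ), class = "atrophy_spec")
}

# The 115 volumetric feature names: 34 Desikan cortical parcels per
# hemisphere plus 47 subcortical / midline / global measures.
default_region_names <- function() {
  desikan <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
  bilateral <- c("Lateral-Ventricle", "Inf-Lat-Vent",
                 "Cerebellum-White-Matter", "Cerebellum-Cortex",
                 "Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
                 "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC",
                 "choroid-plexus", "Cerebral-White-Matter", "Cerebral-Cortex",
                 "vessel")
  midline <- c("3rd-Ventricle", "4th-Ventricle", "Brain-Stem", "CSF",
               "WM-hypointensities", "non-WM-hypointensities", "Optic-Chiasm",
               "CC_Posterior", "CC_Mid_Posterior", "CC_Central",
               "CC_Mid_Anterior", "CC_Anterior", "WholeBrain",
               "SupraTentorial", "SubCortGray")
  c(paste0("lh_", desikan), paste0("rh_", desikan),
    paste0("Left-", bilateral), paste0("Right-", bilateral), midline)
}

default_base_fractions <- function() {
  nm <- default_region_names()
  # order-of-magnitude realistic volume/TIV fractions; config values only
  frac <- stats::setNames(rep(0.004, length(nm)), nm)
  set_val <- function(pattern, value) {
    frac[grepl(pattern, names(frac))] <<- value
  }
  set_val("Hippocampus$", 0.0025)
  set_val("Amygdala$", 0.0011)
  set_val("Lateral-Ventricle$", 0.008)
  set_val("Inf-Lat-Vent$", 0.0003)
  set_val("Thalamus-Proper$", 0.0045)
  set_val("Caudate$", 0.0023)
  set_val("Putamen$", 0.0032)
  set_val("Pallidum$", 0.0010)
  set_val("Accumbens-area$", 0.0004)
  set_val("VentralDC$", 0.0026)
  set_val("choroid-plexus$", 0.0005)
  set_val("Cerebellum-Cortex$", 0.030)
  set_val("Cerebellum-White-Matter$", 0.009)
  set_val("Cerebral-White-Matter$", 0.150)
  set_val("Cerebral-Cortex$", 0.160)
  set_val("vessel$", 0.00004)
  set_val("^3rd-Ventricle$", 0.0007)
  set_val("^4th-Ventricle$", 0.0011)
  set_val("^Brain-Stem$", 0.014)
  set_val("^CSF$", 0.0008)
  set_val("^WM-hypointensities$", 0.0010)
  set_val("^non-WM-hypointensities$", 0.0002)
  set_val("^Optic-Chiasm$", 0.00012)
  set_val("^CC_", 0.0006)
  set_val("^WholeBrain$", 0.75)
  set_val("^SupraTentorial$", 0.65)
  set_val("^SubCortGray$", 0.040)
  # mild deterministic spread over cortical parcels so they are not identical
  ctx <- grepl("^(lh|rh)_", names(frac))
  frac[ctx] <- frac[ctx] * (0.5 + 1.5 * (seq_len(sum(ctx)) %% 7) / 7)
  frac
}

#' Default cohort specification
#'
#' The reference four-group cohort structure used throughout the package:
#' group sizes 125 (CN), 114 (EMCI), 91 (LMCI) and 55 (AD) with the ADNI2-
#' style demographic, neuropsychological and TIV distributions, plus a
#' default atrophy specification in which 13 regions known to discriminate
#' disease stage (hippocampi, amygdalae, lateral ventricles, inferior
#' temporal, precuneus, superior parietal, left caudal anterior cingulate)
#' carry monotone group effects; ventricles enlarge with severity, all other
#' informative regions shrink.
#'
#' @return A list with elements `groups` (list of four [group_spec()]) and
#'   `atrophy` (an [atrophy_spec()]).
#' @export
#' @examples
#' specs <- default_cohort_specs()
#' specs$groups$AD$mmse
default_cohort_specs <- function() {
  groups <- list(
    CN = group_spec("CN", 125, age = c(73.4, 5.9), education = c(16.4, 2.5),
                    gender_male = 58, mmse = c(29.06, 1.17),
                    ravlt = c(5.7, 2.4), cdrsb = c(0.0, 0.1),
                    tiv = c(1472.1, 148.3)),
    EMCI = group_spec("EMCI", 114, age = c(70.7, 6.8), education = c(16.4, 2.7),
                      gender_male = 62, mmse = c(28.58, 1.48),
                      ravlt = c(5.7, 2.5), cdrsb = c(1.3, 0.9),
                      tiv = c(1501.7, 148.8)),
    LMCI = group_spec("LMCI", 91, age = c(71.2, 7.8), education = c(16.6, 2.7),
                      gender_male = 48, mmse = c(27.54, 1.82),
                      ravlt = c(3.7, 2.4), cdrsb = c(1.9, 1.0),
                      tiv = c(1522.7, 163.6)),
    AD = group_spec("AD", 55, age = c(75.4, 8.0), education = c(16.0, 2.4),
                    gender_male = 32, mmse = c(22.80, 1.9),
                    ravlt = c(2.0, 1.77), cdrsb = c(4.6, 1.6),
                    tiv = c(1498.8, 169.7))
  )
  mult <- rbind(
    "Left-Hippocampus"           = c(1.00, 0.97, 0.93, 0.86),
    "Right-Hippocampus"          = c(1.00, 0.97, 0.93, 0.86),
    "Left-Amygdala"              = c(1.00, 0.98, 0.95, 0.88),
    "Right-Amygdala"             = c(1.00, 0.98, 0.95, 0.88),
    "Left-Lateral-Ventricle"     = c(1.00, 1.10, 1.22, 1.45),
    "Right-Lateral-Ventricle"    = c(1.00, 1.10, 1.22, 1.45),
    "lh_inferiortemporal"        = c(1.00, 0.98, 0.96, 0.92),
    "rh_inferiortemporal"        = c(1.00, 0.98, 0.96, 0.92),
    "lh_precuneus"               = c(1.00, 0.99, 0.97, 0.93),
    "rh_precuneus"               = c(1.00, 0.99, 0.97, 0.93),
    "lh_superiorparietal"        = c(1.00, 0.99, 0.97, 0.94),
    "rh_superiorparietal"        = c(1.00, 0.99, 0.97, 0.94),
    "lh_caudalanteriorcingulate" = c(1.00, 0.98, 0.96, 0.93)
  )
  colnames(mult) <- diagnostic_levels()
  atrophy <- atrophy_spec(default_region_names(), default_base_fractions(),
                          multipliers = mult)
  list(groups = groups, atrophy = atrophy)
}

# truncated-normal sampling by resampling out-of-range draws
rtrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation bounds incompatible with mean/sd")
  }
  x
}

#' Simulate a four-group cohort
#'
#' Draws a synthetic cohort with the group structure of `groups` and the
#' volumetric structure of `atrophy`. Demographics and scores come from
#' truncated normals (MMSE in \[0, 30\], RAVLT and CDRSb >= 0, education in
#' \[6, 25\], age in \[50, 95\], TIV > 0); gender is assigned to match each
#' group's male count exactly. Each subject carries a latent standard-normal
#' atrophy severity factor z (a vector when the atrophy spec has several
#' latent factors), and every regional volume is
#' `TIV * base_fraction * group_multiplier * exp(loading . z) * (1 + noise)`
#' with `noise ~ N(0, noise_cv)`, so raw volumes scale with head size and
#' regions are correlated through the shared factors. The result is un-normalized;
#' apply [normalize_volumes()] before modelling.
#'
#' @param groups List of [group_spec()] objects.
#' @param atrophy An [atrophy_spec()].
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return A `feature_table` with demographic (age, gender, education),
#'   neuropsychological (MMSE, RAVLT) and volumetric (`vol_*`) features,
#'   TIV, and CDRSb in `metadata`.
#' @export
generate_cohort <- function(groups = default_cohort_specs()$groups,
                            atrophy = default_cohort_specs()$atrophy,
                            seed = 1L) {
  stopifnot(length(groups) > 0L)
  for (g in groups) stopifnot(inherits(g, "group_spec"))
  stopifnot(inherits(atrophy, "atrophy_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  regions <- atrophy$region_names
  rows <- lapply(groups, function(g) {
    n <- g$n
    age <- rtrunc(n, g$age[1], g$age[2], 50, 95)
    edu <- rtrunc(n, g$education[1], g$education[2], 6, 25)
    mmse <- rtrunc(n, g$mmse[1], g$mmse[2], 0, 30)
    ravlt <- rtrunc(n, g$ravlt[1], g$ravlt[2], 0, Inf)
    cdrsb <- rtrunc(n, g$cdrsb[1], g$cdrsb[2], 0, Inf)
    tiv <- rtrunc(n, g$tiv[1], g$tiv[2], 1e-6, Inf)
    gender <- c(rep(0, g$gender_male), rep(1, n - g$gender_male))
    gender <- gender[sample.int(n)]          # deterministic under the seed
    K <- ncol(atrophy$latent_loading)
    z <- matrix(stats::rnorm(n * K), n, K)
    mult <- rep(1, length(regions))
    names(mult) <- regions
    if (nrow(atrophy$multipliers) > 0L) {
      mult[rownames(atrophy$multipliers)] <-
        atrophy$multipliers[, g$label]
    }
    noise <- matrix(stats::rnorm(n * length(regions)), n, length(regions))
    noise <- noise * rep(atrophy$noise_cv, each = n)
    noise[noise < -0.9] <- -0.9              # keep volumes positive
    vols <- tiv *
      (rep(atrophy$base_fraction, each = n) *
         rep(mult, each = n) *
         exp(z %*% t(atrophy$latent_loading)) *
         (1 + noise))
    dim(vols) <- c(n, length(regions))
    list(label = g$label,
         feats = cbind(age = age, gender = gender, education = edu,
                       MMSE = mmse, RAVLT = ravlt, vols),
         tiv = tiv, cdrsb = cdrsb)
  })

  feats <- do.call(rbind, lapply(rows, `[[`, "feats"))
  colnames(feats) <- c("age", "gender", "education", "MMSE", "RAVLT",
                       paste0("vol_", regions))
  diagnosis <- unlist(lapply(rows, function(r) rep(r$label, nrow(r$feats))),
                      use.names = FALSE)
  ids <- unlist(lapply(rows, function(r)
    sprintf("%s_%04d", r$label, seq_len(nrow(r$feats)))), use.names = FALSE)
  categories <- c(
    age = "demographic", gender = "demographic", education = "demographic",
    MMSE = "neuropsychological", RAVLT = "neuropsychological",
    stats::setNames(rep("volumetric", length(regions)),
                    paste0("vol_", regions))
  )
  feature_table(
    subject_id = ids,
    diagnosis = diagnosis,
    features = feats,
    categories = categories,
    tiv = unlist(lapply(rows, `[[`, "tiv"), use.names = FALSE),
    metadata = data.frame(CDRSb = unlist(lapply(rows, `[[`, "cdrsb"),
                                         use.names = FALSE))
  )
}

#' Planted-feature recovery benchmark specification
#'
#' A calibrated cohort specification for benchmarking the feature-selection
#' pipeline: four equally sized groups whose demographics and cognitive
#' scores are identically distributed (hence uninformative), and exactly
#' five volumetric regions carrying group effects of graded magnitude
#' (12-36% volume change from CN to AD; ventricles enlarge, grey-matter
#' regions shrink). The five regions load on four shared latent anatomical
#' factors with low region-specific noise; the remaining 110 regions load
#' only on the global factor. This structure was calibrated (population-
#' level greedy R-squared analysis) so that, for the CN-vs-AD pair, each
#' planted region clears the 0.1 add threshold with a comfortable margin
#' (minimum population gain about 0.19) while no uninformative region
#' does - so a correct implementation of stability selection recovers
#' exactly the planted set.
#'
#' @param n_per_group Subjects per group (default 400).
#' @return A list with `groups`, `atrophy` and `planted` (the five region
#'   feature names, `vol_`-prefixed).
#' @export
planted_recovery_specs <- function(n_per_group = 400L) {
  base <- default_cohort_specs()$groups$CN
  groups <- lapply(diagnostic_levels(), function(lab) {
    group_spec(lab, n_per_group, age = base$age, education = base$education,
               gender_male = floor(n_per_group / 2), mmse = base$mmse,
               ravlt = base$ravlt, cdrsb = c(1, 0.5), tiv = base$tiv)
  })
  names(groups) <- diagnostic_levels()

  planted <- c("Left-Hippocampus", "Right-Lateral-Ventricle",
               "rh_inferiortemporal", "Left-Lateral-Ventricle",
               "3rd-Ventricle")
  d <- c(-0.121, 0.361, -0.120, 0.185, 0.227)   # CN -> AD fractional change
  mult <- cbind(CN = 1, EMCI = 1 + 0.35 * d, LMCI = 1 + 0.7 * d, AD = 1 + d)
  rownames(mult) <- planted

  regions <- default_region_names()
  L <- matrix(0, length(regions), 4, dimnames = list(regions, NULL))
  L[, 1] <- 0.06                                # global atrophy factor
  L[planted, ] <- rbind(
    c(-0.236, -0.050,  0.181,  0.008),
    c(-0.123,  0.220,  0.262, -0.182),
    c( 0.034,  0.178, -0.032, -0.050),
    c(-0.101,  0.039, -0.136, -0.044),
    c( 0.065,  0.125,  0.005,  0.169))
  cv <- stats::setNames(rep(0.08, length(regions)), regions)
  cv[planted] <- c(0.009, 0.035, 0.010, 0.051, 0.037)

  atrophy <- atrophy_spec(regions, default_base_fractions(),
                          multipliers = mult, latent_loading = L,
                          noise_cv = cv)
  list(groups = groups, atrophy = atrophy,
       planted = paste0("vol_", planted))
}

#' All-noise (null) cohort specification
#'
#' The negative control for feature selection: the reference group sizes
#' and gender counts, but identical demographic/score distributions in all
#' four groups and no informative regions, so every one of the 120
#' candidate features is pure noise with respect to diagnosis. Used to
#' verify that stability selection retains nothing when there is nothing
#' to find.
#'
#' @return A list with `groups` and `atrophy`, as [default_cohort_specs()].
#' @export
null_cohort_specs <- function() {
  ref <- default_cohort_specs()$groups
  cn <- ref$CN
  groups <- lapply(ref, function(g) {
    group_spec(g$label, g$n, age = cn$age, education = cn$education,
               gender_male = g$gender_male, mmse = cn$mmse,
               ravlt = cn$ravlt, cdrsb = c(1, 0.5), tiv = cn$tiv)
  })
  atrophy <- atrophy_spec(default_region_names(), default_base_fractions())
  list(groups = groups, atrophy = atrophy)
}

#' Read a cohort simulation specification from YAML
#'
#' The file holds a `groups` block (one entry per label with `n`, `age`,
#' `education`, `gender_male`, `mmse`, `ravlt`, `cdrsb`, `tiv`, each
#' mean/sd pair a 2-element list) and an optional `atrophy` block
#' (`informative` entries with per-group `multipliers`, plus optional
#' `latent_loading` and `noise_cv` scalars). Omitted parts fall back to
#' [default_cohort_specs()].
#'
#' @param path YAML file path.
#' @return A list with `groups` and `atrophy`, as [default_cohort_specs()].
#' @export
read_cohort_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  out <- default_cohort_specs()
  if (!is.null(spec$groups)) {
    out$groups <- lapply(names(spec$groups), function(lab) {
      g <- spec$groups[[lab]]
      # YAML 1.1 parsers read a bare key `n` as boolean FALSE; accept both
      if (is.null(g$n) && "FALSE" %in% names(g)) g$n <- g[["FALSE"]]
      group_spec(lab, g$n, age = as.numeric(g$age),
                 education = as.numeric(g$education),
                 gender_male = g$gender_male, mmse = as.numeric(g$mmse),
                 ravlt = as.numeric(g$ravlt), cdrsb = as.numeric(g$cdrsb),
                 tiv = as.numeric(g$tiv))
    })
    names(out$groups) <- names(spec$groups)
  }
  if (!is.null(spec$atrophy)) {
    a <- spec$atrophy
    mult <- NULL
    if (!is.null(a$informative)) {
      mult <- do.call(rbind, lapply(a$informative, as.numeric))
      rownames(mult) <- names(a$informative)
      colnames(mult) <- diagnostic_levels()
    }
    out$atrophy <- atrophy_spec(
      default_region_names(), default_base_fractions(), multipliers = mult,
      latent_loading = if (is.null(a$latent_loading)) 0.06 else a$latent_loading,
      noise_cv = if (is.null(a$noise_cv)) 0.08 else a$noise_cv)
  }
  out
}
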