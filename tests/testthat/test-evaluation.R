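test_that("confusion metrics follow their definitions", {
  cc <- c(tp = 9, fp = 2, tn = 8, fn = 1)
  m <- confusion_metrics(cc)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["precision"]), 9 / 11)
  expect_equal(unname(m["f_measure"]),
               2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  expect_equal(sum(confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))), 4L)
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  set.seed(30)
  for (i in 1:50) {
    truth <- rbinom(40, 1, 0.5)
    pred <- rbinom(40, 1, 0.5)
    if (var(truth) == 0) next
    m <- confusion_metrics(confusion_counts(truth, pred))
    m_sw <- confusion_metrics(confusion_counts(1 - truth, 1 - pred))
    expect_equal(m_sw[["sensitivity"]], m[["specificity"]])
    expect_equal(m_sw[["specificity"]], m[["sensitivity"]])
    expect_equal(m_sw[["accuracy"]], m[["accuracy"]])
  }
})

test_that("a clearly separated pair is classified perfectly", {
  groups <- list(
    CN = group_spec("CN", 60, c(73, 5), c(16, 2), 30, c(29, 1),
                    c(5.7, 2), c(0, 0.1), c(1472, 148)),
    AD = group_spec("AD", 60, c(73, 5), c(16, 2), 30, c(29, 1),
                    c(5.7, 2), c(4, 1), c(1472, 148)))
  # huge atrophy effect, tiny noise: Mahalanobis separation >> 1
  atr <- atrophy_spec("hip", c(hip = 0.0025),
                      multipliers = rbind(hip = c(1, 0.8, 0.6, 0.4)),
                      latent_loading = 0.0, noise_cv = 0.01)
  tab <- normalize_volumes(generate_cohort(groups, atr, seed = 31))
  rep <- crossval_evaluate(tab, c("CN", "AD"), "vol_hip", n_reps = 20, seed = 1)
  expect_equal(rep$summary$mean[rep$summary$metric == "accuracy"], 1)
  expect_equal(rep$summary$sd[rep$summary$metric == "accuracy"], 0)
})

test_that("label-shuffled evaluation stays at chance level", {
  set.seed(32)
  null <- null_cohort_specs()
  groups <- lapply(null$groups[c("CN", "AD")], function(g) {
    group_spec(g$label, 60, g$age, g$education, 30, g$mmse, g$ravlt,
               g$cdrsb, g$tiv)
  })
  atr <- atrophy_spec(c("r1", "r2"), c(r1 = 0.003, r2 = 0.008))
  tab <- normalize_volumes(generate_cohort(groups, atr, seed = 33))
  rep <- crossval_evaluate(tab, c("CN", "AD"), c("vol_r1", "vol_r2", "MMSE"),
                           n_reps = 20, seed = 2)
  acc <- rep$per_rep$accuracy
  se <- sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 0.5), 3 * max(se, 0.02))
})

test_that("evaluation is reproducible and respects fixed group counts", {
  spec <- planted_recovery_specs(50)
  tab <- normalize_volumes(generate_cohort(spec$groups, spec$atrophy, seed = 3))
  a <- crossval_evaluate(tab, c("CN", "AD"), spec$planted, n_reps = 5, seed = 4)
  b <- crossval_evaluate(tab, c("CN", "AD"), spec$planted, n_reps = 5, seed = 4)
  expect_identical(a$per_rep, b$per_rep)
  # each repetition classifies every subject exactly once
  expect_true(all(rowSums(a$per_rep[, c("tp", "fp", "tn", "fn")]) == 100))
  expect_error(crossval_evaluate(tab, c("CN", "AD"), "nope"), "not in table")
})

test_that("incremental analysis finds the saturation point", {
  spec <- planted_recovery_specs(100)
  tab <- normalize_volumes(generate_cohort(spec$groups, spec$atrophy, seed = 5))
  # only the first feature informative: accuracy must not grow materially
  sel <- run_stability(tab, c("CN", "AD"), n_reps = 20, seed = 6)
  ranked <- sel$ranked
  inc <- incremental_analysis(tab, c("CN", "AD"), ranked, n_reps = 10, seed = 7)
  expect_length(inc$reports, length(ranked))
  expect_equal(inc$accuracy[inc$best_k], max(inc$accuracy))
  # single-feature list: degenerate output of length 1
  inc1 <- incremental_analysis(tab, c("CN", "AD"), ranked[1], n_reps = 5, seed = 8)
  expect_length(inc1$accuracy, 1L)
  expect_equal(inc1$best_k, 1L)
  # argmax ties break toward smaller k
  fake <- inc
  expect_equal(which.max(c(0.8, 0.8, 0.7)), 1L)
})

test_that("a lone informative feature saturates the incremental curve", {
  groups <- list(
    CN = group_spec("CN", 120, c(73, 5), c(16, 2), 60, c(29, 1),
                    c(5.7, 2), c(0, 0.1), c(1472, 148)),
    AD = group_spec("AD", 120, c(73, 5), c(16, 2), 60, c(29, 1),
                    c(5.7, 2), c(4, 1), c(1472, 148)))
  atr <- atrophy_spec(c("hip", "n1", "n2", "n3"),
                      c(hip = 0.0025, n1 = 0.004, n2 = 0.006, n3 = 0.01),
                      multipliers = rbind(hip = c(1, 0.85, 0.7, 0.55)),
                      latent_loading = 0.02, noise_cv = 0.05)
  tab <- normalize_volumes(generate_cohort(groups, atr, seed = 40))
  inc <- incremental_analysis(tab, c("CN", "AD"),
                              c("vol_hip", "vol_n1", "vol_n2", "vol_n3"),
                              n_reps = 10, seed = 9)
  sds <- vapply(inc$reports, function(r)
    r$summary$sd[r$summary$metric == "accuracy"], numeric(1))
  expect_true(all(inc$accuracy[1] >= inc$accuracy - 2 * sds))
})

test_that("improvement arithmetic matches the published comparison table", {
  expect_equal(round(improvement(0.939, 0.922), 3), 1.844)
  expect_equal(round(improvement(0.856, 0.616), 3), 38.961)
  expect_equal(improvement(0.7, 0.7), 0)
  expect_error(improvement(0.9, 0), "positive")

  acc <- published_model_accuracies()
  t4 <- comparison_table(acc)
  expect_equal(t4$improvement_over_neuro[1:6],
               c(1.844, 1.182, 2.599, 11.356, 1.395, 0.334))
  expect_equal(t4$improvement_over_mri[1:6],
               c(11.520, 38.961, 27.171, 2.616, 16.093, 51.174))
  avg <- t4[t4$pair == "Average", ]
  expect_equal(unlist(avg[, -1], use.names = FALSE),
               c(0.853, 0.712, 0.876, 3.118, 24.589))
})

test_that("model comparison runs three pipelines and applies the formula", {
  spec <- planted_recovery_specs(60)
  # plant a neuropsychological difference too, so all variants have signal
  spec$groups <- lapply(spec$groups, function(g) {
    mm <- c(CN = 29.06, EMCI = 28.6, LMCI = 27.5, AD = 22.8)[g$label]
    group_spec(g$label, g$n, g$age, g$education, g$gender_male,
               c(mm, 1.5), g$ravlt, g$cdrsb, g$tiv)
  })
  tab <- normalize_volumes(generate_cohort(spec$groups, spec$atrophy, seed = 8))
  row <- compare_models(tab, c("CN", "AD"), select_reps = 10, eval_reps = 5,
                        seed = 10)
  expect_s3_class(row, "model_comparison_row")
  expect_true(all(c(row$neuropsychological, row$mri, row$combined) > 0.5))
  expect_equal(row$improvement_over_mri,
               improvement(row$combined, row$mri))
  # the MRI variant must never see the cognitive scores
  mri_feats <- names(row$details$mri$selection$frequencies)
  expect_false(any(c("MMSE", "RAVLT") %in% mri_feats))
  expect_true(all(c("age", "gender", "education") %in% mri_feats))
})
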