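test_that("default specs encode the reference cohort structure", {
  specs <- default_cohort_specs()
  g <- specs$groups
  expect_equal(vapply(g, `[[`, integer(1), "n"),
               c(CN = 125L, EMCI = 114L, LMCI = 91L, AD = 55L))
  expect_equal(sum(vapply(g, `[[`, integer(1), "n")), 385L)
  expect_equal(g$AD$mmse, c(22.80, 1.9))
  expect_equal(g$CN$age, c(73.4, 5.9))
  expect_equal(g$LMCI$ravlt, c(3.7, 2.4))
  expect_equal(g$EMCI$tiv, c(1501.7, 148.8))
  expect_equal(vapply(g, `[[`, integer(1), "gender_male"),
               c(CN = 58L, EMCI = 62L, LMCI = 48L, AD = 32L))
  expect_equal(length(specs$atrophy$region_names), 115L)
  expect_gte(length(specs$atrophy$informative_regions), 10L)
  # ventricles enlarge with severity, grey matter shrinks, all monotone
  m <- specs$atrophy$multipliers
  vent <- grepl("Ventricle", rownames(m))
  expect_true(all(apply(m[vent, , drop = FALSE], 1, diff) >= 0))
  expect_true(all(apply(m[!vent, , drop = FALSE], 1, diff) <= 0))
})

test_that("atrophy_spec rejects non-monotone multipliers", {
  bf <- setNames(c(0.01, 0.02), c("r1", "r2"))
  bad <- rbind(r1 = c(1, 0.9, 0.95, 0.8))
  expect_error(atrophy_spec(c("r1", "r2"), bf, multipliers = bad),
               "monotone")
  ok <- atrophy_spec(c("r1", "r2"), bf,
                     multipliers = rbind(r1 = c(1, 0.95, 0.9, 0.8)))
  expect_equal(ok$informative_regions, "r1")
})

test_that("generation is reproducible and honors group structure exactly", {
  a <- generate_cohort(seed = 99)
  b <- generate_cohort(seed = 99)
  expect_identical(a$features, b$features)
  expect_identical(a$tiv, b$tiv)
  c2 <- generate_cohort(seed = 100)
  expect_false(identical(a$features, c2$features))

  expect_equal(ncol(a$features), 120L)
  expect_equal(sum(a$categories == "volumetric"), 115L)
  expect_equal(sum(a$categories == "demographic"), 3L)
  # gender counts match the spec deterministically
  male <- tapply(a$features[, "gender"] == 0, a$diagnosis, sum)
  expect_equal(as.vector(male), c(58, 62, 48, 32))
  # truncation bounds hold
  expect_true(all(a$features[, "MMSE"] <= 30 & a$features[, "MMSE"] >= 0))
  expect_true(all(a$features[, "RAVLT"] >= 0))
  expect_true(all(a$features[, "age"] >= 50 & a$features[, "age"] <= 95))
  expect_true(all(a$features[, a$categories == "volumetric"] > 0))
})

test_that("sample moments converge to specification values", {
  specs <- default_cohort_specs()
  big <- lapply(specs$groups, function(g) {
    group_spec(g$label, 4000, age = g$age, education = g$education,
               gender_male = 2000, mmse = g$mmse, ravlt = g$ravlt,
               cdrsb = g$cdrsb, tiv = g$tiv)
  })
  # a small region set keeps this fast; moments concern the scores
  atr <- atrophy_spec(c("r1", "r2"),
                      setNames(c(0.0025, 0.008), c("r1", "r2")))
  tab <- generate_cohort(big, atr, seed = 5)
  ad <- tab$diagnosis == "AD"
  # truncation at MMSE <= 30 barely bites for AD (mean 22.8): ~3 sigma
  expect_equal(mean(tab$features[ad, "MMSE"]), 22.80, tolerance = 0.01)
  expect_equal(sd(tab$features[ad, "MMSE"]), 1.9, tolerance = 0.05)
  expect_equal(mean(tab$features[ad, "age"]), 75.4, tolerance = 0.01)
  expect_equal(mean(tab$tiv[ad]), 1498.8, tolerance = 0.01)
})

test_that("planted group effects reproduce their multiplier ratios", {
  # two groups, one region with AD multiplier 0.8: the AD/CN ratio of
  # mean normalized volume must approach 0.8 (law of large numbers)
  groups <- list(
    CN = group_spec("CN", 10000, c(73, 6), c(16, 2.5), 5000,
                    c(29, 1.2), c(5.7, 2.4), c(0, 0.1), c(1472, 148)),
    AD = group_spec("AD", 10000, c(73, 6), c(16, 2.5), 5000,
                    c(29, 1.2), c(5.7, 2.4), c(0, 0.1), c(1472, 148)))
  atr <- atrophy_spec(c("hip", "ctrl"),
                      setNames(c(0.0025, 0.004), c("hip", "ctrl")),
                      multipliers = rbind(hip = c(1, 0.93, 0.87, 0.8)))
  tab <- normalize_volumes(generate_cohort(groups, atr, seed = 21))
  cn <- tab$diagnosis == "CN"; ad <- tab$diagnosis == "AD"
  ratio <- mean(tab$features[ad, "vol_hip"]) / mean(tab$features[cn, "vol_hip"])
  expect_equal(ratio, 0.8, tolerance = 0.02)
  ratio_ctrl <- mean(tab$features[ad, "vol_ctrl"]) / mean(tab$features[cn, "vol_ctrl"])
  expect_equal(ratio_ctrl, 1.0, tolerance = 0.02)
})

test_that("non-informative regions carry no group signal", {
  # Monte-Carlo calibration: at the reference CN/AD sizes a pure-noise
  # region shows no significant difference at alpha = 0.01 in >= 95% of seeds
  null <- null_cohort_specs()
  small <- null$groups[c("CN", "AD")]
  atr <- atrophy_spec(c("r1",
                        "r2"), setNames(c(0.004, 0.01), c("r1", "r2")))
  hits <- 0L
  for (s in 1:100) {
    tab <- normalize_volumes(generate_cohort(small, atr, seed = 300 + s))
    p <- t.test(tab$features[tab$diagnosis == "CN", "vol_r1"],
                tab$features[tab$diagnosis == "AD", "vol_r1"])$p.value
    if (p >= 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("normalization removes the TIV correlation raw volumes carry", {
  groups <- list(CN = group_spec("CN", 2000, c(73, 6), c(16, 2.5), 1000,
                                 c(29, 1.2), c(5.7, 2.4), c(0, 0.1),
                                 c(1472, 148)))
  atr <- atrophy_spec("r1", c(r1 = 0.0025))
  raw <- generate_cohort(groups, atr, seed = 8)
  expect_gt(cor(raw$features[, "vol_r1"], raw$tiv), 0.5)
  norm <- normalize_volumes(raw)
  expect_lt(abs(cor(norm$features[, "vol_r1"], norm$tiv)), 0.05)
})

test_that("informative group means are monotone along severity", {
  tab <- normalize_volumes(generate_cohort(seed = 13))
  atrophy <- default_cohort_specs()$atrophy
  for (reg in c("Left-Hippocampus", "Right-Lateral-Ventricle")) {
    mult <- atrophy$multipliers[reg, ]
    mns <- tapply(tab$features[, paste0("vol_", reg)], tab$diagnosis, mean)
    if (mult["AD"] < 1) expect_true(all(diff(mns) < 0)) else
      expect_true(all(diff(mns) > 0))
  }
})

test_that("cohort spec YAML round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "groups:",
    "  CN: {'n': 20, age: [70, 5], education: [16, 2], gender_male: 10,",
    "       mmse: [29, 1], ravlt: [6, 2], cdrsb: [0, 0.1], tiv: [1470, 150]}",
    "  AD: {n: 10, age: [75, 6], education: [15, 2], gender_male: 5,",
    "       mmse: [23, 2], ravlt: [2, 1.5], cdrsb: [4, 1.5], tiv: [1500, 150]}",
    "atrophy:",
    "  informative:",
    "    Left-Hippocampus: [1.0, 0.95, 0.9, 0.82]",
    "  noise_cv: 0.05"), path)
  spec <- read_cohort_spec(path)
  expect_equal(spec$groups$CN$n, 20L)
  expect_equal(spec$groups$AD$mmse, c(23, 2))
  expect_equal(spec$atrophy$multipliers["Left-Hippocampus", "AD"], 0.82,
               ignore_attr = TRUE)
  tab <- generate_cohort(spec$groups, spec$atrophy, seed = 2)
  expect_equal(nrow(tab$features), 30L)
})
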