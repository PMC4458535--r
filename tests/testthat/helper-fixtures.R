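# Shared fixtures and independent oracles for the test suite.

# minimal in-memory cohort: n subjects, two labels, a few features
tiny_table <- function(n_per = 4, labels = c("CN", "AD"), seed = 1) {
  set.seed(seed)
  n <- n_per * length(labels)
  feats <- cbind(age = rnorm(n, 72, 5),
                 MMSE = rnorm(n, 27, 2),
                 vol_Left = abs(rnorm(n, 150, 10)),
                 vol_Right = abs(rnorm(n, 140, 10)))
  feature_table(
    subject_id = sprintf("S%03d", seq_len(n)),
    diagnosis = rep(labels, each = n_per),
    features = feats,
    categories = c(age = "demographic", MMSE = "neuropsychological",
                   vol_Left = "volumetric", vol_Right = "volumetric"),
    tiv = rnorm(n, 1500, 100)
  )
}

# write a small cohort CSV in the default dialect
write_tiny_csv <- function(path, with_missing = FALSE) {
  df <- data.frame(
    subject_id = c("A1", "A2", "B1", "B2"),
    diagnosis = c("CN", "CN", "AD", "AD"),
    TIV_mL = c(1500, 1450, 1520, 1480),
    age = c(70, 72, 75, 78),
    gender = c(0, 1, 0, 1),
    education = c(16, 14, 12, 18),
    MMSE = c(29, 30, 22, 23),
    RAVLT = c(6, 5, 2, 1),
    CDRSb = c(0, 0, 4, 5),
    `vol_Left-Hippocampus` = c(3.8, 3.6, 2.9, 3.0),
    `vol_rh_inferiortemporal` = c(11.2, 10.8, 9.5, 9.8),
    check.names = FALSE)
  if (with_missing) df$MMSE[2] <- NA
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Independent OLS oracle: explicit normal equations, no QR.
ols_oracle <- function(X, y) {
  A <- cbind(1, X)
  XtX <- crossprod(A)
  b <- solve(XtX, crossprod(A, y))
  res <- y - A %*% b
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- nrow(A) - ncol(A)
  se <- sqrt(rss / df * diag(solve(XtX)))
  tv <- drop(b) / se
  list(coef = drop(b), r2 = 1 - rss / tss,
       p = 2 * pt(-abs(tv), df))
}

# R^2 via normal equations for a feature subset (empty subset -> 0)
oracle_r2 <- function(X, y, idx) {
  if (length(idx) == 0L) return(0)
  A <- cbind(1, X[, idx, drop = FALSE])
  b <- solve(crossprod(A), crossprod(A, y))
  1 - sum((y - A %*% b)^2) / sum((y - mean(y))^2)
}

# Exhaustive-search stepwise oracle: tabulates R^2 for every feature subset
# by normal equations, then replays the add/remove increment rules on that
# table (initial single best feature unconditional; add the max-gain feature
# if gain > add_thr; remove the min-cost feature if cost < rem_thr;
# lexicographic tie-breaks). Entirely independent of the package's
# projection-based scan.
stepwise_oracle <- function(X, y, add_thr = 0.1, rem_thr = 0.05) {
  m <- ncol(X)
  nm <- colnames(X)
  r2tab <- new.env()
  key <- function(idx) paste(sort(idx), collapse = ",")
  r2 <- function(idx) {
    k <- key(idx)
    if (is.null(r2tab[[k]])) r2tab[[k]] <- oracle_r2(X, y, idx)
    r2tab[[k]]
  }
  lex_best <- function(cand, val) {
    top <- max(val)
    tied <- cand[val >= top - 1e-12]
    tied[order(nm[tied])][1L]
  }
  # initial single best feature
  marg <- vapply(1:m, function(j) r2(j), numeric(1))
  sel <- lex_best(1:m, marg)
  for (iter in 1:(4 * m)) {
    fired <- FALSE
    ex <- setdiff(1:m, sel)
    if (length(ex) > 0L && nrow(X) > length(sel) + 2L) {
      gains <- vapply(ex, function(j) r2(c(sel, j)) - r2(sel), numeric(1))
      b <- lex_best(ex, gains)
      if ((r2(c(sel, b)) - r2(sel)) > add_thr) {
        sel <- c(sel, b); fired <- TRUE
      }
    }
    if (length(sel) > 1L) {
      costs <- vapply(sel, function(j) r2(sel) - r2(setdiff(sel, j)), numeric(1))
      w <- lex_best(sel, -costs)
      if ((r2(sel) - r2(setdiff(sel, w))) < rem_thr) {
        sel <- setdiff(sel, w); fired <- TRUE
      }
    }
    if (!fired) break
  }
  nm[sel]
}

# random two-class Gaussian instance with common covariance
gaussian_pair <- function(n0, n1, mu0, mu1, Sigma) {
  L <- chol(Sigma)
  p <- length(mu0)
  X0 <- matrix(rnorm(n0 * p), n0, p) %*% L + rep(mu0, each = n0)
  X1 <- matrix(rnorm(n1 * p), n1, p) %*% L + rep(mu1, each = n1)
  X <- rbind(X0, X1)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = c(rep(0L, n0), rep(1L, n1)))
}
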