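#' Ordinary least squares on a fixed feature set
#'
#' Fits `y = C0 + C1*F1 + ... + Ck*Fk` by least squares (QR decomposition)
#' and reports the model R-squared and a two-sided p-value per coefficient
#' from `t = C_j / SE(C_j)` with `n - k - 1` degrees of freedom. The
#' response in this package is the 0/1 group indicator of a diagnostic
#' pair; the model is deliberately linear on that indicator (no logistic
#' link), matching the feature-extraction regression it supports.
#'
#' @param X Numeric matrix (subjects x k) with column names.
#' @param y Numeric response vector (0/1 in pipeline use).
#' @return An object of class `stepwise_model`: fields `selected`,
#'   `intercept`, `coefficients` (named, per feature), `r_squared`,
#'   `pvalues` (named, per feature), `n`, `trace` (empty for a fixed fit),
#'   `converged = TRUE`.
#' @export
#' @examples
#' X <- cbind(f = c(0, 1, 2))
#' fit_ols(X, c(0, 1, 2))$r_squared  # exact line: R^2 = 1
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= k + 1) stop(sprintf("n = %d too small for %d feature(s) plus intercept", n, k))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response is constant")
  A <- cbind(`(Intercept)` = 1, X)
  qa <- qr(A)
  if (qa$rank < ncol(A)) stop("rank-deficient design (exactly collinear columns)")
  coefs <- qr.coef(qa, y)
  res <- qr.resid(qa, y)
  rss <- sum(res^2)
  df <- n - k - 1
  sigma2 <- rss / df
  R <- qr.R(qa)
  Rinv <- backsolve(R, diag(ncol(A)))
  vfac <- numeric(ncol(A))
  piv <- if (!is.null(qa$pivot)) qa$pivot else seq_len(ncol(A))
  vfac[piv] <- rowSums(Rinv^2)
  se <- sqrt(sigma2 * vfac)
  tval <- coefs / se
  pv <- 2 * stats::pt(-abs(tval), df)
  structure(list(
    selected = colnames(X),
    intercept = unname(coefs[1L]),
    coefficients = coefs[-1L],
    r_squared = 1 - rss / tss,
    pvalues = pv[-1L],
    n = n,
    trace = empty_trace(),
    converged = TRUE
  ), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> %d feature(s), R^2 = %.4f, n = %d%s\n",
              length(x$selected), x$r_squared, x$n,
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  if (length(x$selected) > 0L) {
    print(data.frame(feature = x$selected,
                     coefficient = unname(x$coefficients),
                     p_value = unname(x$pvalues), row.names = NULL))
  }
  invisible(x)
}

empty_trace <- function() {
  data.frame(action = character(), feature = character(),
             delta_r2 = numeric(), r_squared = numeric(),
             stringsAsFactors = FALSE)
}

# R^2 of y on X[, idx] (with intercept); 0 for the empty model
r2_subset <- function(X, y, idx, tss) {
  if (length(idx) == 0L) return(0)
  fit <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / tss
}

# Vectorized Delta-R^2 of adding each candidate column to the current model.
# Q is an orthonormal basis of the current design (intercept + selected);
# projecting out Q from candidate columns and the response reduces each
# candidate's gain to a squared correlation of residuals.
add_gains <- function(X, y, Q, cand, tss) {
  C <- X[, cand, drop = FALSE]
  Cp <- C - Q %*% crossprod(Q, C)
  r <- y - Q %*% crossprod(Q, y)
  num <- as.numeric(crossprod(Cp, r))^2
  den <- colSums(Cp^2)
  gain <- ifelse(den > 1e-10 * colSums(C^2) + 1e-300, num / (den * tss), 0)
  names(gain) <- cand
  gain
}

# among tied maxima (within tol), pick the lexicographically first name
pick_best <- function(gain, tol = 1e-12) {
  top <- max(gain)
  tied <- names(gain)[gain >= top - tol]
  sort(tied)[1L]
}

#' Stepwise feature selection by R-squared increments
#'
#' Grows and prunes a linear model on the 0/1 group response using fixed
#' R-squared increment rules: starting from the single best feature
#' (admitted unconditionally), each iteration (a) adds the excluded feature
#' with the largest R-squared gain if that gain exceeds `add_threshold`
#' (default 0.1), then (b) removes the included feature whose removal costs
#' the least R-squared if that cost is below `remove_threshold` (default
#' 0.05), until neither rule fires. Requiring `add_threshold >
#' remove_threshold` makes an add/remove cycle of the same feature
#' impossible. Ties in gain or cost are broken lexicographically by feature
#' name, so results are seed-independent. A `direction = "backward"` variant
#' starts from the full model and only prunes.
#'
#' @param X Numeric matrix (subjects x m), named columns.
#' @param y Numeric 0/1 response.
#' @param add_threshold Minimum R-squared gain to add a feature.
#' @param remove_threshold Maximum R-squared cost to remove a feature.
#' @param max_iter Iteration cap; default `2 * ncol(X)`.
#' @param direction `"bidirectional"` (default; forward growth with backward
#'   pruning) or `"backward"` (prune-only from the full model).
#' @return A `stepwise_model` whose `trace` records every add/remove with
#'   its Delta R-squared; `converged` is `FALSE` if `max_iter` was hit.
#' @export
stepwise_select <- function(X, y, add_threshold = 0.1, remove_threshold = 0.05,
                            max_iter = 2L * ncol(X),
                            direction = c("bidirectional", "backward")) {
  direction <- match.arg(direction)
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("X has no candidate features")
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  stopifnot(add_threshold > 0, add_threshold < 1,
            remove_threshold > 0, remove_threshold < 1)
  if (add_threshold <= remove_threshold) {
    stop("add_threshold must exceed remove_threshold (prevents add/remove cycling)")
  }
  n <- nrow(X)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response is constant")
  nm <- colnames(X)
  trace <- empty_trace()
  push <- function(action, feature, delta, r2) {
    trace[nrow(trace) + 1L, ] <<- list(action, feature, delta, r2)
  }

  if (direction == "backward") {
    if (n <= ncol(X) + 1L) {
      stop("backward start requires n > m + 1 for the full model")
    }
    sel <- nm
  } else {
    # initial model: single best feature by R^2, admitted unconditionally
    Q0 <- matrix(1 / sqrt(n), n, 1)
    gain <- add_gains(X, y, Q0, nm, tss)
    first <- pick_best(gain)
    sel <- first
    push("add", first, unname(gain[first]), unname(gain[first]))
  }
  cur_r2 <- r2_subset(X, y, sel, tss)

  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    if (it > max_iter) break
    fired <- FALSE
    if (direction == "bidirectional") {
      excl <- setdiff(nm, sel)
      if (length(excl) > 0L && n > length(sel) + 2L) {
        Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
        gain <- add_gains(X, y, Q, excl, tss)
        best <- pick_best(gain)
        if (gain[best] > add_threshold) {
          sel <- c(sel, best)
          cur_r2 <- cur_r2 + unname(gain[best])
          push("add", best, unname(gain[best]), cur_r2)
          fired <- TRUE
        }
      }
    }
    if (length(sel) > 1L) {
      cost <- vapply(sel, function(f) {
        cur_r2 - r2_subset(X, y, setdiff(sel, f), tss)
      }, numeric(1))
      worst <- pick_best(-cost)     # least costly removal, lexicographic ties
      if (cost[worst] < remove_threshold) {
        sel <- setdiff(sel, worst)
        cur_r2 <- cur_r2 - unname(cost[worst])
        push("remove", worst, unname(cost[worst]), cur_r2)
        fired <- TRUE
      }
    }
    if (!fired) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("stepwise_select: max_iter reached before convergence; partial model returned")
  }
  fit <- fit_ols(X[, sel, drop = FALSE], y)
  fit$trace <- trace
  fit$converged <- converged
  fit
}
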