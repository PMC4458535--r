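#' Fit a two-class linear discriminant classifier
#'
#' Gaussian equal-covariance (pooled) plug-in discriminant: with class means
#' `mu_k` and pooled within-class covariance `Sigma` (denominator `n - 2`),
#' each class gets a linear discriminant function
#' `d_k(F) = constant_k + weights_k . F` with `weights_k = Sigma^-1 mu_k`
#' and `constant_k = -0.5 * mu_k' Sigma^-1 mu_k`. Class 1 is the less
#' severe group (response 0), class 2 the more severe (response 1); their
#' parameter vectors are stored as `alpha` and `beta`. The default prior is
#' 0.5 per class, reflecting a clinical setting where the stage mix is
#' unknown; empirical priors are an explicit opt-in.
#'
#' If the pooled covariance is numerically singular (possible when the
#' feature count approaches the fold size) a ridge `lambda * I` with
#' `lambda = 1e-6 * trace(Sigma)/m` is added, with a message.
#'
#' @param X Numeric matrix (subjects x m'), named columns.
#' @param y 0/1 response; 1 = more severe class.
#' @param prior Length-2 priors `c(class1, class2)`, summing to 1.
#' @param class_labels Optional length-2 labels (less severe, more severe).
#' @return An object of class `lda_model` with fields `feature_names`,
#'   `alpha`, `beta` (each `c(constant, weights)`), `prior`, `class_labels`,
#'   plus the fitted `means` and pooled `cov`.
#' @export
fit_lda <- function(X, y, prior = c(0.5, 0.5), class_labels = c("0", "1")) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)),
            length(prior) == 2L, all(prior > 0),
            abs(sum(prior) - 1) < 1e-8, length(class_labels) == 2L)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  if (n0 < 2L || n1 < 2L) stop("need at least 2 subjects per class to pool covariance")
  m <- ncol(X)
  X0 <- X[y == 0L, , drop = FALSE]; X1 <- X[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) /
    (n0 + n1 - 2)
  zv <- diag(S) == 0
  if (any(zv)) {
    stop("zero-variance feature(s): ", paste(colnames(X)[zv], collapse = ", "))
  }
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    lambda <- 1e-6 * sum(diag(S)) / m
    message(sprintf("fit_lda: singular pooled covariance; ridge lambda = %.3g applied", lambda))
    Sinv <- tryCatch(chol2inv(chol(S + diag(lambda, m))), error = function(e) NULL)
    if (is.null(Sinv)) stop("pooled covariance irrecoverably singular")
  }
  w0 <- drop(Sinv %*% mu0); w1 <- drop(Sinv %*% mu1)
  alpha <- c(constant = -0.5 * sum(mu0 * w0), w0)
  beta <- c(constant = -0.5 * sum(mu1 * w1), w1)
  structure(list(
    feature_names = colnames(X),
    alpha = alpha, beta = beta,
    prior = prior, class_labels = as.character(class_labels),
    means = rbind(class1 = mu0, class2 = mu1), cov = S
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %s vs %s, %d feature(s), priors %.3g/%.3g\n",
              x$class_labels[1], x$class_labels[2], length(x$feature_names),
              x$prior[1], x$prior[2]))
  invisible(x)
}

#' Score subjects and assign classes
#'
#' Computes, per subject, the two linear scores `L_k = d_k(F) +
#' log(prior_k)` and the softmax posteriors
#' `p_k = exp(L_k) / (exp(L_1) + exp(L_2))` (evaluated stably by
#' subtracting the larger score before exponentiation). The larger
#' posterior assigns the class; an exact tie is resolved to the less severe
#' class (conservative staging; ties have measure zero on continuous data).
#'
#' @param model An `lda_model`.
#' @param X Numeric matrix whose columns match `model$feature_names` in
#'   order (matched by name when names are present).
#' @return An object of class `lda_classification`: `linear_scores` (n x 2),
#'   `posteriors` (n x 2, rows summing to 1), `assigned` (factor with the
#'   model's class labels).
#' @export
score_and_classify <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    if (!all(model$feature_names %in% colnames(X))) {
      stop("X lacks model feature(s): ",
           paste(setdiff(model$feature_names, colnames(X)), collapse = ", "))
    }
    X <- X[, model$feature_names, drop = FALSE]
  } else if (ncol(X) != length(model$feature_names)) {
    stop("X has ", ncol(X), " columns; model expects ", length(model$feature_names))
  }
  if (!all(is.finite(X))) stop("non-finite feature value in X")
  L1 <- model$alpha[1L] + drop(X %*% model$alpha[-1L]) + log(model$prior[1L])
  L2 <- model$beta[1L] + drop(X %*% model$beta[-1L]) + log(model$prior[2L])
  M <- pmax(L1, L2)
  e1 <- exp(L1 - M); e2 <- exp(L2 - M)
  p1 <- e1 / (e1 + e2); p2 <- e2 / (e1 + e2)
  assigned <- ifelse(p2 > p1, model$class_labels[2L], model$class_labels[1L])
  structure(list(
    linear_scores = cbind(L1 = L1, L2 = L2),
    posteriors = cbind(p1 = p1, p2 = p2),
    assigned = factor(assigned, levels = model$class_labels)
  ), class = "lda_classification")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  score_and_classify(object, newdata)
}

#' Serialize an LDA model to JSON
#'
#' @param model An `lda_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  jsonlite::write_json(list(
    feature_names = model$feature_names,
    alpha = unname(model$alpha), beta = unname(model$beta),
    prior = model$prior, class_labels = model$class_labels
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
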