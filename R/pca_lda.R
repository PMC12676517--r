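#' Fit a PCA projection on training spectra
#'
#' Principal component analysis on mean-centered spectra (no scaling; the
#' spectra are already on a common absorbance scale after EMSC). The number
#' of retained components is the smallest `k` whose cumulative explained
#' variance ratio reaches `variance_target`, capped at the rank of the
#' centered data.
#'
#' @param data A `spectrum_set` or numeric matrix (spectra in rows).
#' @param variance_target Cumulative explained-variance threshold in
#'   (0, 1\] (default 0.99).
#' @return An object of class `pca_projection` with `mean`, `components`
#'   (`k x n_wavenumbers`, orthonormal rows) and `explained_variance_ratio`.
#' @export
fit_pca <- function(data, variance_target = 0.99) {
  X <- if (inherits(data, "spectrum_set")) data$intensities else as.matrix(data)
  if (nrow(X) < 2L) stop("PCA needs at least 2 spectra")
  if (!(variance_target > 0 && variance_target <= 1))
    stop("variance_target must lie in (0, 1]")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  tot <- sum(var_all)
  if (tot <= .Machine$double.eps)
    stop("degenerate training set: all spectra identical")
  ratio <- var_all / tot
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  k <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- rank
  k <- min(k, rank, nrow(X) - 1L)
  structure(
    list(mean = pc$center,
         components = t(pc$rotation[, seq_len(k), drop = FALSE]),
         explained_variance_ratio = ratio[seq_len(k)],
         k = k),
    class = "pca_projection")
}

#' Project spectra onto a fitted PCA basis
#' @param pca A `pca_projection`.
#' @param data A `spectrum_set` or matrix on the same grid.
#' @return Score matrix (`n_spectra x k`).
#' @export
pca_scores <- function(pca, data) {
  X <- if (inherits(data, "spectrum_set")) data$intensities else as.matrix(data)
  if (ncol(X) != length(pca$mean))
    stop("grid mismatch between data and PCA projection")
  sweep(X, 2L, pca$mean) %*% t(pca$components)
}

#' Fisher linear discriminant in PC-score space
#'
#' Two-class LDA with equal priors: the discriminant direction is
#' `Sw^-1 (mu_disease - mu_control)` (unit-normalized, oriented so that
#' disease projects high), with the decision threshold at the midpoint of
#' the projected class means. A near-singular pooled within-class scatter
#' is ridge-regularized with `eps = 1e-6 * trace(Sw)/dims`.
#'
#' @param scores Numeric matrix of PC scores (rows = spectra).
#' @param labels Per-row `control`/`disease` labels.
#' @return An object of class `lda_model` with `direction`, `threshold`
#'   and `class_means`.
#' @export
fit_lda <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- factor(labels, levels = c("control", "disease"))
  if (any(is.na(labels))) stop("labels must be control/disease")
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present")
  mu_c <- colMeans(scores[labels == "control", , drop = FALSE])
  mu_d <- colMeans(scores[labels == "disease", , drop = FALSE])
  center <- function(M, mu) sweep(M, 2L, mu)
  Sc <- crossprod(center(scores[labels == "control", , drop = FALSE], mu_c))
  Sd <- crossprod(center(scores[labels == "disease", , drop = FALSE], mu_d))
  n <- nrow(scores)
  Sw <- (Sc + Sd) / max(1L, n - 2L)
  d <- ncol(scores)
  dir <- tryCatch(solve(Sw, mu_d - mu_c), error = function(e) NULL)
  if (is.null(dir) || rcond(Sw) < 1e-10) {
    eps <- 1e-6 * sum(diag(Sw)) / d
    dir <- solve(Sw + diag(eps, d), mu_d - mu_c)
  }
  dir <- dir / sqrt(sum(dir^2))
  proj_c <- sum(dir * mu_c)
  proj_d <- sum(dir * mu_d)
  if (proj_d < proj_c) {  # orient: disease on the high side
    dir <- -dir
    proj_c <- -proj_c; proj_d <- -proj_d
  }
  structure(
    list(direction = dir, threshold = (proj_c + proj_d) / 2,
         class_means = rbind(control = mu_c, disease = mu_d)),
    class = "lda_model")
}

#' Predict with a PCA-LDA pipeline
#'
#' Projects spectra into PC space, scores them along the discriminant
#' direction, and classifies as disease iff the score strictly exceeds the
#' threshold (a score exactly at the threshold is called control — the
#' conservative tie-break for a positive screen). The pseudo-probability is
#' `plogis(score - threshold)`, monotone in the score with 0.5 at the
#' decision boundary.
#'
#' @param model An `lda_model`.
#' @param pca The `pca_projection` the model was fitted in.
#' @param data A `spectrum_set` or matrix.
#' @return Data frame with `spectrum_id`, `score`, `prob`, `class`.
#' @export
predict_lda <- function(model, pca, data) {
  stopifnot(inherits(model, "lda_model"), inherits(pca, "pca_projection"))
  sc <- pca_scores(pca, data)
  score <- drop(sc %*% model$direction)
  cls <- ifelse(score > model$threshold, "disease", "control")
  ids <- if (inherits(data, "spectrum_set")) data$spectrum_id
         else rownames(data) %||% sprintf("spec%03d", seq_along(score))
  data.frame(spectrum_id = ids, score = unname(score),
             prob = stats::plogis(unname(score) - model$threshold),
             class = factor(cls, levels = c("control", "disease")),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full PCA-LDA chemometric baseline
#'
#' Convenience wrapper chaining [fit_pca()] and [fit_lda()] on a training
#' set; predict with [predict.pca_lda()].
#'
#' @param data Training `spectrum_set` or matrix.
#' @param labels Per-spectrum labels (defaults to the set's donor labels).
#' @param variance_target Passed to [fit_pca()].
#' @return An object of class `pca_lda`.
#' @export
pca_lda <- function(data, labels = NULL, variance_target = 0.99) {
  if (is.null(labels)) {
    stopifnot(inherits(data, "spectrum_set"))
    labels <- spectrum_labels(data)
  }
  pca <- fit_pca(data, variance_target)
  lda <- fit_lda(pca_scores(pca, data), labels)
  structure(list(pca = pca, lda = lda), class = "pca_lda")
}

#' @export
print.pca_lda <- function(x, ...) {
  cat("<pca_lda> ", x$pca$k, " principal components (",
      round(100 * sum(x$pca$explained_variance_ratio), 1),
      "% variance) + linear discriminant\n", sep = "")
  invisible(x)
}

#' @rdname pca_lda
#' @param object A `pca_lda` model.
#' @param ... Unused.
#' @export
predict.pca_lda <- function(object, data, ...) {
  predict_lda(object$lda, object$pca, data)
}
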