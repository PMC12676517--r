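#' Patient-level stratified fold assignment
#'
#' Assigns whole donors (never individual spectra) to `K` folds, shuffling
#' donors within each class by the seed and dealing them round-robin so
#' per-fold class proportions stay within one donor of the cohort
#' proportions. If a class has fewer donors than `K`, `K` is reduced to the
#' smaller class size with a warning.
#'
#' @param donors Donor table (`donor_id`, `label`).
#' @param K Number of folds (default 7).
#' @param seed Integer seed for the donor shuffle.
#' @return An object of class `fold_assignment`: list with `fold_of`
#'   (named integer vector, folds `0..K-1`) and `K`.
#' @export
make_folds <- function(donors, K = 7L, seed = 1L) {
  donors <- as.data.frame(donors, stringsAsFactors = FALSE)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  min_class <- min(table(donors$label))
  if (min_class < K) {
    warning("reducing K from ", K, " to ", min_class,
            " (smallest class size)")
    K <- as.integer(min_class)
  }
  set.seed(seed)
  fold_of <- integer(0)
  offset <- 0L  # continue dealing where the previous class stopped, so
                # total fold sizes stay within one donor of each other
  for (cl in c("control", "disease")) {
    ids <- donors$donor_id[donors$label == cl]
    if (!length(ids)) next
    ids <- sample(ids)
    f <- (offset + seq_along(ids) - 1L) %% K
    fold_of[ids] <- f
    offset <- (offset + length(ids)) %% K
  }
  structure(list(fold_of = fold_of, K = K), class = "fold_assignment")
}

#' Donor-level majority vote
#'
#' Classifies each spectrum as disease iff its probability strictly exceeds
#' `cut`, then assigns each donor the majority class of its spectra. An
#' exact tie votes disease — the sensitivity-favoring rule for a screening
#' test (with the usual odd number of spectra per donor, ties cannot
#' occur).
#'
#' @param prob Numeric per-spectrum probabilities.
#' @param donor_of Character vector of donor ids, parallel to `prob`.
#' @param cut Spectrum-level probability threshold (default 0.5).
#' @return Named factor (levels `control`, `disease`), one entry per donor.
#' @export
majority_vote <- function(prob, donor_of, cut = 0.5) {
  if (length(prob) != length(donor_of))
    stop("prob and donor_of lengths differ")
  if (!length(prob)) stop("no spectra to vote over")
  pred <- prob > cut
  votes <- tapply(pred, donor_of, function(v) sum(v) >= length(v) / 2)
  out <- factor(ifelse(as.logical(votes), "disease", "control"),
                levels = c("control", "disease"))
  names(out) <- names(votes)
  out
}

confusion2 <- function(pred, truth) {
  pred <- factor(pred, levels = c("control", "disease"))
  truth <- factor(truth, levels = c("control", "disease"))
  table(truth = truth, pred = pred)
}

metrics_from_confusion <- function(cm) {
  n <- sum(cm)
  acc <- if (n > 0) sum(diag(cm)) / n else NA_real_
  sens_d <- if (sum(cm["disease", ]) > 0)
    cm["disease", "disease"] / sum(cm["disease", ]) else NA_real_
  sens_c <- if (sum(cm["control", ]) > 0)
    cm["control", "control"] / sum(cm["control", ]) else NA_real_
  list(accuracy = acc, sensitivity = sens_d,
       mean_sensitivity = mean(c(sens_c, sens_d)),
       sensitivity_control = sens_c)
}

#' Score pooled cross-validated predictions
#'
#' Computes spectrum-level and donor-level accuracy, disease-class
#' sensitivity (TPR) and mean sensitivity (unweighted average of the two
#' class recalls, i.e. balanced accuracy), pooled over folds
#' (micro-averaged from the pooled confusion counts) plus a per-fold
#' breakdown. Donor-level predictions come from [majority_vote()].
#'
#' @param predictions Data frame with columns `spectrum_id`, `donor_id`,
#'   `fold`, `prob`, `truth` (`control`/`disease` per spectrum).
#' @param cut Spectrum-level probability threshold (default 0.5).
#' @return An object of class `metrics_report`.
#' @export
score_report <- function(predictions, cut = 0.5) {
  need <- c("spectrum_id", "donor_id", "fold", "prob", "truth")
  stopifnot(all(need %in% names(predictions)))
  p <- predictions
  p$pred <- factor(ifelse(p$prob > cut, "disease", "control"),
                   levels = c("control", "disease"))
  cm_spec <- confusion2(p$pred, p$truth)
  donor_pred <- majority_vote(p$prob, p$donor_id, cut)
  donor_truth <- tapply(as.character(p$truth), p$donor_id,
                        function(v) v[1])[names(donor_pred)]
  cm_donor <- confusion2(donor_pred, donor_truth)
  ms <- metrics_from_confusion(cm_spec)
  md <- metrics_from_confusion(cm_donor)
  per_fold <- do.call(rbind, lapply(sort(unique(p$fold)), function(k) {
    pk <- p[p$fold == k, , drop = FALSE]
    mk <- metrics_from_confusion(confusion2(pk$pred, pk$truth))
    dk_pred <- majority_vote(pk$prob, pk$donor_id, cut)
    dk_truth <- tapply(as.character(pk$truth), pk$donor_id,
                       function(v) v[1])[names(dk_pred)]
    dk <- metrics_from_confusion(confusion2(dk_pred, dk_truth))
    data.frame(fold = k, n_spectra = nrow(pk),
               n_donors = length(dk_pred),
               spectral_accuracy = mk$accuracy,
               spectral_sensitivity = mk$sensitivity,
               donor_accuracy = dk$accuracy,
               donor_sensitivity = dk$sensitivity)
  }))
  structure(
    list(spectral_accuracy = ms$accuracy,
         spectral_sensitivity = ms$sensitivity,
         spectral_mean_sensitivity = ms$mean_sensitivity,
         donor_accuracy = md$accuracy,
         donor_sensitivity = md$sensitivity,
         donor_mean_sensitivity = md$mean_sensitivity,
         confusion_spectral = cm_spec, confusion_donor = cm_donor,
         per_fold = per_fold,
         donor_predictions = donor_pred,
         cut = cut),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  spectrum level: accuracy %.1f%%, sensitivity %.1f%%, mean sensitivity %.1f%%\n",
              100 * x$spectral_accuracy, 100 * x$spectral_sensitivity,
              100 * x$spectral_mean_sensitivity))
  cat(sprintf("  donor level:    accuracy %.1f%%, sensitivity %.1f%%, mean sensitivity %.1f%%\n",
              100 * x$donor_accuracy, 100 * x$donor_sensitivity,
              100 * x$donor_mean_sensitivity))
  cat("  ", nrow(x$per_fold), " folds, ", sum(x$per_fold$n_spectra),
      " spectra, ", sum(x$per_fold$n_donors), " donors\n", sep = "")
  invisible(x)
}

fit_fold_method <- function(train, test, method, fold_seed, variance_target,
                            net, T, policy) {
  labels <- spectrum_labels(train)
  if (method == "pca_lda") {
    model <- pca_lda(train, labels, variance_target)
    list(prob = predict(model, test)$prob, model = model)
  } else if (method == "nn") {
    cfg <- net; cfg$seed <- fold_seed
    model <- windowed_net(train, labels, cfg)
    list(prob = unname(predict(model, test)), model = model)
  } else {
    cfg <- net; cfg$seed <- fold_seed
    fit <- two_phase_train(train, labels, cfg, T = T, policy = policy)
    list(prob = unname(predict(fit$phase2, test)),
         prob_phase1 = unname(predict(fit$phase1, test)),
         mask = fit$mask, reports = fit$reports, model = fit)
  }
}

#' Run a cross-validated classification experiment
#'
#' The full evaluation protocol: donor-stratified K-fold assignment; per
#' fold, an EMSC model whose reference is the mean of the *training-fold*
#' spectra (recomputed per fold, so preprocessing never sees test data),
#' correction of both partitions, cropping to the analysis region, fitting
#' the chosen method on training donors only, and prediction of every
#' test-fold spectrum (no selection is ever applied at test time).
#' Predictions are pooled over folds and scored at spectrum and donor
#' level.
#'
#' @param cohort A `spectrum_set`.
#' @param method `"pca_lda"`, `"nn"` or `"nn_uncertainty"`.
#' @param K Number of folds (default 7).
#' @param seed Master seed; fold assignment and per-fold training seeds
#'   derive from it.
#' @param female_only Drop male donors before folding (default `FALSE`;
#'   the default synthetic cohorts are all-female already).
#' @param emsc_degree EMSC baseline polynomial degree (default 6).
#' @param crop Analysis region applied after EMSC (default `c(650, 3700)`
#'   cm^-1).
#' @param variance_target PCA cumulative-variance threshold (pca_lda).
#' @param net A [net_config()] (nn / nn_uncertainty); its seed is
#'   overridden per fold.
#' @param T Monte Carlo dropout passes for selection scoring.
#' @param policy A [selection_policy()] (nn_uncertainty).
#' @param keep_models Retain per-fold fitted models in the result (needed
#'   for leakage audits; default `FALSE`).
#' @return An object of class `ftir_experiment`: list with `metrics` (a
#'   [score_report()] result), `metrics_phase1` (nn_uncertainty only),
#'   `predictions`, `folds`, `fold_details` and the call parameters.
#' @export
run_experiment <- function(cohort,
                           method = c("pca_lda", "nn", "nn_uncertainty"),
                           K = 7L, seed = 1L, female_only = FALSE,
                           emsc_degree = 6L, crop = c(650, 3700),
                           variance_target = 0.99,
                           net = net_config(), T = 100L,
                           policy = selection_policy(),
                           keep_models = FALSE) {
  stopifnot(inherits(cohort, "spectrum_set"))
  method <- match.arg(method)
  if (female_only) {
    keep_donors <- cohort$donors$donor_id[cohort$donors$sex == "female"]
    cohort <- subset_spectra(
      cohort, cohort$spectrum_id[cohort$donor_id %in% keep_donors])
  }
  folds <- make_folds(cohort$donors, K, seed)
  preds <- list()
  fold_details <- list()
  for (k in seq_len(folds$K) - 1L) {
    res <- tryCatch({
      test_donors <- names(folds$fold_of)[folds$fold_of == k]
      train_ids <- cohort$spectrum_id[!(cohort$donor_id %in% test_donors)]
      test_ids <- cohort$spectrum_id[cohort$donor_id %in% test_donors]
      train <- subset_spectra(cohort, train_ids)
      test <- subset_spectra(cohort, test_ids)
      ref <- colMeans(train$intensities)
      em <- emsc_model(ref, emsc_degree, cohort$wavenumbers)
      train_c <- crop_region(emsc_correct(train, em)$set, crop[1], crop[2])
      test_c <- crop_region(emsc_correct(test, em)$set, crop[1], crop[2])
      fold_seed <- (as.integer(seed) %% 20000000L) * 100L + k  # < 2^31
      fit <- fit_fold_method(train_c, test_c, method, fold_seed,
                             variance_target, net, T, policy)
      pd <- data.frame(spectrum_id = test_c$spectrum_id,
                       donor_id = test_c$donor_id,
                       fold = k, prob = fit$prob,
                       truth = as.character(spectrum_labels(test_c)),
                       stringsAsFactors = FALSE)
      if (!is.null(fit$prob_phase1)) pd$prob_phase1 <- fit$prob_phase1
      detail <- list(emsc_reference = ref, mask = fit$mask,
                     reports = fit$reports)
      if (keep_models) {
        detail$model <- fit$model
        detail$emsc_model <- em
      }
      list(pd = pd, detail = detail)
    }, error = function(e) stop("fold ", k, ": ", conditionMessage(e),
                                call. = FALSE))
    preds[[k + 1L]] <- res$pd
    fold_details[[k + 1L]] <- res$detail
  }
  predictions <- do.call(rbind, preds)
  metrics <- score_report(predictions)
  metrics_phase1 <- NULL
  if (method == "nn_uncertainty") {
    p1 <- predictions
    p1$prob <- p1$prob_phase1
    metrics_phase1 <- score_report(p1)
  }
  structure(
    list(method = method, metrics = metrics, metrics_phase1 = metrics_phase1,
         predictions = predictions, folds = folds,
         fold_details = fold_details, seed = seed, K = folds$K),
    class = "ftir_experiment")
}

#' @export
print.ftir_experiment <- function(x, ...) {
  cat("<ftir_experiment> method = ", x$method, ", ", x$K,
      "-fold donor-stratified CV (seed ", x$seed, ")\n", sep = "")
  print(x$metrics)
  if (!is.null(x$metrics_phase1)) {
    cat("phase-1 (pre-refinement) metrics:\n")
    print(x$metrics_phase1)
  }
  invisible(x)
}
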