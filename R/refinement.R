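#' Uncertainty-based selection policy
#'
#' Controls which positive-class training spectra survive into the second
#' training phase. Control spectra are always kept in full. For each
#' diseased donor, spectra are ranked ascending by Monte Carlo dropout
#' variance and the most confident retained, either as a fixed fraction
#' (`lowest_fraction`, default 40% — one or two of five spectra) or by an
#' absolute variance cut (`below_threshold`). A per-donor floor guarantees
#' at least `max(1, ceiling(retention_floor * n))` spectra survive (default
#' floor 20%), so no patient is ever dropped from training entirely.
#'
#' @param retention_floor Minimum retained proportion per donor (default
#'   0.20).
#' @param keep_rule `"lowest_fraction"` (default) or `"below_threshold"`.
#' @param keep_fraction Retained proportion under `lowest_fraction`
#'   (default 0.40).
#' @param threshold Variance cut under `below_threshold`.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(retention_floor = 0.20,
                             keep_rule = c("lowest_fraction", "below_threshold"),
                             keep_fraction = 0.40, threshold = NULL) {
  keep_rule <- match.arg(keep_rule)
  if (!(retention_floor > 0 && retention_floor <= 1))
    stop("retention_floor must lie in (0, 1]")
  if (keep_rule == "lowest_fraction" &&
      !(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must lie in (0, 1]")
  if (keep_rule == "below_threshold" &&
      (is.null(threshold) || !is.numeric(threshold) || threshold < 0))
    stop("below_threshold requires a non-negative variance threshold")
  structure(list(retention_floor = retention_floor, keep_rule = keep_rule,
                 keep_fraction = keep_fraction, threshold = threshold),
            class = "selection_policy")
}

#' Select training spectra from uncertainty reports
#'
#' Applies a [selection_policy()] to phase-1 Monte Carlo dropout scores:
#' every control spectrum is kept; each diseased donor keeps its
#' lowest-variance spectra subject to the policy and the per-donor floor.
#'
#' @param reports An `uncertainty_report` covering all training spectra.
#' @param donors Donor table (`donor_id`, `label`) covering every donor in
#'   `reports`.
#' @param policy A [selection_policy()].
#' @return An object of class `selection_mask`: list with `keep` (character
#'   vector of retained spectrum ids) and `dropped` (data frame
#'   `spectrum_id`, `donor_id`, `var_y`).
#' @export
select_training_spectra <- function(reports, donors,
                                    policy = selection_policy()) {
  stopifnot(inherits(policy, "selection_policy"))
  donors <- as.data.frame(donors, stringsAsFactors = FALSE)
  lab <- donors$label[match(reports$donor_id, donors$donor_id)]
  if (anyNA(lab))
    stop("reports reference donors missing from the donor table")
  keep <- character(0)
  dropped_idx <- integer(0)
  for (d in unique(reports$donor_id)) {
    i <- which(reports$donor_id == d)
    if (length(i) == 0L) stop("donor with zero spectra: ", d)
    if (donors$label[donors$donor_id == d] == "control") {
      keep <- c(keep, reports$spectrum_id[i])
      next
    }
    o <- i[order(reports$var_y[i], reports$spectrum_id[i])]
    n <- length(o)
    floor_n <- max(1L, ceiling(policy$retention_floor * n))
    n_keep <- if (policy$keep_rule == "lowest_fraction") {
      ceiling(policy$keep_fraction * n)
    } else {
      sum(reports$var_y[o] <= policy$threshold)
    }
    n_keep <- min(n, max(floor_n, n_keep))
    keep <- c(keep, reports$spectrum_id[o[seq_len(n_keep)]])
    if (n_keep < n) dropped_idx <- c(dropped_idx, o[seq.int(n_keep + 1L, n)])
  }
  dropped <- reports[dropped_idx, c("spectrum_id", "donor_id", "var_y")]
  rownames(dropped) <- NULL
  structure(list(keep = keep, dropped = dropped), class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat("<selection_mask> ", length(x$keep), " spectra kept, ",
      nrow(x$dropped), " dropped\n", sep = "")
  invisible(x)
}

#' Two-phase uncertainty-refined training
#'
#' The label-noise-aware training workflow: (phase 1) train a network on
#' all training spectra; score each *training* spectrum by Monte Carlo
#' dropout variance; build a [selection_policy()] mask keeping all controls
#' and each diseased donor's most confident spectra; (phase 2) train a
#' fresh network — re-initialized from a different seed, never
#' warm-started, so the optimizer is not anchored in the noisy phase-1
#' minimum — on the refined set for the full epoch budget. Test spectra
#' are never involved in selection; at prediction time all spectra of a
#' donor are used.
#'
#' @param train_set Training `spectrum_set`.
#' @param labels Per-spectrum labels (see [train_net()]).
#' @param config A [net_config()]; its `seed` drives phase 1, and phase 2
#'   re-initializes from `seed + seed_offset`.
#' @param T Monte Carlo dropout passes for scoring (default 100).
#' @param policy A [selection_policy()].
#' @param seed_offset Offset between the phase-1 and phase-2 seeds
#'   (default 1000).
#' @return An object of class `two_phase_fit`: list with `phase2` (the
#'   refined network), `phase1`, `mask`, and `reports` (phase-1 training
#'   uncertainties).
#' @export
two_phase_train <- function(train_set, labels, config = net_config(),
                            T = 100L, policy = selection_policy(),
                            seed_offset = 1000L) {
  stopifnot(inherits(train_set, "spectrum_set"))
  labels <- factor(labels, levels = c("control", "disease"))
  phase1 <- windowed_net(train_set, labels, config)
  reports <- mc_predict(phase1, train_set, T = T, seed = config$seed + 1L)
  mask <- select_training_spectra(reports, train_set$donors, policy)
  refined <- subset_spectra(train_set, mask$keep)
  refined_labels <- spectrum_labels(refined)
  if (length(unique(refined_labels)) < 2L)
    stop("internal error: refined training set lost a class")  # unreachable
  cfg2 <- config
  cfg2$seed <- config$seed + as.integer(seed_offset)
  phase2 <- windowed_net(refined, refined_labels, cfg2)
  structure(list(phase2 = phase2, phase1 = phase1, mask = mask,
                 reports = reports),
            class = "two_phase_fit")
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat("<two_phase_fit> phase-2 network trained on ", length(x$mask$keep),
      " of ", length(x$mask$keep) + nrow(x$mask$dropped),
      " training spectra\n", sep = "")
  invisible(x)
}

#' @export
predict.two_phase_fit <- function(object, data, ...) {
  predict(object$phase2, data, ...)
}
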