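#' Monte Carlo dropout prediction
#'
#' Keeps dropout active at inference and performs `T` stochastic forward
#' passes through a trained network. For each spectrum the predictive mean
#' is `y_hat = (1/T) sum_t f^(t)(x)` and the uncertainty is the population
#' variance of the passes, `var_y = (1/T) sum_t f^(t)(x)^2 - y_hat^2`
#' (exactly this biased form, not the T-1 estimator). Tiny negative
#' variances from floating-point cancellation are clipped to zero (with a
#' message when it happens).
#'
#' @param net A trained `windowed_net` (with `dropout > 0` for an
#'   informative variance).
#' @param data A `spectrum_set` or numeric matrix.
#' @param T Number of stochastic passes (default 100; must be >= 2).
#' @param seed Integer seed for the dropout masks.
#' @param return_passes Keep the raw `n x T` pass matrix as attribute
#'   `"passes"` (for diagnostics and oracles).
#' @return A data frame of class `uncertainty_report` with columns
#'   `spectrum_id`, `donor_id` (NA for bare matrices), `y_hat`, `var_y`,
#'   `T`.
#' @export
mc_predict <- function(net, data, T = 100L, seed = 1L,
                       return_passes = FALSE) {
  stopifnot(inherits(net, "windowed_net"))
  if (!net$trained) stop("network is untrained")
  T <- as.integer(T)
  if (T < 2L) stop("T must be >= 2")
  X <- as_intensity_matrix(data, net$n)
  cfg <- net$config
  set.seed(seed)
  passes <- cpp_net_mc(X, net$windows - 1L, net$weights, cfg$dropout,
                       if (cfg$dropout_site == "head") 0L else 1L,
                       T, cfg$output == "sigmoid")
  y_hat <- rowMeans(passes)
  var_y <- rowMeans(passes^2) - y_hat^2
  n_neg <- sum(var_y < 0)
  if (n_neg > 0) {
    message("clipped ", n_neg, " negative variance estimates to 0")
    var_y[var_y < 0] <- 0
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(nrow(X)))
  donor <- if (inherits(data, "spectrum_set")) data$donor_id
           else rep(NA_character_, nrow(X))
  out <- data.frame(spectrum_id = ids, donor_id = donor,
                    y_hat = unname(y_hat), var_y = unname(var_y), T = T,
                    stringsAsFactors = FALSE)
  class(out) <- c("uncertainty_report", "data.frame")
  if (return_passes) attr(out, "passes") <- passes
  out
}

#' Rank each donor's spectra by uncertainty
#'
#' Within each donor, spectra are ordered ascending by `var_y` (most
#' confident first) with a stable `spectrum_id` tiebreak.
#'
#' @param reports An `uncertainty_report` covering all of each donor's
#'   spectra.
#' @return Named list (one element per donor) of spectrum ids in ascending
#'   variance order.
#' @export
rank_by_uncertainty <- function(reports) {
  stopifnot(is.data.frame(reports),
            all(c("spectrum_id", "donor_id", "var_y") %in% names(reports)))
  if (anyNA(reports$donor_id))
    stop("reports lack donor ids for some spectra")
  split_ids <- split(seq_len(nrow(reports)), reports$donor_id)
  lapply(split_ids, function(i) {
    o <- order(reports$var_y[i], reports$spectrum_id[i])
    reports$spectrum_id[i][o]
  })
}
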