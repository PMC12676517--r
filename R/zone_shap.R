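#' Default wavenumber zone schemes
#'
#' The fingerprint region 650-1800 cm^-1 tiled into contiguous,
#' non-overlapping zones. The coarse scheme uses the boundaries
#' 650 | 825 | 956 | 1210 | 1312 | 1372 | 1477 | 1579 | 1800 (8 zones; the
#' 1372-1477 interval is its own zone so the scheme tiles the range). The
#' fine scheme additionally splits 956-1210 into band A (956-1030), band B
#' (1030-1170) and 1170-1210 (10 zones). Optionally the remaining
#' 1800-3700 cm^-1 range is appended as a single high-wavenumber zone.
#'
#' @param resolution `"coarse"` (default) or `"fine"`.
#' @param include_high_wavenumber Append a single 1800-3700 zone (default
#'   `FALSE`).
#' @return An object of class `zone_scheme`: data frame with `low`, `high`
#'   (cm^-1) and `label`.
#' @export
default_zones <- function(resolution = c("coarse", "fine"),
                          include_high_wavenumber = FALSE) {
  resolution <- match.arg(resolution)
  edges <- if (resolution == "coarse")
    c(650, 825, 956, 1210, 1312, 1372, 1477, 1579, 1800)
  else
    c(650, 825, 956, 1030, 1170, 1210, 1312, 1372, 1477, 1579, 1800)
  if (include_high_wavenumber) edges <- c(edges, 3700)
  zone_scheme(edges)
}

#' Build a zone scheme from ordered boundaries
#'
#' @param edges Strictly increasing numeric zone boundaries (cm^-1);
#'   `n` edges define `n - 1` contiguous zones.
#' @param labels Optional per-zone labels (default `"low-high"`).
#' @return An object of class `zone_scheme`.
#' @export
zone_scheme <- function(edges, labels = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least 2 values")
  low <- edges[-length(edges)]
  high <- edges[-1L]
  if (is.null(labels)) labels <- paste0(low, "-", high)
  if (length(labels) != length(low)) stop("one label per zone required")
  structure(data.frame(low = low, high = high, label = labels,
                       stringsAsFactors = FALSE),
            class = c("zone_scheme", "data.frame"))
}

zone_membership <- function(wavenumbers, scheme) {
  # zones are contiguous half-open [low, high), closed at the last edge
  idx <- findInterval(wavenumbers, c(scheme$low, scheme$high[nrow(scheme)]),
                      rightmost.closed = TRUE)
  idx[idx < 1L | idx > nrow(scheme)] <- NA_integer_
  idx
}

#' Zone-mean features of a spectrum set
#'
#' Per-zone mean intensity for every spectrum, plus a min-max normalized
#' copy (each zone mapped to \[0, 1\] across the cohort) used for coloring
#' attribution summaries. Raw means are what models consume.
#'
#' @param data A `spectrum_set`.
#' @param scheme A [zone_scheme()] lying within the grid range.
#' @return List with matrices `raw` and `normalized`
#'   (`n_spectra x n_zones`, columns labelled by zone).
#' @export
zone_features <- function(data, scheme) {
  stopifnot(inherits(data, "spectrum_set"), inherits(scheme, "zone_scheme"))
  member <- zone_membership(data$wavenumbers, scheme)
  raw <- matrix(NA_real_, n_spectra(data), nrow(scheme),
                dimnames = list(data$spectrum_id, scheme$label))
  for (z in seq_len(nrow(scheme))) {
    cols <- which(member == z)
    if (!length(cols))
      stop("zone ", scheme$label[z], " contains no grid points")
    raw[, z] <- rowMeans(data$intensities[, cols, drop = FALSE])
  }
  rng_lo <- apply(raw, 2L, min)
  rng_hi <- apply(raw, 2L, max)
  span <- pmax(rng_hi - rng_lo, .Machine$double.eps)
  normalized <- sweep(sweep(raw, 2L, rng_lo), 2L, span, "/")
  list(raw = raw, normalized = normalized)
}

eval_masked <- function(f, x, background, masks, chunk = 20000L) {
  # mean model output with coalition features fixed to x, rest imputed
  # from the background rows; masks is a logical matrix (n_masks x m)
  B <- nrow(background)
  m <- ncol(background)
  vals <- numeric(nrow(masks))
  blocks <- split(seq_len(nrow(masks)),
                  ceiling(seq_len(nrow(masks)) / max(1L, chunk %/% B)))
  for (bl in blocks) {
    big <- background[rep(seq_len(B), times = length(bl)), , drop = FALSE]
    for (j in seq_along(bl)) {
      on <- which(masks[bl[j], ])
      if (length(on))
        big[seq.int((j - 1L) * B + 1L, j * B), on] <-
          matrix(x[on], B, length(on), byrow = TRUE)
    }
    out <- f(big)
    if (any(!is.finite(out))) stop("model returned non-finite outputs")
    vals[bl] <- colMeans(matrix(out, B))
  }
  vals
}

#' Shapley attribution of a zone-feature prediction
#'
#' Shapley values of each zone for the prediction `f(x)` relative to a
#' background feature distribution: the average marginal contribution of
#' fixing a zone to its observed value over all coalitions, with absent
#' zones imputed from the background rows. For up to 12 zones all `2^m`
#' coalitions are enumerated exactly (local accuracy
#' `sum(phi) = f(x) - baseline` then holds to machine precision); beyond
#' that, sampled feature permutations are used.
#'
#' @param f Model: a function taking a feature matrix (rows = instances)
#'   and returning one numeric output per row.
#' @param x Numeric feature row to explain.
#' @param background Matrix of background feature rows (the reference
#'   distribution, e.g. training-fold control spectra's zone means).
#' @param n_samples Number of sampled permutations when `m > 12` (default
#'   200).
#' @param seed Seed for permutation sampling (unused in exact mode).
#' @return An object of class `zone_attribution`: list with `phi` (named
#'   per-zone Shapley values), `baseline` (mean background prediction),
#'   `fx` (`f(x)` averaged over background imputation of nothing, i.e. the
#'   full-coalition value), and `exact`.
#' @export
shapley_attribution <- function(f, x, background, n_samples = 200L,
                                seed = 1L) {
  x <- as.numeric(x)
  background <- as.matrix(background)
  m <- length(x)
  if (ncol(background) != m)
    stop("background and x have different feature counts")
  if (nrow(background) < 1L) stop("background must be non-empty")
  nm <- names(x) %||% colnames(background) %||% paste0("z", seq_len(m))
  if (m <= 12L) {
    n_masks <- bitwShiftL(1L, m)
    masks <- matrix(FALSE, n_masks, m)
    for (i in seq_len(m))
      masks[, i] <- bitwAnd(seq_len(n_masks) - 1L, bitwShiftL(1L, i - 1L)) > 0L
    vals <- eval_masked(f, x, background, masks)
    sizes <- rowSums(masks)
    lf <- lgamma(seq_len(m + 1L))  # lgamma(k+1) = log k!
    phi <- numeric(m)
    for (i in seq_len(m)) {
      bit <- bitwShiftL(1L, i - 1L)
      without <- which(bitwAnd(seq_len(n_masks) - 1L, bit) == 0L)
      s <- sizes[without]
      w <- exp(lf[s + 1L] + lf[m - s] - lf[m + 1L])  # |S|!(m-|S|-1)!/m!
      phi[i] <- sum(w * (vals[without + bit] - vals[without]))
    }
    baseline <- vals[1L]
    fx <- vals[n_masks]
    exact <- TRUE
  } else {
    set.seed(seed)
    phi <- numeric(m)
    prev <- NULL
    base_mask <- matrix(FALSE, 1L, m)
    baseline <- eval_masked(f, x, background, base_mask)
    fx <- eval_masked(f, x, background, matrix(TRUE, 1L, m))
    for (r in seq_len(n_samples)) {
      perm <- sample.int(m)
      cur <- rep(FALSE, m)
      v_prev <- baseline
      for (i in perm) {
        cur[i] <- TRUE
        v_cur <- eval_masked(f, x, background, matrix(cur, 1L, m))
        phi[i] <- phi[i] + (v_cur - v_prev)
        v_prev <- v_cur
      }
    }
    phi <- phi / n_samples
    exact <- FALSE
  }
  names(phi) <- nm
  structure(list(phi = phi, baseline = unname(baseline), fx = unname(fx),
                 exact = exact),
            class = "zone_attribution")
}

#' @export
print.zone_attribution <- function(x, ...) {
  cat("<zone_attribution> f(x) = ", format(x$fx), ", baseline = ",
      format(x$baseline), if (x$exact) " (exact)" else " (sampled)", "\n",
      sep = "")
  print(round(x$phi, 5))
  invisible(x)
}

#' Zone-surrogate view of a trained network
#'
#' Maps zone-feature rows back to full spectra for the network: each zone
#' mean is broadcast across its zone's grid points, out-of-zone points are
#' taken from a fixed template spectrum (typically the training mean), and
#' the network predicts deterministically. This is the bridge that lets
#' zone-level Shapley values be computed for a network trained on full
#' spectra.
#'
#' @param net A trained `windowed_net`.
#' @param wavenumbers The grid the network was trained on.
#' @param scheme A [zone_scheme()].
#' @param template Numeric template spectrum for out-of-zone grid points.
#' @return A function mapping an `n x n_zones` matrix to `n` probabilities.
#' @export
zone_surrogate <- function(net, wavenumbers, scheme, template) {
  stopifnot(inherits(net, "windowed_net"), length(template) == net$n)
  member <- zone_membership(wavenumbers, scheme)
  function(Z) {
    Z <- as.matrix(Z)
    X <- matrix(template, nrow(Z), length(template), byrow = TRUE)
    for (z in seq_len(ncol(Z))) {
      cols <- which(member == z)
      X[, cols] <- Z[, z]
    }
    unname(predict(net, X))
  }
}

#' Zone attributions for a set of spectra
#'
#' Convenience pipeline: zone features for the spectra to explain and for
#' the background set, a [zone_surrogate()] of the network, and one
#' [shapley_attribution()] per spectrum.
#'
#' @param net A trained `windowed_net`.
#' @param data `spectrum_set` of spectra to explain (EMSC-corrected, on the
#'   network's grid).
#' @param background `spectrum_set` serving as the reference distribution
#'   (typically training-fold controls).
#' @param scheme A [zone_scheme()] (default coarse).
#' @param max_background Subsample cap on background rows (default 32; the
#'   first rows in donor order are used, deterministically).
#' @return List of `zone_attribution` objects named by spectrum id, with
#'   the normalized zone values of `data` attached as attribute
#'   `"zone_value"`.
#' @export
zone_attributions <- function(net, data, background,
                              scheme = default_zones(),
                              max_background = 32L) {
  zf <- zone_features(data, scheme)
  bf <- zone_features(background, scheme)$raw
  if (nrow(bf) > max_background)
    bf <- bf[seq_len(max_background), , drop = FALSE]
  template <- colMeans(background$intensities)
  f <- zone_surrogate(net, data$wavenumbers, scheme, template)
  out <- lapply(seq_len(n_spectra(data)), function(i)
    shapley_attribution(f, zf$raw[i, ], bf))
  names(out) <- data$spectrum_id
  attr(out, "zone_value") <- zf$normalized
  out
}

#' Global attribution summary
#'
#' Ranks zones by mean absolute Shapley value over a collection of
#' attributions and assembles the per-point scatter table behind summary
#' ("beeswarm") plots: one row per (spectrum, zone) with the signed phi and
#' the normalized zone intensity for coloring.
#'
#' @param attributions List of `zone_attribution` objects (as returned by
#'   [zone_attributions()]); the optional `"zone_value"` attribute supplies
#'   colors.
#' @return An object of class `shap_summary`: list with `ranking` (data
#'   frame `zone`, `mean_abs_phi`, `rank`) and `points` (data frame
#'   `spectrum_id`, `zone`, `phi`, `zone_value`).
#' @export
summarize_global <- function(attributions) {
  if (!length(attributions)) stop("need at least one attribution")
  phis <- do.call(rbind, lapply(attributions, function(a) a$phi))
  zones <- colnames(phis)
  mean_abs <- colMeans(abs(phis))
  ranking <- data.frame(zone = zones, mean_abs_phi = unname(mean_abs),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs_phi, ranking$zone), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  zv <- attr(attributions, "zone_value")
  ids <- names(attributions) %||% as.character(seq_along(attributions))
  points <- data.frame(
    spectrum_id = rep(ids, times = length(zones)),
    zone = rep(zones, each = length(ids)),
    phi = as.vector(phis),
    zone_value = if (!is.null(zv)) as.vector(zv[ids, zones, drop = FALSE])
                 else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(ranking = ranking, points = points),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat("<shap_summary> zones by mean |phi|:\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' @export
plot.shap_summary <- function(x, ...) {
  rk <- x$ranking
  pts <- x$points
  y <- match(pts$zone, rev(rk$zone))
  col <- if (all(is.na(pts$zone_value))) "grey30"
         else grDevices::rgb(pts$zone_value, 0.2, 1 - pts$zone_value)
  graphics::plot(pts$phi, jitter(y, amount = 0.15), col = col, pch = 16,
                 cex = 0.6, yaxt = "n", xlab = "Shapley value",
                 ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(rk)), labels = rev(rk$zone), las = 1,
                 cex.axis = 0.7)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
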