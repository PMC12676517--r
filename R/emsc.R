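#' Legendre polynomial basis on a normalized wavenumber axis
#'
#' Evaluates Legendre polynomials P_0..P_degree on the wavenumber grid
#' mapped affinely to \[-1, 1\]. The orthogonal basis keeps the EMSC design
#' well conditioned at degree 6 over a multi-thousand cm^-1 span, where raw
#' powers of the wavenumber would be numerically hopeless.
#'
#' @param wavenumbers Numeric grid (any monotone order).
#' @param degree Highest polynomial degree (>= 0).
#' @return Matrix `length(wavenumbers) x (degree + 1)`; column `k` holds
#'   P_{k-1}.
#' @export
legendre_basis <- function(wavenumbers, degree) {
  stopifnot(degree >= 0, length(wavenumbers) >= 1)
  rng <- range(wavenumbers)
  x <- if (rng[2] > rng[1]) 2 * (wavenumbers - rng[1]) / (rng[2] - rng[1]) - 1
       else rep(0, length(wavenumbers))
  B <- matrix(0, length(x), degree + 1L)
  B[, 1L] <- 1
  if (degree >= 1L) B[, 2L] <- x
  if (degree >= 2L) {
    for (k in 2:degree) {  # (k)P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      B[, k + 1L] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1L]) / k
    }
  }
  colnames(B) <- paste0("P", 0:degree)
  B
}

#' Build an EMSC correction model
#'
#' Extended multiplicative signal correction decomposes each raw spectrum as
#' `raw = b * reference + sum_k p_k * basis_k + residual`, where the basis is
#' a polynomial (default degree 6) in the normalized wavenumber. Correction
#' subtracts the fitted baseline and divides by the multiplicative
#' coefficient `b`, removing baseline drift and multiplicative scatter in a
#' single least-squares step.
#'
#' @param reference Numeric reference spectrum (typically the mean of the
#'   training spectra), same length as the grid.
#' @param degree Baseline polynomial degree (default 6).
#' @param wavenumbers The wavenumber grid the model operates on.
#' @return An object of class `emsc_model` with the QR-decomposed design.
#' @export
emsc_model <- function(reference, degree = 6L, wavenumbers) {
  degree <- as.integer(degree)
  stopifnot(degree >= 0L)
  reference <- as.numeric(reference)
  if (length(reference) != length(wavenumbers))
    stop("reference length does not match grid length")
  if (anyNA(reference) || any(!is.finite(reference)))
    stop("reference must be finite")
  if (all(reference == 0)) stop("reference is identically zero")
  if (length(wavenumbers) <= degree + 2L)
    stop("grid too short for degree ", degree, " baseline")
  basis <- legendre_basis(wavenumbers, degree)
  design <- cbind(reference = reference, basis)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("EMSC design is rank deficient (reference collinear with the ",
         "polynomial basis, e.g. a constant reference)")
  structure(
    list(reference = reference, degree = degree, wavenumbers = wavenumbers,
         basis = basis, design = design, qr = qrd),
    class = "emsc_model")
}

#' @export
print.emsc_model <- function(x, ...) {
  cat("<emsc_model> degree-", x$degree, " polynomial baseline, grid of ",
      length(x$wavenumbers), " points\n", sep = "")
  invisible(x)
}

#' Fit the EMSC decomposition of one raw spectrum
#'
#' Least-squares fit of `raw ~ b * reference + polynomial baseline`. The
#' corrected spectrum is `(raw - baseline) / b`.
#'
#' @param model An [emsc_model()].
#' @param raw Numeric raw spectrum on the model grid.
#' @return An object of class `emsc_fit` with elements `b` (multiplicative
#'   coefficient), `p` (baseline coefficients, lowest order first),
#'   `corrected`, `residual_norm` and `degenerate` (logical: `|b|` below
#'   tolerance, correction unreliable).
#' @export
emsc_fit <- function(model, raw) {
  stopifnot(inherits(model, "emsc_model"))
  raw <- as.numeric(raw)
  if (length(raw) != length(model$reference))
    stop("raw spectrum length does not match model grid")
  coefs <- qr.coef(model$qr, raw)
  fitted <- drop(model$design %*% coefs)
  b <- coefs[1L]
  p <- coefs[-1L]
  degenerate <- abs(b) < 1e-6
  baseline <- drop(model$basis %*% p)
  corrected <- if (degenerate) raw - baseline else (raw - baseline) / b
  structure(
    list(b = unname(b), p = unname(p),
         corrected = corrected,
         residual_norm = sqrt(sum((raw - fitted)^2)),
         degenerate = degenerate),
    class = "emsc_fit")
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat("<emsc_fit> b = ", format(x$b), ", residual norm = ",
      format(x$residual_norm), if (x$degenerate) "  [degenerate |b|]", "\n",
      sep = "")
  invisible(x)
}

#' EMSC-correct every spectrum of a set
#'
#' Applies [emsc_fit()] to each spectrum and replaces it by
#' `(raw - baseline) / b`. Spectrum order and all metadata are preserved.
#' Spectra with `|b| < 1e-6` cannot be meaningfully rescaled; they are kept
#' baseline-subtracted but unscaled, flagged in the fit table, and reported
#' via a warning so callers can exclude them from training.
#'
#' @param x A `spectrum_set` on the model grid.
#' @param model An [emsc_model()].
#' @return A list with `set` (the corrected `spectrum_set`) and `fits`
#'   (data frame: `spectrum_id`, `b`, `residual_norm`, `degenerate`, plus
#'   one column per baseline coefficient).
#' @export
emsc_correct <- function(x, model) {
  stopifnot(inherits(x, "spectrum_set"), inherits(model, "emsc_model"))
  if (length(x$wavenumbers) != length(model$wavenumbers) ||
      any(x$wavenumbers != model$wavenumbers))
    stop("spectrum set grid does not match EMSC model grid")
  # one QR solve for the whole block: columns are spectra
  coefs <- qr.coef(model$qr, t(x$intensities))
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1L)
  b <- coefs[1L, ]
  p <- coefs[-1L, , drop = FALSE]
  baselines <- model$basis %*% p                  # n_wn x n_spectra
  degenerate <- abs(b) < 1e-6
  scale <- ifelse(degenerate, 1, b)
  corrected <- t((t(x$intensities) - baselines) / rep(scale, each = nrow(baselines)))
  if (any(degenerate))
    warning(sum(degenerate), " spectra had |b| < 1e-6; left unscaled: ",
            paste(x$spectrum_id[degenerate], collapse = ", "))
  fitted <- model$design %*% coefs
  resid_norm <- sqrt(colSums((t(x$intensities) - fitted)^2))
  fits <- data.frame(spectrum_id = x$spectrum_id, b = unname(b),
                     residual_norm = unname(resid_norm),
                     degenerate = unname(degenerate),
                     stringsAsFactors = FALSE)
  pmat <- t(p)
  colnames(pmat) <- paste0("p", seq_len(ncol(pmat)) - 1L)
  fits <- cbind(fits, as.data.frame(pmat))
  rownames(fits) <- NULL
  out <- spectrum_set(x$wavenumbers, corrected, x$spectrum_id, x$donor_id,
                      x$donors)
  list(set = out, fits = fits)
}
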