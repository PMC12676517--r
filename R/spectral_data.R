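#' Construct a spectrum set
#'
#' A `spectrum_set` is the package's universal container for a block of
#' spectra on a common wavenumber grid together with the donor metadata
#' needed for patient-level analyses. Intensities are stored as an
#' `n_spectra x n_wavenumbers` matrix in absorbance units; the grid is kept
#' strictly ascending internally regardless of the acquisition order
#' (instruments typically export 4000 -> 650 cm^-1).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic (ascending or descending; canonicalized to ascending).
#' @param intensities Numeric matrix, one row per spectrum, columns matching
#'   `wavenumbers`. Row names, if present, must agree with `spectrum_id`.
#' @param spectrum_id Character vector of unique spectrum identifiers.
#' @param donor_id Character vector mapping each spectrum to a donor.
#' @param donors Data frame with columns `donor_id`, `label`
#'   (`"control"`/`"disease"`), `sex` (`"female"`/`"male"`) and optionally
#'   `age_bin`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, intensities, spectrum_id, donor_id, donors) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 1L || anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("wavenumbers must be finite and non-empty")
  if (any(wavenumbers <= 0))
    stop("wavenumbers must be positive (cm^-1)")
  d <- diff(wavenumbers)
  if (length(d) > 0L) {
    if (all(d < 0)) {          # descending export convention: canonicalize
      wavenumbers <- rev(wavenumbers)
      intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
    } else if (!all(d > 0)) {
      stop("wavenumbers must be strictly monotonic with no duplicates")
    }
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(wavenumbers))
    stop("intensity matrix has ", ncol(intensities), " columns but grid has ",
         length(wavenumbers), " wavenumbers")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must all be finite")
  spectrum_id <- as.character(spectrum_id)
  donor_id <- as.character(donor_id)
  if (nrow(intensities) != length(spectrum_id))
    stop("spectrum_id length does not match number of spectra")
  if (length(donor_id) != length(spectrum_id))
    stop("donor_id length does not match number of spectra")
  if (anyDuplicated(spectrum_id))
    stop("duplicate spectrum_id: ",
         paste(unique(spectrum_id[duplicated(spectrum_id)]), collapse = ", "))
  donors <- validate_donors(donors)
  missing_donor <- setdiff(donor_id, donors$donor_id)
  if (length(missing_donor))
    stop("spectra reference donors absent from donor table: ",
         paste(missing_donor, collapse = ", "))
  rownames(intensities) <- spectrum_id
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         spectrum_id = spectrum_id, donor_id = donor_id, donors = donors),
    class = "spectrum_set")
}

validate_donors <- function(donors) {
  donors <- as.data.frame(donors, stringsAsFactors = FALSE)
  need <- c("donor_id", "label", "sex")
  if (!all(need %in% names(donors)))
    stop("donor table must have columns donor_id, label, sex")
  if (nrow(donors) == 0L) stop("donor table is empty")
  donors$donor_id <- as.character(donors$donor_id)
  if (anyDuplicated(donors$donor_id))
    stop("duplicate donor_id in donor table")
  donors$label <- as.character(donors$label)
  bad <- setdiff(unique(donors$label), c("control", "disease"))
  if (length(bad))
    stop("donor label must be 'control' or 'disease'; found: ",
         paste(bad, collapse = ", "))
  donors$sex <- as.character(donors$sex)
  bad <- setdiff(unique(donors$sex), c("female", "male"))
  if (length(bad))
    stop("donor sex must be 'female' or 'male'; found: ",
         paste(bad, collapse = ", "))
  if (is.null(donors$age_bin)) donors$age_bin <- NA_character_
  donors$age_bin <- as.character(donors$age_bin)
  rownames(donors) <- NULL
  donors[, c("donor_id", "label", "sex", "age_bin")]
}

#' @export
print.spectrum_set <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat("<spectrum_set> ", nrow(x$intensities), " spectra from ",
      nrow(x$donors), " donors\n", sep = "")
  cat("  grid: ", length(x$wavenumbers), " points, ",
      format(rng[1]), "-", format(rng[2]), " cm^-1\n", sep = "")
  tab <- table(x$donors$label)
  cat("  donors: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of spectra in a spectrum set
#' @param x A `spectrum_set`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(x) nrow(x$intensities)

#' Per-spectrum class labels
#'
#' Looks up each spectrum's donor label, returned as a factor with levels
#' `control`, `disease` (disease is the positive class throughout).
#' @param x A `spectrum_set`.
#' @return Factor of length `n_spectra(x)`.
#' @export
spectrum_labels <- function(x) {
  lab <- x$donors$label[match(x$donor_id, x$donors$donor_id)]
  factor(lab, levels = c("control", "disease"))
}

#' Subset a spectrum set by spectrum ids
#'
#' Retains only the named spectra (in their original order) and drops donors
#' that no longer have any spectra.
#' @param x A `spectrum_set`.
#' @param ids Character vector of spectrum ids to keep.
#' @return A `spectrum_set`.
#' @export
subset_spectra <- function(x, ids) {
  keep <- x$spectrum_id %in% ids
  if (!any(keep)) stop("no spectra left after subsetting")
  donor_id <- x$donor_id[keep]
  donors <- x$donors[x$donors$donor_id %in% donor_id, , drop = FALSE]
  spectrum_set(x$wavenumbers, x$intensities[keep, , drop = FALSE],
               x$spectrum_id[keep], donor_id, donors)
}

#' Read spectra and donor metadata from CSV
#'
#' The spectral matrix CSV has header `wavenumber,<id1>,<id2>,...` and one
#' row per grid point; the metadata CSV has columns
#' `spectrum_id,donor_id,label,sex,age_bin`. Every spectrum column must have
#' a metadata row and vice versa; orphans are an error, never silently
#' dropped. Grids stored high-to-low (the usual instrument export) are
#' canonicalized to ascending.
#'
#' @param matrix_path Path to the spectral matrix CSV.
#' @param metadata_path Path to the metadata CSV.
#' @return A validated [spectrum_set()].
#' @export
read_spectra <- function(matrix_path, metadata_path) {
  for (p in c(matrix_path, metadata_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  mat <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(mat) < 2L) stop("spectral matrix must have at least one spectrum column")
  if (tolower(names(mat)[1]) != "wavenumber")
    stop("first column of the spectral matrix must be 'wavenumber'")
  wn <- mat[[1]]
  ids <- names(mat)[-1]
  for (j in seq(2L, ncol(mat)))
    if (!is.numeric(mat[[j]]))
      stop("non-numeric intensity in spectrum column '", names(mat)[j], "'")
  intens <- t(as.matrix(mat[, -1, drop = FALSE]))
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("spectrum_id", "donor_id", "label", "sex")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns spectrum_id, donor_id, label, sex, age_bin")
  orphan <- setdiff(ids, meta$spectrum_id)
  if (length(orphan))
    stop("spectra with no metadata row: ", paste(orphan, collapse = ", "))
  extra <- setdiff(meta$spectrum_id, ids)
  if (length(extra))
    stop("metadata rows with no spectrum column: ", paste(extra, collapse = ", "))
  meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
  donors <- unique(meta[, c("donor_id", "label", "sex",
                            intersect("age_bin", names(meta)))])
  if (anyDuplicated(donors$donor_id))
    stop("inconsistent donor metadata: a donor_id appears with conflicting label/sex/age_bin")
  spectrum_set(wn, intens, ids, meta$donor_id, donors)
}

#' Write spectra and donor metadata to CSV
#'
#' Writes the two-file dialect accepted by [read_spectra()];
#' `read_spectra()` after `write_spectra()` reproduces the object up to
#' floating-point formatting (~1e-15 relative).
#'
#' @param x A `spectrum_set`.
#' @param matrix_path Output path for the spectral matrix CSV.
#' @param metadata_path Output path for the metadata CSV.
#' @return Invisibly, `x`.
#' @export
write_spectra <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "spectrum_set"))
  if (nrow(x$donors) == 0L || n_spectra(x) == 0L)
    stop("nothing to write: spectrum set is empty")
  mat <- data.frame(wavenumber = x$wavenumbers, check.names = FALSE)
  mat <- cbind(mat, as.data.frame(t(x$intensities), check.names = FALSE))
  names(mat) <- c("wavenumber", x$spectrum_id)
  utils::write.csv(mat, matrix_path, row.names = FALSE)
  meta <- data.frame(spectrum_id = x$spectrum_id, donor_id = x$donor_id,
                     stringsAsFactors = FALSE)
  idx <- match(meta$donor_id, x$donors$donor_id)
  meta$label <- x$donors$label[idx]
  meta$sex <- x$donors$sex[idx]
  meta$age_bin <- x$donors$age_bin[idx]
  utils::write.csv(meta, metadata_path, row.names = FALSE, na = "")
  invisible(x)
}

#' Crop a spectrum set to a wavenumber region
#'
#' Restricts the grid to the closed interval `[low, high]` (grid values `v`
#' with `low <= v <= high`). Spectrum order, intensities of retained columns
#' and donor links are untouched; cropping is idempotent.
#'
#' @param x A `spectrum_set`.
#' @param low,high Region bounds in cm^-1, `low < high`.
#' @return A `spectrum_set` on the restricted grid.
#' @export
crop_region <- function(x, low, high) {
  stopifnot(inherits(x, "spectrum_set"))
  if (!(is.numeric(low) && is.numeric(high) && low < high))
    stop("need numeric bounds with low < high")
  keep <- x$wavenumbers >= low & x$wavenumbers <= high
  if (!any(keep))
    stop("crop region [", low, ", ", high, "] does not intersect the grid")
  spectrum_set(x$wavenumbers[keep], x$intensities[, keep, drop = FALSE],
               x$spectrum_id, x$donor_id, x$donors)
}
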