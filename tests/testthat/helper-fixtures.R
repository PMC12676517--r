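# Shared fixtures: everything is generated in code at test time.

# A tiny hand-sized spectrum set with random intensities.
tiny_set <- function(n_control = 2L, n_disease = 2L, spectra_per_donor = 3L,
                     n_wn = 24L, seed = 42L) {
  set.seed(seed)
  n_don <- n_control + n_disease
  donor_id <- c(sprintf("C%02d", seq_len(n_control)),
                sprintf("D%02d", seq_len(n_disease)))
  donors <- data.frame(
    donor_id = donor_id,
    label = rep(c("control", "disease"), c(n_control, n_disease)),
    sex = "female", age_bin = "57-70", stringsAsFactors = FALSE)
  spec_donor <- rep(donor_id, each = spectra_per_donor)
  ids <- paste0(spec_donor, "_s", rep(seq_len(spectra_per_donor), n_don))
  wn <- seq(650, by = 10, length.out = n_wn)
  X <- matrix(abs(rnorm(length(ids) * n_wn, 0.5, 0.1)), length(ids), n_wn)
  spectrum_set(wn, X, ids, spec_donor, donors)
}

# Small fast cohort: fingerprint-only grid, fewer donors.
small_cohort_config <- function(..., seed = 1L) {
  cohort_config(
    n_control_donors = 8L, n_disease_donors = 8L,
    wavenumbers = seq(650, 1900, by = 4),
    seed = seed, ...)
}

# Net small enough for sub-second training on small grids.
tiny_net_cfg <- function(..., epochs = 60L, seed = 1L) {
  net_config(window = 30L, stride = 15L, block_units = 4L, head_units = 8L,
             epochs = epochs, seed = seed, ...)
}

# A single-input, single-unit linear network computing f(x) = 2x (for
# x >= 0) with dropout on the input: the stochastic output for input 1 is
# 0 or 2 with equal probability at p = 0.5, so the Monte Carlo dropout
# moments can be enumerated exactly.
linear_unit_net <- function(p = 0.5) {
  cfg <- net_config(window = 1L, stride = 1L, block_units = 1L,
                    head_units = 1L, dropout = p, output = "linear",
                    dropout_site = "input", seed = 1L)
  net <- build_net(cfg, n = 1L)
  set_net_weights(net, list(
    W_blocks = list(matrix(2, 1, 1)), b_blocks = list(matrix(0, 1, 1)),
    W_head = matrix(1, 1, 1), b_head = matrix(0, 1, 1),
    W_out = matrix(1, 1, 1), b_out = 0))
}

# Random uncertainty-report tables for selection-policy property tests.
random_reports <- function(seed) {
  set.seed(seed)
  n_don <- sample(2:8, 1)
  labels <- sample(c("control", "disease"), n_don, replace = TRUE)
  labels[1:2] <- c("control", "disease")  # both classes always present
  donor_id <- sprintf("P%02d", seq_len(n_don))
  rows <- lapply(seq_len(n_don), function(i) {
    k <- sample(1:9, 1)
    data.frame(spectrum_id = sprintf("%s_s%d", donor_id[i], seq_len(k)),
               donor_id = donor_id[i],
               y_hat = runif(k),
               var_y = round(runif(k, 0, 0.25), sample(1:4, 1)),  # ties likely
               T = 100L, stringsAsFactors = FALSE)
  })
  list(reports = do.call(rbind, rows),
       donors = data.frame(donor_id = donor_id, label = labels,
                           stringsAsFactors = FALSE))
}
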