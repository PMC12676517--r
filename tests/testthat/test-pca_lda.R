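# Data with exactly known component variances: orthonormal directions
# scaled so the sample variances along them are as requested.
constructed_variance_data <- function(vars, n = 20, p = 10, seed = 1) {
  set.seed(seed)
  k <- length(vars)
  Q <- qr.Q(qr(matrix(rnorm(p * k), p, k)))        # orthonormal directions
  M <- matrix(rnorm(n * k), n, k)
  S <- qr.Q(qr(sweep(M, 2L, colMeans(M))))         # orthonormal AND centered
  S <- S %*% diag(sqrt(vars * (n - 1)), k)
  S %*% t(Q)
}

test_that("PC count selection matches the explained-variance arithmetic", {
  X <- constructed_variance_data(c(4, 1, 0.25))
  pca <- fit_pca(X, 0.90)
  expect_equal(pca$k, 2L)   # 4/5.25 = 0.762 < 0.90 <= 5/5.25 = 0.952
  expect_equal(fit_pca(X, 0.70)$k, 1L)
  expect_equal(fit_pca(X, 1.0)$k, 3L)  # rank of the centered data
  expect_equal(pca$explained_variance_ratio,
               c(4, 1) / 5.25, tolerance = 1e-8)

  X1 <- constructed_variance_data(2)   # rank-1: one direction of variance
  expect_equal(fit_pca(X1, 0.5)$k, 1L)
  expect_equal(fit_pca(X1, 1.0)$k, 1L)

  expect_error(fit_pca(matrix(1, 5, 4), 0.9), "degenerate")
})

test_that("PCA components are orthonormal and reconstruction improves in k", {
  coh <- generate_cohort(small_cohort_config(seed = 6))
  X <- coh$set$intensities
  pca <- fit_pca(X, 1.0)
  G <- pca$components %*% t(pca$components)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-10)
  errs <- sapply(c(1, 3, 10, pca$k), function(k) {
    C <- pca$components[seq_len(k), , drop = FALSE]
    R <- sweep(X, 2, pca$mean) %*% t(C) %*% C
    sum((sweep(X, 2, pca$mean) - R)^2)
  })
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("LDA recovers the closed-form discriminant direction", {
  # isotropic within-class scatter by construction: direction ~ mu_d - mu_c
  d <- 4
  mu_c <- rep(0, d); mu_d <- c(3, 1, 0, -2)
  pattern <- rbind(diag(d), -diag(d))
  scores <- rbind(sweep(pattern, 2, mu_c, `+`), sweep(pattern, 2, mu_d, `+`))
  labels <- rep(c("control", "disease"), each = 2 * d)
  m <- fit_lda(scores, labels)
  cosang <- sum(m$direction * (mu_d - mu_c)) /
    sqrt(sum((mu_d - mu_c)^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(m$direction^2)), 1, tolerance = 1e-12)

  # random non-singular instances vs the Sw^-1 delta-mu closed form
  set.seed(13)
  for (i in 1:10) {
    S <- matrix(rnorm(60 * 5), 60, 5)
    lab <- rep(c("control", "disease"), 30)
    S[lab == "disease", ] <- S[lab == "disease", ] + rep(runif(5, -1, 1), each = 30)
    m <- fit_lda(S, lab)
    mu_cc <- colMeans(S[lab == "control", ]); mu_dd <- colMeans(S[lab == "disease", ])
    Sw <- (crossprod(sweep(S[lab == "control", ], 2, mu_cc)) +
           crossprod(sweep(S[lab == "disease", ], 2, mu_dd))) / (60 - 2)
    oracle <- solve(Sw, mu_dd - mu_cc)
    oracle <- oracle / sqrt(sum(oracle^2))
    expect_equal(abs(sum(m$direction * oracle)), 1, tolerance = 1e-8)
  }
})

test_that("LDA direction agrees with MASS::lda on well-posed data", {
  skip_if_not_installed("MASS")
  set.seed(14)
  S <- matrix(rnorm(80 * 4), 80, 4)
  lab <- rep(c("control", "disease"), 40)
  S[lab == "disease", 2] <- S[lab == "disease", 2] + 1.5
  m <- fit_lda(S, lab)
  ml <- MASS::lda(S, grouping = lab)
  v <- drop(ml$scaling); v <- v / sqrt(sum(v^2))
  expect_equal(abs(sum(m$direction * v)), 1, tolerance = 1e-6)
})

test_that("mirrored classes give a zero threshold", {
  set.seed(15)
  A <- matrix(rnorm(40 * 3), 40, 3) + matrix(rep(c(2, 0, 0), each = 40), 40)
  scores <- rbind(A, -A)
  labels <- rep(c("disease", "control"), each = 40)
  m <- fit_lda(scores, labels)
  expect_equal(m$threshold, 0, tolerance = 1e-10)
})

test_that("singular within-class scatter falls back to a ridge solve", {
  # scatter confined to the first two coordinates; delta-mu in its range
  base <- rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(0, 1, 0, 0), c(0, -1, 0, 0))
  mu_d <- c(2, 0.5, 0, 0)
  scores <- rbind(base, sweep(base, 2, mu_d, `+`))
  labels <- rep(c("control", "disease"), each = 4)
  m <- fit_lda(scores, labels)
  skip_if_not_installed("MASS")
  mu_cc <- colMeans(scores[labels == "control", ])
  mu_dd <- colMeans(scores[labels == "disease", ])
  Sw <- (crossprod(sweep(scores[labels == "control", ], 2, mu_cc)) +
         crossprod(sweep(scores[labels == "disease", ], 2, mu_dd))) / 6
  oracle <- drop(MASS::ginv(Sw) %*% (mu_dd - mu_cc))
  oracle <- oracle / sqrt(sum(oracle^2))
  expect_gt(abs(sum(m$direction * oracle)), 0.999)
})

test_that("prediction separates a separable toy and breaks ties to control", {
  set.seed(16)
  coh <- generate_cohort(cohort_config(
    n_control_donors = 6, n_disease_donors = 6,
    wavenumbers = seq(650, 1900, by = 8),
    disease_shift = data.frame(low = 956, high = 1210, delta = 0.3),
    ambiguity = 0, noise_sd = 0.001, scatter_sd = 0.01,
    baseline_sd = 0.002, donor_sd = 0.03, seed = 16))
  m <- pca_lda(coh$set)
  pr <- predict(m, coh$set)
  expect_equal(as.character(pr$class),
               as.character(spectrum_labels(coh$set)))

  # a score exactly at the threshold is called control (hand-built model,
  # so the equality is exact in floating point)
  pca0 <- structure(list(mean = c(0, 0), components = diag(2),
                         explained_variance_ratio = c(0.5, 0.5), k = 2L),
                    class = "pca_projection")
  lda0 <- structure(list(direction = c(1, 0), threshold = 0.5,
                         class_means = rbind(control = c(0, 0),
                                             disease = c(1, 0))),
                    class = "lda_model")
  pr0 <- predict_lda(lda0, pca0, matrix(c(0.5, 7), 1))
  expect_identical(pr0$score, 0.5)
  expect_equal(as.character(pr0$class), "control")
  expect_equal(as.character(predict_lda(lda0, pca0,
                                        matrix(c(0.5 + 1e-9, 0), 1))$class),
               "disease")

  pca1 <- fit_pca(coh$set, 0.9)
  expect_error(fit_lda(pca_scores(pca1, coh$set),
                       rep("control", n_spectra(coh$set))), "both classes")
})
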