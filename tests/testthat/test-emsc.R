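make_ref <- function(wn) {
  b <- saliva_bands()
  ftiruq:::gaussian_bands_profile(wn, b$center, b$sigma, b$amplitude)
}

test_that("fitting the reference itself gives b = 1, zero baseline", {
  wn <- seq(650, 3700, by = 10)
  ref <- make_ref(wn)
  m <- emsc_model(ref, 6, wn)
  f <- emsc_fit(m, ref)
  expect_equal(f$b, 1, tolerance = 1e-10)
  expect_lt(max(abs(f$p)), 1e-10)
  expect_lt(f$residual_norm, 1e-8)
  expect_false(f$degenerate)
})

test_that("known multiplicative and polynomial coefficients are recovered", {
  wn <- seq(650, 3700, by = 10)
  ref <- make_ref(wn)
  m <- emsc_model(ref, 6, wn)
  x_norm <- 2 * (wn - min(wn)) / diff(range(wn)) - 1  # the P1 basis column
  raw <- 2 * ref + 0.5 + 0.1 * x_norm
  f <- emsc_fit(m, raw)
  expect_equal(f$b, 2, tolerance = 1e-10)
  expect_equal(f$p[1], 0.5, tolerance = 1e-10)
  expect_equal(f$p[2], 0.1, tolerance = 1e-10)
  expect_lt(max(abs(f$p[3:7])), 1e-10)
  expect_equal(f$corrected, ref, tolerance = 1e-8)
})

test_that("fits agree with a normal-equations least-squares oracle", {
  wn <- seq(650, 3700, by = 10)
  ref <- make_ref(wn)
  m <- emsc_model(ref, 6, wn)
  D <- cbind(ref, legendre_basis(wn, 6))
  set.seed(11)
  for (i in 1:20) {
    raw <- rnorm(1, 1, 0.3) * ref + drop(legendre_basis(wn, 6) %*%
             rnorm(7, 0, 0.1)) + rnorm(length(wn), 0, 0.02)
    f <- emsc_fit(m, raw)
    beta <- solve(crossprod(D), crossprod(D, raw))  # independent oracle
    expect_equal(unname(c(f$b, f$p)), unname(drop(beta)), tolerance = 1e-8)
    expect_equal(f$residual_norm, sqrt(sum((raw - D %*% beta)^2)),
                 tolerance = 1e-8)
  }
})

test_that("projection residual is recovered for off-span components", {
  wn <- seq(650, 1650, by = 10)
  ref <- make_ref(wn)
  m <- emsc_model(ref, 3, wn)
  D <- cbind(ref, legendre_basis(wn, 3))
  set.seed(4)
  raw <- rnorm(length(wn))
  P <- D %*% solve(crossprod(D), t(D))
  perp <- raw - drop(P %*% raw)
  f <- emsc_fit(m, raw)
  expect_equal(f$residual_norm, sqrt(sum(perp^2)), tolerance = 1e-8)
})

test_that("a set built as b*ref + polynomial corrects exactly back to ref", {
  cfg <- small_cohort_config(seed = 5)
  wn <- cfg$wavenumbers
  ref <- make_ref(wn)
  set.seed(5)
  n <- 30
  B6 <- legendre_basis(wn, 6)
  X <- t(sapply(seq_len(n), function(i)
    runif(1, 0.5, 2) * ref + drop(B6 %*% rnorm(7, 0, 0.05))))
  don <- data.frame(donor_id = "C01", label = "control", sex = "female")
  s <- spectrum_set(wn, X, sprintf("s%02d", 1:n), rep("C01", n), don)
  m <- emsc_model(ref, 6, wn)
  out <- emsc_correct(s, m)
  err <- apply(out$set$intensities, 1, function(r)
    sqrt(sum((r - ref)^2)) / sqrt(sum(ref^2)))
  expect_lt(max(err), 1e-8)
  expect_identical(out$set$spectrum_id, s$spectrum_id)
  expect_identical(out$fits$spectrum_id, s$spectrum_id)
})

test_that("correction with the set mean as reference is near-idempotent", {
  # Exact fixed point holds when spectra follow the EMSC corruption model;
  # on realistic cohorts (band-level variability the model does not span)
  # the second pass may still move spectra at the residual scale.
  wn <- seq(650, 1900, by = 4)
  ref <- make_ref(wn)
  set.seed(2)
  B6 <- legendre_basis(wn, 6)
  X <- t(sapply(1:25, function(i)
    runif(1, 0.7, 1.5) * ref + drop(B6 %*% rnorm(7, 0, 0.03)) +
      rnorm(length(wn), 0, 1e-6)))
  s <- spectrum_set(wn, X, sprintf("s%02d", 1:25), rep("C01", 25),
                    data.frame(donor_id = "C01", label = "control",
                               sex = "female"))
  m1 <- emsc_model(colMeans(s$intensities), 6, wn)
  once <- emsc_correct(s, m1)$set
  m2 <- emsc_model(colMeans(once$intensities), 6, wn)
  twice <- emsc_correct(once, m2)$set
  expect_lt(max(abs(twice$intensities - once$intensities)), 1e-6)

  coh <- generate_cohort(small_cohort_config(seed = 2))
  m3 <- emsc_model(colMeans(coh$set$intensities), 6, coh$set$wavenumbers)
  once2 <- emsc_correct(coh$set, m3)$set
  m4 <- emsc_model(colMeans(once2$intensities), 6, coh$set$wavenumbers)
  twice2 <- emsc_correct(once2, m4)$set
  expect_lt(max(abs(twice2$intensities - once2$intensities)), 0.01)
})

test_that("scaling a spectrum scales b and leaves the correction unchanged", {
  wn <- seq(650, 3700, by = 10)
  ref <- make_ref(wn)
  m <- emsc_model(ref, 6, wn)
  set.seed(9)
  raw <- 1.3 * ref + drop(legendre_basis(wn, 6) %*% rnorm(7, 0, 0.05)) +
    rnorm(length(wn), 0, 0.01)
  f1 <- emsc_fit(m, raw)
  f2 <- emsc_fit(m, 5 * raw)
  expect_equal(f2$b, 5 * f1$b, tolerance = 1e-10)
  expect_equal(f2$p, 5 * f1$p, tolerance = 1e-8)
  expect_equal(f2$corrected, f1$corrected, tolerance = 1e-8)
})

test_that("degree 0 reduces to classic MSC (reference + offset)", {
  wn <- seq(650, 1650, by = 10)
  ref <- make_ref(wn)
  m <- emsc_model(ref, 0, wn)
  expect_equal(ncol(m$design), 2L)
  f <- emsc_fit(m, 3 * ref + 0.2)
  expect_equal(f$b, 3, tolerance = 1e-10)
  expect_equal(f$p[1], 0.2, tolerance = 1e-10)
})

test_that("degree 6 has 8 design columns; constant reference is rejected", {
  wn <- seq(650, 3700, by = 10)
  m <- emsc_model(make_ref(wn), 6, wn)
  expect_equal(ncol(m$design), 8L)
  expect_error(emsc_model(rep(1, length(wn)), 6, wn), "rank")
  expect_error(emsc_model(rep(0, length(wn)), 6, wn), "zero")
})

test_that("Legendre basis conditions the design better than raw powers", {
  wn <- seq(650, 3700, length.out = 100)
  ref <- make_ref(wn)
  leg <- cbind(ref, legendre_basis(wn, 6))
  pow <- cbind(ref, outer(wn, 0:6, `^`))  # raw wavenumber powers
  kappa_leg <- kappa(leg, exact = TRUE)
  kappa_pow <- kappa(pow, exact = TRUE)
  expect_true(is.finite(kappa_leg))
  expect_lt(kappa_leg, kappa_pow)
})

test_that("a near-zero multiplicative coefficient is flagged, not divided", {
  wn <- seq(650, 1650, by = 10)
  ref <- make_ref(wn)
  m <- emsc_model(ref, 2, wn)
  raw <- drop(legendre_basis(wn, 2) %*% c(0.4, 0.1, 0.05))  # pure baseline
  f <- emsc_fit(m, raw)
  expect_true(f$degenerate)
  n <- 3
  s <- spectrum_set(wn, rbind(raw, raw, ref), c("a", "b", "c"),
                    rep("C01", n),
                    data.frame(donor_id = "C01", label = "control",
                               sex = "female"))
  expect_warning(out <- emsc_correct(s, m), "1e-6")
  expect_true(all(out$fits$degenerate[1:2]))
  expect_false(out$fits$degenerate[3])
})
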