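fake_donors <- function(n_control, n_disease) {
  data.frame(
    donor_id = c(sprintf("C%02d", seq_len(n_control)),
                 sprintf("D%02d", seq_len(n_disease))),
    label = rep(c("control", "disease"), c(n_control, n_disease)),
    sex = "female", stringsAsFactors = FALSE)
}

test_that("folds are donor-level, stratified and balanced", {
  donors <- fake_donors(11, 10)
  fa <- make_folds(donors, K = 7, seed = 2)
  expect_equal(fa$K, 7L)
  expect_setequal(names(fa$fold_of), donors$donor_id)
  sizes <- table(fa$fold_of)
  expect_true(all(sizes == 3))                       # 21 donors over 7 folds
  for (k in 0:6) {
    ids <- names(fa$fold_of)[fa$fold_of == k]
    lab <- donors$label[match(ids, donors$donor_id)]
    expect_true(all(table(factor(lab, c("control", "disease"))) %in% 1:2))
  }
})

test_that("K equal to the class size gives one donor per class per fold", {
  donors <- fake_donors(4, 4)
  fa <- make_folds(donors, K = 4, seed = 1)
  for (k in 0:3) {
    ids <- names(fa$fold_of)[fa$fold_of == k]
    lab <- donors$label[match(ids, donors$donor_id)]
    expect_equal(sort(lab), c("control", "disease"))
  }
  expect_warning(fa2 <- make_folds(donors, K = 7, seed = 1), "reducing K")
  expect_equal(fa2$K, 4L)
  expect_error(make_folds(donors, K = 1), ">= 2")
})

test_that("majority vote matches exhaustive enumeration of 5-vote patterns", {
  for (pattern in 0:31) {
    votes <- as.integer(intToBits(pattern))[1:5]
    prob <- ifelse(votes == 1, 0.9, 0.1)
    got <- majority_vote(prob, rep("d", 5))
    want <- if (sum(votes) > 2) "disease" else "control"
    expect_equal(as.character(got), want)
  }
  # documented tie rule: 2 vs 2 goes to disease
  expect_equal(as.character(majority_vote(c(0.9, 0.9, 0.1, 0.1), rep("d", 4))),
               "disease")
  expect_equal(as.character(majority_vote(rep(0.2, 5), rep("d", 5))),
               "control")
  expect_error(majority_vote(numeric(0), character(0)), "no spectra")
})

test_that("metric arithmetic matches hand-computed confusions", {
  # disease: 3 of 4 donors correct; control: 2 of 4 -> mean sens 0.625
  pred <- data.frame(
    spectrum_id = sprintf("s%d", 1:8),
    donor_id = sprintf("don%d", 1:8),
    fold = rep(0:1, each = 4),
    prob = c(0.9, 0.9, 0.9, 0.1,   # disease donors: 3 called disease
             0.1, 0.1, 0.9, 0.9),  # control donors: 2 called control
    truth = rep(c("disease", "control"), each = 4),
    stringsAsFactors = FALSE)
  m <- score_report(pred)
  expect_equal(m$donor_accuracy, 5 / 8)
  expect_equal(m$donor_sensitivity, 0.75)
  expect_equal(m$donor_mean_sensitivity, (0.75 + 0.5) / 2)
  expect_equal(m$spectral_accuracy, 5 / 8)   # one spectrum per donor here
  expect_equal(sum(m$confusion_spectral), 8)
  expect_equal(sum(m$confusion_donor), 8)

  # a fold without disease donors reports NA sensitivity there, pooled fine
  pred2 <- pred
  pred2$truth[pred2$fold == 1] <- "control"
  m2 <- score_report(pred2)
  expect_true(is.na(m2$per_fold$donor_sensitivity[m2$per_fold$fold == 1]))
  expect_false(is.na(m2$donor_sensitivity))
})

test_that("pooled confusion equals the sum of per-fold confusions", {
  coh <- generate_cohort(small_cohort_config(seed = 20))
  exp <- run_experiment(coh$set, "pca_lda", K = 4, seed = 20)
  p <- exp$predictions
  p$pred <- ifelse(p$prob > 0.5, "disease", "control")
  per_fold <- lapply(split(p, p$fold), function(pk)
    table(factor(pk$truth, c("control", "disease")),
          factor(pk$pred, c("control", "disease"))))
  expect_equal(unclass(Reduce(`+`, per_fold)),
               unclass(exp$metrics$confusion_spectral),
               ignore_attr = TRUE)
  # every donor evaluated exactly once, in a single fold
  expect_equal(sort(unique(p$donor_id)), sort(coh$set$donors$donor_id))
  expect_true(all(tapply(p$fold, p$donor_id,
                         function(v) length(unique(v))) == 1))
})

test_that("experiments are reproducible and phase-1 equals the plain net", {
  coh <- generate_cohort(small_cohort_config(seed = 21))
  cfg <- tiny_net_cfg(epochs = 15)
  e1 <- run_experiment(coh$set, "nn_uncertainty", K = 3, seed = 5,
                       net = cfg, T = 20)
  e2 <- run_experiment(coh$set, "nn_uncertainty", K = 3, seed = 5,
                       net = cfg, T = 20)
  expect_identical(e1$predictions, e2$predictions)
  expect_equal(e1$metrics$donor_accuracy, e2$metrics$donor_accuracy)

  # the phase-1 model inside nn_uncertainty IS the nn model at equal seeds
  e3 <- run_experiment(coh$set, "nn", K = 3, seed = 5, net = cfg)
  expect_equal(e1$predictions$prob_phase1, e3$predictions$prob)
})

test_that("female-only filtering drops male donors before folding", {
  coh <- generate_cohort(small_cohort_config(seed = 22))
  males <- c("C01", "D01")
  coh$set$donors$sex[coh$set$donors$donor_id %in% males] <- "male"
  exp <- run_experiment(coh$set, "pca_lda", K = 3, seed = 1,
                        female_only = TRUE)
  expect_false(any(exp$predictions$donor_id %in% males))
  expect_equal(length(unique(exp$predictions$donor_id)),
               nrow(coh$set$donors) - 2)
})

test_that("fitted models are untouched by test-fold perturbations", {
  coh <- generate_cohort(small_cohort_config(seed = 23))
  cfg <- tiny_net_cfg(epochs = 10)
  run_fold0 <- function(set) {
    fa <- make_folds(set$donors, K = 3, seed = 9)
    test_donors <- names(fa$fold_of)[fa$fold_of == 0]
    train <- subset_spectra(set, set$spectrum_id[!(set$donor_id %in% test_donors)])
    ref <- colMeans(train$intensities)
    em <- emsc_model(ref, 6, set$wavenumbers)
    train_c <- crop_region(emsc_correct(train, em)$set, 650, 1900)
    list(ref = ref,
         pca_lda = pca_lda(train_c),
         two_phase = two_phase_train(train_c, spectrum_labels(train_c),
                                     cfg, T = 20))
  }
  a <- run_fold0(coh$set)
  perturbed <- coh$set
  fa <- make_folds(coh$set$donors, K = 3, seed = 9)
  test_donors <- names(fa$fold_of)[fa$fold_of == 0]
  rows <- perturbed$donor_id %in% test_donors
  set.seed(1)
  perturbed$intensities[rows, ] <-
    perturbed$intensities[rows, ] + rnorm(sum(rows) * ncol(perturbed$intensities))
  b <- run_fold0(perturbed)
  expect_identical(a$ref, b$ref)
  expect_identical(a$pca_lda, b$pca_lda)
  expect_identical(a$two_phase$phase1$weights, b$two_phase$phase1$weights)
  expect_identical(a$two_phase$phase2$weights, b$two_phase$phase2$weights)
  expect_identical(a$two_phase$mask, b$two_phase$mask)
})
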