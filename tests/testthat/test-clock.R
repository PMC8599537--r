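test_that("the clock recovers a strong age signal sparsely", {
  sim <- simulate_methylation(sim_config(seed = 1))
  fit <- methylclock(sim$betas, sim$sheet$age_years, seed = 1)
  expect_s3_class(fit, "methylclock")
  expect_gte(length(fit$weights), 1)
  expect_lte(length(fit$weights), 200)
  perf <- clock_performance(sim$sheet$age_years, fit$fitted)
  expect_gte(perf$r, 0.95)
  # stored fitted values are reproduced by predict on the training matrix
  expect_lt(max(abs(predict(fit, sim$betas) - fit$fitted)), 1e-8)
  # weights reference only CpGs present in training
  expect_true(all(names(fit$weights) %in% rownames(sim$betas)))
  # provenance
  expect_identical(fit$meta$alpha, 0.5)
  expect_identical(fit$meta$n_samples, ncol(sim$betas))
})

test_that("a perfectly informative CpG is always selected", {
  n <- 40
  for (s in 1:10) {
    x <- noise_betas(50, n, seed = s)
    age <- seq(1, 15, length.out = n)
    x["cg000001", ] <- age / 20          # exact linear image of age
    fit <- methylclock(x, age, seed = s)
    expect_true("cg000001" %in% names(fit$weights))
  }
})

test_that("degenerate inputs are handled as contracts say", {
  x <- matrix(0.5, 50, 24,
              dimnames = list(sprintf("cg%03d", 1:50), paste0("s", 1:24)))
  set.seed(10)
  age <- runif(24, 1, 10)
  fit <- methylclock(x, age, seed = 1)
  expect_length(fit$weights, 0)
  expect_equal(unname(predict(fit, x)), rep(mean(age), 24))
  expect_error(methylclock(x, rep(5, 24)), "degenerate")
  expect_error(methylclock(x[, 1:10], age[1:10], nfolds = 10), "2\\*nfolds")
})

test_that("prediction inverts the transform per species and imputes probes", {
  sim <- tiny_sim(n_cpgs = 300, n = 30, seed = 2)
  tr <- age_transform("relative")
  fit <- methylclock(sim$betas, sim$sheet$age_years,
                     species = rep("marmoset", 30), transform = tr, seed = 2)
  one <- sim$betas[, 1, drop = FALSE]
  both <- cbind(one, one)
  colnames(both) <- c("as_marmoset", "as_human")
  p <- predict(fit, both, species = c("marmoset", "human"))
  expect_equal(unname(p["as_human"] / p["as_marmoset"]), 122.5 / 22.8)
  # mean imputation of a small fraction of model CpGs
  w_cpgs <- names(fit$weights)
  skip_if(length(w_cpgs) < 5)
  drop1 <- w_cpgs[1]
  reduced <- sim$betas[setdiff(rownames(sim$betas), drop1), , drop = FALSE]
  p_full <- predict(fit, sim$betas, species = rep("marmoset", 30))
  p_imp <- predict(fit, reduced, species = rep("marmoset", 30))
  expect_false(isTRUE(all.equal(p_full, p_imp)))
  manual <- sim$betas
  manual[drop1, ] <- fit$training_means[drop1]
  expect_equal(p_imp, predict(fit, manual, species = rep("marmoset", 30)))
  # refusal above 20% missing
  many <- w_cpgs[seq_len(ceiling(0.25 * length(w_cpgs)))]
  expect_error(predict(fit, sim$betas[setdiff(rownames(sim$betas), many), ],
                       species = rep("marmoset", 30)),
               "20%")
})

test_that("performance metrics match hand computation", {
  expect_equal(clock_performance(c(1, 2, 3), c(1, 2, 3)),
               list(r = 1.0, mae = 0.0, n = 3L))
  expect_equal(clock_performance(c(1, 2, 3), c(3, 2, 1)),
               list(r = -1.0, mae = 2.0, n = 3L))
  expect_equal(clock_performance(c(1, 2, 4), c(1, 2, 3))$mae, 0.0)
  expect_error(clock_performance(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(clock_performance(1:4, 1:3), "mismatch")
})

test_that("LOOCV predicts every sample exactly once without leakage", {
  sim <- tiny_sim(n_cpgs = 200, n = 14, seed = 3)
  cv <- loocv_clock(sim$betas, sim$sheet$age_years, seed = 5)
  expect_identical(nrow(cv$predictions), 14L)
  expect_identical(sort(cv$predictions$fold), 1:14)
  expect_identical(cv$predictions$sample_id, colnames(sim$betas))
  expect_true(cv$r >= -1 && cv$r <= 1)
  expect_gte(cv$mae, 0)
  # no leakage: corrupting the held-out sample's betas cannot change the
  # model that predicts it
  j <- 5
  corrupted <- sim$betas
  corrupted[, j] <- 0.99
  clean_fit <- methylclock(sim$betas[, -j], sim$sheet$age_years[-j],
                           nfolds = 6, seed = 5 + j)
  dirty_fit <- methylclock(corrupted[, -j], sim$sheet$age_years[-j],
                           nfolds = 6, seed = 5 + j)
  expect_identical(clean_fit$weights, dirty_fit$weights)
  expect_identical(clean_fit$intercept, dirty_fit$intercept)
  expect_error(loocv_clock(sim$betas[, 1:5], sim$sheet$age_years[1:5]),
               "12")
})

test_that("k-fold CV stratifies by species and reduces to LOOCV at k = n", {
  sim <- simulate_methylation(two_species_config(6, 20, 16,
                                                 n_cpgs = 300))
  tr <- age_transform("relative")
  cv <- kfold_clock(sim$betas, sim$sheet$age_years, sim$sheet$species,
                    k = 4, transform = tr, seed = 9)
  folds <- cv$predictions$fold
  # both species in every training fold (i.e. every fold holds out
  # neither species completely)
  for (f in unique(folds)) {
    train_species <- sim$sheet$species[folds != f]
    expect_setequal(unique(train_species), c("marmoset", "human"))
  }
  expect_identical(nrow(cv$by_stratum), 2L)
  # determinism of fold assignment
  cv2 <- kfold_clock(sim$betas, sim$sheet$age_years, sim$sheet$species,
                     k = 4, transform = tr, seed = 9)
  expect_identical(cv$predictions, cv2$predictions)
  # k = n coincides with LOOCV
  small <- tiny_sim(n_cpgs = 150, n = 13, seed = 7)
  loo <- loocv_clock(small$betas, small$sheet$age_years, seed = 11)
  kn <- kfold_clock(small$betas, small$sheet$age_years, k = 13, seed = 11)
  expect_equal(loo$predictions$predicted_age_years,
               kn$predictions$predicted_age_years)
  # stratum smaller than k falls back with a warning
  expect_warning(
    kfold_clock(sim$betas, sim$sheet$age_years, sim$sheet$species,
                k = 18, transform = tr, seed = 9),
    "unstratified")
})

test_that("LOOCV shows no systematic skill on pure-noise methylation", {
  # null LOOCV R is a high-variance statistic (fold models share any
  # spuriously selected CpGs), so the honest null property is absence of
  # reliable positive skill across seeds, not a tight band per seed
  rs <- vapply(1:10, function(s) {
    sim <- simulate_methylation(sim_config(n_cpgs = 500,
                                           n_per_species = 30,
                                           n_age_cpgs = 0, seed = s))
    loocv_clock(sim$betas, sim$sheet$age_years, seed = s)$r
  }, numeric(1))
  expect_lt(mean(rs), 0.15)
  expect_gt(t.test(atanh(rs), alternative = "greater")$p.value, 0.05)
})
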