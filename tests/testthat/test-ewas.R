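test_that("the correlation screen matches cor.test CpG by CpG", {
  x <- noise_betas(50, 28, seed = 11)
  set.seed(12)
  trait <- runif(28, 0, 16)
  tab <- screen_numeric_trait(x, trait)
  expect_s3_class(tab, "ewas_table")
  for (i in c(1, 7, 25, 50)) {
    ct <- cor.test(x[i, ], trait)
    expect_equal(tab$statistic[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tab$p[i], ct$p.value, tolerance = 1e-12)
  }
  expect_identical(sign(tab$z), sign(tab$statistic))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  # |z| is monotone decreasing in p
  ord <- order(tab$p)
  expect_true(all(diff(abs(tab$z)[ord]) <= 1e-12))
})

test_that("screen closed form: r = 0.5 at n = 27 gives t = 2.8868", {
  # construct a CpG with empirical correlation exactly 0.5
  n <- 27
  set.seed(13)
  trait <- rnorm(n)
  zt <- as.vector(scale(trait))
  resid <- rnorm(n)
  resid <- resid - zt * sum(resid * zt) / sum(zt^2)
  zr <- as.vector(scale(resid))
  cpg <- 0.5 + 0.1 * (0.5 * zt + sqrt(0.75) * zr)
  x <- rbind(cg000001 = cpg, cg000002 = runif(n))
  tab <- screen_numeric_trait(x, trait)
  expect_equal(tab$statistic[1], 0.5, tolerance = 1e-12)
  tstat <- 0.5 * sqrt(25) / sqrt(0.75)
  expect_equal(tstat, 2.886751, tolerance = 1e-6)
  expect_equal(tab$p[1], 2 * pt(tstat, 25, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(tab$p[1], 0.00791274, tolerance = 1e-6)
  # a CpG equal to the trait is a perfect hit
  y <- rbind(cg000001 = (trait - min(trait)) / diff(range(trait)) * 0.8 + 0.1,
             cg000002 = runif(n))
  tab2 <- screen_numeric_trait(y, trait)
  expect_equal(tab2$statistic[1], 1, tolerance = 1e-12)
  expect_lt(tab2$p[1], 1e-30)
})

test_that("constant CpGs are flagged, not propagated as NaN", {
  x <- noise_betas(5, 20, seed = 14)
  x[3, ] <- 0.42
  tab <- screen_numeric_trait(x, seq_len(20))
  expect_identical(tab$p[3], 1)
  expect_identical(tab$z[3], 0)
  expect_true(tab$degenerate[3])
  expect_false(any(tab$degenerate[-3]))
  expect_error(screen_numeric_trait(x, rep(1, 20)), "constant")
})

test_that("the covariate EWAS agrees with per-CpG lm fits", {
  x <- noise_betas(30, 26, seed = 15)
  set.seed(16)
  group <- rep_len(c(0, 1), 26)
  age <- runif(26, 1, 12)
  tab <- ewas_covariate(x, group, cbind(age = age))
  for (i in c(1, 10, 30)) {
    fit <- summary(lm(x[i, ] ~ group + age))$coefficients
    expect_equal(tab$statistic[i], fit["group", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(tab$p[i], fit["group", "Pr(>|t|)"], tolerance = 1e-10)
  }
  # equivalence of the correlation screen and the unadjusted group EWAS
  sc <- screen_numeric_trait(x, group)
  un <- ewas_covariate(x, group)
  expect_equal(sc$p, un$p, tolerance = 1e-10)
  # rank-deficient design names the collinear column
  expect_error(ewas_covariate(x, group, cbind(twice = 2 * group)),
               "collinear.*twice")
})

test_that("an age covariate removes age-confounded signal from the top ranks", {
  sim <- tiny_sim(n_cpgs = 400, n = 60, n_age = 20, seed = 17)
  old <- as.numeric(sim$sheet$age_years > median(sim$sheet$age_years))
  raw <- ewas_covariate(sim$betas, old)
  adj <- ewas_covariate(sim$betas, old, cbind(age = sim$sheet$age_years))
  age_cpgs <- sim$truth$cpg_id[sim$truth$role == "age"]
  top20 <- function(tab) tab$cpg_id[order(-abs(tab$z))][1:20]
  expect_gt(sum(top20(raw) %in% age_cpgs),
            sum(top20(adj) %in% age_cpgs))
})

test_that("an injected treatment CpG dominates the adjusted group EWAS", {
  sim <- simulate_methylation(sim_config(
    n_cpgs = 1000, n_treatment_cpgs = 5, treatment_effect = 0.2,
    precision = 200, seed = 18))
  arm <- sim$sheet$treatment %in% c("control", "rapamycin")
  grp <- as.numeric(sim$sheet$treatment[arm] == "rapamycin")
  tab <- ewas_covariate(sim$betas[, arm], grp,
                        cbind(age = sim$sheet$age_years[arm]))
  cut99 <- quantile(abs(tab$z), 0.99)
  tr_cpgs <- sim$truth$cpg_id[sim$truth$role == "treatment"]
  expect_true(all(abs(tab$z[tab$cpg_id %in% tr_cpgs]) >= cut99))
})

test_that("Stouffer combination matches its closed forms", {
  expect_equal(stouffer_meta(matrix(1.7)), 1.7, ignore_attr = TRUE)
  z <- matrix(c(1.96, 1.96), 1)
  expect_equal(as.numeric(stouffer_meta(z)), 1.96 * sqrt(2),
               tolerance = 1e-10)
  expect_equal(as.numeric(stouffer_meta(matrix(c(2.5, -2.5), 1))), 0)
  # k identical strata scale by sqrt(k)
  for (k in c(2, 3, 7)) {
    zz <- matrix(1.3, 4, k)
    expect_equal(as.numeric(stouffer_meta(zz)), rep(1.3 * sqrt(k), 4),
                 tolerance = 1e-10)
  }
  # sqrt(n) weighting
  z2 <- matrix(c(2, 1), 1)
  expect_equal(as.numeric(stouffer_meta(z2, n_per_stratum = c(100, 25))),
               (10 * 2 + 5 * 1) / sqrt(125), tolerance = 1e-10)
  # missing strata drop with renormalization
  z3 <- matrix(c(1.5, NA, 2, 2), 2)
  out <- stouffer_meta(z3)
  expect_equal(as.numeric(out), c((1.5 + 2) / sqrt(2), 2))
  expect_identical(as.integer(attr(out, "n_strata_used")), c(2L, 1L))
  expect_error(stouffer_meta(z, weights = c(1, -1)), "positive")
})

test_that("top-CpG selection is strict at the threshold and caps per direction", {
  tab <- data.frame(cpg_id = paste0("cg", 1:5),
                    z = c(5, 4, 3, 2, 1),
                    p = c(0.001, 0.004, 0.005, 0.01, 0.5))
  sel <- select_top_cpgs(tab)
  expect_identical(sel$cpg_id, c("cg1", "cg2"))
  # 600 significant positives are capped at the 500 largest |z|
  big <- data.frame(cpg_id = sprintf("cg%04d", 1:600),
                    z = seq(601, 2, length.out = 600),
                    p = rep(1e-4, 600))
  sel2 <- select_top_cpgs(big)
  expect_identical(nrow(sel2), 500L)
  expect_setequal(sel2$cpg_id, big$cpg_id[order(-big$z)][1:500])
  # empty result allowed
  expect_identical(nrow(select_top_cpgs(tab, p_threshold = 1e-6)), 0L)
  # invariance to input row order
  set.seed(19)
  shuffled <- big[sample.int(600), ]
  expect_identical(select_top_cpgs(shuffled), sel2)
  # ties break lexicographically by cpg_id
  ties <- data.frame(cpg_id = c("cgB", "cgA", "cgC"), z = c(3, 3, 3),
                     p = rep(1e-4, 3))
  expect_identical(select_top_cpgs(ties, max_per_direction = 2)$cpg_id,
                   c("cgA", "cgB"))
})

test_that("region distributions match the exact hypergeometric tail", {
  ids <- sprintf("cg%03d", 1:100)
  classes <- rep(c("promoter", "intron"), c(10, 90))
  ann <- toy_annotation(ids, classes)
  # 4 of 5 set members in promoters against 10/100 background
  cpg_set <- c(ids[1:4], ids[15])
  out <- region_distribution(cpg_set, ann)
  prom <- out[out$region_class == "promoter", ]
  expect_identical(prom$fg_count, 4L)
  expect_equal(prom$fg_prop, 0.8)
  expect_equal(prom$bg_prop, 0.1)
  # independent oracle: explicit upper-tail sum of the hypergeometric pmf
  oracle <- sum(dhyper(4:5, 10, 90, 5))
  expect_equal(prom$p_enrichment, oracle, tolerance = 1e-12)
  expect_equal(oracle, 2.543848e-4, tolerance = 1e-6)
  # set = background reproduces background proportions exactly
  all_out <- region_distribution(ids, ann)
  expect_equal(all_out$fg_prop, all_out$bg_prop)
  # empty set: zero counts, no p-values
  empty <- region_distribution(character(0), ann)
  expect_true(all(empty$fg_count == 0))
  expect_true(all(is.na(empty$p_enrichment)))
  expect_error(region_distribution(c("cgXXX"), ann), "cgXXX")
})

test_that("exclusive set intersections count like brute-force enumeration", {
  two <- set_overlap(list(A = c("a", "b", "c"), B = c("d", "e", "f", "g")))
  expect_identical(two$count[two$A & !two$B], 3L)
  expect_identical(two$count[!two$A & two$B], 4L)
  expect_identical(two$count[two$A & two$B], 0L)
  same <- set_overlap(list(A = letters[1:5], B = letters[1:5]))
  expect_identical(same$count[same$A & same$B], 5L)
  expect_identical(sum(same$count), 5L)
  sets <- list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = "3")
  out <- set_overlap(sets)
  # brute-force oracle over the union
  u <- unique(unlist(sets))
  brute <- table(vapply(u, function(el) {
    paste(vapply(sets, function(s) el %in% s, logical(1)), collapse = ".")
  }, character(1)))
  for (i in seq_len(nrow(out))) {
    key <- paste(unlist(out[i, c("A", "B", "C")]), collapse = ".")
    expected <- if (key %in% names(brute)) as.integer(brute[[key]]) else 0L
    expect_identical(out$count[i], expected)
  }
  expect_identical(sum(out$count), length(u))
  expect_error(set_overlap(list(A = "x")), "at least 2")
})
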