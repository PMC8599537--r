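#' Configuration for the methylation-array simulator
#'
#' Describes a synthetic conserved-CpG array study: one or more species with
#' age ranges and maximum lifespans, counts of age-, sex-, and
#' treatment-associated CpGs, beta-scale effect amplitudes, and the
#' beta-distribution concentration that sets array noise.
#'
#' Age-associated CpGs drift linearly in *relative* age (age divided by the
#' species' maximum lifespan), so the aging signal is shared across species
#' on the relative-age scale by construction — the property a dual-species
#' relative-age clock exploits. Sex and treatment CpGs carry constant
#' group offsets. Defaults emulate a marmoset blood cohort: 2,000 probes,
#' 60 samples aged 0.5–15.5 y, 20 age CpGs of amplitude 0.4, noise
#' precision 100, no sex CpGs (marmoset blood is hematopoietically chimeric,
#' which blurs methylation sex signals), and a null treatment effect.
#'
#' @param n_cpgs number of probes.
#' @param n_per_species samples per species, recycled over `species`.
#' @param species named list; each element a list with `max_lifespan`
#'   (years) and `age_range` (length-2, years).
#' @param n_age_cpgs,n_sex_cpgs,n_treatment_cpgs counts of signal CpGs;
#'   their sum must not exceed `n_cpgs`.
#' @param age_effect,sex_effect,treatment_effect beta-scale amplitudes in
#'   \[0, 1\]. `treatment_effect = 0` gives a truly null intervention.
#' @param precision beta-distribution concentration `> 0`; larger is less
#'   noisy (variance is `mean * (1 - mean) / (precision + 1)`).
#' @param treated_fraction fraction of the eligible (older) stratum
#'   assigned to treatment.
#' @param seed integer seed; identical configs with identical seeds give
#'   identical datasets.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cpgs = 2000,
                       n_per_species = 60,
                       species = list(
                         marmoset = list(max_lifespan = 22.8,
                                         age_range = c(0.5, 15.5))),
                       n_age_cpgs = 20,
                       n_sex_cpgs = 0,
                       n_treatment_cpgs = 0,
                       age_effect = 0.4,
                       sex_effect = 0.1,
                       treatment_effect = 0,
                       precision = 100,
                       treated_fraction = 0.46,
                       seed = 1) {
  if (n_cpgs < 1 || any(n_per_species < 1))
    stop("need at least one CpG and one sample per species")
  if (n_age_cpgs + n_sex_cpgs + n_treatment_cpgs > n_cpgs)
    stop("signal CpG counts exceed n_cpgs")
  if (is.null(names(species)) || any(!nzchar(names(species))))
    stop("'species' must be a named list")
  for (sp in species) {
    if (sp$max_lifespan <= 0) stop("max_lifespan must be positive")
    if (length(sp$age_range) != 2 || diff(sp$age_range) <= 0 ||
        any(sp$age_range < 0))
      stop("age_range must be an increasing non-negative pair")
  }
  for (a in c(age_effect, sex_effect, treatment_effect))
    if (a < 0 || a > 1) stop("effect amplitudes must lie in [0, 1]")
  if (precision <= 0) stop("'precision' must be positive")
  if (treated_fraction < 0 || treated_fraction > 1)
    stop("'treated_fraction' must lie in [0, 1]")
  structure(
    list(n_cpgs = n_cpgs,
         n_per_species = rep_len(n_per_species, length(species)),
         species = species,
         n_age_cpgs = n_age_cpgs, n_sex_cpgs = n_sex_cpgs,
         n_treatment_cpgs = n_treatment_cpgs,
         age_effect = age_effect, sex_effect = sex_effect,
         treatment_effect = treatment_effect,
         precision = precision, treated_fraction = treated_fraction,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Expected beta value of a CpG for one sample
#'
#' Mean of the beta-value noise distribution before sampling. Age CpGs are
#' linear in relative age (`baseline + direction * amplitude * relative_age`);
#' sex CpGs add a constant offset for females, treatment CpGs for treated
#' samples; null CpGs sit at baseline. Means are clipped to \[0.01, 0.99\]
#' to keep the beta-noise parameters finite.
#'
#' @param relative_age fraction(s) of maximum lifespan in \[0, 1\].
#' @param role one of `"age"`, `"sex"`, `"treatment"`, `"null"`.
#' @param baseline baseline methylation fraction in (0, 1).
#' @param direction `+1` (hypermethylation with the condition) or `-1`.
#' @param amplitude beta-scale effect size.
#' @param sex `"F"` or `"M"` (sex CpGs shift females).
#' @param treated logical (treatment CpGs shift treated samples).
#' @return expected beta in \[0.01, 0.99\].
#' @export
trajectory_mean <- function(relative_age, role, baseline, direction = 1,
                            amplitude = 0, sex = "F", treated = FALSE) {
  if (any(relative_age < 0) || any(relative_age > 1))
    stop("relative_age must lie in [0, 1]")
  m <- switch(role,
    age       = baseline + direction * amplitude * relative_age,
    sex       = baseline + direction * amplitude * (sex == "F"),
    treatment = baseline + direction * amplitude * treated,
    null      = baseline + 0 * relative_age,
    stop("unknown role: ", role))
  pmin(pmax(m, 0.01), 0.99)
}

#' Draw a beta value around a target mean
#'
#' Noise model for array beta values: `Beta(mean * precision,
#' (1 - mean) * precision)`, whose expectation is `mean` and variance
#' `mean * (1 - mean) / (precision + 1)`. Respects the \[0, 1\] support of
#' methylation fractions.
#'
#' @param mean target mean(s), strictly inside (0, 1).
#' @param precision concentration `> 0`.
#' @param n number of draws (defaults to `length(mean)`).
#' @return beta value(s) in \[0, 1\].
#' @export
sample_beta <- function(mean, precision, n = length(mean)) {
  if (any(mean <= 0) || any(mean >= 1))
    stop("'mean' must lie strictly inside (0, 1)")
  if (any(precision <= 0)) stop("'precision' must be positive")
  stats::rbeta(n, mean * precision, (1 - mean) * precision)
}

#' Simulate a methylation-array dataset with known truth
#'
#' Generates a CpG-by-sample beta matrix, a sample sheet, and a truth table
#' recording each probe's role, direction, and amplitude. Ages are drawn
#' uniformly over each species' range; sexes are balanced. Treatment arms
#' (`"control"` / `"rapamycin"`) are assigned only within the older
#' (above-median-age) stratum of the first species, mirroring an
#' intervention cohort of middle-aged animals; all other samples carry
#' `treatment = "none"` and form the clock-training cohort.
#'
#' @param config a [sim_config()].
#' @return a `methyl_sim` list with elements `betas` (matrix, CpG rows ×
#'   sample columns), `sheet` (data.frame: sample_id, age_years, sex,
#'   species, tissue, treatment), and `truth` (data.frame: cpg_id, role,
#'   direction, amplitude, baseline).
#' @examples
#' sim <- simulate_methylation(sim_config(n_cpgs = 200, n_per_species = 20))
#' dim(sim$betas)
#' @export
simulate_methylation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_cpgs <- config$n_cpgs

  ## --- truth table ------------------------------------------------------
  cpg_id <- sprintf("cg%06d", seq_len(n_cpgs))
  role <- rep("null", n_cpgs)
  idx <- sample.int(n_cpgs,
                    config$n_age_cpgs + config$n_sex_cpgs +
                      config$n_treatment_cpgs)
  role[idx] <- rep(c("age", "sex", "treatment"),
                   c(config$n_age_cpgs, config$n_sex_cpgs,
                     config$n_treatment_cpgs))
  direction <- sample(c(-1L, 1L), n_cpgs, replace = TRUE)
  amplitude <- numeric(n_cpgs)
  amplitude[role == "age"] <- config$age_effect
  amplitude[role == "sex"] <- config$sex_effect
  amplitude[role == "treatment"] <- config$treatment_effect
  ## baseline drawn so baseline and baseline + direction*amplitude both
  ## stay in [0.05, 0.95]: effects are not flattened by clipping
  lo <- 0.05 + pmax(0, -direction * amplitude)
  hi <- 0.95 - pmax(0, direction * amplitude)
  baseline <- stats::runif(n_cpgs, lo, hi)
  truth <- data.frame(cpg_id = cpg_id, role = role, direction = direction,
                      amplitude = amplitude, baseline = baseline,
                      stringsAsFactors = FALSE)

  ## --- sample sheet -----------------------------------------------------
  sp_names <- names(config$species)
  sheets <- vector("list", length(sp_names))
  for (k in seq_along(sp_names)) {
    n_k <- config$n_per_species[k]
    rng <- config$species[[k]]$age_range
    sheets[[k]] <- data.frame(
      sample_id = sprintf("%s_%03d", sp_names[k], seq_len(n_k)),
      age_years = stats::runif(n_k, rng[1], rng[2]),
      sex = rep_len(c("F", "M"), n_k),
      species = sp_names[k],
      tissue = "blood",
      treatment = "none",
      stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, sheets)
  ## treatment within the older stratum of the first species
  first <- sheet$species == sp_names[1]
  older <- first & sheet$age_years > stats::median(sheet$age_years[first])
  eligible <- which(older)
  if (length(eligible) >= 2) {
    n_treat <- round(config$treated_fraction * length(eligible))
    treated <- sample(eligible, n_treat)
    sheet$treatment[eligible] <- "control"
    sheet$treatment[treated] <- "rapamycin"
  }

  ## --- beta matrix ------------------------------------------------------
  ml <- vapply(config$species, `[[`, numeric(1), "max_lifespan")
  rel_age <- sheet$age_years / ml[sheet$species]
  rel_age <- pmin(rel_age, 1)    # an animal at the recorded maximum
  is_f <- as.numeric(sheet$sex == "F")
  is_t <- as.numeric(sheet$treatment == "rapamycin")
  eff <- direction * amplitude
  mu <- matrix(baseline, n_cpgs, nrow(sheet))
  mu[role == "age", ] <- mu[role == "age", , drop = FALSE] +
    outer(eff[role == "age"], rel_age)
  mu[role == "sex", ] <- mu[role == "sex", , drop = FALSE] +
    outer(eff[role == "sex"], is_f)
  mu[role == "treatment", ] <- mu[role == "treatment", , drop = FALSE] +
    outer(eff[role == "treatment"], is_t)
  mu <- pmin(pmax(mu, 0.01), 0.99)
  betas <- matrix(sample_beta(as.vector(mu), config$precision),
                  n_cpgs, nrow(sheet),
                  dimnames = list(cpg_id, sheet$sample_id))

  structure(list(betas = betas, sheet = sheet, truth = truth,
                 config = config),
            class = "methyl_sim")
}

#' @export
print.methyl_sim <- function(x, ...) {
  cat("Simulated methylation dataset:",
      nrow(x$betas), "CpGs x", ncol(x$betas), "samples\n")
  cat("  species:", paste(names(x$config$species), collapse = ", "), "\n")
  cat("  signal CpGs:", sum(x$truth$role == "age"), "age,",
      sum(x$truth$role == "sex"), "sex,",
      sum(x$truth$role == "treatment"), "treatment\n")
  tab <- table(x$sheet$treatment)
  cat("  treatment arms:",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
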