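#' Multivariate regression test of a treatment effect on DNAm age
#'
#' Ordinary least squares of DNAm age (years) on chronological age, a
#' female indicator, and a treatment indicator — the layout of an
#' intervention test where the clock was trained on a disjoint cohort and
#' applied to the control and treated animals. Per-term estimate, standard
#' error, t, and two-sided p are reported along with the model R-squared.
#'
#' Leakage is checked explicitly: if `training_ids` is supplied, any
#' overlap between the test samples and the clock-training samples is an
#' error.
#'
#' @param dnam_age_years DNAm age predictions in years, one per row of
#'   `sheet`.
#' @param sheet data.frame with columns `age_years`, `sex` (`"F"`/`"M"`),
#'   `treatment` (`"control"`/`"rapamycin"`), and optionally `sample_id`.
#' @param training_ids sample ids the clock was trained on, for the
#'   disjointness check.
#' @param covariates which covariates to adjust for: any subset of
#'   `c("age", "sex")`. With `character(0)` the model reduces to a
#'   two-group comparison of DNAm age.
#' @return a `clock_regression` object: `coefficients` table (estimate,
#'   se, t, p per term), `r_squared`, `n`.
#' @export
treatment_effect <- function(dnam_age_years, sheet, training_ids = NULL,
                             covariates = c("age", "sex")) {
  if (length(dnam_age_years) != nrow(sheet))
    stop("one DNAm age per sheet row required")
  if (!is.null(training_ids) && "sample_id" %in% names(sheet)) {
    leak <- intersect(sheet$sample_id, training_ids)
    if (length(leak))
      stop("leakage: test samples also in clock training set: ",
           paste(utils::head(leak, 5), collapse = ", "))
  }
  if (length(covariates))
    covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  if (!all(sheet$treatment %in% c("control", "rapamycin")))
    stop("'treatment' must be 'control' or 'rapamycin' for every sample")
  dat <- data.frame(dnam_age = dnam_age_years,
                    Age = sheet$age_years,
                    Female = as.numeric(sheet$sex == "F"),
                    Rapamycin = as.numeric(sheet$treatment == "rapamycin"))
  terms <- c(if ("age" %in% covariates) "Age",
             if ("sex" %in% covariates) "Female",
             "Rapamycin")
  if (length(unique(dat$Rapamycin)) < 2)
    stop("both treatment arms must be present")
  fml <- stats::reformulate(terms, response = "dnam_age")
  fit <- stats::lm(fml, data = dat)
  if (nrow(dat) < length(terms) + 1 + 3)
    stop("need at least 3 more samples than model terms")
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(coefficients = data.frame(term = rownames(co),
                                   estimate = co[, 1], se = co[, 2],
                                   t = co[, 3], p = co[, 4],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
         r_squared = sm$r.squared,
         n = nrow(dat),
         outcome = "DNAmAge"),
    class = "clock_regression")
}

#' @export
print.clock_regression <- function(x, ...) {
  cat(sprintf("Outcome: %s, R-sq. = %.0f%% (n = %d)\n",
              x$outcome, 100 * x$r_squared, x$n))
  co <- x$coefficients
  cat(sprintf("  %-12s %10s %10s %10s\n", "", "Coef", "Std. error",
              "P value"))
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-12s %10.3f %10.3g %10.3g\n",
                co$term[i], co$estimate[i], co$se[i], co$p[i]))
  invisible(x)
}

#' Epigenetic age acceleration
#'
#' The residual of DNAm age regressed on chronological age: positive
#' values mean epigenetically older than expected for the chronological
#' age. Residuals have mean zero and are uncorrelated with chronological
#' age by construction.
#'
#' @param dnam_age_years DNAm age in years.
#' @param age_years chronological age in years, non-constant,
#'   `length >= 3`.
#' @return numeric vector of residuals in years.
#' @export
age_acceleration <- function(dnam_age_years, age_years) {
  if (length(dnam_age_years) != length(age_years))
    stop("length mismatch")
  if (length(age_years) < 3) stop("need at least 3 samples")
  if (stats::var(age_years) == 0) stop("ages are constant")
  unname(stats::residuals(stats::lm(dnam_age_years ~ age_years)))
}

#' Out-of-bag random-forest sex predictor
#'
#' Trains a random-forest classifier of sex on beta values and scores
#' each sample by the majority vote of the trees for which it was
#' out-of-bag, giving an honest accuracy estimate without a held-out set.
#' Defaults: 500 trees, `sqrt(p)` candidate features per split, unlimited
#' depth. In a species whose blood is hematopoietically chimeric, this
#' accuracy is expected to sit near chance even at large n.
#'
#' @param betas CpG x sample beta matrix.
#' @param sex character or factor of sex labels, both classes present.
#' @param n_trees number of trees.
#' @param seed integer seed; identical inputs and seed reproduce the
#'   report exactly.
#' @return a `sex_oob` object: `oob_accuracy`, per-sample OOB `votes`
#'   (fraction for the true class), `predicted`, `n_trees`, `seed`.
#' @export
sex_predictor_oob <- function(betas, sex, n_trees = 500, seed = 1) {
  betas <- .check_betas(betas)
  y <- factor(sex)
  if (nlevels(y) < 2) stop("both sexes must be present")
  if (length(y) != ncol(betas)) stop("one label per sample required")
  set.seed(seed)
  rf <- randomForest::randomForest(x = t(betas), y = y, ntree = n_trees)
  pred <- rf$predicted
  votes <- rf$votes[cbind(seq_along(y), as.integer(y))]
  structure(
    list(oob_accuracy = mean(pred == y, na.rm = TRUE),
         votes = stats::setNames(votes, colnames(betas)),
         predicted = stats::setNames(as.character(pred), colnames(betas)),
         confusion = table(truth = y, oob = pred),
         n_trees = n_trees, seed = seed, n = length(y)),
    class = "sex_oob")
}

#' @export
print.sex_oob <- function(x, ...) {
  cat(sprintf("Random-forest sex predictor (%d trees, n = %d)\n",
              x$n_trees, x$n))
  cat(sprintf("  out-of-bag accuracy: %.1f%%\n", 100 * x$oob_accuracy))
  invisible(x)
}
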