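#' Fit a sparse elastic-net epigenetic clock
#'
#' Regresses a transform of chronological age on CpG beta values with an
#' elastic-net penalty (mixing fraction `alpha = 0.5` by convention, not
#' tuned), selecting the penalty strength that minimizes internal
#' cross-validated mean-squared error over glmnet's descending penalty
#' path (ties resolve to the larger penalty, i.e. the sparser model).
#' Predictors are standardized internally by the fitting routine; the
#' returned weights are on the original beta scale.
#'
#' @param betas numeric matrix, CpG rows x sample columns, values in
#'   \[0, 1\], rownames = CpG ids.
#' @param ages chronological ages in years, one per sample column.
#' @param species character vector of species labels per sample; required
#'   when `transform` is `relative` or `loglinear`.
#' @param transform an [age_transform()]; default identity (single-species
#'   clock in years).
#' @param alpha elastic-net mixing fraction in \[0, 1\]; 0.5 by default.
#' @param nfolds internal cross-validation folds for penalty selection.
#' @param seed integer seed governing the internal fold assignment.
#' @return an object of class `methylclock`: intercept, sparse `weights`
#'   (named, nonzero only), `training_means` for missing-probe imputation,
#'   the `transform`, stored `fitted` ages (years), and `meta` provenance
#'   (n, p, alpha, penalty chosen, seed, species counts).
#' @seealso [predict.methylclock()], [loocv_clock()], [kfold_clock()]
#' @export
methylclock <- function(betas, ages, species = NULL,
                        transform = age_transform("identity"),
                        alpha = 0.5, nfolds = 10, seed = 1) {
  betas <- .check_betas(betas)
  n <- ncol(betas)
  if (length(ages) != n)
    stop("'ages' must have one entry per sample column")
  if (stats::var(ages) == 0)
    stop("degenerate response: all ages are identical")
  if (!is.null(species)) species <- rep_len(as.character(species), n)
  if (n < 2 * nfolds)
    stop("need at least 2*nfolds = ", 2 * nfolds, " samples, got ", n)

  y <- transform_age(transform, ages, species)
  x <- t(betas)

  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) {
    ## no predictor variance: intercept-only model at the mean response
    intercept <- mean(y)
    weights <- stats::setNames(numeric(0), character(0))
    training_means <- stats::setNames(numeric(0), character(0))
    lambda <- Inf
  } else {
    set.seed(seed)
    ## cv.glmnet warns (benignly) that it switches to ungrouped CV error
    ## estimates when folds hold < 3 samples; routine at LOOCV sizes
    cvfit <- withCallingHandlers(
      glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = nfolds,
                        family = "gaussian"),
      warning = function(w) {
        if (grepl("grouped=FALSE enforced", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    lambda <- cvfit$lambda.min
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1]
    intercept <- cf[1]
    w <- cf[-1]
    w <- w[w != 0]
    weights <- w
    training_means <- colMeans(x)[names(w)]
  }

  score <- intercept + as.vector(x[, names(weights), drop = FALSE] %*%
                                   weights)
  fitted <- inverse_age(transform, score, species)

  structure(
    list(intercept = unname(intercept),
         weights = weights,
         training_means = training_means,
         transform = transform,
         fitted = stats::setNames(fitted, colnames(betas)),
         sample_ids = colnames(betas),
         meta = list(n_samples = n, n_cpgs_input = nrow(betas),
                     alpha = alpha, lambda = lambda, nfolds = nfolds,
                     seed = seed,
                     species = if (is.null(species)) NULL else table(species))),
    class = "methylclock")
}

.check_betas <- function(betas) {
  if (!is.matrix(betas)) betas <- as.matrix(betas)
  if (is.null(rownames(betas)))
    stop("'betas' must carry CpG ids as rownames")
  if (anyNA(betas))
    stop("missing beta values: impute before fitting")
  if (anyDuplicated(rownames(betas)))
    stop("duplicate CpG ids in 'betas'")
  betas
}

#' @export
print.methylclock <- function(x, ...) {
  cat("Epigenetic clock (elastic net, alpha =", x$meta$alpha, ")\n")
  cat("  transform:", x$transform$kind, "\n")
  cat("  CpGs with nonzero weight:", length(x$weights), "of",
      x$meta$n_cpgs_input, "\n")
  cat("  trained on", x$meta$n_samples, "samples; penalty =",
      signif(x$meta$lambda, 4), "\n")
  invisible(x)
}

#' @export
summary.methylclock <- function(object, ...) {
  print(object)
  if (length(object$weights)) {
    ord <- order(-abs(object$weights))
    top <- utils::head(object$weights[ord], 10)
    cat("  largest |weights|:\n")
    print(signif(top, 4))
  }
  invisible(object)
}

#' @export
coef.methylclock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Predict DNAm age from a fitted clock
#'
#' Computes the linear score `intercept + sum(w_j * beta_j)` and inverts
#' the training transform to years using each sample's species parameters.
#' Model CpGs absent from `betas` are imputed at their stored training
#' means; more than 20% missing is refused rather than silently
#' extrapolated.
#'
#' @param object a [methylclock()] fit.
#' @param betas CpG x sample beta matrix to predict on.
#' @param species species label per sample (required for relative and
#'   log-linear clocks).
#' @param ... unused.
#' @return named numeric vector of DNAm age predictions in years.
#' @export
predict.methylclock <- function(object, betas, species = NULL, ...) {
  betas <- .check_betas(betas)
  w <- object$weights
  if (length(w)) {
    missing <- setdiff(names(w), rownames(betas))
    if (length(missing) > 0.2 * length(w))
      stop(length(missing), " of ", length(w),
           " model CpGs missing from input (> 20%); refusing to predict")
    x <- matrix(rep(object$training_means, ncol(betas)),
                nrow = length(w), ncol = ncol(betas),
                dimnames = list(names(w), colnames(betas)))
    present <- intersect(names(w), rownames(betas))
    x[present, ] <- betas[present, , drop = FALSE]
    score <- object$intercept + as.vector(crossprod(x, w))
  } else {
    score <- rep(object$intercept, ncol(betas))
  }
  if (!is.null(species))
    species <- rep_len(as.character(species), ncol(betas))
  stats::setNames(inverse_age(object$transform, score, species),
                  colnames(betas))
}

#' Clock accuracy: age correlation R and median absolute error
#'
#' The two accuracy metrics reported for epigenetic clocks: `r`, the
#' Pearson correlation between DNAm age and chronological age, and `mae`,
#' the median absolute error in years.
#'
#' @param true_age_years,pred_age_years equal-length numeric vectors,
#'   `length >= 3`.
#' @return list with `r`, `mae`, and `n`.
#' @export
clock_performance <- function(true_age_years, pred_age_years) {
  if (length(true_age_years) != length(pred_age_years))
    stop("length mismatch")
  if (length(true_age_years) < 3)
    stop("need at least 3 samples")
  if (stats::var(true_age_years) == 0)
    stop("undefined correlation: true ages are constant")
  list(r = stats::cor(true_age_years, pred_age_years),
       mae = stats::median(abs(pred_age_years - true_age_years)),
       n = length(true_age_years))
}

.cv_result <- function(predictions, strata, scheme, seed) {
  perf <- clock_performance(predictions$true_age_years,
                            predictions$predicted_age_years)
  by_stratum <- NULL
  if (!is.null(strata) && length(unique(strata)) > 1) {
    by_stratum <- do.call(rbind, lapply(split(predictions, strata),
      function(d) {
        p <- clock_performance(d$true_age_years, d$predicted_age_years)
        data.frame(stratum = NA_character_, r = p$r, mae = p$mae, n = p$n,
                   stringsAsFactors = FALSE)
      }))
    by_stratum$stratum <- names(split(predictions, strata))
    rownames(by_stratum) <- NULL
  }
  structure(list(predictions = predictions, r = perf$r, mae = perf$mae,
                 n = perf$n, by_stratum = by_stratum, scheme = scheme,
                 seed = seed),
            class = "clock_cv")
}

#' @export
print.clock_cv <- function(x, ...) {
  cat("Cross-validated clock accuracy (", x$scheme, ", n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  R = %.3f, MAE = %.3f years\n", x$r, x$mae))
  if (!is.null(x$by_stratum)) {
    for (i in seq_len(nrow(x$by_stratum)))
      cat(sprintf("  %s: R = %.3f, MAE = %.3f (n = %d)\n",
                  x$by_stratum$stratum[i], x$by_stratum$r[i],
                  x$by_stratum$mae[i], x$by_stratum$n[i]))
  }
  invisible(x)
}

#' Leave-one-out cross-validation of a clock
#'
#' For each sample, fits a fresh clock on all other samples (penalty
#' selection re-run inside every fold, with fold seed `seed + i` and the
#' internal fold count capped at half the fold's training size) and
#' predicts the held-out sample, so every prediction comes from a model
#' that never saw its sample. Reports overall and per-species Pearson R
#' and median absolute error on the collected predictions.
#'
#' @inheritParams methylclock
#' @return a `clock_cv` object: per-sample prediction table, overall `r`
#'   and `mae` (years), and per-stratum metrics when several species are
#'   present.
#' @export
loocv_clock <- function(betas, ages, species = NULL,
                        transform = age_transform("identity"),
                        alpha = 0.5, nfolds = 10, seed = 1) {
  betas <- .check_betas(betas)
  n <- ncol(betas)
  if (n < 12) stop("LOOCV needs at least 12 samples")
  if (!is.null(species)) species <- rep_len(as.character(species), n)
  ## inner penalty-selection folds never exceed half the fold's samples
  nfolds <- min(nfolds, (n - 1) %/% 2)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- methylclock(betas[, -i, drop = FALSE], ages[-i],
                       species = if (is.null(species)) NULL else species[-i],
                       transform = transform, alpha = alpha,
                       nfolds = nfolds, seed = seed + i)
    pred[i] <- predict(fit, betas[, i, drop = FALSE],
                       species = if (is.null(species)) NULL else species[i])
  }
  predictions <- data.frame(
    sample_id = colnames(betas), true_age_years = ages,
    predicted_age_years = pred, fold = seq_len(n),
    stringsAsFactors = FALSE)
  .cv_result(predictions, species, "LOOCV", seed)
}

#' Stratified k-fold cross-validation of a clock
#'
#' Folds are assigned by seeded round-robin within each stratum (default:
#' species), so for a dual-species clock both species appear in every
#' training fold. With `k = n` the fold assignment is the identity
#' permutation and the scheme coincides with [loocv_clock()]. Strata
#' smaller than `k` fall back to unstratified assignment with a warning.
#'
#' @inheritParams methylclock
#' @param k number of outer folds (default 10).
#' @param stratify_by stratum label per sample; defaults to `species`.
#' @return a `clock_cv` object (see [loocv_clock()]).
#' @export
kfold_clock <- function(betas, ages, species = NULL, k = 10,
                        transform = age_transform("identity"),
                        stratify_by = species,
                        alpha = 0.5, nfolds = 10, seed = 1) {
  betas <- .check_betas(betas)
  n <- ncol(betas)
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  if (!is.null(species)) species <- rep_len(as.character(species), n)

  if (k == n) {
    folds <- seq_len(n)
  } else {
    strata <- if (is.null(stratify_by)) rep("all", n)
              else rep_len(as.character(stratify_by), n)
    if (any(table(strata) < k)) {
      warning("stratum smaller than k; falling back to unstratified folds")
      strata <- rep("all", n)
    }
    set.seed(seed)
    folds <- integer(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }

  pred <- numeric(n)
  for (f in sort(unique(folds))) {
    hold <- folds == f
    nfolds_f <- min(nfolds, sum(!hold) %/% 2)
    fit <- methylclock(betas[, !hold, drop = FALSE], ages[!hold],
                       species = if (is.null(species)) NULL else species[!hold],
                       transform = transform, alpha = alpha,
                       nfolds = nfolds_f, seed = seed + f)
    pred[hold] <- predict(fit, betas[, hold, drop = FALSE],
                          species = if (is.null(species)) NULL
                                    else species[hold])
  }
  predictions <- data.frame(
    sample_id = colnames(betas), true_age_years = ages,
    predicted_age_years = pred, fold = folds, stringsAsFactors = FALSE)
  .cv_result(predictions, species,
             if (k == n) "LOOCV" else sprintf("%d-fold CV", k), seed)
}
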