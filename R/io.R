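#' Read a methylation dataset from disk
#'
#' Reads a beta matrix (TSV, first column `cpg_id`, one column per
#' sample), a sample sheet (CSV with header `sample_id,age_years,sex,
#' species,tissue,treatment`), and an optional probe annotation table
#' (TSV: `chrom`, `pos`, `cpg_id`, `gene`, `tss_distance`,
#' `region_class`; 1-based inclusive coordinates), validates them, and
#' joins them into a dataset. Matrix columns are reordered to the sheet's
#' sample order. Beta values outside \[0, 1\] by more than `1e-6` are
#' rejected; values within that tolerance are clipped with a warning.
#'
#' @param matrix_path path to the beta-matrix TSV.
#' @param sheet_path path to the sample-sheet CSV.
#' @param annotation_path optional path to the probe-annotation TSV.
#' @return a `methyl_dataset` list: `betas`, `sheet`, `annotation`.
#' @export
read_dataset <- function(matrix_path, sheet_path, annotation_path = NULL) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(mat)[1] != "cpg_id")
    stop("matrix file must have 'cpg_id' as its first column")
  if (anyDuplicated(mat$cpg_id))
    stop("duplicate cpg_id in matrix: ",
         paste(utils::head(unique(mat$cpg_id[duplicated(mat$cpg_id)]), 5),
               collapse = ", "))
  betas <- as.matrix(mat[, -1, drop = FALSE])
  rownames(betas) <- mat$cpg_id
  if (!is.numeric(betas)) stop("non-numeric beta values in matrix")
  if (anyNA(betas)) stop("missing beta values in matrix")
  tol <- 1e-6
  if (any(betas < -tol) || any(betas > 1 + tol))
    stop("beta values outside [0, 1] beyond tolerance ", tol)
  if (any(betas < 0) || any(betas > 1)) {
    warning("beta values within ", tol, " of [0, 1] clipped to the bounds")
    betas <- pmin(pmax(betas, 0), 1)
  }

  sheet <- utils::read.csv(sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_years", "sex", "species", "tissue",
            "treatment")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  only_mat <- setdiff(colnames(betas), sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, colnames(betas))
  if (length(only_mat) || length(only_sheet))
    stop("sample identifiers do not match; matrix-only: {",
         paste(only_mat, collapse = ", "), "}; sheet-only: {",
         paste(only_sheet, collapse = ", "), "}")
  betas <- betas[, sheet$sample_id, drop = FALSE]

  annotation <- NULL
  if (!is.null(annotation_path)) {
    annotation <- utils::read.delim(annotation_path,
                                    stringsAsFactors = FALSE)
    if (!all(c("cpg_id", "region_class") %in% names(annotation)))
      stop("annotation must carry 'cpg_id' and 'region_class'")
    if (anyDuplicated(annotation$cpg_id))
      stop("duplicate cpg_id in annotation")
  }
  structure(list(betas = betas, sheet = sheet, annotation = annotation),
            class = "methyl_dataset")
}

#' Write a methylation dataset to disk
#'
#' Inverse of [read_dataset()]: the round trip preserves values and
#' identifiers exactly.
#'
#' @param dataset a `methyl_dataset` or `methyl_sim` (anything with
#'   `betas` and `sheet`).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written (`matrix`, `sheet`, and `truth`
#'   or `annotation` when present).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "betas.tsv"),
                sheet = file.path(dir, "samples.csv"))
  mat <- data.frame(cpg_id = rownames(dataset$betas),
                    dataset$betas, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(mat, paths$matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(dataset$sheet, paths$sheet, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(dataset$truth)) {
    paths$truth <- file.path(dir, "truth.csv")
    utils::write.csv(dataset$truth, paths$truth, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(dataset$annotation)) {
    paths$annotation <- file.path(dir, "annotation.tsv")
    utils::write.table(dataset$annotation, paths$annotation, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Serialize a clock model to CSV
#'
#' Writes a commented header block carrying the transform specification
#' and training provenance, followed by `cpg_id,weight,training_mean`
#' rows; the first data row is the reserved id `__intercept__`. The round
#' trip through [read_clock()] is lossless: reloaded predictions agree to
#' 1e-10.
#'
#' @param model a [methylclock()] fit.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "methylclock"))
  tr <- model$transform
  hdr <- c("# cpgclock model v1",
           paste0("# transform=", tr$kind))
  if (tr$kind == "relative")
    hdr <- c(hdr, sprintf("# max_lifespan.%s=%s", names(tr$max_lifespan),
                          .fmt_num(tr$max_lifespan)))
  if (tr$kind == "loglinear")
    hdr <- c(hdr,
             sprintf("# adult_age.%s=%s", names(tr$adult_age),
                     .fmt_num(tr$adult_age)),
             paste0("# offset=", .fmt_num(tr$offset)))
  hdr <- c(hdr,
           paste0("# alpha=", .fmt_num(model$meta$alpha)),
           paste0("# lambda=", .fmt_num(model$meta$lambda)),
           paste0("# n_samples=", model$meta$n_samples),
           paste0("# n_cpgs_input=", model$meta$n_cpgs_input),
           paste0("# nfolds=", model$meta$nfolds),
           paste0("# seed=", model$meta$seed))
  body <- c("cpg_id,weight,training_mean",
            paste("__intercept__", .fmt_num(model$intercept), "NA",
                  sep = ","))
  if (length(model$weights))
    body <- c(body, paste(names(model$weights),
                          .fmt_num(model$weights),
                          .fmt_num(model$training_means),
                          sep = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a serialized clock model
#'
#' @param path path to a file written by [write_clock()].
#' @return a `methylclock` object.
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  kv <- hdr[grepl("=", hdr, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  get <- function(k) vals[match(k, keys)]

  kind <- get("transform")
  if (is.na(kind) || !kind %in% c("identity", "loglinear", "relative")) {
    ln <- which(is_hdr)[match("transform", keys)]
    stop("unknown or missing transform kind in clock file (line ",
         if (length(ln) && !is.na(ln)) ln else "?", "): ",
         if (is.na(kind)) "<absent>" else kind)
  }
  pick_prefixed <- function(prefix) {
    sel <- startsWith(keys, prefix)
    stats::setNames(as.numeric(vals[sel]), sub(prefix, "", keys[sel],
                                               fixed = TRUE))
  }
  transform <- switch(kind,
    identity = age_transform("identity"),
    relative = age_transform("relative",
                             max_lifespan = pick_prefixed("max_lifespan.")),
    loglinear = age_transform("loglinear",
                              adult_age = pick_prefixed("adult_age."),
                              offset = as.numeric(get("offset"))))

  body <- lines[!is_hdr]
  if (length(body) < 2 || body[1] != "cpg_id,weight,training_mean")
    stop("malformed clock file: missing column header")
  rows <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (nrow(rows) < 1 || rows$cpg_id[1] != "__intercept__" ||
      anyNA(rows$weight))
    stop("truncated or malformed clock file: intercept row missing or ",
         "unparseable weights")
  weights <- stats::setNames(rows$weight[-1], rows$cpg_id[-1])
  training_means <- stats::setNames(rows$training_mean[-1],
                                    rows$cpg_id[-1])
  structure(
    list(intercept = rows$weight[1],
         weights = weights,
         training_means = training_means,
         transform = transform,
         fitted = NULL, sample_ids = NULL,
         meta = list(n_samples = as.integer(get("n_samples")),
                     n_cpgs_input = as.integer(get("n_cpgs_input")),
                     alpha = as.numeric(get("alpha")),
                     lambda = as.numeric(get("lambda")),
                     nfolds = as.integer(get("nfolds")),
                     seed = as.integer(get("seed")),
                     species = NULL)),
    class = "methylclock")
}

#' Run the full clock analysis pipeline
#'
#' Orchestrates the analysis sequence on a dataset: clock
#' cross-validation on the training cohort (samples with
#' `treatment == "none"`, or all samples when no arms exist), training of
#' the final clock, prediction of every sample, the treatment regression
#' on the control/treated arms (clock trained on disjoint animals), an
#' EWAS of age, and the out-of-bag sex predictor on untreated animals.
#' All outputs plus a machine-readable run manifest (seed, input hashes,
#' versions) are written under `out_dir`; a stage failure moves partial
#' outputs into a `failed/` subdirectory and aborts with the stage name.
#'
#' @param dataset a `methyl_dataset` or `methyl_sim`.
#' @param out_dir output directory.
#' @param transform an [age_transform()] for the clock.
#' @param alpha,folds elastic-net mixing fraction and internal CV folds.
#' @param cv `"loocv"` or `"kfold"` for the outer evaluation scheme.
#' @param k outer folds when `cv = "kfold"`.
#' @param p_threshold,max_per_direction top-CpG selection rule.
#' @param seed integer seed for every stochastic step.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `cv`, `model`, `predictions`,
#'   `treatment`, `ewas_age`, `top_age_cpgs`, `sex_oob`, `manifest`.
#' @export
run_pipeline <- function(dataset, out_dir,
                         transform = age_transform("identity"),
                         alpha = 0.5, folds = 10,
                         cv = c("loocv", "kfold"), k = 10,
                         p_threshold = 0.005, max_per_direction = 500,
                         seed = 1, quiet = FALSE) {
  cv <- match.arg(cv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      fail_dir <- file.path(out_dir, "failed")
      dir.create(fail_dir, showWarnings = FALSE)
      for (f in written)
        file.rename(f, file.path(fail_dir, basename(f)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(obj, file, writer) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  tsv <- function(x, p) utils::write.table(x, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE)
  csv <- function(x, p) utils::write.csv(x, p, row.names = FALSE)

  betas <- dataset$betas
  sheet <- dataset$sheet
  train_idx <- which(sheet$treatment == "none")
  if (!length(train_idx)) train_idx <- seq_len(nrow(sheet))
  test_idx <- which(sheet$treatment %in% c("control", "rapamycin"))
  sp <- if (transform$kind == "identity") NULL else sheet$species

  say("stage cv: ", cv, " on ", length(train_idx), " training samples")
  cv_res <- stage("cv", {
    tb <- betas[, train_idx, drop = FALSE]
    ta <- sheet$age_years[train_idx]
    ts <- if (is.null(sp)) NULL else sp[train_idx]
    if (cv == "loocv")
      loocv_clock(tb, ta, ts, transform = transform, alpha = alpha,
                  nfolds = folds, seed = seed)
    else
      kfold_clock(tb, ta, ts, k = k, transform = transform,
                  alpha = alpha, nfolds = folds, seed = seed)
  })
  emit(cv_res$predictions, "cv_predictions.csv", csv)

  say("stage train: final clock")
  model <- stage("train",
    methylclock(betas[, train_idx, drop = FALSE],
                sheet$age_years[train_idx],
                species = if (is.null(sp)) NULL else sp[train_idx],
                transform = transform, alpha = alpha, nfolds = folds,
                seed = seed))
  emit(model, "clock_model.csv", write_clock)

  say("stage predict: all samples")
  preds <- stage("predict", predict(model, betas, species = sp))
  pred_df <- data.frame(sample_id = sheet$sample_id,
                        dnam_age_years = unname(preds),
                        stringsAsFactors = FALSE)
  emit(pred_df, "predictions.csv", csv)

  treat <- NULL
  if (length(test_idx) >= 8 &&
      length(unique(sheet$treatment[test_idx])) == 2) {
    say("stage treatment: regression on ", length(test_idx),
        " test samples")
    treat <- stage("treatment",
      treatment_effect(preds[test_idx], sheet[test_idx, , drop = FALSE],
                       training_ids = sheet$sample_id[train_idx]))
    emit(cbind(outcome = "DNAmAge", r_squared = treat$r_squared,
               treat$coefficients),
         "treatment_test.tsv", tsv)
  }

  say("stage ewas_age")
  ewas_age <- stage("ewas_age",
                    screen_numeric_trait(betas, sheet$age_years))
  emit(ewas_age, "ewas_age.tsv", tsv)
  top <- select_top_cpgs(ewas_age, p_threshold, max_per_direction)
  emit(top, "top_age_cpgs.tsv", tsv)

  untreated <- which(sheet$treatment != "rapamycin")
  sex_oob <- NULL
  if (length(unique(sheet$sex[untreated])) == 2 &&
      length(untreated) >= 20) {
    say("stage sex_oob on ", length(untreated), " untreated samples")
    sex_oob <- stage("sex_oob",
      sex_predictor_oob(betas[, untreated, drop = FALSE],
                        sheet$sex[untreated], seed = seed))
    emit(list(oob_accuracy = sex_oob$oob_accuracy,
              n = sex_oob$n, n_trees = sex_oob$n_trees,
              seed = sex_oob$seed),
         "sex_oob.json",
         function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                             digits = NA))
  }

  manifest <- list(
    package = "cpgclock",
    package_version = as.character(utils::packageVersion("cpgclock")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    transform = transform$kind,
    alpha = alpha, folds = folds, cv = cv,
    p_threshold = p_threshold, max_per_direction = max_per_direction,
    n_cpgs = nrow(betas), n_samples = ncol(betas),
    input_hash = dataset_hash(dataset))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cv = cv_res, model = model, predictions = pred_df,
                 treatment = treat, ewas_age = ewas_age,
                 top_age_cpgs = top, sex_oob = sex_oob,
                 manifest = manifest))
}

#' MD5 hash of a dataset's values and identifiers
#'
#' Content hash used in run manifests so a run can be tied to its exact
#' inputs.
#'
#' @param dataset anything with `betas` and `sheet`.
#' @return a single MD5 hex string.
#' @export
dataset_hash <- function(dataset) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  writeLines(c(rownames(dataset$betas), colnames(dataset$betas),
               sprintf("%.12g", dataset$betas),
               apply(dataset$sheet, 1, paste, collapse = ",")), con)
  close(con)
  unname(tools::md5sum(tmp))
}
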