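#' Epigenome-wide correlation screen for a numeric trait
#'
#' Per-CpG Pearson correlation of beta values with a numeric trait (age,
#' typically), with the usual t test: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`,
#' two-sided p from Student's t with `n - 2` degrees of freedom, and a
#' standard-normal-scale score `z = sign(r) * qnorm(1 - p / 2)` so that
#' results from several strata can be combined with [stouffer_meta()].
#' Constant CpGs have no defined correlation; they are reported with
#' `p = 1`, `z = 0`, and `degenerate = TRUE`.
#'
#' @param betas CpG x sample beta matrix.
#' @param trait numeric vector, one value per sample, non-constant.
#' @return an `ewas_table` data.frame: `cpg_id`, `statistic` (r), `z`,
#'   `p`, `p_bonferroni`, `direction`, `degenerate`.
#' @export
screen_numeric_trait <- function(betas, trait) {
  betas <- .check_betas(betas)
  n <- ncol(betas)
  if (length(trait) != n) stop("'trait' must have one value per sample")
  if (n < 4) stop("need at least 4 samples")
  if (stats::var(trait) == 0) stop("'trait' is constant")

  sds <- apply(betas, 1, stats::sd)
  r <- rep(0, nrow(betas))
  ok <- sds > 0
  r[ok] <- as.vector(stats::cor(t(betas[ok, , drop = FALSE]), trait))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[!ok] <- 1
  .ewas_table(rownames(betas), r, p, degenerate = !ok)
}

.ewas_table <- function(cpg_id, statistic, p, degenerate = FALSE) {
  p <- pmin(p, 1)
  z <- sign(statistic) * stats::qnorm(p / 2, lower.tail = FALSE)
  z[statistic == 0] <- 0
  structure(
    data.frame(cpg_id = cpg_id, statistic = statistic, z = z, p = p,
               p_bonferroni = pmin(p * length(p), 1),
               direction = sign(statistic),
               degenerate = rep_len(degenerate, length(p)),
               stringsAsFactors = FALSE),
    class = c("ewas_table", "data.frame"))
}

#' Covariate-adjusted group EWAS
#'
#' Per-CpG ordinary least squares of beta on `[intercept, group,
#' covariates]`, reporting the group coefficient with its t statistic,
#' two-sided p, and normal-scale z. This is the "multivariate regression
#' with chronological age as a covariate" design: treatment vs control
#' adjusted for age, or a sex contrast adjusted for age in untreated
#' animals.
#'
#' @param betas CpG x sample beta matrix.
#' @param group binary (0/1 or logical) indicator per sample; both groups
#'   must be non-empty.
#' @param covariates optional numeric matrix or data.frame of per-sample
#'   covariates (columns named).
#' @return an `ewas_table` data.frame keyed on the group coefficient.
#' @export
ewas_covariate <- function(betas, group, covariates = NULL) {
  betas <- .check_betas(betas)
  n <- ncol(betas)
  group <- as.numeric(group)
  if (length(group) != n) stop("'group' must have one value per sample")
  if (length(unique(group)) != 2) stop("'group' must take exactly two values")

  X <- cbind(`(Intercept)` = 1, group = group)
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    if (nrow(cov) != n) stop("covariates must have one row per sample")
    if (is.null(colnames(cov)))
      colnames(cov) <- paste0("covariate", seq_len(ncol(cov)))
    X <- cbind(X, cov)
  }
  k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (n < k + 1) stop("too few samples for the design")

  Y <- t(betas)
  coefs <- qr.coef(qrX, Y)               # k x m
  resid <- Y - X %*% coefs
  df <- n - k
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  b <- coefs[2, ]
  tstat <- ifelse(se > 0, b / se, 0)
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  .ewas_table(rownames(betas), unname(b), unname(p),
              degenerate = unname(se == 0 & b == 0))
}

#' Stouffer combination of z-scores across strata
#'
#' `Z = sum(w_i * z_i) / sqrt(sum(w_i^2))` per CpG, the weighted Stouffer
#' meta-analysis. Default weights are `sqrt(n_i)` when stratum sample
#' sizes are supplied, else equal. Strata with a missing z for a CpG are
#' dropped for that CpG with weight renormalization.
#'
#' @param z_by_stratum numeric matrix, CpG rows x stratum columns, of
#'   per-stratum z-scores (a vector is treated as a single stratum).
#' @param weights positive per-stratum weights; overrides `n_per_stratum`.
#' @param n_per_stratum per-stratum sample sizes giving `sqrt(n)` weights.
#' @return numeric vector of meta z-scores, one per CpG, with attribute
#'   `n_strata_used` counting the strata contributing to each.
#' @export
stouffer_meta <- function(z_by_stratum, weights = NULL,
                          n_per_stratum = NULL) {
  z <- as.matrix(z_by_stratum)
  k <- ncol(z)
  if (k < 1) stop("need at least one stratum")
  w <- if (!is.null(weights)) weights
       else if (!is.null(n_per_stratum)) sqrt(n_per_stratum)
       else rep(1, k)
  if (length(w) != k) stop("one weight per stratum required")
  if (any(w <= 0)) stop("weights must be positive")
  W <- matrix(w, nrow(z), k, byrow = TRUE)
  W[is.na(z)] <- 0
  z0 <- z
  z0[is.na(z)] <- 0
  denom <- sqrt(rowSums(W^2))
  if (any(denom == 0))
    stop("some CpGs have no stratum with a defined z-score")
  out <- rowSums(W * z0) / denom
  attr(out, "n_strata_used") <- rowSums(W > 0)
  out
}

#' Directional top-CpG selection
#'
#' Keeps CpGs with `p` strictly below the threshold, then within each
#' direction of association retains at most `max_per_direction` CpGs
#' ranked by decreasing `|z|` (ties broken by CpG id). The defaults are
#' the selection rule used for top-CpG annotation plots: p < 0.005, up to
#' 500 per direction.
#'
#' @param table an `ewas_table` (or any data.frame with `cpg_id`, `z`,
#'   `p`).
#' @param p_threshold strict upper bound on p.
#' @param max_per_direction cap per sign of z.
#' @return data.frame of the selected rows (`cpg_id`, `z`, `p`,
#'   `direction`), ordered by direction then decreasing `|z|`; possibly
#'   empty.
#' @export
select_top_cpgs <- function(table, p_threshold = 0.005,
                            max_per_direction = 500) {
  stopifnot(all(c("cpg_id", "z", "p") %in% names(table)))
  hits <- table[table$p < p_threshold & table$z != 0, , drop = FALSE]
  pick <- function(d) {
    rows <- hits[sign(hits$z) == d, , drop = FALSE]
    rows <- rows[order(-abs(rows$z), rows$cpg_id), , drop = FALSE]
    utils::head(rows, max_per_direction)
  }
  out <- rbind(pick(1), pick(-1))
  out <- out[, intersect(c("cpg_id", "z", "p", "direction"), names(out)),
             drop = FALSE]
  if (!"direction" %in% names(out)) out$direction <- sign(out$z)
  rownames(out) <- NULL
  out
}

#' Genic-region distribution of a CpG set
#'
#' Counts and proportions of a CpG set across genic region classes
#' (promoter, 5'UTR, exon, intron, 3'UTR, downstream, intergenic, or any
#' classes present in the annotation), against the background of all
#' annotated probes, with an upper-tail hypergeometric enrichment p per
#' class.
#'
#' @param cpg_set character vector of CpG ids; all must be annotated.
#' @param annotation data.frame with columns `cpg_id` and `region_class`
#'   (each CpG annotated at most once).
#' @param background character vector of background CpG ids (default: all
#'   annotated probes).
#' @return data.frame per region class: foreground count and proportion,
#'   background count and proportion, and `p_enrichment`
#'   (`P(X >= observed)` under the hypergeometric null). Empty sets give
#'   all-zero counts and `NA` p-values.
#' @export
region_distribution <- function(cpg_set, annotation,
                                background = annotation$cpg_id) {
  stopifnot(all(c("cpg_id", "region_class") %in% names(annotation)))
  if (anyDuplicated(annotation$cpg_id))
    stop("duplicate cpg_id in annotation")
  unknown <- setdiff(cpg_set, annotation$cpg_id)
  if (length(unknown))
    stop("unannotated CpG(s) in set: ", paste(unknown, collapse = ", "))
  cls <- annotation$region_class[match(background, annotation$cpg_id)]
  classes <- sort(unique(annotation$region_class))
  bg_count <- as.integer(table(factor(cls, levels = classes)))
  fg_cls <- annotation$region_class[match(cpg_set, annotation$cpg_id)]
  fg_count <- as.integer(table(factor(fg_cls, levels = classes)))
  N <- length(background)
  n_fg <- length(cpg_set)
  p <- if (n_fg == 0) rep(NA_real_, length(classes))
       else stats::phyper(fg_count - 1L, bg_count, N - bg_count, n_fg,
                          lower.tail = FALSE)
  data.frame(region_class = classes,
             fg_count = fg_count,
             fg_prop = if (n_fg == 0) rep(0, length(classes))
                       else fg_count / n_fg,
             bg_count = bg_count,
             bg_prop = bg_count / N,
             p_enrichment = p,
             stringsAsFactors = FALSE)
}

#' Exclusive intersection counts of named CpG sets
#'
#' Upset-style counting: for every combination of set membership over two
#' or more named sets, the number of elements belonging to exactly that
#' combination. The counts sum to the size of the union.
#'
#' @param named_sets named list (length >= 2) of character vectors.
#' @return data.frame with one logical column per set plus `count`, one
#'   row per nonempty membership combination (zero counts included).
#' @export
set_overlap <- function(named_sets) {
  if (length(named_sets) < 2 || is.null(names(named_sets)))
    stop("need a named list of at least 2 sets")
  u <- unique(unlist(named_sets, use.names = FALSE))
  member <- vapply(named_sets, function(s) u %in% s,
                   logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1,
                                       dimnames = list(NULL,
                                                       names(named_sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(named_sets)))
  names(combos) <- names(named_sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  key <- apply(member, 1, paste, collapse = ".")
  combo_key <- apply(combos, 1, paste, collapse = ".")
  combos$count <- as.integer(table(factor(key, levels = combo_key)))
  rownames(combos) <- NULL
  combos
}
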