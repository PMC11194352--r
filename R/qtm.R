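#' Regress covariates out of a repeated-measures variable
#'
#' Fits `value ~ covariates` with (optionally) a subject-level random
#' intercept and returns the residuals about the *fixed* part only: the
#' random intercept is not subtracted, so within-subject change is
#' preserved for later pairing. Rank-deficient covariate sets have their
#' collinear columns dropped with a warning.
#'
#' @param values per-sample numeric vector, aligned with `samples` rows.
#' @param samples a `sample_sheet`.
#' @param covariates character vector of `samples` column names (may be
#'   empty).
#' @param random_intercept fit a subject random intercept (requires both
#'   visits per subject).
#' @return numeric vector of residuals, named by sample id.
#' @export
residualize_repeated <- function(values, samples, covariates = character(0),
                                 random_intercept = TRUE) {
  miss <- setdiff(covariates, names(samples))
  if (length(miss)) stop("covariates not in sample sheet: ",
                         paste(miss, collapse = ", "))
  df <- data.frame(y = values, subject = factor(samples$subject_id))
  for (cv in covariates) {
    df[[cv]] <- if (is.character(samples[[cv]])) factor(samples[[cv]])
    else samples[[cv]]
  }
  if (length(covariates)) {
    X <- model.matrix(as.formula(paste("~", paste(covariates,
                                                  collapse = " + "))), df)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      warning("dropping collinear covariate column(s): ",
              paste(drop_cols, collapse = ", "))
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
  } else {
    X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (random_intercept) {
    fit <- lme4::lmer(y ~ 0 + X + (1 | subject), data = df, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  check.scaleX = "ignore",
                                                  calc.derivs = FALSE))
    fixed_fit <- drop(X %*% lme4::fixef(fit))
  } else {
    fit <- lm.fit(X, df$y)
    fixed_fit <- drop(X %*% fit$coefficients)
  }
  setNames(df$y - fixed_fit, samples$sample_id)
}

#' Collapse paired-visit residuals to one value per subject
#'
#' @param residuals named per-sample values (names = sample ids).
#' @param samples a `sample_sheet`.
#' @param mode `"delta"` (post minus pre) or `"mean"` ((post + pre) / 2).
#' @return named per-subject numeric vector; subjects missing a visit are
#'   dropped with a message.
#' @export
paired_contrast <- function(residuals, samples, mode = c("delta", "mean")) {
  mode <- match.arg(mode)
  sm <- samples[match(names(residuals), samples$sample_id), ]
  wide <- split(data.frame(v = unname(residuals), visit = sm$visit),
                sm$subject_id)
  vals <- vapply(wide, function(d) {
    pre <- d$v[d$visit == "pre"]; post <- d$v[d$visit == "post"]
    if (length(pre) != 1 || length(post) != 1) return(NA_real_)
    if (mode == "delta") post - pre else (post + pre) / 2
  }, numeric(1))
  if (anyNA(vals))
    message("dropping ", sum(is.na(vals)), " subject(s) missing a visit")
  vals[!is.na(vals)]
}

#' First principal component of a region's CpGs
#'
#' Columns (CpGs) are standardized; zero-variance CpGs are dropped with a
#' warning. The PC1 sign is indeterminate, so the orientation is fixed by
#' requiring a positive correlation with the across-CpG row mean:
#' increasing score means increasing methylation (or increasing change, in
#' delta mode).
#'
#' @param mat numeric matrix, subjects x CpGs (rownames = subject ids).
#' @param mode label recorded on the result (`"delta"` or `"mean"`).
#' @return list of class `region_score`: `scores` (named, zero mean),
#'   `variance_explained`, `orientation`, `mode`, `n_cpgs`.
#' @export
region_pc1 <- function(mat, mode = c("delta", "mean")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop_invalid("need at least 3 subjects for a region PC")
  v <- apply(mat, 2, sd)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance CpG(s)")
    mat <- mat[, v > 0, drop = FALSE]
  }
  if (!ncol(mat)) stop("all CpGs in the region have zero variance")
  zs <- scale(mat)
  attr(zs, "scaled:center") <- attr(zs, "scaled:scale") <- NULL
  if (ncol(zs) == 1) {
    scores <- as.numeric(zs)
    ve <- 1; orientation <- 1L
  } else {
    pc <- prcomp(zs, center = FALSE, scale. = FALSE)
    scores <- pc$x[, 1]
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
    orientation <- if (cor(scores, rowMeans(zs)) < 0) -1L else 1L
    scores <- orientation * scores
  }
  structure(list(scores = setNames(scores - mean(scores), rownames(mat)),
                 variance_explained = ve, orientation = orientation,
                 mode = mode, n_cpgs = ncol(zs)),
            class = "region_score")
}

#' Genes within the cis window of a region midpoint
#'
#' @param region list/one-row data.frame with `chrom`, `start`, `stop`
#'   (1-based inclusive).
#' @param tss_table data.frame with `gene_id`, `chrom`, `tss` columns (same
#'   build/coordinates as the probe manifest). For minus-strand genes the
#'   TSS is the gene end coordinate; [tss_from_genes()] applies that rule.
#' @param window cis half-width in bp (default 500000).
#' @return character vector of gene ids with
#'   `|TSS - midpoint| <= window`; midpoint is `floor((start + stop) / 2)`.
#' @export
cis_features <- function(region, tss_table, window = 500000) {
  if (!nrow(tss_table)) return(character(0))
  midpoint <- floor((region$start + region$stop) / 2)
  hit <- tss_table$chrom == region$chrom &
    abs(tss_table$tss - midpoint) <= window
  tss_table$gene_id[hit]
}

#' @rdname cis_features
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (+1/-1) columns.
#' @export
tss_from_genes <- function(genes) {
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             tss = ifelse(genes$strand < 0, genes$end, genes$start))
}

# Spearman rho via midranks with the t approximation for the p-value
spearman_t <- function(x, y) {
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), df = n - 2))
}

#' Spearman eQTM test of a region score against expression residuals
#'
#' @param region_score a [region_pc1()] result (or a named numeric vector
#'   of per-subject scores).
#' @param expression_residuals named per-subject numeric vector; pairing is
#'   by name intersection.
#' @param region_id,feature_id identifiers copied to the output.
#' @return one-row data.frame (`region_id`, `feature_id`, `panel`,
#'   `statistic` = Spearman rho, `p`, `n`, `flagged`); constant expression
#'   flags the pair with missing statistics.
#' @export
eqtm_test <- function(region_score, expression_residuals,
                      region_id = NA_character_, feature_id = NA_character_) {
  s <- if (inherits(region_score, "region_score")) region_score$scores
  else region_score
  common <- intersect(names(s), names(expression_residuals))
  if (length(common) < 5)
    stop_invalid("need at least 5 paired subjects (have ", length(common), ")")
  x <- s[common]; y <- expression_residuals[common]
  if (sd(y) == 0 || sd(x) == 0) {
    return(data.frame(region_id = region_id, feature_id = feature_id,
                      panel = "expression", statistic = NA_real_,
                      p = NA_real_, n = length(common), flagged = TRUE))
  }
  st <- spearman_t(x, y)
  data.frame(region_id = region_id, feature_id = feature_id,
             panel = "expression", statistic = st$rho, p = st$p,
             n = length(common), flagged = FALSE)
}

#' Box-Cox transform with maximum-likelihood lambda on a fixed grid
#'
#' Profiles the Box-Cox log-likelihood over `lambda` in `[-2, 2]` by steps
#' of 0.1 and applies `y = (x^lambda - 1) / lambda` (natural log at
#' `lambda = 0`). Nonpositive inputs are shifted by `1 - min(x)` with a
#' warning before transforming.
#'
#' @param values numeric vector.
#' @param grid candidate lambdas.
#' @return list with `values` (transformed), `lambda`, `shift`.
#' @export
boxcox_transform <- function(values, grid = seq(-2, 2, by = 0.1)) {
  shift <- 0
  if (any(values <= 0)) {
    shift <- 1 - min(values)
    warning("nonpositive values; shifting by ", format(shift))
    values <- values + shift
  }
  n <- length(values)
  logx <- log(values)
  ll <- vapply(grid, function(lam) {
    y <- if (abs(lam) < 1e-12) logx else (values^lam - 1) / lam
    -n / 2 * log(mean((y - mean(y))^2)) + (lam - 1) * sum(logx)
  }, numeric(1))
  lam <- grid[which.max(ll)]
  y <- if (abs(lam) < 1e-12) logx else (values^lam - 1) / lam
  list(values = y, lambda = lam, shift = shift)
}

#' Standardized-beta metQTM test
#'
#' Both sides are z-scored, so the simple-regression slope equals the
#' Pearson correlation and is reported as the standardized beta (1 SD of
#' metabolite change per 1 SD of regional methylation score); the p-value
#' is the regression t-test.
#'
#' @param region_score a [region_pc1()] result or named numeric vector.
#' @param metabolite_contrast named per-subject numeric vector (delta or
#'   mean of residualized metabolite levels).
#' @param panel panel label (e.g. `"HILIC"`, `"Lipid"`, `"GCTOF"`).
#' @inheritParams eqtm_test
#' @return one-row data.frame as [eqtm_test()], `statistic` = standardized
#'   beta.
#' @export
metqtm_test <- function(region_score, metabolite_contrast, panel,
                        region_id = NA_character_,
                        feature_id = NA_character_) {
  s <- if (inherits(region_score, "region_score")) region_score$scores
  else region_score
  common <- intersect(names(s), names(metabolite_contrast))
  if (length(common) < 5)
    stop_invalid("need at least 5 paired subjects (have ", length(common), ")")
  x <- s[common]; y <- metabolite_contrast[common]
  if (sd(x) == 0 || sd(y) == 0) {
    return(data.frame(region_id = region_id, feature_id = feature_id,
                      panel = panel, statistic = NA_real_, p = NA_real_,
                      n = length(common), flagged = TRUE))
  }
  n <- length(common)
  beta <- cor(x, y)
  tt <- beta * sqrt((n - 2) / max(1 - beta^2, 1e-300))
  data.frame(region_id = region_id, feature_id = feature_id, panel = panel,
             statistic = beta, p = 2 * pt(-abs(tt), df = n - 2),
             n = n, flagged = FALSE)
}

#' Stratified BH-FDR over QTM results
#'
#' Applies [bh_fdr()] separately within each stratum (panel for metQTM,
#' candidate family for eQTM).
#'
#' @param results data.frame of stacked [eqtm_test()] / [metqtm_test()]
#'   rows.
#' @param by column name defining strata (default `"panel"`).
#' @return `results` with a `q_bh` column.
#' @export
qtm_fdr <- function(results, by = "panel") {
  results$q_bh <- NA_real_
  for (lv in unique(results[[by]])) {
    sel <- results[[by]] == lv
    results$q_bh[sel] <- bh_fdr(results$p[sel])
  }
  results
}
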