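region_cpg_matrix <- function(region, mvals, samples, covariates, mode,
                              random_intercept = TRUE) {
  ids <- region$probe_ids[[1]]
  miss <- setdiff(ids, rownames(mvals))
  if (length(miss)) stop("region probes missing from M-value matrix: ",
                         paste(miss, collapse = ", "))
  cols <- lapply(ids, function(pid) {
    res <- residualize_repeated(mvals[pid, samples$sample_id], samples,
                                covariates, random_intercept)
    paired_contrast(res, samples, mode)
  })
  subj <- Reduce(intersect, lapply(cols, names))
  mat <- vapply(cols, function(x) x[subj], numeric(length(subj)))
  dimnames(mat) <- list(subj, ids)
  mat
}

#' Score retained regions per subject (residualize, pair, PCA)
#'
#' For every region, regresses the covariates out of each member CpG's
#' M-values (mixed model with subject random intercept), collapses the
#' residuals to one value per subject (`delta` = post - pre for
#' differentially *changing* regions, `mean` = visit average for
#' differentially *methylated* regions), and extracts the oriented first
#' principal component across the region's CpGs.
#'
#' @param regions `dmr_set` rows (or summarized records) with a
#'   `probe_ids` list column.
#' @param mvals M-value matrix (probes x samples).
#' @param samples a `sample_sheet`.
#' @param mode `"delta"` or `"mean"`.
#' @param covariates columns regressed out of the methylation values;
#'   ancestry PCs are conventionally added for mean-mode (mu) regions. The
#'   default uses five of the six cell proportions (they sum to one, so the
#'   sixth is redundant given an intercept).
#' @return named list of [region_pc1()] scores, one per region.
#' @export
score_regions <- function(regions, mvals, samples, mode = c("delta", "mean"),
                          covariates = c("age", "sex", "platform",
                                         cell_types[-6])) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    mat <- region_cpg_matrix(regions[i, ], mvals, samples, covariates, mode)
    region_pc1(mat, mode)
  })
  names(out) <- regions$region_id
  out
}

#' Region-level eQTM scan
#'
#' Residualizes post-visit expression on age and sex (simple linear
#' models), pairs each region score with every gene whose TSS lies within
#' the cis window of the region midpoint, tests each pair by Spearman
#' correlation, and applies BH-FDR across all cis pairs of the candidate
#' family.
#'
#' @param regions `dmr_set` rows / summarized records (with `chrom`,
#'   `start`, `stop`, `region_id`, `probe_ids`).
#' @param scores output of [score_regions()] for these regions.
#' @param expression genes x subjects matrix (colnames = subject ids),
#'   post-visit values.
#' @param tss_table data.frame `gene_id`, `chrom`, `tss`.
#' @param samples a `sample_sheet` (for the age/sex of the expression
#'   subjects at the post visit).
#' @param cis_window bp half-width (default 500000).
#' @return data.frame of tested pairs with `q_bh` (single FDR stratum).
#' @export
run_eqtm <- function(regions, scores, expression, tss_table, samples,
                     cis_window = 500000) {
  post <- samples[samples$visit == "post", ]
  idx <- match(colnames(expression), post$subject_id)
  if (anyNA(idx)) stop("expression subjects missing from sample sheet: ",
                       paste(colnames(expression)[is.na(idx)], collapse = ", "))
  X <- model.matrix(~ age + sex, data.frame(age = post$age[idx],
                                            sex = factor(post$sex[idx])))
  resid_expr <- t(apply(expression, 1, function(y) {
    f <- lm.fit(X, y); setNames(f$residuals, colnames(expression))
  }))
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    genes <- cis_features(regions[i, ], tss_table, cis_window)
    for (g in intersect(genes, rownames(resid_expr))) {
      rows[[length(rows) + 1]] <-
        eqtm_test(scores[[rid]], resid_expr[g, ], region_id = rid,
                  feature_id = g)
    }
  }
  if (!length(rows))
    return(data.frame(region_id = character(0), feature_id = character(0),
                      panel = character(0), statistic = numeric(0),
                      p = numeric(0), n = integer(0), flagged = logical(0),
                      q_bh = numeric(0)))
  qtm_fdr(do.call(rbind, rows), by = "panel")
}

#' Region-level metQTM scan
#'
#' Box-Cox transforms each metabolite, residualizes age and sex within each
#' visit (plain linear models), collapses to per-subject delta (or mean)
#' values, and regresses them on each region score with z-scored variables
#' so the slope is a standardized beta. BH-FDR is applied separately per
#' panel.
#'
#' @inheritParams run_eqtm
#' @param metabolites metabolites x samples matrix covering both visits of
#'   the metabolite subjects (colnames = sample ids).
#' @param panels named character vector, panel per metabolite.
#' @param mode `"delta"` for differentially changing candidates, `"mean"`
#'   for average-methylation candidates.
#' @return data.frame of tested pairs with per-panel `q_bh`.
#' @export
run_metqtm <- function(regions, scores, metabolites, panels, samples,
                       mode = c("delta", "mean")) {
  mode <- match.arg(mode)
  sm <- samples[match(colnames(metabolites), samples$sample_id), ]
  if (anyNA(sm$sample_id)) stop("metabolite samples missing from sample sheet")
  contrasts <- lapply(rownames(metabolites), function(mid) {
    y <- boxcox_transform(metabolites[mid, ])$values
    res <- y
    for (v in c("pre", "post")) {
      sel <- sm$visit == v
      X <- model.matrix(~ age + sex, data.frame(age = sm$age[sel],
                                                sex = factor(sm$sex[sel])))
      res[sel] <- lm.fit(X, y[sel])$residuals
    }
    paired_contrast(setNames(res, sm$sample_id), sm, mode)
  })
  names(contrasts) <- rownames(metabolites)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    rid <- regions$region_id[i]
    for (mid in rownames(metabolites)) {
      rows[[length(rows) + 1]] <-
        metqtm_test(scores[[rid]], contrasts[[mid]],
                    panel = unname(panels[mid]), region_id = rid,
                    feature_id = mid)
    }
  }
  if (!length(rows))
    return(data.frame(region_id = character(0), feature_id = character(0),
                      panel = character(0), statistic = numeric(0),
                      p = numeric(0), n = integer(0), flagged = logical(0),
                      q_bh = numeric(0)))
  qtm_fdr(do.call(rbind, rows), by = "panel")
}
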