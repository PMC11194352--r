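#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment with enforced monotonicity (a thin wrapper
#' over [stats::p.adjust()]). Missing p-values are excluded from the
#' adjustment and returned missing; output order matches input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return numeric vector of q-values, `q >= p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop_invalid("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

group_levels <- c("maintainer", "progressor", "reverter")

# One row per subject with visit-wise and subject-level covariates; assumes
# a validated sample sheet (exactly one pre and one post row per subject).
subject_table <- function(samples) {
  pre <- samples[samples$visit == "pre", ]
  post <- samples[samples$visit == "post", ]
  post <- post[match(pre$subject_id, post$subject_id), ]
  df <- data.frame(subject_id = pre$subject_id,
                   group = factor(pre$group, levels = group_levels),
                   sexF = as.numeric(pre$sex == "F"),
                   epic = as.numeric(pre$platform == "EPIC"),
                   age_pre = pre$age, age_post = post$age,
                   ancestry_pc1 = pre$ancestry_pc1,
                   ancestry_pc2 = pre$ancestry_pc2,
                   pre_sample = pre$sample_id, post_sample = post$sample_id,
                   stringsAsFactors = FALSE)
  for (ct in cell_types) {
    df[[paste0(ct, "_pre")]] <- pre[[ct]]
    df[[paste0(ct, "_post")]] <- post[[ct]]
  }
  df
}

# drop trailing columns of a design matrix until it has full column rank;
# only columns listed in `droppable` may be removed
prune_design <- function(X, droppable) {
  repeat {
    if (qr(X)$rank == ncol(X)) return(X)
    cand <- intersect(rev(colnames(X)), droppable)
    if (!length(cand))
      stop("design matrix is rank deficient and cannot be repaired")
    X <- X[, setdiff(colnames(X), cand[1]), drop = FALSE]
  }
}

# exact 2-df F-test of `test_cols` given precomputed QR factorizations;
# Y is an n x m matrix of responses (one column per probe)
ftest_2df <- function(qr_full, qr_red, Y, df_den) {
  rss_f <- colSums(qr.resid(qr_full, Y)^2)
  rss_r <- colSums(qr.resid(qr_red, Y)^2)
  fstat <- ((rss_r - rss_f) / 2) / (rss_f / df_den)
  stats::pf(fstat, 2, df_den, lower.tail = FALSE)
}

#' Per-CpG 2-df tests for a balanced longitudinal three-group cohort
#'
#' Fits, for every probe (row) of an M-value matrix, the linear mixed model
#' with a subject-level random intercept implied by a two-visit design, and
#' tests a 2-degree-of-freedom group hypothesis. Because every subject has
#' exactly one pre and one post visit, the mixed model decomposes exactly
#' into two independent strata, and the package works in that
#' parameterization so the 2-df tests are exact F-tests rather than
#' asymptotic likelihood-ratio chi-squares (which are anticonservative at
#' n = 143 subjects):
#'
#' * `model = "interaction"` (does the pre-to-post *change* differ by
#'   group?) is tested in the within-subject stratum: the paired
#'   differences `post - pre` are regressed on group plus the
#'   visit-varying covariates (age change, cell-proportion changes;
#'   sex and platform cancel in the difference), and the 2-df F-test drops
#'   the group terms. Reported effects are the model-implied post minus
#'   pre change per group (`slope_*`, M-units, at zero covariate change).
#' * `model = "group"` (does the *average* methylation differ by group?)
#'   is tested in the between-subject stratum: the per-subject visit means
#'   are regressed on group, mean age, sex, platform, mean cell
#'   proportions, and the first two ancestry PCs; the 2-df F-test drops
#'   the group terms. Reported effects are the pairwise group contrasts
#'   P-R, R-M, P-M (`diff_pvr`, `diff_rvm`, `diff_pvm`). Subjects with
#'   missing ancestry are excluded (complete case).
#'
#' The six cell proportions sum to one, so one collinear proportion column
#' is dropped automatically. Probes with zero variance (or a degenerate
#' fit) are flagged with missing p-values and excluded from the BH-FDR
#' adjustment.
#'
#' @param mvals numeric matrix of M-values, probes x samples, with
#'   `rownames` = probe ids and `colnames` matching `samples$sample_id`.
#' @param samples a `sample_sheet` (see [generate_samples()] for the
#'   expected columns).
#' @param model `"interaction"` or `"group"`.
#' @return object of class `dmp_fit`; `$results` is a data.frame with one
#'   row per probe (`probe_id`, `p_2df`, `q_bh`, effect columns, `n_used`,
#'   `flagged`).
#' @export
dmp_fit <- function(mvals, samples, model = c("interaction", "group")) {
  model <- match.arg(model)
  if (is.null(dim(mvals))) mvals <- matrix(mvals, nrow = 1,
                                           dimnames = list("probe1",
                                                           samples$sample_id))
  validate_sample_sheet(samples)
  if (is.null(colnames(mvals)) ||
      !identical(sort(colnames(mvals)), sort(samples$sample_id)))
    stop("mvals columns must match sample sheet sample_ids")

  st <- subject_table(samples)
  dropped_subjects <- character(0)
  if (model == "group") {
    if (all(is.na(st$ancestry_pc1)))
      stop("ancestry PCs are missing for every subject (group model needs them)")
    keep <- !is.na(st$ancestry_pc1) & !is.na(st$ancestry_pc2)
    dropped_subjects <- st$subject_id[!keep]
    st <- st[keep, , drop = FALSE]
  }
  if (sum(table(st$group) >= 2) < 2)
    stop("need at least 2 groups with at least 2 subjects each")

  Ypre <- t(mvals[, st$pre_sample, drop = FALSE])
  Ypost <- t(mvals[, st$post_sample, drop = FALSE])
  grp <- model.matrix(~ group, st)[, -1, drop = FALSE]
  cells <- function(suffix, op) {
    m <- sapply(cell_types, function(ct)
      op(st[[paste0(ct, "_post")]], st[[paste0(ct, "_pre")]]))
    colnames(m) <- cell_types
    m
  }
  if (model == "interaction") {
    Y <- Ypost - Ypre
    X <- cbind("(Intercept)" = 1, grp,
               d_age = st$age_post - st$age_pre,
               cells("", `-`))
  } else {
    Y <- (Ypost + Ypre) / 2
    X <- cbind("(Intercept)" = 1, grp,
               age = (st$age_post + st$age_pre) / 2,
               sexF = st$sexF, epic = st$epic,
               cells("", function(a, b) (a + b) / 2),
               ancestry_pc1 = st$ancestry_pc1,
               ancestry_pc2 = st$ancestry_pc2)
  }
  X <- prune_design(X, droppable = cell_types)
  cells_used <- intersect(colnames(X), cell_types)
  if (length(cells_used) < 6)
    message("dropped collinear cell-proportion column(s): ",
            paste(setdiff(cell_types, cells_used), collapse = ", "))
  gcols <- colnames(grp)
  Xred <- X[, setdiff(colnames(X), gcols), drop = FALSE]
  qr_full <- qr(X); qr_red <- qr(Xred)
  df_den <- nrow(X) - ncol(X)
  if (df_den < 1) stop("too few subjects for the covariate set")

  n_probe <- ncol(Y)
  probe_id <- rownames(mvals)
  if (is.null(probe_id)) probe_id <- sprintf("probe%d", seq_len(n_probe))
  flagged <- !apply(Y, 2, function(y) all(is.finite(y)) && sd(y) > 0)
  p <- rep(NA_real_, n_probe)
  eff <- matrix(NA_real_, n_probe, 3)
  if (any(!flagged)) {
    Yok <- Y[, !flagged, drop = FALSE]
    p[!flagged] <- ftest_2df(qr_full, qr_red, Yok, df_den)
    B <- qr.coef(qr_full, Yok)  # coefficients x probes
    b0 <- B["(Intercept)", ]
    bP <- B["groupprogressor", ]; bR <- B["groupreverter", ]
    if (model == "interaction") {
      # model-implied change per group at zero covariate change
      eff[!flagged, ] <- cbind(b0, b0 + bP, b0 + bR)
    } else {
      eff[!flagged, ] <- cbind(bP - bR, bR, bP)
    }
  }
  res <- data.frame(probe_id = probe_id, model = model, p_2df = p,
                    q_bh = bh_fdr(p), stringsAsFactors = FALSE)
  if (model == "interaction") {
    res$slope_maintainer <- eff[, 1]
    res$slope_progressor <- eff[, 2]
    res$slope_reverter <- eff[, 3]
  } else {
    res$diff_pvr <- eff[, 1]; res$diff_rvm <- eff[, 2]; res$diff_pvm <- eff[, 3]
  }
  res$n_used <- 2L * nrow(st)
  res$flagged <- flagged
  rownames(res) <- NULL
  structure(list(results = res, model = model,
                 stratum = if (model == "interaction") "within-subject"
                 else "between-subject",
                 design_columns = colnames(X),
                 df_denominator = df_den,
                 n_samples = 2L * nrow(st),
                 n_subjects = nrow(st),
                 dropped_subjects = dropped_subjects,
                 cells_used = cells_used),
            class = "dmp_fit")
}

#' @rdname dmp_fit
#' @param probe_values numeric vector of M-values for one probe, in sample
#'   sheet order (or named by sample id).
#' @export
fit_interaction_dmp <- function(probe_values, samples) {
  fit_one(probe_values, samples, "interaction")
}

#' @rdname dmp_fit
#' @export
fit_group_dmp <- function(probe_values, samples) {
  fit_one(probe_values, samples, "group")
}

fit_one <- function(probe_values, samples, model) {
  m <- matrix(probe_values, nrow = 1,
              dimnames = list("probe1", samples$sample_id))
  fit <- dmp_fit(m, samples, model)
  fit$results
}

#' @export
print.dmp_fit <- function(x, ...) {
  cat("Per-CpG 2-df tests (", x$model, " model, ", x$stratum,
      " stratum)\n", sep = "")
  cat("  probes: ", nrow(x$results), " (", sum(x$results$flagged),
      " flagged)\n", sep = "")
  cat("  samples: ", x$n_samples, " from ", x$n_subjects, " subjects\n",
      sep = "")
  if (length(x$dropped_subjects))
    cat("  dropped (missing ancestry): ",
        paste(x$dropped_subjects, collapse = ", "), "\n", sep = "")
  cat("  F(2, ", x$df_denominator, ") on: ",
      paste(x$design_columns, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dmp_fit <- function(object, fdr_alpha = 0.10, ...) {
  r <- object$results
  out <- list(model = object$model, n_probes = nrow(r),
              n_flagged = sum(r$flagged),
              n_significant = sum(r$q_bh < fdr_alpha, na.rm = TRUE),
              fdr_alpha = fdr_alpha,
              top = head(r[order(r$p_2df), ], 5))
  class(out) <- "summary.dmp_fit"
  out
}

#' @export
print.summary.dmp_fit <- function(x, ...) {
  cat(x$model, "model:", x$n_probes, "probes,", x$n_flagged, "flagged\n")
  cat(x$n_significant, "probes significant at BH-FDR", x$fdr_alpha, "\n")
  cat("top probes:\n")
  print(x$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.dmp_fit <- function(object, ...) {
  r <- object$results
  cols <- if (object$model == "interaction")
    c("slope_maintainer", "slope_progressor", "slope_reverter")
  else c("diff_pvr", "diff_rvm", "diff_pvm")
  out <- as.matrix(r[cols])
  rownames(out) <- r$probe_id
  out
}
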