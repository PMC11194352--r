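#' Describe a synthetic two-visit cohort
#'
#' Bundles the parameters of the synthetic cohort generator. Defaults
#' emulate the published study structure: three islet-autoimmunity
#' progression phenotypes (maintainers n = 60, progressors n = 42,
#' reverters n = 41), each subject measured at a pre-seroconversion and a
#' post-seroconversion visit, with age medians ordered
#' progressor < reverter <= maintainer at both visits, six Houseman-style
#' blood cell proportions drawn from a Dirichlet, random platform
#' assignment (450K vs EPIC, independent of phenotype), and two
#' standard-normal ancestry PCs.
#'
#' @param n_per_group named integer vector (maintainer, progressor,
#'   reverter group sizes).
#' @param age_median list with `pre` and `post` named numeric vectors of
#'   per-group median ages in years (lognormal location = log median).
#' @param age_sdlog lognormal scale for age.
#' @param sex_prob probability of female sex.
#' @param platform_prob probability of EPIC platform assignment.
#' @param cellprop_alpha Dirichlet concentration for the six cell
#'   proportions (CD8T, CD4T, NK, Bcell, Mono, Gran); default is
#'   proportional to typical pediatric whole-blood medians with total
#'   concentration 40.
#' @param subject_sd SD of the subject-level random intercept (M-units).
#' @param residual_sd SD of the independent residual (M-units).
#' @param spatial_sd SD of the spatially correlated noise component
#'   (M-units).
#' @param spatial_decay per-bp exponential decay rate of the within-cluster
#'   noise correlation, `corr(a, b) = exp(-spatial_decay * |pos_a - pos_b|)`.
#' @param n_missing_ancestry number of subjects whose ancestry PCs are set
#'   missing (exercises the complete-case rule of the group-effect model).
#' @param seed integer seed for all cohort-level randomness.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(maintainer = 60L, progressor = 42L,
                                          reverter = 41L),
                          age_median = list(
                            pre  = c(maintainer = 5.7, progressor = 2.2,
                                     reverter = 6.0),
                            post = c(maintainer = 8.0, progressor = 4.9,
                                     reverter = 7.1)),
                          age_sdlog = 1.0,
                          sex_prob = 0.5,
                          platform_prob = 0.5,
                          cellprop_alpha = c(CD8T = 5.2, CD4T = 8.4, NK = 0.6,
                                             Bcell = 6.0, Mono = 3.2,
                                             Gran = 16.6),
                          subject_sd = 0.30,
                          residual_sd = 0.15,
                          spatial_sd = 0.10,
                          spatial_decay = 0.01,
                          n_missing_ancestry = 2L,
                          seed = 1L) {
  groups <- c("maintainer", "progressor", "reverter")
  if (!all(groups %in% names(n_per_group)) || any(n_per_group <= 0))
    stop_invalid("n_per_group must name positive maintainer/progressor/reverter sizes")
  if (any(cellprop_alpha <= 0))
    stop_invalid("Dirichlet concentration parameters must be positive")
  if (subject_sd <= 0 || residual_sd <= 0 || spatial_sd < 0)
    stop_invalid("all standard deviations must be positive")
  structure(list(n_per_group = n_per_group[groups],
                 age_median = age_median, age_sdlog = age_sdlog,
                 sex_prob = sex_prob, platform_prob = platform_prob,
                 cellprop_alpha = cellprop_alpha,
                 subject_sd = subject_sd, residual_sd = residual_sd,
                 spatial_sd = spatial_sd, spatial_decay = spatial_decay,
                 n_missing_ancestry = as.integer(n_missing_ancestry),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

cell_types <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic sample sheet
#'
#' Two rows per subject (visits `pre` and `post`). Sex, platform, ancestry
#' PCs and the subject random-intercept seed are subject-level; age and the
#' six cell proportions are drawn per visit. Platform assignment is
#' independent of phenotype, with both visits of a subject on the same
#' platform.
#'
#' @param design a [cohort_design()].
#' @return data.frame of class `sample_sheet` with columns `sample_id`,
#'   `subject_id`, `group`, `visit`, `age`, `sex`, `platform`, the six cell
#'   proportions, `ancestry_pc1`, `ancestry_pc2`.
#' @export
generate_samples <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    groups <- rep(names(design$n_per_group), design$n_per_group)
    n_sub <- length(groups)
    subject_id <- sprintf("S%03d", seq_len(n_sub))
    sex <- ifelse(runif(n_sub) < design$sex_prob, "F", "M")
    platform <- ifelse(runif(n_sub) < design$platform_prob, "EPIC", "450K")
    pc <- matrix(rnorm(2 * n_sub), ncol = 2)
    if (design$n_missing_ancestry > 0) {
      drop <- sample(n_sub, min(design$n_missing_ancestry, n_sub))
      pc[drop, ] <- NA_real_
    }
    sheets <- lapply(c("pre", "post"), function(v) {
      med <- design$age_median[[v]][groups]
      data.frame(sample_id = paste0(subject_id, "_", v),
                 subject_id = subject_id, group = groups, visit = v,
                 age = rlnorm(n_sub, meanlog = log(med),
                              sdlog = design$age_sdlog),
                 sex = sex, platform = platform,
                 stringsAsFactors = FALSE)
    })
    out <- rbind(sheets[[1]], sheets[[2]])
    cp <- rdirichlet(nrow(out), design$cellprop_alpha)
    colnames(cp) <- cell_types
    out <- cbind(out, as.data.frame(cp))
    out$ancestry_pc1 <- rep(pc[, 1], 2)
    out$ancestry_pc2 <- rep(pc[, 2], 2)
    out <- out[order(out$subject_id, factor(out$visit, c("pre", "post"))), ]
    rownames(out) <- NULL
    class(out) <- c("sample_sheet", "data.frame")
    out
  })
}

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "subject_id", "group", "visit", "age", "sex",
            "platform", cell_types)
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in sample sheet")
  tab <- table(samples$subject_id, samples$visit)
  if (!all(tab == 1))
    stop("each subject must have exactly one pre and one post row")
  invisible(samples)
}
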