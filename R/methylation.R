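#' Generate a synthetic M-value matrix with planted region effects
#'
#' Each entry follows an additive signal model on the M-value scale:
#' probe baseline + probe-specific covariate effects (age, sex, platform,
#' cell proportions) + subject random intercept + planted group mean offset
#' (mu regions, both visits) + planted group-specific visit slope (delta
#' regions, post visit only) + spatially correlated within-cluster noise
#' with correlation `exp(-spatial_decay * distance)` + independent
#' residual. The covariate and correlation structure mirrors what the
#' downstream mixed models adjust for, so with all planted effects zero the
#' per-probe interaction and group tests are calibrated.
#'
#' @param manifest a `probe_manifest` (with `cluster` column).
#' @param samples a `sample_sheet` from [generate_samples()].
#' @param truth a [ground_truth()]; regions must refer to manifest
#'   coordinates.
#' @param design the [cohort_design()] providing variance components and
#'   the seed.
#' @return numeric matrix (probes x samples, M-units) with the manifest
#'   attached as attribute `"manifest"`.
#' @export
generate_methylation <- function(manifest, samples, truth = ground_truth(),
                                 design = cohort_design()) {
  validate_sample_sheet(samples)
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "ground_truth"))
  regs <- rbind(truth$planted_delta_regions[c("region_id", "chrom", "start", "stop")],
                truth$planted_mu_regions[c("region_id", "chrom", "start", "stop")])
  if (nrow(regs)) {
    hit <- vapply(seq_len(nrow(regs)), function(i) {
      any(manifest$chrom == regs$chrom[i] & manifest$pos >= regs$start[i] &
            manifest$pos <= regs$stop[i])
    }, logical(1))
    if (!all(hit))
      stop("ground-truth regions outside manifest coordinates: ",
           paste(regs$region_id[!hit], collapse = ", "))
  }
  n_probe <- nrow(manifest); n_samp <- nrow(samples)
  with_seed(design$seed + 1000003L, {
    # probe baselines: bimodal, like the M-value distribution of real arrays
    baseline <- ifelse(runif(n_probe) < 0.5, -2.5, 2.5) + rnorm(n_probe)
    age_eff <- rnorm(n_probe, 0, 0.005)
    sex_eff <- rnorm(n_probe, 0, 0.05)
    plat_eff <- rnorm(n_probe, 0, 0.08)
    cell_eff <- matrix(rnorm(n_probe * 6, 0, 0.3), ncol = 6)

    subj <- unique(samples$subject_id)
    b <- setNames(rnorm(length(subj), 0, design$subject_sd), subj)

    cellmat <- as.matrix(samples[cell_types])
    fixed <- outer(age_eff, samples$age) +
      outer(sex_eff, as.numeric(samples$sex == "F")) +
      outer(plat_eff, as.numeric(samples$platform == "EPIC")) +
      cell_eff %*% t(cellmat)
    M <- baseline + fixed +
      matrix(rep(b[samples$subject_id], each = n_probe), nrow = n_probe)

    post <- samples$visit == "post"
    add_region <- function(M, reg, kind, post_only) {
      for (i in seq_len(nrow(reg))) {
        rows <- which(manifest$chrom == reg$chrom[i] &
                        manifest$pos >= reg$start[i] &
                        manifest$pos <= reg$stop[i])
        for (g in c("maintainer", "progressor", "reverter")) {
          eff <- reg[[paste(kind, g, sep = "_")]][i]
          cols <- samples$group == g
          if (post_only) cols <- cols & post
          M[rows, cols] <- M[rows, cols] + eff
        }
      }
      M
    }
    M <- add_region(M, truth$planted_mu_regions, "offset", post_only = FALSE)
    M <- add_region(M, truth$planted_delta_regions, "slope", post_only = TRUE)

    # spatially correlated noise, independent across clusters and samples
    clusters <- manifest$cluster
    key <- ifelse(is.na(clusters), paste0(".single", seq_len(n_probe)), clusters)
    for (cl in unique(key)) {
      rows <- which(key == cl)
      k <- length(rows)
      z <- matrix(rnorm(k * n_samp), nrow = k)
      if (k > 1 && is.finite(design$spatial_decay)) {
        d <- abs(outer(manifest$pos[rows], manifest$pos[rows], "-"))
        C <- exp(-design$spatial_decay * d)
        z <- t(chol(C)) %*% z
      }
      M[rows, ] <- M[rows, ] + design$spatial_sd * z
    }
    M <- M + matrix(rnorm(n_probe * n_samp, 0, design$residual_sd),
                    nrow = n_probe)
    dimnames(M) <- list(manifest$probe_id, samples$sample_id)
    attr(M, "manifest") <- manifest
    M
  })
}
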