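#' Generate expression and metabolite matrices linked to regional methylation
#'
#' Builds a post-visit expression matrix (genes x subjects) for a subset of
#' subjects, and paired pre/post metabolite matrices with panel labels for a
#' second subset, with selected features linearly linked to regional
#' methylation signals from the supplied M-value matrix:
#'
#' * a linked gene's expression is the standardized post-visit regional mean
#'   methylation plus noise, calibrated so the population Spearman
#'   correlation equals the truth record's `target_rho` (via the bivariate
#'   normal identity `rho_pearson = 2 sin(pi rho_s / 6)`);
#' * a linked metabolite's pre-to-post change on the latent (log) scale is
#'   the standardized regional delta signal plus noise, with population
#'   standardized beta equal to `target_beta`; raw levels are exponentiated
#'   so the Box-Cox step has work to do.
#'
#' Unlinked features are pure noise. Small age/sex effects are added to all
#' features so the residualization steps are exercised. Gene transcription
#' start sites are placed within the cis window of their linked region;
#' unlinked genes scatter inside and outside it.
#'
#' @param truth a [ground_truth()] with `linked_genes` /
#'   `linked_metabolites` (either may be NULL).
#' @param samples the `sample_sheet`.
#' @param methylation M-value matrix from [generate_methylation()] (carries
#'   its manifest as an attribute).
#' @param seed integer seed.
#' @param n_expr_subjects subjects with expression data (post visit only).
#' @param n_met_subjects subjects with metabolite data at both visits.
#' @param n_genes total genes (linked + unlinked).
#' @param panel_sizes named integer vector of annotated metabolites per
#'   panel; defaults follow a typical untargeted plasma study (HILIC 81,
#'   Lipid 373, GCTOF 98).
#' @return list with elements `expression` (genes x subjects, colnames are
#'   subject ids), `tss_table` (gene_id, chrom, tss), `metabolites`
#'   (metabolites x samples, colnames are sample ids covering both visits
#'   of the metabolite subjects), `panels` (named character vector),
#'   `expr_subjects`, `met_subjects`.
#' @export
generate_linked_omics <- function(truth, samples, methylation, seed = 1L,
                                  n_expr_subjects = 36L,
                                  n_met_subjects = 110L,
                                  n_genes = 60L,
                                  panel_sizes = c(HILIC = 81L, Lipid = 373L,
                                                  GCTOF = 98L)) {
  manifest <- attr(methylation, "manifest")
  if (is.null(manifest)) stop("methylation matrix lacks a manifest attribute")
  lg <- truth$linked_genes
  lm_ <- truth$linked_metabolites
  if (!is.null(lg) && nrow(lg) && any(abs(lg$target_rho) >= 1))
    stop_invalid("target correlations must lie in (-1, 1)")
  regs <- rbind(truth$planted_delta_regions[c("region_id", "chrom", "start", "stop")],
                truth$planted_mu_regions[c("region_id", "chrom", "start", "stop")])
  region_rows <- function(id) {
    r <- regs[regs$region_id == id, ]
    if (!nrow(r)) stop_invalid("linked feature references unknown region ", id)
    which(manifest$chrom == r$chrom & manifest$pos >= r$start &
            manifest$pos <= r$stop)
  }
  zscore <- function(x) (x - mean(x)) / sd(x)

  with_seed(seed, {
    subj <- unique(samples$subject_id)
    expr_subjects <- sort(sample(subj, min(n_expr_subjects, length(subj))))
    met_subjects <- sort(sample(subj, min(n_met_subjects, length(subj))))
    post_id <- samples$sample_id[match(paste0(expr_subjects, "_post"),
                                       paste0(samples$subject_id, "_",
                                              samples$visit))]
    sub_row <- match(post_id, samples$sample_id)
    age_e <- samples$age[sub_row]; sexF_e <- as.numeric(samples$sex[sub_row] == "F")

    n_linked <- if (is.null(lg)) 0L else nrow(lg)
    gene_id <- sprintf("g%04d", seq_len(max(n_genes, n_linked)))
    if (n_linked) gene_id[seq_len(n_linked)] <- lg$gene_id
    expr <- matrix(rnorm(length(gene_id) * length(expr_subjects)),
                   nrow = length(gene_id),
                   dimnames = list(gene_id, expr_subjects))
    tss <- data.frame(gene_id = gene_id, chrom = NA_character_, tss = NA_integer_)
    mid <- function(id) {
      r <- regs[regs$region_id == id, ]
      floor((r$start + r$stop) / 2)
    }
    anchor <- if (nrow(regs)) regs$region_id else NA
    for (j in seq_along(gene_id)) {
      if (j <= n_linked) {
        rid <- lg$region_id[j]
        sig <- zscore(colMeans(methylation[region_rows(rid), post_id,
                                           drop = FALSE]))
        rho <- 2 * sin(pi * lg$target_rho[j] / 6)  # Pearson hitting Spearman target
        expr[j, ] <- rho * sig + sqrt(1 - rho^2) * rnorm(length(sig))
        tss$chrom[j] <- regs$chrom[regs$region_id == rid]
        tss$tss[j] <- mid(rid) + sample(-300000:300000, 1)
      } else if (!is.na(anchor[1])) {
        rid <- sample(anchor, 1)
        tss$chrom[j] <- regs$chrom[regs$region_id == rid]
        tss$tss[j] <- max(1L, mid(rid) + sample(-800000:800000, 1))
      } else {
        tss$chrom[j] <- sample(unique(manifest$chrom), 1)
        tss$tss[j] <- sample(max(manifest$pos), 1)
      }
      expr[j, ] <- expr[j, ] + 0.01 * age_e + 0.05 * sexF_e
    }

    pre_id <- samples$sample_id[match(paste0(met_subjects, "_pre"),
                                      paste0(samples$subject_id, "_",
                                             samples$visit))]
    post_id_m <- samples$sample_id[match(paste0(met_subjects, "_post"),
                                         paste0(samples$subject_id, "_",
                                                samples$visit))]
    n_met <- sum(panel_sizes)
    panels <- rep(names(panel_sizes), panel_sizes)
    met_id <- sprintf("%s_m%04d", panels, seq_len(n_met))
    n_lm <- if (is.null(lm_)) 0L else nrow(lm_)
    if (n_lm) {
      # linked metabolites take the first slots of their panel
      for (i in seq_len(n_lm)) {
        slot <- which(panels == lm_$panel[i])[i]
        met_id[slot] <- lm_$metabolite_id[i]
      }
    }
    names(panels) <- met_id
    nsub <- length(met_subjects)
    agep <- samples$age[match(pre_id, samples$sample_id)]
    ageq <- samples$age[match(post_id_m, samples$sample_id)]
    sexF <- as.numeric(samples$sex[match(pre_id, samples$sample_id)] == "F")
    met <- matrix(NA_real_, nrow = n_met, ncol = 2 * nsub,
                  dimnames = list(met_id, c(pre_id, post_id_m)))
    for (i in seq_len(n_met)) {
      base <- rnorm(1, 5, 1)
      latent_pre <- rnorm(nsub)
      link <- match(met_id[i], if (n_lm) lm_$metabolite_id else character(0))
      if (!is.na(link)) {
        rows <- region_rows(lm_$region_id[link])
        dsig <- zscore(colMeans(methylation[rows, post_id_m, drop = FALSE]) -
                         colMeans(methylation[rows, pre_id, drop = FALSE]))
        bb <- lm_$target_beta[link]
        dlat <- bb * dsig + sqrt(1 - bb^2) * rnorm(nsub)
      } else {
        dlat <- rnorm(nsub)
      }
      lp <- latent_pre + 0.02 * agep + 0.10 * sexF
      lq <- latent_pre + dlat + 0.02 * ageq + 0.10 * sexF
      met[i, ] <- exp(base + 0.4 * c(lp, lq))
    }
    list(expression = expr, tss_table = tss, metabolites = met,
         panels = panels, expr_subjects = expr_subjects,
         met_subjects = met_subjects)
  })
}
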