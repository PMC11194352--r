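#' Ground-truth record for a synthetic cohort
#'
#' Collects the planted effects of a simulation so recovery can be scored:
#' regions whose pre-to-post methylation change differs by group (delta
#' regions, per-group visit slopes in M-units), regions whose average
#' methylation differs by group (mu regions, per-group mean offsets),
#' genes/metabolites linearly linked to regional methylation signals, and
#' the identifiers of probes carrying no planted effect.
#'
#' @param planted_delta_regions data.frame with columns `region_id`,
#'   `chrom`, `start`, `stop` (1-based inclusive), `slope_maintainer`,
#'   `slope_progressor`, `slope_reverter`.
#' @param planted_mu_regions data.frame with columns `region_id`, `chrom`,
#'   `start`, `stop`, `offset_maintainer`, `offset_progressor`,
#'   `offset_reverter`.
#' @param linked_genes data.frame with columns `gene_id`, `region_id`,
#'   `target_rho` (population Spearman correlation, in (-1, 1)).
#' @param linked_metabolites data.frame with columns `metabolite_id`,
#'   `panel`, `region_id`, `target_beta` (population standardized beta).
#' @param null_probes character vector of probe ids with no planted effect
#'   (filled in by [generate_methylation()] when empty).
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(planted_delta_regions = empty_regions("slope"),
                         planted_mu_regions = empty_regions("offset"),
                         linked_genes = NULL,
                         linked_metabolites = NULL,
                         null_probes = character(0)) {
  regs <- rbind(planted_delta_regions[c("region_id", "chrom", "start", "stop")],
                planted_mu_regions[c("region_id", "chrom", "start", "stop")])
  if (nrow(regs) > 1) {
    regs <- regs[order(regs$chrom, regs$start), ]
    same <- regs$chrom[-1] == regs$chrom[-nrow(regs)]
    if (any(same & regs$start[-1] <= regs$stop[-nrow(regs)]))
      stop_invalid("planted regions must not overlap")
  }
  for (df in list(linked_genes, linked_metabolites)) {
    if (!is.null(df) && nrow(df) &&
        !all(df$region_id %in% regs$region_id))
      stop_invalid("linked features must reference planted regions")
  }
  if (!is.null(linked_genes) && nrow(linked_genes) &&
      any(abs(linked_genes$target_rho) >= 1))
    stop_invalid("target correlations must lie in (-1, 1)")
  structure(list(planted_delta_regions = planted_delta_regions,
                 planted_mu_regions = planted_mu_regions,
                 linked_genes = linked_genes,
                 linked_metabolites = linked_metabolites,
                 null_probes = null_probes),
            class = "ground_truth")
}

empty_regions <- function(kind) {
  df <- data.frame(region_id = character(0), chrom = character(0),
                   start = integer(0), stop = integer(0))
  for (g in c("maintainer", "progressor", "reverter"))
    df[[paste(kind, g, sep = "_")]] <- numeric(0)
  df
}

#' Plant region effects into manifest clusters
#'
#' Picks distinct probe clusters from a synthetic manifest and assigns
#' per-group effects, returning a [ground_truth()]. Delta effects are
#' per-group visit slopes; mu effects are per-group mean offsets. Effect
#' scales default to the magnitudes seen in published two-visit
#' methylation cohorts (median |slope| 0.02-0.10 M-units; pairwise offsets
#' up to ~0.4 M-units).
#'
#' @param manifest a `probe_manifest` with a `cluster` column.
#' @param delta_slopes list of length-3 numeric vectors
#'   `c(maintainer, progressor, reverter)`, one per delta region to plant.
#' @param mu_offsets list of length-3 numeric vectors, one per mu region.
#' @param min_probes only clusters with at least this many probes are
#'   eligible.
#' @param seed integer seed for cluster selection.
#' @return a `ground_truth`.
#' @export
plant_regions <- function(manifest, delta_slopes = list(), mu_offsets = list(),
                          min_probes = 4L, seed = 1L) {
  sizes <- table(manifest$cluster[!is.na(manifest$cluster)])
  eligible <- names(sizes)[sizes >= min_probes]
  n_needed <- length(delta_slopes) + length(mu_offsets)
  if (length(eligible) < n_needed)
    stop_invalid("not enough clusters with >= ", min_probes, " probes")
  with_seed(seed, {
    chosen <- sample(eligible, n_needed)
    span <- function(cl) {
      p <- manifest$pos[!is.na(manifest$cluster) & manifest$cluster == cl]
      c(min(p), max(p))
    }
    mk <- function(slopes, labels, kind) {
      if (!length(slopes)) return(empty_regions(kind))
      do.call(rbind, lapply(seq_along(slopes), function(i) {
        cl <- labels[i]; sp <- span(cl)
        ef <- slopes[[i]]
        out <- data.frame(region_id = cl,
                          chrom = manifest$chrom[match(cl, manifest$cluster)],
                          start = sp[1], stop = sp[2])
        out[[paste0(kind, "_maintainer")]] <- ef[1]
        out[[paste0(kind, "_progressor")]] <- ef[2]
        out[[paste0(kind, "_reverter")]] <- ef[3]
        out
      }))
    }
    delta_labels <- chosen[seq_along(delta_slopes)]
    mu_labels <- chosen[length(delta_slopes) + seq_along(mu_offsets)]
    ground_truth(planted_delta_regions = mk(delta_slopes, delta_labels, "slope"),
                 planted_mu_regions = mk(mu_offsets, mu_labels, "offset"))
  })
}
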