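#' Generate a synthetic probe manifest with clustered CpGs
#'
#' Lays out CpG probes along `n_chrom` synthetic chromosomes as tight
#' clusters (candidate region material) separated by gaps wide enough that
#' the sliding-window region caller can never join two clusters, with an
#' isolated singleton probe dropped midway into each inter-cluster gap.
#' Cluster geometry defaults keep intra-cluster spacing well under the
#' 500 bp combination window so regions of four or more probes are
#' producible.
#'
#' Each probe carries the flags consumed by [filter_probes()]: autosomal
#' status, proximity (< 2 bp) to a known SNP, and the observed beta range on
#' each array platform.
#'
#' @param n_chrom number of chromosomes.
#' @param clusters_per_chrom clusters per chromosome.
#' @param probes_per_cluster integer pair, inclusive range of cluster sizes.
#' @param spacing bp pair, inclusive range of intra-cluster gaps; the upper
#'   bound must be < 500 so cluster members stay combinable.
#' @param gap bp pair, range of inter-cluster gaps; lower bound must exceed
#'   500 so clusters cannot merge.
#' @param frac_nonautosomal,frac_near_snp expected fraction of probes
#'   flagged non-autosomal / SNP-adjacent.
#' @param frac_invariant expected fraction of probes whose beta range is
#'   below 3% on both platforms.
#' @param seed integer seed; output is deterministic given the seed.
#' @return data.frame of class `probe_manifest` with columns `probe_id`,
#'   `chrom`, `pos` (1-based), `cluster` (cluster label, NA for singletons),
#'   `autosomal`, `near_snp`, `beta_range_450k`, `beta_range_epic`.
#' @export
generate_manifest <- function(n_chrom = 4, clusters_per_chrom = 10,
                              probes_per_cluster = c(4L, 10L),
                              spacing = c(20L, 80L),
                              gap = c(2000L, 20000L),
                              frac_nonautosomal = 0.05,
                              frac_near_snp = 0.05,
                              frac_invariant = 0.10,
                              seed = 1L) {
  if (n_chrom < 1 || clusters_per_chrom < 1)
    stop_invalid("n_chrom and clusters_per_chrom must be positive")
  if (length(probes_per_cluster) != 2 || any(probes_per_cluster < 1))
    stop_invalid("probes_per_cluster must be a positive integer pair")
  if (max(spacing) >= 500)
    stop_invalid("intra-cluster spacing upper bound must be < 500 bp")
  if (min(gap) <= 500)
    stop_invalid("inter-cluster gaps must exceed 500 bp")
  # sample() treats a length-1 vector as 1:n; guard draws from ranges
  draw <- function(range, n) {
    v <- seq(range[1], range[2])
    if (length(v) == 1) rep(v, n) else sample(v, n, replace = TRUE)
  }
  with_seed(seed, {
    rows <- vector("list", n_chrom)
    for (ch in seq_len(n_chrom)) {
      chrom <- paste0("chr", ch)
      pos <- integer(0); cluster <- character(0)
      cursor <- 1000L
      for (cl in seq_len(clusters_per_chrom)) {
        k <- draw(probes_per_cluster, 1)
        steps <- draw(spacing, k - 1)
        p <- cursor + c(0L, cumsum(steps))
        lab <- sprintf("%s_c%02d", chrom, cl)
        pos <- c(pos, p); cluster <- c(cluster, rep(lab, k))
        g <- draw(gap, 1)
        # isolated singleton midway into the gap (stays > 500 bp from both
        # flanking clusters by the gap lower bound)
        pos <- c(pos, max(p) + g %/% 2L); cluster <- c(cluster, NA_character_)
        cursor <- max(p) + g
      }
      rows[[ch]] <- data.frame(chrom = chrom, pos = as.integer(pos),
                               cluster = cluster, stringsAsFactors = FALSE)
    }
    man <- do.call(rbind, rows)
    n <- nrow(man)
    man$probe_id <- sprintf("cg%08d", seq_len(n))
    man$autosomal <- runif(n) >= frac_nonautosomal
    man$near_snp <- runif(n) < frac_near_snp
    # beta ranges: variable probes get ranges comfortably above the 3%
    # threshold on at least one platform; invariant probes below on both
    invariant <- runif(n) < frac_invariant
    r450 <- ifelse(invariant, runif(n, 0.001, 0.029), runif(n, 0.05, 0.60))
    repic <- ifelse(invariant, runif(n, 0.001, 0.029),
                    pmax(0.031, r450 + rnorm(n, 0, 0.05)))
    man$beta_range_450k <- round(r450, 4)
    man$beta_range_epic <- round(repic, 4)
    man <- man[order(man$chrom, man$pos), c("probe_id", "chrom", "pos",
                                            "cluster", "autosomal", "near_snp",
                                            "beta_range_450k", "beta_range_epic")]
    rownames(man) <- NULL
    class(man) <- c("probe_manifest", "data.frame")
    man
  })
}

#' Probe-level exclusion filter
#'
#' A probe is kept iff it is autosomal, not within 2 bp of a known SNP, and
#' its beta range is at least 3% on at least one platform (removal requires
#' a beta range below 3% on *both* platforms).
#'
#' @param manifest a `probe_manifest` data.frame (see [generate_manifest()]
#'   for the required columns).
#' @param min_beta_range removal threshold on the beta range (default 0.03).
#' @return character vector of retained `probe_id`s.
#' @export
filter_probes <- function(manifest, min_beta_range = 0.03) {
  need <- c("probe_id", "autosomal", "near_snp",
            "beta_range_450k", "beta_range_epic")
  if (!all(need %in% names(manifest)))
    stop("manifest is missing required columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  if (anyNA(manifest$beta_range_450k) || anyNA(manifest$beta_range_epic))
    stop("beta range fields contain missing values")
  keep <- manifest$autosomal & !manifest$near_snp &
    !(manifest$beta_range_450k < min_beta_range &
        manifest$beta_range_epic < min_beta_range)
  manifest$probe_id[keep]
}
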