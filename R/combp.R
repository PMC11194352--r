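p_to_z <- function(p, eps = 1e-16) {
  qnorm(1 - pmin(pmax(p, eps), 1 - eps))
}

# enumerate same-chromosome probe pairs with distance <= window
probe_pairs <- function(positions, chrom, window) {
  dist <- integer(0); ia <- integer(0); ib <- integer(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(positions[idx])]
    pos <- positions[idx]
    n <- length(idx)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      j <- i + 1
      while (j <= n && pos[j] - pos[i] <= window) {
        dist <- c(dist, pos[j] - pos[i])
        ia <- c(ia, idx[i]); ib <- c(ib, idx[j])
        j <- j + 1
      }
    }
  }
  list(dist = dist, a = ia, b = ib)
}

#' Distance-binned autocorrelation of probe-level evidence
#'
#' Transforms p-values to one-sided z-scores (`z = qnorm(1 - p)`) and, for
#' each genomic distance bin `(0, step], (step, 2 step], ..., (window -
#' step, window]`, computes the Pearson correlation over all
#' same-chromosome probe pairs whose separation falls in the bin. Bins with
#' fewer than `min_pairs` pairs inherit the previous bin's correlation (the
#' first bin falls back to 0 with a warning). Correlations are clipped to
#' `[0, 1]` before use in combination: negative estimates would deflate the
#' Stouffer-Liptak variance term and are treated as noise around zero.
#'
#' @param pvals per-probe p-values.
#' @param positions 1-based bp positions, sorted within chromosome.
#' @param chrom chromosome labels (single chromosome assumed if omitted).
#' @param window maximum pair distance considered (bp).
#' @param step distance bin width (bp).
#' @param min_pairs minimum pairs for a bin to estimate its own value.
#' @return list of class `acf_estimate` with `bin_edges`, `correlations`
#'   (clipped), `correlations_raw`, `n_pairs`.
#' @export
estimate_acf <- function(pvals, positions, chrom = NULL, window = 500,
                         step = 50, min_pairs = 10) {
  n <- length(pvals)
  if (length(positions) != n) stop_invalid("pvals/positions length mismatch")
  if (is.null(chrom)) chrom <- rep("chr1", n)
  z <- p_to_z(pvals)
  pairs <- probe_pairs(positions, chrom, window)
  if (!length(pairs$dist))
    stop("insufficient probe pairs within ", window,
         " bp to estimate the autocorrelation")
  bins <- ceiling(window / step)
  bin_of <- pmin(pmax(ceiling(pairs$dist / step), 1L), bins)
  raw <- rep(NA_real_, bins); n_pairs <- integer(bins)
  for (b in seq_len(bins)) {
    sel <- bin_of == b
    n_pairs[b] <- sum(sel)
    if (n_pairs[b] >= min_pairs) {
      za <- z[pairs$a[sel]]; zb <- z[pairs$b[sel]]
      if (sd(za) == 0 || sd(zb) == 0) {
        warning("constant z within distance bin ", b, "; correlation set to 0")
        raw[b] <- 0
      } else raw[b] <- cor(za, zb)
    }
  }
  for (b in seq_len(bins)) {
    if (is.na(raw[b])) {
      if (b == 1) {
        warning("first distance bin has < ", min_pairs, " pairs; using 0")
        raw[b] <- 0
      } else raw[b] <- raw[b - 1]
    }
  }
  structure(list(bin_edges = seq(0, window, by = step),
                 correlations = pmin(pmax(raw, 0), 1),
                 correlations_raw = raw,
                 n_pairs = n_pairs, step = step, window = window),
            class = "acf_estimate")
}

# sigma for a vector of pair distances; distances beyond the last bin take
# the terminal bin's correlation
acf_sigma <- function(acf, dist) {
  bins <- length(acf$correlations)
  idx <- pmin(pmax(ceiling(dist / acf$step), 1L), bins)
  acf$correlations[idx]
}

slk_combine <- function(z, dmat, acf) {
  k <- length(z)
  if (k == 1) return(1 - pnorm(z))
  sig <- acf_sigma(acf, dmat[upper.tri(dmat)])
  zc <- sum(z) / sqrt(k + 2 * sum(sig))
  1 - pnorm(zc)
}

#' Stouffer-Liptak spatial correction of per-probe p-values
#'
#' For each probe, all probes within `window` bp on the same chromosome
#' (including itself) are combined:
#' `z_comb = sum(z_i) / sqrt(k + 2 * sum_{i<j} sigma(d_ij))`, with `sigma`
#' looked up from the distance-binned ACF, and the corrected p-value is
#' `1 - pnorm(z_comb)`. A probe with no neighbours keeps its raw p-value.
#' Raw p-values of 0 or 1 are clamped to `[1e-16, 1 - 1e-16]` before the
#' z-transform.
#'
#' @inheritParams estimate_acf
#' @param acf an [estimate_acf()] result.
#' @return numeric vector of corrected p-values, input order.
#' @export
slk_correct <- function(pvals, positions, acf, chrom = NULL, window = 500) {
  n <- length(pvals)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  z <- p_to_z(pvals)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ord <- idx[order(positions[idx])]
    pos <- positions[ord]
    for (ii in seq_along(ord)) {
      nb <- which(abs(pos - pos[ii]) <= window)
      d <- abs(outer(pos[nb], pos[nb], "-"))
      out[ord[ii]] <- slk_combine(z[ord[nb]], d, acf)
    }
  }
  out
}

#' Sliding-window candidate region finder
#'
#' Maximal runs of *consecutive* probes (in position order) whose corrected
#' p-value is below `seed_p`, where successive members lie at most `dist`
#' bp apart on the same chromosome. A probe at or above the seed threshold
#' breaks the run even if later probes fall back below it.
#'
#' @param corrected_pvals spatially corrected p-values.
#' @param positions 1-based bp positions.
#' @param chrom chromosome labels.
#' @param seed_p seed threshold (default 0.1).
#' @param dist maximum within-region gap (bp, default 500).
#' @return data.frame with one row per candidate run: `chrom`, `start`,
#'   `stop` (1-based inclusive probe span), `n_probes`, and a list column
#'   `probe_idx` of member indices into the input vectors.
#' @export
find_candidate_regions <- function(corrected_pvals, positions, chrom = NULL,
                                   seed_p = 0.1, dist = 500) {
  n <- length(corrected_pvals)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ord <- idx[order(positions[idx])]
    sig <- corrected_pvals[ord] < seed_p
    if (!any(sig)) next
    pos <- positions[ord]
    # run breaks at a non-significant probe or a gap > dist
    new_run <- c(TRUE, !sig[-length(sig)] | diff(pos) > dist)
    run_id <- cumsum(new_run)[sig]
    hit <- ord[sig]
    for (r in unique(run_id)) {
      members <- hit[run_id == r]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(positions[members]),
        stop = max(positions[members]), n_probes = length(members))
      out[[length(out)]]$probe_idx <- list(members)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      stop = integer(0), n_probes = integer(0),
                      probe_idx = I(list())))
  do.call(rbind, out)
}

#' Region-level Stouffer-Liptak p-value
#'
#' Single combination of a region's *raw* probe p-values with ACF-derived
#' pairwise correlations (candidate runs are found on corrected p-values;
#' combining corrected values again would double-count neighbourhood
#' evidence). A singleton region keeps its raw p-value.
#'
#' @param pvals raw p-values of the region's probes.
#' @param positions their bp positions.
#' @param acf an [estimate_acf()] result.
#' @return scalar region p-value.
#' @export
region_pvalue <- function(pvals, positions, acf) {
  if (!length(pvals)) stop_invalid("region must contain at least one probe")
  z <- p_to_z(pvals)
  d <- abs(outer(positions, positions, "-"))
  slk_combine(z, d, acf)
}

#' Sidak adjustment of a region p-value
#'
#' `sidak_p = 1 - (1 - slk_p)^(total_covered_bases / region_width)`: the
#' exponent is the number of similarly sized regions the covered genome
#' could hold, where coverage is the summed per-chromosome span of analyzed
#' probes.
#'
#' @param slk_p region-level p-value in `[0, 1]`.
#' @param region_width region width in bp (>= 1).
#' @param total_covered_bases total analyzed span in bp.
#' @return adjusted p-value.
#' @export
sidak_adjust <- function(slk_p, region_width, total_covered_bases) {
  if (any(slk_p < 0 | slk_p > 1)) stop_invalid("slk_p must lie in [0, 1]")
  if (any(region_width < 1)) stop_invalid("region_width must be >= 1")
  if (any(total_covered_bases < region_width))
    stop_invalid("total_covered_bases must be >= region_width")
  ratio <- total_covered_bases / region_width
  # log1p form keeps precision for tiny slk_p
  -expm1(ratio * log1p(-slk_p))
}

#' Call differentially methylated regions from probe-level p-values
#'
#' The full spatial pipeline: ACF estimation, Stouffer-Liptak correction of
#' every probe against its `window` bp neighbourhood, sliding-window
#' candidate runs of corrected p-values below `seed_p`, a region-level
#' Stouffer-Liptak p-value over raw member p-values, and a Sidak adjustment
#' against the genome-wide analyzed span. Probes with missing p-values are
#' dropped before analysis.
#'
#' @param pvals per-probe p-values (e.g. `$results$p_2df` of a
#'   [dmp_fit()]).
#' @param positions 1-based bp positions.
#' @param chrom chromosome labels.
#' @param probe_id probe identifiers (optional).
#' @param seed_p candidate seed threshold.
#' @param window combination window (bp); also the maximum within-region
#'   gap.
#' @param step ACF distance-bin width (bp).
#' @return object of class `dmr_set`: a data.frame with one row per
#'   candidate region (`region_id`, `chrom`, `start`, `stop`, `n_probes`,
#'   `slk_p`, `sidak_p`, `leading_probe`, list column `probe_ids`), sorted
#'   by `sidak_p`.
#' @export
call_dmrs <- function(pvals, positions, chrom, probe_id = NULL,
                      seed_p = 0.1, window = 500, step = 50) {
  if (is.null(probe_id)) probe_id <- sprintf("p%06d", seq_along(pvals))
  ok <- !is.na(pvals)
  pvals <- pvals[ok]; positions <- positions[ok]
  chrom <- chrom[ok]; probe_id <- probe_id[ok]
  acf <- estimate_acf(pvals, positions, chrom, window = window, step = step)
  corr <- slk_correct(pvals, positions, acf, chrom, window = window)
  cand <- find_candidate_regions(corr, positions, chrom, seed_p = seed_p,
                                 dist = window)
  covered <- sum(vapply(split(positions, chrom),
                        function(p) diff(range(p)), numeric(1)))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    m <- cand$probe_idx[[i]]
    m <- m[order(positions[m])]
    slk <- region_pvalue(pvals[m], positions[m], acf)
    width <- cand$stop[i] - cand$start[i] + 1
    lead <- m[order(pvals[m], positions[m])][1]
    data.frame(chrom = cand$chrom[i], start = cand$start[i],
               stop = cand$stop[i], n_probes = cand$n_probes[i],
               slk_p = slk,
               sidak_p = sidak_adjust(slk, width, max(covered, width)),
               leading_probe = probe_id[lead])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), stop = integer(0),
               n_probes = integer(0), slk_p = numeric(0), sidak_p = numeric(0),
               leading_probe = character(0))
  out$probe_ids <- lapply(cand$probe_idx,
                          function(m) probe_id[m[order(positions[m])]])
  out <- out[order(out$sidak_p, out$chrom, out$start), ]
  if (nrow(out)) out$region_id <- sprintf("DMR%03d", seq_len(nrow(out)))
  else out$region_id <- character(0)
  rownames(out) <- NULL
  out <- out[c("region_id", setdiff(names(out), "region_id"))]
  attr(out, "acf") <- acf
  attr(out, "covered_bases") <- covered
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("DMR set:", nrow(x), "candidate regions over",
      format(attr(x, "covered_bases"), big.mark = ","), "covered bases\n")
  if (nrow(x)) {
    show <- as.data.frame(x)[seq_len(min(nrow(x), 10)),
                             c("region_id", "chrom", "start", "stop",
                               "n_probes", "slk_p", "sidak_p",
                               "leading_probe")]
    print(show, row.names = FALSE, digits = 3)
    if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  }
  invisible(x)
}

#' @export
summary.dmr_set <- function(object, sidak_alpha = 0.10, ...) {
  cat(nrow(object), "candidate regions;",
      sum(object$sidak_p < sidak_alpha), "with Sidak p <", sidak_alpha, "\n")
  invisible(object)
}
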