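# share of values whose sign matches the majority sign; exact zeros count
# with the majority (configurable), a 50/50 split gives 0.5
sign_consistency <- function(x, zero_with_majority = TRUE) {
  s <- sign(x)
  pos <- sum(s > 0); neg <- sum(s < 0); zero <- sum(s == 0)
  maj <- max(pos, neg)
  if (zero_with_majority) maj <- maj + zero
  maj / length(x)
}

#' Summarize a delta region's per-group slope consistency
#'
#' For each group, computes the share of member probes whose within-group
#' visit slope carries the group's majority sign, and the median slope
#' across probes. A region qualifies for retention when the change
#' direction is unanimous (share = 1) in at least one group.
#'
#' @param region one row of a `dmr_set` (needs `region_id`, `n_probes`,
#'   `sidak_p`, and list column `probe_ids`).
#' @param dmp interaction-model results data.frame (`$results` of a
#'   [dmp_fit()]), containing every region probe.
#' @param zero_with_majority count slopes of exactly 0 with the majority
#'   sign (default TRUE).
#' @return one-row data.frame: region columns + `slope_pct_*`,
#'   `median_slope_*` per group, `retained` (filled by
#'   [filter_delta_dmrs()] rules).
#' @export
summarize_delta_region <- function(region, dmp, zero_with_majority = TRUE) {
  ids <- region$probe_ids[[1]]
  rows <- match(ids, dmp$probe_id)
  if (anyNA(rows))
    stop("region ", region$region_id, " has probes without interaction-model ",
         "results: ", paste(ids[is.na(rows)], collapse = ", "))
  d <- dmp[rows, ]
  out <- region[setdiff(names(region), "probe_ids")]
  for (g in c("reverter", "progressor", "maintainer")) {
    slopes <- d[[paste0("slope_", g)]]
    out[[paste0("slope_pct_", g)]] <- sign_consistency(slopes,
                                                       zero_with_majority)
    out[[paste0("median_slope_", g)]] <- median(slopes)
  }
  out$retained <- NA
  out
}

#' @rdname summarize_delta_region
#' @param regions a `dmr_set`.
#' @export
summarize_delta_regions <- function(regions, dmp, zero_with_majority = TRUE) {
  do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    summarize_delta_region(regions[i, ], dmp, zero_with_majority)))
}

#' Retention filter for delta regions
#'
#' A summarized delta region is retained iff it has at least `min_probes`
#' probes, its Sidak-adjusted region p-value is below `sidak_alpha`, and
#' the direction of change is consistent across 100% of member probes in
#' one or more groups.
#'
#' @param records data.frame from [summarize_delta_regions()] (or an
#'   equivalent table with `n_probes`, `sidak_p`, `slope_pct_*` columns).
#' @param min_probes minimum probe count (default 4).
#' @param sidak_alpha Sidak significance threshold (default 0.10).
#' @return `records` rows that pass, with `retained = TRUE`.
#' @export
filter_delta_dmrs <- function(records, min_probes = 4, sidak_alpha = 0.10) {
  pct <- as.matrix(records[paste0("slope_pct_",
                                  c("reverter", "progressor", "maintainer"))])
  keep <- records$n_probes >= min_probes & records$sidak_p < sidak_alpha &
    apply(pct, 1, max) >= 1
  out <- records[keep, , drop = FALSE]
  if (nrow(out)) out$retained <- TRUE
  rownames(out) <- NULL
  out
}

#' Summarize a mu region's pairwise-contrast consistency
#'
#' For each pairwise group contrast (P-R, R-M, P-M), computes the share of
#' member probes whose estimated contrast carries the majority sign, and
#' the median contrast across probes.
#'
#' @inheritParams summarize_delta_region
#' @param dmp group-model results data.frame with `diff_pvr`, `diff_rvm`,
#'   `diff_pvm` columns.
#' @return one-row data.frame with `consistency_*` and `median_*` columns
#'   per contrast.
#' @export
summarize_mu_region <- function(region, dmp, zero_with_majority = TRUE) {
  ids <- region$probe_ids[[1]]
  rows <- match(ids, dmp$probe_id)
  if (anyNA(rows))
    stop("region ", region$region_id, " has probes without group-model ",
         "results: ", paste(ids[is.na(rows)], collapse = ", "))
  d <- dmp[rows, ]
  out <- region[setdiff(names(region), "probe_ids")]
  for (con in c("pvr", "rvm", "pvm")) {
    x <- d[[paste0("diff_", con)]]
    out[[paste0("consistency_", con)]] <- sign_consistency(x,
                                                           zero_with_majority)
    out[[paste0("median_", con)]] <- median(x)
  }
  out$retained <- NA
  out
}

#' @rdname summarize_mu_region
#' @param regions a `dmr_set`.
#' @export
summarize_mu_regions <- function(regions, dmp, zero_with_majority = TRUE) {
  do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    summarize_mu_region(regions[i, ], dmp, zero_with_majority)))
}

#' Retention filter for mu regions
#'
#' Retained iff `n_probes >= min_probes`, `sidak_p < sidak_alpha`, and at
#' least one pairwise contrast is direction-consistent across 100% of
#' member probes.
#'
#' @inheritParams filter_delta_dmrs
#' @param records data.frame from [summarize_mu_regions()].
#' @export
filter_mu_dmrs <- function(records, min_probes = 4, sidak_alpha = 0.10) {
  con <- as.matrix(records[paste0("consistency_", c("pvr", "rvm", "pvm"))])
  keep <- records$n_probes >= min_probes & records$sidak_p < sidak_alpha &
    apply(con, 1, max) >= 1
  out <- records[keep, , drop = FALSE]
  if (nrow(out)) out$retained <- TRUE
  rownames(out) <- NULL
  out
}
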