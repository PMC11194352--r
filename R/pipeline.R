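#' Pipeline configuration
#'
#' Thresholds default to the published analysis settings: candidate seed
#' p-value 0.1, combination window 500 bp, ACF step 50 bp, minimum 4
#' probes per retained region, Sidak alpha 0.10, BH-FDR alpha 0.10, cis
#' window 500 kb.
#'
#' @param paths named list of input file paths (`manifest`, `sample_sheet`,
#'   `mvals`, and optionally `expression`, `tss_table`, `metabolites`,
#'   `panels`).
#' @param seed_p,window,step,min_probes,sidak_alpha,fdr_alpha,cis_window
#'   analysis thresholds.
#' @param seed integer seed recorded in output stamps.
#' @param out_dir output directory (NULL = no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), seed_p = 0.1, window = 500,
                            step = 50, min_probes = 4, sidak_alpha = 0.10,
                            fdr_alpha = 0.10, cis_window = 500000,
                            seed = 1L, out_dir = NULL) {
  if (seed_p <= 0 || seed_p >= 1 || sidak_alpha <= 0 || sidak_alpha >= 1 ||
      fdr_alpha <= 0 || fdr_alpha >= 1)
    stop_invalid("alpha-type thresholds must lie in (0, 1)")
  if (window <= 0 || step <= 0 || min_probes <= 0 || cis_window <= 0)
    stop_invalid("window/step/min_probes/cis_window must be positive")
  structure(list(paths = paths, seed_p = seed_p, window = window,
                 step = step, min_probes = min_probes,
                 sidak_alpha = sidak_alpha, fdr_alpha = fdr_alpha,
                 cis_window = cis_window, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [pipeline_config()].
#'
#' @param path JSON file.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(x$paths)) x$paths <- as.list(x$paths)
  do.call(pipeline_config, x)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper that generates a manifest, sample sheet, M-value
#' matrix with planted effects, and linked omics, optionally writing all of
#' them (plus the ground truth) to a directory in the pipeline's on-disk
#' formats.
#'
#' @param design a [cohort_design()].
#' @param manifest a `probe_manifest` (default: [generate_manifest()] with
#'   the design's seed).
#' @param truth a [ground_truth()] (default: two planted delta regions and
#'   two planted mu regions at published effect scales, with one linked
#'   gene and one linked metabolite).
#' @param out_dir optional output directory.
#' @param with_omics also generate expression/metabolite matrices.
#' @return list with `manifest`, `samples`, `mvals`, `truth`, and (if
#'   requested) `omics`.
#' @export
simulate_cohort <- function(design = cohort_design(), manifest = NULL,
                            truth = NULL, out_dir = NULL, with_omics = TRUE) {
  if (is.null(manifest))
    manifest <- generate_manifest(seed = design$seed)
  if (is.null(truth)) {
    truth <- plant_regions(
      manifest,
      delta_slopes = list(c(-0.08, 0.04, 0.06), c(-0.03, 0.03, -0.06)),
      mu_offsets = list(c(-0.2, 0.2, 0.25), c(0.1, -0.1, 0.15)),
      seed = design$seed)
    truth$linked_genes <- data.frame(
      gene_id = "g0001",
      region_id = truth$planted_delta_regions$region_id[1],
      target_rho = 0.55)
    truth$linked_metabolites <- data.frame(
      metabolite_id = "Lipid_linked01", panel = "Lipid",
      region_id = truth$planted_delta_regions$region_id[1],
      target_beta = 0.4)
  }
  samples <- generate_samples(design)
  mvals <- generate_methylation(manifest, samples, truth, design)
  planted <- unique(unlist(lapply(
    list(truth$planted_delta_regions, truth$planted_mu_regions),
    function(reg) {
      unlist(lapply(seq_len(nrow(reg)), function(i)
        manifest$probe_id[manifest$chrom == reg$chrom[i] &
                            manifest$pos >= reg$start[i] &
                            manifest$pos <= reg$stop[i]]))
    })))
  truth$null_probes <- setdiff(manifest$probe_id, planted)
  out <- list(manifest = manifest, samples = samples, mvals = mvals,
              truth = truth)
  if (with_omics)
    out$omics <- generate_linked_omics(truth, samples, mvals,
                                       seed = design$seed + 7L)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    stamp <- stamp_line(config_hash(deparse(design)), design$seed)
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"), stamp)
    write_sample_sheet(samples, file.path(out_dir, "samples.csv"), stamp)
    write_matrix_tsv(mvals, file.path(out_dir, "mvals.tsv"), stamp,
                     id_col = "probe_id")
    write_ground_truth(truth, file.path(out_dir, "truth.json"))
    if (with_omics) {
      write_matrix_tsv(out$omics$expression,
                       file.path(out_dir, "expression.tsv"), stamp,
                       id_col = "gene_id")
      write.table(out$omics$tss_table, file.path(out_dir, "tss.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      met <- data.frame(metabolite_id = rownames(out$omics$metabolites),
                        panel = unname(out$omics$panels),
                        as.data.frame(out$omics$metabolites,
                                      check.names = FALSE))
      write.table(met, file.path(out_dir, "metabolites.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  out
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[ewasdmr] %-12s %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Probe filtering, both per-CpG mixed models with BH-FDR, both DMR tracks
#' (spatial combination, candidate finding, Sidak adjustment), the
#' direction-consistency retention rules, and -- when expression and/or
#' metabolite inputs are present -- the region-level eQTM and metQTM scans.
#' Every stage logs its record counts and the active seed; outputs are
#' reproducible for a fixed seed.
#'
#' Inputs are taken either from `data` (in-memory objects, as returned by
#' [simulate_cohort()]) or read from `config$paths`.
#'
#' @param config a [pipeline_config()].
#' @param data optional in-memory inputs: list with `manifest`, `samples`,
#'   `mvals`, optionally `omics`.
#' @return list of class `ewasdmr_pipeline` with elements `dmp`
#'   (interaction/group fits), `dmrs` (delta/mu candidate sets),
#'   `delta_records`, `mu_records` (summarized), `delta_retained`,
#'   `mu_retained`, `eqtm`, `metqtm`, `counts`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(data)) {
    p <- config$paths
    need <- c("mvals", "manifest", "sample_sheet")
    if (!all(need %in% names(p)))
      stop("config$paths must provide: ", paste(need, collapse = ", "))
    data <- read_methylation(p$mvals, p$manifest, p$sample_sheet)
    if (!is.null(p$expression)) {
      data$omics <- list(expression = read_matrix_tsv(p$expression),
                         tss_table = read.delim(p$tss_table,
                                                comment.char = "#"))
    }
    if (!is.null(p$metabolites)) {
      met <- read.delim(p$metabolites, comment.char = "#",
                        check.names = FALSE)
      m <- as.matrix(met[, -(1:2), drop = FALSE])
      rownames(m) <- met[[1]]
      data$omics <- c(data$omics,
                      list(metabolites = m,
                           panels = setNames(met[[2]], met[[1]])))
    }
  }
  manifest <- data$manifest; samples <- data$samples; mvals <- data$mvals
  seed <- config$seed
  pipeline_log("config", "seed=", seed, " seed_p=", config$seed_p,
               " window=", config$window, " step=", config$step)

  kept <- filter_probes(manifest)
  pipeline_log("filter", length(kept), " of ", nrow(manifest),
               " probes kept")
  manifest <- manifest[manifest$probe_id %in% kept, ]
  mvals <- mvals[manifest$probe_id, , drop = FALSE]
  attr(mvals, "manifest") <- manifest

  res <- list(config = config)
  res$dmp <- list(interaction = dmp_fit(mvals, samples, "interaction"),
                  group = dmp_fit(mvals, samples, "group"))
  for (m in names(res$dmp)) {
    r <- res$dmp[[m]]$results
    pipeline_log(paste0("dmp/", m), sum(!r$flagged), " probes tested, ",
                 sum(r$q_bh < config$fdr_alpha, na.rm = TRUE),
                 " BH-significant at ", config$fdr_alpha)
  }

  call_track <- function(fit) {
    r <- fit$results
    idx <- match(r$probe_id, manifest$probe_id)
    call_dmrs(r$p_2df, manifest$pos[idx], manifest$chrom[idx],
              probe_id = r$probe_id, seed_p = config$seed_p,
              window = config$window, step = config$step)
  }
  res$dmrs <- list(delta = call_track(res$dmp$interaction),
                   mu = call_track(res$dmp$group))
  res$delta_records <- summarize_delta_regions(res$dmrs$delta,
                                               res$dmp$interaction$results)
  res$mu_records <- summarize_mu_regions(res$dmrs$mu,
                                         res$dmp$group$results)
  res$delta_retained <- filter_delta_dmrs(res$delta_records,
                                          config$min_probes,
                                          config$sidak_alpha)
  res$mu_retained <- filter_mu_dmrs(res$mu_records, config$min_probes,
                                    config$sidak_alpha)
  pipeline_log("dmr/delta", nrow(res$dmrs$delta), " candidates, ",
               nrow(res$delta_retained), " retained")
  pipeline_log("dmr/mu", nrow(res$dmrs$mu), " candidates, ",
               nrow(res$mu_retained), " retained")

  omics <- data$omics
  keep_regions <- function(set, recs) set[set$region_id %in% recs$region_id, ]
  if (!is.null(omics$expression) && nrow(res$delta_retained)) {
    regs <- keep_regions(res$dmrs$delta, res$delta_retained)
    scores <- score_regions(regs, mvals, samples, "delta")
    res$eqtm <- run_eqtm(regs, scores, omics$expression, omics$tss_table,
                         samples, config$cis_window)
    pipeline_log("eqtm", nrow(res$eqtm), " cis pairs tested, ",
                 sum(res$eqtm$q_bh < config$fdr_alpha, na.rm = TRUE),
                 " significant")
  } else pipeline_log("eqtm", "skipped (no expression input or no regions)")
  if (!is.null(omics$metabolites) && nrow(res$delta_retained)) {
    regs <- keep_regions(res$dmrs$delta, res$delta_retained)
    scores <- score_regions(regs, mvals, samples, "delta")
    res$metqtm <- run_metqtm(regs, scores, omics$metabolites, omics$panels,
                             samples, "delta")
    pipeline_log("metqtm", nrow(res$metqtm), " pairs tested, ",
                 sum(res$metqtm$q_bh < config$fdr_alpha, na.rm = TRUE),
                 " significant")
  } else pipeline_log("metqtm", "skipped (no metabolite input or no regions)")

  res$counts <- list(
    probes_total = length(kept), probes_tested =
      sum(!res$dmp$interaction$results$flagged),
    delta_candidates = nrow(res$dmrs$delta),
    delta_retained = nrow(res$delta_retained),
    mu_candidates = nrow(res$dmrs$mu),
    mu_retained = nrow(res$mu_retained),
    eqtm_pairs = if (is.null(res$eqtm)) 0L else nrow(res$eqtm),
    metqtm_pairs = if (is.null(res$metqtm)) 0L else nrow(res$metqtm))

  if (!is.null(config$out_dir)) {
    cfg_for_hash <- unclass(config)
    cfg_for_hash$out_dir <- NULL  # analysis parameters only
    stamp <- stamp_line(config_hash(jsonlite::toJSON(cfg_for_hash,
                                                     auto_unbox = TRUE,
                                                     null = "null")), seed)
    write_regions(res$delta_records, config$out_dir, "delta_dmrs", stamp)
    write_regions(res$mu_records, config$out_dir, "mu_dmrs", stamp)
    if (!is.null(res$eqtm))
      write_stamped(function(con) write.table(res$eqtm, con, sep = "\t",
                                              quote = FALSE,
                                              row.names = FALSE, na = ""),
                    file.path(config$out_dir, "eqtm.tsv"), stamp)
    if (!is.null(res$metqtm))
      write_stamped(function(con) write.table(res$metqtm, con, sep = "\t",
                                              quote = FALSE,
                                              row.names = FALSE, na = ""),
                    file.path(config$out_dir, "metqtm.tsv"), stamp)
    jsonlite::write_json(res$counts, file.path(config$out_dir,
                                               "summary.json"),
                         auto_unbox = TRUE)
  }
  class(res) <- "ewasdmr_pipeline"
  res
}

#' @export
print.ewasdmr_pipeline <- function(x, ...) {
  cat("ewasdmr pipeline result\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %s\n", nm, x$counts[[nm]]))
  invisible(x)
}
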