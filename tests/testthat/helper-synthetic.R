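# Shared fixture builders. Everything is generated in code; sizes are kept
# small where the check does not depend on cohort scale.

small_design <- function(seed = 1L, ...) {
  cohort_design(n_per_group = c(maintainer = 12L, progressor = 10L,
                                reverter = 10L),
                n_missing_ancestry = 0L, seed = seed, ...)
}

small_manifest <- function(seed = 1L, ...) {
  generate_manifest(n_chrom = 2, clusters_per_chrom = 5,
                    probes_per_cluster = c(4, 8), seed = seed, ...)
}

# single-probe response following the generator's signal model, for direct
# mixed-model checks
simulate_probe <- function(samples, slopes = c(maintainer = 0, progressor = 0,
                                               reverter = 0),
                           offsets = c(maintainer = 0, progressor = 0,
                                       reverter = 0),
                           subject_sd = 0.3, residual_sd = 0.15, seed = 1L) {
  set.seed(seed)
  subj <- unique(samples$subject_id)
  b <- stats::setNames(rnorm(length(subj), 0, subject_sd), subj)
  y <- b[samples$subject_id] +
    offsets[samples$group] +
    slopes[samples$group] * (samples$visit == "post") +
    rnorm(nrow(samples), 0, residual_sd)
  stats::setNames(as.numeric(y), samples$sample_id)
}

# zero-correlation ACF object usable wherever an estimate_acf() result is
flat_acf <- function(value = 0, window = 500, step = 50) {
  structure(list(bin_edges = seq(0, window, by = step),
                 correlations = rep(value, window / step),
                 correlations_raw = rep(value, window / step),
                 n_pairs = rep(1000L, window / step),
                 step = step, window = window),
            class = "acf_estimate")
}

# independent oracle: classical Stouffer combination
stouffer_p <- function(p) {
  z <- qnorm(1 - p)
  1 - pnorm(sum(z) / sqrt(length(z)))
}

read_fixture <- function(name) {
  read.delim(system.file("extdata", name, package = "ewasdmr"),
             comment.char = "#", stringsAsFactors = FALSE)
}
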