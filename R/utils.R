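#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova as.formula cor lm lm.fit mad median model.matrix
#'   pchisq pnorm prcomp predict pt qnorm quantile residuals rnorm runif sd
#'   setNames var rbinom rlnorm complete.cases deviance coef
#' @importFrom utils head read.csv read.delim write.csv write.table
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched (all generators must be reproducible without
# clobbering the session seed).
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(...) {
  stop(structure(class = c("ewasdmr_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Convert 1-based inclusive probe coordinates to 0-based half-open intervals
#'
#' Probe manifests and internal region records use 1-based point/inclusive
#' coordinates (the array-manifest convention); BED output is 0-based
#' half-open. This helper is the only place the conversion arithmetic lives.
#'
#' @param start,stop integer vectors, 1-based inclusive.
#' @return data.frame with columns `start` (0-based) and `stop` (half-open).
#' @export
#' @examples
#' coords_to_bed(57426538, 57427974)
coords_to_bed <- function(start, stop) {
  if (any(start < 1) || any(stop < start))
    stop_invalid("coordinates must satisfy 1 <= start <= stop")
  data.frame(start = start - 1L, stop = stop)
}

#' @rdname coords_to_bed
#' @export
bed_to_coords <- function(start, stop) {
  if (any(start < 0) || any(stop <= start))
    stop_invalid("BED coordinates must satisfy 0 <= start < stop")
  data.frame(start = start + 1L, stop = stop)
}

# Polynomial rolling hash over a character vector; used only to stamp
# output files with a config fingerprint (no cryptographic intent).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
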