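stamp_line <- function(config_fingerprint, seed) {
  sprintf("# ewasdmr config=%s seed=%s", config_fingerprint,
          if (is.null(seed)) "NA" else seed)
}

write_stamped <- function(lines_fn, path, stamp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(stamp, con)
  lines_fn(con)
  invisible(path)
}

#' Tabular readers and writers for the pipeline's on-disk formats
#'
#' Plain-text formats only: probe manifest TSV, sample sheet CSV, numeric
#' matrix TSV (features as rows), gene TSS TSV, metabolite TSV with a
#' `panel` column, ground-truth JSON. All writers accept an optional
#' `stamp` comment line (config fingerprint + seed) and all readers skip
#' `#` comment lines. Missing values are written as empty fields.
#'
#' @param manifest,samples,mat,truth object to write.
#' @param path file path.
#' @param stamp optional comment line from the pipeline driver.
#' @name io
NULL

#' @rdname io
#' @export
write_manifest <- function(manifest, path, stamp = NULL) {
  write_stamped(function(con) {
    write.table(as.data.frame(manifest), con, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  }, path, stamp)
}

#' @rdname io
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$probe_id)) stop("duplicate probe ids in manifest")
  man <- man[order(man$chrom, man$pos), ]
  rownames(man) <- NULL
  class(man) <- c("probe_manifest", "data.frame")
  man
}

#' @rdname io
#' @export
write_sample_sheet <- function(samples, path, stamp = NULL) {
  write_stamped(function(con) {
    write.csv(as.data.frame(samples), con, row.names = FALSE, na = "",
              quote = FALSE)
  }, path, stamp)
}

#' @rdname io
#' @export
read_sample_sheet <- function(path) {
  s <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_sheet(s)
  class(s) <- c("sample_sheet", "data.frame")
  s
}

#' @rdname io
#' @export
write_matrix_tsv <- function(mat, path, stamp = NULL, id_col = "id") {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE))
  names(df)[1] <- id_col
  # 17 significant digits so doubles survive the text round trip exactly
  df[-1] <- lapply(df[-1], function(x) sprintf("%.17g", x))
  write_stamped(function(con) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  }, path, stamp)
}

#' @rdname io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read and align a methylation dataset
#'
#' Reads an M-value matrix, probe manifest and sample sheet, validates that
#' ids match one-to-one, and returns objects normalized to (chrom, pos)
#' probe order and sample-sheet column order.
#'
#' @param matrix_path M-value TSV (probes as rows).
#' @param manifest_path probe manifest TSV.
#' @param samples_path sample sheet CSV.
#' @return list with `mvals` (manifest attached as attribute), `manifest`,
#'   `samples`.
#' @export
read_methylation <- function(matrix_path, manifest_path, samples_path) {
  mvals <- read_matrix_tsv(matrix_path)
  manifest <- read_manifest(manifest_path)
  samples <- read_sample_sheet(samples_path)
  extra_s <- setdiff(colnames(mvals), samples$sample_id)
  miss_s <- setdiff(samples$sample_id, colnames(mvals))
  if (length(extra_s) || length(miss_s))
    stop("sample ids do not match the sample sheet; matrix-only: [",
         paste(extra_s, collapse = ", "), "], sheet-only: [",
         paste(miss_s, collapse = ", "), "]")
  extra_p <- setdiff(rownames(mvals), manifest$probe_id)
  miss_p <- setdiff(manifest$probe_id, rownames(mvals))
  if (length(extra_p) || length(miss_p))
    stop("probe ids do not match the manifest; matrix-only: [",
         paste(extra_p, collapse = ", "), "], manifest-only: [",
         paste(miss_p, collapse = ", "), "]")
  if (anyDuplicated(colnames(mvals))) stop("duplicate sample ids in matrix")
  if (!all(is.finite(mvals))) stop("M-value matrix contains non-finite values")
  mvals <- mvals[manifest$probe_id, samples$sample_id, drop = FALSE]
  attr(mvals, "manifest") <- manifest
  list(mvals = mvals, manifest = manifest, samples = samples)
}

#' Write called regions as BED6 and a summary TSV
#'
#' The BED file is 0-based half-open with score
#' `min(-10 log10(sidak_p), 1000)`; the TSV reproduces the summary columns
#' (probe counts, Sidak p, leading probe, consistency percentages,
#' medians). Internal coordinates are 1-based inclusive; [coords_to_bed()]
#' does the conversion.
#'
#' @param records summarized (delta or mu) region records.
#' @param dir output directory.
#' @param prefix file name prefix (`<prefix>.bed`, `<prefix>.tsv`).
#' @param stamp optional comment line.
#' @return invisibly, the two paths.
#' @export
write_regions <- function(records, dir, prefix = "dmrs", stamp = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed_path <- file.path(dir, paste0(prefix, ".bed"))
  tsv_path <- file.path(dir, paste0(prefix, ".tsv"))
  df <- as.data.frame(records)
  df$probe_ids <- NULL
  write_stamped(function(con) {
    if (nrow(df)) {
      cc <- coords_to_bed(df$start, df$stop)
      score <- round(pmin(-10 * log10(pmax(df$sidak_p, 1e-100)), 1000))
      bed <- data.frame(df$chrom, cc$start, cc$stop, df$region_id, score, ".")
      write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }, bed_path, stamp)
  write_stamped(function(con) {
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  }, tsv_path, stamp)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' @rdname io
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(planted_delta_regions = as.data.frame(x$planted_delta_regions),
               planted_mu_regions = as.data.frame(x$planted_mu_regions),
               linked_genes = if (is.null(x$linked_genes)) NULL
               else as.data.frame(x$linked_genes),
               linked_metabolites = if (is.null(x$linked_metabolites)) NULL
               else as.data.frame(x$linked_metabolites),
               null_probes = unlist(x$null_probes))
}
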