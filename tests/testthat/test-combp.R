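test_that("ACF on independent p-values is near zero in every bin", {
  set.seed(101)
  n <- 5000
  pos <- cumsum(sample(10:40, n, replace = TRUE))
  p <- runif(n)
  acf <- estimate_acf(p, pos, window = 500, step = 50)
  expect_length(acf$correlations_raw, 10)
  expect_true(all(abs(acf$correlations_raw) < 0.05))
  expect_true(all(acf$correlations >= 0 & acf$correlations <= 1))
})

test_that("perfectly duplicated p-values give first-bin correlation 1", {
  set.seed(7)
  p_half <- runif(12)
  # 12 pairs, 10 bp apart, pairs separated by > 500 bp
  p <- rep(p_half, each = 2)
  pos <- as.vector(vapply(seq_along(p_half),
                          function(i) c(i * 1000, i * 1000 + 10),
                          numeric(2)))
  acf <- estimate_acf(p, pos)
  expect_equal(acf$correlations[1], 1, tolerance = 1e-12)
})

test_that("too few probe pairs is an error", {
  expect_error(estimate_acf(c(0.5, 0.5), c(100, 10000),
                            chrom = c("chr1", "chr2")),
               "insufficient")
})

test_that("sparse bins inherit the previous bin's correlation", {
  set.seed(8)
  # 30 probe pairs 10 bp apart, pairs > 500 bp from each other: only the
  # first distance bin has pairs, all later bins inherit its value
  pos <- as.vector(vapply(1:30, function(i) c(i * 1000, i * 1000 + 10),
                          numeric(2)))
  expect_no_warning(acf <- estimate_acf(runif(60), pos))
  expect_true(all(!is.na(acf$correlations)))
  expect_equal(acf$correlations_raw, rep(acf$correlations_raw[1], 10))
  expect_equal(acf$n_pairs[2:10], rep(0L, 9))
})

test_that("Stouffer-Liptak correction matches closed forms", {
  pos <- c(0, 100, 200, 300)
  p <- rep(0.05, 4)
  z <- qnorm(0.95)
  corr0 <- slk_correct(p, pos, flat_acf(0))
  expect_equal(corr0, rep(1 - pnorm(2 * z), 4), tolerance = 1e-12)
  corr1 <- slk_correct(p, pos, flat_acf(1))
  expect_equal(corr1, rep(0.05, 4), tolerance = 1e-12)
  # isolated probe keeps its raw p
  expect_equal(slk_correct(0.2, 1000, flat_acf(0)), 0.2)
  iso <- slk_correct(c(0.01, 0.2), c(0, 5000), flat_acf(0.3))
  expect_equal(iso, c(0.01, 0.2))
})

test_that("candidate runs break on threshold and distance", {
  expect_equal(nrow(find_candidate_regions(rep(0.05, 3), c(0, 100, 200))), 1)
  r <- find_candidate_regions(c(0.05, 0.5, 0.05), c(0, 100, 200))
  expect_equal(nrow(r), 2)
  expect_equal(r$n_probes, c(1, 1))
  r2 <- find_candidate_regions(c(0.01, 0.01), c(0, 900))
  expect_equal(nrow(r2), 2)
  expect_equal(nrow(find_candidate_regions(c(0.5, 0.9), c(0, 100))), 0)
})

test_that("region p-value matches the independent Stouffer oracle", {
  expect_equal(region_pvalue(0.2, 50, flat_acf(0)), 0.2)
  p4 <- rep(0.01, 4)
  expect_equal(region_pvalue(p4, c(0, 50, 100, 150), flat_acf(0)),
               stouffer_p(p4), tolerance = 1e-12)
  expect_equal(region_pvalue(p4, c(0, 50, 100, 150), flat_acf(0)),
               1 - pnorm(2 * qnorm(0.99)), tolerance = 1e-12)
  # monotone: lowering any member p lowers the region p
  set.seed(9)
  p <- runif(5, 0.01, 0.5)
  pos <- c(0, 60, 120, 180, 240)
  base <- region_pvalue(p, pos, flat_acf(0.2))
  for (i in seq_along(p)) {
    p2 <- p; p2[i] <- p[i] / 10
    expect_lt(region_pvalue(p2, pos, flat_acf(0.2)), base)
  }
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.01, 100, 100), 0.01)
  expect_equal(sidak_adjust(0.001, 10, 1000), 1 - 0.999^100,
               tolerance = 1e-12)
  expect_equal(sidak_adjust(0, 10, 1000), 0)
  expect_error(sidak_adjust(1.2, 10, 1000), "0, 1")
  expect_error(sidak_adjust(0.5, 100, 10), "total_covered_bases")
})

test_that("region calling is invariant to probe input order", {
  set.seed(11)
  man <- generate_manifest(n_chrom = 2, clusters_per_chrom = 4, seed = 11)
  p <- runif(nrow(man))^3
  base <- call_dmrs(p, man$pos, man$chrom, man$probe_id)
  perm <- sample(nrow(man))
  shuf <- call_dmrs(p[perm], man$pos[perm], man$chrom[perm],
                    man$probe_id[perm])
  expect_equal(as.data.frame(base), as.data.frame(shuf))
})

test_that("missing p-values are excluded before region calling", {
  set.seed(12)
  man <- generate_manifest(n_chrom = 1, clusters_per_chrom = 4, seed = 12)
  p <- runif(nrow(man))
  p[c(1, 5)] <- NA
  expect_no_error(res <- call_dmrs(p, man$pos, man$chrom, man$probe_id))
  expect_false(any(unlist(res$probe_ids) %in% man$probe_id[c(1, 5)]))
})
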