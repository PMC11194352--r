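mk_region <- function(ids, n = length(ids), sidak = 0.01, id = "R1") {
  r <- data.frame(region_id = id, chrom = "chr1", start = 100L,
                  stop = 100L + 50L * n, n_probes = n, slk_p = sidak / 10,
                  sidak_p = sidak, leading_probe = ids[1])
  r$probe_ids <- list(ids)
  r
}

mk_dmp_delta <- function(ids, R, P, M) {
  data.frame(probe_id = ids, slope_reverter = R, slope_progressor = P,
             slope_maintainer = M)
}

mk_dmp_mu <- function(ids, pvr, rvm, pvm) {
  data.frame(probe_id = ids, diff_pvr = pvr, diff_rvm = rvm, diff_pvm = pvm)
}

test_that("delta summaries match hand computation", {
  ids <- paste0("cg", 1:4)
  dmp <- mk_dmp_delta(ids, R = c(0.1, 0.2, -0.1, 0.05),
                      P = c(0.1, 0.2, 0.3, 0.4), M = -c(0.1, 0.2, 0.3, 0.4))
  rec <- summarize_delta_region(mk_region(ids), dmp)
  expect_equal(rec$slope_pct_reverter, 0.75)
  expect_equal(rec$median_slope_reverter, 0.075)
  expect_equal(rec$slope_pct_progressor, 1.0)
  expect_equal(rec$slope_pct_maintainer, 1.0)
  expect_equal(rec$median_slope_maintainer, -0.25)
})

test_that("zero slopes count with the majority and 50/50 gives 0.5", {
  ids <- paste0("cg", 1:4)
  dmp <- mk_dmp_delta(ids, R = c(0.1, -0.1, 0.2, -0.2),
                      P = c(0, 0.1, 0.2, -0.3), M = c(0, 0, 0.1, 0.1))
  rec <- summarize_delta_region(mk_region(ids), dmp)
  expect_equal(rec$slope_pct_reverter, 0.5)
  expect_equal(rec$slope_pct_progressor, 0.75)  # zero joins the + majority
  expect_equal(rec$slope_pct_maintainer, 1.0)
  rec2 <- summarize_delta_region(mk_region(ids), dmp,
                                 zero_with_majority = FALSE)
  expect_equal(rec2$slope_pct_progressor, 0.5)
  expect_equal(rec2$slope_pct_maintainer, 0.5)
})

test_that("delta retention applies all three rules", {
  ids <- paste0("cg", 1:4)
  unanimous <- mk_dmp_delta(ids, R = c(-0.03, -0.02, -0.04, -0.01),
                            P = c(0.03, 0.02, 0.04, 0.05),
                            M = c(-0.06, -0.05, -0.07, -0.04))
  rec <- summarize_delta_region(mk_region(ids, sidak = 0.0338), unanimous)
  expect_equal(nrow(filter_delta_dmrs(rec)), 1)
  # no unanimous group
  mixed <- mk_dmp_delta(ids, R = c(0.1, -0.1, 0.2, 0.1),
                        P = c(0.1, 0.1, -0.1, 0.1),
                        M = c(-0.1, 0.1, 0.1, 0.1))
  rec2 <- summarize_delta_region(mk_region(ids, sidak = 1e-6), mixed)
  expect_equal(nrow(filter_delta_dmrs(rec2)), 0)
  # probe-count and alpha rules
  ids3 <- ids[1:3]
  rec3 <- summarize_delta_region(mk_region(ids3, sidak = 1e-6),
                                 mk_dmp_delta(ids3, R = c(1, 1, 1),
                                              P = c(1, 1, 1), M = c(1, 1, 1)))
  expect_equal(nrow(filter_delta_dmrs(rec3)), 0)
  rec4 <- summarize_delta_region(mk_region(ids, sidak = 0.11), unanimous)
  expect_equal(nrow(filter_delta_dmrs(rec4)), 0)
  expect_equal(nrow(filter_delta_dmrs(rec4, sidak_alpha = 0.2)), 1)
})

test_that("mu summaries and retention mirror the pairwise rules", {
  ids <- paste0("cg", 1:4)
  dmp <- mk_dmp_mu(ids, pvr = c(0.1, 0.2, 0.1, 0.05),
                   rvm = c(0.3, -0.1, 0.4, 0.2),
                   pvm = c(0.4, 0.1, 0.5, 0.25))
  rec <- summarize_mu_region(mk_region(ids), dmp)
  expect_equal(rec$consistency_pvr, 1.0)
  expect_equal(rec$median_pvr, 0.1)
  expect_equal(rec$consistency_rvm, 0.75)
  expect_equal(nrow(filter_mu_dmrs(rec)), 1)
  alt <- mk_dmp_mu(ids, pvr = c(0.1, -0.1, 0.1, -0.1),
                   rvm = c(0.3, -0.1, 0.4, -0.2),
                   pvm = c(0.4, -0.1, 0.5, -0.25))
  rec2 <- summarize_mu_region(mk_region(ids), alt)
  expect_equal(rec2$consistency_pvr, 0.5)
  expect_equal(nrow(filter_mu_dmrs(rec2)), 0)
  rec3 <- rec
  rec3$sidak_p <- 0.11
  expect_equal(nrow(filter_mu_dmrs(rec3)), 0)
})

test_that("summaries are invariant to probe order within the region", {
  ids <- paste0("cg", 1:6)
  set.seed(3)
  dmp <- mk_dmp_delta(ids, R = rnorm(6), P = rnorm(6), M = rnorm(6))
  rec <- summarize_delta_region(mk_region(ids), dmp)
  perm <- sample(6)
  rec2 <- summarize_delta_region(mk_region(ids[perm]), dmp)
  rec2$leading_probe <- rec$leading_probe
  expect_equal(rec[-1], rec2[-1], ignore_attr = TRUE)
})

test_that("retention is monotone in significance and consistency", {
  ids <- paste0("cg", 1:5)
  dmp <- mk_dmp_delta(ids, R = c(0.1, 0.1, 0.1, 0.1, 0.1),
                      P = rnorm(5), M = rnorm(5))
  rec <- summarize_delta_region(mk_region(ids, sidak = 0.09), dmp)
  expect_equal(nrow(filter_delta_dmrs(rec)), 1)
  rec_better <- rec
  rec_better$sidak_p <- rec$sidak_p / 100
  expect_equal(nrow(filter_delta_dmrs(rec_better)), 1)
})

test_that("regions with missing probe results are an error", {
  ids <- paste0("cg", 1:4)
  dmp <- mk_dmp_delta(ids[1:3], R = 1:3, P = 1:3, M = 1:3)
  expect_error(summarize_delta_region(mk_region(ids), dmp), "without")
  dmp_mu <- mk_dmp_mu(ids[1:2], 1:2, 1:2, 1:2)
  expect_error(summarize_mu_region(mk_region(ids), dmp_mu), "without")
})
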