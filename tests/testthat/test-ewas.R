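test_that("bh_fdr matches a brute-force step-up oracle", {
  # oracle: q_(i) = min_{j >= i} m p_(j) / j, capped at 1
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- pmin(1, m * p[o] / seq_len(m))
    q <- rev(cummin(rev(q)))
    out <- numeric(m); out[o] <- q; out
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.42), 0.42)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("bh_fdr handles NA, preserves order, and dominates p", {
  set.seed(2)
  p <- c(runif(30), NA, NA)
  q <- bh_fdr(p)
  expect_true(all(is.na(q[31:32])))
  expect_true(all(q >= p, na.rm = TRUE))
  perm <- sample(length(p))
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("interaction model recovers planted per-group visit slopes", {
  # six independent replicate probes with the same planted truth; a single
  # probe at this effect scale is only borderline-powered, so significance
  # is judged on the Stouffer-combined evidence and slopes on the medians
  s <- generate_samples(cohort_design(seed = 21))
  slopes <- c(maintainer = -0.08, progressor = 0, reverter = 0.06)
  m <- t(vapply(1:6, function(i) simulate_probe(s, slopes = slopes,
                                                seed = 210 + i),
                numeric(nrow(s))))
  rownames(m) <- paste0("rep", 1:6)
  fit <- dmp_fit(m, s, "interaction")
  p_comb <- 1 - pnorm(sum(qnorm(1 - fit$results$p_2df)) / sqrt(6))
  expect_lt(p_comb, 1e-3)
  n_g <- c(maintainer = 60, progressor = 42, reverter = 41)
  se <- sqrt(2) * 0.15 / sqrt(n_g)  # within-subject contrast SE
  for (g in names(slopes))
    expect_lt(abs(median(fit$results[[paste0("slope_", g)]]) - slopes[g]),
              3 * se[g])
})

test_that("swapping visit labels negates the fitted slopes", {
  s <- generate_samples(small_design(seed = 3))
  y <- simulate_probe(s, slopes = c(maintainer = -0.3, progressor = 0.2,
                                    reverter = 0), seed = 3)
  res <- fit_interaction_dmp(y, s)
  s2 <- s
  s2$visit <- ifelse(s$visit == "pre", "post", "pre")
  res2 <- fit_interaction_dmp(y, s2)
  for (g in c("maintainer", "progressor", "reverter"))
    expect_equal(res2[[paste0("slope_", g)]], -res[[paste0("slope_", g)]],
                 tolerance = 1e-6)
  expect_equal(res2$p_2df, res$p_2df, tolerance = 1e-6)
})

test_that("degenerate probes are flagged, not fatal", {
  s <- generate_samples(small_design(seed = 4))
  m <- rbind(const = rep(1, nrow(s)),
             ok = simulate_probe(s, seed = 4))
  colnames(m) <- s$sample_id
  fit <- dmp_fit(m, s, "interaction")
  expect_true(fit$results$flagged[1])
  expect_false(fit$results$flagged[2])
  expect_true(is.na(fit$results$p_2df[1]))
  expect_true(is.na(fit$results$q_bh[1]))  # excluded from FDR
  expect_false(is.na(fit$results$q_bh[2]))
})

test_that("group model recovers planted pairwise contrasts", {
  s <- generate_samples(cohort_design(seed = 31, n_missing_ancestry = 0L))
  # offsets chosen so P-R = 0.09, R-M = 0.37
  offs <- c(maintainer = 0, progressor = 0.46, reverter = 0.37)
  y <- simulate_probe(s, offsets = offs, seed = 31)
  res <- fit_group_dmp(y, s)
  expect_lt(res$p_2df, 1e-3)
  sdm <- sqrt(0.3^2 + 0.15^2 / 2)  # SD of a subject's visit-mean level
  se_pair <- function(n1, n2) sdm * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(res$diff_pvr - 0.09), 3 * se_pair(42, 41))
  expect_lt(abs(res$diff_rvm - 0.37), 3 * se_pair(41, 60))
  expect_lt(abs(res$diff_pvm - 0.46), 3 * se_pair(42, 60))
})

test_that("subjects with missing ancestry are dropped from the group model", {
  s <- generate_samples(cohort_design(seed = 5, n_missing_ancestry = 2L))
  y <- simulate_probe(s, seed = 5)
  res_i <- fit_interaction_dmp(y, s)
  res_g <- fit_group_dmp(y, s)
  expect_equal(res_i$n_used, 286)
  expect_equal(res_g$n_used, 282)  # 2 subjects x 2 visits fewer
  s_all_na <- s
  s_all_na$ancestry_pc1 <- NA_real_
  expect_error(fit_group_dmp(y, s_all_na), "ancestry")
})

test_that("dmp_fit validates its inputs and exposes S3 methods", {
  s <- generate_samples(small_design(seed = 6))
  m <- rbind(p1 = simulate_probe(s, seed = 6),
             p2 = simulate_probe(s, seed = 7))
  colnames(m) <- s$sample_id
  fit <- dmp_fit(m, s, "interaction")
  expect_s3_class(fit, "dmp_fit")
  expect_output(print(fit), "interaction")
  expect_output(print(summary(fit)), "probes")
  expect_equal(dim(coef(fit)), c(2, 3))
  bad <- m
  colnames(bad)[1] <- "nope"
  expect_error(dmp_fit(bad, s), "match")
})
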