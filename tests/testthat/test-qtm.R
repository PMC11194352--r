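test_that("residualization preserves within-subject structure", {
  s <- generate_samples(small_design(seed = 13))
  y <- rnorm(nrow(s))
  # no covariates, no random intercept: centered values
  r0 <- residualize_repeated(y, s, character(0), random_intercept = FALSE)
  expect_equal(unname(r0), y - mean(y))
  # invariance to covariate location shifts
  r1 <- residualize_repeated(y, s, c("age", "sex"), random_intercept = FALSE)
  s2 <- s; s2$age <- s$age + 100
  r2 <- residualize_repeated(y, s2, c("age", "sex"),
                             random_intercept = FALSE)
  expect_equal(r1, r2)
  # known age effect is removed (mixed model)
  set.seed(13)
  y_age <- 0.1 * s$age + rep(rnorm(nrow(s) / 2, 0, 0.3), each = 2) +
    rnorm(nrow(s), 0, 0.2)
  res <- residualize_repeated(y_age, s, "age")
  expect_lt(abs(cor(res, s$age)), 0.05)
  expect_lt(abs(mean(res)), 0.05)
})

test_that("collinear covariates are dropped with a warning", {
  s <- generate_samples(small_design(seed = 14))
  s$age2 <- 2 * s$age
  expect_warning(residualize_repeated(rnorm(nrow(s)), s, c("age", "age2"),
                                      random_intercept = FALSE),
                 "collinear")
})

test_that("paired contrasts behave as delta/mean with label symmetry", {
  s <- generate_samples(small_design(seed = 15))
  v <- setNames(rnorm(nrow(s)), s$sample_id)
  one <- s$subject_id == s$subject_id[1]
  vv <- v[s$sample_id[one]]
  pre <- vv[grep("_pre", names(vv))]; post <- vv[grep("_post", names(vv))]
  d <- paired_contrast(v, s, "delta")
  m <- paired_contrast(v, s, "mean")
  expect_equal(unname(d[s$subject_id[1]]), unname(post - pre))
  expect_equal(unname(m[s$subject_id[1]]), unname((post + pre) / 2))
  # swap labels: delta negates, mean unchanged
  s2 <- s; s2$visit <- ifelse(s$visit == "pre", "post", "pre")
  s2$sample_id <- s$sample_id
  expect_equal(paired_contrast(v, s2, "delta"), -d)
  expect_equal(paired_contrast(v, s2, "mean"), m)
  # missing visit: subject dropped with a message
  v2 <- v[-1]
  expect_message(d2 <- paired_contrast(v2, s[-1, ], "delta"), "dropping")
  expect_equal(length(d2), length(d) - 1)
})

test_that("region PC1 matches closed-form special cases", {
  set.seed(16)
  x <- rnorm(30)
  one <- region_pc1(matrix(x, ncol = 1, dimnames = list(paste0("s", 1:30))))
  expect_equal(one$variance_explained, 1)
  expect_equal(unname(one$scores), as.vector(scale(x)), tolerance = 1e-12)
  two <- region_pc1(cbind(a = x, b = 2 * x + 1))
  expect_equal(two$variance_explained, 1)
  # equicorrelated CpGs: leading eigenvalue (1 + (k-1) rho) / k
  n <- 110; k <- 4; rho <- 0.6
  shared <- rnorm(n)
  mat <- vapply(1:k, function(j) sqrt(rho) * shared +
                  sqrt(1 - rho) * rnorm(n), numeric(n))
  rownames(mat) <- paste0("s", 1:n)
  pc <- region_pc1(mat)
  expect_lt(abs(pc$variance_explained - (1 + (k - 1) * rho) / k), 0.08)
  # orientation: increasing score tracks increasing methylation
  expect_gt(cor(pc$scores, rowMeans(scale(mat))), 0)
  flipped <- region_pc1(-mat)
  expect_gt(cor(flipped$scores, rowMeans(scale(-mat))), 0)
})

test_that("zero-variance CpGs are dropped, empty regions error", {
  set.seed(17)
  mat <- cbind(a = rnorm(20), b = rep(1, 20))
  rownames(mat) <- paste0("s", 1:20)
  expect_warning(pc <- region_pc1(mat), "zero-variance")
  expect_equal(pc$n_cpgs, 1)
  expect_error(suppressWarnings(region_pc1(mat[, 2, drop = FALSE])), "zero")
  expect_error(region_pc1(mat[1:2, ]), "3 subjects")
})

test_that("cis window selects genes around the region midpoint", {
  region <- data.frame(chrom = "chr20", start = 57426538L, stop = 57427974L)
  genes <- data.frame(
    gene_id = c("GNAS", "ATP5E", "FAR1", "OTHERCHR"),
    chrom = c("chr20", "chr20", "chr20", "chr7"),
    start = c(57414773L, 57600522L, 58030000L, 57414773L),
    end = c(57486247L, 57607437L, 58040000L, 57486247L),
    strand = c(1L, -1L, 1L, 1L))
  tss <- tss_from_genes(genes)
  # minus strand: TSS is the gene end
  expect_equal(tss$tss[2], 57607437)
  hits <- cis_features(region, tss)
  expect_setequal(hits, c("GNAS", "ATP5E"))
  expect_identical(cis_features(region, tss[0, ]), character(0))
})

test_that("eQTM statistic is a rank statistic with a t-approximate p", {
  set.seed(18)
  sc <- setNames(rnorm(36), paste0("s", 1:36))
  y <- exp(2 * sc) + 1  # strictly monotone, nonlinear
  res <- eqtm_test(sc, setNames(y, names(sc)))
  expect_equal(res$statistic, 1)
  # monotone transform invariance on noisy data
  y2 <- sc + rnorm(36)
  r_raw <- eqtm_test(sc, setNames(y2, names(sc)))
  r_tr <- eqtm_test(sc, setNames(exp(y2), names(sc)))
  expect_equal(r_raw$statistic, r_tr$statistic)
  expect_equal(r_raw$p, r_tr$p)
  # constant expression flags the pair
  flat <- eqtm_test(sc, setNames(rep(1, 36), names(sc)))
  expect_true(flat$flagged)
  expect_error(eqtm_test(sc[1:4], setNames(rnorm(4), names(sc)[1:4])),
               "5 paired")
})

test_that("null eQTM calibration at the overlap sample size", {
  set.seed(19)
  n <- 36; reps <- 1000
  rho <- numeric(reps); p <- numeric(reps)
  nm <- paste0("s", 1:n)
  for (i in seq_len(reps)) {
    r <- eqtm_test(setNames(rnorm(n), nm), setNames(rnorm(n), nm))
    rho[i] <- r$statistic; p[i] <- r$p
  }
  expect_lt(abs(mean(rho)), 0.02)
  rej <- mean(p < 0.05)
  ci <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
})

test_that("Box-Cox lambda search behaves like an MLE", {
  set.seed(20)
  ln <- exp(rnorm(500))
  expect_true(abs(boxcox_transform(ln)$lambda) <= 0.2)
  nrm <- rnorm(500, 50, 5)
  lam <- boxcox_transform(nrm)$lambda
  expect_true(lam >= 0.6 && lam <= 1.4)
  x <- runif(20, 1, 5)
  bc <- boxcox_transform(x, grid = 1)
  expect_equal(bc$values, x - 1)
  expect_warning(sh <- boxcox_transform(c(-1, 2, 3)), "shifting")
  expect_equal(sh$shift, 2)
})

test_that("standardized beta equals Pearson r and flags degenerate input", {
  set.seed(21)
  nm <- paste0("s", 1:110)
  sc <- setNames(rnorm(110), nm)
  y <- setNames(0.4 * sc + rnorm(110), nm)
  res <- metqtm_test(sc, y, panel = "Lipid")
  expect_equal(res$statistic, cor(sc, y), tolerance = 1e-12)
  ident <- metqtm_test(sc, sc, panel = "Lipid")
  expect_equal(ident$statistic, 1)
  expect_true(metqtm_test(sc, setNames(rep(2, 110), nm), "Lipid")$flagged)
})

test_that("FDR is stratified by panel", {
  set.seed(22)
  res <- data.frame(region_id = "r", feature_id = sprintf("m%02d", 1:30),
                    panel = rep(c("HILIC", "Lipid", "GCTOF"), each = 10),
                    statistic = rnorm(30), p = runif(30)^2,
                    n = 100, flagged = FALSE)
  q <- qtm_fdr(res)
  for (pl in unique(res$panel)) {
    sel <- res$panel == pl
    expect_equal(q$q_bh[sel], bh_fdr(res$p[sel]))
  }
  # permuting features within one panel leaves other panels untouched
  perm <- res
  sel <- res$panel == "Lipid"
  perm[sel, ] <- perm[which(sel)[sample(sum(sel))], ]
  q2 <- qtm_fdr(perm)
  expect_setequal(q2$q_bh[perm$panel == "Lipid"], q$q_bh[sel])
  expect_equal(q2$q_bh[perm$panel == "HILIC"], q$q_bh[res$panel == "HILIC"])
})

test_that("flipping region-score orientation flips statistics, not p-values", {
  set.seed(23)
  nm <- paste0("s", 1:40)
  sc <- setNames(rnorm(40), nm)
  y <- setNames(0.5 * sc + rnorm(40), nm)
  a <- eqtm_test(sc, y); b <- eqtm_test(-sc, y)
  expect_equal(b$statistic, -a$statistic)
  expect_equal(b$p, a$p)
  am <- metqtm_test(sc, y, "Lipid"); bm <- metqtm_test(-sc, y, "Lipid")
  expect_equal(bm$statistic, -am$statistic)
  expect_equal(bm$p, am$p)
})
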