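make_traits <- function(X) {
  df <- as.data.frame(X)
  df$sample_id <- paste0("s", seq_len(nrow(df)))
  df
}

test_that("VIF values follow 1 / (1 - R^2)", {
  set.seed(51)
  n <- 40
  a <- rnorm(n)
  b <- as.numeric(residuals(lm(rnorm(n) ~ a)))  # exactly uncorrelated with a
  t <- make_traits(cbind(a = a, b = b))
  v <- vif_values(t)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-9)

  # agreement with the correlation-matrix-inverse identity
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 4] <- X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.3)
  colnames(X) <- paste0("t", 1:4)
  v <- vif_values(make_traits(X))
  expect_equal(unname(v), unname(diag(solve(stats::cor(X)))),
               tolerance = 1e-8)
  # direct formula on one column
  r2 <- summary(lm(X[, 4] ~ X[, 1:3]))$r.squared
  expect_equal(unname(v[4]), 1 / (1 - r2), tolerance = 1e-10)

  # exact collinearity -> infinite VIF for all three
  Y <- cbind(a = rnorm(n), b = rnorm(n))
  Y <- cbind(Y, c = Y[, 1] + Y[, 2])
  expect_equal(unname(vif_values(make_traits(Y))), rep(Inf, 3))

  expect_error(vif_values(make_traits(cbind(a = rnorm(3), b = rnorm(3),
                                            c = rnorm(3), d = rnorm(3)))),
               "more samples than traits")
  expect_error(vif_values(make_traits(cbind(a = rnorm(9), k = rep(2, 9)))),
               "constant.*k")
})

test_that("vif_prune removes the worst trait until all pass", {
  set.seed(52)
  n <- 60
  base <- matrix(rnorm(n * 3), n, 3)
  X <- cbind(base, dup = base[, 1])
  colnames(X) <- c("a", "b", "c", "dup")
  pruned <- vif_prune(make_traits(X), threshold = 8)
  left <- setdiff(names(pruned), "sample_id")
  # exactly one of the duplicated pair goes; ties remove the later column
  expect_equal(length(left), 3)
  expect_true("a" %in% left && !("dup" %in% left))
  expect_true(all(vif_values(pruned) <= 8))
  log <- attr(pruned, "removal_log")
  expect_equal(log$trait, "dup")

  # already-clean table unchanged
  clean <- make_traits(matrix(rnorm(n * 3), n, 3,
                              dimnames = list(NULL, c("x", "y", "z"))))
  expect_equal(names(vif_prune(clean, 8)), names(clean))

  # independent columns rarely trip a threshold of 8 at n = 500
  set.seed(53)
  big <- make_traits(matrix(rnorm(500 * 10), 500, 10,
                            dimnames = list(NULL, paste0("v", 1:10))))
  expect_equal(length(setdiff(names(vif_prune(big, 8)), "sample_id")), 10)
})

test_that("threshold sweep counts are non-decreasing", {
  set.seed(54)
  n <- 80
  base <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(base,
             m1 = base[, 1] + rnorm(n, sd = 0.2),
             m2 = base[, 2] + rnorm(n, sd = 0.2))
  colnames(X)[1:4] <- paste0("b", 1:4)
  t <- make_traits(X)
  sw <- vif_threshold_sweep(t, c(1.5, 3, 6, 12, 50))
  expect_true(all(diff(sw$n_traits) >= 0))
  expect_equal(sw$n_traits[5], 6)    # above max VIF: nothing removed
  expect_lt(sw$n_traits[1], 6)       # tight threshold prunes the collinear pair
  expect_error(vif_threshold_sweep(t, c(2, 5)), "at least 4")
})

test_that("log-curve fit recovers known parameters", {
  x <- seq(2, 50, by = 1)
  y <- 15.71 * log(x - 0.8853) + 57.88
  f <- fit_log_curve(x, y)
  expect_equal(f$a, 15.71, tolerance = 1e-3)
  expect_equal(f$b, 0.8853, tolerance = 1e-3)
  expect_equal(f$c, 57.88, tolerance = 1e-3)

  set.seed(55)
  f2 <- fit_log_curve(x, y + rnorm(length(x), sd = 0.5))
  expect_equal(f2$a, 15.71, tolerance = 0.5)
  expect_equal(f2$b, 0.8853, tolerance = 0.5)

  expect_warning(f3 <- fit_log_curve(x, rep(5, length(x))), "degenerate")
  expect_equal(f3$a, 0)
})

test_that("high and median VIF thresholds from the slope-1 rule", {
  expect_equal(high_vif_threshold(list(a = 15.71, b = 0.8853)), 16.5953)
  expect_equal(high_vif_threshold(list(a = 1, b = 0)), 1)
  expect_equal(high_vif_threshold(list(a = 2, b = 3)), 5)
  expect_error(high_vif_threshold(list(a = -1, b = 0)), "a > 0")
  # closed form a + b for random parameters
  set.seed(56)
  for (i in 1:20) {
    a <- runif(1, 0.1, 30); b <- runif(1, -5, 5)
    expect_equal(high_vif_threshold(list(a = a, b = b)), a + b)
  }
  expect_equal(as.numeric(median_vif_threshold(16.5953)), 8.29765)
  expect_equal(attr(median_vif_threshold(16.5953), "rounded"), 8)
  expect_equal(as.numeric(median_vif_threshold(10)), 5)
  expect_error(median_vif_threshold(2), "exceed 2")
})

test_that("multivariate PCs name, count and permutation behavior", {
  set.seed(57)
  y <- rnorm(30)
  t <- make_traits(cbind(a = y, b = 2 * y + 3))
  m <- multivariate_pcs(t, 0.9)
  expect_equal(setdiff(names(m), "sample_id"), "mPC1")

  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("v", 1:5)))
  t <- make_traits(X)
  m <- multivariate_pcs(t, 0.90)
  k <- select_num_pcs(attr(m, "variance_fractions"), 0.90)
  expect_equal(setdiff(names(m), "sample_id"), paste0("mPC", seq_len(k)))

  perm <- sample(30)
  m2 <- multivariate_pcs(t[perm, ], 0.90)
  expect_equal(m2$sample_id, m$sample_id[perm])
  expect_equal(m2$mPC1, m$mPC1[perm], tolerance = 1e-10)
})

test_that("heritability: closed-form cases and simulation", {
  # balanced data engineered so MSB and MSW give Vg = 2, Vr = 2, nrep = 2:
  # genotype means -2, 0, 2 with within-pair spread sqrt(2)/?; construct
  # directly from the moment equations instead
  g <- rep(1:3, each = 2)
  # within-genotype deviations with sample variance exactly 1 per genotype
  dev <- rep(c(-1, 1), 3) / sqrt(2)
  means <- c(-2, 0, 2)
  y <- means[g] + dev
  h <- heritability(y, g)
  msw <- 1                    # sum dev^2 = 3, df = 3 -> MSW = 1
  msb <- 2 * var(means)       # ni * var of means = 8
  vg <- (msb - msw) / 2
  expect_equal(as.numeric(h), vg / (vg + msw / 2))

  # all genotype means equal: Vg floored at 0
  y0 <- c(1, -1, 1, -1, 1, -1)
  expect_equal(as.numeric(heritability(y0, rep(1:3, each = 2))), 0)

  # simulation around the closed form 1 / (1 + 1/3) = 0.75
  set.seed(58)
  h2s <- replicate(10, {
    gg <- rep(1:200, each = 3)
    yy <- rnorm(200)[gg] + rnorm(600)
    as.numeric(heritability(yy, gg))
  })
  expect_true(all(abs(h2s - 0.75) < 0.1))

  expect_error(heritability(rnorm(4), rep(1, 4)), "single genotype")
  expect_error(heritability(rnorm(3), 1:3), "replicated")
})

test_that("heritability variance components agree with lme4 on balanced data", {
  skip_if_not_installed("lme4")
  set.seed(59)
  g <- factor(rep(1:80, each = 4))
  y <- rnorm(80, sd = sqrt(2))[as.integer(g)] + rnorm(320)
  h <- heritability(y, g)
  fit <- lme4::lmer(y ~ (1 | g))
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(attr(h, "Vg"), vc$vcov[1], tolerance = 1e-4)
  expect_equal(attr(h, "Vr"), vc$vcov[2], tolerance = 1e-4)
})

test_that("allele effect size scales estimate by major-allele mean", {
  expect_equal(allele_effect_size(1.5, c(2, 3, 4)), 0.5)
  expect_equal(allele_effect_size(-0.6, c(2, 3, 4)), -0.2)
  expect_equal(allele_effect_size(0, c(5, 5)), 0)
  expect_error(allele_effect_size(1, c(-1, 1)), "zero")
})

test_that("TAS co-localization merges transitively within the window", {
  rec <- data.frame(
    snp = paste0("S", 1:5),
    chrom = c("4", "4", "2", "2", "2"),
    pos = c(170.0e6, 170.5e6, 0, 0.9e6, 1.8e6),
    trait = c("GH_PC5", "WidthDepthRatio3D", "t1", "t2", "t3"),
    group = c("PH", "univariate", "univariate", "PH", "multivariate"))
  cl <- colocalize_tas(rec, window = 1e6)
  expect_equal(nrow(cl$loci), 2)
  # chained chr2 SNPs merge transitively despite 1.8 Mb total span
  chr2 <- cl$loci[cl$loci$chrom == "2", ]
  expect_equal(chr2$n_snps, 3)
  expect_equal(chr2$groups, "PH+multivariate+univariate")
  expect_equal(unname(cl$venn["PH+univariate"]), 1L)

  # same positions on different chromosomes stay apart
  rec2 <- data.frame(snp = c("a", "b"), chrom = c("1", "2"),
                     pos = c(5e6, 5e6), trait = "t", group = "PH")
  expect_equal(nrow(colocalize_tas(rec2)$loci), 2)

  # window 0: one locus per unique position
  rec3 <- data.frame(snp = paste0("s", 1:4), chrom = "1",
                     pos = c(10, 10, 11, 30), trait = "t",
                     group = c("PH", "univariate", "PH", "PH"))
  expect_equal(nrow(colocalize_tas(rec3, window = 0)$loci), 3)
})
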