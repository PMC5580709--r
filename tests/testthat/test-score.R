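test_that("divide-by-average normalization gives per-sample mean 1", {
  m <- cbind(a = c(5L, 5L, 5L, 5L))
  expect_equal(unname(normalize_counts(m)[, 1]), rep(1, 4))
  m2 <- cbind(a = c(10L, 20L, 30L))
  expect_equal(unname(normalize_counts(m2)[, 1]), c(0.5, 1, 1.5))
  m3 <- cbind(a = c(0L, 10L, 10L))
  expect_equal(unname(normalize_counts(m3)[, 1]), c(0, 1.5, 1.5))
  # property: mean 1 per sample for random matrices
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rpois(60, sample(5:500, 1)), 10, 6,
                dimnames = list(paste0("s", 1:10), paste0("c", 1:6)))
    expect_equal(unname(colMeans(normalize_counts(m))), rep(1, 6),
                 tolerance = 1e-9)
  }
  m_bad <- cbind(a = c(1L, 2L), b = c(0L, 0L))
  expect_error(normalize_counts(m_bad), "b")
})

test_that("z-scores standardise the log ratios", {
  # construct counts whose log ratios are exactly [1, -1, 0, 0] when the
  # pseudocount is 0: equal GLU counts and GAL counts 2x / 0.5x / 1x / 1x
  counts <- cbind(Q_GLU = c(100L, 100L, 100L, 100L),
                  Q_GAL = c(200L, 50L, 100L, 100L))
  counts <- counts * 1L
  rownames(counts) <- paste0("s", 1:4)
  norm <- normalize_counts(counts)
  th0 <- 0
  zt <- compute_zscores(norm, counts, "Q", pseudocount = 0)
  # GAL normalization rescales by the mean (112.5/100), a constant shared
  # by all strains, so it shifts every log ratio equally and cancels in z
  expect_equal(zt$log_ratio - mean(zt$log_ratio), c(1, -1, 0, 0),
               tolerance = 1e-12)
  sd_expect <- sqrt(2 / 3)
  expect_equal(zt$z, c(1, -1, 0, 0) / sd_expect, tolerance = 1e-12)
  # a strain at the across-strain mean has z = 0
  expect_equal(zt$z[3], 0, tolerance = 1e-12)
  # zero GAL count with a positive pseudocount stays finite
  counts0 <- cbind(Q_GLU = c(50L, 50L, 50L), Q_GAL = c(0L, 60L, 90L))
  rownames(counts0) <- paste0("s", 1:3)
  zt0 <- compute_zscores(normalize_counts(counts0), counts0, "Q", 0.5)
  expect_true(all(is.finite(zt0$log_ratio)))
  expect_lt(zt0$log_ratio[1], -3)
  # degenerate screen: all ratios equal
  cdeg <- cbind(Q_GLU = c(10L, 10L, 10L), Q_GAL = c(10L, 10L, 10L))
  rownames(cdeg) <- paste0("s", 1:3)
  expect_error(compute_zscores(normalize_counts(cdeg), cdeg, "Q", 0),
               "degenerate")
  expect_error(compute_zscores(norm, counts, "R"), "GAL and GLU")
})

test_that("error propagation follows the Poisson delta-method chain", {
  # n_gal = n_glu = 100, pc = 0: delta = sqrt(0.02)/ln 2
  delta <- sqrt(0.02) / log(2)
  expect_equal(delta, 0.2040, tolerance = 1e-3)
  # with sd_logratio = 1 and z = 1 the error rate equals delta itself
  expect_equal(estimate_error_rate(100, 100, 1, 1, pseudocount = 0),
               delta, tolerance = 1e-12)
  # error rate vanishes as counts grow
  expect_lt(estimate_error_rate(1e8, 1e8, 1, 1, 0.5), 1e-3)
  # z = 0 is fully uncertain by convention
  expect_equal(estimate_error_rate(100, 100, 0, 1), 1)
  expect_error(estimate_error_rate(-1, 10, 1, 1), ">= 0")
  expect_error(estimate_error_rate(10, 10, 1, 0), "> 0")
})

test_that("corrected Z-score bounds shrink and inflate without sign flips", {
  cz <- correct_zscores(2.5, 0.1)
  expect_equal(cz$low, 2.25)
  expect_equal(cz$high, 2.75)
  expect_equal(correct_zscores(0, 5), list(low = 0, high = 0))
  # error rates above 1 cap the low bound at zero
  cz2 <- correct_zscores(2, 1.4)
  expect_equal(cz2$low, 0)
  expect_equal(cz2$high, 4.8)
  set.seed(8)
  z <- rnorm(200, sd = 3)
  er <- rexp(200)
  cz3 <- correct_zscores(z, er)
  expect_true(all(abs(cz3$low) <= abs(z) + 1e-15))
  expect_true(all(abs(cz3$high) >= abs(z) - 1e-15))
  expect_true(all(sign(cz3$low) == sign(z) | cz3$low == 0))
})

test_that("classification uses strict corrected-Z cutoffs", {
  th <- screen_thresholds()
  expect_equal(classify_modifiers(c(2.5, -2.5, 0.3), th),
               c("suppressor", "enhancer", "no_effect"))
  # boundary values are not hits (strict inequality)
  expect_equal(classify_modifiers(c(1.96, -1.96), th),
               c("no_effect", "no_effect"))
  expect_error(screen_thresholds(suppressor_cut = -1), "suppressor_cut")
})

test_that("the full scoring chain matches a spreadsheet recomputation", {
  set.seed(12)
  for (case in 1:25) {
    n <- sample(3:10, 1)
    counts <- matrix(rpois(2 * n, lambda = sample(c(5, 50, 500), 1)),
                     n, 2, dimnames = list(paste0("s", seq_len(n)),
                                           c("Q_GLU", "Q_GAL")))
    if (sd(log2((counts[, 2] + 0.5) / (counts[, 1] + 0.5))) == 0) next
    fit <- score_screen(counts)
    bf <- bf_score(counts, "Q", pc = 0.5)
    zt <- fit$ztable
    expect_equal(zt$z, bf$z, tolerance = 1e-12)
    # see test-acceptance: the error-rate ratio is ill-conditioned at
    # z ~ 0, so it is compared only where |z| is appreciable
    wp <- abs(bf$z) > 1e-8
    expect_equal(zt$error_rate[wp], bf$error_rate[wp], tolerance = 1e-12)
    expect_equal(zt$z_corrected_low, bf$low, tolerance = 1e-12)
    expect_equal(zt$z_corrected_high, bf$high, tolerance = 1e-12)
    # invariant bundle: centering, shrinkage, partition
    expect_equal(mean(zt$z), 0, tolerance = 1e-9)
    expect_equal(sd(zt$z), 1, tolerance = 1e-9)
    expect_true(all(abs(zt$z_corrected_low) <= abs(zt$z) + 1e-12))
    expect_true(all(zt$label %in% c("suppressor", "enhancer",
                                    "no_effect")))
  }
})

test_that("z is invariant to rescaling a sample's sequencing depth", {
  set.seed(33)
  counts <- matrix(rpois(40, 400) + 100L, 20, 2,
                   dimnames = list(paste0("s", 1:20),
                                   c("Q_GLU", "Q_GAL")))
  z1 <- score_screen(counts)$ztable$z
  counts2 <- counts
  counts2[, "Q_GAL"] <- counts2[, "Q_GAL"] * 7L
  z2 <- score_screen(counts2)$ztable$z
  # residual perturbation is O(pseudocount / count): the pseudocount is
  # fixed on the raw-count scale, so rescaling shifts it slightly
  expect_equal(z1, z2, tolerance = 1e-3)
})

test_that("the modifier_screen object exposes the classic methods", {
  set.seed(2)
  counts <- matrix(rpois(60, 200), 15, 4,
                   dimnames = list(sprintf("s%02d", 1:15),
                                   c("Q1_GLU", "Q1_GAL", "Q2_GLU",
                                     "Q2_GAL")))
  fit <- score_screen(counts, fdr = TRUE)
  expect_s3_class(fit, "modifier_screen")
  expect_output(print(fit), "cutoffs")
  sm <- summary(fit)
  expect_equal(sm$n_strains, c(15L, 15L))
  expect_equal(sm$suppressors + sm$enhancers + sm$no_effect, c(15L, 15L))
  cf <- coef(fit)
  expect_equal(dim(cf), c(15L, 2L))
  expect_equal(cf["s01", "Q1"],
               fit$ztable$z_corrected_low[fit$ztable$strain_id == "s01" &
                                            fit$ztable$query == "Q1"])
  expect_true(all(fit$ztable$q_value >= 0 & fit$ztable$q_value <= 1))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  # ztable TSV round trip preserves values and labels
  path <- tempfile(fileext = ".tsv")
  write_ztable(fit, path)
  back <- read_ztable(path)
  expect_equal(back$z, fit$ztable$z, tolerance = 1e-15)
  expect_identical(back$label, fit$ztable$label)
})

test_that("robust and quantile modes run and differ where they should", {
  set.seed(5)
  counts <- matrix(rpois(100, 300), 25, 4,
                   dimnames = list(sprintf("s%02d", 1:25),
                                   c("Q_GLU", "Q_GAL", "R_GLU", "R_GAL")))
  fit_r <- score_screen(counts, robust = TRUE)
  expect_true(all(is.finite(fit_r$ztable$z)))
  skip_if_not_installed("limma")
  # tie-free columns so quantile normalization is exact
  counts_u <- matrix(as.integer(sample.int(5000, 100)), 25, 4,
                     dimnames = dimnames(counts))
  nq <- normalize_counts(counts_u, method = "quantile")
  # true quantile normalization forces identical sorted columns
  expect_equal(apply(nq, 2, sort), matrix(rep(sort(nq[, 1]), 4), ncol = 4),
               ignore_attr = TRUE)
})
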