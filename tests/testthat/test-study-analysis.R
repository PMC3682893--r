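make_fake_fit <- function(fp_mid, strain = "S01", treatment = "ampicillin",
                          replicate = "1", converged = TRUE,
                          detection_limited = FALSE, fp_bound = NA_real_,
                          slow_fraction = fp_mid) {
  structure(list(strain = strain, treatment = treatment, replicate = replicate,
                 fp_mid = fp_mid, slow_fraction = slow_fraction,
                 converged = converged, detection_limited = detection_limited,
                 fp_bound = fp_bound),
            class = "persister_fit")
}

test_that("strain summaries aggregate log10 fractions across replicates", {
  # constant input: zero spread
  s1 <- summarize_strain(lapply(1:3, function(r)
    make_fake_fit(1e-3, replicate = r)))
  expect_equal(s1$mean_log10_fp, -3)
  expect_equal(s1$se_log10_fp, 0)
  expect_equal(s1$n_replicates, 3)
  # two-point log-scale arithmetic: mean -3, se 1
  s2 <- summarize_strain(list(make_fake_fit(1e-2), make_fake_fit(1e-4)))
  expect_equal(s2$mean_log10_fp, -3)
  expect_equal(s2$se_log10_fp, 1)
  # non-converged fits are excluded from the replicate count
  s3 <- summarize_strain(list(make_fake_fit(1e-2),
                              make_fake_fit(1e-3, converged = FALSE)))
  expect_equal(s3$n_replicates, 1)
  expect_equal(s3$n_not_converged, 1)
  expect_true(is.na(s3$se_log10_fp))
  # detection-limited replicates contribute their bound and raise the flag
  s4 <- summarize_strain(list(make_fake_fit(1e-2),
                              make_fake_fit(5e-3, detection_limited = TRUE,
                                            fp_bound = 1e-4)))
  expect_equal(s4$mean_log10_fp, mean(c(-2, -4)))
  expect_equal(s4$n_detection_limited, 1)
  # zero converged fits: summary unavailable
  s5 <- summarize_strain(list(make_fake_fit(1e-2, converged = FALSE)))
  expect_false(s5$available)
  expect_true(is.na(s5$mean_log10_fp))
})

test_that("spearman matches brute-force rank computation, with and without ties", {
  expect_equal(spearman_perm(1:4, c(2, 3, 5, 9))$rho, 1)
  expect_equal(spearman_perm(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  set.seed(71)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    x <- sample(1:5, n, replace = TRUE) + runif(n) * (i %% 2)  # ties when even
    y <- sample(1:5, n, replace = TRUE) + runif(n) * (i %% 2)
    got <- spearman_perm(x, y, seed = i)
    want <- brute_spearman(x, y)
    if (is.na(want)) expect_false(got$defined)
    else expect_equal(got$rho, want, tolerance = 1e-12)
  }
  # constant vector: rho undefined, flagged not errored
  flat <- spearman_perm(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
})

test_that("permutation p-values are exact at small n", {
  # co-monotone n = 4: only the identity and the reversal reach |rho| = 1
  res <- spearman_perm(1:4, c(2, 3, 5, 9))
  expect_identical(res$method, "exact-permutation")
  expect_equal(res$p_value, 2 / 24)
  # exhaustive check at n = 3 against direct enumeration
  x <- c(1, 2, 3); y <- c(3, 1, 2)
  res3 <- spearman_perm(x, y)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  rhos <- vapply(perms, function(p) cor(x, y[p], method = "spearman"), numeric(1))
  expect_equal(res3$p_value, mean(abs(rhos) >= abs(res3$rho) - 1e-12))
  # monte-carlo arm is seeded and reproducible
  set.seed(72)
  xl <- rnorm(12); yl <- rnorm(12)
  a <- spearman_perm(xl, yl, n_perm = 2000, seed = 5)
  b <- spearman_perm(xl, yl, n_perm = 2000, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$method, "monte-carlo")
  expect_gt(a$p_value, 0); expect_lte(a$p_value, 1)
})

test_that("cross-antibiotic correlations pair strains and skip sparse pairs", {
  mk <- function(strain, treatment, fp) {
    data.frame(strain = strain, treatment = treatment,
               mean_log10_fp = log10(fp), available = TRUE)
  }
  fps <- 10^seq(-5, -1, length.out = 8)
  summaries <- rbind(
    do.call(rbind, Map(mk, sprintf("S%02d", 1:8), "drugA", fps)),
    do.call(rbind, Map(mk, sprintf("S%02d", 1:8), "drugB", fps)),      # identical ranks
    do.call(rbind, Map(mk, sprintf("S%02d", 1:2), "drugC", fps[1:2]))) # too sparse
  res <- cross_antibiotic_correlations(summaries, n_perm = 500, seed = 1)
  expect_equal(nrow(res), 3)  # AB, AC, BC
  ab <- res[res$treatment_a == "drugA" & res$treatment_b == "drugB", ]
  expect_equal(ab$rho, 1)
  expect_equal(ab$n, 8)
  expect_false(ab$skipped)
  sparse <- res[res$treatment_b == "drugC", ]
  expect_true(all(sparse$skipped))
  expect_match(sparse$reason[1], "complete strain pairs")
  # strains missing one member are dropped and counted
  summaries2 <- summaries[-1, ]  # S01 missing from drugA
  res2 <- cross_antibiotic_correlations(summaries2, treatments = c("drugA", "drugB"),
                                        n_perm = 500, seed = 1)
  expect_equal(res2$n, 7)
  expect_equal(res2$n_dropped, 1)
})

test_that("combination classification follows the three-hypothesis geometry", {
  # constructed cases from the classifier's contract
  cc <- classify_combination(1e-2, 1e-3, 1.2e-3)
  expect_identical(cc$label, "coincident")
  expect_equal(cc$d_coincident, abs(log10(1.2e-3) - log10(1e-3)), tolerance = 1e-12)
  expect_equal(cc$d_independent, abs(log10(1.2e-3) - log10(1e-5)), tolerance = 1e-12)
  expect_identical(classify_combination(1e-2, 1e-3, 1e-5)$label, "independent")
  expect_identical(classify_combination(1e-2, 1e-3, 0)$label, "exclusive")
  # below-detection f_AB is exclusive regardless of distances
  expect_identical(classify_combination(1e-2, 1e-3, 1e-10,
                                        detection_bound = 1e-9)$label,
                   "exclusive")
  # neither hypothesis within tau: ambiguous
  expect_identical(classify_combination(1e-2, 1e-2, 1e-3)$label, "ambiguous")
  # scale equivariance of the non-exclusive labels
  for (k in c(1, 0.3, 0.05)) {
    expect_identical(classify_combination(k * 1e-2, k * 1e-3, k * 1.2e-3)$label,
                     "coincident")
  }
  expect_error(classify_combination(0, 1e-3, 1e-4), "detection bound")
})

test_that("parameter determinants recover a constructed monotone dependence", {
  # fp varies through a at fixed b, m (balanced-growth equilibrium)
  fps <- 10^seq(-5, -1, length.out = 12)
  tab <- do.call(rbind, lapply(fps, function(fp) {
    d <- recovery_truth(fp, m = 2, b = 1e-3)
    data.frame(fp_mid = fp, a = d$mech$a, b = d$mech$b, m = d$mech$m)
  }))
  set.seed(73)
  tab$b <- tab$b * 10^runif(12, -0.05, 0.05)  # mild jitter so b is not constant
  res <- parameter_determinants(tab, n_perm = 500, seed = 2)
  expect_equal(nrow(res), 3)
  expect_setequal(res$variable, c("fp_vs_a", "fp_vs_b", "fp_vs_m"))
  expect_gt(res$rho[res$variable == "fp_vs_a"], 0.9)
  expect_lt(abs(res$rho[res$variable == "fp_vs_b"]), 0.58)
  expect_false(res$defined[res$variable == "fp_vs_m"])  # m constant: flagged
})
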