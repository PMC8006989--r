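test_that("permutation ensemble shapes, identity first permutation, P >= 1", {
  sim <- simulate_sequences(list(list(label = "c", n_proteins = 20),
                                 list(label = "d", n_proteins = 2)),
                            seed = 61)
  fm <- build_feature_matrices(sim$records, sim$manifest, "APF")[["c.APF"]]
  ens <- permutation_ensemble(fm, P = 4, seed = 5, measures = c("CR", "nMIR"))
  expect_setequal(names(ens),
                  c("CR.degree", "CR.eigenvector", "nMIR.degree",
                    "nMIR.eigenvector"))
  expect_identical(dim(ens[["CR.degree"]]$samples), c(4L, 10L))
  expect_true(all(ens[["CR.degree"]]$samples >= 0 &
                    ens[["CR.degree"]]$samples <= 1))
  # P = 1: single sample, zero SD by convention
  e1 <- permutation_ensemble(fm, P = 1, seed = 5, measures = "CR")
  rt1 <- robustness_table(list(e1))
  expect_equal(rt1$mean_sd, rep(0, nrow(rt1)))
  expect_error(permutation_ensemble(fm, P = 0, seed = 5), "P must be")
})

test_that("strict recomputation confirms CR/nMIR permutation invariance", {
  sim <- simulate_sequences(list(list(label = "c", n_proteins = 30),
                                 list(label = "d", n_proteins = 2)),
                            seed = 62)
  fm <- build_feature_matrices(sim$records, sim$manifest, "N")[["c.N"]]
  strict <- permutation_ensemble(fm, P = 8, seed = 9,
                                 measures = c("CR", "nMIR"), strict = TRUE)
  fast <- permutation_ensemble(fm, P = 8, seed = 9,
                               measures = c("CR", "nMIR"), strict = FALSE)
  for (key in names(strict)) {
    expect_lt(max(apply(strict[[key]]$samples, 2, sd)), 1e-12)
    expect_equal(strict[[key]]$samples[1, ], fast[[key]]$samples[1, ],
                 tolerance = 1e-12)
  }
})

test_that("TE centrality samples vary across permutations on coupled data", {
  x <- simulate_feature_series(120, 3, "var_coupled",
                               edges = list(list(from = 1, to = 2, coef = 0.8),
                                            list(from = 2, to = 3, coef = 0.5)),
                               seed = 63)
  ens <- permutation_ensemble(x, P = 6, seed = 10, measures = "TE",
                              params = connectivity_params(l = 2, k = 2,
                                                           q = 3, seed = 1))
  sds <- apply(ens[["TE.in_degree"]]$samples, 2, sd)
  expect_gt(max(sds), 1e-3)  # order-dependent estimator
})

test_that("robustness table implements the two-stage average", {
  # one class, one feature with SD 0.2, others 0 (K = 20) -> entry 0.01
  samples <- matrix(0.5, 10, 20, dimnames = list(NULL, paste0("f", 1:20)))
  samples[, 7] <- seq(0, by = 1, length.out = 10) * 0.2 / sd(seq(0, 9)) + 0.2
  stopifnot(abs(sd(samples[, 7]) - 0.2) < 1e-12)
  cs <- structure(list(samples = samples, network = "CR",
                       centrality = "degree", scheme = "N",
                       class_label = "c1", P = 10),
                  class = "centrality_samples")
  rt <- robustness_table(list(list(CR.degree = cs)))
  expect_equal(rt$mean_sd, 0.2 / 20, tolerance = 1e-12)
  # identical samples everywhere -> zero
  cs0 <- cs; cs0$samples <- matrix(0.4, 10, 20)
  expect_equal(robustness_table(list(list(CR.degree = cs0)))$mean_sd, 0)
  # two classes: brute-force SD-then-mean oracle
  set.seed(64)
  s1 <- cs; s1$samples <- matrix(runif(200), 10, 20)
  s2 <- cs; s2$samples <- matrix(runif(200), 10, 20)
  rt2 <- robustness_table(list(list(CR.degree = s1), list(CR.degree = s2)))
  oracle <- mean(c(mean(apply(s1$samples, 2, sd)),
                   mean(apply(s2$samples, 2, sd))))
  expect_equal(rt2$mean_sd, oracle, tolerance = 1e-12)
})

test_that("Levene test matches car::leveneTest and detects heteroscedasticity", {
  set.seed(65)
  y <- matrix(rnorm(100 * 6), 100, 6)
  res <- levene_test(y, theta = 0.05)
  long <- data.frame(v = as.numeric(y),
                     g = factor(rep(seq_len(6), each = 100)))
  ref <- car::leveneTest(v ~ g, data = long, center = "mean")
  expect_equal(res$F, ref[1, "F value"], tolerance = 1e-10)
  expect_identical(res$df, c(ref[1, "Df"], ref[2, "Df"]))
  # one group with 10x the SD is flagged
  y2 <- y; y2[, 3] <- rnorm(100, sd = 10)
  expect_false(levene_test(y2, theta = 0.05)$homogeneous)
  # identical constant groups -> F = 0, homogeneous
  y3 <- matrix(1, 50, 4)
  res3 <- levene_test(y3)
  expect_equal(res3$F, 0)
  expect_true(res3$homogeneous)
})

test_that("Levene type-I error is near theta under the null", {
  set.seed(66)
  rejections <- vapply(1:200, function(i) {
    y <- matrix(rnorm(30 * 4), 30, 4)
    !levene_test(y, theta = 0.05)$homogeneous
  }, logical(1))
  # binomial 3 sigma around 0.05 with 200 replicates
  expect_lt(abs(mean(rejections) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Welch pairwise separates well-separated means and scores them", {
  set.seed(67)
  y <- cbind(A = rnorm(100, 1, 0.01), B = rnorm(100, 0, 0.01))
  ord <- welch_pairwise(y, theta = 0.005)
  expect_identical(ord$decisions["A", "B"], "higher")
  expect_identical(ord$decisions["B", "A"], "lower")
  expect_identical(unname(ord$scores), c(1L, 0L))
  expect_identical(ord$order, c("A", "B"))
  # exactly equal variances, n = 100 -> Welch-Satterthwaite df = 198
  a <- rnorm(100)
  ord_eq <- welch_pairwise(cbind(A = a, B = a + 1))
  expect_equal(ord_eq$df["A", "B"], 198, tolerance = 1e-10)
  y_eq <- cbind(A = rnorm(100), B = rnorm(100))
  v <- welch_pairwise(y_eq)$df["A", "B"]
  s2 <- apply(y_eq, 2, var)
  v_closed <- (sum(s2) / 100)^2 / sum((s2 / 100)^2 / 99)
  expect_equal(v, v_closed, tolerance = 1e-12)
})

test_that("Welch statistic agrees with t.test and decisions are antisymmetric", {
  set.seed(68)
  y <- matrix(rnorm(50 * 5, sd = runif(5, 0.5, 2)), 50, 5, byrow = TRUE)
  colnames(y) <- paste0("f", 1:5)
  ord <- welch_pairwise(y, theta = 0.05)
  for (i in 1:4) for (j in (i + 1):5) {
    tt <- t.test(y[, i], y[, j])
    expect_equal(ord$T[i, j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(ord$df[i, j], unname(tt$parameter), tolerance = 1e-8)
    # antisymmetry
    expect_identical(ord$decisions[i, j] == "higher",
                     ord$decisions[j, i] == "lower")
    expect_identical(ord$decisions[i, j] == "none",
                     ord$decisions[j, i] == "none")
  }
  # scores are a tournament summary
  expect_lte(sum(ord$scores), 5 * 4 / 2)
})

test_that("degenerate constant samples give no decision, no error", {
  y <- cbind(A = rep(0.3, 20), B = rep(0.3, 20), C = rep(0.9, 20))
  ord <- welch_pairwise(y)
  expect_identical(ord$decisions["A", "B"], "none")
  expect_identical(ord$decisions["C", "A"], "higher")
  expect_identical(unname(ord$scores), c(0L, 0L, 2L))
})

test_that("one-sided Welch type-I error matches theta over null pairs", {
  set.seed(69)
  for (theta in c(0.05, 0.01)) {
    hits <- vapply(1:2000, function(i) {
      a <- rnorm(25); b <- rnorm(25)
      ord <- welch_pairwise(cbind(A = a, B = b), theta = theta)
      ord$decisions["A", "B"] == "higher"
    }, logical(1))
    expect_lt(abs(mean(hits) - theta), 3 * sqrt(theta * (1 - theta) / 2000))
  }
})

test_that("significance sweep is monotone in theta", {
  set.seed(70)
  y <- matrix(rnorm(100 * 8, mean = rep(seq(0, 0.35, length.out = 8),
                                        each = 100), sd = 0.5), 100, 8)
  colnames(y) <- paste0("f", 1:8)
  sweep <- significance_sweep(y)
  expect_length(sweep, 6L)
  mono <- attr(sweep, "monotonicity")
  expect_true(all(diff(mono$resolved_pairs) <= 0))  # thetas decreasing
  # decisions at theta = 0.005 are a subset of those at theta = 0.25
  d25 <- sweep[["0.25"]]$decisions
  d005 <- sweep[["0.005"]]$decisions
  expect_true(all(d25[d005 == "higher"] == "higher"))
  expect_error(significance_sweep(y, thetas = c(0.5, 0.1)), "0, 0.5")
})

test_that("significance_table ranks by descending score with shared ties", {
  ord <- list(scores = c(a = 3L, b = 1L, c = 3L, d = 0L))
  class(ord) <- "significance_order"
  tab <- significance_table(ord)
  expect_identical(tab$score, c(3L, 3L, 1L, 0L))
  expect_identical(tab$rank, c(1L, 1L, 2L, 3L))
})
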