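test_that("absolute correlation handles exact linear relations and sign", {
  x1 <- rnorm(50)
  fm <- cbind(X1 = x1, X2 = 2 * x1, X3 = -x1)
  cr <- correlation_matrix(fm)
  expect_equal(cr$values[1, 2], 1)
  expect_equal(cr$values[1, 3], 1)   # absolute value of r = -1
  expect_true(isSymmetric(cr$values))
  expect_equal(unname(diag(cr$values)), rep(1, 3))
  expect_true(all(cr$values >= 0 & cr$values <= 1))
})

test_that("correlation recovers a planted rho within sampling error", {
  rho <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  x <- simulate_feature_series(2000, structure = "correlated", rho = rho,
                               seed = 21)
  cr <- correlation_matrix(x)
  expect_equal(cr$values[1, 2], 0.8, tolerance = 0.05 / 0.8)
})

test_that("constant columns give zero CR off-diagonals with a warning", {
  fm <- cbind(X1 = rnorm(30), X2 = rep(2, 30))
  expect_warning(cr <- correlation_matrix(fm), "constant")
  expect_equal(cr$values[1, 2], 0)
  expect_equal(cr$values[2, 2], 1)
})

test_that("equal-frequency discretization yields balanced value-based states", {
  p <- connectivity_params(bins = 10)
  s <- discretize(1:100, p)
  expect_identical(as.integer(table(s)), rep(10L, 10))
  # equal width on an evenly spaced grid gives the same partition
  pw <- connectivity_params(bins = 10, binning = "equal_width")
  expect_identical(discretize(1:100, p), discretize(1:100, pw))
  # value-based: any reordering maps to the permuted states
  set.seed(31)
  x <- rnorm(200)
  perm <- sample(200)
  expect_identical(discretize(x, p)[perm], discretize(x[perm], p))
  expect_warning(s1 <- discretize(rep(3.3, 50), p), "single state")
  expect_identical(s1, rep(1L, 50))
})

test_that("nMIR is 1 for a copy of the maximum-entropy series and bounded", {
  set.seed(32)
  x1 <- rnorm(400)
  fm <- cbind(X1 = x1, X2 = x1, X3 = rep(c(0, 1), 200))
  nm <- nmir_matrix(fm)
  # X1 has maximal entropy (10 balanced bins) -> diagonal exactly 1
  expect_equal(nm$values[1, 1], 1)
  expect_equal(nm$values[1, 2], 1)   # exact copy shares all information
  expect_true(all(nm$values >= 0 & nm$values <= 1 + 1e-12))
  expect_identical(nm$values, t(nm$values))
  expect_error(nmir_matrix(cbind(rep(1, 50), rep(2, 50))) |>
                 suppressWarnings(), "H_max")
})

test_that("independent series have small plug-in nMIR at n = 5000", {
  set.seed(33)
  fm <- cbind(X1 = runif(5000), X2 = runif(5000))
  nm <- nmir_matrix(fm)
  expect_lt(nm$values[1, 2], 0.05)
})

test_that("CR and nMIR are invariant under joint row permutations", {
  set.seed(34)
  sim <- simulate_sequences(list(list(label = "c", n_proteins = 40),
                                 list(label = "d", n_proteins = 2)),
                            seed = 35)
  fm <- build_feature_matrices(sim$records, sim$manifest, "N")[["c.N"]]
  values <- unclass(fm)
  cr0 <- correlation_matrix(values)$values
  nm0 <- nmir_matrix(values)$values
  for (rep in 1:5) {
    perm <- sample(nrow(values))
    expect_equal(correlation_matrix(values[perm, ])$values, cr0,
                 tolerance = 1e-12)
    expect_equal(nmir_matrix(values[perm, ])$values, nm0, tolerance = 1e-12)
  }
})

test_that("null CR magnitude scales as sqrt(2 / (pi n))", {
  set.seed(36)
  n <- 400
  means <- replicate(30, {
    x <- matrix(rnorm(n * 2), n, 2)
    correlation_matrix(x)$values[1, 2]
  })
  expect_equal(mean(means), sqrt(2 / (pi * n)), tolerance = 0.15)
})

test_that("transfer entropy vanishes for a deterministic self-copy", {
  set.seed(37)
  y <- rnorm(500)
  te <- transfer_entropy(y, y, connectivity_params())
  expect_lt(abs(te), 0.05)
})

test_that("raw TE on independent white noise stays within estimator noise", {
  p <- connectivity_params()
  tes <- vapply(1:20, function(s) {
    set.seed(100 + s)
    transfer_entropy(rnorm(1000), rnorm(1000), p)
  }, numeric(1))
  expect_true(all(abs(tes) <= 0.05))
})

test_that("TE detects the direction of an autoregressive coupling", {
  p <- connectivity_params()
  wins <- vapply(1:20, function(s) {
    x <- simulate_feature_series(1000, 2, "var_coupled",
                                 edges = list(list(from = 1, to = 2,
                                                   coef = 0.8)),
                                 seed = 200 + s)
    transfer_entropy(x[, 1], x[, 2], p) > transfer_entropy(x[, 2], x[, 1], p)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("KSG TE agrees with a discrete plug-in oracle on a binary chain", {
  # X iid +/-1; Y_{t+1} copies X_t with probability 0.9. With embedding
  # length 1 the true TE is log 2 - H_b(0.9) ~ 0.368 nats.
  set.seed(38)
  n <- 2000
  x <- sample(c(0, 1), n, replace = TRUE)
  y <- numeric(n)
  y[1] <- 0
  flip <- runif(n) < 0.1
  y[2:n] <- ifelse(flip[2:n], 1 - x[1:(n - 1)], x[1:(n - 1)])
  oracle <- oracle_discrete_te(x, y)
  p <- connectivity_params(l = 1, k = 1)
  # jitter breaks the exact ties of the binary states without adding
  # information
  xj <- x + runif(n) * 1e-6
  yj <- y + runif(n) * 1e-6
  ksg <- transfer_entropy(xj, yj, p)
  expect_equal(ksg, oracle, tolerance = 0.1)
  expect_equal(oracle, log(2) + 0.9 * log(0.9) + 0.1 * log(0.1),
               tolerance = 0.05)
})

test_that("bias-corrected TE matrix recovers planted directed coupling", {
  hits <- vapply(1:20, function(s) {
    x <- simulate_feature_series(600, 2, "var_coupled",
                                 edges = list(list(from = 1, to = 2,
                                                   coef = 0.8)),
                                 seed = 300 + s)
    te <- te_matrix_bias_corrected(x, connectivity_params(seed = s))
    c(te$values[2, 1] > 0, te$values[1, 2] == 0)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)   # planted edge found as entry (2,1)
  expect_gte(mean(hits[2, ]), 0.9)   # reverse direction clipped to zero
})

test_that("independent columns give mostly exact zeros after clipping", {
  x <- simulate_feature_series(400, 5, "independent", seed = 44)
  te <- te_matrix_bias_corrected(x, connectivity_params(seed = 45))
  off <- te$values[row(te$values) != col(te$values)]
  expect_gte(mean(off == 0), 0.9)
  expect_true(all(off >= 0))
  expect_true(all(diag(te$values) == 0))
})

test_that("connectivity params enforce the embedding and surrogate contracts", {
  expect_error(connectivity_params(l = 5, k = 3), "l == k")
  expect_error(connectivity_params(bins = 1), "bins")
  expect_error(connectivity_params(q = 0), "q")
  expect_error(transfer_entropy(rnorm(6), rnorm(6),
                                connectivity_params(l = 5, k = 5)),
               "too short")
})

test_that("relation matrices round-trip through TSV", {
  x <- simulate_feature_series(100, 3, "independent", seed = 46)
  cr <- correlation_matrix(x)
  path <- tempfile(fileext = ".tsv")
  write_relation_matrix(cr, path)
  back <- read_relation_matrix(path, "CR")
  expect_equal(back$values, cr$values, tolerance = 1e-12)
  expect_identical(back$feature_labels, cr$feature_labels)
})
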