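#' Connectivity parameters
#'
#' Bundles the tunable parameters of the three relationship measures.
#'
#' @param bins number of discretization bins B for the entropy / mutual
#'   information plug-in estimator (default 10).
#' @param binning `"equal_frequency"` (value-based quantile bins; default)
#'   or `"equal_width"`.
#' @param l,k source / target embedding lengths for transfer entropy;
#'   information-transfer detection requires `l == k` (default 5).
#' @param knn neighbour count of the nearest-neighbour TE estimator
#'   (default 4).
#' @param q number of surrogates for the TE bias correction (default 10).
#' @param surrogate `"shift"` (circular time shift by a random offset in
#'   `[N/4, 3N/4]`, preserving marginals and autocorrelation; default) or
#'   `"shuffle"` (full random permutation).
#' @param seed integer seed driving surrogate generation.
#' @return a list of class `connectivity_params`.
#' @export
connectivity_params <- function(bins = 10L, binning = c("equal_frequency",
                                                        "equal_width"),
                                l = 5L, k = 5L, knn = 4L, q = 10L,
                                surrogate = c("shift", "shuffle"),
                                seed = 1L) {
  binning <- match.arg(binning)
  surrogate <- match.arg(surrogate)
  if (l != k) stop("information transfer detection requires l == k")
  if (bins < 2L) stop("bins must be >= 2")
  if (q < 1L) stop("q must be >= 1")
  structure(list(bins = as.integer(bins), binning = binning,
                 l = as.integer(l), k = as.integer(k),
                 knn = as.integer(knn), q = as.integer(q),
                 surrogate = surrogate, seed = as.integer(seed)),
            class = "connectivity_params")
}

relation_matrix <- function(values, measure, feature_labels) {
  dimnames(values) <- list(feature_labels, feature_labels)
  structure(list(values = values, measure = measure,
                 symmetric = measure %in% c("CR", "nMIR"),
                 direction_convention = if (measure == "TE")
                   "entry (i,j) = influence of feature j on feature i"
                 else NA_character_,
                 feature_labels = feature_labels),
            class = "relation_matrix")
}

#' Absolute correlation matrix (CR)
#'
#' Entry (i, j) is the absolute Pearson correlation between feature series
#' X_i and X_j: symmetric, diagonal 1, values in `[0, 1]`. A constant
#' column has undefined correlation; its off-diagonal entries are set to 0
#' with a warning.
#'
#' @param fm numeric matrix (columns = feature series), e.g. a
#'   `feature_matrix`.
#' @return a `relation_matrix` with measure `"CR"`.
#' @export
correlation_matrix <- function(fm) {
  values <- unclass(as.matrix(fm))
  if (nrow(values) < 3L) stop("need at least 3 rows to estimate correlations")
  r <- suppressWarnings(abs(cor(values)))
  if (anyNA(r)) {
    const <- which(apply(values, 2L, function(col) var(col) == 0))
    warning("constant feature series (off-diagonal CR set to 0): ",
            paste(colnames(values)[const], collapse = ", "))
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  relation_matrix(r, "CR", colnames(values))
}

#' Discretize a real-valued series into integer states
#'
#' Equal-frequency mode cuts at the unique empirical quantiles of the
#' values, so the state of an observation depends only on its value - the
#' binning is therefore invariant under any reordering of the series,
#' which carries the joint-row-permutation invariance of the mutual
#' information measures. Equal-width mode partitions `[min, max]`
#' uniformly. A series with fewer than 2 distinct values collapses to a
#' single state with a warning.
#'
#' @param series numeric vector.
#' @param params a [connectivity_params()] object (uses `bins`, `binning`).
#' @return integer vector of states in `1..B'` with `B' <= bins`.
#' @export
discretize <- function(series, params = connectivity_params()) {
  if (length(unique(series)) < 2L) {
    warning("series has fewer than 2 distinct values; single state returned")
    return(rep(1L, length(series)))
  }
  if (length(series) < params$bins)
    stop("series length must be at least the number of bins")
  breaks <- if (params$binning == "equal_frequency") {
    unique(quantile(series, probs = seq(0, 1, length.out = params$bins + 1L),
                    names = FALSE, type = 7))
  } else {
    seq(min(series), max(series), length.out = params$bins + 1L)
  }
  cut(series, breaks = breaks, labels = FALSE, include.lowest = TRUE)
}

# Plug-in Shannon entropy (nats) of an integer-state series.
shannon_entropy <- function(states) {
  p <- tabulate(states)
  p <- p[p > 0] / length(states)
  -sum(p * log(p))
}

# Plug-in mutual information (nats) between two integer-state series.
mutual_information <- function(si, sj) {
  n <- length(si)
  joint <- table(si, sj) / n
  pi_ <- rowSums(joint)
  pj <- colSums(joint)
  idx <- joint > 0
  sum(joint[idx] * log(joint[idx] / outer(pi_, pj)[idx]))
}

#' Normalized mutual information rate matrix (nMIR)
#'
#' Feature series are discretized (see [discretize()]) and plug-in
#' entropies / mutual informations computed in nats. With
#' `H_max = max_i H(X_i)`, off-diagonal entries are
#' `I(X_i; X_j) / H_max` and diagonal entries `H(X_i) / H_max`, so the
#' feature of maximal entropy has diagonal entry exactly 1 and all entries
#' lie in `[0, 1]`. The normalization cancels the logarithm base.
#'
#' @param fm numeric matrix (columns = feature series).
#' @param params a [connectivity_params()] object.
#' @return a `relation_matrix` with measure `"nMIR"`.
#' @export
nmir_matrix <- function(fm, params = connectivity_params()) {
  values <- unclass(as.matrix(fm))
  K <- ncol(values)
  states <- lapply(seq_len(K), function(j) discretize(values[, j], params))
  H <- vapply(states, shannon_entropy, numeric(1))
  Hmax <- max(H)
  if (Hmax == 0)
    stop("all feature series are constant; nMIR undefined (H_max = 0)")
  I <- diag(H / Hmax)
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      I[i, j] <- I[j, i] <- mutual_information(states[[i]], states[[j]]) / Hmax
    }
  }
  relation_matrix(I, "nMIR", colnames(values))
}

#' Transfer entropy between two feature series
#'
#' Estimates `TE(source -> target) = I(target_{n+1};
#' source^{(l)}_n | target^{(k)}_n)` - the information the source's past l
#' values carry about the target's next value beyond the target's own past
#' k values - with the Kraskov-Stoegbauer-Grassberger nearest-neighbour
#' conditional-MI estimator (max-norm, `knn` neighbours), in nats. The raw
#' estimate may be slightly negative; bias correction and clipping happen
#' in [te_matrix_bias_corrected()]. Exact ties in the series make
#' neighbour counts degenerate, so callers working on tied data should
#' jitter first (the matrix driver does).
#'
#' @param source,target numeric vectors of equal length.
#' @param params a [connectivity_params()] object (uses `l`, `k`, `knn`).
#' @return a real number (nats); can be negative before correction.
#' @export
transfer_entropy <- function(source, target, params = connectivity_params()) {
  l <- params$l; k <- params$k
  n <- length(target)
  if (length(source) != n) stop("source and target must have equal length")
  emb <- max(l, k)
  if (n <= emb + 1L) stop("series too short for embedding length ", emb)
  t_idx <- (emb + 1L):n   # indices of the predicted value
  m <- length(t_idx)
  y <- matrix(target[t_idx], ncol = 1L)
  z <- embed_series(target, t_idx, k)
  x <- embed_series(source, t_idx, l)
  ksg_cmi_cpp(y, x, z, params$knn)
}

# Lagged embedding: row r holds series[t-1], ..., series[t-depth] for the
# r-th predicted index t.
embed_series <- function(series, t_idx, depth) {
  out <- matrix(0, length(t_idx), depth)
  for (d in seq_len(depth)) out[, d] <- series[t_idx - d]
  out
}

# Surrogate of the target series: circular time shift by a random offset
# in [N/4, 3N/4], or a full random permutation.
surrogate_series <- function(series, style = c("shift", "shuffle")) {
  style <- match.arg(style)
  n <- length(series)
  if (style == "shift") {
    off <- sample(seq.int(floor(n / 4), ceiling(3 * n / 4)), 1L)
    series[((seq_len(n) - 1L + off) %% n) + 1L]
  } else {
    series[sample.int(n)]
  }
}

#' Bias-corrected transfer entropy matrix
#'
#' For every ordered pair (j -> i), computes the raw TE, then `q`
#' surrogate TEs in which the *target* X_i is randomized (time-shifted or
#' shuffled) while the source X_j is kept, and subtracts the surrogate
#' maximum: `TE_C = TE - max_q TE^(q)`. Negative corrected values are set
#' to 0 ("no significant information transfer"). Entries follow the
#' network convention `entry (i, j) = TE_C(j -> i)`; the diagonal is 0.
#'
#' A deterministic jitter of relative amplitude `jitter` is added to each
#' feature series before estimation so that exact ties (common in count
#' features) do not degenerate the nearest-neighbour counts; the jitter is
#' far below the data scale and does not move the estimates.
#'
#' @param fm numeric matrix (columns = feature series).
#' @param params a [connectivity_params()] object; `params$seed` drives
#'   jitter and surrogate randomness.
#' @param jitter relative jitter amplitude (default 1e-10; 0 disables).
#' @return a `relation_matrix` with measure `"TE"`.
#' @export
te_matrix_bias_corrected <- function(fm, params = connectivity_params(),
                                     jitter = 1e-10) {
  values <- unclass(as.matrix(fm))
  K <- ncol(values)
  te <- matrix(0, K, K)
  with_seed(params$seed, {
    if (jitter > 0) {
      scales <- apply(values, 2L, function(col) max(sd(col), 1e-12))
      values <- values + matrix(rnorm(length(values)), nrow(values)) *
        rep(scales * jitter, each = nrow(values))
    }
    for (i in seq_len(K)) {      # target
      for (j in seq_len(K)) {    # source
        if (i == j) next
        raw <- transfer_entropy(values[, j], values[, i], params)
        surr <- vapply(seq_len(params$q), function(s) {
          transfer_entropy(values[, j],
                           surrogate_series(values[, i], params$surrogate),
                           params)
        }, numeric(1))
        te[i, j] <- max(raw - max(surr), 0)
      }
    }
  })
  relation_matrix(te, "TE", colnames(values))
}

#' Write a relation matrix as square TSV
#'
#' Feature labels appear as both header and first column.
#'
#' @param rm a `relation_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relation_matrix <- function(rm, path) {
  df <- data.frame(feature = rm$feature_labels, rm$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relation matrix TSV written by [write_relation_matrix()]
#'
#' @param path TSV path.
#' @param measure `"CR"`, `"nMIR"` or `"TE"`.
#' @return a `relation_matrix`.
#' @export
read_relation_matrix <- function(path, measure = c("CR", "nMIR", "TE")) {
  measure <- match.arg(measure)
  df <- read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  relation_matrix(values, measure, as.character(df[[1]]))
}
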