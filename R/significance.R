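#' Normalized centralities over a permutation ensemble
#'
#' Applies P seeded joint row permutations to the feature matrix
#' (permutation 1 is the identity ordering), recomputes the requested
#' relation matrices, builds the networks and collects the max-normalized
#' centralities. CR and nMIR are invariant under joint row permutations up
#' to floating-point summation order, so by default they are computed once
#' and replicated across permutations; `strict = TRUE` recomputes them for
#' every permutation (the literal procedure). TE depends on the row order
#' through its embeddings and is always recomputed, with fresh surrogate
#' randomness per permutation.
#'
#' @param fm a `feature_matrix` (or plain numeric matrix).
#' @param P number of permutations (default 100).
#' @param seed master seed; per-permutation seeds are spawned from it so
#'   any single permutation is reproducible in isolation.
#' @param measures subset of `c("CR", "nMIR", "TE")`.
#' @param params a [connectivity_params()] object.
#' @param katz_attenuation,pagerank_damping see [directed_centralities()].
#' @param strict recompute CR/nMIR per permutation (default `FALSE`).
#' @return named list of `centrality_samples` objects (one per network
#'   measure x centrality, e.g. `"CR.degree"`, `"TE.katz"`), each a list
#'   with `samples` (P x K matrix of normalized centralities), `network`,
#'   `centrality`, `scheme`, `class_label`.
#' @export
permutation_ensemble <- function(fm, P = 100L, seed = 1L,
                                 measures = c("CR", "nMIR", "TE"),
                                 params = connectivity_params(),
                                 katz_attenuation = 0.9,
                                 pagerank_damping = 0.85,
                                 strict = FALSE) {
  P <- as.integer(P)
  if (P < 1L) stop("P must be >= 1")
  measures <- match.arg(measures, several.ok = TRUE)
  values <- unclass(as.matrix(fm))
  scheme <- attr(fm, "scheme")
  class_label <- attr(fm, "class_label")
  N <- nrow(values)
  seeds <- spawn_seeds(seed, P)
  samples <- list()

  add_sample <- function(network, cents, p) {
    for (nm in names(cents)) {
      key <- paste(network, nm, sep = ".")
      if (is.null(samples[[key]])) {
        samples[[key]] <<- matrix(NA_real_, P, ncol(values),
                                  dimnames = list(NULL, colnames(values)))
      }
      samples[[key]][p, ] <<- cents[[nm]]$normalized
    }
  }

  undirected_once <- NULL
  if (!strict && any(c("CR", "nMIR") %in% measures)) {
    undirected_once <- lapply(intersect(measures, c("CR", "nMIR")),
                              function(m) relation_for(values, m, params))
    names(undirected_once) <- intersect(measures, c("CR", "nMIR"))
  }

  for (p in seq_len(P)) {
    perm <- if (p == 1L) seq_len(N)
            else with_seed(seeds[p], sample.int(N))
    vp <- values[perm, , drop = FALSE]
    for (m in measures) {
      if (m %in% c("CR", "nMIR") && !strict) {
        rm_ <- undirected_once[[m]]
      } else {
        pm <- params
        pm$seed <- seeds[p]
        rm_ <- relation_for(vp, m, pm)
      }
      cents <- network_centralities(build_network(rm_), katz_attenuation,
                                    pagerank_damping)
      add_sample(m, cents, p)
    }
  }

  lapply_names <- names(samples)
  out <- lapply(lapply_names, function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    structure(list(samples = samples[[key]], network = parts[1],
                   centrality = parts[2], scheme = scheme,
                   class_label = class_label, P = P),
              class = "centrality_samples")
  })
  names(out) <- lapply_names
  out
}

relation_for <- function(values, measure, params) {
  switch(measure,
    CR = correlation_matrix(values),
    nMIR = nmir_matrix(values, params),
    TE = te_matrix_bias_corrected(values, params),
    stop("unknown measure: ", measure)
  )
}

#' Mean-standard-deviation robustness table
#'
#' The robustness recipe behind the published permutation tables: for each
#' network measure x centrality, the standard deviation of every feature's
#' normalized centrality is taken over the P permutations, averaged over
#' the K features of a class, then averaged over the structural classes.
#'
#' @param samples_by_class list of `permutation_ensemble()` results, one
#'   per structural class (same scheme, same measure set).
#' @return data frame with columns `network`, `centrality`,
#'   `mean_sd` (all entries >= 0).
#' @export
robustness_table <- function(samples_by_class) {
  if (inherits(samples_by_class[[1]], "centrality_samples"))
    samples_by_class <- list(samples_by_class)
  keys <- names(samples_by_class[[1]])
  # a single permutation has no spread: SD defined as 0
  col_sd <- function(v) if (length(v) < 2L) 0 else sd(v)
  rows <- lapply(keys, function(key) {
    per_class <- vapply(samples_by_class, function(cls) {
      mean(apply(cls[[key]]$samples, 2L, col_sd))
    }, numeric(1))
    s <- samples_by_class[[1]][[key]]
    data.frame(network = s$network, centrality = s$centrality,
               mean_sd = mean(per_class), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Levene test of centrality variance homogeneity
#'
#' Standard (upper-tail) Levene statistic on the absolute deviations
#' `Z_is = |Y_is - mean(Y_i)|` across the K features:
#' `F = (N - K) sum_i n_i (Zbar_i - Zbar)^2 /
#'      ((K - 1) sum_is (Z_is - Zbar_i)^2)`,
#' with df (K - 1, N - K); homogeneity is rejected when
#' `F > F_(1 - theta)`. Its role in the pipeline is diagnostic: the
#' published analysis found the centrality variances heterogeneous at all
#' tested levels, which motivates Welch (unequal-variance) t-tests for the
#' pairwise ordering.
#'
#' @param samples a `centrality_samples` object or a P x K matrix.
#' @param theta significance level (default 0.05).
#' @return list with `F`, `df`, `p_value`, `homogeneous`.
#' @export
levene_test <- function(samples, theta = 0.05) {
  y <- if (inherits(samples, "centrality_samples")) samples$samples
       else as.matrix(samples)
  K <- ncol(y)
  n_i <- nrow(y)
  if (K < 2L) stop("need at least 2 feature groups")
  if (n_i < 2L) stop("every group needs at least 2 samples")
  z <- abs(sweep(y, 2L, colMeans(y)))
  zbar_i <- colMeans(z)
  zbar <- mean(z)
  N <- K * n_i
  num <- (N - K) * sum(n_i * (zbar_i - zbar)^2)
  den <- (K - 1) * sum(sweep(z, 2L, zbar_i)^2)
  F_ <- if (den == 0) { if (num == 0) 0 else Inf } else num / den
  p <- pf(F_, K - 1, N - K, lower.tail = FALSE)
  list(F = F_, df = c(K - 1L, N - K), p_value = p,
       homogeneous = F_ <= qf(1 - theta, K - 1, N - K))
}

#' Pairwise one-sided Welch t-tests ordering features by centrality
#'
#' For every ordered feature pair (i, j) computes the Welch statistic
#' `T = (Ybar_i - Ybar_j) / sqrt(S_i^2/n_i + S_j^2/n_j)` with
#' Welch-Satterthwaite degrees of freedom, and decides `i` *higher* than
#' `j` when `T >= t_theta(v)`, *lower* when `T <= -t_theta(v)`, otherwise
#' *none*. A feature's score counts how many other features have
#' significantly lower centrality; features are returned in descending
#' score order, ties sharing a score. No multiple-testing correction is
#' applied across the K(K-1)/2 pairs - the analysis sweeps raw theta
#' levels instead (see [significance_sweep()]).
#'
#' @param samples a `centrality_samples` object or P x K matrix.
#' @param theta one-sided significance level.
#' @return a `significance_order`: list with `theta`, `decisions` (K x K
#'   character matrix in higher/lower/none), `scores` (named integer
#'   vector), `order` (feature labels by descending score), `T`, `df`.
#' @export
welch_pairwise <- function(samples, theta = 0.05) {
  y <- if (inherits(samples, "centrality_samples")) samples$samples
       else as.matrix(samples)
  K <- ncol(y)
  n <- nrow(y)
  if (n < 2L) stop("need at least 2 samples per feature")
  labels <- colnames(y)
  if (is.null(labels)) labels <- paste0("F", seq_len(K))
  means <- colMeans(y)
  vars <- apply(y, 2L, var)
  Tm <- matrix(0, K, K, dimnames = list(labels, labels))
  Vm <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  decisions <- matrix("none", K, K, dimnames = list(labels, labels))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i == j) next
      se2 <- vars[i] / n + vars[j] / n
      if (se2 == 0) {
        # both variances zero: degenerate; decide by mean difference alone
        if (means[i] > means[j]) decisions[i, j] <- "higher"
        else if (means[i] < means[j]) decisions[i, j] <- "lower"
        Tm[i, j] <- sign(means[i] - means[j]) * Inf
        next
      }
      T_ <- (means[i] - means[j]) / sqrt(se2)
      v <- se2^2 / ((vars[i] / n)^2 / (n - 1) + (vars[j] / n)^2 / (n - 1))
      tcrit <- qt(1 - theta, v)
      Tm[i, j] <- T_
      Vm[i, j] <- v
      if (T_ >= tcrit) decisions[i, j] <- "higher"
      else if (T_ <= -tcrit) decisions[i, j] <- "lower"
    }
  }
  scores <- apply(decisions == "higher", 1L, sum)
  structure(list(theta = theta, decisions = decisions,
                 scores = scores,
                 order = labels[order(scores, decreasing = TRUE)],
                 T = Tm, df = Vm),
            class = "significance_order")
}

#' Welch significance sweep over several theta levels
#'
#' Runs [welch_pairwise()] at each level and reports how the number of
#' resolved (higher/lower) pairs shrinks as theta decreases: smaller theta
#' narrows the rejection regions, so fewer significant differences are
#' detected.
#'
#' @param samples a `centrality_samples` object or P x K matrix.
#' @param thetas decreasing vector of levels in (0, 0.5); default the
#'   standard sweep `{0.25, 0.1, 0.05, 0.025, 0.01, 0.005}`.
#' @return named list of `significance_order` objects, one per theta, with
#'   attribute `monotonicity` (data frame theta x resolved-pair count).
#' @export
significance_sweep <- function(samples,
                               thetas = c(0.25, 0.1, 0.05, 0.025, 0.01,
                                          0.005)) {
  if (any(thetas <= 0 | thetas >= 0.5)) stop("thetas must lie in (0, 0.5)")
  thetas <- sort(thetas, decreasing = TRUE)
  orders <- lapply(thetas, function(th) welch_pairwise(samples, th))
  names(orders) <- as.character(thetas)
  resolved <- vapply(orders, function(o) sum(o$decisions == "higher"),
                     integer(1))
  attr(orders, "monotonicity") <- data.frame(theta = thetas,
                                             resolved_pairs = resolved)
  orders
}

#' Flatten a significance order into a table
#'
#' @param ord a `significance_order`.
#' @return data frame with `feature`, `score`, `rank` (1 = highest score;
#'   tied scores share a rank).
#' @export
significance_table <- function(ord) {
  scores <- sort(ord$scores, decreasing = TRUE)
  data.frame(feature = names(scores), score = as.integer(scores),
             rank = match(-scores, sort(unique(-scores))),
             row.names = NULL, stringsAsFactors = FALSE)
}
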