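#' Build a weighted network from a relation matrix
#'
#' CR and nMIR matrices give undirected networks; the diagonal is zeroed
#' (edges exist only between distinct features, i != j). TE matrices give
#' directed networks with `a(i, j) = TE_C(j -> i)`, i.e. columns act as
#' sources. Zero entries mean no edge.
#'
#' @param rm a `relation_matrix`.
#' @return a `weighted_network`: list with `adjacency` (zero-diagonal,
#'   non-negative), `directed`, `feature_labels`.
#' @export
build_network <- function(rm) {
  if (!inherits(rm, "relation_matrix")) stop("rm must be a relation_matrix")
  a <- rm$values
  if (any(a < 0)) stop("relation matrix has negative entries")
  diag(a) <- 0
  structure(list(adjacency = a, directed = rm$measure == "TE",
                 feature_labels = rm$feature_labels),
            class = "weighted_network")
}

#' Max-normalize a centrality vector
#'
#' Divides by the maximum so the most central node scores 1; an all-zero
#' vector stays all-zero.
#'
#' @param raw non-negative numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_centrality <- function(raw) {
  if (any(raw < 0)) stop("raw centralities must be non-negative")
  m <- max(raw)
  if (m == 0) raw else raw / m
}

centrality_vector <- function(measure, raw, labels) {
  names(raw) <- labels
  list(measure = measure, raw = raw, normalized = normalize_centrality(raw))
}

#' Degree and eigenvector centralities of an undirected network
#'
#' Degree is the sum of incident edge weights. Eigenvector centrality is
#' the leading right eigenvector of the adjacency matrix (power iteration,
#' tolerance 1e-12, oriented non-negative), satisfying `A y = k1 y`. Both
#' are max-normalized.
#'
#' @param net an undirected `weighted_network`.
#' @return list with elements `degree` and `eigenvector`, each holding
#'   `raw` and `normalized` vectors.
#' @export
undirected_centralities <- function(net) {
  if (net$directed) stop("network must be undirected")
  a <- net$adjacency
  if (max(a) == 0) {
    warning("all-zero adjacency; centralities are all zero")
    zero <- numeric(ncol(a))
    return(list(degree = centrality_vector("degree", zero, net$feature_labels),
                eigenvector = centrality_vector("eigenvector", zero,
                                                net$feature_labels)))
  }
  degree <- colSums(a)
  ev <- power_iteration(a)
  list(degree = centrality_vector("degree", degree, net$feature_labels),
       eigenvector = centrality_vector("eigenvector", ev$vector,
                                       net$feature_labels))
}

# Leading eigenvector by power iteration with non-negative orientation.
power_iteration <- function(a, tol = 1e-12, max_iter = 10000L) {
  y <- rep(1 / sqrt(ncol(a)), ncol(a))
  lambda <- 0
  for (it in seq_len(max_iter)) {
    z <- a %*% y
    nz <- sqrt(sum(z^2))
    if (nz == 0) return(list(vector = numeric(ncol(a)), value = 0))
    z <- as.numeric(z) / nz
    if (sum(abs(z - y)) < tol) { y <- z; lambda <- nz; break }
    y <- z
    lambda <- nz
  }
  if (sum(y) < 0) y <- -y
  y[abs(y) < .Machine$double.eps] <- 0
  list(vector = pmax(y, 0), value = lambda)
}

#' In/out degree, Katz and PageRank centralities of a directed network
#'
#' With the convention `a(i, j)` = weight of the link from node j to node
#' i: in-degree of node j is the j-th row sum, out-degree the j-th column
#' sum. Katz centrality is `y = (I - alpha A)^(-1) 1` with
#' `alpha = katz_attenuation / k1` (k1 the leading eigenvalue magnitude;
#' alpha = 0 when k1 = 0), so I - alpha*A is guaranteed invertible for
#' attenuation < 1. PageRank is `y = D (D - alpha A)^(-1) 1` with
#' `d_ii = max(1, out-degree_i)` and `alpha = pagerank_damping`. All four
#' are max-normalized; an empty network yields all-ones Katz and PageRank.
#'
#' @param net a directed `weighted_network`.
#' @param katz_attenuation attenuation factor in (0, 1), default 0.9.
#' @param pagerank_damping damping factor in (0, 1), default 0.85.
#' @return list with `in_degree`, `out_degree`, `katz`, `pagerank`.
#' @export
directed_centralities <- function(net, katz_attenuation = 0.9,
                                  pagerank_damping = 0.85) {
  if (!net$directed) stop("network must be directed")
  if (katz_attenuation <= 0 || katz_attenuation >= 1)
    stop("katz_attenuation must be in (0, 1)")
  if (pagerank_damping <= 0 || pagerank_damping >= 1)
    stop("pagerank_damping must be in (0, 1)")
  a <- net$adjacency
  K <- ncol(a)
  in_deg <- rowSums(a)
  out_deg <- colSums(a)
  k1 <- max(Mod(eigen(a, only.values = TRUE)$values))
  alpha <- if (k1 == 0) 0 else katz_attenuation / k1
  katz <- solve_attenuated(diag(K) - alpha * a, rep(1, K), alpha, a)
  D <- diag(pmax(1, out_deg), K)
  pr <- as.numeric(D %*% solve(D - pagerank_damping * a, rep(1, K)))
  list(in_degree = centrality_vector("in_degree", in_deg, net$feature_labels),
       out_degree = centrality_vector("out_degree", out_deg,
                                      net$feature_labels),
       katz = centrality_vector("katz", katz, net$feature_labels),
       pagerank = centrality_vector("pagerank", pr, net$feature_labels))
}

# Solve (I - alpha A) y = 1; if numerically singular, retry once with
# alpha halved, then fail.
solve_attenuated <- function(m, b, alpha, a) {
  out <- tryCatch(solve(m, b), error = function(e) NULL)
  if (is.null(out)) {
    alpha <- alpha / 2
    out <- solve(diag(nrow(m)) - alpha * a, b)  # errors if still singular
  }
  as.numeric(out)
}

#' Compute all centralities appropriate for a network
#'
#' Degree + eigenvector for undirected networks; in/out degree, Katz and
#' PageRank for directed ones.
#'
#' @param net a `weighted_network`.
#' @param katz_attenuation,pagerank_damping see [directed_centralities()].
#' @return named list of centrality vectors.
#' @export
network_centralities <- function(net, katz_attenuation = 0.9,
                                 pagerank_damping = 0.85) {
  if (net$directed)
    directed_centralities(net, katz_attenuation, pagerank_damping)
  else undirected_centralities(net)
}
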