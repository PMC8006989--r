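#' Simulate class-structured protein sequences
#'
#' Emulates the per-class inputs of the feature analysis: for each
#' structural class, sequences are drawn residue by residue from a
#' class-specific amino-acid composition (a point on the 20-simplex),
#' optionally with first-order Markov arrangement bias: with probability
#' `markov_coupling` the next residue repeats the previous one, otherwise
#' it is drawn from the composition. Lengths are drawn uniformly in
#' `[length_min, length_max]` (all >= 20 so every record passes the
#' feature-extraction length filter). Deterministic given `seed`.
#'
#' @param classes list of class specs, each a list with `label`,
#'   `n_proteins`, and optionally `composition` (named or ordered
#'   20-vector summing to 1; default uniform), `markov_coupling` in
#'   `[0, 1)` (default 0), `length_min` (default 50), `length_max`
#'   (default 200).
#' @param seed integer seed.
#' @return list with `records` (named list of protein records),
#'   `manifest` (a `class_manifest`) and `ground_truth` (per-class
#'   composition and coupling actually used).
#' @export
simulate_sequences <- function(classes, seed = 1L) {
  records <- list()
  ids <- character(0)
  labels <- character(0)
  truth <- list()
  with_seed(seed, {
    for (cl in classes) {
      comp <- cl$composition
      if (is.null(comp)) comp <- rep(1 / 20, 20)
      if (abs(sum(comp) - 1) > 1e-8 || any(comp < 0))
        stop("composition of class ", cl$label,
             " must be a point on the 20-simplex")
      comp <- as.numeric(comp)
      mc <- if (is.null(cl$markov_coupling)) 0 else cl$markov_coupling
      if (mc < 0 || mc >= 1) stop("markov_coupling must be in [0, 1)")
      lmin <- if (is.null(cl$length_min)) 50L else as.integer(cl$length_min)
      lmax <- if (is.null(cl$length_max)) 200L else as.integer(cl$length_max)
      if (lmin < 20L) stop("length_min must be >= 20")
      for (p in seq_len(cl$n_proteins)) {
        len <- if (lmax > lmin) sample(lmin:lmax, 1L) else lmin
        chars <- character(len)
        chars[1] <- sample(AA_ALPHABET, 1L, prob = comp)
        for (t in 2:len) {
          chars[t] <- if (mc > 0 && runif(1) < mc) chars[t - 1L]
                      else sample(AA_ALPHABET, 1L, prob = comp)
        }
        id <- sprintf("%s_%04d", cl$label, p)
        records[[id]] <- list(id = id, sequence = paste(chars, collapse = ""))
        ids <- c(ids, id)
        labels <- c(labels, cl$label)
      }
      truth[[cl$label]] <- list(composition = comp, markov_coupling = mc)
    }
  })
  list(records = records, manifest = class_manifest(ids, labels),
       ground_truth = truth)
}

#' Dirichlet-perturbed class composition profiles
#'
#' Helper producing distinct per-class amino-acid compositions by
#' perturbing the uniform profile: each class composition is a draw from
#' Dirichlet(concentration * 20-vector of 1/20). Smaller concentration
#' gives more distinct classes.
#'
#' @param n_classes number of profiles.
#' @param concentration Dirichlet concentration (default 50).
#' @param seed integer seed.
#' @return list of composition vectors (each sums to 1).
#' @export
class_compositions <- function(n_classes, concentration = 50, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_classes), function(i) {
      g <- rgamma(20, shape = concentration / 20)
      g / sum(g)
    })
  })
}

#' Simulate feature series with planted dependence structure
#'
#' Generates an n x K matrix of feature series realizing one of four
#' ground-truth structures used to validate the connectivity measures:
#'
#' * `independent`: i.i.d. standard normal columns;
#' * `correlated`: multivariate normal with the given correlation matrix
#'   `rho` (must be positive semi-definite);
#' * `nonlinear`: column 1 standard normal, column 2 its standardized
#'   square (strong symmetric dependence with near-zero linear
#'   correlation), remaining columns independent noise;
#' * `var_coupled`: first-order vector autoregression
#'   `X_t = C X_(t-1) + noise_sd * eps_t` with coupling matrix `C` built
#'   from `edges` (list of `list(from=, to=, coef=)`); the spectral radius
#'   of `C` must be < 1 for stationarity.
#'
#' @param n number of rows (samples).
#' @param K number of columns (feature series).
#' @param structure one of `"independent"`, `"correlated"`, `"nonlinear"`,
#'   `"var_coupled"`.
#' @param rho K x K correlation matrix (for `"correlated"`).
#' @param edges coupling edges (for `"var_coupled"`).
#' @param noise_sd innovation SD for the VAR (default 0.2).
#' @param seed integer seed.
#' @return numeric matrix with attribute `ground_truth` describing the
#'   planted structure.
#' @export
simulate_feature_series <- function(n, K = 2L,
                                    structure = c("independent",
                                                  "correlated", "nonlinear",
                                                  "var_coupled"),
                                    rho = NULL, edges = NULL,
                                    noise_sd = 0.2, seed = 1L) {
  structure_ <- match.arg(structure)
  K <- as.integer(K)
  x <- with_seed(seed, {
    switch(structure_,
      independent = matrix(rnorm(n * K), n, K),
      correlated = {
        if (is.null(rho)) stop("structure 'correlated' needs a rho matrix")
        rho <- as.matrix(rho)
        ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-10)
          stop("rho is not positive semi-definite")
        MASS::mvrnorm(n, mu = rep(0, ncol(rho)), Sigma = rho)
      },
      nonlinear = {
        m <- matrix(rnorm(n * K), n, K)
        z <- m[, 1]
        sq <- z^2
        m[, 2] <- (sq - mean(sq)) / sd(sq)
        m
      },
      var_coupled = {
        if (is.null(edges)) stop("structure 'var_coupled' needs edges")
        C <- matrix(0, K, K)
        for (e in edges) C[e$to, e$from] <- e$coef
        if (max(Mod(eigen(C, only.values = TRUE)$values)) >= 1)
          stop("unstable VAR: spectral radius of the coupling matrix >= 1")
        m <- matrix(0, n, K)
        m[1, ] <- rnorm(K, sd = noise_sd)
        for (t in 2:n)
          m[t, ] <- as.numeric(C %*% m[t - 1L, ]) + rnorm(K, sd = noise_sd)
        m
      }
    )
  })
  colnames(x) <- paste0("X", seq_len(ncol(x)))
  attr(x, "ground_truth") <- list(structure = structure_, rho = rho,
                                  edges = edges, noise_sd = noise_sd,
                                  seed = seed)
  x
}
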