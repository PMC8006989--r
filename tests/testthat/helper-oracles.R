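# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# Loop-based natural-vector oracle: literal evaluation of the count /
# mean-position / normalized-second-moment definitions.
oracle_natural_vector <- function(sequence, offset = 1) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  out <- numeric(0)
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  counts <- mus <- d2s <- numeric(20)
  for (k in seq_along(alphabet)) {
    s <- c()
    for (i in seq_len(n)) {
      if (chars[i] == alphabet[k]) s <- c(s, i - 1 + offset)
    }
    counts[k] <- length(s)
    if (length(s) > 0) {
      total <- 0
      for (v in s) total <- total + v
      mus[k] <- total / length(s)
      acc <- 0
      for (v in s) acc <- acc + (v - mus[k])^2
      d2s[k] <- acc / (length(s) * n)
    }
  }
  c(counts, mus, d2s)
}

# Brute-force APF oracle: accumulate per-residue property rows, divide.
oracle_apf <- function(sequence, table) {
  chars <- strsplit(sequence, "")[[1]]
  acc <- rep(0, ncol(table))
  for (ch in chars) acc <- acc + table[ch, ]
  acc / length(chars)
}

# Brute-force theta_j oracle: enumerate all residue pairs j apart and
# average the correlation function (mean squared standardized-property
# difference).
oracle_theta <- function(sequence, j, triplet) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  vals <- numeric(0)
  for (i in 1:(n - j)) {
    a <- triplet[chars[i], ]
    b <- triplet[chars[i + j], ]
    vals <- c(vals, mean((a - b)^2))
  }
  mean(vals)
}

# Plug-in (histogram) transfer entropy oracle on integer-state series,
# in nats, embedding length 1: TE = I(y_{t+1}; x_t | y_t) evaluated by
# exhaustive enumeration of the empirical joint distribution.
oracle_discrete_te <- function(x, y) {
  n <- length(y)
  yf <- y[2:n]; xp <- x[1:(n - 1)]; yp <- y[1:(n - 1)]
  states <- data.frame(yf, xp, yp)
  te <- 0
  p3 <- table(yf, xp, yp) / (n - 1)
  pyp <- table(yp) / (n - 1)
  p_yf_yp <- table(yf, yp) / (n - 1)
  p_xp_yp <- table(xp, yp) / (n - 1)
  for (a in dimnames(p3)$yf) for (b in dimnames(p3)$xp)
    for (c in dimnames(p3)$yp) {
      pj <- p3[a, b, c]
      if (pj > 0) {
        te <- te + pj * log(pj * pyp[c] / (p_yf_yp[a, c] * p_xp_yp[b, c]))
      }
    }
  as.numeric(te)
}

# Dense linear-algebra oracles for Katz and the out-strength-scaled
# PageRank variant.
oracle_katz <- function(A, attenuation) {
  k1 <- max(Mod(eigen(A, only.values = TRUE)$values))
  alpha <- if (k1 == 0) 0 else attenuation / k1
  as.numeric(solve(diag(nrow(A)) - alpha * A, rep(1, nrow(A))))
}
oracle_pagerank <- function(A, damping) {
  D <- diag(pmax(1, colSums(A)), nrow(A))
  as.numeric(D %*% solve(D - damping * A, rep(1, nrow(A))))
}

# Random small weighted digraph adjacency (zero diagonal).
random_digraph <- function(K, density = 0.5) {
  A <- matrix(runif(K * K) * (runif(K * K) < density), K, K)
  diag(A) <- 0
  A
}

# Tiny FASTA writer independent of the package.
write_test_fasta <- function(entries, path) {
  lines <- unlist(mapply(function(id, s) c(paste0(">", id), s),
                         names(entries), entries, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}
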