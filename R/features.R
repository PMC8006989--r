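#' Natural vector of a protein sequence
#'
#' The 60-component natural vector encodes, for each of the 20 amino acids
#' k: its count `n_k`, the mean position `mu_k = T_k / n_k` (T_k the total
#' distance of the k-residues from the origin), and the normalized second
#' central moment `D2_k = sum_i (s_ki - mu_k)^2 / (n_k * n)` with n the
#' sequence length. Positions are measured as `index - 1 + offset`: with
#' `offset = 1` (default) the first residue sits at distance 1 from the
#' origin, with `offset = 0` at distance 0; both readings of "the first
#' amino acid regarded as origin" are supported. Amino acids absent from
#' the sequence contribute the triple (0, 0, 0), keeping the vector finite
#' and 60-dimensional.
#'
#' @param sequence character scalar over the 20-letter alphabet, or a
#'   record list with a `sequence` field.
#' @param offset 0 or 1; distance of the first residue from the origin.
#' @return named numeric vector of length 60 (`n_A..n_V`, `mu_A..mu_V`,
#'   `D2_A..D2_V`).
#' @export
natural_vector <- function(sequence, offset = 1L) {
  sequence <- as_sequence(sequence)
  if (!offset %in% c(0L, 1L)) stop("offset must be 0 or 1")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- seq_len(n) - 1L + offset
  nv <- numeric(60)
  names(nv) <- c(paste0("n_", AA_ALPHABET), paste0("mu_", AA_ALPHABET),
                 paste0("D2_", AA_ALPHABET))
  for (k in seq_along(AA_ALPHABET)) {
    s <- pos[chars == AA_ALPHABET[k]]
    nk <- length(s)
    nv[k] <- nk
    if (nk > 0L) {
      mu <- sum(s) / nk
      nv[20L + k] <- mu
      nv[40L + k] <- sum((s - mu)^2) / (nk * n)
    }
  }
  nv
}

#' Averaged property factors of a protein sequence
#'
#' Component m is the sequence average of the m-th physical property
#' factor over all residues: `(1/N) * sum_n f_n^(m)`.
#'
#' @param sequence character scalar or record list.
#' @param table 20 x 10 property-factor matrix from
#'   [load_property_table()] (`"factors"`); any 20 x M numeric table with
#'   amino-acid rownames works.
#' @return named numeric vector of length `ncol(table)`.
#' @export
apf_vector <- function(sequence, table = load_property_table("factors")) {
  sequence <- as_sequence(sequence)
  validate_property_table(table)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  colMeans(table[chars, , drop = FALSE])
}

#' Pseudo amino acid composition (type 1)
#'
#' The (20 + lambda)-component PseAAC vector combines the amino-acid
#' occurrence frequencies `f_u` with lambda sequence-order correlation
#' tiers `theta_j`, jointly normalized:
#' `x_u = f_u / (sum f + w sum theta)` for `u <= 20` and
#' `x_(20+j) = w theta_j / (sum f + w sum theta)`.
#' `theta_j` averages the correlation function `Theta(R_i, R_(i+j))` over
#' all residue pairs j apart, where `Theta(a, b)` is the mean of squared
#' differences of three standardized properties (hydrophobicity,
#' hydrophilicity, side-chain mass). With `lambda = 0` the output is the
#' plain frequency vector. The output is non-negative and sums to 1.
#'
#' @param sequence character scalar or record list.
#' @param lambda non-negative integer, strictly less than the sequence
#'   length.
#' @param w positive sequence-order weight (default 0.05).
#' @param triplet standardized 20 x 3 property matrix from
#'   [load_property_table()] (`"pseaac"`).
#' @return named numeric vector of length `20 + lambda`.
#' @export
pseaac_vector <- function(sequence, lambda = 0L, w = 0.05,
                          triplet = load_property_table("pseaac")) {
  sequence <- as_sequence(sequence)
  lambda <- as.integer(lambda)
  if (lambda < 0L) stop("lambda must be non-negative")
  if (w <= 0) stop("w must be positive")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (lambda >= n) stop("lambda (", lambda, ") must be smaller than the ",
                        "sequence length (", n, ")")
  f <- table(factor(chars, levels = AA_ALPHABET)) / n
  f <- as.numeric(f)
  theta <- numeric(lambda)
  if (lambda > 0L) {
    props <- triplet[chars, , drop = FALSE]
    for (j in seq_len(lambda)) {
      d <- props[(1L + j):n, , drop = FALSE] - props[1L:(n - j), , drop = FALSE]
      theta[j] <- mean(rowMeans(d^2))
    }
  }
  denom <- sum(f) + w * sum(theta)
  x <- c(f, w * theta) / denom
  names(x) <- c(AA_ALPHABET,
                if (lambda > 0L) paste0("tier_", seq_len(lambda)))
  x
}

as_sequence <- function(sequence) {
  if (is.list(sequence)) sequence <- sequence$sequence
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  sequence
}

FEATURE_SCHEMES <- c("N", "mu", "D", "APF", "PseAAC0", "PseAAC10")

# Feature vector of one record under one scheme.
scheme_vector <- function(record, scheme, offset = 1L, w = 0.05,
                          factors = NULL, triplet = NULL) {
  switch(scheme,
    N = natural_vector(record, offset)[1:20],
    mu = natural_vector(record, offset)[21:40],
    D = natural_vector(record, offset)[41:60],
    APF = apf_vector(record, factors),
    PseAAC0 = pseaac_vector(record, 0L, w, triplet),
    PseAAC10 = pseaac_vector(record, 10L, w, triplet),
    stop("unknown scheme: ", scheme)
  )
}

# For NV sub-schemes strip the block prefix so labels are plain amino acids.
scheme_labels <- function(scheme, example) {
  labs <- names(example)
  if (scheme %in% c("N", "mu", "D")) labs <- sub("^[^_]*_", "", labs)
  labs
}

#' Construct a feature matrix
#'
#' @param values numeric matrix, rows = proteins, columns = feature series.
#' @param scheme one of `r paste(FEATURE_SCHEMES, collapse = ", ")`.
#' @param class_label structural class of the rows.
#' @param protein_ids,feature_labels row/column names.
#' @return a `feature_matrix`: the numeric matrix with `scheme` and
#'   `class_label` attributes.
#' @export
feature_matrix <- function(values, scheme, class_label,
                           protein_ids = rownames(values),
                           feature_labels = colnames(values)) {
  values <- as.matrix(values)
  expected_k <- c(N = 20L, mu = 20L, D = 20L, APF = 10L,
                  PseAAC0 = 20L, PseAAC10 = 30L)
  if (scheme %in% names(expected_k) && ncol(values) != expected_k[[scheme]])
    stop("scheme ", scheme, " must have K = ", expected_k[[scheme]],
         " columns, got ", ncol(values))
  rownames(values) <- protein_ids
  colnames(values) <- feature_labels
  structure(values, scheme = scheme, class_label = class_label,
            class = c("feature_matrix", class(values)))
}

#' Build per-class feature matrices for a set of schemes
#'
#' For every structural class in the manifest and every requested scheme,
#' assembles the N_s x K feature matrix whose rows are the per-protein
#' feature vectors (in manifest order) and whose columns are the feature
#' series X_1..X_K analyzed by the connectivity measures. The six schemes
#' are analyzed separately; K = 20 for N, mu, D and PseAAC0, K = 10 for
#' APF, K = 30 for PseAAC10.
#'
#' @param records named list of protein records ([read_fasta()]).
#' @param manifest a `class_manifest`; every record id must appear in it
#'   and every manifest id must have a record.
#' @param schemes subset of `r paste(FEATURE_SCHEMES, collapse = ", ")`.
#' @param offset natural-vector position offset (0 or 1).
#' @param w PseAAC sequence-order weight.
#' @return named list of `feature_matrix` objects, names `<class>.<scheme>`.
#' @export
build_feature_matrices <- function(records, manifest,
                                   schemes = FEATURE_SCHEMES,
                                   offset = 1L, w = 0.05) {
  schemes <- match.arg(schemes, FEATURE_SCHEMES, several.ok = TRUE)
  missing_ids <- setdiff(manifest$ids, names(records))
  if (length(missing_ids) > 0L)
    stop("manifest ids without records: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  extra <- setdiff(names(records), manifest$ids)
  if (length(extra) > 0L)
    stop("records missing from manifest: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  factors <- load_property_table("factors")
  triplet <- load_property_table("pseaac")
  out <- list()
  for (cl in manifest$class_levels) {
    ids <- manifest$ids[manifest$classes == cl]
    for (sc in schemes) {
      rows <- lapply(records[ids], scheme_vector, scheme = sc,
                     offset = offset, w = w, factors = factors,
                     triplet = triplet)
      values <- do.call(rbind, rows)
      fm <- feature_matrix(values, sc, cl, protein_ids = ids,
                           feature_labels = scheme_labels(sc, rows[[1]]))
      out[[paste(cl, sc, sep = ".")]] <- fm
    }
  }
  out
}

#' Write a feature matrix as TSV
#'
#' First column `protein_id`, then one column per feature label.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(protein_id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
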