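#' Read protein sequences from a FASTA file
#'
#' Reads amino-acid sequences and applies the canonical-alphabet and
#' minimum-length filters used throughout the feature analysis: sequences
#' are upper-cased, and any record containing a letter outside the 20
#' canonical amino acids (B, J, O, U, X, Z, gaps, ...) or shorter than
#' `min_length` residues is dropped. The feature formulas are defined only
#' on the 20 canonical types, so non-canonical records are removed whole,
#' never translated.
#'
#' @param path path to a FASTA file.
#' @param min_length minimum sequence length kept (default 20).
#' @return a list with elements
#'   * `records`: named list of protein records, each a list with `id` and
#'     `sequence`;
#'   * `filter_report`: data frame with one row per dropped record
#'     (`id`, `reason` in `"non_canonical"`/`"too_short"`) plus counts in
#'     attributes `n_total`, `n_kept`.
#' @export
read_fasta <- function(path, min_length = 20L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  filter_records(ids, seqs, min_length)
}

# Shared filtering used by read_fasta and the synthetic generator.
filter_records <- function(ids, seqs, min_length = 20L) {
  canonical <- vapply(
    strsplit(seqs, "", fixed = TRUE),
    function(ch) all(ch %in% AA_ALPHABET),
    logical(1)
  )
  long_enough <- nchar(seqs) >= min_length
  reason <- rep(NA_character_, length(ids))
  reason[!canonical] <- "non_canonical"
  reason[canonical & !long_enough] <- "too_short"
  keep <- canonical & long_enough
  records <- mapply(function(i, s) list(id = i, sequence = s),
                    ids[keep], seqs[keep], SIMPLIFY = FALSE)
  names(records) <- ids[keep]
  report <- data.frame(id = ids[!keep], reason = reason[!keep],
                       stringsAsFactors = FALSE)
  attr(report, "n_total") <- length(ids)
  attr(report, "n_kept") <- sum(keep)
  if (sum(keep) == 0L)
    stop("no records survive filtering (", length(ids), " read, all dropped)")
  list(records = records, filter_report = report)
}

#' Write protein records to a FASTA file
#'
#' @param records named list of records as returned by [read_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$sequence)),
                  use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a class manifest (id -> structural class)
#'
#' The manifest is a two-column tab-delimited file `id<TAB>class` mapping
#' each protein identifier to a structural class label (free-form strings,
#' e.g. `mainly_alpha` / `mainly_beta` / `mixed`). Every id must be unique
#' and every class must contain at least two members, since feature series
#' of length 1 support no relationship analysis.
#'
#' @param path path to the TSV manifest (no header).
#' @return an object of class `class_manifest`: a list with `ids`, `classes`
#'   (character vectors aligned by position) and `class_levels` (unique
#'   labels in order of first appearance).
#' @export
read_class_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("manifest must have two columns: id<TAB>class")
  class_manifest(df[[1]], df[[2]])
}

#' Construct and validate a class manifest
#'
#' @param ids character vector of protein ids.
#' @param classes character vector of class labels, same length.
#' @return a `class_manifest` object.
#' @export
class_manifest <- function(ids, classes) {
  if (length(ids) != length(classes))
    stop("ids and classes must have the same length")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate ids in manifest: ", paste(unique(dup), collapse = ", "))
  counts <- table(classes)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L)
    stop("classes with fewer than 2 members: ", paste(small, collapse = ", "))
  structure(
    list(ids = as.character(ids), classes = as.character(classes),
         class_levels = unique(as.character(classes))),
    class = "class_manifest"
  )
}

#' Write a class manifest as TSV
#'
#' @param manifest a `class_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_class_manifest <- function(manifest, path) {
  write.table(data.frame(manifest$ids, manifest$classes),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load an amino-acid property table
#'
#' Two tables ship with the package (see
#' `system.file("extdata", "PROVENANCE.md", package = "pfnet")`):
#' * `"factors"` - the ten physical property factors per amino acid
#'   (20 x 10), used by the averaged-property-factor features;
#' * `"pseaac"` - hydrophobicity, hydrophilicity and side-chain mass
#'   (20 x 3), the correlation triplet of type-1 pseudo amino acid
#'   composition. Each column is standardized to mean 0 and sample SD 1
#'   across the 20 amino acids.
#'
#' A file path to a user TSV of the same shape (first column `aa` with
#' one-letter labels) may be given instead, so the tables are swappable.
#'
#' @param source `"factors"`, `"pseaac"`, or a file path.
#' @return a numeric matrix with rownames in the 20-letter alphabet;
#'   attribute `standardized` is `TRUE` for the PseAAC triplet.
#' @export
load_property_table <- function(source = c("factors", "pseaac")) {
  standardize <- FALSE
  if (length(source) == 1L && file.exists(source) &&
      !source %in% c("factors", "pseaac")) {
    path <- source
  } else {
    source <- match.arg(source)
    fname <- c(factors = "property_factors.tsv",
               pseaac = "pseaac_properties.tsv")[[source]]
    path <- system.file("extdata", fname, package = "pfnet")
    standardize <- source == "pseaac"
  }
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"aa" %in% names(df)) stop("property table needs an 'aa' label column")
  m <- as.matrix(df[, setdiff(names(df), "aa"), drop = FALSE])
  rownames(m) <- df$aa
  validate_property_table(m)
  if (standardize) {
    m <- scale(m)  # mean 0, sample SD 1 per column over the 20 amino acids
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    attr(m, "standardized") <- TRUE
  }
  m[AA_ALPHABET, , drop = FALSE]
}

validate_property_table <- function(m) {
  if (nrow(m) != 20L)
    stop("property table must have exactly 20 amino-acid rows, got ", nrow(m))
  unknown <- setdiff(rownames(m), AA_ALPHABET)
  if (length(unknown) > 0L)
    stop("unknown amino-acid rows: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(rownames(m)))
    stop("duplicated amino-acid rows in property table")
  if (anyNA(m) || !is.numeric(m))
    stop("property table contains missing or non-numeric values")
  invisible(m)
}
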