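#' Default pipeline configuration
#'
#' Reproduces the analysis settings of the published procedure: all six
#' feature schemes, PseAAC weight w = 0.05 with lambda in {0, 10},
#' natural-vector offset 1, discretization into 10 equal-frequency bins,
#' TE embeddings l = k = 5 with 4 nearest neighbours and q = 10
#' time-shifted surrogates, P = 100 permutations, Katz attenuation 0.9,
#' PageRank damping 0.85, and the theta sweep
#' {0.25, 0.1, 0.05, 0.025, 0.01, 0.005}.
#'
#' @param ... overrides for any field.
#' @return a named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    schemes = FEATURE_SCHEMES,
    offset = 1L,
    pseaac_w = 0.05,
    bins = 10L,
    binning = "equal_frequency",
    l = 5L, k = 5L, knn = 4L, q = 10L,
    surrogate = "shift",
    P = 100L,
    measures = c("CR", "nMIR", "TE"),
    thetas = c(0.25, 0.1, 0.05, 0.025, 0.01, 0.005),
    katz_attenuation = 0.9,
    pagerank_damping = 0.85,
    strict_permutations = FALSE,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the full feature-network analysis
#'
#' For every structural class x feature scheme: builds the feature matrix,
#' runs the permutation ensemble of relation matrices -> weighted networks
#' -> normalized centralities for the configured measures, assembles the
#' robustness (mean standard deviation) table, and orders features by
#' pairwise Welch t-tests at every theta level. With an `out_dir`, all
#' artifacts are written as TSV (identity-permutation relation matrices,
#' long-format centrality samples, robustness table, significance tables)
#' plus a JSON run summary; outputs are deterministic given the config
#' seed.
#'
#' @param records named list of protein records ([read_fasta()],
#'   [simulate_sequences()]).
#' @param manifest a `class_manifest`.
#' @param config list from [default_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return invisibly, a list with `feature_matrices`, `ensembles` (nested
#'   class -> scheme), `robustness` (per scheme), `significance` (nested
#'   class -> scheme -> measure -> theta), `summary`.
#' @export
run_pipeline <- function(records, manifest, config = default_config(),
                         out_dir = NULL) {
  if (config$P < 1L) stop("config$P must be >= 1")
  t0 <- proc.time()[["elapsed"]]
  params <- connectivity_params(bins = config$bins, binning = config$binning,
                                l = config$l, k = config$k, knn = config$knn,
                                q = config$q, surrogate = config$surrogate,
                                seed = config$seed)
  fms <- build_feature_matrices(records, manifest, config$schemes,
                                offset = config$offset, w = config$pseaac_w)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(fms)) {
      f <- file.path(out_dir, paste0(nm, ".features.tsv"))
      write_feature_matrix(fms[[nm]], f)
      files <- c(files, f)
    }
  }

  seeds <- spawn_seeds(config$seed, length(fms))
  names(seeds) <- names(fms)
  ensembles <- list()
  for (nm in names(fms)) {
    fm <- fms[[nm]]
    message("[pfnet] ensemble class=", attr(fm, "class_label"),
            " scheme=", attr(fm, "scheme"))
    ens <- tryCatch(
      permutation_ensemble(fm, P = config$P, seed = seeds[[nm]],
                           measures = config$measures, params = params,
                           katz_attenuation = config$katz_attenuation,
                           pagerank_damping = config$pagerank_damping,
                           strict = config$strict_permutations),
      error = function(e) stop("permutation ensemble failed for ", nm, ": ",
                               conditionMessage(e), call. = FALSE))
    ensembles[[attr(fm, "class_label")]][[attr(fm, "scheme")]] <- ens
    if (!is.null(out_dir)) {
      pm <- params; pm$seed <- seeds[[nm]]
      for (m in config$measures) {
        f <- file.path(out_dir, paste0(nm, ".", m, ".perm1.tsv"))
        write_relation_matrix(relation_for(unclass(as.matrix(fm)), m, pm), f)
        files <- c(files, f)
      }
    }
  }

  robustness <- list()
  for (sc in config$schemes) {
    per_class <- lapply(ensembles, function(cls) cls[[sc]])
    robustness[[sc]] <- robustness_table(unname(per_class))
  }

  significance <- list()
  for (cl in names(ensembles)) {
    for (sc in names(ensembles[[cl]])) {
      for (key in names(ensembles[[cl]][[sc]])) {
        significance[[cl]][[sc]][[key]] <-
          significance_sweep(ensembles[[cl]][[sc]][[key]],
                             thetas = config$thetas)
      }
    }
  }

  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "robustness.tsv")
    rob <- do.call(rbind, lapply(names(robustness), function(sc)
      cbind(scheme = sc, robustness[[sc]])))
    write.table(rob, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)

    sig_rows <- list()
    cent_rows <- list()
    for (cl in names(ensembles)) {
      for (sc in names(ensembles[[cl]])) {
        for (key in names(ensembles[[cl]][[sc]])) {
          s <- ensembles[[cl]][[sc]][[key]]
          cent_rows[[length(cent_rows) + 1L]] <- data.frame(
            class = cl, scheme = sc, network = s$network,
            centrality = s$centrality,
            feature = rep(colnames(s$samples), each = nrow(s$samples)),
            permutation = rep(seq_len(nrow(s$samples)),
                              times = ncol(s$samples)),
            normalized = as.numeric(s$samples), stringsAsFactors = FALSE)
          for (th in names(significance[[cl]][[sc]][[key]])) {
            tab <- significance_table(significance[[cl]][[sc]][[key]][[th]])
            sig_rows[[length(sig_rows) + 1L]] <- cbind(
              class = cl, scheme = sc, network = s$network,
              centrality = s$centrality, theta = as.numeric(th), tab)
          }
        }
      }
    }
    f <- file.path(out_dir, "centrality_samples.tsv")
    write.table(do.call(rbind, cent_rows), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "significance.tsv")
    write.table(do.call(rbind, sig_rows), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }

  summary <- list(
    n_proteins = length(records),
    classes = table(manifest$classes),
    schemes = config$schemes,
    measures = config$measures,
    P = config$P,
    seed = config$seed,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    files = files
  )
  if (!is.null(out_dir)) {
    summary$classes <- as.list(summary$classes)
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(feature_matrices = fms, ensembles = ensembles,
                 robustness = robustness, significance = significance,
                 summary = summary))
}
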