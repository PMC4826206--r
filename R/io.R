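## Readers and writers for the external formats consumed by the pipeline:
## TSV feature matrices, clinical tables, GISTIC-style gene-level copy-number
## call tables, SIF / two-column interaction edge lists, miRNA target tables
## and the YAML pipeline configuration.

#' Read a feature matrix from a tab-separated file
#'
#' Reads an omics view (e.g. mRNA or miRNA expression) stored as a TSV table
#' with identifiers in the first row and column. The first token of the
#' header row (the "gene"/"id" slot) is ignored. Internally patients are
#' always rows, regardless of the file orientation.
#'
#' Cells that are empty or `NA` are handled by `na_action`: features holding
#' any missing value are dropped (with a message reporting the count), or the
#' file is rejected. Any other non-numeric cell is always rejected, with its
#' row/column coordinates.
#'
#' @param path Path to a tab-separated file.
#' @param orientation `"features-in-rows"` (default, the usual omics layout)
#'   or `"patients-in-rows"`.
#' @param na_action `"drop_features"` (default) or `"error"`.
#' @return A numeric matrix, patients in rows, features in columns, with
#'   unique dimnames.
#' @export
read_feature_matrix <- function(path,
                                orientation = c("features-in-rows",
                                                "patients-in-rows"),
                                na_action = c("drop_features", "error")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(tab) == 0L) stopf("no data rows in '%s'", path)
  row_ids <- tab[[1L]]
  col_ids <- colnames(tab)[-1L]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyDuplicated(row_ids)) {
    stopf("duplicate row identifier(s): %s",
          paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    stopf("duplicate column identifier(s): %s",
          paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  missing_cell <- is.na(body) | body == "" | body == "NA"
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !missing_cell, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("non-numeric value '%s' at row '%s', column '%s'",
          body[bad[1L, 1L], bad[1L, 2L]], row_ids[bad[1L, 1L]],
          col_ids[bad[1L, 2L]])
  }
  dimnames(num) <- list(row_ids, col_ids)
  x <- if (orientation == "features-in-rows") t(num) else num
  miss_feat <- apply(is.na(x), 2L, any)
  if (any(miss_feat)) {
    if (na_action == "error") {
      stopf("missing values in %d feature(s), e.g. '%s'", sum(miss_feat),
            colnames(x)[which(miss_feat)[1L]])
    }
    message(sprintf("dropping %d feature(s) with missing values",
                    sum(miss_feat)))
    x <- x[, !miss_feat, drop = FALSE]
  }
  x
}

#' Write a feature matrix as a tab-separated file
#'
#' Full-precision round-trip companion of [read_feature_matrix()].
#'
#' @param x Numeric patients-by-features matrix with dimnames.
#' @param path Output path.
#' @param orientation Layout to write; see [read_feature_matrix()].
#' @export
write_feature_matrix <- function(x, path,
                                 orientation = c("features-in-rows",
                                                 "patients-in-rows")) {
  orientation <- match.arg(orientation)
  out <- if (orientation == "features-in-rows") t(x) else x
  body <- apply(out, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(out))
  lines <- c(paste(c("id", colnames(out)), collapse = "\t"),
             paste(rownames(out), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table with overall-survival columns
#'
#' Expects a TSV with columns `patient_id`, `os_time` (days, nonnegative) and
#' `os_event` (1 = death observed, 0 = censored).
#'
#' @param path Path to the clinical TSV.
#' @return A data frame with validated columns.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "os_time", "os_event")
  if (!all(need %in% colnames(tab))) {
    stopf("clinical table must have columns %s", paste(need, collapse = ", "))
  }
  validate_clinical(tab[, need])
}

validate_clinical <- function(clin) {
  if (anyDuplicated(clin$patient_id)) {
    stopf("duplicate patient_id(s): %s",
          paste(unique(clin$patient_id[duplicated(clin$patient_id)]),
                collapse = ", "))
  }
  if (!is.numeric(clin$os_time) || any(!is.finite(clin$os_time)) ||
      any(clin$os_time < 0)) {
    stopf("'os_time' must be nonnegative and finite")
  }
  if (!all(clin$os_event %in% c(0, 1))) stopf("'os_event' must be 0 or 1")
  clin$patient_id <- as.character(clin$patient_id)
  clin
}

#' Read a gene-level copy-number call table
#'
#' GISTIC-style table of integer codes in -2..2, genes in rows, samples in
#' columns. Codes outside that range are rejected, naming the offending
#' gene and sample.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_copy_number_calls <- function(path) {
  x <- t(read_feature_matrix(path, "features-in-rows", na_action = "error"))
  check_gistic_codes(x)
  x
}

check_gistic_codes <- function(x) {
  ok <- array(x %in% c(-2L, -1L, 0L, 1L, 2L), dim = dim(x))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("copy-number code %g out of range {-2,...,2} for gene '%s', sample '%s'",
          x[bad[1L, 1L], bad[1L, 2L]], rownames(x)[bad[1L, 1L]],
          colnames(x)[bad[1L, 2L]])
  }
  invisible(x)
}

#' Read an undirected interaction network from SIF or edge-list format
#'
#' Accepts Cytoscape SIF lines (`nodeA relation nodeB`) or two-column
#' edge-list lines separated by whitespace/tabs. Self-loops and duplicate
#' edges are dropped; the counts of dropped items are reported.
#'
#' @param path Path to the network file.
#' @return An undirected simple [igraph][igraph::igraph-package] graph.
#' @export
read_network_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("network file '%s' is empty", path)
  edges <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    if (length(tok) < 2L) {
      stopf("line %d of '%s' has fewer than 2 node tokens", i, path)
    }
    edges[[i]] <- if (length(tok) >= 3L) tok[c(1L, 3L)] else tok[1:2]
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops + n_multi > 0L) {
    message(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_multi))
  }
  gs
}

#' Read a miRNA-to-target table with evidence tiers
#'
#' TSV with columns `mirna`, `gene`, `evidence`; evidence must be `strong`
#' or `weak`.
#'
#' @param path Path to the TSV.
#' @return A data frame with the three validated columns.
#' @export
read_target_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "evidence")
  if (!all(need %in% colnames(tab))) {
    stopf("target table must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(tab$evidence %in% c("strong", "weak"))) {
    stopf("'evidence' must be 'strong' or 'weak'")
  }
  tab[, need]
}

#' Restrict all cohort structures to their common patients
#'
#' Intersects the patient identifiers of the expression views, the clinical
#' table and (optionally) an alteration/copy-number matrix, and reorders
#' everything into one canonical (lexicographic) patient order so that
#' downstream results do not depend on file order.
#'
#' @param views Named (or unnamed) list of patients-by-features matrices.
#' @param clinical Optional clinical data frame (see
#'   [read_clinical_table()]).
#' @param alterations Optional genes-by-samples matrix.
#' @return A list with elements `views`, `clinical`, `alterations` and
#'   `patients` (the canonical order). Missing inputs are returned as `NULL`.
#' @export
align_cohort <- function(views, clinical = NULL, alterations = NULL) {
  if (!is.list(views) || length(views) < 1L) {
    stopf("'views' must be a non-empty list of matrices")
  }
  sets <- lapply(views, rownames)
  if (!is.null(clinical)) sets <- c(sets, list(clinical$patient_id))
  if (!is.null(alterations)) sets <- c(sets, list(colnames(alterations)))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) stopf("no patients shared across all inputs")
  common <- canonical_order(common)
  message(sprintf("aligned cohort: %d shared patient(s)", length(common)))
  views <- lapply(views, function(v) v[common, , drop = FALSE])
  if (!is.null(clinical)) {
    clinical <- clinical[match(common, clinical$patient_id), , drop = FALSE]
    rownames(clinical) <- NULL
  }
  if (!is.null(alterations)) {
    alterations <- alterations[, common, drop = FALSE]
  }
  list(views = views, clinical = clinical, alterations = alterations,
       patients = common)
}

#' Build and validate a pipeline configuration
#'
#' Collects the tunable parameters of the whole pipeline with their default
#' values, validating every field against its allowed domain. Violations are
#' rejected with a message naming the field.
#'
#' @param snf_mu Affinity kernel bandwidth multiplier (mu > 0).
#' @param snf_k Neighbourhood size for the local kernel; `NULL` means
#'   ceiling(n/10), bounded to 10..30 (or n-1 if smaller), chosen at fit time.
#' @param snf_iters Number of fusion iterations.
#' @param cluster_range Candidate numbers of subtypes (each >= 2).
#' @param score_threshold Alteration-score cutoff on the normalised gene
#'   score (default 2e-4).
#' @param linker_alpha BH-adjusted p cutoff for linker genes.
#' @param null_iters Null-model iterations (default 1000).
#' @param rng_seed Base RNG seed; stage seeds are derived by fixed offsets.
#' @param fold_change_cutoff Fold-change cutoff for upregulation (default 1.2).
#' @param de_p_cutoff Rank-sum p cutoff for upregulation (default 0.01).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(snf_mu = 0.5, snf_k = NULL, snf_iters = 20L,
                            cluster_range = 2:5, score_threshold = 2e-4,
                            linker_alpha = 0.05, null_iters = 1000L,
                            rng_seed = 1L, fold_change_cutoff = 1.2,
                            de_p_cutoff = 0.01) {
  check_scalar(snf_mu, "snf_mu", lower = 0, open_lower = TRUE)
  if (!is.null(snf_k)) {
    check_scalar(snf_k, "snf_k", lower = 1, integer = TRUE)
  }
  check_scalar(snf_iters, "snf_iters", lower = 1, integer = TRUE)
  if (length(cluster_range) < 1L || any(cluster_range < 2) ||
      any(cluster_range != round(cluster_range))) {
    stopf("'cluster_range' must be integers >= 2")
  }
  check_scalar(score_threshold, "score_threshold", lower = 0)
  check_scalar(linker_alpha, "linker_alpha", lower = 0, upper = 1,
               open_lower = TRUE)
  check_scalar(null_iters, "null_iters", lower = 1, integer = TRUE)
  check_scalar(rng_seed, "rng_seed", integer = TRUE)
  check_scalar(fold_change_cutoff, "fold_change_cutoff", lower = 0,
               open_lower = TRUE)
  check_scalar(de_p_cutoff, "de_p_cutoff", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  structure(list(snf_mu = snf_mu, snf_k = snf_k,
                 snf_iters = as.integer(snf_iters),
                 cluster_range = sort(unique(as.integer(cluster_range))),
                 score_threshold = score_threshold,
                 linker_alpha = linker_alpha,
                 null_iters = as.integer(null_iters),
                 rng_seed = as.integer(rng_seed),
                 fold_change_cutoff = fold_change_cutoff,
                 de_p_cutoff = de_p_cutoff),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown fields are rejected; known fields are validated by
#' [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @param n_patients Optional cohort size used to check `cluster_range`.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path, n_patients = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(n_patients) && any(cfg$cluster_range > n_patients)) {
    stopf("'cluster_range' contains values larger than the number of patients (%d)",
          n_patients)
  }
  cfg
}
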