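#' Read a connectivity matrix or edge list
#'
#' Matrix files are comma- or tab-delimited (auto-detected), square, with
#' an optional header row of node labels. Edge-list files have two or three
#' whitespace-separated columns `u v [weight]`. Asymmetric matrix input is
#' symmetrized by maximum with a warning.
#'
#' @param path file to read.
#' @param format `"matrix"` or `"edgelist"`.
#' @param one_based are edge-list indices 1-based (default) or 0-based?
#' @param n_nodes optional node count for edge lists.
#' @return A list with `matrix` (square numeric) and `labels`.
#' @export
read_connectivity <- function(path, format = c("matrix", "edgelist"),
                              one_based = TRUE, n_nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edgelist") {
    el <- utils::read.table(path, header = FALSE)
    if (ncol(el) < 2L) stop(path, ": an edge list needs at least 2 columns")
    net <- network_from_edges(as.matrix(el[, 1:2]), n_nodes = n_nodes,
                              one_based = one_based)
    return(list(matrix = net$adjacency * 1.0, labels = net$labels))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  if (!has_header) {
    # labels may themselves be numeric: a header row then shows up as one
    # extra line over a square body
    n_lines <- length(readLines(path))
    has_header <- n_lines == length(fields) + 1L
  }
  raw <- utils::read.table(path, header = has_header, sep = sep,
                           check.names = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(!apply(raw, 1, function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
    stop(path, ": non-numeric entries (line ",
         paste(bad + has_header, collapse = ", "), ")")
  }
  if (nrow(m) != ncol(m)) {
    stop(path, ": matrix is not square (", nrow(m), " x ", ncol(m), ")")
  }
  if (any(m < 0)) stop(path, ": negative entries are not a valid connectivity matrix")
  labels <- if (has_header) colnames(raw) else paste0("v", seq_len(nrow(m)))
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    warning(path, ": asymmetric matrix symmetrized by maximum")
    m <- pmax(m, t(m))
  }
  dimnames(m) <- list(labels, labels)
  list(matrix = m, labels = labels)
}

#' Read a cohort from a manifest
#'
#' The manifest is a delimited file with columns `subject_id`, `path`
#' (matrix file, relative to the manifest's directory) and `group`. An
#' optional node-tag file has columns `node_label`, `tag`.
#'
#' @param manifest_path path to the manifest file.
#' @param tag_path optional node-tag file.
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest_path, tag_path = NULL) {
  man <- utils::read.table(manifest_path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "group")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  subjects <- lapply(man$path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_connectivity(full, "matrix")$matrix
  })
  names(subjects) <- man$subject_id
  labels <- rownames(subjects[[1L]])
  tags <- NULL
  if (!is.null(tag_path)) {
    tg <- utils::read.table(tag_path, header = TRUE, sep = "",
                            stringsAsFactors = FALSE)
    tags <- tg$tag[match(labels, tg$node_label)]
    if (anyNA(tags)) stop("tag file does not cover all nodes")
  }
  cohort(subjects, groups = man$group, node_labels = labels, node_tags = tags)
}

#' Write a cohort to a directory
#'
#' One tab-delimited matrix file per subject plus `manifest.tsv`; if the
#' cohort carries a planted ground truth it is written to
#' `planted_pairs.tsv`, and node tags to `node_tags.tsv`.
#'
#' @param ch a [cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(ch$subjects)) {
    write_matrix(ch$subjects[[id]], file.path(dir, paste0(id, ".tsv")),
                 labels = ch$node_labels)
  }
  man <- data.frame(subject_id = names(ch$subjects),
                    path = paste0(names(ch$subjects), ".tsv"),
                    group = ch$groups)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ch$node_tags)) {
    utils::write.table(data.frame(node_label = ch$node_labels, tag = ch$node_tags),
                       file.path(dir, "node_tags.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(ch$planted_pairs) && nrow(ch$planted_pairs) > 0) {
    pp <- data.frame(u = ch$node_labels[ch$planted_pairs[, 1L]],
                     v = ch$node_labels[ch$planted_pairs[, 2L]])
    utils::write.table(pp, file.path(dir, "planted_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write a labeled matrix as delimited text
#'
#' Tab-delimited with a header row of labels; infinite entries are written
#' as the literal `inf`; floats at fixed precision so reruns are
#' byte-identical.
#'
#' @param m matrix to write.
#' @param path output file.
#' @param labels column labels; default from `m`'s dimnames.
#' @param digits decimal places.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, labels = NULL, digits = 10L) {
  m <- as.matrix(m)
  if (is.null(labels)) labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("v", seq_len(ncol(m)))
  fmt <- matrix(formatC(m, digits = digits, format = "g"), nrow(m))
  fmt[is.infinite(m) & m > 0] <- "inf"
  fmt[is.infinite(m) & m < 0] <- "-inf"
  lines <- c(paste(labels, collapse = "\t"),
             apply(fmt, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Emits the per-pair results table (pair, delta, p, significance flags,
#' categories when tags exist), the per-node median profile, and a JSON
#' run-metadata file recording configuration, seed and package version.
#' Column order and float formatting are deterministic: identical
#' configuration and seed give byte-identical files.
#'
#' @param pr a [permutation_test()] result.
#' @param out_dir output directory (created if needed).
#' @param config optional named list recorded in the metadata file.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(pr, out_dir, config = list()) {
  stopifnot(inherits(pr, "permutation_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- rownames(pr$p_values)
  n <- length(labels)
  idx <- which(upper.tri(pr$p_values), arr.ind = TRUE)
  tab <- data.frame(
    node_u = labels[idx[, 1L]],
    node_v = labels[idx[, 2L]],
    delta = formatC(pr$observed_delta[idx], digits = 10, format = "g"),
    p_value = formatC(pr$p_values[idx], digits = 10, format = "g"),
    significant_fdr = pr$significant_fdr[idx],
    significant_bonferroni = pr$significant_bonferroni[idx]
  )
  if (!is.null(pr$node_tags)) {
    tab$category <- paste(pmin(pr$node_tags[idx[, 1L]], pr$node_tags[idx[, 2L]]),
                          pmax(pr$node_tags[idx[, 1L]], pr$node_tags[idx[, 2L]]),
                          sep = "-")
  }
  pairs_path <- file.path(out_dir, "pairs.tsv")
  utils::write.table(tab, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- node_median_profile(pr$observed_delta)
  prof_path <- file.path(out_dir, "node_profile.tsv")
  utils::write.table(
    data.frame(node = labels,
               median_delta = formatC(prof, digits = 10, format = "g")),
    prof_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(measure = pr$measure, n_permutations = pr$n_permutations,
                 alpha = pr$alpha, seed = pr$seed,
                 n_excluded_pairs = pr$n_excluded_pairs,
                 package_version = as.character(utils::packageVersion("commgeom"))),
            config)
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(pairs_path, prof_path, meta_path))
}
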