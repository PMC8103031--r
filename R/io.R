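# Readers and writers for the package's TSV dialect: matrices carry molecule
# ids in the first column and sample ids in the header; labels are a
# two-column table (sample_id, group).

#' Read one omics matrix
#'
#' @param path TSV/CSV file; first column molecule id, header row sample ids
#' @param sep field separator (tab by default)
#' @return numeric matrix with molecule rownames and sample colnames
#' @export
read_omics_matrix <- function(path, sep = "\t") {
  d <- utils::read.delim(path, sep = sep, header = TRUE, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in ", path)
  m
}

#' Write a matrix in the package's TSV dialect
#'
#' @param mat matrix with rownames and colnames
#' @param path output file
#' @param id_header header for the identifier column
#' @export
write_omics_matrix <- function(mat, path, id_header = "id") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE)
  colnames(d)[1] <- id_header
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample label table
#'
#' @param path two-column TSV with header `sample_id`, `group`
#' @param sep field separator
#' @return named character vector (sample id -> group)
#' @export
read_labels <- function(path, sep = "\t") {
  d <- utils::read.delim(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("label file needs two columns: sample_id, group")
  stats::setNames(as.character(d[[2]]), as.character(d[[1]]))
}

#' Load and align a multi-omics stack from files
#'
#' Reads each matrix, checks that all omics cover exactly the same sample
#' set (order may differ; columns are aligned to the first matrix), rejects
#' negative entries, and attaches the partial labels.
#'
#' @param paths character vector of matrix file paths
#' @param label_path optional label TSV (see [read_labels()]); samples absent
#'   from it are treated as unlabeled
#' @param sep field separator
#' @return an [omics_stack()]
#' @export
load_stack <- function(paths, label_path = NULL, sep = "\t") {
  mats <- lapply(paths, read_omics_matrix, sep = sep)
  ref <- colnames(mats[[1]])
  for (p in seq_along(mats)[-1]) {
    missing <- setdiff(ref, colnames(mats[[p]]))
    extra <- setdiff(colnames(mats[[p]]), ref)
    if (length(missing) > 0 || length(extra) > 0)
      stop("sample sets differ between omic 1 and omic ", p,
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")))
    mats[[p]] <- mats[[p]][, ref, drop = FALSE]
  }
  labels <- if (!is.null(label_path)) read_labels(label_path, sep = sep)
  omics_stack(mats, sample_ids = ref, labels = labels)
}

#' Write a simulated dataset to disk in the loadable TSV dialect
#'
#' @param sim a [simulate_multiomics()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the list of written paths
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (p in seq_along(sim$stack$matrices)) {
    f <- file.path(dir, sprintf("omic%d.tsv", p))
    write_omics_matrix(sim$stack$matrices[[p]], f, "molecule_id")
    paths$omics <- c(paths$omics, f)
  }
  lab <- data.frame(
    sample_id = sim$stack$sample_ids[sim$stack$labeled_index],
    group = sim$stack$labels)
  paths$labels <- file.path(dir, "labels.tsv")
  utils::write.table(lab, paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$side_matrix <- file.path(dir, "side_matrix.tsv")
  write_omics_matrix(sim$side_matrix, paths$side_matrix, "feature_id")
  el <- igraph::as_data_frame(sim$network, what = "edges")
  colnames(el)[1:2] <- c("source", "target")
  paths$network <- file.path(dir, "network.tsv")
  utils::write.table(el, paths$network, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(labels = as.list(sim$truth$labels),
         noise_sd = sim$truth$noise_sd,
         labeled_fraction = sim$truth$labeled_fraction,
         seed = sim$truth$seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write the fitted factors, weights and objective trace
#'
#' @param state a fitted `jtf_state`
#' @param stack the [omics_stack()] it was fitted on
#' @param dir output directory
#' @return invisibly, the list of written paths
#' @export
write_factor_state <- function(state, stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- nrow(state$V)
  fac <- sprintf("factor%d", seq_len(k))
  paths <- list()
  for (p in seq_along(state$U)) {
    U <- state$U[[p]]; colnames(U) <- fac
    f <- file.path(dir, sprintf("U_omic%d.tsv", p))
    write_omics_matrix(U, f, "molecule_id"); paths$U <- c(paths$U, f)
    S <- state$S[[p]]; dimnames(S) <- list(fac, fac)
    f <- file.path(dir, sprintf("S_omic%d.tsv", p))
    write_omics_matrix(S, f, "factor"); paths$S <- c(paths$S, f)
  }
  V <- state$V; rownames(V) <- fac
  paths$V <- file.path(dir, "V.tsv")
  write_omics_matrix(V, paths$V, "factor")
  paths$pi <- file.path(dir, "pi.tsv")
  utils::write.table(
    data.frame(omic = seq_along(state$pi), pi = state$pi),
    paths$pi, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$objective <- file.path(dir, "objective_trace.tsv")
  utils::write.table(
    data.frame(sweep = seq_along(state$objective_trace) - 1L,
               objective = state$objective_trace),
    paths$objective, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
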