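# From fitted factors to connected multi-omics modules: per-factor z-score
# feature selection, projection onto an interaction network, factor-to-group
# matching, unlabeled-sample classification, and gene-set enrichment.

#' Select high-loading molecules of one latent factor by z-score
#'
#' Standardizes a factor's loading column as `z = (x - mean(x)) / sd(x)`
#' (sample standard deviation, `n - 1` denominator) and keeps entries with
#' `z` strictly greater than `cutoff`. Selection is invariant to positive
#' affine rescaling of the loadings.
#'
#' @param column numeric loading vector (one column of a molecular factor U),
#'   optionally named by molecule id.
#' @param cutoff z-score threshold; the default 2 keeps roughly the top 2\%
#'   of a Gaussian loading profile.
#' @return data.frame with columns `index`, `id`, `z` for the selected
#'   entries, ordered by decreasing `z`. A zero-variance column yields an
#'   empty selection with a warning.
#' @examples
#' zscore_select(c(10, rep(0, 9)))  # one member, z = 9/sqrt(10)
#' @export
zscore_select <- function(column, cutoff = 2) {
  stopifnot(length(column) >= 2)
  s <- stats::sd(column)
  ids <- if (is.null(names(column))) as.character(seq_along(column))
         else names(column)
  if (s == 0 || !is.finite(s)) {
    warning("zero-variance loading column; no molecules selected")
    return(data.frame(index = integer(0), id = character(0), z = numeric(0)))
  }
  z <- (column - mean(column)) / s
  keep <- which(z > cutoff)
  keep <- keep[order(z[keep], decreasing = TRUE)]
  data.frame(index = keep, id = ids[keep], z = unname(z[keep]),
             row.names = NULL)
}

#' Load a molecular interaction network
#'
#' Reads an edge list as either a 2/3-column TSV (`source`, `target`,
#' optional `weight`) or SIF (`source relation target [target ...]`).
#' Self-loops are dropped.
#'
#' @param path file path
#' @param format `"tsv"` or `"sif"`
#' @param directed logical; keep edge direction (components are always found
#'   on the undirected skeleton)
#' @param sep field separator for the TSV dialect
#' @return an `igraph` graph with a `weight` edge attribute
#' @export
read_network <- function(path, format = c("tsv", "sif"), directed = FALSE,
                         sep = "\t") {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(d) < 2) stop("network TSV needs source and target columns")
    edges <- data.frame(from = as.character(d[[1]]),
                        to = as.character(d[[2]]),
                        weight = if (ncol(d) >= 3) as.numeric(d[[3]]) else 1)
  } else {
    lines <- strsplit(readLines(path), "[\t ]+")
    lines <- lines[lengths(lines) >= 3]
    edges <- do.call(rbind, lapply(lines, function(f)
      data.frame(from = f[1], to = f[-(1:2)], weight = 1)))
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = directed)
}

#' Extract the connected module(s) induced by selected molecules
#'
#' Induces the subgraph of `network` on `members` and decomposes it into
#' connected components, treating directed regulatory edges as undirected for
#' connectivity (direction is retained in the returned edge lists). Members
#' absent from the network are reported as unmapped, not an error.
#'
#' @param members character vector of molecule ids
#' @param network an `igraph` graph (see [read_network()])
#' @param mode `"all"` returns every component; `"largest"` only the biggest
#'   (size ties broken in favor of the component holding the
#'   lexicographically smallest node id)
#' @return list with `components` (list of character node vectors), `edges`
#'   (data.frame `from`, `to`, `weight` restricted to the returned nodes) and
#'   `unmapped` (members not present in the network)
#' @export
extract_subnetwork <- function(members, network, mode = c("all", "largest")) {
  mode <- match.arg(mode)
  members <- unique(as.character(members))
  present <- intersect(members, igraph::V(network)$name)
  unmapped <- setdiff(members, present)
  if (length(present) == 0)
    return(list(components = list(), edges = empty_edges(), unmapped = unmapped))

  sub <- igraph::induced_subgraph(network, present)
  comp <- igraph::components(igraph::as_undirected(sub, mode = "collapse"))
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  # deterministic order: larger first, then by smallest node id
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  groups <- unname(groups[ord])
  if (mode == "largest") groups <- groups[1]

  keep_nodes <- unlist(groups)
  kept <- igraph::induced_subgraph(sub, keep_nodes)
  el <- igraph::as_data_frame(kept, what = "edges")
  if (nrow(el) == 0) el <- empty_edges()
  if (is.null(el$weight)) el$weight <- rep(1, nrow(el))
  el <- el[order(el$from, el$to), c("from", "to", "weight"), drop = FALSE]
  rownames(el) <- NULL
  list(components = groups, edges = el, unmapped = sort(unmapped))
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), weight = numeric(0))
}

#' Match latent factors to sample groups
#'
#' Averages each factor's labeled-sample loadings within every group and
#' finds the one-to-one factor-to-group assignment maximizing the total mean
#' loading (exhaustive over injective assignments; the factor count `k` is
#' small). Ties are broken deterministically by group-id order and ascending
#' factor index.
#'
#' @param V_L `k x N_L` labeled-sample factor matrix
#' @param labels group per labeled sample (length `N_L`)
#' @return list with `factor_to_group` (length-`k` character vector, `NA` for
#'   factors left without a group when `k` exceeds the group count),
#'   `group_to_factor` (named integer vector), and `mean_loadings`
#'   (`k x groups` matrix of group-mean loadings)
#' @export
map_factors_to_groups <- function(V_L, labels) {
  V_L <- as.matrix(V_L)
  k <- nrow(V_L)
  stopifnot(ncol(V_L) == length(labels))
  groups <- sort(unique(as.character(labels)))
  g <- length(groups)
  if (g > k) stop("more groups (", g, ") than factors (", k, ")")
  if (g < k) warning("k = ", k, " exceeds the number of groups (", g,
                     "); some factors will stay unassigned")
  M <- vapply(groups,
              function(gr) rowMeans(V_L[, labels == gr, drop = FALSE]),
              numeric(k))
  M <- matrix(M, nrow = k, dimnames = list(NULL, groups))

  best <- list(score = -Inf, assign = NULL)
  search <- function(gi, used, score, assign) {
    if (gi > g) {
      if (score > best$score) best <<- list(score = score, assign = assign)
      return(invisible(NULL))
    }
    for (f in setdiff(seq_len(k), used)) {
      search(gi + 1L, c(used, f), score + M[f, gi], c(assign, f))
    }
  }
  search(1L, integer(0), 0, integer(0))

  group_to_factor <- stats::setNames(best$assign, groups)
  factor_to_group <- rep(NA_character_, k)
  factor_to_group[best$assign] <- groups
  list(factor_to_group = factor_to_group,
       group_to_factor = group_to_factor,
       mean_loadings = M)
}

#' Classify unlabeled samples from their latent loadings
#'
#' Assigns every unlabeled sample the group matched to its largest factor
#' loading. Ties go to the lowest factor index; an all-zero column is
#' reported as `"unassigned"`.
#'
#' @param V_UL `k x N_UL` unlabeled-sample factor matrix (columns optionally
#'   named by sample id)
#' @param factor_to_group length-`k` character vector mapping factor index to
#'   group (see [map_factors_to_groups()])
#' @return character vector of predicted groups, named by sample id when
#'   column names are present
#' @export
classify_unlabeled <- function(V_UL, factor_to_group) {
  V_UL <- as.matrix(V_UL)
  stopifnot(nrow(V_UL) == length(factor_to_group))
  if (ncol(V_UL) == 0) return(stats::setNames(character(0), character(0)))
  pred <- apply(V_UL, 2, function(col) {
    if (all(col == 0)) return("unassigned")
    factor_to_group[which.max(col)]
  })
  pred[is.na(pred)] <- "unassigned"
  stats::setNames(as.character(pred), colnames(V_UL))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>member...`
#' @return named list of character member vectors; descriptions kept in the
#'   `"description"` attribute
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 3]
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2)
  sets
}

#' Hypergeometric over-representation test of a module in an annotation set
#'
#' One-sided tail probability `P(overlap >= observed)` of drawing the module
#' from the universe: the classical gene-set over-representation test.
#'
#' @param members molecule ids in the module (must lie in `universe`)
#' @param annotation_set annotation molecule ids (intersected with the
#'   universe)
#' @param universe background molecule ids
#' @return list with `overlap`, `members`, `annotation` (counts restricted to
#'   the universe), `universe`, and `p_value`
#' @export
enrich_hyper <- function(members, annotation_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  members <- unique(as.character(members))
  if (!all(members %in% universe))
    stop("module members must be contained in the universe")
  ann <- intersect(unique(as.character(annotation_set)), universe)
  ov <- length(intersect(members, ann))
  p <- stats::phyper(ov - 1, m = length(ann),
                     n = length(universe) - length(ann),
                     k = length(members), lower.tail = FALSE)
  list(overlap = ov, members = length(members), annotation = length(ann),
       universe = length(universe), p_value = p)
}

#' Enrichment of each module against each annotation set
#'
#' @param module_members named list of module member vectors
#' @param gmt named list of annotation sets (see [read_gmt()])
#' @param universe background molecule ids; defaults to the union of all
#'   module members and annotation members
#' @param adjust apply Benjamini-Hochberg correction across all tests
#' @return data.frame with one row per module x set
#' @export
enrich_modules <- function(module_members, gmt, universe = NULL,
                           adjust = FALSE) {
  if (is.null(universe))
    universe <- unique(c(unlist(module_members), unlist(gmt)))
  rows <- list()
  for (mod in names(module_members)) {
    mem <- intersect(module_members[[mod]], universe)
    for (set in names(gmt)) {
      e <- enrich_hyper(mem, gmt[[set]], universe)
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, set = set, overlap = e$overlap,
        module_size = e$members, set_size = e$annotation,
        universe_size = e$universe, p_value = e$p_value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Derive connected modules from a fitted state
#'
#' For every latent factor, selects high-loading molecules per omic by
#' [zscore_select()], pools them, and (when a network is supplied) extracts
#' the induced connected component(s) with [extract_subnetwork()].
#'
#' @param state a fitted `jtf_state`
#' @param stack the [omics_stack()] it was fitted on
#' @param network optional `igraph` interaction network
#' @param cutoff z-score cutoff passed to [zscore_select()]
#' @param mode component mode passed to [extract_subnetwork()]
#' @return list (one element per factor) of lists with `members` (data.frame
#'   `id`, `omic`, `z`) and, with a network, `subnetwork` from
#'   [extract_subnetwork()]
#' @export
derive_modules <- function(state, stack, network = NULL, cutoff = 2,
                           mode = "largest") {
  k <- nrow(state$V)
  lapply(seq_len(k), function(f) {
    per_omic <- lapply(seq_along(state$U), function(p) {
      col <- state$U[[p]][, f]
      names(col) <- stack$molecule_ids[[p]]
      sel <- zscore_select(col, cutoff)
      if (nrow(sel) > 0) data.frame(id = sel$id, omic = p, z = sel$z)
      else data.frame(id = character(0), omic = integer(0), z = numeric(0))
    })
    members <- do.call(rbind, per_omic)
    out <- list(factor = f, members = members)
    if (!is.null(network))
      out$subnetwork <- extract_subnetwork(members$id, network, mode = mode)
    out
  })
}
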