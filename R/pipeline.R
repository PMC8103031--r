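#' End-to-end analysis pipeline
#'
#' Runs load -> labeled-sample graphs -> joint tri-factorization -> module
#' extraction -> unlabeled-sample classification -> enrichment (when
#' annotation sets are given), writing every artifact plus a JSON run
#' manifest into `config$out_dir`. Deterministic given the config and seed.
#'
#' `config` is a list (or path to a YAML file with the same fields):
#' \describe{
#'   \item{omics}{character vector of matrix paths, or a ready
#'     `omics_stack` under `stack`}
#'   \item{labels}{label TSV path (optional when `stack` is given)}
#'   \item{side_matrix}{side feature TSV over the labeled samples (optional;
#'     without it the fit runs with `beta = 0`)}
#'   \item{network}{interaction network TSV/SIF (optional)}
#'   \item{gmt}{annotation GMT path (optional)}
#'   \item{k, beta, omega, max_iter, tol, seed}{see [jtf_params()]}
#'   \item{laplacian_mode}{`"clip"` (default) or `"abs"`}
#'   \item{zscore_cutoff}{module member cutoff, default 2}
#'   \item{normalize}{divide each matrix by its mean before fitting
#'     (default `FALSE`)}
#'   \item{out_dir}{output directory}
#' }
#'
#' @param config list or YAML path
#' @return invisibly, a list with the fitted `state`, `mapping`,
#'   `predictions`, `modules`, `enrichment` and written `paths`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stack <- if (!is.null(config$stack)) config$stack
           else load_stack(config$omics, config$labels,
                           sep = config$sep %||% "\t")
  if (isTRUE(config$normalize))
    stack$matrices <- lapply(stack$matrices, function(x) x / mean(x))

  params <- jtf_params(
    k = config$k %||% 4, beta = config$beta %||% 10,
    omega = config$omega %||% 1e5, max_iter = config$max_iter %||% 500,
    tol = config$tol %||% 1e-6, seed = config$seed %||% 1)

  laplacians <- NULL
  if (length(stack$labeled_index) > 0 && params$beta > 0) {
    side <- config$side_matrix_data %||% (
      if (!is.null(config$side_matrix)) read_omics_matrix(config$side_matrix))
    if (!is.null(side)) {
      side <- side[, stack$sample_ids[stack$labeled_index], drop = FALSE]
      laplacians <- build_laplacians(side, stack$labels,
                                     mode = config$laplacian_mode %||% "clip")
    }
  }

  state <- jtf_fit(stack, params, laplacians)
  paths <- write_factor_state(state, stack, out_dir)

  network <- config$network_data %||% (
    if (!is.null(config$network))
      read_network(config$network, directed = isTRUE(config$directed)))
  modules <- derive_modules(state, stack, network,
                            cutoff = config$zscore_cutoff %||% 2)

  mapping <- NULL; predictions <- NULL
  if (length(stack$labeled_index) > 0) {
    mapping <- map_factors_to_groups(
      state$V[, stack$labeled_index, drop = FALSE], stack$labels)
    ul <- unlabeled_index(stack)
    if (length(ul) > 0) {
      predictions <- classify_unlabeled(state$V[, ul, drop = FALSE],
                                        mapping$factor_to_group)
      paths$predictions <- file.path(out_dir, "predictions.tsv")
      utils::write.table(
        data.frame(sample_id = names(predictions),
                   predicted_group = unname(predictions)),
        paths$predictions, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  mod_dir <- file.path(out_dir, "modules")
  dir.create(mod_dir, showWarnings = FALSE)
  module_members <- list()
  for (mod in modules) {
    grp <- if (!is.null(mapping)) mapping$factor_to_group[mod$factor]
           else NA_character_
    tag <- if (!is.na(grp)) grp else sprintf("factor%d", mod$factor)
    f <- file.path(mod_dir, sprintf("module_%s.tsv", tag))
    utils::write.table(mod$members, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$modules <- c(paths$modules, f)
    module_members[[tag]] <- mod$members$id
    if (!is.null(mod$subnetwork)) {
      f <- file.path(mod_dir, sprintf("module_%s_edges.tsv", tag))
      utils::write.table(mod$subnetwork$edges, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths$module_edges <- c(paths$module_edges, f)
    }
  }

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    gmt <- read_gmt(config$gmt)
    universe <- unique(unlist(stack$molecule_ids))
    enrichment <- enrich_modules(
      lapply(module_members, intersect, universe), gmt, universe,
      adjust = isTRUE(config$adjust_p))
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enrichment, paths$enrichment, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    params = unclass(params),
    laplacian_mode = config$laplacian_mode %||% "clip",
    zscore_cutoff = config$zscore_cutoff %||% 2,
    normalize = isTRUE(config$normalize),
    inputs = config[intersect(names(config),
                              c("omics", "labels", "side_matrix", "network",
                                "gmt"))],
    n_samples = n_samples(stack),
    n_labeled = length(stack$labeled_index),
    converged = isTRUE(state$converged),
    iterations = state$iterations,
    final_objective = utils::tail(state$objective_trace, 1),
    pi = state$pi)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(state = state, mapping = mapping, predictions = predictions,
                 modules = modules, enrichment = enrichment, paths = paths,
                 stack = stack, laplacians = laplacians))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
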