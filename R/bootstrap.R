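#' Fit the branching oncogenetic tree to a cohort
#'
#' Convenience wrapper: probability estimates, pairwise weights,
#' maximum-weight arborescence, and moment edge probabilities.
#'
#' @param matrix an [alteration_matrix()].
#' @return An [onco_tree()] with weights and probabilities filled.
#' @export
fit_branching <- function(matrix) {
  freq <- estimate_probabilities(matrix)
  tree <- optimal_branching(pair_weights(freq))
  edge_probabilities(tree, freq)
}

#' Fit the distance-based oncogenetic tree to a cohort
#'
#' Probability estimates, additive distances, neighbor-joining topology,
#' optionally followed by a maximum-likelihood branch-length refit.
#'
#' @param matrix an [alteration_matrix()].
#' @param ml_lengths refit branch lengths by maximum likelihood (default
#'   `FALSE`; the neighbor-joining lengths are already additive-consistent).
#' @return A [weighted_rooted_tree()].
#' @export
fit_distance <- function(matrix, ml_lengths = FALSE) {
  freq <- estimate_probabilities(matrix)
  tree <- build_topology(additive_distance(freq))
  if (ml_lengths) tree <- ml_edge_probabilities(tree, matrix)$tree
  tree
}

# canonical topology identifiers ------------------------------------------

# branching: sorted "child<parent" pairs; the pairs double as the edge units
# of bootstrap support
canonical_branching <- function(tree) {
  sort(paste0(tree$events, "<", tree$parent[tree$events]))
}

# distance: sorted leaf bipartitions, root pseudo-leaf included (a split is
# identified by the sorted leaves below the cut edge)
canonical_distance <- function(tree) wrt_splits(tree)

canonical_string <- function(units) paste(units, collapse = ";")

#' Nonparametric bootstrap of an oncogenetic tree fit
#'
#' Resamples the n tumors with replacement B times, refits the chosen tree
#' model on each resample, and tallies canonical topologies and
#' split/edge support.  Branching topologies are canonicalized as the sorted
#' list of `child<parent` pairs; distance topologies as the sorted set of
#' leaf bipartitions (root pseudo-leaf included).  Replicate b uses the
#' derived seed `seed + b`, so results are independent of execution order
#' and bit-reproducible.
#'
#' Events absent from a resample are retained (probability clamping keeps
#' every weight finite), so topologies stay comparable across replicates.
#'
#' @param matrix an [alteration_matrix()].
#' @param method `"branching"` or `"distance"`.
#' @param B number of bootstrap replicates.
#' @param seed master seed.
#' @return An object of class `bootstrap_result`: list with `B`, `seed`,
#'   `method`, `topology_counts` (named count vector, canonical string ->
#'   count), `split_support` (named fraction vector), `original_units`
#'   (splits/edges of the full-data tree), `original_topology`, and
#'   `replicate_units` (list of canonical unit sets, one per replicate).
#' @export
bootstrap <- function(matrix, method = c("branching", "distance"),
                      B = 1000L, seed = 1L) {
  stopifnot(inherits(matrix, "alteration_matrix"), B >= 1L)
  method <- match.arg(method)
  fit <- switch(method, branching = fit_branching, distance = fit_distance)
  canon <- switch(method, branching = canonical_branching,
                  distance = canonical_distance)
  n <- nrow(matrix)
  original <- canon(fit(matrix))
  units_list <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample.int(n, n, replace = TRUE)
    res <- alteration_matrix(unclass(matrix)[idx, , drop = FALSE],
                             sample_ids = paste0("b", seq_len(n)))
    units_list[[b]] <- canon(fit(res))
  }
  topo <- vapply(units_list, canonical_string, character(1))
  counts <- table(topo)
  counts <- stats::setNames(as.integer(counts), names(counts))
  all_units <- sort(unique(c(unlist(units_list), original)))
  support <- vapply(all_units, function(u)
    mean(vapply(units_list, function(s) u %in% s, logical(1))), numeric(1))
  structure(list(B = as.integer(B), seed = as.integer(seed), method = method,
                 topology_counts = counts, split_support = support,
                 original_units = original,
                 original_topology = canonical_string(original),
                 replicate_units = units_list),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%s method): B = %d, seed = %d\n", x$method, x$B,
              x$seed))
  cat(sprintf("  %d distinct topologies; original tree reconstructed %d/%d times\n",
              length(x$topology_counts),
              if (x$original_topology %in% names(x$topology_counts))
                x$topology_counts[[x$original_topology]] else 0L, x$B))
  invisible(x)
}

#' Consensus splits above a support threshold
#'
#' Reports every split/edge whose bootstrap support strictly exceeds the
#' threshold (the conventional display rule keeps splits occurring in more
#' than 10 percent of the bootstrap datasets), sorted by decreasing support,
#' together with the support of each split of the original full-data tree.
#'
#' @param result a [bootstrap()] result.
#' @param threshold support threshold in `[0, 1)`; strict inequality.
#' @return List of class `consensus_report` with `threshold`, `consensus`
#'   (data frame: unit, support, in_original) and `original` (data frame of
#'   the full-data tree's own units with their support).
#' @export
consensus_report <- function(result, threshold = 0.10) {
  stopifnot(inherits(result, "bootstrap_result"),
            threshold >= 0, threshold < 1)
  sup <- result$split_support
  keep <- sup > threshold
  units <- names(sup)[keep]
  o <- order(-sup[keep], units)
  consensus <- data.frame(unit = units[o], support = unname(sup[keep][o]),
                          in_original = units[o] %in% result$original_units,
                          stringsAsFactors = FALSE)
  orig <- data.frame(unit = result$original_units,
                     support = unname(sup[result$original_units]),
                     stringsAsFactors = FALSE)
  structure(list(threshold = threshold, consensus = consensus,
                 original = orig),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("Consensus splits with support > %.0f%%\n", 100 * x$threshold))
  print(x$consensus, row.names = FALSE)
  invisible(x)
}

#' Most frequent bootstrap topologies
#'
#' @param result a [bootstrap()] result.
#' @param top_m number of topologies to return (default all).
#' @return Data frame (topology, count), descending by count, ties broken
#'   lexicographically.
#' @export
frequent_trees <- function(result, top_m = Inf) {
  stopifnot(inherits(result, "bootstrap_result"))
  cnt <- result$topology_counts
  o <- order(-cnt, names(cnt))
  df <- data.frame(topology = names(cnt)[o], count = unname(cnt[o]),
                   stringsAsFactors = FALSE)
  utils::head(df, top_m)
}

#' Majority-parent consensus tree for branching bootstraps
#'
#' For each event picks its modal bootstrap parent.  The resulting parent
#' map need not be a valid arborescence; cycles are reported, never silently
#' repaired.
#'
#' @param result a branching-method [bootstrap()] result.
#' @return List with `parent` (modal parent per event), `valid` (whether the
#'   map is an arborescence) and `tree` (an [onco_tree()] if valid, else
#'   `NULL`).
#' @export
modal_parent_tree <- function(result) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (result$method != "branching")
    stop("modal_parent_tree applies to branching bootstraps only")
  pairs <- unlist(result$replicate_units)
  child <- sub("<.*$", "", pairs)
  par <- sub("^.*<", "", pairs)
  events <- sort(unique(child))
  modal <- vapply(events, function(ev) {
    tab <- sort(table(par[child == ev]), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  tree <- tryCatch(onco_tree(modal), error = function(e) NULL)
  list(parent = modal, valid = !is.null(tree), tree = tree)
}

#' Serialize a bootstrap result to JSON
#'
#' @param result a [bootstrap()] result.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
bootstrap_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "bootstrap_result"))
  obj <- list(B = result$B, seed = result$seed, method = result$method,
              topology_counts = as.list(result$topology_counts),
              split_support = as.list(result$split_support),
              original_topology = result$original_topology)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Write the frequent-trees table as plain text
#'
#' @param result a [bootstrap()] result.
#' @param path output path.
#' @param top_m number of topologies to include.
#' @export
write_frequent_trees <- function(result, path, top_m = Inf) {
  df <- frequent_trees(result, top_m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
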