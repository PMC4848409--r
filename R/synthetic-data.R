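#' Generative specification for a simulated tumor cohort
#'
#' Bundles a progression tree (branching [onco_tree()] with firing
#' probabilities, or a distance-model [weighted_rooted_tree()]), a cohort
#' size, observation error rates, and a seed.
#'
#' @param tree the generating tree.
#' @param n cohort size (>= 1).
#' @param eps_plus,eps_minus observation error probabilities in `[0, 0.5)`.
#' @param seed integer seed.
#' @export
generative_spec <- function(tree, n, eps_plus = 0, eps_minus = 0, seed = 1L) {
  if (!(inherits(tree, "onco_tree") || inherits(tree, "weighted_rooted_tree")))
    stop("tree must be an onco_tree or a weighted_rooted_tree")
  if (inherits(tree, "onco_tree") && is.null(tree$fire_prob))
    stop("onco_tree needs fire_prob for simulation")
  stopifnot(n >= 1)
  err <- error_model(eps_plus, eps_minus)  # validates the [0, 0.5) range
  structure(list(tree = tree, n = as.integer(n),
                 eps_plus = err$eps_plus, eps_minus = err$eps_minus,
                 seed = as.integer(seed)),
            class = "generative_spec")
}

# nodes ordered so that every parent precedes its children
topo_order <- function(nodes, parent) {
  out <- character()
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[parent[remaining] == "root" |
                         parent[remaining] %in% out]
    if (!length(ready)) stop("parent map is not a tree")
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

#' Simulate a tumor cohort from a progression tree
#'
#' Per tumor, edges fire independently with their probability, traversed
#' top-down (a child edge can only fire when its parent edge fired); an
#' event is truly present iff its whole root path fired.  Observed
#' indicators then flip 0 to 1 with `eps_plus` and 1 to 0 with `eps_minus`.
#' Fully reproducible from the spec's seed.
#'
#' @param spec a [generative_spec()].
#' @return An [alteration_matrix()] (tumors x events; for distance-model
#'   trees the events are the leaves).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  tree <- spec$tree
  if (inherits(tree, "onco_tree")) {
    nodes <- tree$events; parent <- tree$parent; p <- tree$fire_prob
    out_cols <- nodes
  } else {
    nodes <- tree$nodes; parent <- tree$parent; p <- tree$p
    out_cols <- tree$leaves
  }
  n <- spec$n
  set.seed(spec$seed)
  state <- matrix(FALSE, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in topo_order(nodes, parent)) {
    reach <- if (parent[[v]] == "root") rep(TRUE, n) else state[, parent[[v]]]
    state[, v] <- reach & (stats::runif(n) < p[[v]])
  }
  truth <- state[, out_cols, drop = FALSE] + 0L
  u <- matrix(stats::runif(n * length(out_cols)), n)
  obs <- ifelse(truth == 1L, (u >= spec$eps_minus) + 0L,
                (u < spec$eps_plus) + 0L)
  alteration_matrix(obs, sample_ids = paste0("T", seq_len(n)),
                    event_names = out_cols)
}

#' Deterministic fixture matrix with exact marginal counts
#'
#' Lays out a binary matrix whose column sums equal the given per-event
#' counts exactly and, when `any_altered` is given, whose number of nonzero
#' rows equals it exactly.  The layout is greedy and fully deterministic:
#' the first `any_altered` rows receive one event each (largest-count events
#' first), then each event's remaining 1s are stacked into already-altered
#' rows from the top.
#'
#' @param n number of samples.
#' @param counts named integer vector of per-event counts (each <= n).
#' @param any_altered optional target number of rows with at least one
#'   event; must satisfy `max(counts) <= any_altered <= min(n, sum(counts))`.
#' @return An [alteration_matrix()] with the events in the order given.
#' @export
fixture_from_counts <- function(n, counts, any_altered = NULL) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts > n))
    stop("infeasible: count for '", names(counts)[which.max(counts)],
         "' exceeds n = ", n)
  events <- names(counts)
  m <- matrix(0L, n, length(events), dimnames = list(paste0("S", seq_len(n)),
                                                     events))
  if (is.null(any_altered)) {
    for (ev in events) if (counts[[ev]] > 0L)
      m[seq_len(counts[[ev]]), ev] <- 1L
    return(alteration_matrix(m))
  }
  any_altered <- as.integer(any_altered)
  if (any_altered > min(n, sum(counts)))
    stop("infeasible: any_altered = ", any_altered, " exceeds min(n, sum ",
         "of counts) = ", min(n, sum(counts)))
  if (length(counts) && max(counts) > any_altered)
    stop("infeasible: any_altered = ", any_altered, " is below max count = ",
         max(counts))
  ord <- events[order(-counts, events)]
  placed <- stats::setNames(integer(length(events)), events)
  row <- 1L
  for (ev in ord) {  # phase 1: one event per altered row, largest first
    if (row > any_altered) break
    take <- min(counts[[ev]], any_altered - row + 1L)
    if (take > 0L) {
      m[seq(row, row + take - 1L), ev] <- 1L
      placed[[ev]] <- take
      row <- row + take
    }
  }
  if (row <= any_altered)
    stop("infeasible: counts cannot fill ", any_altered, " altered rows")
  for (ev in ord) {  # phase 2: stack the remainder into altered rows
    rem <- counts[[ev]] - placed[[ev]]
    if (rem > 0L) {
      free <- which(m[seq_len(any_altered), ev] == 0L)[seq_len(rem)]
      m[free, ev] <- 1L
    }
  }
  stopifnot(identical(unname(colSums(m)), as.numeric(counts)))
  alteration_matrix(m)
}

#' Marginal CNA counts of the six-gene breast carcinoma panel
#'
#' The per-gene alteration counts of the 963-tumor TCGA breast invasive
#' carcinoma cohort analysed by the models in this package: PIK3CA 51, AKT2
#' 22, KRAS 25, PTEN 55, ErbB2 121, CCND1 153, with 342 tumors altered in at
#' least one gene.
#'
#' @return Named integer vector of counts with attributes `n` (963) and
#'   `any_altered` (342).
#' @export
breast_cna_counts <- function() {
  counts <- c(PIK3CA = 51L, AKT2 = 22L, KRAS = 25L, PTEN = 55L,
              ErbB2 = 121L, CCND1 = 153L)
  attr(counts, "n") <- 963L
  attr(counts, "any_altered") <- 342L
  counts
}

#' Reference breast-carcinoma progression tree
#'
#' The branching topology inferred for the six-gene breast cohort: CCND1,
#' PTEN, AKT2 and ErbB2 attach directly to the root, with KRAS and PIK3CA
#' below ErbB2.  Edge firing probabilities are set so that the model
#' marginals reproduce the cohort frequencies exactly (e.g. the ErbB2 edge
#' fires with 121/963 and the KRAS edge with 25/121, so the KRAS marginal is
#' 25/963).
#'
#' Two variants are available.  The default `"sibling"` places KRAS and
#' PIK3CA as siblings under ErbB2, the only arrangement compatible with the
#' observed marginals (51 PIK3CA vs 25 KRAS of 963 violates
#' ancestor-frequency monotonicity for a KRAS -> PIK3CA edge).  The
#' `"chain"` variant (ErbB2 -> KRAS -> PIK3CA) caps the PIK3CA edge
#' probability at 1, so its model marginal is 25/963 rather than 51/963.
#'
#' @param variant `"sibling"` (default) or `"chain"`.
#' @param n cohort size (default 963).
#' @param eps_plus,eps_minus observation error rates (default 0).
#' @param seed simulation seed (default 1).
#' @return A [generative_spec()].
#' @export
paper_tree_fixture <- function(variant = c("sibling", "chain"), n = 963L,
                               eps_plus = 0, eps_minus = 0, seed = 1L) {
  variant <- match.arg(variant)
  counts <- breast_cna_counts()
  N <- attr(counts, "n")
  parent <- c(CCND1 = "root", PTEN = "root", AKT2 = "root", ErbB2 = "root",
              KRAS = "ErbB2",
              PIK3CA = if (variant == "sibling") "ErbB2" else "KRAS")
  pi <- c(CCND1 = counts[["CCND1"]] / N,
          PTEN = counts[["PTEN"]] / N,
          AKT2 = counts[["AKT2"]] / N,
          ErbB2 = counts[["ErbB2"]] / N,
          KRAS = counts[["KRAS"]] / counts[["ErbB2"]],
          PIK3CA = if (variant == "sibling")
            counts[["PIK3CA"]] / counts[["ErbB2"]]
          else min(1, counts[["PIK3CA"]] / counts[["KRAS"]]))
  tree <- onco_tree(parent, fire_prob = pi, cond_prob = pi)
  generative_spec(tree, n = n, eps_plus = eps_plus, eps_minus = eps_minus,
                  seed = seed)
}

#' Round-trip a generative specification through JSON
#'
#' @param spec a [generative_spec()].
#' @param path output path.
#' @export
spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "generative_spec"))
  tree <- spec$tree
  kind <- if (inherits(tree, "onco_tree")) "branching" else "distance"
  obj <- list(kind = kind, n = spec$n, eps_plus = spec$eps_plus,
              eps_minus = spec$eps_minus, seed = spec$seed)
  if (kind == "branching") {
    obj$parent <- as.list(tree$parent)
    obj$fire_prob <- as.list(tree$fire_prob)
  } else {
    obj$parent <- as.list(tree$parent)
    obj$length <- as.list(tree$length)
    obj$leaves <- tree$leaves
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' @rdname spec_json
#' @export
read_spec_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  parent <- unlist(obj$parent)
  tree <- if (obj$kind == "branching") {
    pi <- unlist(obj$fire_prob)[names(parent)]
    onco_tree(parent, fire_prob = pi, cond_prob = pi)
  } else {
    weighted_rooted_tree(parent, unlist(obj$length)[names(parent)],
                         obj$leaves)
  }
  generative_spec(tree, n = obj$n, eps_plus = obj$eps_plus,
                  eps_minus = obj$eps_minus, seed = obj$seed)
}
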