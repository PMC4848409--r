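#' Event distance matrix
#'
#' Pairwise additive distances between events plus the root-to-event
#' distances implied by the edge-firing model.
#'
#' @param D symmetric nonnegative k x k matrix with zero diagonal, dimnames
#'   set to the event names.
#' @param root_dist named nonnegative vector of root-to-event distances.
#' @export
event_distance <- function(D, root_dist) {
  events <- colnames(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D), !is.null(events),
            identical(rownames(D), events),
            setequal(names(root_dist), events))
  if (any(abs(diag(D)) > 1e-12)) stop("distance diagonal must be zero")
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(D < -1e-12) || any(root_dist < -1e-12))
    stop("distances must be nonnegative")
  structure(list(D = pmax(D, 0), root_dist = pmax(root_dist[events], 0)),
            class = "event_distance")
}

#' Additive event distances from co-occurrence probabilities
#'
#' Under the edge-firing model with branch length `-log p_e`, the path length
#' between the leaves of events i and j is
#' `D_ij = log p_i + log p_j - 2 log p_ij`, and the root-to-leaf distance is
#' `r_i = -log p_i`.  Clamped inputs with `p_ij <= min(p_i, p_j)` guarantee
#' `D_ij >= 0`.
#'
#' @param freq a `freq_estimates` object.
#' @return An [event_distance()].
#' @export
additive_distance <- function(freq) {
  check_freq(freq)
  p <- freq$marginal
  lj <- log(freq$joint)
  D <- outer(log(p), log(p), `+`) - 2 * lj
  diag(D) <- 0
  event_distance(pmax(D, 0), -log(p))
}

#' Weighted rooted tree with events at the leaves
#'
#' The distance-model tree: events are leaves, internal nodes are anonymous
#' hidden events, every edge has a nonnegative length interpreted as
#' `-log p_e` for firing probability `p_e`.
#'
#' @param parent named character vector over all non-root nodes (leaves and
#'   hidden nodes), value `"root"` or another node name.
#' @param edge_length named nonnegative numeric vector over the same nodes
#'   (length of the incoming edge).
#' @param leaves character vector naming which nodes are event leaves.
#' @export
weighted_rooted_tree <- function(parent, edge_length, leaves) {
  nodes <- names(parent)
  stopifnot(!is.null(nodes), !anyDuplicated(nodes),
            setequal(names(edge_length), nodes), all(leaves %in% nodes))
  if ("root" %in% nodes) stop("'root' is reserved")
  edge_length <- edge_length[nodes]
  if (any(edge_length < 0)) stop("branch lengths must be nonnegative")
  if (!all(parent %in% c("root", nodes)))
    stop("unknown parent node(s)")
  kids <- split(nodes, parent[nodes])
  for (v in setdiff(nodes, leaves))
    if (is.null(kids[[v]]) || !length(kids[[v]]))
      stop("hidden node '", v, "' has no children")
  for (v in leaves)
    if (!is.null(kids[[v]]) && length(kids[[v]]))
      stop("leaf '", v, "' has children")
  # acyclicity
  for (v in nodes) {
    cur <- v; seen <- character()
    while (cur != "root") {
      if (cur %in% seen) stop("cycle detected at '", v, "'")
      seen <- c(seen, cur); cur <- parent[[cur]]
    }
  }
  structure(list(nodes = nodes, parent = parent, length = edge_length,
                 leaves = leaves, p = exp(-edge_length)),
            class = "weighted_rooted_tree")
}

#' @export
print.weighted_rooted_tree <- function(x, ...) {
  cat(sprintf("Weighted rooted tree: %d leaves, %d hidden nodes\n",
              length(x$leaves), length(x$nodes) - length(x$leaves)))
  cat(write_newick(x), "\n")
  invisible(x)
}

# root-to-node depths (path length)
wrt_depths <- function(tree) {
  d <- stats::setNames(numeric(length(tree$nodes)), tree$nodes)
  pending <- tree$nodes
  while (length(pending)) {
    for (v in pending) {
      p <- tree$parent[[v]]
      if (p == "root" || !(p %in% pending)) {
        d[v] <- tree$length[[v]] + if (p == "root") 0 else d[[p]]
        pending <- setdiff(pending, v)
      }
    }
  }
  d
}

#' Leaf-to-leaf and root-to-leaf path lengths of a weighted rooted tree
#'
#' @param tree a [weighted_rooted_tree()].
#' @return An [event_distance()] over the tree's leaves.
#' @export
tree_distances <- function(tree) {
  stopifnot(inherits(tree, "weighted_rooted_tree"))
  depth <- wrt_depths(tree)
  lv <- tree$leaves
  anc <- lapply(lv, function(v) {
    path <- character(); cur <- v
    while (cur != "root") { path <- c(path, cur); cur <- tree$parent[[cur]] }
    c(path, "root")
  })
  names(anc) <- lv
  k <- length(lv)
  D <- matrix(0, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    common <- intersect(anc[[i]], anc[[j]])[1L]  # nearest common ancestor
    dm <- if (common == "root") 0 else depth[[common]]
    D[i, j] <- D[j, i] <- depth[[lv[i]]] + depth[[lv[j]]] - 2 * dm
  }
  event_distance(D, depth[lv])
}

# splits of the leaf set (root pseudo-leaf included): each non-root edge cuts
# the leaves below it from the rest; canonical id = sorted leaves below,
# joined by "+"
wrt_splits <- function(tree) {
  below <- stats::setNames(vector("list", length(tree$nodes)), tree$nodes)
  remaining <- tree$nodes
  while (length(remaining)) {
    for (v in remaining) {
      kids <- tree$nodes[tree$parent == v]
      if (!any(kids %in% remaining)) {
        below[[v]] <- if (v %in% tree$leaves) v
                      else sort(unique(unlist(below[kids])))
        remaining <- setdiff(remaining, v)
      }
    }
  }
  sort(unique(vapply(tree$nodes, function(v)
    paste(below[[v]], collapse = "+"), character(1))))
}

#' Build the distance-tree topology by neighbor joining
#'
#' Runs agglomerative neighbor joining over the k events plus a pseudo-leaf
#' for the normal (root) state, with `d(root, i) = r_i`, then re-roots the
#' tree at the pseudo-leaf.  Negative inferred branch lengths are clamped to
#' zero (with a warning), and internal edges of (near-)zero length are
#' collapsed so polytomies and direct root attachments are represented
#' faithfully.
#'
#' @param dist an [event_distance()].
#' @param collapse_tol internal edges shorter than this are collapsed
#'   (default 1e-9).
#' @return A [weighted_rooted_tree()].
#' @export
build_topology <- function(dist, collapse_tol = 1e-9) {
  stopifnot(inherits(dist, "event_distance"))
  events <- colnames(dist$D)
  k <- length(events)
  if (k == 1L)
    return(weighted_rooted_tree(
      stats::setNames("root", events),
      stats::setNames(dist$root_dist[[1L]], events), events))
  full <- matrix(0, k + 1L, k + 1L,
                 dimnames = list(c(".root.", events), c(".root.", events)))
  full[events, events] <- dist$D
  full[".root.", events] <- dist$root_dist
  full[events, ".root."] <- dist$root_dist
  phy <- ape::nj(stats::as.dist(full))
  if (any(phy$edge.length < -1e-9))
    warning("negative neighbor-joining branch lengths clamped to 0")
  phy$edge.length <- pmax(phy$edge.length, 0)
  tree <- root_at_pseudo_leaf(phy, ".root.")
  collapse_short_edges(tree, collapse_tol)
}

# orient an unrooted phylo away from the pseudo-leaf tip, which becomes the
# root; hidden nodes are renamed h1, h2, ... in traversal order
root_at_pseudo_leaf <- function(phy, pseudo) {
  tips <- phy$tip.label
  ntip <- length(tips)
  ridx <- match(pseudo, tips)
  edges <- rbind(phy$edge, phy$edge[, 2:1])
  lens <- c(phy$edge.length, phy$edge.length)
  name_of <- function(i) {
    if (i <= ntip) tips[i] else paste0(".n", i)
  }
  parent <- character(); len <- numeric()
  queue <- ridx
  seen <- ridx
  pname <- stats::setNames("root", name_of(ridx))
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    out <- which(edges[, 1L] == cur & !(edges[, 2L] %in% seen))
    for (e in out) {
      ch <- edges[e, 2L]
      parent[[name_of(ch)]] <- pname[[name_of(cur)]]
      len[[name_of(ch)]] <- lens[e]
      pname[[name_of(ch)]] <- name_of(ch)
      seen <- c(seen, ch)
      queue <- c(queue, ch)
    }
  }
  # the pseudo-leaf itself is the root: its one neighbor hangs off "root"
  # with the pendant length folded in
  pname <- NULL
  nodes <- names(parent)
  parent[parent == pseudo] <- "root"
  hidden <- setdiff(nodes, tips)
  rename <- stats::setNames(paste0("h", seq_along(hidden)), hidden)
  relab <- function(x) ifelse(x %in% names(rename), rename[x], x)
  new_parent <- stats::setNames(as.character(relab(parent)), relab(nodes))
  new_len <- stats::setNames(len, relab(nodes))
  weighted_rooted_tree(new_parent, new_len, setdiff(tips, pseudo))
}

# merge hidden nodes whose incoming edge is shorter than `tol` into their
# parent (restores polytomies and direct root attachments)
collapse_short_edges <- function(tree, tol) {
  repeat {
    hidden <- setdiff(tree$nodes, tree$leaves)
    short <- hidden[tree$length[hidden] <= tol]
    if (!length(short)) return(tree)
    v <- short[1L]
    tgt <- tree$parent[[v]]
    parent <- tree$parent
    parent[parent == v] <- tgt
    parent <- parent[names(parent) != v]
    len <- tree$length[names(parent)]
    tree <- weighted_rooted_tree(parent, len, tree$leaves)
  }
}

#' Exact log-likelihood of a cohort under a distance-model tree
#'
#' Each edge fires independently with `p_e = exp(-length)`, a child edge only
#' when its parent edge fired; an event is observed iff every edge on its
#' root path fired (no observation-error layer).  The per-sample pattern
#' probability is computed exactly by enumerating all downward-closed
#' edge-firing states (at most 16 edges).
#'
#' @param tree a [weighted_rooted_tree()].
#' @param matrix an [alteration_matrix()] whose events are exactly the
#'   tree's leaves.
#' @return The summed log-likelihood.  If any observed pattern has
#'   probability zero the result is `-Inf` with attribute
#'   `impossible_patterns`.
#' @export
tree_loglik <- function(tree, matrix) {
  stopifnot(inherits(tree, "weighted_rooted_tree"),
            inherits(matrix, "alteration_matrix"))
  if (!setequal(colnames(matrix), tree$leaves))
    stop("matrix events and tree leaves differ")
  if (length(tree$nodes) > 16L)
    stop("exact enumeration supports at most 16 edges")
  dist <- wrt_pattern_distribution(tree)
  m <- unclass(matrix)[, tree$leaves, drop = FALSE]
  key <- apply(m, 1L, paste, collapse = "")
  p <- dist[key]
  if (any(p <= 0 | !is.finite(p))) {
    bad <- sort(unique(key[p <= 0 | !is.finite(p)]))
    out <- -Inf
    attr(out, "impossible_patterns") <- bad
    return(out)
  }
  sum(log(p))
}

# exact distribution over the 2^k leaf patterns by edge-state enumeration
wrt_pattern_distribution <- function(tree, p = tree$p) {
  nodes <- tree$nodes
  dc <- dc_sets(list(events = nodes, parent = tree$parent))
  logP <- dc_log_prob(dc, stats::setNames(p, nodes))
  leaf_idx <- match(tree$leaves, nodes)
  keys <- apply(dc$Tmat[, leaf_idx, drop = FALSE] * 1L, 1L, paste,
                collapse = "")
  out <- tapply(exp(logP), keys, sum)
  k <- length(tree$leaves)
  all_keys <- apply(all_patterns(k), 1L, paste, collapse = "")
  res <- stats::setNames(numeric(length(all_keys)), all_keys)
  res[names(out)] <- out
  res
}

#' Maximum-likelihood edge probabilities on a fixed distance-tree topology
#'
#' Re-estimates every branch length by maximizing [tree_loglik()] over the
#' per-edge firing probabilities `p_e` in `[1e-6, 1]`, with bounded
#' multistart optimization (input lengths, a flat start, and deterministic
#' logit perturbations).  The returned objective is never below the
#' objective of the input lengths.
#'
#' @param topology a [weighted_rooted_tree()].
#' @param matrix an [alteration_matrix()] over the tree's leaves.
#' @return List with `tree` (lengths replaced by `-log p_e` of the fit) and
#'   `loglik`.
#' @export
ml_edge_probabilities <- function(topology, matrix) {
  stopifnot(inherits(topology, "weighted_rooted_tree"),
            inherits(matrix, "alteration_matrix"))
  if (length(topology$nodes) > 16L)
    stop("exact enumeration supports at most 16 edges")
  nodes <- topology$nodes
  dc <- dc_sets(list(events = nodes, parent = topology$parent))
  leaf_idx <- match(topology$leaves, nodes)
  keys <- apply(dc$Tmat[, leaf_idx, drop = FALSE] * 1L, 1L, paste,
                collapse = "")
  m <- unclass(matrix)[, topology$leaves, drop = FALSE]
  obs <- table(apply(m, 1L, paste, collapse = ""))
  cnt <- as.numeric(obs)
  obs_key <- names(obs)

  lo <- 1e-6; hi <- 1 - 1e-9
  negll <- function(p) {
    logP <- dc_log_prob(dc, stats::setNames(p, nodes))
    probs <- tapply(exp(logP), keys, sum)
    pr <- probs[obs_key]
    if (anyNA(pr) || any(pr <= 0)) return(1e12)
    -sum(cnt * log(pr))
  }

  p0 <- pmin(pmax(topology$p, lo), hi)
  nE <- length(nodes)
  starts <- list(p0, rep(0.5, nE))
  for (s in 1:3) {
    off <- c(0.75, -0.75, 1.5)[s] * (-1)^seq_len(nE)
    starts[[s + 2L]] <- pmin(pmax(stats::plogis(stats::qlogis(p0) + off),
                                  lo), hi)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B", lower = rep(lo, nE),
                   upper = rep(hi, nE), control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")
  if (best$value > negll(p0)) best <- list(par = p0, value = negll(p0))
  p_hat <- stats::setNames(pmin(pmax(best$par, lo), 1), nodes)
  tree <- weighted_rooted_tree(topology$parent,
                               stats::setNames(-log(p_hat), nodes),
                               topology$leaves)
  list(tree = tree, loglik = -best$value)
}

#' Exhaustive maximum-likelihood topology search (slow path)
#'
#' Enumerates every unrooted binary topology over the events plus the root
#' pseudo-leaf (via `phangorn::allTrees`), roots each at the pseudo-leaf,
#' fits branch lengths by [ml_edge_probabilities()], and returns the
#' highest-likelihood tree.  Intended as a cross-check for small panels.
#'
#' @param matrix an [alteration_matrix()] with at most 5 events.
#' @return List with `tree` and `loglik`.
#' @export
exhaustive_ml_topology <- function(matrix) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  if (ncol(matrix) > 5L) stop("exhaustive search limited to 5 events")
  if (!requireNamespace("phangorn", quietly = TRUE))
    stop("phangorn is required for the exhaustive topology search")
  labels <- c(".root.", colnames(matrix))
  cand <- phangorn::allTrees(length(labels), rooted = FALSE,
                             tip.label = labels)
  best <- NULL
  for (i in seq_along(cand)) {
    phy <- cand[[i]]  # [[ restores tip labels on a compressed multiPhylo
    phy$edge.length <- rep(log(2), nrow(phy$edge))
    wrt <- root_at_pseudo_leaf(phy, ".root.")
    fit <- ml_edge_probabilities(wrt, matrix)
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  best
}

#' Serialize a weighted rooted tree to Newick
#'
#' Hidden nodes are unlabeled; branch lengths are written with full
#' precision.
#'
#' @param tree a [weighted_rooted_tree()].
#' @param path optional output path; if `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "weighted_rooted_tree"))
  kids <- function(v) sort(tree$nodes[tree$parent == v])
  rec <- function(v) {
    ch <- kids(v)
    lab <- if (v %in% tree$leaves) v else ""
    inner <- if (length(ch))
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")")
    else ""
    len <- if (v == "root") "" else sprintf(":%.10g", tree$length[[v]])
    paste0(inner, lab, len)
  }
  ch <- kids("root")
  nwk <- paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","),
                ")root;")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Serialize a weighted rooted tree to JSON
#'
#' @param tree a [weighted_rooted_tree()].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
wrt_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "weighted_rooted_tree"))
  obj <- list(
    leaves = tree$leaves,
    nodes = stats::setNames(lapply(tree$nodes, function(v)
      list(parent = tree$parent[[v]], length = tree$length[[v]],
           p = tree$p[[v]])), tree$nodes))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
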