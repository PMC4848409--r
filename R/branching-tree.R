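#' Oncogenetic branching tree
#'
#' A rooted directed tree over \{root\} and the events: every event has
#' exactly one parent (another event or the root), all edges point away from
#' the root.  Edges optionally carry the fitted arborescence weight, the
#' conditional probability of the child given its parent, and the firing
#' probability used by the generative model.
#'
#' @param parent named character vector: for each event, the name of its
#'   parent (`"root"` or another event).
#' @param edge_weight,fire_prob,cond_prob optional named numeric vectors over
#'   the same events.
#' @return An object of class `onco_tree`.
#' @export
onco_tree <- function(parent, edge_weight = NULL, fire_prob = NULL,
                      cond_prob = NULL) {
  events <- names(parent)
  if (is.null(events) || anyDuplicated(events))
    stop("`parent` must be named by unique event names")
  if ("root" %in% events) stop("'root' is reserved for the normal state")
  if (!all(parent %in% c("root", events)))
    stop("unknown parent name(s): ",
         paste(setdiff(parent, c("root", events)), collapse = ", "))
  # acyclicity / reachability from root
  for (ev in events) {
    seen <- character()
    cur <- ev
    while (cur != "root") {
      if (cur %in% seen) stop("cycle detected through event '", ev, "'")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  chk <- function(x, lo = -Inf, hi = Inf) {
    if (is.null(x)) return(NULL)
    stopifnot(setequal(names(x), events))
    x <- x[events]
    if (any(x < lo - 1e-12 | x > hi + 1e-12))
      stop("value out of [", lo, ", ", hi, "]")
    pmin(pmax(x, lo), hi)
  }
  structure(list(events = events, parent = parent,
                 edge_weight = chk(edge_weight),
                 fire_prob = chk(fire_prob, 0, 1),
                 cond_prob = chk(cond_prob, 0, 1)),
            class = "onco_tree")
}

#' @export
print.onco_tree <- function(x, ...) {
  cat("Oncogenetic branching tree (", length(x$events), " events)\n", sep = "")
  for (ev in x$events) {
    lab <- sprintf("  %s -> %s", x$parent[[ev]], ev)
    if (!is.null(x$cond_prob))
      lab <- sprintf("%s  [p = %.3f]", lab, x$cond_prob[[ev]])
    cat(lab, "\n")
  }
  invisible(x)
}

#' Observation error model
#'
#' Shared false-positive (`eps_plus`, a truly absent event observed present)
#' and false-negative (`eps_minus`) probabilities applied independently to
#' every event indicator.
#'
#' @param eps_plus,eps_minus probabilities in `[0, 0.5)`.
#' @export
error_model <- function(eps_plus = 0, eps_minus = 0) {
  if (eps_plus < 0 || eps_plus >= 0.5 || eps_minus < 0 || eps_minus >= 0.5)
    stop("error probabilities must lie in [0, 0.5)")
  structure(list(eps_plus = eps_plus, eps_minus = eps_minus),
            class = "error_model")
}

#' Pairwise edge weights from event probabilities
#'
#' For ordered pairs (i, j) of distinct events the weight combines a nesting
#' term and a correlation term:
#' `w(i -> j) = 2 log p_ij - log(p_i + p_j) - log p_i - log p_j`.
#' The root is treated as an always-present event (`p_root = 1`,
#' `p_root,j = p_j`), which gives `w(root -> j) = log(p_j / (1 + p_j))`.
#'
#' @param freq a `freq_estimates` object (clamped, see
#'   [estimate_probabilities()]).
#' @return A `(k + 1) x k` matrix of finite weights; rows are candidate
#'   parents (`root` first), columns are child events.  Diagonal pairs are
#'   `NA`.
#' @export
pair_weights <- function(freq) {
  check_freq(freq)
  p <- freq$marginal
  pj <- freq$joint
  events <- names(p)
  k <- length(events)
  W <- matrix(NA_real_, k + 1L, k,
              dimnames = list(c("root", events), events))
  W["root", ] <- log(p / (1 + p))
  for (i in events) for (j in events) {
    if (i == j) next
    W[i, j] <- 2 * log(pj[i, j]) - log(p[i] + p[j]) - log(p[i]) - log(p[j])
  }
  W
}

# Chu-Liu/Edmonds maximum-weight arborescence over a complete digraph.
# `edges`: data.frame(tail, head, weight, id); ties in the best-incoming
# choice broken by lexicographic tail name so results are bit-reproducible.
edmonds_branching <- function(edges, nodes, root) {
  sel <- list()
  for (v in setdiff(nodes, root)) {
    inc <- edges[edges$head == v, , drop = FALSE]
    if (!nrow(inc)) stop("node '", v, "' has no incoming edge")
    inc <- inc[order(-inc$weight, inc$tail), , drop = FALSE]
    sel[[v]] <- inc[1L, ]
  }
  sel_tail <- vapply(sel, function(e) e$tail, character(1))
  # cycle detection over selected edges
  cyc <- NULL
  for (v in names(sel_tail)) {
    path <- character()
    cur <- v
    while (cur != root && !is.na(match(cur, names(sel_tail)))) {
      if (cur %in% path) {
        i <- match(cur, path)
        cyc <- path[seq(i, length(path))]
        break
      }
      path <- c(path, cur)
      cur <- sel_tail[[cur]]
    }
    if (!is.null(cyc)) break
  }
  if (is.null(cyc))
    return(vapply(sel, function(e) e$id, integer(1)))

  cnode <- paste0("#", paste(sort(cyc), collapse = "+"))
  sel_w <- vapply(sel, function(e) e$weight, numeric(1))
  in_cyc <- edges$head %in% cyc
  out_cyc <- edges$tail %in% cyc
  new_edges <- edges[!(in_cyc & out_cyc), , drop = FALSE]
  # entering edges are reweighted by the selected cycle edge they displace
  adj <- new_edges$head %in% cyc
  new_edges$weight[adj] <- new_edges$weight[adj] -
    sel_w[new_edges$head[adj]]
  new_edges$head[adj] <- cnode
  new_edges$tail[new_edges$tail %in% cyc] <- cnode
  new_edges <- new_edges[new_edges$tail != new_edges$head, , drop = FALSE]
  new_nodes <- c(setdiff(nodes, cyc), cnode)
  res <- edmonds_branching(new_edges, new_nodes, root)
  # expand: the original edge entering the cycle displaces one cycle edge
  chosen <- edges[match(res, edges$id), , drop = FALSE]
  enter <- chosen[chosen$head %in% cyc, , drop = FALSE]
  stopifnot(nrow(enter) == 1L)
  keep_cycle <- setdiff(cyc, enter$head)
  cycle_ids <- vapply(sel[keep_cycle], function(e) e$id, integer(1))
  c(res, cycle_ids)
}

#' Maximum-weight branching (arborescence) rooted at the normal state
#'
#' Finds the parent assignment maximizing the total edge weight among all
#' arborescences rooted at `root`, by the Chu-Liu/Edmonds optimum-branching
#' algorithm.  Ties are broken deterministically (lexicographic parent name
#' within each best-incoming choice).
#'
#' @param weights a `(k + 1) x k` weight matrix as produced by
#'   [pair_weights()] (`root` row first, `NA` diagonal allowed).
#' @return An [onco_tree()] with `edge_weight` filled.
#' @export
optimal_branching <- function(weights) {
  events <- colnames(weights)
  stopifnot(identical(rownames(weights)[1L], "root"),
            all(rownames(weights)[-1L] == events))
  df <- expand.grid(tail = rownames(weights), head = events,
                    stringsAsFactors = FALSE)
  df$weight <- weights[cbind(df$tail, df$head)]
  df <- df[df$tail != df$head & is.finite(df$weight), , drop = FALSE]
  df$id <- seq_len(nrow(df))
  ids <- edmonds_branching(df, c("root", events), "root")
  chosen <- df[match(ids, df$id), ]
  parent <- stats::setNames(chosen$tail, chosen$head)[events]
  onco_tree(parent,
            edge_weight = stats::setNames(chosen$weight, chosen$head)[events])
}

#' Conditional and firing probabilities on a fixed topology
#'
#' Moment estimates from the event probabilities: for an event `j` with
#' parent `i`, `cond_prob(j) = p_ij / p_i`; for root children it is the
#' marginal `p_j`.  The firing probability is the conditional probability
#' capped into `[0, 1]`.
#'
#' @param tree an [onco_tree()] (topology is used; probabilities replaced).
#' @param freq a `freq_estimates` object.
#' @return The tree with `cond_prob` and `fire_prob` filled.
#' @export
edge_probabilities <- function(tree, freq) {
  stopifnot(inherits(tree, "onco_tree"))
  check_freq(freq)
  if (!all(tree$events %in% names(freq$marginal)))
    stop("frequency estimates missing events: ",
         paste(setdiff(tree$events, names(freq$marginal)), collapse = ", "))
  cp <- vapply(tree$events, function(j) {
    i <- tree$parent[[j]]
    if (i == "root") freq$marginal[[j]]
    else freq$joint[i, j] / freq$marginal[[i]]
  }, numeric(1))
  cp <- pmin(pmax(cp, 0), 1)
  onco_tree(tree$parent, edge_weight = tree$edge_weight,
            cond_prob = cp, fire_prob = cp)
}

# Enumerate downward-closed true-event sets for a topology.
# Returns Tmat (nT x k logical: membership) and Amat (nT x k logical: edge j
# "active", i.e. j's parent is in T ∪ {root} so edge j contributes a factor).
dc_sets <- function(tree) {
  k <- length(tree$events)
  if (k > 20L) stop("exact enumeration supports at most 20 events")
  pidx <- match(tree$parent, tree$events)  # NA for root children
  n_all <- 2L^k
  Tmat <- matrix(FALSE, n_all, k)
  for (j in seq_len(k))
    Tmat[, j] <- bitwAnd(seq_len(n_all) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  parent_in <- matrix(TRUE, n_all, k)
  has_par <- !is.na(pidx)
  parent_in[, has_par] <- Tmat[, pidx[has_par], drop = FALSE]
  closed <- rowSums(Tmat & !parent_in) == 0L
  list(Tmat = Tmat[closed, , drop = FALSE],
       Amat = parent_in[closed, , drop = FALSE])
}

# log P(T) for every downward-closed set given firing probabilities
dc_log_prob <- function(dc, pi) {
  l1 <- log(pi)
  l0 <- log1p(-pi)
  l0[pi >= 1] <- -Inf
  A <- dc$Amat
  Tm <- dc$Tmat
  on <- (A & Tm) %*% ifelse(is.finite(l1), l1, 0) +
        (A & !Tm) %*% ifelse(is.finite(l0), l0, 0)
  # -Inf bookkeeping for boundary probabilities
  bad <- (A & Tm) %*% (!is.finite(l1)) + (A & !Tm) %*% (!is.finite(l0))
  on[bad > 0] <- -Inf
  as.numeric(on)
}

#' Likelihood of an observed alteration pattern
#'
#' Generative model: starting from the root, each edge fires independently
#' with its firing probability, a child edge only being reachable when its
#' parent fired; the true indicator of an event is 1 iff every edge on its
#' root path fired.  The observed indicator then flips 0 to 1 with
#' `eps_plus` and 1 to 0 with `eps_minus`.  The likelihood sums over all
#' downward-closed true-event sets (exact enumeration, at most 20 events).
#'
#' @param tree an [onco_tree()] with `fire_prob` set.
#' @param err an [error_model()].
#' @param pattern 0/1 vector over the tree's events (named or in event
#'   order).
#' @return The pattern probability.
#' @export
pattern_likelihood <- function(tree, err, pattern) {
  stopifnot(inherits(tree, "onco_tree"), inherits(err, "error_model"))
  if (is.null(tree$fire_prob)) stop("tree has no firing probabilities")
  k <- length(tree$events)
  if (!is.null(names(pattern))) pattern <- pattern[tree$events]
  stopifnot(length(pattern) == k, all(pattern %in% c(0, 1)))
  dc <- dc_sets(tree)
  sum(pattern_prob_rows(dc, tree$fire_prob, err, matrix(pattern, 1L)))
}

# probabilities of one or more observed patterns (rows of `O`)
pattern_prob_rows <- function(dc, pi, err, O) {
  logP <- dc_log_prob(dc, pi)
  P <- exp(logP)
  Tm <- dc$Tmat * 1
  tp <- Tm %*% t(O)                  # true 1 observed 1
  fn <- Tm %*% t(1 - O)              # true 1 observed 0
  fp <- (1 - Tm) %*% t(O)            # true 0 observed 1
  tn <- (1 - Tm) %*% t(1 - O)        # true 0 observed 0
  pow <- function(b, e) if (b == 0) (e == 0) * 1 else b^e
  E <- pow(1 - err$eps_minus, tp) * pow(err$eps_minus, fn) *
       pow(err$eps_plus, fp) * pow(1 - err$eps_plus, tn)
  as.numeric(crossprod(E, P))
}

# full distribution over the 2^k observable patterns (used by tests and fits)
pattern_distribution <- function(tree, err) {
  k <- length(tree$events)
  O <- all_patterns(k)
  dc <- dc_sets(tree)
  stats::setNames(pattern_prob_rows(dc, tree$fire_prob, err, O),
                  apply(O, 1L, paste, collapse = ""))
}

all_patterns <- function(k) {
  O <- matrix(0L, 2L^k, k)
  for (j in seq_len(k))
    O[, j] <- (bitwAnd(seq_len(2L^k) - 1L, bitwShiftL(1L, j - 1L)) > 0L) + 0L
  O
}

#' Maximum-likelihood fit of firing probabilities and error rates
#'
#' On a fixed topology, maximizes the cohort log-likelihood (sum over samples
#' of the log pattern probability) over the per-edge firing probabilities and
#' a shared false-positive/false-negative error pair, by bounded multistart
#' quasi-Newton optimization (5 starts: the moment estimate with small error
#' rates plus 4 deterministic logit perturbations).  The returned objective
#' is guaranteed to be at least the objective at the moment-based start.
#'
#' @param matrix an [alteration_matrix()].
#' @param topology an [onco_tree()] whose events match the matrix columns.
#' @param eps_upper upper bound for both error rates (default 0.3).
#' @param fix_eps optional length-2 numeric `c(eps_plus, eps_minus)` to hold
#'   the error rates fixed while fitting the firing probabilities.
#' @return List with `tree` (topology with fitted `fire_prob`), `error`
#'   (an [error_model()]), and `loglik`.
#' @export
fit_error_model <- function(matrix, topology, eps_upper = 0.3,
                            fix_eps = NULL) {
  stopifnot(inherits(matrix, "alteration_matrix"),
            inherits(topology, "onco_tree"))
  if (!setequal(colnames(matrix), topology$events))
    stop("matrix events and tree events differ")
  m <- unclass(matrix)[, topology$events, drop = FALSE]
  k <- length(topology$events)
  key <- apply(m, 1L, paste, collapse = "")
  tab <- table(key)
  O <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
  cnt <- as.numeric(tab)
  dc <- dc_sets(topology)

  eps_lo <- 1e-6
  negll <- function(par) {
    pi <- par[seq_len(k)]
    err <- if (is.null(fix_eps)) error_model(par[k + 1L], par[k + 2L])
           else error_model(fix_eps[1L], fix_eps[2L])
    p <- pattern_prob_rows(dc, pi, err, O)
    if (any(!is.finite(p)) || any(p <= 0)) return(1e12)
    -sum(cnt * log(p))
  }

  freq <- estimate_probabilities(matrix)
  mom <- edge_probabilities(topology, freq)
  pi0 <- pmin(pmax(mom$cond_prob, eps_lo), 1 - eps_lo)
  base <- if (is.null(fix_eps)) c(pi0, 0.01, 0.01) else pi0
  lower <- if (is.null(fix_eps)) c(rep(eps_lo, k), 0, 0) else rep(eps_lo, k)
  upper <- if (is.null(fix_eps)) c(rep(1 - eps_lo, k), eps_upper, eps_upper)
           else rep(1 - eps_lo, k)

  starts <- list(base)
  for (s in 1:4) {
    off <- c(0.75, -0.75, 1.5, -1.5)[s] * (-1)^seq_len(k)
    pis <- stats::plogis(stats::qlogis(pi0) + off)
    pis <- pmin(pmax(pis, eps_lo), 1 - eps_lo)
    starts[[s + 1L]] <- if (is.null(fix_eps))
      c(pis, 0.05 * s / 4, 0.05 * s / 4) else pis
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500, factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")
  # contract: never worse than the moment start
  if (best$value > negll(base)) best <- list(par = base, value = negll(base))
  if (!is.finite(best$value))
    stop("non-finite likelihood at the optimum; check for impossible ",
         "patterns under the fitted boundary probabilities")

  pi_hat <- stats::setNames(best$par[seq_len(k)], topology$events)
  err_hat <- if (is.null(fix_eps))
    error_model(best$par[k + 1L], best$par[k + 2L])
  else error_model(fix_eps[1L], fix_eps[2L])
  list(tree = onco_tree(topology$parent, edge_weight = topology$edge_weight,
                        fire_prob = pi_hat, cond_prob = pi_hat),
       error = err_hat, loglik = -best$value)
}

#' Serialize an oncogenetic tree to DOT
#'
#' @param tree an [onco_tree()].
#' @param path optional output path; if `NULL` the DOT text is returned.
#' @export
onco_tree_dot <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "onco_tree"))
  lines <- c("digraph oncotree {")
  for (ev in tree$events) {
    lab <- if (!is.null(tree$cond_prob))
      sprintf(" [label=%.4g]", tree$cond_prob[[ev]]) else ""
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s", tree$parent[[ev]],
                              ev, lab))
  }
  lines <- c(lines, "}")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize an oncogenetic tree to JSON
#'
#' Schema: `{event: {parent, weight, fire_prob, cond_prob}}`.
#'
#' @param tree an [onco_tree()].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
onco_tree_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "onco_tree"))
  obj <- stats::setNames(lapply(tree$events, function(ev) {
    rec <- list(parent = tree$parent[[ev]])
    if (!is.null(tree$edge_weight)) rec$weight <- tree$edge_weight[[ev]]
    if (!is.null(tree$fire_prob)) rec$fire_prob <- tree$fire_prob[[ev]]
    if (!is.null(tree$cond_prob)) rec$cond_prob <- tree$cond_prob[[ev]]
    rec
  }), tree$events)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
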