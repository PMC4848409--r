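# Shared fixtures and independent oracles for the test suite.

# hand-built probability estimates (bypasses counting, for micro-examples)
make_freq <- function(marginal, joint, n = 100L) {
  k <- length(marginal)
  events <- names(marginal)
  stopifnot(identical(dim(joint), c(k, k)))
  dimnames(joint) <- list(events, events)
  structure(list(n = n, marginal = marginal, joint = joint,
                 pseudo_floor = 1 / (2 * n)),
            class = "freq_estimates")
}

canon_parent <- function(parent)
  paste(sort(paste0(names(parent), "<", parent)), collapse = ";")

# exhaustive maximum-weight arborescence search: enumerates every parent
# map, keeps arborescences, maximizes total weight (independent of the
# Chu-Liu/Edmonds path)
brute_arborescence <- function(W) {
  events <- colnames(W)
  k <- length(events)
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(0:k), k)))  # 0 = root, i = events[i]
  keep <- rep(TRUE, nrow(grid))
  for (j in seq_len(k)) keep <- keep & grid[, j] != j  # no self-parents
  grid <- grid[keep, , drop = FALSE]
  # arborescence iff k parent-jumps from every node reach the root
  reach <- grid
  for (t in seq_len(k)) {
    nz <- reach > 0L
    reach[nz] <- grid[cbind(row(reach)[nz], reach[nz])]
  }
  grid <- grid[rowSums(reach) == 0L, , drop = FALSE]
  tails <- matrix(c("root", events)[grid + 1L], nrow(grid))
  tot <- rowSums(matrix(W[cbind(as.vector(tails),
                               rep(events, each = nrow(grid)))],
                        nrow(grid)))
  best <- which.max(tot)
  list(parent = stats::setNames(tails[best, ], events),
       weight = tot[best])
}

# chain-rule enumeration over ALL 2^k true-event vectors (invalid ones get
# probability zero), then the error layer; independent of the
# downward-closed-set machinery in the package
oracle_pattern_prob <- function(tree, err, pattern) {
  events <- tree$events
  k <- length(events)
  pattern <- if (is.null(names(pattern))) pattern else pattern[events]
  total <- 0
  for (code in 0:(2^k - 1)) {
    truth <- as.integer(intToBits(code)[seq_len(k)])
    p <- 1
    for (j in seq_len(k)) {
      par <- tree$parent[[events[j]]]
      reached <- par == "root" || truth[match(par, events)] == 1L
      pj <- tree$fire_prob[[events[j]]]
      p <- p * if (reached) (if (truth[j]) pj else 1 - pj)
               else (if (truth[j]) 0 else 1)
    }
    e <- prod(ifelse(truth == 1L,
                     ifelse(pattern == 1L, 1 - err$eps_minus, err$eps_minus),
                     ifelse(pattern == 1L, err$eps_plus, 1 - err$eps_plus)))
    total <- total + p * e
  }
  total
}

# pruning recursion for the distance-model pattern probability; independent
# of the edge-state enumeration in the package
oracle_wrt_pattern_prob <- function(tree, pattern) {
  pattern <- pattern[tree$leaves]
  kids <- function(v) tree$nodes[tree$parent == v]
  all_zero_below <- function(v) {
    if (v %in% tree$leaves) return(pattern[[v]] == 0L)
    all(vapply(kids(v), all_zero_below, logical(1)))
  }
  f <- function(v) {  # P(observed sub-pattern | v reached)
    if (v %in% tree$leaves) return(as.numeric(pattern[[v]] == 1L))
    prod(vapply(kids(v), function(c) {
      pc <- tree$p[[c]]
      down <- if (c %in% tree$leaves) as.numeric(pattern[[c]] == 1L) else f(c)
      zero <- as.numeric(all_zero_below(c))
      pc * down + (1 - pc) * zero
    }, numeric(1)))
  }
  prod(vapply(kids("root"), function(c) {
    pc <- tree$p[[c]]
    down <- if (c %in% tree$leaves) as.numeric(pattern[[c]] == 1L) else f(c)
    zero <- as.numeric(all_zero_below(c))
    pc * down + (1 - pc) * zero
  }, numeric(1)))
}

# random weighted rooted tree: hidden nodes always have >= 2 children,
# branch lengths in [0.1, 1] so neighbor joining is exact
rand_rooted_tree <- function(k, seed) {
  set.seed(seed)
  leaves <- paste0("E", seq_len(k))
  parent <- character()
  hid <- 0L
  grow <- function(members, par) {
    if (length(members) == 1L) {
      parent[[members]] <<- par
      return(invisible())
    }
    ngroups <- if (length(members) == 2L) 2L
               else sample(2:min(3L, length(members)), 1L)
    groups <- split(members, sort(rep_len(seq_len(ngroups), length(members))))
    for (g in groups) {
      if (length(g) == 1L) parent[[g]] <<- par
      else {
        hid <<- hid + 1L
        h <- paste0("h", hid)
        parent[[h]] <<- par
        grow(g, h)
      }
    }
  }
  grow(sample(leaves), "root")
  len <- stats::setNames(stats::runif(length(parent), 0.1, 1),
                         names(parent))
  weighted_rooted_tree(parent, len, leaves)
}

# random branching tree over k events with firing probabilities in a range
rand_onco_tree <- function(k, seed, pi_range = c(0.2, 0.8)) {
  set.seed(seed)
  events <- paste0("G", seq_len(k))
  parent <- stats::setNames(character(k), events)
  for (j in seq_len(k))
    parent[j] <- if (j == 1L) "root"
                 else sample(c("root", events[seq_len(j - 1L)]), 1L)
  pi <- stats::setNames(stats::runif(k, pi_range[1L], pi_range[2L]), events)
  onco_tree(parent, fire_prob = pi, cond_prob = pi)
}

rand_weights <- function(k, seed) {
  set.seed(seed)
  events <- LETTERS[seq_len(k)]
  W <- matrix(stats::runif((k + 1) * k, -3, 1), k + 1, k,
              dimnames = list(c("root", events), events))
  for (e in events) W[e, e] <- NA
  W
}
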