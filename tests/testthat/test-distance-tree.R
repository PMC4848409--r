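test_that("additive distances match the model algebra", {
  fr <- make_freq(c(A = 0.8, B = 0.4), matrix(c(0.8, 0.4, 0.4, 0.4), 2))
  d <- additive_distance(fr)
  expect_equal(d$D["A", "B"], log(2), tolerance = 1e-9)   # nested pair
  expect_equal(diag(d$D), c(A = 0, B = 0))
  expect_equal(unname(d$root_dist), -log(c(0.8, 0.4)))
  # independent events: leaf paths meet exactly at the root
  fri <- make_freq(c(A = 0.5, B = 0.3), matrix(c(0.5, 0.15, 0.15, 0.3), 2))
  di <- additive_distance(fri)
  expect_equal(di$D["A", "B"], di$root_dist[["A"]] + di$root_dist[["B"]],
               tolerance = 1e-12)
})

test_that("neighbor joining inverts exact model distances", {
  for (seed in 1:10) {
    k <- 3 + (seed %% 4)
    wt <- rand_rooted_tree(k, seed)
    wt2 <- build_topology(tree_distances(wt))
    expect_identical(oncotreefit:::wrt_splits(wt2),
                     oncotreefit:::wrt_splits(wt))
    d1 <- tree_distances(wt); d2 <- tree_distances(wt2)
    expect_lt(max(abs(d2$D - d1$D)), 1e-9)
    expect_lt(max(abs(d2$root_dist - d1$root_dist)), 1e-9)
  }
})

test_that("independent events attach directly to the root; nesting hangs j below i", {
  fri <- make_freq(c(A = 0.5, B = 0.3), matrix(c(0.5, 0.15, 0.15, 0.3), 2))
  ti <- build_topology(additive_distance(fri))
  expect_identical(unname(ti$parent[c("A", "B")]), c("root", "root"))
  expect_equal(ti$length[["A"]], -log(0.5), tolerance = 1e-9)

  frn <- make_freq(c(A = 0.8, B = 0.4), matrix(c(0.8, 0.4, 0.4, 0.4), 2))
  tn <- build_topology(additive_distance(frn))
  dd <- tree_distances(tn)
  expect_equal(dd$root_dist[["A"]], -log(0.8), tolerance = 1e-9)  # 0.2231
  # B's root path passes through A's attachment point at depth -log 0.8
  anc_depth <- dd$root_dist[["B"]] - tn$length[["B"]]
  expect_equal(anc_depth, -log(0.8), tolerance = 1e-9)

  # degenerate single event
  d1 <- event_distance(matrix(0, 1, 1, dimnames = list("A", "A")),
                       c(A = 0.7))
  t1 <- build_topology(d1)
  expect_identical(unname(t1$parent), "root")
  expect_equal(t1$length[["A"]], 0.7)
})

test_that("tree likelihood matches hand values and the pruning oracle", {
  # deterministic tree: every sample must carry all events
  det <- weighted_rooted_tree(c(A = "root", B = "root"), c(A = 0, B = 0),
                              c("A", "B"))
  ones <- alteration_matrix(matrix(1L, 4, 2,
    dimnames = list(paste0("s", 1:4), c("A", "B"))))
  expect_equal(tree_loglik(det, ones), 0)
  zero <- alteration_matrix(rbind(s1 = c(A = 0L, B = 1L)))
  llz <- tree_loglik(det, zero)
  expect_identical(llz, structure(-Inf, impossible_patterns = "01"))

  # chain root -> h (p = 0.5) -> leaf (p = 1): present pattern scores log 0.5
  ch <- weighted_rooted_tree(c(h = "root", A = "h"),
                             c(h = -log(0.5), A = 0), "A")
  m1 <- alteration_matrix(rbind(s1 = c(A = 1L)))
  expect_equal(tree_loglik(ch, m1), log(0.5), tolerance = 1e-12)

  # random trees: every pattern probability equals the pruning oracle
  for (seed in 1:5) {
    wt <- rand_rooted_tree(4, seed + 50)
    dist <- oncotreefit:::wrt_pattern_distribution(wt)
    pats <- expand.grid(rep(list(0:1), 4))
    for (r in seq_len(nrow(pats))) {
      pat <- stats::setNames(as.integer(pats[r, ]), wt$leaves)
      key <- paste(pat, collapse = "")
      expect_equal(unname(dist[[key]]), oracle_wrt_pattern_prob(wt, pat),
                   tolerance = 1e-12)
    }
  }
})

test_that("ML edge probabilities recover truth and handle degenerate data", {
  par <- c(h1 = "root", A = "h1", B = "h1", C = "root")
  wt <- weighted_rooted_tree(par, -log(c(h1 = 0.7, A = 0.5, B = 0.6,
                                         C = 0.4)), c("A", "B", "C"))
  m <- simulate_cohort(generative_spec(wt, 5000, seed = 8))
  fit <- ml_edge_probabilities(wt, m)
  expect_lt(max(abs(fit$tree$p - c(h1 = 0.7, A = 0.5, B = 0.6, C = 0.4))),
            0.05)
  expect_gte(fit$loglik, tree_loglik(wt, m))

  # single-edge tree, event present in 40% of samples: Bernoulli MLE
  one <- weighted_rooted_tree(c(A = "root"), c(A = 1), "A")
  m40 <- alteration_matrix(cbind(A = rep(c(1L, 0L), c(40L, 60L))))
  f40 <- ml_edge_probabilities(one, m40)
  expect_equal(unname(f40$tree$p[["A"]]), 0.4, tolerance = 1e-4)

  # all-zero cohort: root-adjacent probabilities at the lower bound
  mz <- alteration_matrix(matrix(0L, 20, 3,
    dimnames = list(paste0("s", 1:20), c("A", "B", "C"))))
  fz <- ml_edge_probabilities(wt, mz)
  expect_lt(unname(fz$tree$p[["h1"]]), 1e-3)
  expect_lt(unname(fz$tree$p[["C"]]), 1e-3)
})

test_that("newick export is a valid rooted tree with correct path lengths", {
  wt <- rand_rooted_tree(5, 99)
  nwk <- write_newick(wt)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, wt$leaves)
  # root-to-leaf depths in the parsed tree match the structure
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  want <- tree_distances(wt)$root_dist[phy$tip.label]
  expect_equal(unname(depths), unname(want), tolerance = 1e-8)
  js <- jsonlite::fromJSON(wrt_json(wt))
  expect_setequal(js$leaves, wt$leaves)
})

test_that("exhaustive ML topology search agrees with neighbor joining on clean data", {
  skip_if_not_installed("phangorn")
  wt <- weighted_rooted_tree(c(h1 = "root", A = "h1", B = "h1", C = "root"),
                             -log(c(h1 = 0.75, A = 0.55, B = 0.65, C = 0.4)),
                             c("A", "B", "C"))
  m <- simulate_cohort(generative_spec(wt, 3000, seed = 17))
  best <- exhaustive_ml_topology(m)
  nj_fit <- fit_distance(m, ml_lengths = TRUE)
  # same split structure and essentially the same likelihood
  expect_gte(best$loglik, tree_loglik(nj_fit, m) - 1e-3)
})
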