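test_that("pair weights match the closed-form micro-examples", {
  fr <- make_freq(c(A = 0.5, B = 0.5), matrix(c(0.5, 0.25, 0.25, 0.5), 2))
  W <- pair_weights(fr)
  expect_equal(W["A", "B"], log(0.25), tolerance = 1e-12)   # independence
  expect_equal(W["root", "B"], log(1 / 3), tolerance = 1e-12)
  # identical events: nesting and correlation terms cancel exactly
  fr2 <- make_freq(c(A = 0.5, B = 0.5), matrix(c(0.5, 0.5, 0.5, 0.5), 2))
  expect_equal(pair_weights(fr2)["A", "B"], 0, tolerance = 1e-12)
})

test_that("optimal branching picks the nested-pair chain and breaks ties", {
  fr <- make_freq(c(A = 0.8, B = 0.4), matrix(c(0.8, 0.4, 0.4, 0.4), 2))
  W <- pair_weights(fr)
  expect_equal(W["A", "B"], 2 * log(0.4) - log(1.2) - log(0.8) - log(0.4),
               tolerance = 1e-12)
  tr <- optimal_branching(W)
  expect_identical(unname(tr$parent[c("A", "B")]), c("root", "A"))
  expect_equal(sum(tr$edge_weight), W["root", "A"] + W["A", "B"])

  # single event: only one arborescence exists
  W1 <- matrix(log(0.3 / 1.3), 2, 1, dimnames = list(c("root", "A"), "A"))
  expect_identical(unname(optimal_branching(W1)$parent), "root")

  # exact tie between two parents resolves to the lexicographically
  # smaller parent, deterministically
  events <- c("A", "B", "C")
  Wt <- matrix(-10, 4, 3, dimnames = list(c("root", events), events))
  for (e in events) Wt[e, e] <- NA
  Wt["root", "C"] <- -1; Wt["A", "C"] <- -1; Wt["B", "C"] <- -5
  Wt["root", "A"] <- 0; Wt["root", "B"] <- -4; Wt["A", "B"] <- 0
  tr1 <- optimal_branching(Wt)
  expect_identical(unname(tr1$parent[["C"]]), "A")
  expect_identical(tr1, optimal_branching(Wt))
})

test_that("optimal branching agrees with the exhaustive oracle with cycles", {
  # weights engineered so greedy best-incoming creates a 2-cycle
  events <- c("A", "B", "C")
  W <- matrix(-10, 4, 3, dimnames = list(c("root", events), events))
  for (e in events) W[e, e] <- NA
  W["B", "A"] <- -0.1; W["A", "B"] <- -0.1   # mutual attraction
  W["root", "A"] <- -0.5; W["root", "B"] <- -3; W["A", "C"] <- -0.2
  tr <- optimal_branching(W)
  bo <- brute_arborescence(W)
  expect_equal(sum(tr$edge_weight), bo$weight, tolerance = 1e-12)
  expect_identical(canon_parent(tr$parent), canon_parent(bo$parent))
})

test_that("edge probabilities are conditional frequencies on the topology", {
  fr <- make_freq(c(A = 0.8, B = 0.4), matrix(c(0.8, 0.4, 0.4, 0.4), 2))
  tr <- edge_probabilities(onco_tree(c(A = "root", B = "A")), fr)
  expect_equal(unname(tr$cond_prob[["B"]]), 0.5)        # 0.4 / 0.8
  expect_equal(unname(tr$cond_prob[["A"]]), 0.8)        # root child: marginal
  expect_identical(tr$fire_prob, tr$cond_prob)
  # perfect nesting: p_parent == p_joint -> conditional 1
  fr3 <- make_freq(c(A = 0.4, B = 0.4), matrix(0.4, 2, 2))
  expect_equal(unname(edge_probabilities(
    onco_tree(c(A = "root", B = "A")), fr3)$cond_prob[["B"]]), 1)
})

test_that("pattern likelihood matches hand values and the chain-rule oracle", {
  chain <- onco_tree(c(A = "root", B = "A"), fire_prob = c(A = 1, B = 1))
  e0 <- error_model(0, 0)
  expect_equal(pattern_likelihood(chain, e0, c(A = 1, B = 1)), 1)
  half <- onco_tree(c(A = "root", B = "A"), fire_prob = c(A = 0.5, B = 0.5))
  expect_equal(pattern_likelihood(half, e0, c(A = 0, B = 1)), 0)
  e1 <- error_model(0.1, 0.1)
  expect_equal(pattern_likelihood(half, e1, c(A = 0, B = 1)), 0.07,
               tolerance = 1e-9)

  # random trees vs the independent enumeration oracle, all patterns
  for (seed in 1:5) {
    tr <- rand_onco_tree(4, seed)
    err <- error_model(0.08, 0.15)
    pats <- expand.grid(rep(list(0:1), 4))
    for (r in seq_len(nrow(pats))) {
      pat <- stats::setNames(as.integer(pats[r, ]), tr$events)
      expect_equal(pattern_likelihood(tr, err, pat),
                   oracle_pattern_prob(tr, err, pat), tolerance = 1e-12)
    }
  }
})

test_that("pattern likelihood is invariant under consistent relabeling", {
  tr <- rand_onco_tree(5, 42)
  err <- error_model(0.05, 0.1)
  pat <- stats::setNames(c(1L, 0L, 1L, 0L, 0L), tr$events)
  relab <- stats::setNames(paste0("X", 5:1), tr$events)
  parent2 <- stats::setNames(
    ifelse(tr$parent == "root", "root", relab[tr$parent]), relab[tr$events])
  tr2 <- onco_tree(parent2,
                   fire_prob = stats::setNames(tr$fire_prob, relab[tr$events]))
  pat2 <- stats::setNames(pat, relab[names(pat)])
  expect_equal(pattern_likelihood(tr2, err, pat2),
               pattern_likelihood(tr, err, pat), tolerance = 1e-12)
})

test_that("error-model fit recovers parameters and honors the moment bound", {
  tr <- onco_tree(c(A = "root", B = "A"), fire_prob = c(A = 0.6, B = 0.5))
  m <- simulate_cohort(generative_spec(tr, 5000, seed = 7))
  fit <- fit_error_model(m, tr)
  expect_lt(max(abs(fit$tree$fire_prob - c(A = 0.6, B = 0.5))), 0.05)
  expect_lt(fit$error$eps_plus, 0.02)
  expect_lt(fit$error$eps_minus, 0.02)

  # contract: objective at least the moment start with eps = 0.01
  mom <- edge_probabilities(tr, estimate_probabilities(m))
  e01 <- error_model(0.01, 0.01)
  ll0 <- sum(log(vapply(seq_len(nrow(m)), function(i)
    pattern_likelihood(mom, e01, unclass(m)[i, ]), numeric(1))))
  expect_gte(fit$loglik, ll0 - 1e-6)

  # eps fixed at 0 on noise-free data: closed-form MLE = conditional freqs
  fit0 <- fit_error_model(m, tr, fix_eps = c(0, 0))
  expect_lt(max(abs(fit0$tree$fire_prob - mom$cond_prob)), 1e-4)
})

test_that("degenerate all-zero cohort drives the fit to the boundary", {
  tr <- onco_tree(c(A = "root", B = "A"))
  m <- alteration_matrix(matrix(0L, 30, 2, dimnames =
    list(paste0("s", 1:30), c("A", "B"))))
  fit <- fit_error_model(m, tr)
  expect_lt(unname(fit$tree$fire_prob[["A"]]), 1e-3)
  expect_lt(fit$error$eps_plus, 1e-3)
})

test_that("tree serializers emit DOT and JSON with the fitted quantities", {
  fr <- make_freq(c(A = 0.8, B = 0.4), matrix(c(0.8, 0.4, 0.4, 0.4), 2))
  tr <- edge_probabilities(onco_tree(c(A = "root", B = "A")), fr)
  dot <- onco_tree_dot(tr)
  expect_match(dot, "\"root\" -> \"A\"", fixed = TRUE)
  expect_match(dot, "\"A\" -> \"B\" [label=0.5]", fixed = TRUE)
  js <- jsonlite::fromJSON(onco_tree_json(tr))
  expect_equal(js$B$parent, "A")
  expect_equal(js$B$cond_prob, 0.5)
})
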