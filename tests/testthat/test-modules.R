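test_that("degenerate thresholds yield no modules", {
  net <- interaction_network(rbind(c("A", "B"), c("B", "C")))
  op <- build_diffusion(net)
  h <- setNames(c(1, 1, 1), c("A", "B", "C"))
  E <- exchanged_heat(op, h)
  expect_length(extract_modules(E, delta = max(E) * 1.01)$modules, 0L)
  E0 <- exchanged_heat(op, h * 0)
  expect_length(extract_modules(E0, delta = 0.01)$modules, 0L)
})

test_that("a hot near-clique is extracted and matches the closure oracle", {
  toy <- toy_hot_graph(seed = 4)
  op <- build_diffusion(toy$net)
  E <- exchanged_heat(op, toy$heat)
  ms <- extract_modules(E, delta = 0.15)
  expect_equal(length(ms$modules), 1L)
  expect_setequal(ms$modules[[1]], toy$hot)
  expect_gt(ms$mean_heat[1], 1)

  # same thresholded digraph through the transitive-closure oracle
  A <- (E >= 0.15) & !diag(TRUE, nrow(E))
  oracle <- canon_sets(lapply(closure_sccs(A, 3L),
                              function(ix) rownames(E)[ix]))
  expect_equal(canon_sets(ms$modules), oracle)
})

test_that("SCC extraction equals brute-force reachability on random digraphs", {
  for (s in 1:50) {
    set.seed(400 + s)
    n <- sample(4:12, 1)
    E <- matrix(runif(n * n), n, n,
                dimnames = list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n)))
    E[runif(n * n) < 0.55] <- 0
    delta <- runif(1, 0.2, 0.8)
    got <- canon_sets(extract_modules(E, delta, min_size = 2L)$modules)
    A <- (E >= delta) & !diag(TRUE, n)
    want <- canon_sets(lapply(closure_sccs(A, 2L),
                              function(ix) rownames(E)[ix]))
    expect_equal(got, want)
  }
})

test_that("raising delta refines modules", {
  toy <- toy_hot_graph(seed = 6)
  op <- build_diffusion(toy$net)
  E <- exchanged_heat(op, toy$heat)
  deltas <- sort(unique(E[E > 0]))
  probe <- deltas[round(seq(1, length(deltas), length.out = 12))]
  prev <- NULL
  for (d in probe) {
    mods <- extract_modules(E, d, min_size = 2L)$modules
    if (!is.null(prev)) {
      # every module at the larger delta is contained in one earlier module
      for (m in mods) {
        containing <- vapply(prev, function(p) all(m %in% p), logical(1L))
        expect_true(length(prev) == 0L || any(containing) || length(m) == 0L)
      }
    }
    prev <- mods
  }
})

test_that("delta selection is invariant to the seed under constant heat", {
  net <- interaction_network(t(utils::combn(LETTERS[1:6], 2)))  # K6
  op <- build_diffusion(net)
  h <- setNames(rep(2, 6), LETTERS[1:6])
  d1 <- select_delta(op, h, n_perm = 10, l_max = 3, seed = 1)
  d2 <- select_delta(op, h, n_perm = 10, l_max = 3, seed = 999)
  expect_equal(d1, d2)
  # l_max = 1 admits no component of size 2: nothing survives the threshold
  d_strict <- select_delta(op, h, n_perm = 10, l_max = 1, seed = 1)
  expect_length(extract_modules(exchanged_heat(op, h), d_strict,
                                min_size = 2L)$modules, 0L)
})

test_that("selected delta separates background from planted heat scales", {
  toy <- toy_hot_graph(seed = 2)
  op <- build_diffusion(toy$net)
  delta <- select_delta(op, toy$heat, n_perm = 20, l_max = 10, seed = 11)

  # oracle: identical permutation stream, but the per-permutation minimal
  # delta found by scanning every distinct candidate value linearly
  h <- toy$heat[op$nodes]
  oracle <- netheat:::with_seed(11, vapply(1:20, function(b) {
    hp <- setNames(sample(unname(h)), names(h))
    E <- exchanged_heat(op, hp)
    offdiag <- E[row(E) != col(E)]
    cand <- sort(unique(offdiag[offdiag > 0]))
    for (d in cand) {
      A <- (E >= d) & !diag(TRUE, nrow(E))
      sizes <- lengths(closure_sccs(A, 1L))
      if (max(c(sizes, 1L)) <= 10) return(d)
    }
    max(cand) * (1 + 1e-9)
  }, numeric(1)))
  expect_equal(delta, median(oracle))

  # and it sits between the background and within-module exchange scales
  E <- exchanged_heat(op, toy$heat)
  bg <- setdiff(rownames(E), toy$hot)
  bg_block <- E[bg, bg]
  bg_scale <- median(bg_block[bg_block > 0 &
                                row(bg_block) != col(bg_block)])
  hot_scale <- min(E[toy$hot, toy$hot][row(E[toy$hot, toy$hot]) !=
                                         col(E[toy$hot, toy$hot])])
  expect_gt(delta, bg_scale)
  expect_lt(delta, hot_scale)
})

test_that("module significance hits the boundaries", {
  toy <- toy_hot_graph(seed = 3, h_hot = 0.3)   # no hot cluster: constant-ish
  op <- build_diffusion(toy$net)
  h <- setNames(rep(0.3, length(op$nodes)), op$nodes)
  E <- exchanged_heat(op, h)
  # no observed components at a high threshold: all p = 1
  ms <- extract_modules(E, delta = max(E) * 1.01)
  ms <- module_significance(ms, op, h, n_perm = 19, seed = 1)
  expect_true(all(ms$significance$p == 1))
  # constant heat: permutations are equivalent to the observation
  ms2 <- extract_modules(E, delta = quantile(E[E > 0], 0.5))
  ms2 <- module_significance(ms2, op, h, n_perm = 19, seed = 1)
  expect_true(all(ms2$significance$p > 0.9))
})

test_that("a planted hot module is significant at its size", {
  # sparse background so a six-node component cannot easily arise by chance
  hits <- 0L
  for (s in 1:20) {
    toy <- toy_hot_graph(n_bg = 44L, seed = 500 + s)
    op <- build_diffusion(toy$net)
    E <- exchanged_heat(op, toy$heat)
    ms <- extract_modules(E, delta = 0.15)
    ms <- module_significance(ms, op, toy$heat, n_perm = 99, seed = s)
    k6 <- ms$significance$p[ms$significance$k == 6]
    if (length(k6) && k6 < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)   # >= 90% of 20 generator seeds
})

test_that("multi-delta significance agrees with the single-delta test", {
  toy <- toy_hot_graph(seed = 8)
  op <- build_diffusion(toy$net)
  E <- exchanged_heat(op, toy$heat)
  deltas <- c(0.1, 0.2)
  runs <- lapply(deltas, function(d) extract_modules(E, d))
  multi <- multi_delta_significance(runs, op, toy$heat, deltas,
                                    n_perm = 49, seed = 7)
  single <- lapply(deltas, function(d) {
    module_significance(extract_modules(E, d), op, toy$heat,
                        n_perm = 49, seed = 7)
  })
  # same permutation machinery, same tabulation: identical significance at
  # matched thresholds up to the shared-vs-separate permutation streams
  for (i in 1:2) {
    expect_equal(multi[[i]]$significance$observed,
                 single[[i]]$significance$observed)
    expect_equal(dim(multi[[i]]$significance), dim(single[[i]]$significance))
  }
})

test_that("consensus follows the majority co-occurrence rule", {
  mk <- function(mods, net) {
    structure(list(modules = mods, mean_heat = rep(1, length(mods)),
                   delta = 0.1, min_size = 3L,
                   provenance = list(network = net),
                   component_sizes = lengths(mods),
                   significant = rep(TRUE, length(mods))),
              class = "ModuleSet")
  }
  # single input: identity
  one <- consensus(list(mk(list(c("A", "B", "C")), "n1")))
  expect_equal(one$modules, list(c("A", "B", "C")))
  # two identical inputs: unchanged, support both networks
  two <- consensus(list(mk(list(c("A", "B", "C")), "n1"),
                        mk(list(c("A", "B", "C")), "n2")))
  expect_equal(two$modules, list(c("A", "B", "C")))
  expect_setequal(two$provenance$support[[1]], c("n1", "n2"))
  # {A,B,C} in 2 of 3 networks, {C,D} in 1: majority keeps only {A,B,C}
  three <- consensus(list(mk(list(c("A", "B", "C")), "n1"),
                          mk(list(c("A", "B", "C")), "n2"),
                          mk(list(c("C", "D", "E")), "n3")))
  expect_equal(three$modules, list(c("A", "B", "C")))
  # non-significant modules never contribute
  ns <- mk(list(c("X", "Y", "Z")), "n1")
  ns$significant <- FALSE
  expect_length(consensus(list(ns))$modules, 0L)
})
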