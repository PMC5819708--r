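test_that("the interactome generator is seeded and scale-free-ish", {
  n1 <- generate_network(100, 2, seed = 5)
  n2 <- generate_network(100, 2, seed = 5)
  expect_identical(n1$edges, n2$edges)
  # m = 1 gives a connected tree
  tr <- generate_network(10, 1, seed = 2)
  expect_equal(nrow(tr$edges), 9L)
  expect_true(igraph::is_connected(as_igraph(tr)))
  # heavy-tailed degrees: max degree far above the median
  ratios <- vapply(1:10, function(s) {
    net <- generate_network(2000, 3, seed = s)
    deg <- igraph::degree(as_igraph(net))
    max(deg) / median(deg)
  }, numeric(1))
  expect_true(all(ratios >= 10))
})

test_that("planted modules are connected, disjoint and separated", {
  net <- generate_network(500, 2, seed = 9)
  mods <- plant_modules(net, c(8, 6, 10), seed = 4)
  expect_equal(lengths(mods), c(8L, 6L, 10L))
  expect_equal(anyDuplicated(unlist(mods)), 0L)
  g <- as_igraph(net)
  for (m in mods) {
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, m)))
  }
  # pairwise graph distance at least 3 hops
  for (i in 1:2) {
    for (j in (i + 1):3) {
      d <- igraph::distances(g, v = mods[[i]], to = mods[[j]])
      expect_gte(min(d), 3)
    }
  }
  expect_error(plant_modules(net, c(400, 200), seed = 1), "exceed")
})

test_that("clique-ish densification only adds edges inside modules", {
  net <- generate_network(200, 2, seed = 3)
  mods <- plant_modules(net, c(8, 8), seed = 3)
  dens <- densify_modules(net, mods, p_edge = 1, seed = 1)
  added <- setdiff(paste(dens$edges[, 1], dens$edges[, 2]),
                   paste(net$edges[, 1], net$edges[, 2]))
  for (e in strsplit(added, " ")) {
    inside <- vapply(mods, function(m) all(e %in% m), logical(1))
    expect_true(any(inside))
  }
  # p_edge = 1 makes each module a clique
  g <- as_igraph(dens)
  for (m in mods) {
    sub <- igraph::induced_subgraph(g, m)
    expect_equal(igraph::ecount(sub), choose(length(m), 2))
  }
})

test_that("expression simulation is a seeded two-group two-timepoint design", {
  sc <- synth_scenario(11, n_genes = 200, planted = NULL, n_networks = 1)
  net <- generate_network(200, 2, seed = 1)
  e1 <- simulate_expression(sc, list(), net$nodes)
  e2 <- simulate_expression(sc, list(), net$nodes)
  expect_identical(e1$values, e2$values)
  expect_equal(dim(e1$values), c(200L, 2L * (15L + 12L)))
  expect_setequal(unique(e1$metadata$group), c("COPD", "healthy"))
  expect_setequal(unique(e1$metadata$timepoint), c("pre", "post"))
})

test_that("null simulation shows no systematic group differences", {
  sc <- synth_scenario(13, n_genes = 300, planted = NULL, diffuse_sd = 0)
  net <- generate_network(300, 2, seed = 1)
  expr <- simulate_expression(sc, list(), net$nodes)
  md <- expr$metadata
  a <- expr$values[, md$sample[md$group == "COPD" & md$timepoint == "pre"]]
  b <- expr$values[, md$sample[md$group == "healthy" & md$timepoint == "pre"]]
  diff <- rowMeans(a) - rowMeans(b)
  se <- sqrt(apply(a, 1, var) / ncol(a) + apply(b, 1, var) / ncol(b))
  expect_lt(mean(abs(diff) > 3 * se), 0.02)
})

test_that("planted effects push module genes into the top decile", {
  hits <- vapply(1:20, function(s) {
    sc <- synth_scenario(s, n_genes = 400,
                         planted = data.frame(size = 8, effect = 2.0,
                                              contrast = "COPD-DE"),
                         n_networks = 1)
    net <- generate_network(400, 2, seed = derive_seed(s, "network"))
    mods <- plant_modules(net, 8, seed = derive_seed(s, "plant"))
    expr <- simulate_expression(sc, mods, net$nodes)
    md <- expr$metadata
    a <- expr$values[, md$sample[md$group == "COPD" & md$timepoint == "pre"]]
    b <- expr$values[, md$sample[md$group == "healthy" & md$timepoint == "pre"]]
    d <- abs(rowMeans(a) - rowMeans(b))
    cut <- quantile(d, 0.9)
    all(d[mods[[1]]] >= cut)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("phenotype couplings realize their target Kendall tau", {
  # strong coupling survives sampling at the study size
  strong <- vapply(1:20, function(s) {
    st <- synth_generate(synth_scenario(
      s, n_genes = 200,
      planted = data.frame(size = 8, effect = 2.0, contrast = "COPD-DE"),
      couplings = data.frame(module = 1, variable = "v", tau = 0.9,
                             direction = 1),
      n_networks = 1
    ))
    md <- st$expr$metadata
    pre <- md$timepoint == "pre"
    act <- colMeans(t(scale(t(st$expr$values[st$truth$planted[[1]],
                                             md$sample[pre]]))))
    cor(act, st$pheno$v[pre], method = "kendall")
  }, numeric(1))
  expect_gte(mean(strong >= 0.6), 0.9)

  # tau = 0 coupling is indistinguishable from noise at n = 27
  null_tau <- vapply(1:20, function(s) {
    st <- synth_generate(synth_scenario(
      s + 100, n_genes = 200,
      planted = data.frame(size = 8, effect = 2.0, contrast = "COPD-DE"),
      couplings = data.frame(module = 1, variable = "v", tau = 0,
                             direction = 1),
      n_networks = 1
    ))
    md <- st$expr$metadata
    pre <- md$timepoint == "pre"
    act <- colMeans(t(scale(t(st$expr$values[st$truth$planted[[1]],
                                             md$sample[pre]]))))
    cor(act, st$pheno$v[pre], method = "kendall")
  }, numeric(1))
  expect_gte(mean(abs(null_tau) < 0.25), 0.9)
})

test_that("coupling to a constant module is rejected", {
  sc <- synth_scenario(3, n_genes = 50,
                       planted = data.frame(size = 4, effect = 0,
                                            contrast = "COPD-DE"),
                       couplings = data.frame(module = 1, variable = "v",
                                              tau = 0.5, direction = 1),
                       baseline_sd = 0, subject_sd = 0, noise_sd = 0,
                       diffuse_sd = 0, n_networks = 1)
  net <- generate_network(50, 2, seed = 1)
  mods <- plant_modules(net, 4, seed = 1)
  expr <- simulate_expression(sc, mods, net$nodes)
  expect_error(simulate_phenotypes(sc, mods, expr), "no varying genes")
})

test_that("a generated study is deterministic and round-trips through the readers", {
  sc <- synth_scenario(17, n_genes = 150,
                       planted = data.frame(size = 6, effect = 2,
                                            contrast = "COPD-DE"),
                       couplings = data.frame(module = 1, variable = "VO2_peak",
                                              tau = 0.5, direction = 1),
                       uncoupled = "FEV1", n_networks = 2)
  s1 <- synth_generate(sc)
  s2 <- synth_generate(sc)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$nets[[2]]$edges, s2$nets[[2]]$edges)
  expect_identical(s1$pheno, s2$pheno)

  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(s1, dir)
  back <- read_expression(paths$expression, paths$metadata)
  expect_equal(back$values, s1$expr$values, tolerance = 1e-10)
  expect_equal(read_network(paths$network_1, name = s1$nets[[1]]$name)$edges,
               s1$nets[[1]]$edges)
  expect_equal(read_gmt(paths$gmt)$sets, s1$gmt$sets)
  ph <- read_phenotypes(paths$phenotypes)
  expect_equal(ph$VO2_peak, s1$pheno$VO2_peak, tolerance = 1e-10)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = FALSE)
  expect_setequal(unlist(truth$planted[[1]]), s1$truth$planted[[1]])
})

test_that("presets encode the study conditions", {
  sc <- synth_preset("disease-effect", seed = 2)
  expect_equal(sc$n_copd, 15L)
  expect_equal(sc$n_healthy, 12L)
  expect_equal(nrow(sc$planted), 4L)
  expect_true(all(sc$planted$size %in% 6:10))
  expect_equal(sc$planted$effect, rep(2.0, 4))
  expect_equal(sc$couplings$tau, 0.5)
  expect_null(synth_preset("global-null", seed = 2)$planted)
})
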