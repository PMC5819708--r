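test_that("comparison construction follows the contrast design", {
  expr <- toy_expression(n_genes = 5L, n_copd = 2L, n_healthy = 2L)
  # all-pairs enumeration: 2 x 2 = 4 comparisons (hand-built selectors)
  md <- expr$metadata
  de <- structure(list(label = "tiny", design = "two-class-unpaired",
                       a = md$sample[md$group == "COPD" & md$timepoint == "pre"],
                       b = md$sample[md$group == "healthy" & md$timepoint == "pre"]),
                  class = "Contrast")
  cmp <- pairwise_comparisons(expr, de, max_pairs = 30L, pairing = "all")
  expect_equal(ncol(cmp), 4L)
  expect_equal(cmp[, 1], expr$values[, de$a[1]] - expr$values[, de$b[1]])

  # paired: one post - pre difference per subject
  expr5 <- toy_expression(n_genes = 4L, n_copd = 5L, n_healthy = 3L)
  te <- standard_contrast("COPD-TE", expr5$metadata)
  cmp5 <- pairwise_comparisons(expr5, te)
  expect_equal(ncol(cmp5), 5L)
  md <- expr5$metadata
  s1 <- md$sample[md$subject == "C01"]
  expect_equal(unname(cmp5[, 1]),
               unname(expr5$values[, s1[2]] - expr5$values[, s1[1]]))

  # seeded cap is reproducible
  big <- toy_expression(n_genes = 4L, n_copd = 15L, n_healthy = 12L)
  deb <- standard_contrast("COPD-DE", big$metadata)
  c1 <- pairwise_comparisons(big, deb, max_pairs = 30L, seed = 7L, pairing = "all")
  c2 <- pairwise_comparisons(big, deb, max_pairs = 30L, seed = 7L, pairing = "all")
  expect_equal(ncol(c1), 30L)
  expect_identical(c1, c2)

  # disjoint pairing uses every sample at most once
  cd <- pairwise_comparisons(big, deb, seed = 3L)
  expect_equal(ncol(cd), 12L)
  used <- unlist(strsplit(colnames(cd), "-", fixed = TRUE))
  expect_false(any(duplicated(used)))

  expect_error(pairwise_comparisons(toy_expression(n_copd = 3L, n_healthy = 3L),
                                    contrast("x", "two-class-unpaired",
                                             a = paste0("C0", 1:3, "_pre"),
                                             b = paste0("H0", 1:3, "_pre"),
                                             metadata = toy_expression()$metadata),
                                    max_pairs = 2L, pairing = "all"),
               "fewer than 3")
})

test_that("rank products match closed forms and a counting oracle", {
  # a gene ranked 1 everywhere has RP = 1; ranks (1, 2) give sqrt(2)
  X <- cbind(c(-5, 1, 2), c(-4, 3, -1))
  rownames(X) <- c("low", "mid", "hi")
  rp <- rank_product(X)
  expect_equal(unname(rp$RP_down["low"]), 1)            # rank 1 everywhere
  expect_equal(unname(rp$RP_down["hi"]), sqrt(3 * 2))   # ranks 3 then 2
  # ranks (1, 2) across two comparisons give sqrt(2)
  rp12 <- rank_product(cbind(c(0, 5), c(3, 0)))
  expect_equal(unname(rp12$RP_down[1]), sqrt(1 * 2))

  set.seed(42)
  Y <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], NULL))
  rp2 <- rank_product(Y)
  # oracle: counting ranks and explicit products
  for (g in 1:4) {
    r_dn <- c(count_ranks(Y[, 1])[g], count_ranks(Y[, 2])[g])
    r_up <- c(count_ranks(-Y[, 1])[g], count_ranks(-Y[, 2])[g])
    expect_equal(unname(rp2$RP_down[g]), prod(r_dn)^(1 / 2))
    expect_equal(unname(rp2$RP_up[g]), prod(r_up)^(1 / 2))
  }
  expect_error(rank_product(cbind(c(1, NA), c(1, 2))), "non-finite")
})

test_that("ties receive average ranks", {
  X <- cbind(c(1, 1, 3), c(2, 5, 5))
  rp <- rank_product(X)
  expect_equal(unname(rp$RP_down[1]), sqrt(1.5 * 1))
  expect_equal(unname(rp$RP_down[2]), sqrt(1.5 * 2.5))
  expect_equal(unname(rp$RP_down[3]), sqrt(3 * 2.5))
})

test_that("permutation p-values are deterministic and hit the boundaries", {
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(letters[1:10], NULL))
  rp <- rank_product(X)
  p1 <- rp_pvalues(rp, n_perm = 50, seed = 5)
  p2 <- rp_pvalues(rp, n_perm = 50, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$p_up > 0 & p1$p_up <= 1))
  expect_true(all(p1$p <= 1))

  # a gene at the maximum possible rank product gets p ~ 1
  worst <- which.max(rp$RP_up)
  expect_gt(p1$p_up[worst], 0.85)
})

test_that("gene relabeling permutes all outputs identically", {
  set.seed(11)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  perm <- sample(8)
  rp <- rank_product(X)
  rp_p <- rank_product(X[perm, ])
  expect_equal(unname(rp_p$RP_up), unname(rp$RP_up[perm]))
  # the exhaustive permutation null does not depend on gene labels
  Y <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  perm5 <- sample(5)
  pv <- rp_pvalues(rank_product(Y), exhaustive = TRUE)
  pv_p <- rp_pvalues(rank_product(Y[perm5, ]), exhaustive = TRUE)
  expect_equal(pv_p$p_up, pv$p_up[perm5])
  expect_equal(pv_p$p, pv$p[perm5])
})

test_that("raising a gene's log-ratios never increases its RP_up", {
  set.seed(13)
  for (rep in 1:10) {
    X <- matrix(rnorm(24), 6, 4)
    rownames(X) <- letters[1:6]
    g <- sample(6, 1)
    X2 <- X
    X2[g, ] <- X2[g, ] + abs(rnorm(4))
    expect_lte(rank_product(X2)$RP_up[g], rank_product(X)$RP_up[g])
  }
})

test_that("BH adjustment matches the step-up rule and a textbook oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(21)
  p <- runif(50)
  # textbook step-up with explicit cumulative minimum from the largest p
  ord <- order(p, decreasing = TRUE)
  m <- length(p)
  adj <- numeric(m)
  run <- Inf
  for (i in seq_along(ord)) {
    k <- ord[i]
    rank_k <- m - i + 1
    run <- min(run, p[k] * m / rank_k)
    adj[k] <- min(1, run)
  }
  expect_equal(bh_adjust(p), adj)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("diffexp produces a coherent per-gene table", {
  expr <- toy_expression(n_genes = 40L, n_copd = 5L, n_healthy = 4L, seed = 3)
  res <- diffexp(expr, standard_contrast("COPD-DE", expr$metadata),
                 n_perm = 100, seed = 2)
  expect_s3_class(res, "DifferentialResult")
  expect_true(all(res$RP_up >= 1 & res$RP_up <= 40))
  expect_true(all(res$FDR >= res$p))
  expect_equal(res$direction, ifelse(res$effect >= 0, "up", "down"))
  # reruns are identical; output header records the permutation count
  res2 <- diffexp(expr, standard_contrast("COPD-DE", expr$metadata),
                  n_perm = 100, seed = 2)
  expect_identical(res, res2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_diffexp(res, f)
  expect_match(readLines(f, n = 1), "n_perm=100")
})
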