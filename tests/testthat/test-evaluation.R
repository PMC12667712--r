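test_that("r2_score is the squared Pearson correlation with guard rails", {
  expect_equal(r2_score(1:5, 1:5), 1)
  expect_equal(r2_score(c(1, 2, 3), c(3, 2, 1)), 1)
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  expect_equal(as.numeric(r2_score(x, y)), oracle_r2(x, y),
               tolerance = 1e-12)
  const <- r2_score(rep(2, 4), 1:4)
  expect_identical(as.numeric(const), 0)
  expect_true(isTRUE(attr(const, "constant_input")))
  expect_error(r2_score(1:3, 1:4), "length")
})

test_that("r2_score is symmetric, affine-invariant and bounded", {
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    r <- as.numeric(r2_score(x, y))
    expect_gte(r, 0)
    expect_lte(r, 1)
    expect_equal(r, as.numeric(r2_score(y, x)), tolerance = 1e-12)
    a <- runif(1, 0.5, 3)
    b <- rnorm(1)
    expect_equal(r, as.numeric(r2_score(a * x + b, y)), tolerance = 1e-9)
  }
})

test_that("js_divergence matches its definition and bounds", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  set.seed(42)
  for (rep in 1:20) {
    a <- rgamma(6, 1)
    a <- a / sum(a)
    b <- rgamma(6, 1)
    b <- b / sum(b)
    d <- js_divergence(a, b)
    expect_equal(d, oracle_js(a, b), tolerance = 1e-12)
    expect_equal(d, js_divergence(b, a), tolerance = 1e-12)
    expect_lte(d, log(2))
  }
  expect_error(js_divergence(c(-0.1, 1.1), c(0.5, 0.5)), "nonnegative")
  expect_error(js_divergence(c(0.5, 0.4), c(0.5, 0.5)), "expected 1")
})

test_that("make_folds partitions the panel with balanced sizes", {
  panel10 <- paste0("g", 1:10)
  s <- make_folds(panel10, n_folds = 10, seed = 1)
  expect_length(s$folds, 10)
  expect_true(all(lengths(s$folds) == 1))
  expect_setequal(unlist(s$folds), panel10)

  panel23 <- paste0("g", 1:23)
  s23 <- make_folds(panel23, n_folds = 10, seed = 2)
  expect_setequal(unlist(s23$folds), panel23)
  expect_true(all(lengths(s23$folds) %in% 2:3))
  expect_equal(sum(lengths(s23$folds)), 23)
  expect_true(all(table(unlist(s23$folds)) == 1))

  expect_identical(make_folds(panel23, 10, seed = 7)$folds,
                   make_folds(panel23, 10, seed = 7)$folds)
  expect_false(identical(make_folds(panel23, 10, seed = 7)$folds,
                         make_folds(panel23, 10, seed = 8)$folds))
  expect_error(make_folds(paste0("g", 1:5), n_folds = 6), "exceeds")
})

test_that("baseline A splits the mapped spot's counts equally", {
  # one cell mapped to one spot: imputed row equals the spot's row
  xen <- srt_slice(matrix(c(2L, 1L), 1, 2), rbind(c(10, 10)), c("a", "b"))
  vis <- srt_slice(matrix(c(5L, 7L, 9L), 1, 3), rbind(c(12, 12)),
                   c("a", "b", "c"))
  gamma <- build_mapping(rbind(c(10, 10)), rbind(c(12, 12)), 100)
  pd <- align_panels(xen, vis, gamma, gene_universe = c("a", "b", "c"))
  got <- baseline_impute(pd, "A", genes = "c")
  expect_equal(as.numeric(got), 9)
})

test_that("baseline B splits proportionally to observed totals", {
  # two cells with panel totals 1 and 3 share a spot with count 8 -> 2 and 6
  xen <- srt_slice(matrix(c(1L, 3L), 2, 1), rbind(c(10, 10), c(14, 10)),
                   "a")
  vis <- srt_slice(matrix(c(4L, 8L), 1, 2), rbind(c(12, 12)), c("a", "g"))
  gamma <- build_mapping(xen$coords, vis$coords, 100)
  pd <- align_panels(xen, vis, gamma, gene_universe = c("a", "g"))
  got <- baseline_impute(pd, "B", genes = "g")
  expect_equal(as.numeric(got), c(2, 6))
  # baseline A on the same spot splits equally
  gotA <- baseline_impute(pd, "A", genes = "g")
  expect_equal(as.numeric(gotA), c(4, 4))
})

test_that("baseline C with a full neighbourhood returns the global mean", {
  pd <- tiny_pair(nx = 7, nv = 2, n_genes = 5, n_panel = 3, seed = 43)
  g <- pd$gene_universe[4:5]
  a <- baseline_impute(pd, "A", genes = g)
  cfull <- baseline_impute(pd, "C", genes = g, k_neighbors = 7)
  expect_equal(unname(cfull),
               matrix(colMeans(a), 7, 2, byrow = TRUE), tolerance = 1e-12)
  expect_error(baseline_impute(pd, "C", genes = g, k_neighbors = 8),
               "exceeds")
  expect_error(baseline_impute(pd, "A", genes = "absent"), "absent")
})

test_that("unmapped cells receive zero from every baseline", {
  xen <- srt_slice(matrix(c(1L, 3L), 2, 1),
                   rbind(c(10, 10), c(500, 500)), "a")
  vis <- srt_slice(matrix(c(4L, 8L), 1, 2), rbind(c(12, 12)), c("a", "g"))
  gamma <- build_mapping(xen$coords, vis$coords, 100)
  pd <- align_panels(xen, vis, gamma, gene_universe = c("a", "g"))
  for (v in c("A", "B")) {
    got <- baseline_impute(pd, v, genes = "g")
    expect_equal(got[2, "g"], 0, ignore_attr = TRUE)
  }
})

test_that("cosine similarity of labelings matches the indicator oracle", {
  ident <- cosine_similarity_matrix(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(unname(ident), diag(2), tolerance = 1e-12)
  # single-class vs single-class covering all items
  expect_equal(as.numeric(cosine_similarity_matrix(rep(1, 5), rep(9, 5))),
               1)
  set.seed(44)
  a <- sample(1:3, 30, replace = TRUE)
  b <- sample(1:4, 30, replace = TRUE)
  got <- cosine_similarity_matrix(a, b)
  for (t in 1:3) {
    for (f in 1:4) {
      ia <- as.numeric(a == t)
      ib <- as.numeric(b == f)
      expect_equal(got[t, f],
                   sum(ia * ib) / sqrt(sum(ia) * sum(ib)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("adjusted Rand index matches pair counting and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 7, 7)), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0)
  set.seed(45)
  a <- sample(1:4, 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
               tolerance = 1e-12)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("match_factors pairs factors with their dominant type", {
  ref <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  fac <- c(2, 2, 2, 3, 3, 3, 1, 1, 1)
  perm <- match_factors(ref, fac, n_types = 3, h = 3)
  expect_identical(perm, c(3L, 1L, 2L))
})

test_that("holdout evaluation covers each panel gene exactly once", {
  pd <- tiny_pair(nx = 12, nv = 3, n_genes = 8, n_panel = 6, seed = 46)
  scheme <- make_folds(pd$xenium$gene_names, n_folds = 3, seed = 1)
  cfg <- siid_config(h = 2, epochs = 150, restarts = 1, seed = 5)
  res <- holdout_evaluate(pd, cfg, scheme)
  expect_setequal(names(res$per_gene_r2), pd$xenium$gene_names)
  expect_equal(res$mean_r2, mean(res$per_gene_r2))
  expect_true(all(res$per_gene_r2 >= 0 & res$per_gene_r2 <= 1))
  # degenerate scheme: holding out the whole panel leaves nothing to train
  whole <- make_folds(pd$xenium$gene_names, n_folds = 1, seed = 1)
  expect_error(holdout_evaluate(pd, cfg, whole), "no training genes")
})
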