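test_that("checkerboard assigns (row + col) mod n_types over the grid", {
  # four spots, one per cell of a 2x2 grid
  coords <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  types <- make_checkerboard(coords, grid_side = 2, n_types = 2)
  expect_identical(types, c(1L, 2L, 2L, 1L))
  expect_error(make_checkerboard(cbind(1:4, rep(2, 4)), 2, 2), "degenerate")
})

test_that("edge-adjacent checkerboard cells never share a type", {
  for (l in c(2, 4, 7)) {
    for (h in c(2, 3, 5)) {
      centers <- expand.grid(c = (seq_len(l) - 0.5) / l,
                             r = (seq_len(l) - 0.5) / l)
      types <- matrix(make_checkerboard(as.matrix(centers), l, h), l, l,
                      byrow = TRUE)
      if (l > 1) {
        expect_true(all(types[-1, ] != types[-l, ]),
                    label = sprintf("vertical neighbours differ (l=%d h=%d)", l, h))
        expect_true(all(types[, -1] != types[, -l]),
                    label = sprintf("horizontal neighbours differ (l=%d h=%d)", l, h))
      }
    }
  }
})

test_that("checkerboard matches a brute-force binning oracle", {
  set.seed(31)
  coords <- cbind(runif(50, -3, 7), runif(50, 10, 30))
  got <- make_checkerboard(coords, grid_side = 4, n_types = 3)
  rx <- range(coords[, 1])
  ry <- range(coords[, 2])
  want <- integer(50)
  for (i in 1:50) {
    cc <- min(floor((coords[i, 1] - rx[1]) / (rx[2] - rx[1]) * 4), 3)
    rr <- min(floor((coords[i, 2] - ry[1]) / (ry[2] - ry[1]) * 4), 3)
    want[i] <- (rr + cc) %% 3 + 1
  }
  expect_identical(got, as.integer(want))
})

test_that("profiles are stochastic, distinguishable and concentration-sensitive", {
  expect_equal(make_profiles(3, 1, seed = 1), matrix(1, 3, 1),
               ignore_attr = TRUE)
  prof <- make_profiles(5, 40, concentration = 0.3, seed = 2)
  expect_equal(rowSums(prof), rep(1, 5), tolerance = 1e-12)
  nrm <- prof / sqrt(rowSums(prof^2))
  cosm <- tcrossprod(nrm)
  diag(cosm) <- 0
  expect_lt(max(cosm), 0.95)
  # lower concentration -> sparser profiles -> lower mean row entropy
  ent <- function(p) mean(apply(p, 1, function(r) -sum(r[r > 0] * log(r[r > 0]))))
  sparse <- make_profiles(20, 50, concentration = 0.1, seed = 3)
  diffuse <- make_profiles(20, 50, concentration = 10, seed = 3)
  expect_lt(ent(sparse), ent(diffuse))
})

test_that("high-resolution counts have the prescribed Poisson means", {
  set.seed(33)
  n <- 1200
  types <- sample.int(3, n, replace = TRUE)
  prof <- make_profiles(3, 25, seed = 5)
  umi <- runif(n, 80, 120)
  rho <- 0.5
  sim <- simulate_xenium(types, prof, umi, coverage = rho, panel = 1:10,
                         seed = 6)
  expect_identical(dim(sim$latent_counts), c(1200L, 25L))
  expect_identical(sim$panel_counts, sim$latent_counts[, 1:10])
  # mean total within 3 standard errors of rho * mean(umi)
  totals <- rowSums(sim$latent_counts)
  se <- sd(totals) / sqrt(n)
  expect_lt(abs(mean(totals) - rho * mean(umi)), 3 * se)
  expect_error(simulate_xenium(types, prof, umi, coverage = 0, panel = 1:10),
               "coverage")
})

test_that("one-hot profiles put all counts on a single gene per spot", {
  prof <- diag(3)
  sim <- simulate_xenium(c(1, 2, 3), prof, c(50, 50, 50), coverage = 1,
                         panel = 1:3, seed = 7)
  for (i in 1:3) {
    expect_true(all(sim$latent_counts[i, -i] == 0))
  }
})

test_that("low-resolution aggregation is an exact sum over mapped spots", {
  # single mapped spot: identity
  g1 <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  x <- matrix(c(3L, 0L, 7L), 1, 3)
  expect_identical(unname(simulate_visium(x, g1)), unname(x))
  # empty mapping: all-zero output
  g0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(4, 2))
  lat <- matrix(rpois(12, 5), 4, 3)
  expect_true(all(simulate_visium(lat, g0) == 0))
  # random instance vs explicit aggregation oracle, with conservation
  set.seed(34)
  xc <- cbind(runif(30, 0, 200), runif(30, 0, 200))
  vc <- cbind(runif(5, 0, 200), runif(5, 0, 200))
  g <- build_mapping(xc, vc, 150)
  lat <- matrix(rpois(30 * 4, 6), 30, 4)
  got <- simulate_visium(lat, g)
  want <- matrix(0L, 5, 4)
  gt <- methods::as(g, "TsparseMatrix")
  for (k in seq_along(gt@i)) {
    want[gt@j[k] + 1, ] <- want[gt@j[k] + 1, ] + lat[gt@i[k] + 1, ]
  }
  expect_identical(unname(got), unname(want))
  mapped <- Matrix::rowSums(g) > 0
  expect_identical(sum(got), sum(lat[mapped, ]))
})

test_that("simulate_pair satisfies all output invariants and reproduces", {
  cfg <- simulation_config(grid_side = 2, n_types = 2, coverage = 1,
                           n_genes = 12, panel_size = 6, n_x_spots = 40,
                           n_v_spots = 9, base_umi = 60, seed = 35)
  sim <- simulate_pair(cfg)
  expect_s3_class(sim$data, "paired_data")
  expect_identical(dim(sim$data$xenium$counts), c(40L, 6L))
  expect_identical(dim(sim$data$visium$counts), c(9L, 12L))
  expect_true(all(sim$truth$cell_type %in% 1:2))
  expect_equal(rowSums(sim$truth$profiles), rep(1, 2), tolerance = 1e-12)
  occupied <- rowSums(sim$truth$v_mixture) > 0
  expect_equal(rowSums(sim$truth$v_mixture)[occupied],
               rep(1, sum(occupied)), tolerance = 1e-12)
  # panel genes are a subset of the transcriptome and match the slice
  expect_identical(sim$data$xenium$gene_names,
                   sim$truth$gene_names[sim$truth$panel])
  sim2 <- simulate_pair(cfg)
  expect_identical(as.matrix(sim$data$xenium$counts),
                   as.matrix(sim2$data$xenium$counts))
  expect_identical(sim$truth$v_mixture, sim2$truth$v_mixture)
})

test_that("ground-truth parameters outscore random draws in likelihood", {
  cfg <- simulation_config(grid_side = 2, n_types = 2, coverage = 1,
                           n_genes = 12, panel_size = 12, n_x_spots = 40,
                           n_v_spots = 9, base_umi = 60, seed = 36)
  sim <- simulate_pair(cfg)
  mcfg <- siid_config(h = 2, lambda_entropy = NULL, l2_weight = 0,
                      epochs = 1, restarts = 1)
  truth <- sim$truth
  P_true <- diag(2)[truth$cell_type, ]
  Q_true <- truth$profiles[, truth$panel, drop = FALSE]
  Q_true <- Q_true / rowSums(Q_true)
  N_true <- truth$x_umi *
    rowSums(truth$profiles[truth$cell_type, truth$panel, drop = FALSE])
  M_true <- as.matrix(sim$data$gamma) * N_true
  exact <- total_loss(list(P = P_true, Q = Q_true, N = N_true, M = M_true),
                      sim$data, 0, mcfg)
  set.seed(37)
  for (draw in 1:20) {
    P <- matrix(rgamma(80, 1), 40, 2)
    P <- P / rowSums(P)
    Q <- matrix(rgamma(24, 1), 2, 12)
    Q <- Q / rowSums(Q)
    N <- runif(40, 10, 120)
    M <- as.matrix(sim$data$gamma) * runif(40, 1, 100)
    expect_gt(total_loss(list(P = P, Q = Q, N = N, M = M), sim$data, 0,
                         mcfg), exact)
  }
})
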