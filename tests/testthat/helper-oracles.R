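# Independent scalar-loop oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the package's vectorized code
# paths.

oracle_poisson_loss <- function(Y, Z, floor = 1e-8) {
  s <- 0
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      s <- s + Z[i, j] - Y[i, j] * log(max(Z[i, j], floor))
    }
  }
  s
}

oracle_entropy <- function(P) {
  s <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) s <- s - P[i, j] * log(P[i, j])
    }
  }
  s
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  cv <- sum((x - mx) * (y - my)) / (n - 1)
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cv^2 / (vx * vy)
}

oracle_js <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log(q[i] / m[i])
  }
  s
}

# pair-counting ARI: loops over all item pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# exhaustive nearest-neighbour-with-cutoff mapping
oracle_mapping <- function(xc, vc, max_dist) {
  G <- matrix(0, nrow(xc), nrow(vc))
  for (i in seq_len(nrow(xc))) {
    best_j <- 0L
    best_d <- Inf
    for (j in seq_len(nrow(vc))) {
      d <- sqrt(sum((xc[i, ] - vc[j, ])^2))
      if (d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    if (best_d <= max_dist) G[i, best_j] <- 1
  }
  G
}

# minimal two-slice fixture: nx high-res spots, nv low-res spots, every
# high-res spot mapped, xenium panel = first n_panel genes
tiny_pair <- function(nx = 4, nv = 2, n_genes = 3, n_panel = 2, seed = 42) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  xc <- cbind(runif(nx, 0, 100), runif(nx, 0, 100))
  vc <- cbind(c(25, 75)[rep_len(1:2, nv)], seq(10, 90, length.out = nv))
  xen <- srt_slice(matrix(rpois(nx * n_panel, 3), nx, n_panel), xc,
                   genes[seq_len(n_panel)])
  vis <- srt_slice(matrix(rpois(nv * n_genes, 8), nv, n_genes), vc, genes)
  gamma <- build_mapping(xc, vc, max_dist = 200)
  align_panels(xen, vis, gamma, gene_universe = genes)
}

# simulation settings shared by the model-quality checks: a well-separated
# three-type tissue at small size
recovery_sim_config <- function(seed, coverage = 2) {
  simulation_config(grid_side = 3, n_types = 3, coverage = coverage,
                    n_genes = 30, panel_size = 20, n_x_spots = 60,
                    n_v_spots = 12, base_umi = 150,
                    profile_concentration = 0.3, seed = seed)
}

# true per-spot Poisson mean over the whole simulated transcriptome (the
# modeled gene universe of a simulated pair)
true_latent_mean <- function(truth) {
  truth$x_umi * truth$profiles[truth$cell_type, , drop = FALSE]
}

# mean JS divergence between deconvolved mixtures (after factor-to-type
# matching) and the true mixtures, over spots with support
matched_mean_js <- function(model, truth) {
  mix <- deconvolve_visium(model)
  perm <- match_factors(truth$cell_type, assign_cell_types(model),
                        n_types = ncol(truth$v_mixture), h = ncol(mix))
  aligned <- matrix(0, nrow(mix), ncol(truth$v_mixture))
  for (f in seq_along(perm)) {
    if (!is.na(perm[f])) aligned[, perm[f]] <- aligned[, perm[f]] + mix[, f]
  }
  keep <- !attr(mix, "empty_spots") & rowSums(truth$v_mixture) > 0
  mean(vapply(which(keep), function(j) {
    js_divergence(aligned[j, ] / sum(aligned[j, ]), truth$v_mixture[j, ])
  }, numeric(1)))
}
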