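#' Simulation configuration
#'
#' Parameters of the synthetic paired-slice generator. The generator lays
#' single-cell-resolution spots uniformly over a rectangular tissue domain,
#' assigns each one a cell type on a checkerboard (so neighboring grid
#' cells always differ in type), samples its counts from a Poisson with a
#' type-specific expression profile scaled by a per-spot UMI total and a
#' global coverage fraction, and aggregates mapped spots onto a coarse
#' square lattice of low-resolution spots.
#'
#' @param grid_side Checkerboard cells per side (default 10).
#' @param n_types Number of cell types / latent factors (default 4).
#' @param coverage Coverage fraction rho multiplying every per-spot UMI
#'   total (default 1; values below 1 emulate shallower sequencing).
#' @param n_genes Total genes measured by the whole-transcriptome slice.
#' @param panel_size Size of the targeted panel (subset of the genes).
#' @param n_x_spots,n_v_spots Number of high- and low-resolution spots. The
#'   low-resolution spots sit on a 100-micrometer square lattice, so the
#'   tissue extent scales with \code{n_v_spots}.
#' @param base_umi Mean per-spot UMI total before coverage scaling.
#' @param profile_concentration Symmetric Dirichlet concentration of the
#'   synthetic expression profiles; smaller values give sparser, more
#'   distinct cell types.
#' @param seed RNG seed.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(grid_side = 10L,
                              n_types = 4L,
                              coverage = 1,
                              n_genes = 200L,
                              panel_size = 50L,
                              n_x_spots = 1500L,
                              n_v_spots = 150L,
                              base_umi = 150,
                              profile_concentration = 0.3,
                              seed = 1L) {
  assert_scalar_num(grid_side, "grid_side", lower = 1)
  assert_scalar_num(n_types, "n_types", lower = 2)
  assert_scalar_num(coverage, "coverage", lower = 0, strict = TRUE)
  assert_scalar_num(n_genes, "n_genes", lower = 1)
  assert_scalar_num(panel_size, "panel_size", lower = 1)
  if (panel_size > n_genes) stop_siid("panel_size must be <= n_genes")
  assert_scalar_num(n_x_spots, "n_x_spots", lower = 1)
  assert_scalar_num(n_v_spots, "n_v_spots", lower = 1)
  assert_scalar_num(base_umi, "base_umi", lower = 0, strict = TRUE)
  assert_scalar_num(profile_concentration, "profile_concentration",
                    lower = 0, strict = TRUE)
  structure(
    list(grid_side = as.integer(grid_side), n_types = as.integer(n_types),
         coverage = coverage, n_genes = as.integer(n_genes),
         panel_size = as.integer(panel_size),
         n_x_spots = as.integer(n_x_spots),
         n_v_spots = as.integer(n_v_spots), base_umi = base_umi,
         profile_concentration = profile_concentration,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Checkerboard cell-type layout
#'
#' Partitions the bounding box of the coordinates into
#' \code{grid_side x grid_side} cells and assigns the spot in cell
#' \code{(r, c)} (0-based) the type \code{(r + c) mod n_types}, returned
#' 1-based. Any two edge-adjacent grid cells receive different types for
#' every \code{n_types >= 2}.
#'
#' @param coords Numeric matrix, spots x 2.
#' @param grid_side Cells per side, >= 1.
#' @param n_types Number of types, >= 2.
#' @return Integer vector of 1-based types, one per spot.
#' @export
make_checkerboard <- function(coords, grid_side, n_types) {
  coords <- as.matrix(coords)
  assert_scalar_num(grid_side, "grid_side", lower = 1)
  assert_scalar_num(n_types, "n_types", lower = 2)
  rx <- range(coords[, 1])
  ry <- range(coords[, 2])
  if (rx[1] == rx[2] || ry[1] == ry[2]) {
    stop_siid("degenerate bounding box: coordinates are collinear on an axis")
  }
  cc <- pmin(floor((coords[, 1] - rx[1]) / diff(rx) * grid_side),
             grid_side - 1)
  rr <- pmin(floor((coords[, 2] - ry[1]) / diff(ry) * grid_side),
             grid_side - 1)
  as.integer((rr + cc) %% n_types) + 1L
}

#' Synthetic cell-type expression profiles
#'
#' Draws each profile from a symmetric Dirichlet. Profile pairs with cosine
#' similarity >= 0.95 are resampled (bounded attempts) so the types remain
#' distinguishable.
#'
#' @param n_types Number of profiles.
#' @param n_genes Number of genes.
#' @param concentration Dirichlet concentration (> 0).
#' @param seed Optional seed; \code{NULL} uses the current RNG state.
#' @return Row-stochastic matrix, n_types x n_genes.
#' @export
make_profiles <- function(n_types, n_genes, concentration = 0.3,
                          seed = NULL) {
  assert_scalar_num(n_types, "n_types", lower = 1)
  assert_scalar_num(n_genes, "n_genes", lower = 1)
  assert_scalar_num(concentration, "concentration", lower = 0, strict = TRUE)
  draw <- function() {
    if (n_genes == 1L) return(matrix(1, n_types, 1))
    g <- matrix(stats::rgamma(n_types * n_genes, shape = concentration),
                n_types, n_genes)
    g[rowSums(g) == 0, ] <- 1  # pathological all-zero Gamma draw
    g / rowSums(g)
  }
  gen <- function() {
    prof <- draw()
    if (n_genes == 1L || n_types == 1L) return(prof)
    for (attempt in 1:100) {
      nrm <- sqrt(rowSums(prof^2))
      cosm <- tcrossprod(prof / nrm)
      diag(cosm) <- 0
      bad <- which(apply(cosm, 1, max) >= 0.95)
      if (!length(bad)) return(prof)
      # resample the most redundant profile and retry
      prof[bad[1], ] <- draw()[1, ]
    }
    stop_siid("could not generate %d distinguishable profiles; lower the concentration",
              n_types)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate high-resolution targeted counts
#'
#' Spot i's latent counts over all genes are Poisson with mean
#' \code{coverage * x_umi[i] * profiles[cell_type[i], ]}, so its expected
#' total equals \code{coverage * x_umi[i]}. The observed slice is the
#' column restriction to the targeted panel.
#'
#' @param cell_type Integer vector of 1-based types.
#' @param profiles Row-stochastic type-by-gene profile matrix.
#' @param x_umi Positive per-spot UMI totals (before coverage scaling).
#' @param coverage Coverage fraction rho (> 0).
#' @param panel Integer indices of panel genes.
#' @param seed Optional seed; \code{NULL} uses the current RNG state.
#' @return List with \code{latent_counts} (spots x all genes) and
#'   \code{panel_counts} (spots x panel).
#' @export
simulate_xenium <- function(cell_type, profiles, x_umi, coverage, panel,
                            seed = NULL) {
  profiles <- as_dense(profiles)
  assert_scalar_num(coverage, "coverage", lower = 0, strict = TRUE)
  cell_type <- as.integer(cell_type)
  if (any(cell_type < 1L) || any(cell_type > nrow(profiles))) {
    stop_siid("cell_type indices must lie in 1..%d", nrow(profiles))
  }
  if (length(x_umi) != length(cell_type)) {
    stop_siid("x_umi and cell_type must have the same length")
  }
  panel <- as.integer(panel)
  if (any(panel < 1L) || any(panel > ncol(profiles))) {
    stop_siid("panel indices must lie in 1..%d", ncol(profiles))
  }
  gen <- function() {
    mu <- (coverage * x_umi) * profiles[cell_type, , drop = FALSE]
    cnt <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    list(latent_counts = cnt,
         panel_counts = cnt[, panel, drop = FALSE])
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Aggregate high-resolution counts onto low-resolution spots
#'
#' Low-resolution spot j receives the exact sum of the latent counts of all
#' high-resolution spots mapped to it, so total counts are conserved over
#' the mapped spots.
#'
#' @param latent_counts Integer matrix, high-res spots x genes.
#' @param gamma Binary mapping matrix (rows may have at most one nonzero).
#' @return Integer matrix, low-res spots x genes.
#' @export
simulate_visium <- function(latent_counts, gamma) {
  latent_counts <- as_dense(latent_counts)
  if (nrow(latent_counts) != nrow(gamma)) {
    stop_siid("latent_counts rows (%d) must match gamma rows (%d)",
              nrow(latent_counts), nrow(gamma))
  }
  if (any(Matrix::rowSums(gamma) > 1)) {
    stop_siid("each gamma row may have at most one nonzero entry")
  }
  out <- as_dense(Matrix::crossprod(gamma, latent_counts))
  storage.mode(out) <- "integer"
  out
}

#' Simulate a paired high/low-resolution data set with ground truth
#'
#' End-to-end generator: uniform high-resolution coordinates over the
#' domain spanned by a 100-micrometer square lattice of low-resolution
#' spots, nearest-spot mapping with a 100-micrometer cutoff, checkerboard
#' cell types, Dirichlet expression profiles, log-normal per-spot UMI
#' totals, Poisson high-resolution counts and exact-sum low-resolution
#' aggregation. Ground-truth mixtures weight each mapped spot by its
#' expected total \code{coverage * x_umi}, matching the count-mass
#' interpretation of the mixing weights M.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{data} (a \code{paired_data}) and \code{truth}
#'   (a \code{simulated_truth} with \code{cell_type}, \code{profiles},
#'   \code{x_umi}, \code{v_mixture}, \code{panel}).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    pitch <- 100  # low-resolution lattice spacing, micrometers
    n_cols <- ceiling(sqrt(config$n_v_spots))
    n_rows <- ceiling(config$n_v_spots / n_cols)
    grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    grid <- grid[seq_len(config$n_v_spots), ]
    v_coords <- cbind(x = (grid$col - 0.5) * pitch,
                      y = (grid$row - 0.5) * pitch)
    x_coords <- cbind(x = stats::runif(config$n_x_spots, 0, n_cols * pitch),
                      y = stats::runif(config$n_x_spots, 0, n_rows * pitch))

    gamma <- build_mapping(x_coords, v_coords, max_dist = pitch)
    cell_type <- make_checkerboard(x_coords, config$grid_side,
                                   config$n_types)
    profiles <- make_profiles(config$n_types, config$n_genes,
                              config$profile_concentration)
    x_umi <- stats::rlnorm(config$n_x_spots,
                           meanlog = log(config$base_umi) - 0.5 * 0.25,
                           sdlog = 0.5)
    gene_names <- sprintf("gene_%04d", seq_len(config$n_genes))
    panel <- sort(sample.int(config$n_genes, config$panel_size))

    sim <- simulate_xenium(cell_type, profiles, x_umi, config$coverage,
                           panel)
    v_counts <- simulate_visium(sim$latent_counts, gamma)

    xen <- srt_slice(sim$panel_counts, x_coords, gene_names[panel],
                     spot_ids = sprintf("x_%05d", seq_len(config$n_x_spots)))
    vis <- srt_slice(v_counts, v_coords, gene_names,
                     spot_ids = sprintf("v_%05d", seq_len(config$n_v_spots)))
    # model the full transcriptome: out-of-panel genes are imputation targets
    data <- align_panels(xen, vis, gamma, gene_universe = gene_names)

    # ground-truth mixture: expected count mass per type within each v-spot
    w <- config$coverage * x_umi
    gT <- methods::as(gamma, "TsparseMatrix")
    v_mixture <- matrix(0, config$n_v_spots, config$n_types)
    if (length(gT@i)) {
      for (k in seq_along(gT@i)) {
        v_mixture[gT@j[k] + 1L, cell_type[gT@i[k] + 1L]] <-
          v_mixture[gT@j[k] + 1L, cell_type[gT@i[k] + 1L]] + w[gT@i[k] + 1L]
      }
    }
    mass <- rowSums(v_mixture)
    v_mixture[mass > 0, ] <- v_mixture[mass > 0, , drop = FALSE] /
      mass[mass > 0]

    truth <- structure(
      list(cell_type = cell_type, profiles = profiles,
           x_umi = config$coverage * x_umi, v_mixture = v_mixture,
           panel = panel, gene_names = gene_names),
      class = "simulated_truth"
    )
    list(data = data, truth = truth)
  })
}
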