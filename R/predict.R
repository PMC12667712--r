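#' Impute gene expression at high resolution
#'
#' Returns the model mean \code{diag(N) P Q} restricted to the requested
#' gene columns. This is the imputation rule for genes missing from (or
#' held out of) the targeted panel: their Q columns are informed by the
#' low-resolution slice, and \code{diag(N) P} places them at high
#' resolution. No platform scaling is applied, so imputed values live on
#' the latent (high-resolution) scale.
#'
#' @param model A fitted \code{siid_model}.
#' @param genes Character vector of genes in the model's gene universe.
#' @return A nonnegative matrix, spots x length(genes).
#' @export
impute <- function(model, genes) {
  stopifnot(inherits(model, "siid_model"))
  genes <- as.character(genes)
  unknown <- setdiff(genes, model$gene_universe)
  if (length(unknown)) {
    stop_siid("genes not in the model's gene universe: %s",
              paste(unknown, collapse = ", "))
  }
  cols <- match(genes, model$gene_universe)
  out <- (model$N * model$P) %*% model$Q[, cols, drop = FALSE]
  dimnames(out) <- list(model$spot_ids, genes)
  out
}

#' Deconvolve low-resolution spots into latent-factor mixtures
#'
#' Computes \code{t(M) P} and normalizes each row to sum to 1, giving the
#' per-spot latent factor (cell type) mixture proportions. Spots with no
#' mapped high-resolution spots have no mass; their rows are returned as
#' all zeros and flagged.
#'
#' @param model A fitted \code{siid_model}.
#' @return A matrix, low-resolution spots x h, with attribute
#'   \code{"empty_spots"}: a logical vector marking rows with no support.
#' @export
deconvolve_visium <- function(model) {
  stopifnot(inherits(model, "siid_model"))
  mix <- crossprod(model$M, model$P)
  mass <- rowSums(mix)
  empty <- mass <= 0
  mix[!empty, ] <- mix[!empty, , drop = FALSE] / mass[!empty]
  mix[empty, ] <- 0
  rownames(mix) <- model$v_spot_ids
  attr(mix, "empty_spots") <- empty
  mix
}

#' Assign each high-resolution spot to its dominant latent factor
#'
#' Per-row argmax of P, with ties broken toward the lowest factor index.
#'
#' @param model A fitted \code{siid_model}, or a row-stochastic matrix P.
#' @return Integer vector of 1-based factor indices, one per spot.
#' @export
assign_cell_types <- function(model) {
  P <- if (inherits(model, "siid_model")) model$P else as_dense(model)
  max.col(P, ties.method = "first")
}

#' Convert a raw NMF factorization to the count-scaled form
#'
#' Rewrites \code{W H} (with mixing weights K) as
#' \code{diag(N) P Q} (with mixing weights \code{M = diag(N) K}) where P
#' and Q are row-stochastic and N carries the per-spot total scale. The
#' products agree exactly: \code{diag(N) P Q = W H} up to floating point.
#' Zero rows of W yield N = 0 with a uniform P row.
#'
#' @param W Nonnegative matrix, spots x h.
#' @param H Nonnegative matrix, h x genes, with no all-zero row.
#' @param K Optional nonnegative mixing matrix, spots x low-res spots.
#' @return List with \code{N}, \code{P}, \code{Q} and (if K given) \code{M}.
#' @export
raw_to_scaled <- function(W, H, K = NULL) {
  W <- as_dense(W)
  H <- as_dense(H)
  if (any(W < 0) || any(H < 0)) stop_siid("W and H must be nonnegative")
  h_rs <- rowSums(H)
  if (any(h_rs == 0)) {
    stop_siid("H has an all-zero row (factor %s has no expression)",
              paste(which(h_rs == 0), collapse = ", "))
  }
  Q <- H / h_rs
  Ws <- W * rep(h_rs, each = nrow(W))  # W %*% diag(rowSums(H))
  N <- rowSums(Ws)
  P <- Ws
  nz <- N > 0
  P[nz, ] <- P[nz, , drop = FALSE] / N[nz]
  P[!nz, ] <- 1 / ncol(W)
  out <- list(N = N, P = P, Q = Q)
  if (!is.null(K)) {
    K <- as_dense(K)
    if (any(K < 0)) stop_siid("K must be nonnegative")
    out$M <- N * K
  }
  out
}

#' Convert a count-scaled factorization back to raw NMF factors
#'
#' Inverse direction of \code{\link{raw_to_scaled}} at the level of
#' products: returns \code{W = diag(N) P}, \code{H = Q} and (if M given)
#' \code{K = diag(1/N) M}, so that \code{W H} reproduces
#' \code{diag(N) P Q}. The individual factors are one representative of the
#' scaling equivalence class, not the originals.
#'
#' @param N Nonnegative per-spot totals.
#' @param P Row-stochastic spots x h matrix.
#' @param Q Row-stochastic h x genes matrix.
#' @param M Optional mixing matrix with \code{M = diag(N) K}.
#' @return List with \code{W}, \code{H} and (if M given) \code{K}.
#' @export
scaled_to_raw <- function(N, P, Q, M = NULL) {
  N <- as.numeric(N)
  W <- N * as_dense(P)
  out <- list(W = W, H = as_dense(Q))
  if (!is.null(M)) {
    M <- as_dense(M)
    K <- M
    nz <- N > 0
    K[nz, ] <- K[nz, , drop = FALSE] / N[nz]
    if (any(M[!nz, ] != 0)) {
      stop_siid("M has mass on spots with N = 0; K is undefined there")
    }
    out$K <- K
  }
  out
}
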