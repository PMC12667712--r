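#' Squared Pearson correlation (coefficient of determination)
#'
#' \code{cov(x, y)^2 / (var(x) * var(y))}: symmetric in its arguments,
#' invariant to affine rescaling of either one, and bounded in [0, 1]. If
#' either vector is constant the score is defined as 0 and flagged via the
#' \code{"constant_input"} attribute, so fold aggregation never aborts on
#' an all-zero holdout gene.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single number in [0, 1].
#' @export
r2_score <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop_siid("x and y must have the same length")
  if (length(x) < 2L) stop_siid("r2_score needs at least 2 observations")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 || vy == 0) {
    return(structure(0, constant_input = TRUE))
  }
  min(stats::cov(x, y)^2 / (vx * vy), 1)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' \code{0.5 KL(p || m) + 0.5 KL(q || m)} with \code{m = (p + q) / 2},
#' natural log: symmetric, bounded by \code{log(2)}, and zero exactly when
#' the inputs agree. Inputs are renormalized if their sums deviate from 1
#' by no more than 1e-6.
#'
#' @param p,q Nonnegative vectors of equal length summing to 1.
#' @return A single number in [0, log(2)].
#' @export
js_divergence <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != length(q)) stop_siid("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) {
    stop_siid("probability vectors must be nonnegative")
  }
  for (s in list(sum(p), sum(q))) {
    if (abs(s - 1) > 1e-6) {
      stop_siid("input sums to %.8f; expected 1 within 1e-6", s)
    }
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Split a gene panel into holdout folds
#'
#' Sorted gene names are shuffled with the given seed and dealt round-robin
#' into \code{n_folds} disjoint folds whose sizes differ by at most one and
#' whose union is the panel.
#'
#' @param panel Character vector of panel genes.
#' @param n_folds Number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return A \code{holdout_scheme}: list with \code{folds} (list of gene
#'   vectors), \code{n_folds} and \code{seed}.
#' @export
make_folds <- function(panel, n_folds = 10L, seed = 1L) {
  panel <- as.character(panel)
  assert_scalar_num(n_folds, "n_folds", lower = 1)
  n_folds <- as.integer(n_folds)
  if (n_folds > length(panel)) {
    stop_siid("n_folds (%d) exceeds panel size (%d)", n_folds, length(panel))
  }
  shuffled <- with_seed(seed, sample(sort(panel)))
  folds <- split(shuffled, rep_len(seq_len(n_folds), length(shuffled)))
  structure(
    list(folds = unname(folds), n_folds = n_folds, seed = as.integer(seed)),
    class = "holdout_scheme"
  )
}

#' Holdout-fold imputation evaluation
#'
#' For each fold, refits the model with the fold's genes removed from the
#' high-resolution training panel, imputes them, and scores each imputed
#' gene against the observed (held-out) high-resolution counts with
#' \code{\link{r2_score}}. Each panel gene is held out exactly once; the
#' summary is the arithmetic mean of the per-gene scores.
#'
#' @param data A \code{paired_data}.
#' @param config A \code{\link{siid_config}} (ignored by baseline methods
#'   except for its presence).
#' @param scheme A \code{holdout_scheme} covering the high-resolution panel.
#' @param method One of \code{"siid"} or \code{"baseline_A"} ...
#'   \code{"baseline_D"}.
#' @param k_neighbors Neighborhood size for baselines C/D.
#' @return An \code{evaluation_result}: list with \code{per_gene_r2}
#'   (named numeric), \code{mean_r2}, and \code{method_label}.
#' @export
holdout_evaluate <- function(data, config, scheme,
                             method = c("siid", "baseline_A", "baseline_B",
                                        "baseline_C", "baseline_D"),
                             k_neighbors = 10L) {
  stopifnot(inherits(data, "paired_data"), inherits(scheme, "holdout_scheme"))
  method <- match.arg(method)
  panel <- data$xenium$gene_names
  all_fold_genes <- unlist(scheme$folds)
  if (!setequal(all_fold_genes, panel)) {
    stop_siid("holdout scheme must cover exactly the high-resolution panel")
  }
  AX <- as_dense(data$xenium$counts)
  per_gene <- stats::setNames(numeric(length(panel)), panel)
  for (f in seq_along(scheme$folds)) {
    fold <- scheme$folds[[f]]
    est <- tryCatch({
      if (method == "siid") {
        model <- siid_fit(data, config, holdout_genes = fold)
        impute(model, fold)
      } else {
        baseline_impute(data, variant = sub("baseline_", "", method),
                        genes = fold, k_neighbors = k_neighbors)
      }
    }, error = function(e) {
      stop_siid("fold %d (%s): %s", f, paste(fold, collapse = ","),
                conditionMessage(e))
    })
    for (g in fold) {
      per_gene[g] <- as.numeric(r2_score(est[, g], AX[, match(g, panel)]))
    }
  }
  structure(
    list(per_gene_r2 = per_gene, mean_r2 = mean(per_gene),
         method_label = method),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s: mean holdout R^2 = %.4f over %d genes\n",
              x$method_label, x$mean_r2, length(x$per_gene_r2)))
  invisible(x)
}

#' Mapping-based baseline imputation
#'
#' Four reference imputers that use only the spot mapping (no model fit):
#' \describe{
#'   \item{A}{each cell receives its mapped low-resolution spot's count
#'     divided equally among the cells mapped there (mass-conserving);
#'     unmapped cells receive 0.}
#'   \item{B}{as A but the spot's count is split proportionally to each
#'     cell's total observed panel count (totals are computed over the
#'     panel genes not being imputed; an all-zero spot falls back to the
#'     equal split).}
#'   \item{C, D}{the per-cell values of A (resp. B) smoothed by averaging
#'     over the \code{k_neighbors} spatially nearest cells, self included.}
#' }
#'
#' @param data A \code{paired_data}.
#' @param variant One of \code{"A"}, \code{"B"}, \code{"C"}, \code{"D"}.
#' @param genes Genes to impute (must be in the modeled gene universe).
#' @param k_neighbors Neighborhood size for C/D (default 10).
#' @return Matrix, high-resolution spots x length(genes).
#' @export
baseline_impute <- function(data, variant = c("A", "B", "C", "D"), genes,
                            k_neighbors = 10L) {
  stopifnot(inherits(data, "paired_data"))
  variant <- match.arg(variant)
  genes <- as.character(genes)
  unknown <- setdiff(genes, data$visium$gene_names)
  if (length(unknown)) {
    stop_siid("genes not in the low-resolution panel: %s",
              paste(unknown, collapse = ", "))
  }
  nx <- nrow(data$xenium$counts)
  AVg <- as_dense(data$visium$counts[, match(genes, data$visium$gene_names),
                                     drop = FALSE])
  gT <- methods::as(data$gamma, "TsparseMatrix")
  map_j <- rep(NA_integer_, nx)
  map_j[gT@i + 1L] <- gT@j + 1L

  base_variant <- if (variant %in% c("A", "C")) "A" else "B"
  if (base_variant == "A") {
    wt <- rep(1, nx)
  } else {
    keep <- setdiff(data$xenium$gene_names, genes)
    wt <- if (length(keep)) {
      as.numeric(Matrix::rowSums(
        data$xenium$counts[, match(keep, data$xenium$gene_names),
                           drop = FALSE]))
    } else {
      rep(0, nx)
    }
  }
  share <- numeric(nx)
  mapped <- which(!is.na(map_j))
  denom <- tapply(wt[mapped], map_j[mapped], sum)
  d <- denom[as.character(map_j[mapped])]
  eq <- tapply(rep(1, length(mapped)), map_j[mapped], sum)
  e <- eq[as.character(map_j[mapped])]
  # proportional split, falling back to equal split when the spot's
  # weights are all zero
  share[mapped] <- ifelse(d > 0, wt[mapped] / d, 1 / e)
  out <- matrix(0, nx, length(genes))
  out[mapped, ] <- share[mapped] * AVg[map_j[mapped], , drop = FALSE]
  colnames(out) <- genes
  rownames(out) <- data$xenium$spot_ids

  if (variant %in% c("C", "D")) {
    assert_scalar_num(k_neighbors, "k_neighbors", lower = 1)
    k_neighbors <- as.integer(k_neighbors)
    if (k_neighbors > nx) {
      stop_siid("k_neighbors (%d) exceeds the number of cells (%d)",
                k_neighbors, nx)
    }
    xc <- data$xenium$coords
    sm <- matrix(0, nx, length(genes))
    v_sq <- rowSums(xc^2)
    chunk <- max(1L, as.integer(2^21 / nx))
    for (start in seq(1L, nx, by = chunk)) {
      idx <- start:min(nx, start + chunk - 1L)
      d2 <- outer(rowSums(xc[idx, , drop = FALSE]^2), v_sq, "+") -
        2 * tcrossprod(xc[idx, , drop = FALSE], xc)
      for (ii in seq_along(idx)) {
        nb <- order(d2[ii, ])[seq_len(k_neighbors)]
        sm[idx[ii], ] <- colMeans(out[nb, , drop = FALSE])
      }
    }
    dimnames(sm) <- dimnames(out)
    out <- sm
  }
  out
}

#' Cosine similarity between the classes of two labelings
#'
#' Entry (t, f) is the cosine similarity between the binary indicator
#' vectors of class t in \code{labels_a} and class f in \code{labels_b}:
#' \code{n_tf / sqrt(n_t * n_f)}. Empty classes give zero rows/columns.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Matrix with one row per class of \code{labels_a} (sorted) and
#'   one column per class of \code{labels_b}.
#' @export
cosine_similarity_matrix <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_siid("labelings must have the same length")
  }
  ta <- sort(unique(labels_a))
  tb <- sort(unique(labels_b))
  tab <- table(factor(labels_a, levels = ta), factor(labels_b, levels = tb))
  n_a <- rowSums(tab)
  n_b <- colSums(tab)
  denom <- sqrt(outer(n_a, n_b))
  out <- unclass(tab / ifelse(denom > 0, denom, 1))
  dimnames(out) <- list(as.character(ta), as.character(tb))
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table of the two labelings: 1 for identical partitions, approximately 0
#' for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 2).
#' @return A single number.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_siid("labelings must have the same length")
  }
  n <- length(labels_a)
  if (n < 2L) stop_siid("adjusted_rand_index needs at least 2 items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' Match latent factors to reference types by greedy cosine similarity
#'
#' Given factor assignments of the high-resolution spots and reference type
#' labels, repeatedly pairs the factor/type combination with the highest
#' cosine similarity of indicator vectors until every factor is matched
#' (factors beyond the number of types remain unmatched).
#'
#' @param reference_labels Reference type labels (values 1..n_types).
#' @param factor_labels Factor assignments (values 1..h), e.g. from
#'   \code{\link{assign_cell_types}}.
#' @param n_types,h Number of reference types and factors; default to the
#'   observed maxima.
#' @return Integer vector of length h: entry f is the reference type
#'   matched to factor f (NA if unmatched).
#' @export
match_factors <- function(reference_labels, factor_labels,
                          n_types = max(reference_labels),
                          h = max(factor_labels)) {
  tab <- table(factor(reference_labels, levels = seq_len(n_types)),
               factor(factor_labels, levels = seq_len(h)))
  denom <- sqrt(outer(rowSums(tab), colSums(tab)))
  cs <- unclass(tab / ifelse(denom > 0, denom, 1))
  assignment <- rep(NA_integer_, h)
  free_t <- rep(TRUE, n_types)
  free_f <- rep(TRUE, h)
  for (k in seq_len(min(n_types, h))) {
    sub <- cs
    sub[!free_t, ] <- -Inf
    sub[, !free_f] <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    assignment[best[2]] <- best[1]
    free_t[best[1]] <- FALSE
    free_f[best[2]] <- FALSE
  }
  assignment
}
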