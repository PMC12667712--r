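#' Fit the paired Poisson NMF
#'
#' Jointly factorizes a high-resolution targeted-panel slice and a
#' low-resolution whole-transcriptome slice linked by a binary spot mapping.
#' The high-resolution counts are modeled as Poisson with mean
#' \code{diag(N) P Q_X} and the low-resolution counts as Poisson with mean
#' \code{t(M) P Q diag(phi)}, where P (spots x h) and Q (h x genes) are
#' row-stochastic, N holds per-spot latent totals, M is supported only on
#' the mapping, and phi is an optional gene-wise platform scaling.
#'
#' Constraints are enforced by construction: P and Q are row-softmaxes of
#' unconstrained logits, while N, M and phi are exponentials of log
#' parameters (M parameterized only on the support of the mapping, phi
#' fixed at 1 off the training panel). Raw parameters are optimized with
#' Adam; each restart is seeded independently and the restart with the
#' lowest final loss is returned.
#'
#' @param data A \code{paired_data} object from \code{\link{align_panels}}
#'   or \code{\link{simulate_pair}}.
#' @param config A \code{\link{siid_config}}.
#' @param holdout_genes Character vector of panel genes to exclude from the
#'   high-resolution training loss (their columns of Q are still informed
#'   by the low-resolution slice, which is what makes holdout imputation
#'   possible).
#'
#' @return A \code{siid_model} with elements \code{P}, \code{Q}, \code{N},
#'   \code{M}, \code{phi}, \code{trained_gene_mask}, \code{final_loss},
#'   \code{loss_history}, \code{restart_losses}, \code{config},
#'   \code{gene_universe}, \code{holdout_genes}.
#' @export
siid_fit <- function(data, config, holdout_genes = character()) {
  stopifnot(inherits(data, "paired_data"), inherits(config, "siid_config"))
  holdout_genes <- as.character(holdout_genes)
  unknown <- setdiff(holdout_genes, data$gene_universe)
  if (length(unknown)) {
    stop_siid("holdout genes not in the gene universe: %s",
              paste(unknown, collapse = ", "))
  }
  universe <- data$gene_universe
  mask <- universe %in% setdiff(data$xenium$gene_names, holdout_genes)
  if (!any(mask)) {
    stop_siid("no training genes remain in the high-resolution panel%s",
              if (length(holdout_genes)) " after holdout removal" else "")
  }
  gamma <- data$gamma
  if (Matrix::nnzero(gamma) == 0L) {
    stop_siid("the spot mapping is empty: the low-resolution loss has no support")
  }

  nx <- nrow(data$xenium$counts)
  nv <- nrow(data$visium$counts)
  ng <- length(universe)
  h <- config$h
  AX <- as_dense(data$xenium$counts)[,
    match(universe[mask], data$xenium$gene_names), drop = FALSE]
  AV <- as_dense(data$visium$counts)
  gT <- methods::as(gamma, "TsparseMatrix")
  sup <- cbind(gT@i + 1L, gT@j + 1L)
  tr_cols <- which(mask)
  fit_phi <- isTRUE(config$platform_scaling)

  best <- NULL
  restart_losses <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    res <- with_seed(config$seed + r - 1L, {
      siid_fit_once(AX, AV, sup, nx, nv, ng, h, tr_cols, fit_phi, config)
    })
    restart_losses[r] <- res$final_loss
    if (is.null(best) || res$final_loss < best$final_loss) best <- res
  }

  factors <- paste0("factor_", seq_len(h))
  dimnames(best$P) <- list(data$xenium$spot_ids, factors)
  dimnames(best$Q) <- list(factors, universe)
  dimnames(best$M) <- list(data$xenium$spot_ids, data$visium$spot_ids)
  names(best$N) <- data$xenium$spot_ids
  names(best$phi) <- universe
  model <- structure(
    list(P = best$P, Q = best$Q, N = best$N, M = best$M, phi = best$phi,
         trained_gene_mask = mask, final_loss = min(restart_losses),
         loss_history = best$loss_history,
         restart_losses = restart_losses, config = config,
         gene_universe = universe, holdout_genes = holdout_genes,
         spot_ids = data$xenium$spot_ids,
         v_spot_ids = data$visium$spot_ids),
    class = "siid_model"
  )
  validate_model(model, data)
  model
}

# Single restart: Adam on raw parameters. All inputs dense; RNG already
# seeded by the caller.
siid_fit_once <- function(AX, AV, sup, nx, nv, ng, h, tr_cols, fit_phi,
                          config) {
  lr <- config$learning_rate
  l2 <- config$l2_weight
  floorv <- config$mean_floor
  lam <- config$lambda_entropy
  n_tr <- length(tr_cols)

  raw <- list(
    Lp = matrix(stats::rnorm(nx * h, 0, 0.1), nx, h),
    Lq = matrix(stats::rnorm(h * ng, 0, 0.1), h, ng),
    lN = stats::rnorm(nx, 0, 0.1),
    lM = stats::rnorm(nrow(sup), 0, 0.1)
  )
  if (fit_phi) raw$lphi <- stats::rnorm(n_tr, 0, 0.1)

  mom <- lapply(raw, function(x) x * 0)
  vel <- lapply(raw, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  loss_history <- numeric(config$epochs)
  M <- matrix(0, nx, nv)
  phi <- rep(1, ng)

  eval_at <- function(raw, epoch) {
    P <- row_softmax(raw$Lp)
    Q <- row_softmax(raw$Lq)
    N <- exp(raw$lN)
    M[sup] <- exp(raw$lM)
    if (fit_phi) phi[tr_cols] <- exp(raw$lphi)

    PQ <- P %*% Q
    ZX <- N * PQ[, tr_cols, drop = FALSE]
    MtP <- crossprod(M, P)
    ZV <- (MtP %*% Q) * rep(phi, each = nv)

    loss <- sum(ZX) - sum(AX * log(pmax(ZX, floorv))) +
      sum(ZV) - sum(AV * log(pmax(ZV, floorv)))
    omega <- 0
    if (!is.null(lam)) {
      omega <- exp(epoch / lam)
      pos <- P > 0
      loss <- loss - omega * sum(P[pos] * log(P[pos]))
    }
    if (l2 > 0) {
      loss <- loss + l2 * sum(vapply(raw, function(x) sum(x^2), numeric(1)))
    }
    list(loss = loss, P = P, Q = Q, N = N, M = M, phi = phi,
         PQ = PQ, ZX = ZX, ZV = ZV, MtP = MtP, omega = omega)
  }

  for (epoch in seq_len(config$epochs) - 1L) {
    st <- eval_at(raw, epoch)
    if (!is.finite(st$loss)) {
      stop_siid("non-finite loss at epoch %d; check input counts and config",
                epoch)
    }
    loss_history[epoch + 1L] <- st$loss

    # gradient of Z - Y log(max(Z, floor)); the floor acts as an epsilon-
    # smoothed log, keeping a restoring force when a mean underflows
    GX <- 1 - AX / pmax(st$ZX, floorv)
    GV <- 1 - AV / pmax(st$ZV, floorv)
    P <- st$P; Q <- st$Q; N <- st$N; phi <- st$phi

    Qtr <- Q[, tr_cols, drop = FALSE]
    Qphi <- Q * rep(phi, each = h)
    GVphi <- GV * rep(phi, each = nv)

    gP <- (N * GX) %*% t(Qtr) + st$M %*% (GVphi %*% t(Q))
    if (st$omega > 0) {
      gP <- gP - st$omega * (log(pmax(P, 1e-300)) + 1)
    }
    gQ <- matrix(0, h, ng)
    gQ[, tr_cols] <- crossprod(P, N * GX)
    gQ <- gQ + crossprod(st$MtP, GVphi)
    g <- list(
      Lp = P * (gP - rowSums(P * gP)),
      Lq = Q * (gQ - rowSums(Q * gQ)),
      lN = rowSums(GX * st$PQ[, tr_cols, drop = FALSE]) * N,
      lM = ((P %*% Qphi) %*% t(GV))[sup] * st$M[sup]
    )
    if (fit_phi) {
      g$lphi <- colSums(GV * (st$MtP %*% Q))[tr_cols] * phi[tr_cols]
    }
    if (l2 > 0) g <- Map(function(gi, xi) gi + 2 * l2 * xi, g, raw)

    t_adam <- epoch + 1L
    for (nm in names(raw)) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
      vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1^t_adam)
      vhat <- vel[[nm]] / (1 - b2^t_adam)
      raw[[nm]] <- raw[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  final <- eval_at(raw, config$epochs - 1L)
  list(P = final$P, Q = final$Q, N = final$N, M = final$M,
       phi = final$phi, final_loss = final$loss,
       loss_history = loss_history)
}

#' Check the structural invariants of a fitted model
#'
#' Verifies row-stochasticity of P and Q (tolerance 1e-6), exact support of
#' M within the spot mapping, phi fixed at 1 off the training panel, strict
#' positivity of N, and the best-of-restarts contract. Called internally at
#' the end of every fit; exported for use in validation pipelines.
#'
#' @param model A \code{siid_model}.
#' @param data Optional \code{paired_data}; if given, M's support is
#'   checked against its mapping.
#' @return Invisibly \code{TRUE}; errors describe any violated invariant.
#' @export
validate_model <- function(model, data = NULL) {
  stopifnot(inherits(model, "siid_model"))
  if (max(abs(rowSums(model$P) - 1)) > 1e-6) {
    stop_siid("P rows do not sum to 1 within 1e-6")
  }
  if (max(abs(rowSums(model$Q) - 1)) > 1e-6) {
    stop_siid("Q rows do not sum to 1 within 1e-6")
  }
  if (any(model$N <= 0)) stop_siid("N must be strictly positive")
  if (any(model$phi[!model$trained_gene_mask] != 1)) {
    stop_siid("phi must equal 1 exactly for genes outside the training panel")
  }
  if (!is.null(data)) {
    off <- model$M * (1 - as_dense(data$gamma))
    if (any(off != 0)) stop_siid("M has mass outside the mapping support")
  }
  if (abs(model$final_loss - min(model$restart_losses)) > 0) {
    stop_siid("final_loss must equal the minimum restart loss")
  }
  invisible(TRUE)
}

#' @export
print.siid_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<siid_model> h=%d | %d high-res spots x %d genes ",
    "(%d trained, %d holdout)\n  final loss %.4f over %d restart(s)\n"),
    x$config$h, nrow(x$P), length(x$gene_universe),
    sum(x$trained_gene_mask), length(x$holdout_genes),
    x$final_loss, length(x$restart_losses)))
  invisible(x)
}
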