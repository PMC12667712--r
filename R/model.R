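#' Model configuration
#'
#' Collects the tunable parameters of the paired Poisson NMF. Defaults
#' follow the reference training recipe: Adam at learning rate 0.05 for
#' 5000 epochs, three random restarts, and an l2 penalty of 1e-5 on the raw
#' (pre-softmax / pre-exponential) parameters.
#'
#' @param h Number of latent factors (intended cell types), >= 1.
#' @param lambda_entropy Entropy-schedule scale lambda, or \code{NULL} to
#'   disable entropy regularization. The entropy term is weighted by
#'   \code{exp(epoch / lambda)}, so smaller lambda pushes spot loadings
#'   toward one-hot late in training. Suggested values: 1000 when the goal
#'   is imputation, 500 for deconvolution.
#' @param learning_rate Adam step size.
#' @param epochs Number of training epochs.
#' @param restarts Number of random restarts; the fit with the lowest final
#'   loss is kept.
#' @param l2_weight Weight of the l2 penalty on raw parameters.
#' @param platform_scaling If \code{TRUE}, fit a gene-wise multiplicative
#'   factor phi on the low-resolution means to absorb platform-specific
#'   capture-efficiency differences. phi is fixed at 1 for genes outside
#'   the training panel.
#' @param seed Base RNG seed; restart r uses \code{seed + r - 1}.
#' @param mean_floor Floor applied inside the Poisson log term to keep the
#'   likelihood finite when a reconstructed mean underflows.
#'
#' @return A \code{siid_config} list.
#' @export
siid_config <- function(h,
                        lambda_entropy = NULL,
                        learning_rate = 0.05,
                        epochs = 5000L,
                        restarts = 3L,
                        l2_weight = 1e-5,
                        platform_scaling = FALSE,
                        seed = 1L,
                        mean_floor = 1e-8) {
  assert_scalar_num(h, "h", lower = 1)
  if (!is.null(lambda_entropy)) {
    assert_scalar_num(lambda_entropy, "lambda_entropy", lower = 0,
                      strict = TRUE)
  }
  assert_scalar_num(learning_rate, "learning_rate", lower = 0, strict = TRUE)
  assert_scalar_num(epochs, "epochs", lower = 1)
  assert_scalar_num(restarts, "restarts", lower = 1)
  assert_scalar_num(l2_weight, "l2_weight", lower = 0)
  assert_scalar_num(mean_floor, "mean_floor", lower = 0, strict = TRUE)
  stopifnot(is.logical(platform_scaling), length(platform_scaling) == 1L)
  structure(
    list(h = as.integer(h), lambda_entropy = lambda_entropy,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         restarts = as.integer(restarts), l2_weight = l2_weight,
         platform_scaling = platform_scaling, seed = as.integer(seed),
         mean_floor = mean_floor),
    class = "siid_config"
  )
}

#' Poisson negative log-likelihood loss
#'
#' \code{sum(Z - Y * log(max(Z, mean_floor)))}, the negative log-likelihood
#' (up to the data-only \code{log(Y!)} constant) of observing counts
#' \code{Y ~ Pois(Z)}. The floor applies only inside the log, never to the
#' linear term.
#'
#' @param Y Observed nonnegative counts.
#' @param Z Nonnegative means, same shape as \code{Y}.
#' @param mean_floor Positive floor for the log argument.
#' @return A single number.
#' @export
poisson_loss <- function(Y, Z, mean_floor = 1e-8) {
  Y <- as_dense(Y)
  Z <- as_dense(Z)
  if (!identical(dim(Y), dim(Z))) {
    stop_siid("Y (%s) and Z (%s) must have the same shape",
              paste(dim(Y), collapse = "x"), paste(dim(Z), collapse = "x"))
  }
  if (anyNA(Y) || anyNA(Z)) stop_siid("poisson_loss inputs contain NA/NaN")
  if (any(Y < 0) || any(Z < 0)) {
    stop_siid("poisson_loss inputs must be nonnegative")
  }
  assert_scalar_num(mean_floor, "mean_floor", lower = 0, strict = TRUE)
  sum(Z) - sum(Y * log(pmax(Z, mean_floor)))
}

#' Entropy-schedule weight
#'
#' Weight \code{exp(epoch / lambda)} applied to the entropy penalty at a
#' given (0-based) training epoch; equals 1 at epoch 0 and grows
#' monotonically, so the penalty dominates only late in training.
#'
#' @param epoch Nonnegative 0-based epoch index.
#' @param lambda_entropy Positive schedule scale.
#' @return A single number.
#' @export
entropy_weight <- function(epoch, lambda_entropy) {
  assert_scalar_num(epoch, "epoch", lower = 0)
  assert_scalar_num(lambda_entropy, "lambda_entropy", lower = 0,
                    strict = TRUE)
  exp(epoch / lambda_entropy)
}

#' Row-entropy of a stochastic matrix
#'
#' Returns \code{-sum(P * log(P))} with \code{0 * log(0) = 0} (natural
#' log). Zero exactly when every row is one-hot; the training loss
#' multiplies this by the scheduled weight from \code{\link{entropy_weight}}.
#'
#' @param P Matrix with nonnegative entries and rows summing to 1.
#' @return A single nonnegative number.
#' @export
entropy_term <- function(P) {
  P <- as_dense(P)
  if (any(P < 0)) stop_siid("entropy_term requires nonnegative entries")
  pos <- P > 0
  -sum(P[pos] * log(P[pos]))
}

# Model mean of the high-resolution slice over the given gene columns.
siid_mean_x <- function(N, P, Q, cols) {
  (N * P) %*% Q[, cols, drop = FALSE]
}

# Model mean of the low-resolution slice: t(M) P Q diag(phi).
siid_mean_v <- function(M, P, Q, phi) {
  Z <- crossprod(M, P) %*% Q
  if (!is.null(phi)) Z <- Z * rep(phi, each = nrow(Z))
  Z
}

#' Full training objective
#'
#' Evaluates the joint loss at a given parameter set: the Poisson loss of
#' the high-resolution counts against \code{diag(N) P Q_X}, plus the
#' Poisson loss of the low-resolution counts against
#' \code{t(M) P Q diag(phi)}, plus (if configured) the scheduled entropy
#' penalty on P and the l2 penalty on raw parameters.
#'
#' @param params List with elements \code{P}, \code{Q}, \code{N}, \code{M},
#'   \code{phi} (constrained scale) and optionally \code{raw} (list of raw
#'   parameter vectors/matrices entering the l2 penalty) and
#'   \code{trained_gene_mask} (logical over the gene universe; defaults to
#'   the xenium panel).
#' @param data A \code{paired_data} object.
#' @param epoch 0-based epoch index used by the entropy schedule.
#' @param config A \code{siid_config}.
#' @return A single number.
#' @export
total_loss <- function(params, data, epoch = 0, config) {
  stopifnot(inherits(data, "paired_data"), inherits(config, "siid_config"))
  AX <- as_dense(data$xenium$counts)
  AV <- as_dense(data$visium$counts)
  mask <- params$trained_gene_mask
  if (is.null(mask)) {
    mask <- data$gene_universe %in% data$xenium$gene_names
  }
  P <- as_dense(params$P)
  Q <- as_dense(params$Q)
  N <- as.numeric(params$N)
  M <- as_dense(params$M)
  phi <- if (is.null(params$phi)) rep(1, ncol(Q)) else as.numeric(params$phi)
  if (ncol(Q) != length(data$gene_universe)) {
    stop_siid("Q has %d columns but the gene universe has %d genes",
              ncol(Q), length(data$gene_universe))
  }
  if (nrow(P) != nrow(AX) || length(N) != nrow(AX)) {
    stop_siid("P/N sized for %d spots but data has %d", nrow(P), nrow(AX))
  }
  if (!identical(dim(M), dim(data$gamma))) {
    stop_siid("M must match gamma dimensions %s",
              paste(dim(data$gamma), collapse = "x"))
  }
  x_cols_in_universe <- which(mask)
  x_cols_in_panel <- match(data$gene_universe[x_cols_in_universe],
                           data$xenium$gene_names)
  loss <- poisson_loss(AX[, x_cols_in_panel, drop = FALSE],
                       siid_mean_x(N, P, Q, x_cols_in_universe),
                       config$mean_floor) +
    poisson_loss(AV, siid_mean_v(M, P, Q, phi), config$mean_floor)
  if (!is.null(config$lambda_entropy)) {
    loss <- loss + entropy_weight(epoch, config$lambda_entropy) *
      entropy_term(P)
  }
  if (config$l2_weight > 0 && !is.null(params$raw)) {
    loss <- loss + config$l2_weight *
      sum(vapply(params$raw, function(r) sum(r^2), numeric(1)))
  }
  loss
}
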