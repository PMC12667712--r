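#' Write a fitted model to a directory
#'
#' P, Q and M are written as Matrix Market files; N, phi, the loss history
#' and the restart losses as TSV; the configuration, gene universe, holdout
#' genes and spot identifiers as JSON.
#'
#' @param model A \code{siid_model}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, \code{dir}.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "siid_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mm <- function(x, f) {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), file.path(dir, f))
  }
  mm(model$P, "P.mtx")
  mm(model$Q, "Q.mtx")
  mm(model$M, "M.mtx")
  tsv <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(data.frame(spot_id = model$spot_ids, N = model$N), "N.tsv")
  tsv(data.frame(gene = model$gene_universe, phi = model$phi), "phi.tsv")
  tsv(data.frame(epoch = seq_along(model$loss_history) - 1L,
                 loss = model$loss_history), "loss_history.tsv")
  tsv(data.frame(restart = seq_along(model$restart_losses),
                 loss = model$restart_losses), "restart_losses.tsv")
  meta <- list(
    config = unclass(model$config),
    gene_universe = model$gene_universe,
    holdout_genes = model$holdout_genes,
    trained_gene_mask = model$trained_gene_mask,
    spot_ids = model$spot_ids,
    v_spot_ids = model$v_spot_ids,
    final_loss = model$final_loss
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a fitted model written by \code{\link{write_model}}
#'
#' @param dir Directory containing the serialized model.
#' @return A \code{siid_model}.
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  config <- siid_config(
    h = cfg$h,
    lambda_entropy = if (is.null(cfg$lambda_entropy)) NULL else
      cfg$lambda_entropy,
    learning_rate = cfg$learning_rate, epochs = cfg$epochs,
    restarts = cfg$restarts, l2_weight = cfg$l2_weight,
    platform_scaling = cfg$platform_scaling, seed = cfg$seed,
    mean_floor = cfg$mean_floor)
  rd <- function(f, dn) {
    m <- as_dense(Matrix::readMM(file.path(dir, f)))
    dimnames(m) <- dn
    m
  }
  N <- utils::read.table(file.path(dir, "N.tsv"), header = TRUE, sep = "\t")
  phi <- utils::read.table(file.path(dir, "phi.tsv"), header = TRUE,
                           sep = "\t")
  lh <- utils::read.table(file.path(dir, "loss_history.tsv"), header = TRUE,
                          sep = "\t")
  rl <- utils::read.table(file.path(dir, "restart_losses.tsv"),
                          header = TRUE, sep = "\t")
  factors <- paste0("factor_", seq_len(cfg$h))
  structure(
    list(P = rd("P.mtx", list(meta$spot_ids, factors)),
         Q = rd("Q.mtx", list(factors, meta$gene_universe)),
         M = rd("M.mtx", list(meta$spot_ids, meta$v_spot_ids)),
         N = stats::setNames(N$N, meta$spot_ids),
         phi = stats::setNames(phi$phi, meta$gene_universe),
         trained_gene_mask = meta$trained_gene_mask,
         final_loss = meta$final_loss, loss_history = lh$loss,
         restart_losses = rl$loss, config = config,
         gene_universe = meta$gene_universe,
         holdout_genes = as.character(meta$holdout_genes %||% character()),
         spot_ids = meta$spot_ids, v_spot_ids = meta$v_spot_ids),
    class = "siid_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
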