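#' Construct a spatially resolved transcriptomics (SRT) slice
#'
#' Bundles a spots-by-genes count matrix with per-spot 2-D spatial
#' coordinates (micrometers) and gene names into a validated container.
#' Counts are stored as a sparse \code{dgCMatrix}.
#'
#' @param counts Nonnegative integer matrix (spots x genes), dense or sparse.
#' @param coords Numeric matrix or data frame with one row per spot and two
#'   columns (x, y) in micrometers.
#' @param gene_names Character vector of unique gene names, one per column
#'   of \code{counts}.
#' @param spot_ids Optional character vector of spot identifiers; defaults
#'   to \code{spot_1 ... spot_n}.
#'
#' @return An object of class \code{srt_slice} with elements \code{counts},
#'   \code{coords}, \code{gene_names} and \code{spot_ids}.
#' @export
srt_slice <- function(counts, coords, gene_names, spot_ids = NULL) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (any(counts@x < 0)) stop_siid("counts contain negative entries")
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L) {
    stop_siid("coords must be a numeric matrix with 2 columns, got %d",
              ncol(coords))
  }
  gene_names <- as.character(gene_names)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(counts)))
  spot_ids <- as.character(spot_ids)
  if (nrow(counts) != nrow(coords)) {
    stop_siid("spot axis mismatch: counts have %d rows but coords have %d",
              nrow(counts), nrow(coords))
  }
  if (nrow(counts) != length(spot_ids)) {
    stop_siid("spot axis mismatch: counts have %d rows but %d spot_ids given",
              nrow(counts), length(spot_ids))
  }
  if (ncol(counts) != length(gene_names)) {
    stop_siid("gene axis mismatch: counts have %d columns but %d gene names",
              ncol(counts), length(gene_names))
  }
  if (anyDuplicated(gene_names)) {
    stop_siid("gene_names must be unique (duplicated: %s)",
              paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  }
  dimnames(counts) <- list(spot_ids, gene_names)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(
    list(counts = counts, coords = coords, gene_names = gene_names,
         spot_ids = spot_ids),
    class = "srt_slice"
  )
}

#' @export
print.srt_slice <- function(x, ...) {
  cat(sprintf("<srt_slice> %d spots x %d genes (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) /
                max(1, prod(dim(x$counts)))))
  invisible(x)
}

#' Read an SRT slice from disk
#'
#' Reads a count matrix (Matrix Market \code{.mtx} or delimited text),
#' a coordinate table (columns \code{spot_id}, \code{x}, \code{y}) and a
#' gene list (one name per line) and assembles a validated
#' \code{\link{srt_slice}}.
#'
#' @param counts_path Path to counts: \code{.mtx} (spots x genes) or a
#'   delimited text matrix (TSV/CSV inferred from extension).
#' @param coords_path Path to a TSV/CSV with columns spot_id, x, y.
#' @param genes_path Path to a plain-text gene list, one gene per line.
#'
#' @return An \code{srt_slice}.
#' @export
read_slice <- function(counts_path, coords_path, genes_path) {
  for (p in c(counts_path, coords_path, genes_path)) {
    if (!file.exists(p)) stop_siid("file not found: %s", p)
  }
  counts <- if (grepl("\\.mtx$", counts_path)) {
    Matrix::readMM(counts_path)
  } else {
    sep <- if (grepl("\\.csv$", counts_path)) "," else "\t"
    as.matrix(utils::read.table(counts_path, sep = sep, header = FALSE))
  }
  sep <- if (grepl("\\.csv$", coords_path)) "," else "\t"
  coords_df <- utils::read.table(coords_path, sep = sep, header = TRUE,
                                 stringsAsFactors = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(coords_df))) {
    stop_siid("coords file must have columns spot_id, x, y (found: %s)",
              paste(names(coords_df), collapse = ", "))
  }
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  srt_slice(counts, coords_df[, c("x", "y")], genes,
            spot_ids = coords_df$spot_id)
}

#' Write an SRT slice to disk
#'
#' Counterpart of \code{\link{read_slice}}: writes \code{counts.mtx},
#' \code{coords.tsv} and \code{genes.txt} under \code{dir}. Round-trips are
#' lossless for integer counts.
#'
#' @param slice An \code{srt_slice}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_slice <- function(slice, dir) {
  stopifnot(inherits(slice, "srt_slice"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.mtx"),
             coords = file.path(dir, "coords.tsv"),
             genes = file.path(dir, "genes.txt"))
  Matrix::writeMM(slice$counts, paths[["counts"]])
  utils::write.table(
    data.frame(spot_id = slice$spot_ids,
               x = slice$coords[, 1], y = slice$coords[, 2]),
    paths[["coords"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(slice$gene_names, paths[["genes"]])
  invisible(paths)
}

#' Build the binary spatial mapping between two slices
#'
#' Maps each high-resolution spot to its nearest low-resolution spot by
#' Euclidean distance, provided the distance does not exceed
#' \code{max_dist}. Each row of the result has at most one nonzero entry;
#' ties are broken toward the lowest low-resolution spot index. Coordinates
#' must already live in a shared (registered) frame.
#'
#' @param x_coords Numeric matrix, high-resolution spots x 2 (micrometers).
#' @param v_coords Numeric matrix, low-resolution spots x 2 (micrometers).
#' @param max_dist Positive cutoff in micrometers (default 100, matching
#'   the half-pitch scale of common spot arrays).
#'
#' @return A sparse binary \code{dgCMatrix} of dimension
#'   \code{nrow(x_coords) x nrow(v_coords)}.
#' @export
build_mapping <- function(x_coords, v_coords, max_dist = 100) {
  x_coords <- as.matrix(x_coords)
  v_coords <- as.matrix(v_coords)
  if (nrow(x_coords) == 0L || nrow(v_coords) == 0L) {
    stop_siid("build_mapping requires nonempty coordinate sets")
  }
  if (ncol(x_coords) != 2L || ncol(v_coords) != 2L) {
    stop_siid("coordinates must have exactly 2 columns")
  }
  assert_scalar_num(max_dist, "max_dist", lower = 0, strict = TRUE)
  nx <- nrow(x_coords)
  nv <- nrow(v_coords)
  v_sq <- rowSums(v_coords^2)
  hit_i <- integer(0)
  hit_j <- integer(0)
  # chunked nearest-neighbour search keeps the distance block bounded
  chunk <- max(1L, as.integer(2^21 / nv))
  for (start in seq(1L, nx, by = chunk)) {
    idx <- start:min(nx, start + chunk - 1L)
    xb <- x_coords[idx, , drop = FALSE]
    d2 <- outer(rowSums(xb^2), v_sq, "+") - 2 * tcrossprod(xb, v_coords)
    j <- max.col(-d2, ties.method = "first")
    d <- sqrt(pmax(d2[cbind(seq_along(idx), j)], 0))
    keep <- d <= max_dist
    hit_i <- c(hit_i, idx[keep])
    hit_j <- c(hit_j, j[keep])
  }
  Matrix::sparseMatrix(i = hit_i, j = hit_j, x = 1, dims = c(nx, nv))
}

#' Pair two SRT slices for joint modeling
#'
#' Validates gene-panel containment (every targeted-panel gene must be
#' present in the whole-transcriptome slice), reorders gene columns so
#' shared genes occupy matching positions, and bundles the slices with the
#' binary spot mapping into a \code{paired_data} object.
#'
#' @param xenium High-resolution targeted-panel \code{srt_slice}.
#' @param visium Low-resolution whole-transcriptome \code{srt_slice}.
#' @param gamma Binary sparse mapping from \code{\link{build_mapping}}
#'   (rows = xenium spots, columns = visium spots).
#' @param gene_universe Optional character vector of genes to model; must
#'   contain the full xenium panel and be a subset of the visium panel.
#'   Defaults to the xenium panel, so out-of-panel visium genes are dropped
#'   unless explicitly requested as imputation targets.
#'
#' @return A \code{paired_data} object with elements \code{xenium},
#'   \code{visium} (columns restricted to \code{gene_universe}),
#'   \code{gamma} and \code{gene_universe}.
#' @export
align_panels <- function(xenium, visium, gamma, gene_universe = NULL) {
  stopifnot(inherits(xenium, "srt_slice"), inherits(visium, "srt_slice"))
  missing_in_v <- setdiff(xenium$gene_names, visium$gene_names)
  if (length(missing_in_v)) {
    stop_siid("xenium genes absent from visium panel: %s",
              paste(missing_in_v, collapse = ", "))
  }
  if (is.null(gene_universe)) {
    gene_universe <- xenium$gene_names
  } else {
    gene_universe <- as.character(gene_universe)
    missing_x <- setdiff(xenium$gene_names, gene_universe)
    if (length(missing_x)) {
      stop_siid("gene_universe must contain the full xenium panel (missing: %s)",
                paste(missing_x, collapse = ", "))
    }
    missing_u <- setdiff(gene_universe, visium$gene_names)
    if (length(missing_u)) {
      stop_siid("gene_universe genes absent from visium panel: %s",
                paste(missing_u, collapse = ", "))
    }
  }
  x_order <- gene_universe[gene_universe %in% xenium$gene_names]
  xen <- srt_slice(xenium$counts[, match(x_order, xenium$gene_names),
                                 drop = FALSE],
                   xenium$coords, x_order, xenium$spot_ids)
  vis <- srt_slice(visium$counts[, match(gene_universe, visium$gene_names),
                                 drop = FALSE],
                   visium$coords, gene_universe, visium$spot_ids)
  gamma <- methods::as(methods::as(methods::as(
    Matrix::Matrix(gamma, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (nrow(gamma) != nrow(xen$counts) || ncol(gamma) != nrow(vis$counts)) {
    stop_siid("gamma must be %d x %d, got %d x %d",
              nrow(xen$counts), nrow(vis$counts), nrow(gamma), ncol(gamma))
  }
  if (length(gamma@x) && !all(gamma@x %in% c(0, 1))) {
    stop_siid("gamma entries must be 0 or 1")
  }
  if (any(Matrix::rowSums(gamma) > 1)) {
    stop_siid("each gamma row may map to at most one low-resolution spot")
  }
  structure(
    list(xenium = xen, visium = vis, gamma = Matrix::drop0(gamma),
         gene_universe = gene_universe),
    class = "paired_data"
  )
}

#' @export
print.paired_data <- function(x, ...) {
  cat(sprintf(paste0(
    "<paired_data> %d high-res spots (panel %d) | %d low-res spots ",
    "(universe %d) | %d mapped spots\n"),
    nrow(x$xenium$counts), length(x$xenium$gene_names),
    nrow(x$visium$counts), length(x$gene_universe),
    sum(Matrix::rowSums(x$gamma) > 0)))
  invisible(x)
}

#' Write / read a spatial mapping as a sparse triplet table
#'
#' The mapping is stored as a 3-column TSV (\code{x_index}, \code{v_index},
#' \code{value}) preceded by comment lines recording the matrix dimensions
#' and the index base (1).
#'
#' @param gamma Binary sparse mapping matrix.
#' @param path Output TSV path.
#' @return \code{write_mapping}: invisibly, \code{path};
#'   \code{read_mapping}: the sparse mapping matrix.
#' @export
write_mapping <- function(gamma, path) {
  g <- methods::as(methods::as(methods::as(
    Matrix::Matrix(gamma, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dims=%d,%d", nrow(g), ncol(g)),
               "# index_base=1",
               "x_index\tv_index\tvalue"), con)
  if (length(g@i)) {
    utils::write.table(data.frame(g@i + 1L, g@j + 1L, g@x), con,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# dims=", lines, value = TRUE)
  if (!length(hdr)) stop_siid("mapping file lacks a '# dims=' header: %s", path)
  dims <- as.integer(strsplit(sub("^# dims=", "", hdr[1]), ",")[[1]])
  body <- lines[!grepl("^#", lines)][-1]  # drop column header
  if (length(body)) {
    trip <- utils::read.table(text = body, sep = "\t")
    Matrix::sparseMatrix(i = trip[[1]], j = trip[[2]], x = trip[[3]],
                         dims = dims)
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = dims)
  }
}
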