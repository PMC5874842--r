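#' Encode a classified campaign as a method-by-cell feature matrix
#'
#' Builds the feature matrix for method comparison: one row per screening
#' method, one column per (drug, polymer, drug loading) cell. The default
#' ordinal encoding treats the classes as a miscibility gradient
#' (A = 2 > AA = 1 > AC = 0); the one-hot alternative expands each cell
#' into three indicator columns.
#'
#' @param cells Aggregated classification cells ([classify_campaign()]'s
#'   `cells`), covering a complete (drug, polymer, loading) grid for every
#'   method.
#' @param encoding `"ordinal"` (default) or `"onehot"`.
#' @return Numeric matrix with methods as row names.
#' @export
encode_class_matrix <- function(cells, encoding = c("ordinal", "onehot")) {
  encoding <- match.arg(encoding)
  cell_id <- paste(cells$drug, cells$polymer, cells$drug_loading, sep = "|")
  methods <- sort(unique(cells$method))
  ids <- sort(unique(cell_id))
  full <- as.vector(outer(ids, methods, paste, sep = "@"))
  have <- paste(cell_id, cells$method, sep = "@")
  missing_cells <- setdiff(full, have)
  if (length(missing_cells) > 0)
    stop("incomplete class grid; missing cell(s): ",
         paste(utils::head(missing_cells, 5), collapse = ", "),
         if (length(missing_cells) > 5) " ...")
  ord <- c(A = 2, AA = 1, AC = 0)
  if (encoding == "ordinal") {
    mat <- matrix(NA_real_, length(methods), length(ids),
                  dimnames = list(methods, ids))
    mat[cbind(match(cells$method, methods), match(cell_id, ids))] <-
      ord[cells$class]
  } else {
    cols <- as.vector(t(outer(ids, c("A", "AA", "AC"), paste, sep = ":")))
    mat <- matrix(0, length(methods), length(cols),
                  dimnames = list(methods, cols))
    mat[cbind(match(cells$method, methods),
              match(paste(cell_id, cells$class, sep = ":"), cols))] <- 1
  }
  mat
}

#' Principal component analysis of a screening feature matrix
#'
#' Columns are standardized (mean-centered, unit variance; constant columns
#' are dropped with a warning) and the decomposition is computed from the
#' singular values of the standardized matrix. Component signs are fixed by
#' making the largest-magnitude loading of each component positive.
#'
#' @param mat Numeric matrix (rows = methods or method-by-drug units).
#' @param n_components Components to retain (default
#'   `min(nrow-1, ncol)`).
#' @return A `pca_result` list: `scores`, `loadings`,
#'   `explained_variance_ratio`, `n_components`, `dropped` (names of
#'   constant columns).
#' @export
pca_screen <- function(mat, n_components = NULL) {
  stopifnot(is.matrix(mat), all(is.finite(mat)))
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 rows and 2 columns")
  sds <- apply(mat, 2, stats::sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " zero-variance column(s)")
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (ncol(mat) < 2)
    stop("fewer than 2 non-degenerate columns: PCA is not meaningful")
  z <- scale(mat)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k_max <- min(nrow(mat) - 1, ncol(mat))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max)
    stop("n_components must not exceed min(rows - 1, columns) = ", k_max)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  keep <- seq_len(n_components)
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 explained_variance_ratio = ratio[keep],
                 all_ratios = ratio,
                 n_components = n_components,
                 dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s); explained variance: %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Rank rows by proximity to a reference row in score space
#'
#' Euclidean distance in the retained-component score space from every row
#' to the reference row, ascending -- a quantitative surrogate for reading
#' relative positions off a score plot.
#'
#' @param result A `pca_result`.
#' @param reference Row name (or index) of the reference method.
#' @return Data frame with `method` and `distance`, ascending.
#' @export
proximity_report <- function(result, reference) {
  sc <- result$scores
  if (is.character(reference)) {
    if (!reference %in% rownames(sc))
      stop("reference row '", reference, "' not found")
    ref <- sc[reference, ]
  } else ref <- sc[reference, ]
  d <- sqrt(rowSums(sweep(sc, 2, ref)^2))
  out <- data.frame(method = rownames(sc), distance = unname(d),
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$method), , drop = FALSE]
}
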