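#' Build a row-standardized spatial weights matrix over grid cells
#'
#' Constructs sparse neighbour weights for a set of retained cells on the
#' analysis lattice.  Contiguity schemes: `"queen"` (8 neighbours, the
#' default for regular grids), `"rook"` (4 neighbours), or `"knn:k"`
#' (k nearest cell centres, symmetrised so adjacency is mutual — the
#' fallback for fragmented cell sets).  The binary adjacency is symmetric;
#' weights are then row-standardized to sum to one.  Cells with no
#' neighbours are flagged as isolated (SAR fits drop them).
#'
#' @param cell_ids Integer vector of retained 0-based row-major cell ids.
#' @param grid A [grid_spec()].
#' @param scheme `"queen"`, `"rook"` or `"knn:k"` (e.g. `"knn:8"`).
#' @return A `spatial_weights` object: list with `W` (sparse row-standardized
#'   matrix), `ids`, `scheme`, `isolated` (logical), and an environment
#'   caching the eigenvalues of the similar symmetric matrix.
#' @examples
#' w <- build_weights(0:3, grid_spec(2, 2), "rook")
#' Matrix::rowSums(w$W)  # all 1
#' @export
build_weights <- function(cell_ids, grid, scheme = "queen") {
  stopifnot(inherits(grid, "grid_spec"))
  cell_ids <- sort(unique(as.integer(cell_ids)))
  n <- length(cell_ids)
  if (n < 2) stop("need at least 2 cells to build weights")
  if (any(cell_ids < 0 | cell_ids >= n_cells(grid)))
    stop("cell ids outside grid bounds")

  r <- cell_row(cell_ids, grid$cols)
  cc <- cell_col(cell_ids, grid$cols)

  if (grepl("^knn:", scheme)) {
    k <- as.integer(sub("^knn:", "", scheme))
    if (is.na(k) || k < 1 || k >= n) stop("bad knn scheme: ", scheme)
    d2 <- outer(r, r, "-")^2 + outer(cc, cc, "-")^2
    diag(d2) <- Inf
    nb <- apply(d2, 1, function(x) order(x)[seq_len(k)])  # ties: lowest index
    ii <- rep(seq_len(n), each = k); jj <- as.vector(nb)
    A <- sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n))
    A@x[] <- 1  # symmetrise: mutual adjacency, weight 1
  } else {
    offs <- switch(scheme,
      rook  = cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)),
      queen = cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1)),
      stop("unknown scheme: ", scheme))
    pos <- rep(NA_integer_, n_cells(grid))
    pos[cell_ids + 1L] <- seq_len(n)
    ii <- integer(0); jj <- integer(0)
    for (k in seq_len(nrow(offs))) {
      nr <- r + offs[k, 1]; nc <- cc + offs[k, 2]
      ok <- nr >= 0 & nr < grid$rows & nc >= 0 & nc < grid$cols
      tgt <- rep(NA_integer_, n)
      tgt[ok] <- pos[cell_id(nr[ok], nc[ok], grid$cols) + 1L]
      keep <- !is.na(tgt)
      ii <- c(ii, which(keep)); jj <- c(jj, tgt[keep])
    }
    A <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  }

  deg <- rowSums(A)
  isolated <- deg == 0
  if (all(isolated)) stop("all cells are isolated under scheme ", scheme)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  W <- Diagonal(x = inv) %*% A
  structure(list(W = methods::as(W, "generalMatrix"), A = A,
                 ids = cell_ids, scheme = scheme,
                 isolated = as.logical(isolated), cache = new.env()),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d cells, scheme %s, %d isolated\n",
              length(x$ids), x$scheme, sum(x$isolated)))
  invisible(x)
}

## Eigenvalues of W (real: W = D^-1 A is similar to D^-1/2 A D^-1/2).
## Cached per weights object; isolated cells contribute eigenvalue 0.
weights_eigenvalues <- function(w) {
  if (!is.null(w$cache$eig)) return(w$cache$eig)
  keep <- !w$isolated
  A <- w$A[keep, keep, drop = FALSE]
  dh <- 1 / sqrt(rowSums(A))
  M <- Diagonal(x = dh) %*% A %*% Diagonal(x = dh)
  ev <- eigen(as.matrix(Matrix::forceSymmetric(M)), symmetric = TRUE,
              only.values = TRUE)$values
  w$cache$eig <- ev
  ev
}

## Subset a weights object to its non-isolated cells (adjacency is symmetric,
## so isolated cells never neighbour retained ones and row sums stay 1).
drop_isolated <- function(w) {
  if (!any(w$isolated)) return(w)
  keep <- !w$isolated
  w2 <- build_like(w, keep)
  w2
}

build_like <- function(w, keep) {
  A <- w$A[keep, keep, drop = FALSE]
  deg <- rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  structure(list(W = methods::as(Diagonal(x = inv) %*% A, "generalMatrix"),
                 A = A, ids = w$ids[keep], scheme = w$scheme,
                 isolated = deg == 0, cache = new.env()),
            class = "spatial_weights")
}

#' Export spatial weights as a sparse triplet table
#'
#' @param w A `spatial_weights` object.
#' @param path Output TSV path (columns `from_cell`, `to_cell`, `weight`).
#' @export
write_weights <- function(w, path) {
  T3 <- methods::as(w$W, "TsparseMatrix")
  d <- data.frame(from_cell = w$ids[T3@i + 1L], to_cell = w$ids[T3@j + 1L],
                  weight = T3@x)
  d <- d[order(d$from_cell, d$to_cell), ]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
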