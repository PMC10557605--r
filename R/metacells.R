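#' Latent semantic indexing embedding of a peak matrix
#'
#' Standard TF-IDF (term frequency scaled by inverse document
#' frequency of the binarized matrix) followed by singular value
#' decomposition, the usual dimensionality reduction for single-cell
#' chromatin accessibility.
#'
#' @param atac sparse peak x cell count matrix.
#' @param n_dims number of components returned.
#' @param scale_components divide each component by its singular value
#'   so dimensions are comparable.
#' @return cells x `n_dims` matrix.
#' @export
lsi_embedding <- function(atac, n_dims = 10L, scale_components = TRUE) {
  bin <- atac > 0
  tf <- t(t(as.matrix(bin)) / pmax(Matrix::colSums(bin), 1))
  idf <- log(1 + ncol(bin) / pmax(Matrix::rowSums(bin), 1))
  m <- log1p(tf * idf * 1e4)
  n_dims <- min(n_dims, nrow(m) - 1L, ncol(m) - 1L)
  sv <- svd(t(m), nu = n_dims, nv = 0)
  emb <- sv$u[, seq_len(n_dims), drop = FALSE]
  if (!scale_components) {
    emb <- sweep(emb, 2L, sv$d[seq_len(n_dims)], `*`)
  }
  rownames(emb) <- colnames(atac)
  emb
}

#' Aggregate cells into metacells by k-nearest-neighbor grouping
#'
#' Metacells are sums of counts over k-NN neighborhoods in an embedding,
#' sampled greedily in random order and accepted only when they share at
#' most `max_overlap` of their members with every previously accepted
#' metacell — the aggregation used before co-accessibility estimation to
#' densify sparse accessibility profiles. `k = 1` returns single cells.
#'
#' @param mat feature x cell count matrix.
#' @param embedding cells x dims matrix (rows aligned with columns of
#'   `mat`).
#' @param k neighborhood size.
#' @param seed RNG seed for the sampling order.
#' @param max_overlap maximum shared-member fraction between any two
#'   metacells.
#' @param n_target stop after this many metacells (default: as many as
#'   fit).
#' @return list of class `metacells`: `counts` (feature x metacell),
#'   `members` (list of column indices per metacell).
#' @export
make_metacells <- function(mat, embedding, k = 30L, seed = 1L,
                           max_overlap = 0.1, n_target = Inf) {
  n <- ncol(mat)
  stopifnot(nrow(embedding) == n)
  if (k < 1) stop("k must be at least 1")
  if (k >= n) stop("k must be smaller than the number of cells")
  if (k == 1L) {
    members <- as.list(seq_len(n))
  } else {
    d <- as.matrix(stats::dist(embedding))
    nn <- apply(d, 1L, function(r) order(r)[seq_len(k)], simplify = FALSE)
    members <- with_seed(seed, {
      ord <- sample.int(n)
      acc <- list()
      max_shared <- floor(max_overlap * k)
      usage <- vector("list", n)  # metacell ids touching each cell
      for (i in ord) {
        cand <- nn[[i]]
        touching <- unlist(usage[cand])
        ok <- TRUE
        if (length(touching) > 0) {
          shared <- table(touching)
          ok <- all(shared <= max_shared)
        }
        if (ok) {
          id <- length(acc) + 1L
          acc[[id]] <- cand
          for (cell in cand) usage[[cell]] <- c(usage[[cell]], id)
          if (length(acc) >= n_target) break
        }
      }
      acc
    })
  }
  counts <- vapply(members, function(ix) {
    Matrix::rowSums(mat[, ix, drop = FALSE])
  }, numeric(nrow(mat)))
  rownames(counts) <- rownames(mat)
  colnames(counts) <- sprintf("mc_%04d", seq_along(members))
  structure(list(counts = counts, members = members, k = k),
            class = "metacells")
}

#' @export
print.metacells <- function(x, ...) {
  cat(sprintf("%d metacells of %d cells each over %d features\n",
              length(x$members), x$k, nrow(x$counts)))
  invisible(x)
}
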