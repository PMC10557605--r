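#' Flat per-locus variant weights aggregated to peaks
#'
#' Each locus's unit probability mass is divided evenly across its
#' CCVs; a peak's weight is the sum of the weights of the CCVs falling
#' inside it. Mass carried by CCVs outside every peak is reported, so
#' total locus weight is conserved up to those variants.
#'
#' @param ccvs CCV table with `variant_id` and a locus column
#'   (`merged_locus_id` or `locus_id`).
#' @param overlaps colocalization table (`variant_id`, `peak_id`).
#' @param peak_ids universe of peak ids for the output vector.
#' @return numeric weight vector named by `peak_ids`, with attribute
#'   `unassigned` (weight outside peaks per locus).
#' @export
variant_peak_weights <- function(ccvs, overlaps, peak_ids) {
  lcol <- if ("merged_locus_id" %in% names(ccvs)) "merged_locus_id"
          else "locus_id"
  stopifnot(lcol %in% names(ccvs))
  w <- setNames(numeric(length(peak_ids)), peak_ids)
  unassigned <- c()
  for (loc in unique(ccvs[[lcol]])) {
    members <- ccvs$variant_id[ccvs[[lcol]] == loc]
    if (length(members) == 0) {
      warning("empty locus skipped: ", loc)
      next
    }
    per_ccv <- 1 / length(members)
    hit <- overlaps[overlaps$variant_id %in% members, , drop = FALSE]
    # a CCV can sit in several overlapping peaks; its weight goes to each
    for (i in seq_len(nrow(hit))) {
      w[hit$peak_id[i]] <- w[hit$peak_id[i]] + per_ccv
    }
    unassigned[loc] <- per_ccv * sum(!members %in% hit$variant_id)
  }
  attr(w, "unassigned") <- unassigned
  w
}

#' Variant-weighted accessibility deviation z-scores per cell
#'
#' chromVAR-style colocalization scores: the raw deviation of cell `i`
#' is `sum_j w_j (x_ij - e_ij)` where the expectation
#' `e_ij = depth_i * peak_total_j / grand_total` assumes reads
#' distribute by cell depth and peak popularity alone. The deviation is
#' standardized against `n_bg` background weight vectors that move each
#' unit of weight to a random peak from the same (GC, mean
#' accessibility) equal-frequency bin.
#'
#' @param atac peak x cell counts.
#' @param weights per-peak weight vector (length = rows), non-negative.
#' @param gc per-peak GC content.
#' @param n_bg number of background weight vectors.
#' @param n_bins number of equal-frequency 2-d bins for matching.
#' @param seed RNG seed.
#' @return numeric z-score per cell (named by barcodes).
#' @export
colocalization_zscores <- function(atac, weights, gc, n_bg = 50L,
                                   n_bins = 50L, seed = 1L) {
  stopifnot(length(weights) == nrow(atac), length(gc) == nrow(atac))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("all-zero weight vector")
  x <- as.matrix(atac)
  depth <- colSums(x)
  ptot <- rowSums(x)
  total <- sum(depth)
  dev_of <- function(w) {
    as.vector(w %*% x) - sum(w * ptot) * depth / total
  }
  obs <- dev_of(weights)

  # equal-frequency bins over (gc, mean accessibility)
  k <- max(2L, round(sqrt(n_bins)))
  bin_of <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = k + 1)))
    findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  bins <- paste(bin_of(gc), bin_of(ptot / ncol(x)))
  by_bin <- split(seq_len(nrow(x)), bins)

  bg <- with_seed(seed, {
    vapply(seq_len(n_bg), function(b) {
      wb <- numeric(length(weights))
      nz <- which(weights > 0)
      repl <- vapply(nz, function(j) {
        pool <- by_bin[[bins[j]]]
        pool[sample.int(length(pool), 1L)]
      }, 0L)
      for (i in seq_along(nz)) wb[repl[i]] <- wb[repl[i]] + weights[nz[i]]
      dev_of(wb)
    }, numeric(ncol(x)))
  })
  mu <- rowMeans(bg)
  s <- apply(bg, 1L, sd)
  z <- (obs - mu) / ifelse(s > 0, s, 1)
  names(z) <- colnames(atac)
  z
}

#' Build a (mutual) k-nearest-neighbor cell graph
#'
#' @param embedding cells x dims matrix.
#' @param k neighbors per cell.
#' @param mutual keep only reciprocated edges.
#' @return an undirected igraph over cell indices (vertex names =
#'   rownames of the embedding when present).
#' @export
knn_graph <- function(embedding, k = 30L, mutual = TRUE) {
  n <- nrow(embedding)
  stopifnot(k < n)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(r) order(r)[seq_len(k)])
  edges <- cbind(rep(seq_len(n), each = k), as.vector(nn))
  if (mutual) {
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))
    keep <- key %in% names(which(table(key) == 2L))
    edges <- edges[keep, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(
    unique(cbind(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]))), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (!is.null(rownames(embedding))) {
    igraph::V(g)$name <- rownames(embedding)[seq_len(igraph::vcount(g))]
  }
  g
}

#' Propagate seed-cell signal over the cell graph (random walk with
#' restart)
#'
#' Seeds are the top `seed_proportion` of cells by raw deviation
#' z-score (default 5%). The walk restarts to the uniform seed
#' distribution with probability `restart_prob` and iterates until the
#' L1 change drops below `tol`. Scores are min-max scaled to [0, 1];
#' cells disconnected from every seed stay at 0.
#'
#' @param raw_z per-cell deviation z-scores (named).
#' @param graph undirected igraph over the same cells (vertex order =
#'   order of `raw_z`).
#' @param seed_proportion fraction of cells used as seeds.
#' @param restart_prob restart probability of the walk.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return data.frame of class `trs_result`: `cell`, `raw_z`,
#'   `is_seed`, `trs`.
#' @export
propagate_trs <- function(raw_z, graph, seed_proportion = 0.05,
                          restart_prob = 0.05, tol = 1e-6,
                          max_iter = 5000L) {
  n <- length(raw_z)
  stopifnot(igraph::vcount(graph) == n)
  n_seed <- max(1L, round(seed_proportion * n))
  seeds <- order(raw_z, decreasing = TRUE)[seq_len(n_seed)]
  if (length(seeds) == 0) stop("no seed cells selected")

  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  deg <- Matrix::colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  p0 <- numeric(n)
  p0[seeds] <- 1 / n_seed
  s <- p0
  for (it in seq_len(max_iter)) {
    s_new <- (1 - restart_prob) * as.vector(A %*% (s * inv)) +
      restart_prob * p0
    # mass lost at isolated vertices is not redistributed
    if (sum(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  rng <- range(s)
  trs <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else s
  out <- data.frame(
    cell = if (!is.null(names(raw_z))) names(raw_z) else seq_len(n),
    raw_z = as.numeric(raw_z),
    is_seed = seq_len(n) %in% seeds,
    trs = trs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trs_result", "data.frame")
  out
}

#' Mean trait relevance score by cell type and category
#'
#' @param trs a [propagate_trs()] result.
#' @param cells cell metadata with `barcode`, `cell_type`, `category`.
#' @return list with `by_cell_type` and `by_category` data.frames,
#'   sorted by decreasing mean TRS.
#' @export
compare_trs_groups <- function(trs, cells) {
  m <- merge(trs, cells, by.x = "cell", by.y = "barcode")
  agg <- function(col) {
    a <- aggregate(m$trs, list(group = m[[col]]), mean)
    names(a) <- c(col, "mean_trs")
    a$n_cells <- as.vector(table(m[[col]])[a[[col]]])
    a[order(-a$mean_trs), ]
  }
  list(by_cell_type = agg("cell_type"), by_category = agg("category"))
}
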