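# Graphical lasso with an elementwise penalty matrix (blockwise
# coordinate descent). Small-p version sufficient for sliding genomic
# windows of peaks. Returns the precision matrix.
glasso_fit <- function(S, Rho, tol = 1e-4, max_iter = 100L) {
  p <- ncol(S)
  if (p == 1L) return(matrix(1 / (S[1, 1] + Rho[1, 1]), 1, 1))
  W <- S + diag(diag(Rho), p)
  B <- matrix(0, p, p)  # lasso coefficients per column
  for (iter in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      r12 <- Rho[idx, j]
      beta <- B[idx, j]
      # coordinate descent for the penalized regression
      for (cd in seq_len(50L)) {
        beta_old <- beta
        for (a in seq_along(idx)) {
          x <- s12[a] - sum(W11[a, -a] * beta[-a])
          beta[a] <- sign(x) * max(abs(x) - r12[a], 0) / W11[a, a]
        }
        if (max(abs(beta - beta_old)) < tol * 1e-2) break
      }
      B[idx, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(diag(S)))) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    denom <- W[j, j] - sum(W[idx, j] * B[idx, j])
    Theta[j, j] <- 1 / denom
    Theta[idx, j] <- -B[idx, j] / denom
  }
  (Theta + t(Theta)) / 2
}

#' Distance-penalized co-accessibility scores between peaks
#'
#' Within sliding genomic windows, computes regularized partial
#' correlations between peak accessibility profiles across metacells
#' via a graphical lasso whose penalty increases with genomic distance:
#' `penalty(d) = rho0 + dist_scale * (d / window)^2`. Scores of pairs
#' appearing in several windows are averaged. Counts are log-normalized
#' per metacell before the correlation matrix is formed.
#'
#' @param metacell_counts peak x metacell count matrix.
#' @param peaks data.frame with `peak_id`, `chrom`, `start`, `end`
#'   matching the rows.
#' @param window window span in bp.
#' @param step window step in bp.
#' @param rho0 baseline graphical-lasso penalty.
#' @param dist_scale weight of the quadratic distance penalty.
#' @return data.frame of class `coaccess_edges` (peak_a, peak_b, score),
#'   symmetric by convention (each unordered pair once, `peak_a` <
#'   `peak_b` by position), only non-zero scores.
#' @export
coaccessibility <- function(metacell_counts, peaks, window = 5e5,
                            step = 2.5e5, rho0 = 0.12, dist_scale = 0.2) {
  stopifnot(nrow(metacell_counts) == nrow(peaks))
  ord <- order(peaks$chrom, peaks$start)
  peaks <- peaks[ord, , drop = FALSE]
  m <- as.matrix(metacell_counts)[ord, , drop = FALSE]
  # log CPM-style normalization per metacell
  depth <- pmax(colSums(m), 1)
  x <- log1p(t(t(m) / depth * 1e4))

  mid <- (peaks$start + peaks$end) / 2
  acc_sum <- list()
  acc_n <- list()
  for (ch in unique(peaks$chrom)) {
    on_ch <- which(peaks$chrom == ch)
    lo <- min(mid[on_ch])
    hi <- max(mid[on_ch])
    starts <- seq(lo, max(lo, hi - window / 2), by = step)
    for (ws in starts) {
      in_w <- on_ch[mid[on_ch] >= ws & mid[on_ch] < ws + window]
      if (length(in_w) < 2L) next
      xs <- x[in_w, , drop = FALSE]
      keep <- apply(xs, 1L, sd) > 0
      in_w <- in_w[keep]
      if (length(in_w) < 2L) next
      S <- cor(t(x[in_w, , drop = FALSE]))
      if (anyNA(S)) next
      d <- abs(outer(mid[in_w], mid[in_w], `-`))
      Rho <- rho0 + dist_scale * (d / window)^2
      Theta <- glasso_fit(S, Rho)
      dn <- sqrt(diag(Theta))
      pc <- -Theta / outer(dn, dn)
      diag(pc) <- 1
      for (a in seq_along(in_w)[-length(in_w)]) {
        for (b in (a + 1L):length(in_w)) {
          if (pc[a, b] == 0) next
          key <- paste(in_w[a], in_w[b], sep = "_")
          acc_sum[[key]] <- (acc_sum[[key]] %||% 0) + pc[a, b]
          acc_n[[key]] <- (acc_n[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  if (length(acc_sum) == 0) {
    edges <- data.frame(peak_a = character(), peak_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  } else {
    ij <- do.call(rbind, strsplit(names(acc_sum), "_"))
    edges <- data.frame(
      peak_a = peaks$peak_id[as.integer(ij[, 1])],
      peak_b = peaks$peak_id[as.integer(ij[, 2])],
      score = pmax(pmin(unlist(acc_sum) / unlist(acc_n), 1), -1),
      stringsAsFactors = FALSE
    )
    rownames(edges) <- NULL
  }
  class(edges) <- c("coaccess_edges", "data.frame")
  edges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect co-accessible peak modules by Louvain community detection
#'
#' Thresholds the co-accessibility graph at `cutoff` and partitions it
#' with the Louvain algorithm; modules of fewer than two peaks are
#' discarded. Module ids are deterministic under a fixed seed and
#' renumbered by their first member's id.
#'
#' @param edges a [coaccessibility()] result (peak_a, peak_b, score).
#' @param cutoff minimum co-accessibility score for an edge (default
#'   0.32, the module-graph threshold; 0.5 defines "directly
#'   co-accessible" pairs).
#' @param seed RNG seed for Louvain.
#' @return named list of modules (character vectors of peak ids),
#'   names `module_1`, `module_2`, ...
#' @export
detect_modules <- function(edges, cutoff = 0.32, seed = 1L) {
  keep <- edges$score >= cutoff
  if (!any(keep)) return(structure(list(), names = character()))
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("peak_a", "peak_b")], directed = FALSE)
  igraph::E(g)$weight <- e$score
  comm <- with_seed(seed, igraph::cluster_louvain(g))
  mem <- igraph::membership(comm)
  mods <- split(names(mem), mem)
  mods <- mods[vapply(mods, length, 0L) >= 2L]
  if (length(mods) == 0) return(structure(list(), names = character()))
  mods <- mods[order(vapply(mods, function(z) sort(z)[1], ""))]
  names(mods) <- sprintf("module_%d", seq_along(mods))
  mods
}
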