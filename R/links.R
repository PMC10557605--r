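#' Link peak accessibility to gene expression with matched backgrounds
#'
#' For each gene, candidate peaks are those within `distance` bp of the
#' TSS and detected (non-zero) in at least `min_cells` cells. The
#' observed statistic is the Pearson correlation between log-normalized
#' peak accessibility and gene expression across barcode-matched cells.
#' Its null distribution is estimated from `n_bg` background peaks
#' matched to the candidate by nearest neighbors in the standardized
#' (GC content, mean accessibility, peak width) space, correcting the
#' test for these technical covariates: `z = (r - mean(r_bg)) /
#' sd(r_bg)` with a one-sided p-value. Links with `p < p_cutoff` and
#' `|r| > score_cutoff` are retained.
#'
#' @param atac peak x cell counts (sparse ok).
#' @param rna gene x cell counts, same barcodes.
#' @param peaks data.frame: `peak_id`, `chrom`, `start`, `end`, `gc`,
#'   `width` (rows = atac rows).
#' @param genes data.frame: `gene_id`, `chrom`, `tss` (rows = rna rows).
#' @param distance cis window around the TSS in bp.
#' @param min_cells minimum cells with a non-zero peak count.
#' @param n_bg background peaks per candidate.
#' @param p_cutoff,score_cutoff retention thresholds.
#' @param normalize log-CPM normalize counts before correlating.
#' @return list of class `peak_gene_links`: `links` (retained rows:
#'   peak_id, gene_id, r, z, p, n_cells_detected), `all_pairs` (every
#'   tested pair, for calibration studies), `skipped` (zero-variance or
#'   under-detected pairs count).
#' @export
link_peaks_to_genes <- function(atac, rna, peaks, genes,
                                distance = 1e6, min_cells = 10L,
                                n_bg = 200L, p_cutoff = 0.05,
                                score_cutoff = 0.05, normalize = TRUE) {
  stopifnot(ncol(atac) == ncol(rna),
            nrow(peaks) == nrow(atac), nrow(genes) == nrow(rna))
  norm <- function(m) {
    m <- as.matrix(m)
    if (!normalize) return(m)
    log1p(t(t(m) / pmax(colSums(m), 1) * 1e4))
  }
  xa <- norm(atac)
  xr <- norm(rna)

  n_detected <- Matrix::rowSums(atac > 0)
  # exclude peaks constant on either scale (raw-constant peaks acquire
  # spurious variation from depth normalization)
  raw_sd <- apply(as.matrix(atac), 1L, sd)
  peak_sd <- apply(xa, 1L, sd)
  gene_sd <- apply(xr, 1L, sd)
  usable <- n_detected >= min_cells & peak_sd > 0 & raw_sd > 0

  # full gene x peak correlation matrix (fast: both modest at desk scale)
  R <- suppressWarnings(cor(t(xr), t(xa)))

  # background neighbor table in standardized (gc, accessibility, width)
  feat <- scale(cbind(peaks$gc, Matrix::rowMeans(atac), peaks$width))
  feat[is.na(feat)] <- 0
  fd <- as.matrix(stats::dist(feat))
  diag(fd) <- Inf
  bg_of <- apply(fd, 1L, function(r) {
    order(r)[seq_len(min(n_bg, length(r) - 1L))]
  }, simplify = FALSE)

  mid <- (peaks$start + peaks$end) / 2
  rows <- vector("list", nrow(genes))
  skipped <- 0L
  for (gi in seq_len(nrow(genes))) {
    if (gene_sd[gi] == 0) next
    cand <- which(peaks$chrom == genes$chrom[gi] &
                    abs(mid - genes$tss[gi]) <= distance)
    bad <- cand[!usable[cand]]
    skipped <- skipped + length(bad)
    cand <- cand[usable[cand]]
    if (length(cand) == 0) next
    res <- lapply(cand, function(pj) {
      r_obs <- R[gi, pj]
      if (is.na(r_obs)) return(NULL)
      r_bg <- R[gi, bg_of[[pj]]]
      r_bg <- r_bg[!is.na(r_bg)]
      if (length(r_bg) < 10L || sd(r_bg) == 0) return(NULL)
      z <- (r_obs - mean(r_bg)) / sd(r_bg)
      data.frame(peak_id = peaks$peak_id[pj], gene_id = genes$gene_id[gi],
                 r = r_obs, z = z, p = pnorm(z, lower.tail = FALSE),
                 n_cells_detected = n_detected[pj],
                 stringsAsFactors = FALSE)
    })
    rows[[gi]] <- do.call(rbind, res)
  }
  all_pairs <- do.call(rbind, rows)
  if (is.null(all_pairs)) {
    all_pairs <- data.frame(peak_id = character(), gene_id = character(),
                            r = numeric(), z = numeric(), p = numeric(),
                            n_cells_detected = integer(),
                            stringsAsFactors = FALSE)
  }
  rownames(all_pairs) <- NULL
  links <- all_pairs[all_pairs$p < p_cutoff &
                       abs(all_pairs$r) > score_cutoff, , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links, all_pairs = all_pairs, skipped = skipped),
            class = "peak_gene_links")
}

#' @export
print.peak_gene_links <- function(x, ...) {
  cat(sprintf("peak-gene links: %d retained of %d tested pairs (%d skipped)\n",
              nrow(x$links), nrow(x$all_pairs), x$skipped))
  invisible(x)
}
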