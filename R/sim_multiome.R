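#' Simulate a barcode-matched single-nucleus multiome with planted truth
#'
#' Generates a peak-by-cell accessibility matrix and a gene-by-cell
#' expression matrix over the same barcodes, together with peak and gene
#' models and a ground-truth record of everything that was planted:
#' cell-type-private peaks, co-accessible peak modules, and peak-gene
#' links driven by a shared latent factor.
#'
#' The accessibility model is a Bernoulli-gated Poisson: peak `j` in cell
#' `i` is open with a peak-specific probability (0 outside the home type
#' for private peaks; gated by a module on/off state for module members)
#' and, when open, contributes `Poisson(lambda_j * depth_i * exp(a * f))`
#' fragments, where `f` is the standard-normal latent factor of a planted
#' link and `a` its loading. Expression is negative binomial with
#' cell-type-specific means, the same latent factor entering the linked
#' gene's log-mean.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_multiome` with elements `atac` (sparse
#'   peaks x cells), `rna` (genes x cells), `cells` (metadata
#'   data.frame), `peaks`, `genes` (feature tables; BED-style 0-based
#'   half-open peak intervals, 1-based TSS), and `truth` (planted links,
#'   modules, specificity, relevant cell type).
#' @examples
#' sim <- simulate_multiome(sim_config(n_cells_per_type = 5, n_peaks = 40,
#'                                     n_genes = 10, seed = 7))
#' dim(sim$atac)
#' @export
simulate_multiome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  types <- names(config$taxonomy)
  n_types <- length(types)
  n_cells <- config$n_cells
  n_peaks <- config$n_peaks
  n_genes <- config$n_genes

  ## ---- genome layout -------------------------------------------------
  layout <- with_seed(child_seed(config$seed, "layout"), {
    spacing <- 40000 + sample(-8000:8000, n_peaks, replace = TRUE)
    start <- cumsum(spacing)
    width <- sample(350:700, n_peaks, replace = TRUE)

    # planted links seed modules: each link peak gets (module_size - 1)
    # partner peaks packed within a few kb so a GWAS LD block can span them
    n_links <- config$n_links
    m <- max(config$module_size, 1L)
    anchor_slots <- if (n_links > 0) {
      round(seq(10, n_peaks - 10 - m, length.out = n_links))
    } else integer(0)
    link_peaks <- anchor_slots
    module_members <- vector("list", n_links)
    if (m > 1 && n_links > 0) {
      for (l in seq_len(n_links)) {
        a <- anchor_slots[l]
        partners <- a + seq_len(m - 1L)
        # pull partners close to the anchor: 1-3 kb downstream, so one
        # GWAS LD block can cover the whole module
        off <- cumsum(sample(1000:1400, m - 1L, replace = TRUE))
        start[partners] <- start[a] + off
        width[partners] <- sample(300:500, m - 1L, replace = TRUE)
        module_members[[l]] <- c(a, partners)
      }
    } else if (n_links > 0) {
      module_members <- as.list(anchor_slots)
    }
    peaks <- data.frame(
      peak_id = sprintf("peak_%04d", seq_len(n_peaks)),
      chrom = "chr1",
      start = as.integer(start),
      end = as.integer(start + width),
      stringsAsFactors = FALSE
    )
    peaks$gc <- round(0.3 + 0.4 * rbeta(n_peaks, 5, 5), 4)
    peaks$width <- peaks$end - peaks$start

    # private peaks: never a module member or link anchor
    reserved <- unique(unlist(module_members))
    free <- setdiff(seq_len(n_peaks), reserved)
    n_private <- round(config$frac_private_peaks * n_peaks)
    n_private <- min(n_private, length(free))
    private_idx <- sort(sample(free, n_private))
    private_type <- rep(NA_character_, n_peaks)
    private_type[private_idx] <- sample(types, n_private, replace = TRUE)
    # the designated trait-relevant type (first in the taxonomy) always
    # owns a few private peaks, so planted GWAS loci have somewhere to go
    if (n_private >= 3) {
      private_type[private_idx[seq_len(3)]] <- types[[1L]]
    }
    peaks$private_type <- private_type

    # genes: linked genes within the cis window of their anchor peak,
    # the rest spread across the chromosome
    tss <- round(runif(n_genes, min(start), max(start)))
    link_genes <- if (n_links > 0) seq_len(n_links) else integer(0)
    for (l in seq_along(link_genes)) {
      tss[link_genes[l]] <- start[anchor_slots[l]] +
        sample(c(-1, 1), 1) * sample(50000:400000, 1)
    }
    genes <- data.frame(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      chrom = "chr1",
      tss = as.integer(pmax(tss, 1)),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(peaks = peaks, genes = genes, link_peaks = link_peaks,
         link_genes = link_genes, module_members = module_members)
  })
  peaks <- layout$peaks
  genes <- layout$genes

  ## ---- cells ---------------------------------------------------------
  cells <- with_seed(child_seed(config$seed, "cells"), {
    cell_type <- rep(types, each = config$n_cells_per_type)
    n <- length(cell_type)
    data.frame(
      barcode = sprintf("BC%05d", seq_len(n)),
      cell_type = cell_type,
      category = unname(config$taxonomy[cell_type]),
      sample = sprintf("S%02d", 1 + (seq_len(n) %% 16)),
      smoking = ifelse((seq_len(n) %% 16) < 8, "ever", "never"),
      stringsAsFactors = FALSE
    )
  })

  ## ---- shared latent factors and module gates ------------------------
  n_links <- config$n_links
  latents <- with_seed(child_seed(config$seed, "latent"), {
    f <- if (n_links > 0) {
      matrix(rnorm(n_links * n_cells), n_links, n_cells)
    } else matrix(0, 0, n_cells)
    # the module gate is the dichotomized link latent: the whole module
    # co-activates in cells where the shared regulator is high, which is
    # what couples module membership to the linked gene's expression
    gate <- if (n_links > 0 && config$module_size > 1) {
      (f > 0) + 0L
    } else matrix(0L, 0, n_cells)
    list(f = f, gate = gate)
  })

  ## ---- ATAC counts ---------------------------------------------------
  atac <- with_seed(child_seed(config$seed, "atac"), {
    depth <- exp(rnorm(n_cells, 0, 0.3))
    p0 <- runif(n_peaks, 0.10, 0.28)
    lam <- runif(n_peaks, 1.2, 3.0)
    popen <- matrix(rep(p0, n_cells), n_peaks, n_cells)
    # private peaks: closed outside the home type
    for (j in which(!is.na(peaks$private_type))) {
      popen[j, cells$cell_type != peaks$private_type[j]] <- 0
    }
    # module gating: partner peaks switch between near-closed and open
    # with the shared gate; the anchor stays mostly open (so its counts
    # remain graded) but follows the gate enough to co-access with them
    if (nrow(latents$gate) > 0) {
      s <- config$module_strength
      for (l in seq_len(n_links)) {
        mem <- layout$module_members[[l]]
        for (j in setdiff(mem, layout$link_peaks[l])) {
          popen[j, ] <- (1 - s) * p0[j] + s * latents$gate[l, ]
        }
        a <- layout$link_peaks[l]
        popen[a, ] <- 0.25 + 0.80 * s * latents$gate[l, ]
      }
    }
    # link latent raises both the open propensity (logit scale) and the
    # fragment intensity (log scale) of the anchor peak
    logmu <- outer(log(lam), log(depth), `+`)
    for (l in seq_len(n_links)) {
      j <- layout$link_peaks[l]
      a <- config$link_loading
      popen[j, ] <- stats::plogis(stats::qlogis(pmin(pmax(popen[j, ],
                                                          0.02), 0.98)) +
                                    a * latents$f[l, ])
      logmu[j, ] <- logmu[j, ] + a * latents$f[l, ] +
        max(0, log(2.5) - log(lam[j]))
    }
    open <- matrix(rbinom(n_peaks * n_cells, 1, as.vector(popen)),
                   n_peaks, n_cells)
    counts <- open * matrix(rpois(n_peaks * n_cells,
                                  pmin(exp(as.vector(logmu)), 50)),
                            n_peaks, n_cells)
    m <- Matrix::Matrix(counts, sparse = TRUE)
    dimnames(m) <- list(peaks$peak_id, cells$barcode)
    m
  })

  ## ---- RNA counts ----------------------------------------------------
  rna <- with_seed(child_seed(config$seed, "rna"), {
    depth <- exp(rnorm(n_cells, 0, 0.3))
    base <- exp(rnorm(n_genes, log(2), 0.8))
    type_fx <- matrix(exp(rnorm(n_genes * length(types), 0, 0.5)),
                      n_genes, length(types),
                      dimnames = list(NULL, types))
    logmu <- log(base) + log(type_fx[, cells$cell_type, drop = FALSE]) +
      rep(log(depth), each = n_genes)
    for (l in seq_len(n_links)) {
      g <- layout$link_genes[l]
      logmu[g, ] <- logmu[g, ] + config$link_loading * latents$f[l, ]
    }
    counts <- matrix(rnbinom(n_genes * n_cells, mu = exp(as.vector(logmu)),
                             size = 2),
                     n_genes, n_cells)
    m <- Matrix::Matrix(counts, sparse = TRUE)
    dimnames(m) <- list(genes$gene_id, cells$barcode)
    m
  })

  truth <- list(
    true_links = data.frame(
      peak_id = peaks$peak_id[layout$link_peaks],
      gene_id = genes$gene_id[layout$link_genes],
      loading = rep(config$link_loading, n_links),
      stringsAsFactors = FALSE
    ),
    true_modules = lapply(layout$module_members,
                          function(ix) peaks$peak_id[ix]),
    true_specificity = setNames(peaks$private_type, peaks$peak_id),
    relevant_cell_type = types[[1L]]
  )

  out <- list(atac = atac, rna = rna, cells = cells, peaks = peaks,
              genes = genes, truth = truth, config = config)
  class(out) <- "sim_multiome"
  out
}

#' @export
print.sim_multiome <- function(x, ...) {
  cat(sprintf("sim_multiome: %d peaks x %d cells (ATAC), %d genes (RNA)\n",
              nrow(x$atac), ncol(x$atac), nrow(x$rna)))
  cat(sprintf("  %d planted links, %d planted modules, %d private peaks\n",
              nrow(x$truth$true_links), length(x$truth$true_modules),
              sum(!is.na(x$peaks$private_type))))
  invisible(x)
}

#' Which cell types is each peak detected in?
#'
#' A peak is called detected in a cell type when it is non-zero in at
#' least `min_frac` of that type's cells (and at least one cell).
#'
#' @param atac sparse peak x cell count matrix.
#' @param cell_types character vector of per-cell type labels, aligned
#'   with the matrix columns.
#' @param min_frac minimum fraction of cells of a type with a non-zero
#'   count.
#' @return named list, peak id -> character vector of cell types.
#' @export
detected_cell_types <- function(atac, cell_types, min_frac = 0.05) {
  stopifnot(ncol(atac) == length(cell_types))
  types <- unique(cell_types)
  det <- sapply(types, function(ct) {
    cols <- which(cell_types == ct)
    frac <- Matrix::rowSums(atac[, cols, drop = FALSE] > 0) / length(cols)
    frac >= min_frac & frac > 0
  })
  rn <- rownames(atac)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(atac)))
  out <- apply(det, 1L, function(z) types[z], simplify = FALSE)
  names(out) <- rn
  out
}

#' Write a simulated multiome to disk in standard plain-text formats
#'
#' Emits MatrixMarket matrices with barcode and feature TSVs, a cell
#' metadata TSV, per-cell-type BED peak files, a TSS table and the ground
#' truth as JSON.
#'
#' @param sim a [simulate_multiome()] result.
#' @param outdir output directory (created if absent).
#' @param min_frac detection threshold passed to [detected_cell_types()].
#' @return `outdir`, invisibly.
#' @export
write_multiome <- function(sim, outdir, min_frac = 0.05) {
  stopifnot(inherits(sim, "sim_multiome"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sim$atac, file.path(outdir, "atac.mtx"))
  Matrix::writeMM(sim$rna, file.path(outdir, "rna.mtx"))
  writeLines(colnames(sim$atac), file.path(outdir, "barcodes.tsv"))
  writeLines(rownames(sim$atac), file.path(outdir, "peaks.tsv"))
  writeLines(rownames(sim$rna), file.path(outdir, "genes.tsv"))
  write.table(sim$cells, file.path(outdir, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$peaks, file.path(outdir, "peak_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$genes, file.path(outdir, "tss_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  det <- detected_cell_types(sim$atac, sim$cells$cell_type, min_frac)
  dir.create(file.path(outdir, "peaks_by_type"), showWarnings = FALSE)
  for (ct in unique(sim$cells$cell_type)) {
    keep <- vapply(det, function(z) ct %in% z, logical(1))
    bed <- sim$peaks[keep, c("chrom", "start", "end", "peak_id")]
    write.table(bed, file.path(outdir, "peaks_by_type",
                               paste0(gsub("[/ ]", "_", ct), ".bed")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(outdir)
}
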