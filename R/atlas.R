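#' Annotate peaks by position relative to gene models
#'
#' Classifies each peak as promoter, exonic, intronic or intergenic with
#' the precedence promoter > exonic > intronic > intergenic. The
#' promoter window is the strand-aware TSS +/- `tss_flank` bp (default
#' 3,000 on both sides). Gene bodies (for the intronic class) run from
#' TSS to the transcription end; exons are optional.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `peak_id`.
#' @param gene_models data.frame with `gene_id`, `chrom`, `tss`
#'   (1-based), `strand`, and optionally `tes` (transcription end) and an
#'   `exons` attribute-style data.frame (`chrom`, `start`, `end`,
#'   1-based closed) passed via `exons`.
#' @param exons optional data.frame of exon intervals (`chrom`, `start`,
#'   `end`, 1-based closed).
#' @param tss_flank promoter half-window in bp.
#' @return `peaks` with columns `annotation` and `promoter_gene` added
#'   (`promoter_gene` is `NA` unless the class is promoter).
#' @examples
#' pk <- data.frame(peak_id = "p1", chrom = "chr1",
#'                  start = 990L, end = 1400L)
#' gm <- data.frame(gene_id = "g1", chrom = "chr1", tss = 2000L,
#'                  strand = "+")
#' annotate_peaks(pk, gm)$annotation
#' @export
annotate_peaks <- function(peaks, gene_models, exons = NULL,
                           tss_flank = 3000) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)),
            all(c("gene_id", "chrom", "tss", "strand") %in%
                  names(gene_models)))
  if (nrow(peaks) > 0 &&
      !all(peaks$chrom %in% c(gene_models$chrom, peaks$chrom))) {
    stop("unknown chromosome in peaks")
  }
  # peaks: BED half-open -> 1-based closed for overlap arithmetic
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  prom <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(pmax(gene_models$tss - tss_flank, 1L),
                     gene_models$tss + tss_flank))
  hits_prom <- GenomicRanges::findOverlaps(pk, prom)

  annotation <- rep("intergenic", nrow(peaks))
  promoter_gene <- rep(NA_character_, nrow(peaks))

  if (length(hits_prom) > 0) {
    q <- S4Vectors::queryHits(hits_prom)
    s <- S4Vectors::subjectHits(hits_prom)
    # nearest TSS wins when several promoter windows overlap a peak
    mid <- (peaks$start + peaks$end) / 2
    d <- abs(mid[q] - gene_models$tss[s])
    best <- tapply(seq_along(q), q, function(ix) ix[which.min(d[ix])])
    bi <- unlist(best)
    annotation[q[bi]] <- "promoter"
    promoter_gene[q[bi]] <- gene_models$gene_id[s[bi]]
  }

  if (!is.null(exons) && nrow(exons) > 0) {
    ex <- GenomicRanges::GRanges(exons$chrom,
                                 IRanges::IRanges(exons$start, exons$end))
    hit <- GenomicRanges::countOverlaps(pk, ex) > 0
    annotation[hit & annotation != "promoter"] <- "exonic"
  }

  if ("tes" %in% names(gene_models)) {
    body_start <- pmin(gene_models$tss, gene_models$tes)
    body_end <- pmax(gene_models$tss, gene_models$tes)
    bd <- GenomicRanges::GRanges(gene_models$chrom,
                                 IRanges::IRanges(body_start, body_end))
    hit <- GenomicRanges::countOverlaps(pk, bd) > 0
    annotation[hit & annotation == "intergenic"] <- "intronic"
  }

  peaks$annotation <- annotation
  peaks$promoter_gene <- promoter_gene
  peaks
}

#' Colocalize CCVs with cCREs
#'
#' A variant (1-based position) falls in a peak (0-based half-open) iff
#' `start < pos <= end`, i.e. the first base of the peak is `start + 1`.
#'
#' @param ccvs data.frame with `variant_id`, `chrom`, `pos` (1-based).
#' @param atlas data.frame with `peak_id`, `chrom`, `start`, `end` and
#'   optionally a `detected_in` list-column of cell types.
#' @return data.frame of (variant_id, peak_id) rows plus locus id and
#'   the peak's detected cell types when available.
#' @export
colocalize_ccvs <- function(ccvs, atlas) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(ccvs)),
            all(c("peak_id", "chrom", "start", "end") %in% names(atlas)))
  if (nrow(ccvs) == 0 || nrow(atlas) == 0) {
    return(data.frame(variant_id = character(), peak_id = character(),
                      stringsAsFactors = FALSE))
  }
  vr <- GenomicRanges::GRanges(ccvs$chrom,
                               IRanges::IRanges(ccvs$pos, ccvs$pos))
  pk <- GenomicRanges::GRanges(atlas$chrom,
                               IRanges::IRanges(atlas$start + 1L, atlas$end))
  h <- GenomicRanges::findOverlaps(vr, pk)
  q <- S4Vectors::queryHits(h)
  s <- S4Vectors::subjectHits(h)
  out <- data.frame(variant_id = ccvs$variant_id[q],
                    peak_id = atlas$peak_id[s],
                    stringsAsFactors = FALSE)
  if ("locus_id" %in% names(ccvs)) out$locus_id <- ccvs$locus_id[q]
  if ("merged_locus_id" %in% names(ccvs)) {
    out$locus_id <- ccvs$merged_locus_id[q]
  }
  if ("detected_in" %in% names(atlas)) {
    out$detected_in <- atlas$detected_in[s]
  }
  rownames(out) <- NULL
  out
}

#' Per-category strict detection thresholds from the quartile rule
#'
#' For a category with `n_c` cell types, a peak exceeds the expected
#' 75th percentile when it is detected in strictly more than
#' `0.75 * n_c` of them. With the default taxonomy this gives epithelial
#' > 6 of 8, immune > 5.25 of 7, endothelial and stromal > 3 of 4.
#'
#' @param taxonomy named character vector, cell type -> category.
#' @return named numeric vector of strict lower bounds per category.
#' @examples
#' category_thresholds(default_taxonomy())
#' @export
category_thresholds <- function(taxonomy = default_taxonomy()) {
  n_c <- table(taxonomy)
  setNames(0.75 * as.numeric(n_c), names(n_c))
}

#' Assign cell-type/category specificity to a peak
#'
#' Implements the quartile rule: a peak detected in a single cell type
#' is specific to that type (and its category); a peak whose detected
#' types all share one category is specific to that category; otherwise
#' each category in which the detected count strictly exceeds its 75th
#' percentile threshold (`> 0.75 * n_c`) is assigned, with multiple
#' categories allowed on ties. If no category passes, the peak is
#' "shared". A `depleted` attribute records categories below the 25th
#' percentile (`< 0.25 * n_c`), which plays no role in assignment.
#'
#' @param detected_in character vector of cell types the peak is
#'   detected in.
#' @param taxonomy named character vector, cell type -> category.
#' @return list of class `specificity_call`: `level` in
#'   `c("single_cell_type", "single_category", "multi_category",
#'   "shared")`, `assigned` (categories), `assigned_cell_type`
#'   (or `NA`), `counts`, `depleted`.
#' @examples
#' tax <- default_taxonomy()
#' ep <- names(tax)[tax == "epithelial"][1:7]
#' im <- names(tax)[tax == "immune"][1:2]
#' st <- names(tax)[tax == "stromal"][1]
#' en <- names(tax)[tax == "endothelial"][1]
#' assign_specificity(c(ep, im, st, en), tax)$assigned  # "epithelial"
#' @export
assign_specificity <- function(detected_in, taxonomy = default_taxonomy()) {
  detected_in <- unique(detected_in)
  if (length(detected_in) == 0) stop("peak detected in no cell type")
  unknown <- setdiff(detected_in, names(taxonomy))
  if (length(unknown) > 0) {
    stop("cell type(s) not in taxonomy: ", paste(unknown, collapse = ", "))
  }
  cats <- taxonomy[detected_in]
  n_c <- table(factor(taxonomy, levels = unique(taxonomy)))
  counts <- table(factor(cats, levels = names(n_c)))
  thr_hi <- 0.75 * as.numeric(n_c)
  thr_lo <- 0.25 * as.numeric(n_c)
  depleted <- names(n_c)[as.numeric(counts) < thr_lo]

  if (length(detected_in) == 1L) {
    out <- list(level = "single_cell_type",
                assigned = unname(cats[1]),
                assigned_cell_type = detected_in)
  } else if (length(unique(cats)) == 1L) {
    out <- list(level = "single_category",
                assigned = unique(unname(cats)),
                assigned_cell_type = NA_character_)
  } else {
    hits <- names(n_c)[as.numeric(counts) > thr_hi]
    if (length(hits) == 0) {
      out <- list(level = "shared", assigned = "shared",
                  assigned_cell_type = NA_character_)
    } else {
      out <- list(level = "multi_category", assigned = hits,
                  assigned_cell_type = NA_character_)
    }
  }
  out$counts <- counts
  out$depleted <- depleted
  class(out) <- "specificity_call"
  out
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("specificity: %s -> %s%s\n", x$level,
              paste(x$assigned, collapse = "+"),
              if (!is.na(x$assigned_cell_type)) {
                paste0(" (", x$assigned_cell_type, ")")
              } else ""))
  invisible(x)
}

#' Summarize a locus to a single category label
#'
#' A locus is assigned to a category iff every CCV-colocalized cCRE of
#' the locus is assigned solely to that category; otherwise "mixed".
#' With `rule = "majority"` the most frequent single-category call wins
#' (ties -> "mixed").
#'
#' @param overlaps colocalization table for one locus (needs `peak_id`).
#' @param calls named list of `specificity_call`s keyed by peak id.
#' @param rule "unanimity" (default) or "majority".
#' @return a single category label or "mixed".
#' @export
summarize_locus_category <- function(overlaps, calls,
                                     rule = c("unanimity", "majority")) {
  rule <- match.arg(rule)
  if (nrow(overlaps) == 0) stop("no colocalized cCREs for this locus")
  pks <- unique(overlaps$peak_id)
  asg <- lapply(pks, function(p) calls[[p]]$assigned)
  single <- vapply(asg, function(a) length(a) == 1L && a != "shared",
                   logical(1))
  labs <- vapply(asg[single], `[`, "", 1L)
  if (rule == "unanimity") {
    if (all(single) && length(unique(labs)) == 1L) unique(labs) else "mixed"
  } else {
    if (length(labs) == 0) return("mixed")
    tab <- sort(table(labs), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "mixed" else names(tab)[1]
  }
}
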