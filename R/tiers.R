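#' Six-level cCRE-to-gene tier assignment
#'
#' For every CCV-colocalizing cCRE `e` and every gene `g` with a TSS
#' within `distance` bp of the peak, the evidence levels are:
#' \describe{
#'   \item{1}{`e`'s module contains a promoter cCRE of `g` (other than
#'     `e` itself).}
#'   \item{2}{`e` is directly co-accessible (edge score > `direct_cutoff`)
#'     with a promoter cCRE of `g` (other than `e`).}
#'   \item{3}{`e` is itself annotated as a promoter of `g`.}
#'   \item{4}{`e`'s module contains a cCRE with a retained expression
#'     link to `g`.}
#'   \item{5}{`e` is directly co-accessible with an expression-linked
#'     cCRE of `g` (other than `e`).}
#'   \item{6}{`e` itself has a retained expression link to `g` — the
#'     strongest evidence.}
#' }
#' `max_level` is the highest attained level per (variant, peak, gene).
#'
#' @param ccv_overlaps colocalization table (`variant_id`, `peak_id`,
#'   optionally `locus_id`).
#' @param modules named list of peak-id vectors (see [detect_modules()]).
#' @param edges co-accessibility edge table (`peak_a`, `peak_b`,
#'   `score`).
#' @param atlas annotated peak table (`peak_id`, `chrom`, `start`,
#'   `end`, `annotation`, `promoter_gene`).
#' @param links retained peak-gene link table (`peak_id`, `gene_id`).
#' @param genes gene table (`gene_id`, `chrom`, `tss`).
#' @param distance cis window in bp.
#' @param direct_cutoff minimum edge score for "directly co-accessible".
#' @return data.frame (variant_id, locus_id?, peak_id, gene_id, levels
#'   as comma-string, max_level), one row per (variant, peak, gene)
#'   with at least one level.
#' @export
assign_tiers <- function(ccv_overlaps, modules, edges, atlas, links,
                         genes, distance = 1e6, direct_cutoff = 0.5) {
  if (nrow(ccv_overlaps) == 0) {
    return(data.frame(variant_id = character(), peak_id = character(),
                      gene_id = character(), levels = character(),
                      max_level = integer(), stringsAsFactors = FALSE))
  }
  missing_pk <- setdiff(ccv_overlaps$peak_id, atlas$peak_id)
  if (length(missing_pk) > 0) {
    stop("peak(s) absent from atlas: ", paste(missing_pk, collapse = ", "))
  }
  mod_of <- list()
  for (mn in names(modules)) for (p in modules[[mn]]) mod_of[[p]] <- mn

  # symmetric adjacency of direct edges above the cutoff
  direct <- list()
  if (nrow(edges) > 0) {
    ed <- edges[edges$score > direct_cutoff, , drop = FALSE]
    for (i in seq_len(nrow(ed))) {
      direct[[ed$peak_a[i]]] <- c(direct[[ed$peak_a[i]]], ed$peak_b[i])
      direct[[ed$peak_b[i]]] <- c(direct[[ed$peak_b[i]]], ed$peak_a[i])
    }
  }
  prom_of_gene <- split(
    atlas$peak_id[atlas$annotation == "promoter"],
    atlas$promoter_gene[atlas$annotation == "promoter"])
  linked_of_gene <- if (nrow(links) > 0) {
    split(links$peak_id, links$gene_id)
  } else list()
  mid <- setNames((atlas$start + atlas$end) / 2, atlas$peak_id)
  prom_gene_of <- setNames(atlas$promoter_gene, atlas$peak_id)

  uniq <- unique(ccv_overlaps[, c("peak_id"), drop = FALSE])
  out <- list()
  for (e in uniq$peak_id) {
    g_cand <- genes$gene_id[
      genes$chrom == atlas$chrom[match(e, atlas$peak_id)] &
        abs(genes$tss - mid[[e]]) <= distance]
    mod_members <- if (!is.null(mod_of[[e]])) {
      setdiff(modules[[mod_of[[e]]]], e)
    } else character()
    nbrs <- setdiff(unique(direct[[e]] %||% character()), e)
    for (g in g_cand) {
      proms <- setdiff(prom_of_gene[[g]] %||% character(), e)
      linked <- linked_of_gene[[g]] %||% character()
      lv <- c(
        if (length(intersect(mod_members, proms)) > 0) 1L,
        if (length(intersect(nbrs, proms)) > 0) 2L,
        if (!is.na(prom_gene_of[[e]]) && prom_gene_of[[e]] == g) 3L,
        if (length(intersect(mod_members, linked)) > 0) 4L,
        if (length(intersect(nbrs, setdiff(linked, e))) > 0) 5L,
        if (e %in% linked) 6L
      )
      if (length(lv) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        peak_id = e, gene_id = g,
        levels = paste(lv, collapse = ","),
        max_level = max(lv), stringsAsFactors = FALSE)
    }
  }
  tiers <- do.call(rbind, out)
  if (is.null(tiers)) {
    return(data.frame(variant_id = character(), peak_id = character(),
                      gene_id = character(), levels = character(),
                      max_level = integer(), stringsAsFactors = FALSE))
  }
  # expand to one row per colocalized variant
  vcols <- intersect(c("variant_id", "locus_id", "peak_id"),
                     names(ccv_overlaps))
  merged <- merge(ccv_overlaps[, vcols, drop = FALSE], tiers,
                  by = "peak_id")
  ord <- order(merged$peak_id, merged$gene_id, merged$variant_id)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}
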