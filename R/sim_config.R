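#' Default lung cell-type taxonomy
#'
#' Twenty-three cell types grouped into four categories: 8 epithelial,
#' 7 immune, 4 endothelial and 4 stromal, mirroring a typical annotated
#' human-lung multiome atlas.
#'
#' @return named character vector mapping cell type to category.
#' @examples
#' table(default_taxonomy())
#' @export
default_taxonomy <- function() {
  c(
    AT2 = "epithelial", AT1 = "epithelial", club = "epithelial",
    ciliated = "epithelial", goblet = "epithelial", basal = "epithelial",
    "AT1/AT2" = "epithelial", "AT2-proliferating" = "epithelial",
    NK = "immune", T_cell = "immune", macrophage = "immune",
    monocyte = "immune", B_cell = "immune", dendritic = "immune",
    "NK/T" = "immune",
    lymphatic = "endothelial", artery = "endothelial",
    vein = "endothelial", capillary = "endothelial",
    fibroblast = "stromal", smooth_muscle = "stromal",
    mesothelial = "stromal", myofibroblast = "stromal"
  )
}

#' Configuration for the synthetic multiome generator
#'
#' Bundles every knob of the synthetic data generator: the cell-type
#' taxonomy, matrix dimensions, the fraction of cell-type-private peaks,
#' planted peak-gene links and co-accessible modules, the LD block for the
#' simulated GWAS locus, planted allelic motifs, footprint depletion and
#' the MPRA allelic effect. Defaults emulate the study design at desk
#' scale: 23 cell types in 4 categories, roughly 2,000 cells, 37% private
#' peaks, planted links with latent loading 0.5 inside a +/- 1 Mb cis
#' window, 3-peak modules, a 50-variant LD block, a 40% footprint core
#' depletion and an MPRA allelic log-ratio shift of 0.5.
#'
#' @param n_cells_per_type cells simulated per cell type.
#' @param taxonomy named character vector, cell type -> category.
#' @param n_peaks number of accessibility peaks (before module partners are
#'   added; partner peaks of planted modules are carved out of this total).
#' @param n_genes number of genes.
#' @param frac_private_peaks fraction of peaks accessible in a single cell
#'   type only.
#' @param n_links number of planted peak-gene links.
#' @param link_loading latent-factor loading shared by a planted peak-gene
#'   pair (log-scale effect per standard-normal latent unit).
#' @param module_size peaks per planted co-accessible module; each planted
#'   link's peak seeds one module (0 or 1 disables modules).
#' @param module_strength gate strength in [0,1]: member peaks are open
#'   with probability `(1-s)*p0 + s` in module-active cells and
#'   `(1-s)*p0` otherwise.
#' @param n_variants variants in the simulated LD block.
#' @param ld_decay LD decay rate per kb (pairwise latent haplotype
#'   correlation `exp(-decay * distance_kb)`; thresholding to alleles
#'   attenuates it further). The default 0.003/kb, with near-shared
#'   allele frequencies within a block, yields a few dozen proxy
#'   variants at r2 > 0.8 per lead — the scale of real credible sets,
#'   which average ~50 CCVs per GWAS locus.
#' @param n_individuals diploid individuals genotyped for the locus.
#' @param footprint_depletion fraction of Tn5 insertion signal removed
#'   inside a bound motif core.
#' @param mpra_effect planted allelic shift of the MPRA activity ratio.
#' @param seed master RNG seed; fans out per component via [child_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cells_per_type = 10, n_peaks = 50, n_genes = 10)
#' cfg$n_cells
#' @export
sim_config <- function(n_cells_per_type = 87,
                       taxonomy = default_taxonomy(),
                       n_peaks = 250,
                       n_genes = 60,
                       frac_private_peaks = 0.37,
                       n_links = 5,
                       link_loading = 0.5,
                       module_size = 3,
                       module_strength = 0.85,
                       n_variants = 50,
                       ld_decay = 0.003,
                       n_individuals = 500,
                       footprint_depletion = 0.4,
                       mpra_effect = 0.5,
                       seed = 1L) {
  if (!is.character(taxonomy) || is.null(names(taxonomy)) ||
      any(!nzchar(names(taxonomy)))) {
    stop("taxonomy must be a named character vector: cell type -> category")
  }
  if (anyDuplicated(names(taxonomy))) stop("duplicate cell types in taxonomy")
  if (length(unique(taxonomy)) < 1L) stop("taxonomy has no categories")
  if (any(table(taxonomy) < 1L)) stop("taxonomy contains an empty category")
  props <- c(frac_private_peaks = frac_private_peaks,
             module_strength = module_strength,
             footprint_depletion = footprint_depletion)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  }
  if (n_variants < 2) stop("LD block needs at least 2 variants")
  if (ld_decay <= 0) stop("LD decay rate must be positive")
  if (n_links > n_genes) stop("more planted links than genes")
  if (n_links > n_peaks) stop("more planted links than peaks")
  if (module_size > 1 && n_links * module_size > n_peaks) {
    stop("planted modules do not fit into n_peaks")
  }
  cfg <- list(
    n_cells_per_type = as.integer(n_cells_per_type),
    taxonomy = taxonomy,
    n_cells = as.integer(n_cells_per_type) * length(taxonomy),
    n_peaks = as.integer(n_peaks),
    n_genes = as.integer(n_genes),
    frac_private_peaks = frac_private_peaks,
    n_links = as.integer(n_links),
    link_loading = link_loading,
    module_size = as.integer(module_size),
    module_strength = module_strength,
    n_variants = as.integer(n_variants),
    ld_decay = ld_decay,
    n_individuals = as.integer(n_individuals),
    footprint_depletion = footprint_depletion,
    mpra_effect = mpra_effect,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multiome configuration\n")
  cat(sprintf("  %d cell types in %d categories, %d cells total\n",
              length(x$taxonomy), length(unique(x$taxonomy)), x$n_cells))
  cat(sprintf("  %d peaks (%.0f%% private), %d genes, %d planted links (loading %.2f)\n",
              x$n_peaks, 100 * x$frac_private_peaks, x$n_genes,
              x$n_links, x$link_loading))
  cat(sprintf("  modules of %d peaks (strength %.2f); LD block of %d variants (decay %.3f/kb)\n",
              x$module_size, x$module_strength, x$n_variants, x$ld_decay))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
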