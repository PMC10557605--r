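#' Run the variant-to-gene pipeline end to end on synthetic data
#'
#' Orchestrates all stages on a generated multiome: simulation, GWAS
#' locus generation and CCV compilation, atlas annotation and
#' CCV-cCRE colocalization, category-specificity calls, allelic-TF
#' prediction with abundance filtering and footprinting, metacell
#' aggregation, co-accessibility, module detection, peak-gene links,
#' six-level tier assignment, and per-cell trait relevance scores.
#' One GWAS locus is planted per peak-gene link (its LD block spanning
#' the link peak and its module partners) plus up to `n_trs_loci` loci
#' on peaks private to the designated trait-relevant cell type.
#'
#' @param config a [sim_config()], a list of `sim_config` arguments, or
#'   a path to a YAML file with those arguments.
#' @param outdir optional output directory for stage TSVs.
#' @param with_tf run the allelic-TF stage.
#' @param with_trs run the trait-relevance stage.
#' @param n_trs_loci loci planted on trait-relevant private peaks.
#' @param metacell_k neighborhood size for metacell aggregation.
#' @return list of class `cremap_run`: `report` (one row per merged
#'   locus), `stages` (intermediate objects), `manifest` (config echo,
#'   seeds, stage row counts).
#' @examples
#' \donttest{
#' run <- run_pipeline(sim_config(n_cells_per_type = 20, n_peaks = 80,
#'                                n_genes = 20, n_links = 2, seed = 11))
#' run$report
#' }
#' @export
run_pipeline <- function(config, outdir = NULL, with_tf = TRUE,
                         with_trs = TRUE, n_trs_loci = 4L,
                         metacell_k = 30L) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }

  ## ---- simulate ------------------------------------------------------
  sim <- simulate_multiome(config)
  peaks <- sim$peaks
  mid <- (peaks$start + peaks$end) / 2

  ## ---- GWAS loci + CCVs ----------------------------------------------
  # center each planted locus on its module's footprint so the CCV
  # cluster (which tracks the causal variant) can span all members
  centers <- vapply(seq_len(nrow(sim$truth$true_links)), function(l) {
    mem <- sim$truth$true_modules[[l]] %||%
      sim$truth$true_links$peak_id[l]
    mean(mid[match(mem, peaks$peak_id)])
  }, numeric(1))
  priv <- which(peaks$private_type == sim$truth$relevant_cell_type)
  priv <- utils::head(priv, n_trs_loci)
  centers <- c(centers, mid[priv])
  ccv_sets <- list()
  for (i in seq_along(centers)) {
    loc <- simulate_gwas_locus(config, locus_id = sprintf("locus_%02d", i),
                               center = centers[i])
    ccv_sets[[i]] <- compile_ccvs(loc)
  }
  if (length(ccv_sets) == 0) {
    warning("no CCV input: empty report")
    return(structure(list(report = data.frame(), stages = list(sim = sim),
                          manifest = list(config = unclass(config))),
                     class = "cremap_run"))
  }
  merged <- merge_loci(ccv_sets)
  ccvs <- merged$ccvs

  ## ---- atlas ---------------------------------------------------------
  det <- detected_cell_types(sim$atac, sim$cells$cell_type)
  atlas <- annotate_peaks(peaks, sim$genes)
  atlas$detected_in <- unname(det[atlas$peak_id])
  overlaps <- colocalize_ccvs(ccvs, atlas)
  calls <- lapply(setNames(nm = unique(overlaps$peak_id)), function(p) {
    if (length(det[[p]]) == 0) {
      # below the detection threshold in every type: no specificity call
      return(list(level = "undetected", assigned = "shared",
                  assigned_cell_type = NA_character_))
    }
    assign_specificity(det[[p]], config$taxonomy)
  })

  ## ---- allelic TFs ---------------------------------------------------
  tf_stage <- NULL
  if (with_tf && nrow(overlaps) > 0) {
    tf_stage <- with_seed(child_seed(config$seed, "tfstage"), {
      planted <- allelic_pwm(8L, tf_name = "TF_planted")
      pwms <- c(list(TF_planted = planted),
                setNames(lapply(1:3, function(i) {
                  random_pwm(8L, tf_name = paste0("TF_decoy", i))
                }), paste0("TF_decoy", 1:3)))
      leads <- unique(overlaps$variant_id)[
        seq_len(min(3L, length(unique(overlaps$variant_id))))]
      preds <- do.call(rbind, lapply(leads, function(vid) {
        scene <- plant_motif_scene(planted)
        pr <- predict_allelic_tfs(scene$window, scene$ref, scene$alt,
                                  scene$variant_offset, pwms)
        if (nrow(pr) > 0) pr$variant_id <- vid
        pr
      }))
      tf_genes <- setNames(sim$genes$gene_id[seq_along(pwms)], names(pwms))
      abund <- abundant_tfs(tf_genes, sim$rna, sim$cells$cell_type)
      tr <- simulate_footprint_track(config, n_sites = 100)
      fp <- footprint_test(tr$counts, tr$bias, tr$positions, tr$motif_len)
      list(predictions = preds, abundance = abund, footprint = fp)
    })
  }

  ## ---- linkage -------------------------------------------------------
  emb <- lsi_embedding(sim$atac)
  mc <- make_metacells(sim$atac, emb, k = min(metacell_k, ncol(sim$atac) - 1L),
                       seed = child_seed(config$seed, "metacells"))
  edges <- coaccessibility(mc$counts, peaks)
  modules <- detect_modules(edges, seed = child_seed(config$seed, "louvain"))
  links <- link_peaks_to_genes(sim$atac, sim$rna, peaks, sim$genes)
  tiers <- assign_tiers(overlaps, modules, edges, atlas, links$links,
                        sim$genes)

  ## ---- trait relevance -----------------------------------------------
  trs_stage <- NULL
  if (with_trs && nrow(overlaps) > 0) {
    w <- variant_peak_weights(ccvs, overlaps, peaks$peak_id)
    z <- colocalization_zscores(sim$atac, w, peaks$gc,
                                seed = child_seed(config$seed, "trsbg"))
    g <- knn_graph(emb, k = min(30L, nrow(emb) - 1L))
    trs <- propagate_trs(z, g)
    trs_stage <- list(weights = w, raw_z = z, trs = trs,
                      groups = compare_trs_groups(trs, sim$cells))
  }

  ## ---- per-locus report ----------------------------------------------
  report <- do.call(rbind, lapply(split(ccvs, ccvs$merged_locus_id),
    function(cc) {
      loc <- cc$merged_locus_id[1]
      ov <- overlaps[overlaps$variant_id %in% cc$variant_id, , drop = FALSE]
      cat_lab <- if (nrow(ov) > 0) {
        summarize_locus_category(ov, calls)
      } else NA_character_
      tl <- tiers[tiers$variant_id %in% cc$variant_id, , drop = FALSE]
      lvl_counts <- vapply(1:6, function(l) {
        length(unique(tl$gene_id[tl$max_level == l]))
      }, 0L)
      n_allelic <- if (!is.null(tf_stage) && nrow(ov) > 0 &&
                       NROW(tf_stage$predictions) > 0) {
        length(intersect(
          ov$variant_id,
          tf_stage$predictions$variant_id[tf_stage$predictions$allelic]))
      } else 0L
      data.frame(locus_id = loc, n_ccvs = nrow(cc),
                 n_colocalized_ccvs = length(unique(ov$variant_id)),
                 n_ccres = length(unique(ov$peak_id)),
                 category = cat_lab,
                 n_allelic_tf_ccvs = n_allelic,
                 genes_l1 = lvl_counts[1], genes_l2 = lvl_counts[2],
                 genes_l3 = lvl_counts[3], genes_l4 = lvl_counts[4],
                 genes_l5 = lvl_counts[5], genes_l6 = lvl_counts[6],
                 stringsAsFactors = FALSE)
    }))
  rownames(report) <- NULL

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    stage_rows = c(ccvs = nrow(ccvs), overlaps = nrow(overlaps),
                   edges = nrow(edges), modules = length(modules),
                   links = nrow(links$links), tiers = nrow(tiers)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- structure(list(report = report,
                        stages = list(sim = sim, ccv_sets = ccv_sets,
                                      merged = merged, atlas = atlas,
                                      overlaps = overlaps, calls = calls,
                                      tf = tf_stage, metacells = mc,
                                      edges = edges, modules = modules,
                                      links = links, tiers = tiers,
                                      trs = trs_stage),
                        manifest = manifest),
                   class = "cremap_run")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(report, file.path(outdir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ccvs, file.path(outdir, "ccvs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(edges, file.path(outdir, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(tiers, file.path(outdir, "tiers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null",
                         force = TRUE)
  }
  out
}

#' @export
print.cremap_run <- function(x, ...) {
  cat("cremap pipeline run\n")
  print(x$report)
  invisible(x)
}
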