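#' Predict allele-specific TF binding at a variant
#'
#' Scores both alleles of a variant against a PWM collection. A factor
#' is reported when its best match (for either allele) passes the match
#' p-value threshold (default 1e-4); the allelic-binding flag requires
#' an absolute score difference (alt minus ref, on the [0, 1] relative
#' scale) larger than `delta_cutoff` (default 0.7).
#'
#' @param window upper-case DNA window centered on (or covering) the
#'   variant.
#' @param ref,alt reference and alternative bases.
#' @param variant_offset 1-based position of the variant in `window`.
#' @param pwms named list of [pwm()] objects.
#' @param match_p_max maximum match p-value for a reportable site.
#' @param delta_cutoff minimum |score_alt - score_ref| for the allelic
#'   flag.
#' @return data.frame with one row per passing factor: `tf_name`,
#'   `score_ref`, `score_alt`, `delta`, `strand`, `motif_offset`,
#'   `match_p`, `allelic`.
#' @export
predict_allelic_tfs <- function(window, ref, alt, variant_offset, pwms,
                                match_p_max = 1e-4, delta_cutoff = 0.7) {
  if (length(pwms) == 0) stop("empty PWM set")
  rows <- lapply(names(pwms), function(nm) {
    p <- pwms[[nm]]
    if (p$length > nchar(window)) return(NULL)
    sr <- score_allele(p, window, ref, variant_offset)
    sa <- score_allele(p, window, alt, variant_offset)
    best <- if (sa$score >= sr$score) sa else sr
    if (best$match_p > match_p_max) return(NULL)
    data.frame(tf_name = nm,
               score_ref = sr$score, score_alt = sa$score,
               delta = sa$score - sr$score,
               strand = best$strand, motif_offset = best$motif_offset,
               match_p = best$match_p,
               allelic = abs(sa$score - sr$score) > delta_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf_name = character(), score_ref = numeric(),
                      score_alt = numeric(), delta = numeric(),
                      strand = character(), motif_offset = integer(),
                      match_p = numeric(), allelic = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Filter predicted TFs by cell-type abundance
#'
#' A (TF, cell type) pair is "abundant" when (1) the TF's gene is
#' expressed (non-zero) in more than half of the cells of that type and
#' (2) its mean expression in that type strictly exceeds the 75th
#' percentile of the mean expressions over all candidate (TF, cell
#' type) pairs. TFs without a mapped gene are reported in the
#' `unmapped` attribute rather than silently dropped.
#'
#' @param tf_genes named character vector mapping TF name -> gene id.
#' @param expr gene x cell matrix (sparse or dense).
#' @param cell_types per-cell type labels aligned with columns.
#' @return data.frame (tf_name, cell_type, frac_expressing, mean_expr,
#'   abundant) for all candidate pairs, with attribute `unmapped`.
#' @export
abundant_tfs <- function(tf_genes, expr, cell_types) {
  stopifnot(ncol(expr) == length(cell_types))
  types <- unique(cell_types)
  if (any(table(cell_types) == 0)) stop("cell type with zero cells")
  unmapped <- names(tf_genes)[!tf_genes %in% rownames(expr)]
  mapped <- tf_genes[tf_genes %in% rownames(expr)]
  if (length(mapped) == 0) {
    out <- data.frame(tf_name = character(), cell_type = character(),
                      frac_expressing = numeric(), mean_expr = numeric(),
                      abundant = logical(), stringsAsFactors = FALSE)
    attr(out, "unmapped") <- unmapped
    return(out)
  }
  grid <- expand.grid(tf_name = names(mapped), cell_type = types,
                      stringsAsFactors = FALSE)
  grid$frac_expressing <- NA_real_
  grid$mean_expr <- NA_real_
  for (ct in types) {
    cols <- which(cell_types == ct)
    sub <- expr[mapped, cols, drop = FALSE]
    fr <- Matrix::rowSums(sub > 0) / length(cols)
    mn <- Matrix::rowMeans(sub)
    ix <- grid$cell_type == ct
    grid$frac_expressing[ix] <- unname(fr[match(mapped[grid$tf_name[ix]],
                                                rownames(sub))])
    grid$mean_expr[ix] <- unname(mn[match(mapped[grid$tf_name[ix]],
                                          rownames(sub))])
  }
  q75 <- quantile(grid$mean_expr, 0.75, names = FALSE)
  grid$abundant <- grid$frac_expressing > 0.5 & grid$mean_expr > q75
  attr(grid, "unmapped") <- unmapped
  grid
}

#' Draw a random high-information PWM
#'
#' Each position concentrates most probability on one base (Dirichlet
#' draw with one heavy component), giving motifs with a clear consensus
#' — convenient for planting allelic scenes in synthetic windows.
#'
#' @param length motif length.
#' @param tf_name label.
#' @param concentration weight of the dominant base.
#' @return a [pwm()] object.
#' @export
random_pwm <- function(length = 8L, tf_name = "TF", concentration = 20) {
  mat <- sapply(seq_len(length), function(i) {
    alpha <- rep(0.5, 4)
    alpha[sample.int(4, 1)] <- concentration
    g <- stats::rgamma(4, alpha)
    g / sum(g)
  })
  pwm(mat, tf_name = tf_name)
}

#' Draw a PWM capable of allele-specific binding at one position
#'
#' On the min-max-rescaled [0, 1] score, a single-base substitution can
#' only shift the score by that position's share of the motif's total
#' score range. A factor whose binding is destroyable by one SNV
#' therefore needs one near-deterministic position (here probability
#' ~0.997 for the preferred base) amid otherwise moderately informative
#' positions, so that the spike carries most of the information
#' content. This mirrors real allelic-binding motifs, where the variant
#' hits the core recognition base.
#'
#' @param length motif length.
#' @param spike_pos position carrying the near-deterministic base
#'   (default: center).
#' @param tf_name label.
#' @return a [pwm()] object with attribute `spike_pos`.
#' @export
allelic_pwm <- function(length = 8L, spike_pos = (length %/% 2L) + 1L,
                        tf_name = "TF_allelic") {
  spike_base <- sample.int(4, 1)
  # off-spike dominant bases avoid the spike base and its complement, so
  # shifted or reverse-strand placements cannot re-create the core match
  allowed <- setdiff(seq_len(4), c(spike_base, 5L - spike_base))
  mat <- sapply(seq_len(length), function(i) {
    p <- rep(0.55 / 3, 4)
    p[sample(allowed, 1)] <- 0.45
    p
  })
  spike <- rep(0.001, 4)
  spike[spike_base] <- 0.997
  mat[, spike_pos] <- spike
  out <- pwm(mat, tf_name = tf_name)
  attr(out, "spike_pos") <- spike_pos
  attr(out, "spike_base") <- BASES[spike_base]
  out
}

#' Plant a motif scene around a variant
#'
#' Builds a random background window, writes the motif consensus into
#' its center, and defines ref/alt alleles at a chosen motif position so
#' that the reference matches the consensus and the alternative is the
#' motif's least-favored base — a planted allelic-binding variant.
#'
#' @param p a [pwm()] object.
#' @param window_len total window length (odd recommended).
#' @param motif_pos 1-based position within the motif carrying the
#'   variant.
#' @return list: `window` (with ref allele), `ref`, `alt`,
#'   `variant_offset`.
#' @export
plant_motif_scene <- function(p, window_len = 41L,
                              motif_pos = which.max(p$ic)) {
  stopifnot(inherits(p, "pwm"), window_len >= p$length)
  pool <- BASES
  sb <- attr(p, "spike_base")
  if (!is.null(sb)) {
    # keep the critical base (and its complement) out of the flanks so
    # no shifted placement can substitute for the disrupted core
    pool <- setdiff(BASES, c(sb, chartr("ACGT", "TGCA", sb)))
  }
  chars <- sample(pool, window_len, replace = TRUE)
  start <- (window_len - p$length) %/% 2L + 1L
  cons <- strsplit(p$consensus, "")[[1]]
  chars[start:(start + p$length - 1L)] <- cons
  offset <- start + motif_pos - 1L
  ref <- cons[motif_pos]
  alt_pool <- BASES
  if (!is.null(sb)) {
    # an alt equal to the complement of the core base would re-create
    # the motif on the minus strand
    alt_pool <- setdiff(BASES, c(sb, chartr("ACGT", "TGCA", sb)))
  }
  probs <- p$prob[alt_pool, motif_pos]
  alt <- alt_pool[which.min(probs)]
  list(window = paste(chars, collapse = ""), ref = ref, alt = alt,
       variant_offset = offset)
}
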