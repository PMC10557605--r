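#' Simulate a GWAS locus with an LD block and a planted causal variant
#'
#' Haplotypes are generated by thresholding a first-order Gaussian
#' autoregressive process whose step correlation decays exponentially
#' with inter-variant distance (`exp(-decay * d_kb)`), which mimics a
#' haplotype copying process. Genotype dosages are sums of two
#' haplotypes; R-squared to the lead is the squared Pearson correlation
#' of dosages. A quantitative phenotype with a planted effect at the
#' causal variant yields marginal association p-values; the declared lead
#' is the variant with the smallest observed p (the index-SNP
#' convention), while the planted causal index is recorded separately.
#'
#' @param config a [sim_config()] object (`n_variants`, `ld_decay`,
#'   `n_individuals`, `seed`).
#' @param locus_id label for the locus.
#' @param center genomic position (bp) on which the variant block is
#'   centered; variants are spaced ~200 bp apart around it.
#' @param chrom chromosome name.
#' @param effect standardized effect size of the causal variant on the
#'   phenotype.
#' @param stream suffix for the RNG child stream, so several loci drawn
#'   from one config are independent.
#' @return a `gwas_locus`: list with `variants` (data.frame: locus_id,
#'   variant_id, chrom, pos, ref, alt, p, r2_to_lead, is_lead,
#'   is_conditional), `genotypes` (individuals x variants dosage matrix),
#'   `lead_index`, `causal_index`.
#' @examples
#' loc <- simulate_gwas_locus(sim_config(seed = 3), center = 1e6)
#' head(loc$variants)
#' @export
simulate_gwas_locus <- function(config, locus_id = "locus_1",
                                center = 1e6, chrom = "chr1",
                                effect = 0.35, stream = "") {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_variants < 2) stop("LD block needs at least 2 variants")
  if (config$ld_decay <= 0) stop("LD decay rate must be positive")
  m <- config$n_variants
  n <- config$n_individuals
  with_seed(child_seed(config$seed, paste0("gwas:", locus_id, stream)), {
    gaps <- sample(100:200, m - 1L, replace = TRUE)
    pos <- cumsum(c(0L, gaps))
    pos <- as.integer(round(center - pos[ceiling(m / 2)] + pos))
    step_r <- exp(-config$ld_decay * gaps / 1000)

    nh <- 2L * n
    z <- matrix(NA_real_, nh, m)
    z[, 1L] <- rnorm(nh)
    for (k in 2L:m) {
      z[, k] <- step_r[k - 1L] * z[, k - 1L] +
        sqrt(1 - step_r[k - 1L]^2) * rnorm(nh)
    }
    # variants on a tight haplotype block share their frequency up to
    # small perturbations, which keeps dosage r2 high among true proxies
    maf <- pmin(pmax(runif(1, 0.15, 0.45) + runif(m, -0.02, 0.02),
                     0.05), 0.5)
    hap <- sweep(z, 2L, qnorm(maf), `<`) + 0L
    geno <- hap[seq_len(n), ] + hap[n + seq_len(n), ]

    # drop monomorphic variants from consideration for causality
    mono <- apply(geno, 2L, function(g) var(g) == 0)
    causal <- sample(which(!mono)[abs(which(!mono) - m / 2) <= m / 6], 1L)
    y <- effect * scale(geno[, causal])[, 1L] + rnorm(n)

    r <- suppressWarnings(cor(geno, y))[, 1L]
    r[is.na(r)] <- 0
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    lead <- which.min(p)
    r2 <- suppressWarnings(cor(geno, geno[, lead]))[, 1L]^2
    r2[is.na(r2)] <- 0

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    variants <- data.frame(
      locus_id = locus_id,
      variant_id = sprintf("rs%s_%03d", gsub("[^0-9A-Za-z]", "", locus_id),
                           seq_len(m)),
      chrom = chrom,
      pos = pos,
      ref = ref,
      alt = unname(alt),
      p = p,
      r2_to_lead = r2,
      is_lead = seq_len(m) == lead,
      is_conditional = FALSE,
      stringsAsFactors = FALSE
    )
    structure(list(variants = variants, genotypes = geno,
                   lead_index = lead, causal_index = causal),
              class = "gwas_locus")
  })
}

#' @export
print.gwas_locus <- function(x, ...) {
  v <- x$variants
  cat(sprintf("gwas_locus %s: %d variants on %s:%d-%d, lead %s (p = %.2e)\n",
              v$locus_id[1], nrow(v), v$chrom[1], min(v$pos), max(v$pos),
              v$variant_id[x$lead_index], v$p[x$lead_index]))
  invisible(x)
}
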