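#' Simulate MPRA tag-level activity ratios for one variant
#'
#' Reporter activity (RNA TPM / DNA TPM) per sequence tag, strand and
#' transfection batch: `ratio = base + effect * alt + strand_shift +
#' batch_shift + noise`, with mildly heteroskedastic noise (variance
#' grows with the mean) as tag-count ratios show in practice. The
#' default design is 25 tags x 2 strands x 5 batches per allele.
#'
#' @param config a [sim_config()] (`mpra_effect`, `seed`).
#' @param variant_id label.
#' @param n_tags unique sequence tags per allele.
#' @param n_batches transfection replicates.
#' @param effect override of `config$mpra_effect` (0 simulates a null
#'   variant).
#' @param stream RNG child-stream suffix.
#' @return data.frame: variant_id, allele, strand, tag, batch, ratio.
#' @export
simulate_mpra <- function(config, variant_id = "rs1", n_tags = 25L,
                          n_batches = 5L, effect = NULL, stream = "") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(effect)) effect <- config$mpra_effect
  with_seed(child_seed(config$seed, paste0("mpra:", variant_id, stream)), {
    d <- expand.grid(allele = c("ref", "alt"), strand = c("fwd", "rev"),
                     tag = sprintf("tag%02d", seq_len(n_tags)),
                     batch = sprintf("b%d", seq_len(n_batches)),
                     stringsAsFactors = FALSE)
    strand_shift <- c(fwd = 0, rev = -0.15)
    batch_shift <- setNames(rnorm(n_batches, 0, 0.1),
                            sprintf("b%d", seq_len(n_batches)))
    mu <- 1 + effect * (d$allele == "alt") +
      strand_shift[d$strand] + batch_shift[d$batch]
    d$ratio <- pmax(mu + rnorm(nrow(d), 0, 0.15 + 0.1 * abs(mu)), 0)
    cbind(variant_id = variant_id, d, stringsAsFactors = FALSE)
  })
}

#' Allelic-activity test for one variant's MPRA records
#'
#' Ordinary least squares of the activity ratio on allele, strand and
#' transfection batch (`ratio ~ allele + strand + batch`), with a
#' heteroskedasticity-consistent sandwich covariance (HC0 by default)
#' and a two-sided Wald test of the allele coefficient.
#'
#' @param records data.frame with `allele` (ref/alt), `strand`,
#'   `batch`, `ratio` for a single variant.
#' @param hc_type sandwich estimator variant ("HC0"-"HC3").
#' @return list: `beta` (alt vs ref), `se` (sandwich), `z`, `p`, `fit`.
#' @export
fit_allelic_activity <- function(records, hc_type = "HC0") {
  stopifnot(all(c("allele", "strand", "batch", "ratio") %in%
                  names(records)))
  if (length(unique(records$allele)) < 2L) {
    stop("both alleles must be observed")
  }
  records$allele <- factor(records$allele, levels = c("ref", "alt"))
  fit <- lm(ratio ~ allele + strand + batch, data = records)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design: allele confounded with a nuisance term")
  }
  V <- sandwich::vcovHC(fit, type = hc_type)
  beta <- coef(fit)[["allelealt"]]
  se <- sqrt(V["allelealt", "allelealt"])
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)), fit = fit)
}

#' Allelic MPRA test across variants with BH correction
#'
#' @param records data.frame with `variant_id`, `allele`, `strand`,
#'   `batch`, `ratio`.
#' @param hc_type sandwich estimator variant.
#' @return data.frame (variant_id, beta, se, z, p, fdr), FDR by the
#'   Benjamini-Hochberg step-up procedure.
#' @export
mpra_allelic_test <- function(records, hc_type = "HC0") {
  out <- do.call(rbind, lapply(split(records, records$variant_id),
    function(d) {
      f <- fit_allelic_activity(d, hc_type = hc_type)
      data.frame(variant_id = d$variant_id[1], beta = f$beta, se = f$se,
                 z = f$z, p = f$p, stringsAsFactors = FALSE)
    }))
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
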