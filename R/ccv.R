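#' Likelihood ratio of a variant against the locus lead
#'
#' Approximates the likelihood of each variant being causal from its
#' two-sided association p-value through the 1-df chi-square quantile:
#' `LR = exp((chisq_variant - chisq_lead) / 2)`. A variant at least
#' 1/1000 as likely as the lead (`LR >= 1e-3`) passes the credible-set
#' inclusion rule.
#'
#' @param p_variant,p_lead two-sided p-values in (0, 1].
#' @return the likelihood ratio (vectorized over `p_variant`).
#' @examples
#' likelihood_ratio_vs_lead(1e-6, 1e-6)   # 1
#' likelihood_ratio_vs_lead(1e-4, 5e-8)
#' @export
likelihood_ratio_vs_lead <- function(p_variant, p_lead) {
  if (any(p_variant <= 0 | p_variant > 1) || any(p_lead <= 0 | p_lead > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  chi_v <- qchisq(p_variant, df = 1, lower.tail = FALSE)
  chi_l <- qchisq(p_lead, df = 1, lower.tail = FALSE)
  exp((chi_v - chi_l) / 2)
}

#' Compile candidate causal variants for one locus
#'
#' Applies the credible-set selection rules to a locus's summary
#' statistics: the lead is always kept; a variant is kept when its
#' likelihood ratio against the lead is at least `llr_cutoff` (LLR rule)
#' and/or when its LD with the lead exceeds `r2_cutoff` (R-squared rule,
#' compared after rounding to 6 decimals so boundary values are
#' inclusive). Variants flagged `is_conditional` (independent signals
#' from conditional analysis without LD proxies) enter as singleton
#' members. Either rule can be switched off per study.
#'
#' @param locus a `gwas_locus` or a variant data.frame with columns
#'   `variant_id`, `p`, `r2_to_lead`, `is_lead` and optionally
#'   `is_conditional`, `chrom`, `pos`, `ref`, `alt`, `locus_id`.
#' @param llr_cutoff minimum likelihood ratio vs the lead (default
#'   1/1000); `NULL` disables the LLR rule.
#' @param r2_cutoff LD threshold (default 0.8); `NULL` disables the rule.
#' @return a `ccv_set`: list with `locus_id`, `lead_variant_id`, and
#'   `members` (data.frame variant_id + logical reason columns
#'   `reason_lead`, `reason_llr`, `reason_r2`, `reason_conditional`,
#'   plus coordinates when available).
#' @examples
#' loc <- simulate_gwas_locus(sim_config(seed = 5), center = 2e6)
#' compile_ccvs(loc)$members[1:3, ]
#' @export
compile_ccvs <- function(locus, llr_cutoff = 1e-3, r2_cutoff = 0.8) {
  v <- if (inherits(locus, "gwas_locus")) locus$variants else locus
  stopifnot(is.data.frame(v), all(c("variant_id", "is_lead") %in% names(v)))
  if (!any(v$is_lead)) stop("no lead variant declared in locus")
  if (sum(v$is_lead) > 1L) stop("more than one lead variant declared")
  lead <- which(v$is_lead)

  llr_hit <- rep(FALSE, nrow(v))
  if (!is.null(llr_cutoff)) {
    if (!"p" %in% names(v) || anyNA(v$p)) {
      stop("LLR rule requested but p-values are missing")
    }
    lr <- likelihood_ratio_vs_lead(v$p, v$p[lead])
    llr_hit <- lr >= llr_cutoff
  }
  r2_hit <- rep(FALSE, nrow(v))
  if (!is.null(r2_cutoff) && "r2_to_lead" %in% names(v)) {
    r2 <- round(v$r2_to_lead, 6)
    r2_hit <- !is.na(r2) & r2 >= round(r2_cutoff, 6) & r2 > 0
  }
  cond_hit <- if ("is_conditional" %in% names(v)) v$is_conditional else FALSE
  cond_hit <- cond_hit & !v$is_lead
  keep <- v$is_lead | llr_hit | r2_hit | cond_hit

  members <- v[keep, intersect(c("locus_id", "variant_id", "chrom", "pos",
                                 "ref", "alt", "p", "r2_to_lead"),
                               names(v)), drop = FALSE]
  members$reason_lead <- v$is_lead[keep]
  members$reason_llr <- llr_hit[keep] & !v$is_lead[keep]
  members$reason_r2 <- r2_hit[keep] & !v$is_lead[keep]
  members$reason_conditional <- cond_hit[keep]
  rownames(members) <- NULL
  structure(list(
    locus_id = if ("locus_id" %in% names(v)) v$locus_id[1] else "locus",
    lead_variant_id = v$variant_id[lead],
    members = members
  ), class = "ccv_set")
}

#' @export
print.ccv_set <- function(x, ...) {
  cat(sprintf("ccv_set %s: %d members (lead %s; %d by LLR, %d by R2, %d conditional)\n",
              x$locus_id, nrow(x$members), x$lead_variant_id,
              sum(x$members$reason_llr), sum(x$members$reason_r2),
              sum(x$members$reason_conditional)))
  invisible(x)
}

#' Merge overlapping loci and build the union CCV table
#'
#' Loci whose CCV footprints (the genomic span of their members) overlap
#' by any base pair are merged under one locus id; member variants are
#' deduplicated by (chrom, pos, ref, alt).
#'
#' @param ccv_sets list of `ccv_set` objects whose members carry `chrom`
#'   and `pos`.
#' @return list with `loci` (data.frame: merged_locus_id, chrom, start,
#'   end, source loci) and `ccvs` (union member table with
#'   `merged_locus_id`).
#' @export
merge_loci <- function(ccv_sets) {
  stopifnot(length(ccv_sets) > 0)
  spans <- do.call(rbind, lapply(ccv_sets, function(s) {
    m <- s$members
    if (!all(c("chrom", "pos") %in% names(m))) {
      stop("merge_loci needs member coordinates")
    }
    data.frame(locus_id = s$locus_id, chrom = m$chrom[1],
               start = min(m$pos), end = max(m$pos),
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start, spans$end))
  comp <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr))
  grp <- S4Vectors::subjectHits(comp)[order(S4Vectors::queryHits(comp))]
  merged_id <- sprintf("mlocus_%02d", grp)

  loci <- do.call(rbind, lapply(split(seq_along(ccv_sets), merged_id),
    function(ix) {
      data.frame(
        merged_locus_id = merged_id[ix[1]],
        chrom = spans$chrom[ix[1]],
        start = min(spans$start[ix]),
        end = max(spans$end[ix]),
        source_loci = paste(spans$locus_id[ix], collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  rownames(loci) <- NULL

  ccvs <- do.call(rbind, lapply(seq_along(ccv_sets), function(i) {
    m <- ccv_sets[[i]]$members
    m$merged_locus_id <- merged_id[i]
    m
  }))
  key <- with(ccvs, paste(chrom, pos,
                          if ("ref" %in% names(ccvs)) ref else "",
                          if ("alt" %in% names(ccvs)) alt else ""))
  ccvs <- ccvs[!duplicated(key), , drop = FALSE]
  rownames(ccvs) <- NULL
  list(loci = loci, ccvs = ccvs)
}
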