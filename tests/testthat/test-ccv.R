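test_that("likelihood ratio identities and the chi-square oracle hold", {
  expect_equal(likelihood_ratio_vs_lead(1e-6, 1e-6), 1)
  expect_equal(likelihood_ratio_vs_lead(0.5, 0.5), 1)
  # independent oracle: the 1-df chi-square quantile of a two-sided p
  # is the squared normal quantile of p/2
  oracle <- exp((qnorm(1e-4 / 2)^2 - qnorm(5e-8 / 2)^2) / 2)
  expect_equal(likelihood_ratio_vs_lead(1e-4, 5e-8), oracle,
               tolerance = 1e-10)
  expect_identical(likelihood_ratio_vs_lead(1e-4, 5e-8) >= 1e-3,
                   oracle >= 1e-3)
  expect_error(likelihood_ratio_vs_lead(0, 0.5), "0, 1")
  expect_error(likelihood_ratio_vs_lead(0.5, 1.5), "0, 1")
})

test_that("compiled CCV sets equal exhaustive rule evaluation", {
  for (s in 1:20) {
    loc <- simulate_gwas_locus(sim_config(seed = s), center = 3e6)
    got <- compile_ccvs(loc)
    v <- loc$variants
    lr <- exp((qchisq(v$p, 1, lower.tail = FALSE) -
                 qchisq(v$p[loc$lead_index], 1, lower.tail = FALSE)) / 2)
    want <- v$variant_id[v$is_lead | lr >= 1e-3 |
                           round(v$r2_to_lead, 6) >= 0.8]
    expect_setequal(got$members$variant_id, want)
    expect_true(v$variant_id[loc$lead_index] %in% got$members$variant_id)
  }
})

test_that("the lead is always a member and tagged as such", {
  loc <- simulate_gwas_locus(sim_config(seed = 30), center = 1e6)
  ccv <- compile_ccvs(loc)
  lead_row <- ccv$members[ccv$members$reason_lead, ]
  expect_equal(nrow(lead_row), 1L)
  expect_equal(lead_row$variant_id, ccv$lead_variant_id)
})

test_that("relaxing either rule never removes a member", {
  loc <- simulate_gwas_locus(sim_config(seed = 31), center = 1e6)
  base <- compile_ccvs(loc, llr_cutoff = 1e-3, r2_cutoff = 0.8)
  lower_r2 <- compile_ccvs(loc, llr_cutoff = 1e-3, r2_cutoff = 0.5)
  higher_llr <- compile_ccvs(loc, llr_cutoff = 1e-5, r2_cutoff = 0.8)
  expect_true(all(base$members$variant_id %in% lower_r2$members$variant_id))
  expect_true(all(base$members$variant_id %in%
                    higher_llr$members$variant_id))
})

test_that("conditional singletons enter without LD proxies", {
  v <- data.frame(
    locus_id = "L", variant_id = c("a", "b", "c"),
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = "A", alt = "C",
    p = c(1e-10, 0.5, 0.4), r2_to_lead = c(1, 0, 0),
    is_lead = c(TRUE, FALSE, FALSE),
    is_conditional = c(FALSE, FALSE, TRUE))
  ccv <- compile_ccvs(v)
  expect_setequal(ccv$members$variant_id, c("a", "c"))
  expect_true(ccv$members$reason_conditional[ccv$members$variant_id == "c"])
})

test_that("missing p-values fail only when the LLR rule is requested", {
  v <- data.frame(locus_id = "L", variant_id = c("a", "b"),
                  chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G",
                  p = c(NA, NA), r2_to_lead = c(1, 0.9),
                  is_lead = c(TRUE, FALSE))
  expect_error(compile_ccvs(v), "missing")
  ccv <- compile_ccvs(v, llr_cutoff = NULL)
  expect_setequal(ccv$members$variant_id, c("a", "b"))
})

test_that("merge_loci unions overlapping footprints and deduplicates", {
  mk <- function(id, pos, ids = NULL) {
    m <- data.frame(locus_id = id,
                    variant_id = ids %||% paste0(id, "_", seq_along(pos)),
                    chrom = "chr1", pos = pos, ref = "A", alt = "C",
                    reason_lead = seq_along(pos) == 1)
    structure(list(locus_id = id, lead_variant_id = m$variant_id[1],
                   members = m), class = "ccv_set")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  disjoint <- merge_loci(list(mk("A", c(100, 200)), mk("B", c(5000, 6000))))
  expect_equal(nrow(disjoint$loci), 2L)
  # overlapping spans sharing one variant position
  ov <- merge_loci(list(mk("A", c(100, 300)), mk("B", c(300, 500))))
  expect_equal(nrow(ov$loci), 1L)
  expect_equal(nrow(ov$ccvs), 3L)  # |A| + |B| - 1 shared coordinate
})

test_that("merged partition equals an interval-union oracle", {
  set.seed(40)
  mk <- function(id, lo, hi) {
    m <- data.frame(locus_id = id,
                    variant_id = paste0(id, "_", 1:2),
                    chrom = "chr1", pos = c(lo, hi), ref = "A", alt = "C")
    structure(list(locus_id = id, lead_variant_id = m$variant_id[1],
                   members = m), class = "ccv_set")
  }
  for (rep in 1:5) {
    lo <- sample(1:1000, 12)
    hi <- lo + sample(50:400, 12, replace = TRUE)
    sets <- lapply(seq_along(lo), function(i) {
      mk(sprintf("L%02d", i), lo[i], hi[i])
    })
    got <- merge_loci(sets)
    # sweep-line union oracle over the spans
    ord <- order(lo)
    groups <- integer(12)
    gid <- 0L
    cur_hi <- -Inf
    for (i in ord) {
      if (lo[i] > cur_hi) {
        gid <- gid + 1L
        cur_hi <- hi[i]
      } else cur_hi <- max(cur_hi, hi[i])
      groups[i] <- gid
    }
    expect_equal(nrow(got$loci), max(groups))
  }
})
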