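test_that("consensus scores exactly 1 and anti-consensus exactly 0", {
  set.seed(31)
  for (rep in 1:5) {
    p <- random_pwm(sample(5:9, 1))
    cons <- p$consensus
    anti <- paste(c("A", "C", "G", "T")[apply(p$prob, 2, which.min)],
                  collapse = "")
    sc <- score_allele(p, cons, substr(cons, 1, 1), 1)
    expect_equal(sc$score, 1, tolerance = 1e-12)
    sa <- score_allele(p, anti, substr(anti, 1, 1), 1)
    # anti-consensus is the floor unless a reverse-strand placement
    # scores higher; the rescaled floor itself is exactly 0
    expect_gte(sa$score, 0)
  }
})

test_that("best allele scores equal brute-force enumeration", {
  set.seed(32)
  for (rep in 1:50) {
    p <- random_pwm(sample(5:10, 1))
    window <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                    collapse = "")
    off <- sample(7:15, 1)
    allele <- sample(c("A", "C", "G", "T"), 1)
    got <- score_allele(p, window, allele, off)$score
    expect_equal(got, brute_score(p, window, allele, off),
                 tolerance = 1e-12)
  }
})

test_that("scoring is strand-symmetric", {
  set.seed(33)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
          collapse = "")
  }
  for (rep in 1:10) {
    p <- random_pwm(7)
    window <- paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE),
                    collapse = "")
    off <- 10L
    allele <- sample(c("A", "C", "G", "T"), 1)
    fwd <- score_allele(p, window, allele, off)
    rev_ <- score_allele(p, rc(window), chartr("ACGT", "TGCA", allele),
                         nchar(window) - off + 1L)
    expect_equal(fwd$score, rev_$score, tolerance = 1e-12)
  }
})

test_that("match p-values equal exhaustive k-mer enumeration", {
  set.seed(34)
  for (rep in 1:15) {
    p <- random_pwm(sample(4:8, 1))
    rel <- runif(1)
    expect_equal(pwm_match_pvalue(p, rel), enum_match_p(p, rel),
                 tolerance = 1e-12)
  }
  # boundary scores
  p <- random_pwm(6)
  expect_equal(pwm_match_pvalue(p, 0), 1, tolerance = 1e-12)
  expect_equal(pwm_match_pvalue(p, 1), enum_match_p(p, 1),
               tolerance = 1e-12)
})

test_that("identical alleles give delta zero and N windows give nothing", {
  set.seed(35)
  p <- random_pwm(6)
  window <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                  collapse = "")
  pr <- predict_allelic_tfs(window, "A", "A", 8, list(TF = p),
                            match_p_max = 1)
  expect_equal(pr$delta, 0)
  blank <- paste(c(rep("N", 7), "A", rep("N", 7)), collapse = "")
  pr2 <- predict_allelic_tfs(blank, "A", "C", 8, list(TF = p))
  expect_equal(nrow(pr2), 0L)
  expect_error(predict_allelic_tfs(window, "A", "C", 8, list()), "empty")
})

test_that("a planted core-disrupting variant is flagged allelic", {
  set.seed(36)
  for (rep in 1:10) {
    p <- allelic_pwm(8)
    sc <- plant_motif_scene(p)
    pr <- predict_allelic_tfs(sc$window, sc$ref, sc$alt,
                              sc$variant_offset, list(TF = p))
    expect_equal(nrow(pr), 1L)
    expect_lte(pr$match_p, 1e-4)
    expect_true(pr$allelic)
    expect_lt(pr$delta, -0.7)
  }
})

test_that("JASPAR round trip preserves the probability matrix", {
  set.seed(37)
  pwms <- list(M1 = random_pwm(6, "F1"), M2 = random_pwm(9, "F2"))
  path <- tempfile(fileext = ".jaspar")
  write_jaspar(pwms, path, counts_scale = 1e6)
  # probabilities were already pseudocounted at construction
  back <- read_jaspar(path, pseudocount = 0)
  expect_equal(names(back), c("F1", "F2"))
  expect_equal(back$F1$prob, pwms$M1$prob, tolerance = 1e-4)
  unlink(path)
})

test_that("abundance rule keeps the strongly expressed pair only", {
  cells <- rep(c("T1", "T2", "T3"), each = 20)
  set.seed(38)
  expr <- matrix(rpois(3 * 60, 1), 3, 60,
                 dimnames = list(c("gA", "gB", "gC"), NULL))
  expr["gA", cells == "T1"] <- rpois(20, 10)  # 10x higher in T1
  tf_genes <- c(TFA = "gA", TFB = "gB", TFX = "gMissing")
  res <- abundant_tfs(tf_genes, expr, cells)
  expect_equal(attr(res, "unmapped"), "TFX")
  kept <- res[res$abundant, ]
  expect_true(any(kept$tf_name == "TFA" & kept$cell_type == "T1"))
  # direct percentile oracle
  q75 <- quantile(res$mean_expr, 0.75, names = FALSE)
  expect_true(all(kept$mean_expr > q75 & kept$frac_expressing > 0.5))
})

test_that("uniform expression defeats the strict percentile rule", {
  cells <- rep(c("T1", "T2"), each = 10)
  expr <- matrix(5, 2, 20, dimnames = list(c("g1", "g2"), NULL))
  res <- abundant_tfs(c(TF1 = "g1", TF2 = "g2"), expr, cells)
  expect_false(any(res$abundant))
})

test_that("planted footprints are detected and flat tracks are not", {
  cfg <- sim_config(seed = 39)
  tr <- simulate_footprint_track(cfg, n_sites = 200, depletion = 0.4)
  fp <- footprint_test(tr$counts, tr$bias, tr$positions, tr$motif_len)
  expect_true(fp$significant)
  # statistic close to depletion x normalized core bias level
  core_level <- mean(fp$expected[fp$core])
  expect_lt(abs(fp$footprint_stat - 0.4 * core_level), 4 * fp$se)
  flat <- matrix(2L, 100, length(tr$bias))
  fp0 <- footprint_test(flat, rep(1, length(tr$bias)), tr$positions,
                        tr$motif_len)
  expect_false(fp0$significant)
  expect_lt(max(abs(fp0$corrected)), 1e-9)
  expect_error(footprint_test(tr$counts[0, ], tr$bias, tr$positions, 10),
               "no motif sites")
})
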