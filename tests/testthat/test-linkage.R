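test_that("metacells conserve counts and k=1 is the identity", {
  sim <- simulate_multiome(small_config(seed = 41))
  emb <- lsi_embedding(sim$atac, n_dims = 5)
  mc1 <- make_metacells(sim$atac, emb, k = 1)
  expect_equal(mc1$counts, as.matrix(sim$atac), ignore_attr = TRUE)
  mc <- make_metacells(sim$atac, emb, k = 10, seed = 2)
  for (i in seq_len(min(5, length(mc$members)))) {
    expect_equal(mc$counts[, i],
                 Matrix::rowSums(sim$atac[, mc$members[[i]], drop = FALSE]))
  }
  # pairwise overlap bounded at 10%
  for (i in seq_along(mc$members)) {
    for (j in seq_len(i - 1L)) {
      expect_lte(length(intersect(mc$members[[i]], mc$members[[j]])), 1L)
    }
  }
  expect_error(make_metacells(sim$atac, emb, k = 0), "at least 1")
  expect_error(make_metacells(sim$atac, emb, k = ncol(sim$atac)),
               "smaller")
})

test_that("metacells do not mix well-separated clusters", {
  set.seed(42)
  emb <- rbind(matrix(rnorm(100, 0), 50, 2),
               matrix(rnorm(100, 20), 50, 2))
  mat <- matrix(rpois(10 * 100, 2), 10, 100)
  mc <- make_metacells(mat, emb, k = 8, seed = 3)
  cluster <- rep(1:2, each = 50)
  purity <- vapply(mc$members, function(ix) {
    max(table(cluster[ix])) / length(ix)
  }, 0)
  expect_true(all(purity == 1))
})

test_that("duplicated peak profiles reach near-maximal co-accessibility", {
  set.seed(43)
  base <- rpois(150, 8)
  counts <- rbind(base, base + rpois(150, 1),
                  matrix(rpois(4 * 150, 8), 4, 150))
  peaks <- data.frame(peak_id = sprintf("p%d", 1:6), chrom = "chr1",
                      start = c(1000L, 2000L, 50000L, 90000L, 130000L,
                                170000L))
  peaks$end <- peaks$start + 400L
  edges <- coaccessibility(counts, peaks)
  dup <- edges[edges$peak_a == "p1" & edges$peak_b == "p2", ]
  # regularization caps the attainable partial correlation below 1;
  # the duplicated pair must clear the direct-edge cutoff and dominate
  expect_gt(dup$score, 0.5)
  expect_equal(dup$score, max(edges$score))
})

test_that("independent peaks rarely exceed |score| 0.1", {
  set.seed(44)
  counts <- matrix(rbinom(40 * 200, 20, 0.3), 40, 200)
  peaks <- data.frame(peak_id = sprintf("p%d", 1:40), chrom = "chr1",
                      start = seq(1000L, by = 12000L, length.out = 40))
  peaks$end <- peaks$start + 400L
  edges <- coaccessibility(counts, peaks)
  expect_gt(nrow(edges), 0)
  expect_gte(mean(abs(edges$score) < 0.1), 0.99)
})

test_that("co-accessibility is invariant to metacell order", {
  set.seed(45)
  counts <- matrix(rpois(10 * 80, 5), 10, 80)
  peaks <- data.frame(peak_id = sprintf("p%d", 1:10), chrom = "chr1",
                      start = seq(1000L, by = 9000L, length.out = 10))
  peaks$end <- peaks$start + 300L
  e1 <- coaccessibility(counts, peaks)
  e2 <- coaccessibility(counts[, sample(80)], peaks)
  m <- merge(e1, e2, by = c("peak_a", "peak_b"))
  expect_equal(m$score.x, m$score.y, tolerance = 1e-8)
})

test_that("Louvain modules recover planted cliques and drop singletons", {
  toy <- planted_module_edges(intra = 0.6, inter = 0.1)
  mods <- detect_modules(toy$edges)
  expect_length(mods, 5L)
  got <- setNames(rep(seq_along(mods), lengths(mods)), unlist(mods))
  expect_gte(adjusted_rand(got[names(toy$truth)], toy$truth), 0.999)
  # everything below the cutoff: no modules at all
  weak <- toy$edges
  weak$score <- 0.2
  expect_length(detect_modules(weak), 0L)
  # two clean cliques, no cross edges
  two <- planted_module_edges(n_mod = 2L, size = 5L, inter = 0)
  two$edges <- two$edges[two$edges$score > 0.3, ]
  expect_length(detect_modules(two$edges), 2L)
})

test_that("zero-variance peaks are excluded from linking", {
  sim <- simulate_multiome(small_config(seed = 46))
  atac <- as.matrix(sim$atac)
  atac[3, ] <- 5L  # constant accessibility
  res <- link_peaks_to_genes(atac, sim$rna, sim$peaks, sim$genes,
                             min_cells = 1)
  expect_false(sim$peaks$peak_id[3] %in% res$all_pairs$peak_id)
  expect_gt(res$skipped, 0)
})

test_that("a planted link is retained with r near the direct oracle", {
  cfg <- sim_config(n_links = 1, seed = 47)
  sim <- simulate_multiome(cfg)
  res <- link_peaks_to_genes(sim$atac, sim$rna, sim$peaks, sim$genes)
  tl <- sim$truth$true_links
  row <- res$links[res$links$peak_id == tl$peak_id &
                     res$links$gene_id == tl$gene_id, ]
  expect_equal(nrow(row), 1L)
  # oracle: direct Pearson on the same normalized matrices
  norm <- function(m) log1p(t(t(as.matrix(m)) /
                                pmax(colSums(as.matrix(m)), 1) * 1e4))
  oracle <- cor(norm(sim$atac)[tl$peak_id, ], norm(sim$rna)[tl$gene_id, ])
  expect_equal(row$r, oracle, tolerance = 1e-10)
  expect_gt(row$r, 0)
})

test_that("min.cells and the cis window bound the tested pairs", {
  sim <- simulate_multiome(small_config(seed = 48))
  res <- link_peaks_to_genes(sim$atac, sim$rna, sim$peaks, sim$genes,
                             min_cells = 10, distance = 1e6)
  expect_true(all(res$all_pairs$n_cells_detected >= 10))
  mid <- (sim$peaks$start + sim$peaks$end) / 2
  d <- abs(mid[match(res$all_pairs$peak_id, sim$peaks$peak_id)] -
             sim$genes$tss[match(res$all_pairs$gene_id,
                                 sim$genes$gene_id)])
  expect_true(all(d <= 1e6))
})

test_that("tier assignment matches the hand-enumerated table", {
  toy <- tier_toy()
  got <- assign_tiers(toy$overlaps, toy$modules, toy$edges, toy$atlas,
                      toy$links, toy$genes)
  want <- tier_toy_expected()
  key <- paste(got$peak_id, got$gene_id, sep = "|")
  expect_setequal(key, names(want))
  for (k in names(want)) {
    expect_equal(got$levels[key == k], want[[k]], label = k)
  }
  expect_equal(got$max_level[key == "p1|g1"], 5L)
  expect_equal(got$max_level[key == "p1|g4"], 6L)
})

test_that("tier assignment validates inputs and handles empties", {
  toy <- tier_toy()
  bad <- toy$overlaps
  bad$peak_id[1] <- "p99"
  expect_error(assign_tiers(bad, toy$modules, toy$edges, toy$atlas,
                            toy$links, toy$genes), "absent from atlas")
  empty <- assign_tiers(toy$overlaps[0, ], toy$modules, toy$edges,
                        toy$atlas, toy$links, toy$genes)
  expect_equal(nrow(empty), 0L)
  # genes outside the cis window are never assigned
  far <- toy$genes
  far$tss <- far$tss + 5e6L
  none <- assign_tiers(toy$overlaps, toy$modules, toy$edges, toy$atlas,
                       toy$links, far)
  expect_equal(nrow(none), 0L)
})
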