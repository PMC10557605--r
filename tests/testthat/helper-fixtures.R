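# small configurations used across test files
small_config <- function(seed = 1L, ...) {
  sim_config(n_cells_per_type = 10, n_peaks = 60, n_genes = 15,
             n_links = 2, seed = seed, ...)
}

# brute-force relative motif score: every placement x strand, plain loops
brute_score <- function(p, window, allele, off) {
  chars <- strsplit(window, "")[[1]]
  chars[off] <- allele
  L <- p$length
  W <- length(chars)
  rc <- function(x) rev(chartr("ACGT", "TGCA", x))
  best <- -Inf
  for (strand in c("+", "-")) {
    cc <- if (strand == "+") chars else rc(chars)
    oo <- if (strand == "+") off else W - off + 1L
    for (t in max(1, oo - L + 1):min(oo, W - L + 1)) {
      s <- sum(vapply(seq_len(L),
                      function(i) p$score[cc[t + i - 1L], i], 0))
      best <- max(best, s)
    }
  }
  (best - p$score_min) / (p$score_max - p$score_min)
}

# exhaustive k-mer match p-value for short motifs
enum_match_p <- function(p, rel) {
  L <- p$length
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(p$score[cbind(as.vector(grid),
                                     rep(seq_len(L), each = nrow(grid)))],
                       nrow(grid), L))
  relv <- (sc - p$score_min) / (p$score_max - p$score_min)
  bgp <- apply(matrix(p$bg[as.vector(grid)], nrow(grid), L), 1L, prod)
  sum(bgp[relv >= rel - 1e-9])
}

# edge list with five planted cliques and weak cross-links
planted_module_edges <- function(n_mod = 5L, size = 5L, intra = 0.6,
                                 inter = 0.1) {
  truth <- rep(seq_len(n_mod), each = size)
  pk <- sprintf("p%02d", seq_along(truth))
  intra_e <- do.call(rbind, lapply(seq_len(n_mod), function(m) {
    ix <- which(truth == m)
    cmb <- t(combn(ix, 2))
    data.frame(peak_a = pk[cmb[, 1]], peak_b = pk[cmb[, 2]],
               score = intra, stringsAsFactors = FALSE)
  }))
  firsts <- match(seq_len(n_mod), truth)
  cross <- data.frame(peak_a = pk[firsts[-n_mod]],
                      peak_b = pk[firsts[-1]],
                      score = inter, stringsAsFactors = FALSE)
  list(edges = rbind(intra_e, cross),
       truth = setNames(truth, pk))
}

# hand-built ten-peak / four-gene graph covering all six evidence levels
# and both exclusion conventions (the CCV cCRE never counts as its own
# promoter partner; level 6 does not imply level 5)
tier_toy <- function() {
  peaks <- data.frame(
    peak_id = sprintf("p%d", 1:10), chrom = "chr1",
    start = seq(10000L, by = 10000L, length.out = 10))
  peaks$end <- peaks$start + 500L
  atlas <- peaks
  atlas$annotation <- "intergenic"
  atlas$promoter_gene <- NA_character_
  atlas$annotation[c(1, 2, 6)] <- "promoter"
  atlas$promoter_gene[c(1, 2, 6)] <- c("g2", "g3", "g4")
  genes <- data.frame(gene_id = sprintf("g%d", 1:4), chrom = "chr1",
                      tss = c(150000L, 160000L, 170000L, 180000L))
  modules <- list(module_1 = c("p1", "p2"), module_2 = c("p9", "p10"))
  edges <- data.frame(
    peak_a = c("p1", "p5", "p7", "p9"),
    peak_b = c("p2", "p6", "p8", "p10"),
    score = c(0.6, 0.55, 0.7, 0.4))
  links <- data.frame(peak_id = c("p2", "p8", "p10", "p1"),
                      gene_id = c("g1", "g1", "g1", "g4"))
  overlaps <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                         peak_id = c("p1", "p5", "p7", "p9"))
  list(overlaps = overlaps, modules = modules, edges = edges,
       atlas = atlas, links = links, genes = genes)
}

# hand-derived level table for tier_toy()
tier_toy_expected <- function() {
  list(
    "p1|g1" = "4,5",  # module partner p2 linked to g1; direct 0.6 edge
    "p1|g2" = "3",    # own promoter only: e itself never counts for 1/2
    "p1|g3" = "1,2",  # p2 is promoter of g3: module and direct routes
    "p1|g4" = "6",    # own expression link; 6 does not force 5
    "p5|g4" = "2",    # direct edge to promoter of g4, no module
    "p7|g1" = "5",    # direct edge to an expression-linked cCRE
    "p9|g1" = "4"     # module route only: 0.4 edge is below direct 0.5
  )
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ij <- sum_a * sum_b / n
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}
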