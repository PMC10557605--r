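test_that("peak annotation follows the stated precedence", {
  gm <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   tss = c(10000L, 50000L), strand = c("+", "-"),
                   tes = c(30000L, 40000L))
  ex <- data.frame(chrom = "chr1", start = c(10000L, 25000L),
                   end = c(10200L, 25500L))
  pk <- data.frame(
    peak_id = c("prom", "prom_and_exon", "exon", "intron", "inter",
                "nochrom"),
    chrom = c(rep("chr1", 5), "chr9"),
    start = c(8000L, 12500L, 25100L, 20000L, 200000L, 100L),
    end = c(8400L, 13400L, 25300L, 20400L, 200400L, 500L))
  ann <- annotate_peaks(pk, gm, exons = ex)
  expect_equal(ann$annotation,
               c("promoter", "promoter", "exonic", "intronic",
                 "intergenic", "intergenic"))
  expect_equal(ann$promoter_gene[1], "g1")
  expect_true(is.na(ann$promoter_gene[3]))
})

test_that("promoter window is the TSS +/- 3000 bp, strand-aware input", {
  gm <- data.frame(gene_id = "g", chrom = "chr1", tss = 100000L,
                   strand = "-")
  inside <- data.frame(peak_id = "a", chrom = "chr1",
                       start = 102900L, end = 103200L)
  outside <- data.frame(peak_id = "b", chrom = "chr1",
                        start = 103001L, end = 103400L)
  expect_equal(annotate_peaks(inside, gm)$annotation, "promoter")
  expect_equal(annotate_peaks(outside, gm)$annotation, "intergenic")
})

test_that("annotation matches a per-class interval oracle on random peaks", {
  set.seed(21)
  gm <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr1",
                   tss = sort(sample(1e4:5e5, 8)), strand = "+")
  gm$tes <- gm$tss + sample(5000:20000, 8)
  ex <- data.frame(chrom = "chr1", start = gm$tss + 100L,
                   end = gm$tss + 400L)
  pk <- data.frame(peak_id = sprintf("p%d", 1:200), chrom = "chr1",
                   start = sample(1e3:6e5, 200))
  pk$end <- pk$start + 300L
  ann <- annotate_peaks(pk, gm, exons = ex)
  for (i in seq_len(nrow(pk))) {
    s <- pk$start[i] + 1L
    e <- pk$end[i]
    in_prom <- any(s <= gm$tss + 3000 & e >= gm$tss - 3000)
    in_exon <- any(s <= ex$end & e >= ex$start)
    in_body <- any(s <= gm$tes & e >= gm$tss)
    want <- if (in_prom) "promoter" else if (in_exon) "exonic" else
      if (in_body) "intronic" else "intergenic"
    expect_equal(ann$annotation[i], want)
  }
})

test_that("variant-in-peak uses 1-based versus half-open boundaries", {
  atlas <- data.frame(peak_id = "pk", chrom = "chr1",
                      start = 1000L, end = 1500L)
  first_base <- data.frame(variant_id = "v1", chrom = "chr1", pos = 1001L)
  before <- data.frame(variant_id = "v0", chrom = "chr1", pos = 1000L)
  last_base <- data.frame(variant_id = "v2", chrom = "chr1", pos = 1500L)
  after <- data.frame(variant_id = "v3", chrom = "chr1", pos = 1501L)
  expect_equal(colocalize_ccvs(first_base, atlas)$variant_id, "v1")
  expect_equal(nrow(colocalize_ccvs(before, atlas)), 0L)
  expect_equal(colocalize_ccvs(last_base, atlas)$variant_id, "v2")
  expect_equal(nrow(colocalize_ccvs(after, atlas)), 0L)
})

test_that("colocalization equals the brute-force double loop", {
  set.seed(22)
  atlas <- data.frame(peak_id = sprintf("p%d", 1:60),
                      chrom = sample(c("chr1", "chr2"), 60, TRUE),
                      start = sample(1:5e4, 60))
  atlas$end <- atlas$start + sample(200:600, 60, TRUE)
  ccvs <- data.frame(variant_id = sprintf("v%d", 1:150),
                     chrom = sample(c("chr1", "chr2"), 150, TRUE),
                     pos = sample(1:5e4, 150, TRUE))
  got <- colocalize_ccvs(ccvs, atlas)
  want <- 0L
  for (i in seq_len(nrow(ccvs))) {
    for (j in seq_len(nrow(atlas))) {
      hit <- ccvs$chrom[i] == atlas$chrom[j] &&
        atlas$start[j] < ccvs$pos[i] && ccvs$pos[i] <= atlas$end[j]
      if (hit) {
        want <- want + 1L
        expect_true(any(got$variant_id == ccvs$variant_id[i] &
                          got$peak_id == atlas$peak_id[j]))
      }
    }
  }
  expect_equal(nrow(got), want)
})

test_that("quartile-rule worked example assigns epithelial above 6 of 8", {
  tax <- default_taxonomy()
  detected <- c(names(tax)[tax == "epithelial"][1:7],
                names(tax)[tax == "immune"][1:2],
                names(tax)[tax == "stromal"][1],
                names(tax)[tax == "endothelial"][1])
  call <- assign_specificity(detected, tax)
  expect_equal(call$assigned, "epithelial")
  expect_equal(unname(category_thresholds(tax)["epithelial"]), 6)
  # 6 of 8 epithelial is not strictly above the threshold
  below <- assign_specificity(c(names(tax)[tax == "epithelial"][1:6],
                                names(tax)[tax == "immune"][1:2],
                                names(tax)[tax == "stromal"][1]), tax)
  expect_false("epithelial" %in% below$assigned &&
                 below$level == "multi_category")
})

test_that("single-type and single-category calls short-circuit", {
  tax <- default_taxonomy()
  one <- assign_specificity("AT2", tax)
  expect_equal(one$level, "single_cell_type")
  expect_equal(one$assigned_cell_type, "AT2")
  imm <- assign_specificity(names(tax)[tax == "immune"][1:3], tax)
  expect_equal(imm$level, "single_category")
  expect_equal(imm$assigned, "immune")
  expect_error(assign_specificity(character(0), tax), "no cell type")
  expect_error(assign_specificity("krill", tax), "not in taxonomy")
})

test_that("specificity rule matches a direct count oracle on all vectors", {
  tax <- default_taxonomy()
  n_c <- c(epithelial = 8, immune = 7, endothelial = 4, stromal = 4)
  set.seed(23)
  for (rep in 1:200) {
    counts <- vapply(n_c, function(n) sample(0:n, 1), 0L)
    if (sum(counts) == 0) next
    detected <- unlist(lapply(names(n_c), function(cat) {
      names(tax)[tax == cat][seq_len(counts[cat])]
    }))
    got <- assign_specificity(detected, tax)
    # direct rule evaluation
    want <- if (length(detected) == 1L) {
      unname(tax[detected])
    } else if (sum(counts > 0) == 1L) {
      names(counts)[counts > 0]
    } else {
      hits <- names(n_c)[counts > 0.75 * n_c]
      if (length(hits) == 0) "shared" else hits
    }
    expect_setequal(got$assigned, want)
  }
})

test_that("specificity is order-invariant and monotone in added types", {
  tax <- default_taxonomy()
  detected <- c(names(tax)[tax == "epithelial"][1:7],
                names(tax)[tax == "immune"][1:2])
  a <- assign_specificity(detected, tax)
  b <- assign_specificity(rev(detected), tax)
  expect_identical(a$assigned, b$assigned)
  # adding another epithelial type cannot drop epithelial
  more <- c(detected, names(tax)[tax == "epithelial"][8],
            names(tax)[tax == "stromal"][1])
  expect_true("epithelial" %in% assign_specificity(more, tax)$assigned)
})

test_that("a tie above both thresholds assigns both categories", {
  tax <- default_taxonomy()
  detected <- c(names(tax)[tax == "epithelial"][1:7],
                names(tax)[tax == "endothelial"][1:4])
  call <- assign_specificity(detected, tax)
  expect_setequal(call$assigned, c("epithelial", "endothelial"))
  expect_equal(call$level, "multi_category")
})

test_that("locus category summary follows the unanimity rule", {
  calls <- list(
    a = list(assigned = "epithelial"),
    b = list(assigned = "epithelial"),
    c = list(assigned = "immune"),
    d = list(assigned = c("epithelial", "immune")))
  ov <- function(pks) data.frame(variant_id = seq_along(pks),
                                 peak_id = pks)
  expect_equal(summarize_locus_category(ov(c("a", "b")), calls),
               "epithelial")
  expect_equal(summarize_locus_category(ov(c("a", "c")), calls), "mixed")
  expect_equal(summarize_locus_category(ov(c("a", "d")), calls), "mixed")
  expect_equal(summarize_locus_category(ov(c("a", "b", "c")), calls,
                                        rule = "majority"), "epithelial")
  expect_error(summarize_locus_category(ov(character(0)), calls),
               "no colocalized")
})
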