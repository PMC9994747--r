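mk_feats <- function() {
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(101, 501, 901), c(400, 800, 1200)))
  gr$id <- c("te1", "te2", "gene1")
  gr$type <- c("te", "te", "gene")
  gr$family <- c("famA", "famA", NA)
  gr
}

test_that("unique reads are counted by the half-overlap rule", {
  feats <- mk_feats()
  pl <- data.table(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    chrom = "chr1",
    #        inside te1, half in te1, 40% in te1, intergenic, inside gene1
    start = c(150L, 375L, 381L, 1300L, 1000L),
    end = c(250L, 425L, 431L, 1400L, 1100L))
  cm <- count_features(pl, feats)
  expect_identical(cm$counts[, 1], c(te1 = 2L, te2 = 0L, gene1 = 1L))
  # library size counts every placed read, assigned or not
  expect_identical(unname(cm$lib_size), 5L)
})

test_that("overlap ties and multi-feature reads resolve deterministically", {
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(101, 301), c(300, 500)))
  gr$id <- c("gene1", "te1")
  gr$type <- c("gene", "te")
  gr$family <- c(NA, "famA")
  # read [251, 350): 50 bp in each feature -> tie goes to the TE
  pl <- data.table(read_id = "r1", chrom = "chr1", start = 250L, end = 350L)
  cm <- count_features(pl, gr, min_overlap = 0.4)
  expect_identical(cm$counts[, 1], c(gene1 = 0L, te1 = 1L))
  # unequal overlap: the larger overlap wins regardless of type
  pl2 <- data.table(read_id = "r1", chrom = "chr1", start = 230L, end = 330L)
  cm2 <- count_features(pl2, gr, min_overlap = 0.4)
  expect_identical(cm2$counts[, 1], c(gene1 = 1L, te1 = 0L))
})

test_that("multimapped reads get one seeded assignment; >= max_hits discard", {
  feats <- mk_feats()
  many <- data.table(read_id = "multi", chrom = "chr1",
                     start = c(150L, 550L), end = c(250L, 650L))
  cm <- count_features(many, feats, seed = 5)
  expect_equal(sum(cm$counts), 1)  # exactly one of the two loci counted
  expect_identical(unname(cm$lib_size), 1L)
  rep1 <- count_features(many, feats, seed = 5)
  expect_identical(cm$counts, rep1$counts)
  # a read with max_hits candidate loci is dropped entirely
  sat <- data.table(read_id = "sat", chrom = "chr1",
                    start = rep(150L, 100), end = rep(250L, 100))
  cm3 <- count_features(sat, feats, max_hits = 100)
  expect_equal(sum(cm3$counts), 0)
  expect_identical(unname(cm3$lib_size), 0L)
  # one candidate fewer and it is kept
  cm4 <- count_features(sat[1:99], feats, max_hits = 100)
  expect_equal(sum(cm4$counts), 1)
})

test_that("family RPM is the normalized family sum with correct SE", {
  counts <- matrix(c(10L, 30L, 5L,
                     20L, 60L, 10L), ncol = 2,
                   dimnames = list(c("te1", "te2", "gene1"), c("a", "b")))
  cm <- structure(list(counts = counts, genotype = c("WT", "WT"),
                       lib_size = c(a = 1e5, b = 2e5),
                       features = data.table(id = c("te1", "te2", "gene1"),
                                             type = c("te", "te", "gene"),
                                             family = c("famA", "famA", NA))),
                  class = "count_matrix")
  fr <- family_rpm(cm)
  rpm <- c(1e6 * 40 / 1e5, 1e6 * 80 / 2e5)  # 400, 400
  expect_equal(fr$mean_rpm, mean(rpm))
  expect_equal(fr$se_rpm, stats::sd(rpm) / sqrt(2))
  expect_equal(fr$n_reps, 2L)
  # a single replicate yields NA standard error
  cm1 <- cm; cm1$counts <- counts[, 1, drop = FALSE]
  cm1$genotype <- "WT"; cm1$lib_size <- c(a = 1e5)
  expect_true(is.na(family_rpm(cm1)$se_rpm))
  cm0 <- cm; cm0$lib_size <- c(a = 0, b = 2e5)
  expect_error(family_rpm(cm0), "zero library size")
})

test_that("differential expression applies filter, fold and p thresholds", {
  mk_cm <- function(counts) {
    structure(list(counts = counts,
                   genotype = rep(c("WT", "MUT"), each = 3),
                   lib_size = rep(1e6, 6),
                   features = data.table(id = rownames(counts),
                                         type = "gene",
                                         family = NA_character_)),
              class = "count_matrix")
  }
  counts <- rbind(
    strong_up = c(100L, 110L, 90L, 800L, 820L, 790L),
    strong_down = c(800L, 820L, 790L, 100L, 110L, 90L),
    flat = c(500L, 510L, 490L, 505L, 495L, 500L),
    low = c(1L, 0L, 2L, 1L, 2L, 0L),
    small_shift = c(100L, 110L, 90L, 130L, 140L, 120L))
  de <- differential_expression(mk_cm(counts))
  expect_identical(de$status,
                   c("up", "down", "unchanged", "filtered", "unchanged"))
  expect_true(is.na(de[id == "low", pvalue]))
  expect_gt(de[id == "strong_up", log2fc], log2(2))
  # log2fc matches the CPM definition with a 0.5 pseudo-count
  expect_equal(de[id == "strong_up", log2fc],
               mean(log2(counts[1, 4:6] + 0.5)) -
                 mean(log2(counts[1, 1:3] + 0.5)))
  # constant-within-both-groups features: p = 1 iff the means are equal
  counts2 <- rbind(const_eq = rep(50L, 6),
                   const_diff = c(50L, 50L, 50L, 400L, 400L, 400L))
  de2 <- differential_expression(mk_cm(counts2))
  expect_equal(de2[id == "const_eq", pvalue], 1)
  expect_equal(de2[id == "const_diff", pvalue], 0)
  expect_identical(de2$status, c("unchanged", "up"))
  cm_single <- mk_cm(counts)
  cm_single$counts <- counts[, c(1, 4), drop = FALSE]
  cm_single$genotype <- c("WT", "MUT")
  cm_single$lib_size <- rep(1e6, 2)
  expect_error(differential_expression(cm_single), "two replicates")
})

test_that("simulated counts follow the configured truth on average", {
  p <- small_params(n_reps = 200, de_fold = 8)
  b <- small_bundle()
  cm <- simulate_expression_counts(b, p)
  expect_identical(dim(cm$counts), c(nrow(cm$features), 400L))
  expect_identical(cm$truth$id,
                   cm$features[predisposed == TRUE, id])
  wt <- cm$genotype == "WT"; mut <- cm$genotype == "MUT"
  # law of large numbers: per-feature means approach base_mean and the fold
  pred <- cm$features$predisposed
  mw <- unname(rowMeans(cm$counts[, wt])[pred])
  mm <- unname(rowMeans(cm$counts[, mut])[pred])
  expect_equal(mm / mw, rep(8, sum(pred)), tolerance = 0.15)
  expect_equal(unname(rowMeans(cm$counts[, wt])), cm$features$base_mean,
               tolerance = 0.35)
  # determinism and the de_fold = 1 null truth
  cm2 <- simulate_expression_counts(b, p)
  expect_identical(cm$counts, cm2$counts)
  cm_null <- simulate_expression_counts(b, small_params(de_fold = 1))
  expect_equal(nrow(cm_null$truth), 0)
})
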