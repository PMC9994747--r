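test_that("converted index applies both conversion modes", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  idx <- build_converted_index(g, k = 2)
  expect_identical(idx$ct, c(chr1 = "ATGT"))
  expect_identical(idx$ga, c(chr1 = "ACAT"))
  expect_identical(idx$lengths, c(chr1 = 4L))
  # conversion is idempotent
  expect_identical(chartr("C", "T", idx$ct), idx$ct)
  expect_identical(chartr("G", "A", idx$ga), idx$ga)
  expect_warning(build_converted_index(g, k = 20), "shorter than k")
  expect_error(build_converted_index(Biostrings::DNAStringSet()),
               "empty genome")
})

test_that("exact reads place uniquely on the correct template strand", {
  set.seed(31)
  g <- random_genome(3000)
  s <- as.character(g[[1]])
  idx <- build_converted_index(g)

  seg <- substr(s, 501, 560)
  # mate 1, plus template, fully protected (read equals the genome)
  h <- align_read(seg, idx, mate = 1)
  expect_identical(h[, .(pos0, strand, orient, mismatches, multiplicity)],
                   data.table(pos0 = 500L, strand = "+", orient = 0L,
                              mismatches = 0L, multiplicity = 1L))
  # mate 1, minus template: the sequenced read is the reverse complement
  h <- align_read(revcomp_chr(seg), idx, mate = 1)
  expect_identical(h[, .(pos0, strand, orient)],
                   data.table(pos0 = 500L, strand = "-", orient = 1L))
  # mate 2 of a plus-template fragment is reverse-complemented
  h <- align_read(revcomp_chr(seg), idx, mate = 2)
  expect_identical(h[, .(pos0, strand, orient)],
                   data.table(pos0 = 500L, strand = "+", orient = 1L))
  # a fully C-to-T converted read still places exactly (three-letter space)
  h <- align_read(chartr("C", "T", seg), idx, mate = 1)
  expect_identical(h[, .(pos0, strand, mismatches)],
                   data.table(pos0 = 500L, strand = "+", mismatches = 0L))
})

test_that("mismatch budget is honoured and excess mismatches are discarded", {
  set.seed(32)
  g <- random_genome(3000)
  s <- as.character(g[[1]])
  idx <- build_converted_index(g)
  seg <- substr(s, 1001, 1060)

  mutate <- function(x, at) {
    # A -> C shows as a mismatch even after C-to-T conversion
    ch <- strsplit(x, "")[[1]]
    stopifnot(all(ch[at] == "A"))
    ch[at] <- "C"
    paste(ch, collapse = "")
  }
  a_pos <- which(strsplit(seg, "")[[1]] == "A")
  # two mismatches spread over different thirds still align
  at2 <- c(a_pos[a_pos <= 20][1], a_pos[a_pos > 40][1])
  h <- align_reads(mutate(seg, at2), idx)
  expect_equal(nrow(h), 1)
  expect_identical(h$pos0, 1000L)
  expect_identical(h$mismatches, 2L)
  # three mismatches exceed the budget
  at3 <- c(at2, a_pos[a_pos > 20 & a_pos <= 40][1])
  h <- align_reads(mutate(seg, at3), idx)
  expect_equal(nrow(h), 0)
  expect_identical(attr(h, "discarded")[["no_hit"]], 1L)
})

test_that("short reads and foreign reads are discarded with a reason", {
  set.seed(33)
  g <- random_genome(2000)
  idx <- build_converted_index(g)
  expect_null(align_read(strrep("ACGT", 3), idx))
  h <- align_reads(c(strrep("ACGT", 3),
                     paste(rep("ACGTT", 12), collapse = "")), idx)
  disc <- attr(h, "discarded")
  expect_identical(disc[["too_short"]], 1L)
  expect_identical(sum(disc), 2L)
})

test_that("repeated sequence yields capped multiplicity or rejection", {
  set.seed(34)
  unit <- as.character(random_genome(100)[[1]])
  g <- Biostrings::DNAStringSet(
    c(chr1 = paste0(strrep(unit, 5), as.character(random_genome(500)[[1]]))))
  idx <- build_converted_index(g)
  read <- substr(unit, 11, 70)
  h <- align_read(read, idx)
  bf <- brute_force_hits(read, g[[1]])
  best <- bf[mm == min(bf$mm)]
  expect_identical(h$multiplicity, nrow(best))
  expect_gte(h$multiplicity, 5L)
  expect_true(best[h, on = c("pos0", "strand"), nomatch = NULL][, .N] == 1L)
  # with max_hits below the repeat count the read is rejected
  h2 <- align_reads(read, idx, max_hits = 4)
  expect_equal(nrow(h2), 0)
  expect_identical(attr(h2, "discarded")[["too_many_hits"]], 1L)
})

test_that("aligner agrees with a brute-force oracle on random reads", {
  set.seed(35)
  for (rep in 1:5) {
    g <- random_genome(3000)
    s <- as.character(g[[1]])
    idx <- build_converted_index(g)
    reads <- vapply(1:30, function(i) {
      st <- sample(nchar(s) - 60, 1)
      seg <- substr(s, st, st + 59)
      ch <- strsplit(seg, "")[[1]]
      conv <- ch == "C" & runif(60) < 0.6   # partial bisulfite conversion
      ch[conv] <- "T"
      err <- sample(60, sample(0:3, 1))     # up to 3 sequencing errors
      ch[err] <- sample(c("A", "C", "G", "T"), length(err), replace = TRUE)
      seg <- paste(ch, collapse = "")
      if (runif(1) < 0.5) seg else revcomp_chr(seg)
    }, character(1))
    h <- align_reads(reads, idx, seed = rep)
    for (i in seq_along(reads)) {
      bf <- brute_force_hits(reads[i], g[[1]])
      best <- if (is.null(bf)) bf else bf[mm == min(bf$mm)]
      row <- h[id == paste0("r", i)]
      if (is.null(best) || nrow(best) > 10) {
        expect_equal(nrow(row), 0)
      } else {
        expect_equal(nrow(row), 1)
        expect_identical(row$mismatches, min(best$mm))
        expect_identical(row$multiplicity, nrow(best))
        expect_true(best[row, on = c("pos0", "strand"),
                         nomatch = NULL][, .N] == 1L)
      }
    }
  }
})

test_that("tie-breaking among equal hits is seeded and deterministic", {
  unit <- "ACCATGGTTACAGGATTACCGGTAACCATA"
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep(unit, 4),
                                                strrep("T", 200))))
  idx <- build_converted_index(g, k = 10)
  picks <- vapply(1:25, function(sd) align_read(unit, idx, seed = sd)$pos0,
                  integer(1))
  expect_identical(picks,
                   vapply(1:25, function(sd)
                     align_read(unit, idx, seed = sd)$pos0, integer(1)))
  expect_gt(length(unique(picks)), 1)
  expect_true(all(picks %% 30L == 0L))
})
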