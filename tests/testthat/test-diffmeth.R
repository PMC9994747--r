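test_that("percent change satisfies its defining properties on a grid", {
  m <- seq(0, 1, length.out = 51)
  grid <- CJ(m_a = m, m_b = m)
  pc <- grid[, percent_change(m_a, m_b)]
  # bounded, antisymmetric, zero on the diagonal (incl. 0/0), correct sign
  expect_true(all(pc >= -100 & pc <= 100))
  expect_equal(pc, -grid[, percent_change(m_b, m_a)])
  expect_true(all(pc[grid$m_a == grid$m_b] == 0))
  expect_true(all(pc[grid$m_b > grid$m_a] > 0))
  expect_true(all(pc[grid$m_b < grid$m_a] < 0))
  # the bounds are attained exactly when one side is 0 and the other is not
  at_bound <- abs(abs(pc) - 100) < 1e-9
  expect_identical(at_bound, xor(grid$m_a == 0, grid$m_b == 0))
  # normalization by the larger value
  expect_equal(pc, 100 * (grid$m_b - grid$m_a) / pmax(grid$m_a, grid$m_b, 1e-300))
  # scale invariance: common positive scaling leaves the value unchanged
  expect_equal(percent_change(0.4 * 0.5, 0.1 * 0.5), percent_change(0.4, 0.1))
  expect_equal(percent_change(0.8, 0.2), -75)
  expect_true(is.na(percent_change(NA, 0.5)))
  expect_error(percent_change(1.2, 0.5), "\\[0, 1\\]")
})

test_that("window percent change joins on shared defined windows", {
  w <- function(m, sites = 5L) {
    data.table(chrom = "chr1", start = c(0L, 50L, 100L),
               end = c(50L, 100L, 150L),
               sites_CG = sites, sites_CHG = sites, m_CG = m, m_CHG = m / 2)
  }
  a <- w(c(0.8, NA, 0.4))
  b <- w(c(0.2, 0.5, 0.4))
  ch <- window_percent_change(a, b, "CG")
  expect_equal(nrow(ch), 2)  # NA window dropped
  expect_equal(ch$pct_change, c(percent_change(0.8, 0.2), 0))
})

test_that("matched windows require equal covered CG/CHG site counts", {
  base <- data.table(chrom = "chr1", start = seq(0L, 150L, 50L),
                     end = seq(50L, 200L, 50L))
  a <- copy(base)[, `:=`(sites_CG = c(4L, 3L, 5L, 2L),
                         sites_CHG = c(4L, 6L, 5L, 2L),
                         m_CG = c(0.8, 0.8, 0.7, 0.1),
                         m_CHG = c(0.7, 0.8, 0.75, 0.1))]
  b <- copy(base)[, `:=`(sites_CG = c(4L, 3L, 5L, 2L),
                         sites_CHG = c(4L, 3L, 5L, 2L),
                         m_CG = c(0.2, 0.2, 0.15, 0.05),
                         m_CHG = c(0.25, 0.2, 0.2, 0.05))]
  m <- select_matched_windows(a, b)
  # window 2 has unequal counts in A; window 4 fails the >0.5 threshold
  expect_identical(m$start, c(0L, 100L))
  expect_equal(m$diff_a, c(0.8 - 0.7, 0.7 - 0.75))
  expect_equal(m$diff_b, c(0.2 - 0.25, 0.15 - 0.2))
  smry <- attr(m, "summary")
  expect_equal(smry[sample == "A", median], median(m$diff_a))
  expect_equal(smry[sample == "B", median], median(m$diff_b))
  # raising the threshold above every level empties the selection
  expect_warning(m0 <- select_matched_windows(a, b, min_meth = 0.9),
                 "no matched")
  expect_equal(nrow(m0), 0)
})

test_that("region restriction keeps windows by overlap fraction", {
  win <- data.table(chrom = "chr1", start = seq(0L, 450L, 50L),
                    end = seq(50L, 500L, 50L), m_CG = 0.5)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(77, 220))
  # overlaps: [50,100) 24 bp (<50%), [100,150) full, [150,200) full,
  # [200,250) 21 bp (<50%)
  kept <- windows_in_regions(win, reg)
  expect_identical(kept$start, c(100L, 150L))
  # two abutting regions accumulate overlap for one window
  reg2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 31), c(20, 60)))
  expect_identical(windows_in_regions(win, reg2)$start, 0L)
})

test_that("stratification respects quantile sizes and attribute order", {
  set.seed(61)
  n <- 100
  ch <- data.table(chrom = "chr1", start = seq_len(n) * 50L,
                   end = seq_len(n) * 50L + 50L,
                   pct_change = rep(c(-40, 40), each = n / 2))
  attr_v <- c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1))
  st <- stratify_by_attribute(ch, attr_v, n_quantiles = 5)
  expect_equal(st$quantile, 1:5)
  expect_true(all(st$n == 20))
  expect_true(all(diff(st$attr_min) > 0))
  # low-attribute windows carry -40, high-attribute +40; the middle group
  # straddles the change point, so its median is 0
  expect_equal(st$median, c(-40, -40, 0, 40, 40))
  expect_error(stratify_by_attribute(ch[1:3], attr_v[1:3], 5),
               "fewer windows")
  # joining form agrees with the vector form
  st2 <- stratify_by_attribute(ch, data.table(chrom = "chr1",
                                              start = ch$start,
                                              value = attr_v), 5)
  expect_equal(st, st2)
})

test_that("chromosome profile re-derives from raw counts", {
  cx <- small_cx()$wt
  b <- small_bundle()
  pr <- chromosome_profile(cx, b, window = 10000)
  expect_setequal(unique(pr$context), c("CG", "CHG", "CHH", "total"))
  o <- cx[!is.na(context) & context == "CG",
          .(nC = sum(n_C), cov = sum(n_C + n_T)),
          by = .(start = (pos0 %/% 10000L) * 10000L)]
  m <- merge(pr[context == "CG"], o, by = "start")
  expect_equal(m$m, m$nC.y / m$cov.y)
  # total bin equals the sum of the three contexts
  tot <- pr[, .(s = sum(nC[context != "total"]),
                t = nC[context == "total"]), by = start]
  expect_equal(tot$s, tot$t)
})

test_that("context reduction recovers an exact construction", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 200)))
  mk <- function(scale) {
    cg <- data.table(chrom = "chr1", pos0 = c(10L, 60L, 110L, 160L),
                     strand = "+", context = "CG", trinuc = NA_character_,
                     n_C = as.integer(round(c(8, 8, 4, 4) * scale)),
                     n_T = as.integer(c(2, 2, 6, 6) +
                                        round(c(8, 8, 4, 4) * (1 - scale))))
    other <- data.table(chrom = "chr1", pos0 = c(20L, 30L), strand = "+",
                        context = c("CHG", "CHH"), trinuc = NA_character_,
                        n_C = 5L, n_T = 5L)
    rbind(cg, other)
  }
  win_wt <- window_methylation(mk(1), g)
  win_mut <- window_methylation(mk(0.5), g)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  red <- estimate_context_reduction(win_wt, win_mut, reg)
  cg <- red[context == "CG"]
  expect_equal(cg$m_wt, 16 / 20)
  expect_equal(cg$m_mut, 8 / 20)
  expect_equal(cg$reduction_pct, 50)
  expect_equal(cg$change_pct, -50)
  expect_error(estimate_context_reduction(win_wt, win_mut,
                 GenomicRanges::GRanges("chr1", IRanges::IRanges(190, 200))),
               "no covered")
})
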