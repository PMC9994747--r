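#' Signed percent methylation change
#'
#' The difference in methylation between two samples divided by the level in
#' the sample with the higher methylation, as a percent: magnitude
#' `100 * |m_a - m_b| / max(m_a, m_b)`, signed positive when sample B is
#' higher (hyper-methylation in B) and negative when lower. The degenerate
#' `0/0` case is defined as 0 (no evidence of change). Values are bounded in
#' \[-100, 100\] and reach the bounds exactly when one argument is 0 and the
#' other is not.
#'
#' @param m_a,m_b methylation fractions in \[0,1\] (vectorized; `NA` in gives
#'   `NA` out).
#' @return signed percent change.
#' @export
#' @examples
#' percent_change(0.8, 0.2)  # -75
#' percent_change(0.2, 0.8)  # +75
percent_change <- function(m_a, m_b) {
  if (any(m_a < 0 | m_a > 1 | m_b < 0 | m_b > 1, na.rm = TRUE))
    stop("methylation fractions must be in [0, 1]")
  hi <- pmax(m_a, m_b)
  ifelse(is.na(m_a) | is.na(m_b), NA_real_,
         ifelse(hi == 0, 0, 100 * (m_b - m_a) / hi))
}

#' Window-level percent methylation change between two samples
#'
#' Joins two [window_methylation()] tables on coordinates (the intersection
#' of windows with a defined fraction in both samples) and computes the
#' signed percent change of the requested context, sample B versus sample A.
#'
#' @param win_a,win_b window tables for samples A (e.g. wild type) and B
#'   (e.g. mutant).
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"total"`.
#' @return data.table: `chrom`, `start`, `end`, `context`, `m_a`, `m_b`,
#'   `pct_change`.
#' @export
window_percent_change <- function(win_a, win_b, context = "CG") {
  mcol <- paste0("m_", context)
  a <- win_a[, .(chrom, start, end, m_a = get(mcol))]
  b <- win_b[, .(chrom, start, end, m_b = get(mcol))]
  m <- merge(a, b, by = c("chrom", "start", "end"))
  m <- m[!is.na(m_a) & !is.na(m_b)]
  ctx_val <- context
  m[, `:=`(context = ctx_val, pct_change = percent_change(m_a, m_b))]
  setcolorder(m, c("chrom", "start", "end", "context"))
  setorder(m, chrom, start)
  m[]
}

#' Matched CG/CHG windows and their per-sample differential
#'
#' CG and CHG methylation levels can be confounded by site density, so the
#' contexts are compared within windows carrying an equal number of covered
#' CG and CHG sites. Windows qualify when the site counts are equal (and
#' nonzero) in both samples, both fractions are defined, and the maximum
#' methylation over both symmetric contexts and both samples exceeds
#' `min_meth`. The per-sample `mCG - mCHG` differential and its distribution
#' summary are returned.
#'
#' @param win_a,win_b window tables sharing coordinates.
#' @param min_meth methylated-window threshold (default 0.5): max over
#'   \{mCG, mCHG\} x \{samples\} must exceed it.
#' @return data.table of matched windows: coordinates, `n_sites`,
#'   per-sample `mCG_*`, `mCHG_*` and `diff_* = mCG - mCHG`; attribute
#'   `"summary"` holds per-sample median and quartiles of the differential.
#'   Empty (with a warning) when no window qualifies.
#' @export
select_matched_windows <- function(win_a, win_b, min_meth = 0.5) {
  cols <- c("chrom", "start", "end", "sites_CG", "sites_CHG", "m_CG", "m_CHG")
  a <- win_a[, ..cols]
  setnames(a, c("sites_CG", "sites_CHG", "m_CG", "m_CHG"),
           c("sCG_a", "sCHG_a", "mCG_a", "mCHG_a"))
  b <- win_b[, ..cols]
  setnames(b, c("sites_CG", "sites_CHG", "m_CG", "m_CHG"),
           c("sCG_b", "sCHG_b", "mCG_b", "mCHG_b"))
  m <- merge(a, b, by = c("chrom", "start", "end"))
  m <- m[sCG_a == sCHG_a & sCG_b == sCHG_b & sCG_a >= 1L & sCG_b >= 1L &
         !is.na(mCG_a) & !is.na(mCHG_a) & !is.na(mCG_b) & !is.na(mCHG_b)]
  m <- m[pmax(mCG_a, mCHG_a, mCG_b, mCHG_b) > min_meth]
  if (nrow(m) == 0) {
    warning("no matched CG/CHG window qualifies")
    setattr(m, "summary", data.table(sample = character(0)))
    return(m)
  }
  m[, `:=`(n_sites = sCG_a, diff_a = mCG_a - mCHG_a, diff_b = mCG_b - mCHG_b)]
  smry <- rbind(
    data.table(sample = "A", n = nrow(m),
               median = median(m$diff_a),
               q1 = unname(quantile(m$diff_a, 0.25)),
               q3 = unname(quantile(m$diff_a, 0.75))),
    data.table(sample = "B", n = nrow(m),
               median = median(m$diff_b),
               q1 = unname(quantile(m$diff_b, 0.25)),
               q3 = unname(quantile(m$diff_b, 0.75))))
  setorder(m, chrom, start)
  setattr(m, "summary", smry)
  m[]
}

#' Restrict a window table to windows inside a region set
#'
#' Keeps windows overlapping the (strand-ignored, merged) region set by at
#' least `min_overlap` of their width — the boundary-window rule used for
#' TE-restricted statistics.
#'
#' @param windows a [window_methylation()] or [window_percent_change()]
#'   table (any table with `chrom`, `start`, `end`).
#' @param regions a `GRanges`.
#' @param min_overlap minimum overlapping fraction of the window
#'   (default 0.5).
#' @return the filtered table.
#' @export
windows_in_regions <- function(windows, regions, min_overlap = 0.5) {
  gr <- GRanges(windows$chrom, IRanges(windows$start + 1L, windows$end))
  red <- reduce(regions, ignore.strand = TRUE)
  ov <- findOverlaps(gr, red, ignore.strand = TRUE)
  inter <- width(pintersect(gr[queryHits(ov)], red[subjectHits(ov)],
                            ignore.strand = TRUE))
  covf <- data.table(i = queryHits(ov), bp = inter)[, .(bp = sum(bp)), by = i]
  keep <- covf[bp >= min_overlap * (windows$end[i] - windows$start[i]), i]
  windows[sort(keep)]
}

#' Quantile stratification of percent change by a window attribute
#'
#' Ranks windows by an attribute (GC content, H3 or H3K9me2 proxy, or the
#' wild-type methylation level of the same context), cuts them into
#' `n_quantiles` equal-size groups (ties broken by coordinate order) and
#' summarizes the signed percent change per group.
#'
#' @param changes a [window_percent_change()] table.
#' @param attribute either a numeric vector aligned with `changes` rows, or
#'   a data.table with `chrom`, `start` and a `value` column to be joined on
#'   window coordinates.
#' @param n_quantiles number of groups (default 5).
#' @return data.table per group: `quantile` (1 = lowest attribute values),
#'   `n`, `attr_min`, `attr_max`, `median`, `q1`, `q3`, `mean` of
#'   `pct_change`.
#' @export
stratify_by_attribute <- function(changes, attribute, n_quantiles = 5L) {
  ch <- copy(changes)
  if (is.numeric(attribute)) {
    stopifnot(length(attribute) == nrow(ch))
    ch[, attr_value := attribute]
  } else {
    att <- as.data.table(attribute)
    stopifnot(all(c("chrom", "start", "value") %in% names(att)))
    ch <- merge(ch, att[, .(chrom, start, attr_value = value)],
                by = c("chrom", "start"))
  }
  ch <- ch[!is.na(attr_value) & !is.na(pct_change)]
  if (nrow(ch) < n_quantiles)
    stop("fewer windows (", nrow(ch), ") than quantiles (", n_quantiles, ")")
  setorder(ch, attr_value, chrom, start)
  ch[, quantile := ceiling(.I * n_quantiles / .N)]
  ch[, .(n = .N, attr_min = min(attr_value), attr_max = max(attr_value),
         median = median(pct_change),
         q1 = unname(quantile(pct_change, 0.25)),
         q3 = unname(quantile(pct_change, 0.75)),
         mean = mean(pct_change)),
     by = quantile]
}

#' Chromosome-scale methylation profile
#'
#' Weighted per-context methylation averaged in large bins (default 100 kb)
#' along each chromosome, as a plot-ready long table.
#'
#' @param records a cytosine-record table.
#' @param genome a `DNAStringSet` or `GenomeBundle`.
#' @param window bin width in bp (default 100000).
#' @param step step between bin starts (default `window`).
#' @return data.table: `chrom`, `start`, `end`, `context` (including
#'   `"total"`), `m` (`NA` for empty bins), `nC`, `cov`.
#' @export
chromosome_profile <- function(records, genome, window = 100000L,
                               step = window) {
  w <- window_methylation(records, genome, width = as.integer(window),
                          step = as.integer(step), min_calls = 1L)
  long <- rbindlist(lapply(c("CG", "CHG", "CHH", "total"), function(ctx) {
    w[, .(chrom, start, end, context = ctx,
          m = get(paste0("m_", ctx)),
          nC = get(paste0("nC_", ctx)), cov = get(paste0("cov_", ctx)))]
  }))
  setorder(long, chrom, start, context)
  long[]
}

#' Per-context methylation reduction over a region set
#'
#' The pipeline's headline summary: for each context, the weighted
#' methylation of the TE (or other region) set is aggregated per sample
#' (summing window counts over windows that overlap the regions by at least
#' `min_overlap` of their width) and the two aggregates are compared with
#' [percent_change()]. The reported `reduction_pct` is positive when the
#' mutant (sample B) is lower.
#'
#' @param win_wt,win_mut window tables for the two samples.
#' @param regions a `GRanges` of regions (e.g. TEs).
#' @param min_overlap minimum fraction of a window overlapping the region
#'   set (default 0.5).
#' @return data.table: `context`, `m_wt`, `m_mut`, `change_pct` (signed,
#'   negative = lower in mutant), `reduction_pct` (= `-change_pct`).
#' @export
estimate_context_reduction <- function(win_wt, win_mut, regions,
                                       min_overlap = 0.5) {
  a <- windows_in_regions(win_wt, regions, min_overlap)
  b <- windows_in_regions(win_mut, regions, min_overlap)
  out <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx) {
    nCa <- sum(a[[paste0("nC_", ctx)]]); cva <- sum(a[[paste0("cov_", ctx)]])
    nCb <- sum(b[[paste0("nC_", ctx)]]); cvb <- sum(b[[paste0("cov_", ctx)]])
    if (cva == 0 || cvb == 0)
      stop("no covered ", ctx, " sites within the region set")
    data.table(context = ctx, m_wt = nCa / cva, m_mut = nCb / cvb)
  }))
  out[, change_pct := percent_change(m_wt, m_mut)]
  out[, reduction_pct := -change_pct]
  out[]
}
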