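#' Windowed fractional methylation
#'
#' Tiles each chromosome with fixed-width windows (sliding when
#' `step < width`) and computes, per window, the weighted fractional
#' methylation of each context and of all contexts pooled:
#' `sum(n_C) / sum(n_C + n_T)` over both strands. A window-context with
#' fewer than `min_calls` informative calls (total C + T evidence) has an
#' undefined fraction (`NA`); counts are still reported.
#'
#' @param records a cytosine-record table ([pileup_cytosines()]).
#' @param genome a `DNAStringSet` or `GenomeBundle` (supplies chromosome
#'   lengths).
#' @param width window width in bp (default 50).
#' @param step step between window starts (default `width`, i.e.
#'   non-overlapping tiles).
#' @param min_calls minimum informative calls per window-context for a
#'   defined fraction (default 4).
#' @return data.table with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open), per-context `nC_*`, `cov_*` (informative calls),
#'   `sites_*` (covered cytosines), `m_*` (fraction or `NA`), and the pooled
#'   `nC_total`, `cov_total`, `sites_total`, `m_total`.
#' @export
window_methylation <- function(records, genome, width = 50L, step = width,
                               min_calls = 4L) {
  stopifnot(width >= 1L, step >= 1L)
  genome <- first_genome(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))

  grid <- rbindlist(lapply(names(lens), function(cn) {
    starts <- seq(0L, max(0L, lens[[cn]] - 1L), by = step)
    data.table(chrom = cn, start = as.integer(starts),
               end = as.integer(pmin(starts + width, lens[[cn]])))
  }))
  grid[, wid := .I]

  r <- records[!is.na(context) & (n_C + n_T) > 0]
  if (nrow(r) > 0) {
    if (step == width) {
      r <- copy(r)
      r[, start := (pos0 %/% as.integer(width)) * as.integer(width)]
      r <- merge(r, grid, by = c("chrom", "start"))
    } else {
      wgr <- GRanges(grid$chrom, IRanges(grid$start + 1L, grid$end))
      cgr <- GRanges(r$chrom, IRanges(r$pos0 + 1L, width = 1L))
      ov <- findOverlaps(cgr, wgr)
      r <- r[queryHits(ov)][, wid := grid$wid[subjectHits(ov)]]
    }
    agg <- r[, .(nC = sum(n_C), cov = sum(n_C + n_T), sites = .N),
             by = .(wid, context)]
  } else {
    agg <- data.table(wid = integer(0), context = character(0),
                      nC = integer(0), cov = integer(0), sites = integer(0))
  }

  out <- copy(grid)
  for (ctx in c("CG", "CHG", "CHH")) {
    a <- agg[context == ctx]
    out[, paste0(c("nC_", "cov_", "sites_"), ctx) := 0L]
    if (nrow(a) > 0)
      out[a, on = "wid", paste0(c("nC_", "cov_", "sites_"), ctx) :=
            .(i.nC, i.cov, i.sites)]
  }
  out[, `:=`(nC_total = nC_CG + nC_CHG + nC_CHH,
             cov_total = cov_CG + cov_CHG + cov_CHH,
             sites_total = sites_CG + sites_CHG + sites_CHH)]
  for (ctx in c("CG", "CHG", "CHH", "total")) {
    nc <- out[[paste0("nC_", ctx)]]
    cv <- out[[paste0("cov_", ctx)]]
    out[, paste0("m_", ctx) := ifelse(cv >= min_calls & cv > 0, nc / cv,
                                      NA_real_)]
  }
  out[, wid := NULL]
  setattr(out, "window_width", as.integer(width))
  out[]
}

#' Per-region weighted methylation
#'
#' Weighted fractional methylation of annotated regions, optionally
#' restricted to a sub-part of LTR-class TEs: the whole element, the internal
#' sequence between the two terminal repeats, or the LTR sequences only.
#' For `part != "whole"` regions must carry an `ltr_len` column; elements
#' lacking LTR annotation are skipped (and counted in the `skipped`
#' attribute).
#'
#' @param records a cytosine-record table.
#' @param regions a `GRanges` with an identifier column (`te_id` or
#'   `gene_id`).
#' @param part `"whole"`, `"internal"` or `"ltr"`.
#' @param min_calls minimum informative calls for a defined fraction.
#' @return data.table: `id`, `part`, per-context `m_*`, `cov_*`, `sites_*`,
#'   and `m_total`, `cov_total`. Fractions are `NA` where coverage is below
#'   `min_calls`.
#' @export
region_methylation <- function(records, regions, part = c("whole", "internal",
                                                          "ltr"),
                               min_calls = 4L) {
  part <- match.arg(part)
  id_col <- intersect(c("te_id", "gene_id", "id"), names(mcols(regions)))[1]
  if (is.na(id_col)) stop("regions need an identifier column")
  ids_all <- mcols(regions)[[id_col]]
  skipped <- character(0)
  if (part != "whole") {
    if (!"ltr_len" %in% names(mcols(regions)))
      stop("part = '", part, "' requires an ltr_len column")
    has <- !is.na(mcols(regions)$ltr_len) & mcols(regions)$ltr_len > 0
    skipped <- ids_all[!has]
    target <- te_subintervals(regions, part)
    ids <- mcols(target)$te_id
  } else {
    target <- regions
    ids <- ids_all
  }
  r <- records[!is.na(context) & (n_C + n_T) > 0]
  cgr <- GRanges(r$chrom, IRanges(r$pos0 + 1L, width = 1L))
  ov <- findOverlaps(cgr, target, ignore.strand = TRUE)
  rr <- r[queryHits(ov)][, id := ids[subjectHits(ov)]]
  agg <- rr[, .(nC = sum(n_C), cov = sum(n_C + n_T), sites = .N),
            by = .(id, context)]
  base <- data.table(id = unique(ids))
  out <- base
  for (ctx in c("CG", "CHG", "CHH")) {
    a <- agg[context == ctx]
    out[, paste0(c("nC_", "cov_", "sites_"), ctx) := 0L]
    if (nrow(a) > 0)
      out[a, on = "id", paste0(c("nC_", "cov_", "sites_"), ctx) :=
            .(i.nC, i.cov, i.sites)]
  }
  out[, `:=`(nC_total = nC_CG + nC_CHG + nC_CHH,
             cov_total = cov_CG + cov_CHG + cov_CHH)]
  for (ctx in c("CG", "CHG", "CHH", "total")) {
    nc <- out[[paste0("nC_", ctx)]]
    cv <- out[[paste0("cov_", ctx)]]
    out[, paste0("m_", ctx) := ifelse(cv >= min_calls & cv > 0, nc / cv,
                                      NA_real_)]
  }
  out[, part := part]
  setattr(out, "skipped", skipped)
  out[]
}
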