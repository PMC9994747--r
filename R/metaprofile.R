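#' Methylation meta-profile around TE ends
#'
#' Aligns TEs at their 5' or 3' ends (strandwise) and averages methylation in
#' fixed-width offset bins inside the element and in the adjacent flank.
#' Offsets are measured in the element's orientation; for the 5' anchor,
#' offsets >= 0 lie inside the element and negative offsets upstream; for the
#' 3' anchor, negative offsets lie inside and offsets >= 0 downstream. Each
#' element's contribution is truncated at the end of its own sequence, at the
#' first other annotated element (any TE or gene), or at `max_offset`,
#' whichever comes first. Per-offset values are count-weighted means pooled
#' over contributing elements.
#'
#' @param records a cytosine-record table, or a named list of them (one per
#'   sample) profiled on the identical element set.
#' @param bundle a [simulate_genome()] result (supplies `tes`, `genes` and
#'   chromosome lengths); alternatively a list with those elements.
#' @param anchor `"5prime"` or `"3prime"`.
#' @param bin offset bin width in bp (default 100; 50 reproduces
#'   figure-style profiles).
#' @param max_offset maximum distance profiled on either side of the anchor
#'   (default 2000).
#' @return long data.table: `anchor`, `offset` (bin start), `context`,
#'   `sample` (when a list was given), `m`, `nC`, `cov`, `n_elements`.
#' @export
te_metaprofile <- function(records, bundle, anchor = c("5prime", "3prime"),
                           bin = 100L, max_offset = 2000L) {
  anchor <- match.arg(anchor)
  tes <- bundle$tes
  if (length(tes) == 0) stop("empty TE set")
  lens <- seqlengths(tes)
  feats <- data.table(
    chrom = as.character(c(seqnames(tes), seqnames(bundle$genes))),
    start0 = c(start(tes), start(bundle$genes)) - 1L,
    end0 = c(end(tes), end(bundle$genes)))
  setorder(feats, chrom, start0)

  te <- data.table(idx = seq_along(tes),
                   chrom = as.character(seqnames(tes)),
                   s = start(tes) - 1L, e = end(tes),
                   str = as.character(strand(tes)))
  te[str == "*", str := "+"]
  te[, len := e - s]
  te[, L := lens[chrom]]

  # allowed flank depth: distance from the anchor to the nearest other
  # annotated feature (or chromosome edge), capped at max_offset
  left_room <- function(chrom_, point, self_idx) {
    vapply(seq_along(point), function(i) {
      f <- feats[chrom == chrom_[i] & end0 <= point[i]]
      f <- f[!(end0 == te$e[self_idx[i]] & start0 == te$s[self_idx[i]])]
      gap <- if (nrow(f) == 0) point[i] else point[i] - max(f$end0)
      min(gap, max_offset)
    }, numeric(1))
  }
  right_room <- function(chrom_, point, self_idx) {
    vapply(seq_along(point), function(i) {
      f <- feats[chrom == chrom_[i] & start0 >= point[i]]
      f <- f[!(end0 == te$e[self_idx[i]] & start0 == te$s[self_idx[i]])]
      gap <- if (nrow(f) == 0) te$L[self_idx[i]] - point[i]
             else min(f$start0) - point[i]
      min(gap, max_offset)
    }, numeric(1))
  }

  te[, inside_len := pmin(len, max_offset)]
  if (anchor == "5prime") {
    te[str == "+", `:=`(in_lo = s, in_hi = s + inside_len,
                        ref = s, dir = 1L)]
    te[str == "-", `:=`(in_lo = e - inside_len, in_hi = e,
                        ref = e - 1L, dir = -1L)]
    te[str == "+", flank_d := left_room(chrom, s, idx)]
    te[str == "-", flank_d := right_room(chrom, e, idx)]
    te[str == "+", `:=`(fl_lo = s - flank_d, fl_hi = s)]
    te[str == "-", `:=`(fl_lo = e, fl_hi = e + flank_d)]
  } else {
    te[str == "+", `:=`(in_lo = e - inside_len, in_hi = e,
                        ref = e, dir = 1L)]
    te[str == "-", `:=`(in_lo = s, in_hi = s + inside_len,
                        ref = s - 1L, dir = -1L)]
    te[str == "+", flank_d := right_room(chrom, e, idx)]
    te[str == "-", flank_d := left_room(chrom, s, idx)]
    te[str == "+", `:=`(fl_lo = e, fl_hi = e + flank_d)]
    te[str == "-", `:=`(fl_lo = s - flank_d, fl_hi = s)]
  }

  spans <- rbind(te[, .(idx, chrom, lo = in_lo, hi = in_hi, ref, dir)],
                 te[fl_hi > fl_lo, .(idx, chrom, lo = fl_lo, hi = fl_hi,
                                     ref, dir)])
  span_gr <- GRanges(spans$chrom, IRanges(spans$lo + 1L, spans$hi))

  profile_one <- function(recs) {
    r <- recs[!is.na(context) & (n_C + n_T) > 0]
    cgr <- GRanges(r$chrom, IRanges(r$pos0 + 1L, width = 1L))
    ov <- findOverlaps(cgr, span_gr, ignore.strand = TRUE)
    rr <- r[queryHits(ov)]
    si <- subjectHits(ov)
    rr[, `:=`(te_idx = spans$idx[si],
              offset = spans$dir[si] * (pos0 - spans$ref[si]))]
    rr[, off_bin := as.integer(floor(offset / bin) * bin)]
    out <- rr[, .(m = sum(n_C) / sum(n_C + n_T), nC = sum(n_C),
                  cov = sum(n_C + n_T), n_elements = uniqueN(te_idx)),
              by = .(offset = off_bin, context)]
    anch <- anchor
    out[, anchor := anch]
    setcolorder(out, c("anchor", "offset", "context"))
    setorder(out, context, offset)
    out[]
  }

  if (is.data.table(records)) return(profile_one(records))
  stopifnot(is.list(records), !is.null(names(records)))
  rbindlist(lapply(names(records), function(nm) {
    p <- profile_one(records[[nm]])
    p[, sample := nm]
    p
  }))
}
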