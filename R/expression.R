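#' Assign read placements to features and build a count matrix
#'
#' Uniquely placed reads are assigned to the feature covering at least half
#' of the read at their locus; reads with 2 to `max_hits - 1` candidate loci
#' are assigned to a single locus by a seeded uniform draw; reads with
#' `max_hits` (default 100) or more candidates are discarded. A read whose
#' chosen locus overlaps two features goes to the larger overlap, ties to
#' the TE.
#'
#' @param placements a data.table of candidate loci with columns `read_id`,
#'   `chrom`, `start`, `end` (0-based half-open), one row per candidate; or a
#'   named list of such tables (one per replicate library).
#' @param annotations a `GRanges` of features carrying `te_id` and/or
#'   `gene_id` columns (TEs and genes may be concatenated), plus an optional
#'   `type` column; or a `GenomeBundle`.
#' @param max_hits discard threshold on the candidate-locus count
#'   (default 100: reads with fewer than 100 candidates are kept).
#' @param min_overlap fraction of the read that must overlap a feature
#'   (default 0.5).
#' @param seed RNG seed for the random assignment of multimapped reads.
#' @param genotype per-library genotype labels (required when `placements`
#'   is a list, recycled otherwise ignored).
#' @return a `count_matrix` list (`counts`, `genotype`, `lib_size`,
#'   `features`); `lib_size` counts all assigned reads (including those
#'   landing outside any feature).
#' @export
count_features <- function(placements, annotations, max_hits = 100L,
                           min_overlap = 0.5, seed = 1L, genotype = NULL) {
  feats <- feature_granges(annotations)
  if (is.data.table(placements) || is.data.frame(placements))
    placements <- list(lib1 = as.data.table(placements))
  ids <- mcols(feats)$id
  counts <- matrix(0L, nrow = length(feats), ncol = length(placements),
                   dimnames = list(ids, names(placements)))
  lib_size <- integer(length(placements))
  for (li in seq_along(placements)) {
    pl <- as.data.table(placements[[li]])
    pl[, n_loci := .N, by = read_id]
    pl <- pl[n_loci < max_hits]
    if (nrow(pl) == 0) next
    chosen <- with_seed(seed + li, {
      pl[, pick := {
        if (.N == 1L) TRUE else {
          k <- sample.int(.N, 1L)
          seq_len(.N) == k
        }
      }, by = read_id]
      pl[pick == TRUE]
    })
    lib_size[li] <- nrow(chosen)
    if (nrow(chosen) == 0) next
    rgr <- GRanges(chosen$chrom, IRanges(chosen$start + 1L, chosen$end))
    ov <- findOverlaps(rgr, feats, ignore.strand = TRUE)
    if (length(ov) > 0) {
      ow <- width(pintersect(rgr[queryHits(ov)], feats[subjectHits(ov)],
                             ignore.strand = TRUE))
      cand <- data.table(read = queryHits(ov), feat = subjectHits(ov),
                         ov_bp = ow,
                         is_te = mcols(feats)$type[subjectHits(ov)] == "te")
      cand <- cand[ov_bp >= min_overlap * (chosen$end[read] -
                                           chosen$start[read])]
      # larger overlap wins; ties go to the TE
      setorder(cand, read, -ov_bp, -is_te)
      cand <- cand[!duplicated(read)]
      tab <- cand[, .N, by = feat]
      counts[tab$feat, li] <- tab$N
    }
  }
  out <- list(counts = counts,
              genotype = genotype %||% rep("NA", length(placements)),
              lib_size = setNames(lib_size, names(placements)),
              features = data.table(id = ids, type = mcols(feats)$type,
                                    family = mcols(feats)$family))
  class(out) <- "count_matrix"
  out
}

feature_granges <- function(annotations) {
  if (inherits(annotations, "GenomeBundle")) {
    te <- annotations$tes
    gn <- annotations$genes
    mcols(te) <- S4Vectors::DataFrame(id = mcols(te)$te_id, type = "te",
                                      family = mcols(te)$family)
    mcols(gn) <- S4Vectors::DataFrame(id = mcols(gn)$gene_id, type = "gene",
                                      family = NA_character_)
    return(c(te, gn))
  }
  gr <- annotations
  mc <- mcols(gr)
  id <- if ("id" %in% names(mc)) mc$id
        else if ("te_id" %in% names(mc)) mc$te_id
        else if ("gene_id" %in% names(mc)) mc$gene_id
        else stop("annotations need an id column")
  type <- if ("type" %in% names(mc)) mc$type
          else if ("te_id" %in% names(mc)) "te" else "gene"
  family <- if ("family" %in% names(mc)) mc$family else NA_character_
  mcols(gr) <- S4Vectors::DataFrame(id = id, type = type, family = family)
  gr
}

#' TE-family expression in reads per million
#'
#' Sums member-TE counts (multimapped reads included through their single
#' random assignment) per family and replicate, normalizes to reads per
#' million of the library, and reports per-genotype mean and standard error
#' over replicates.
#'
#' @param cm a `count_matrix` whose `features` carry `family` labels for TEs.
#' @return data.table: `family`, `genotype`, `mean_rpm`, `se_rpm` (`NA` with
#'   a single replicate), `n_reps`.
#' @export
family_rpm <- function(cm) {
  if (any(cm$lib_size == 0)) stop("zero library size")
  f <- cm$features
  te_rows <- which(f$type == "te" & !is.na(f$family))
  if (length(te_rows) == 0) stop("no TE features with family labels")
  long <- rbindlist(lapply(seq_len(ncol(cm$counts)), function(li) {
    data.table(family = f$family[te_rows],
               rpm = 1e6 * cm$counts[te_rows, li] / cm$lib_size[li],
               genotype = cm$genotype[li], rep = li)
  }))
  fam_rep <- long[, .(rpm = sum(rpm)), by = .(family, genotype, rep)]
  fam_rep[, .(mean_rpm = mean(rpm),
              se_rpm = if (.N > 1) stats::sd(rpm) / sqrt(.N) else NA_real_,
              n_reps = .N),
          by = .(family, genotype)]
}

#' Differential expression of genes and TEs
#'
#' Features with a total read count (summed over all replicates) below
#' `min_count` are filtered. Remaining counts are normalized to counts per
#' million, log2-transformed with a 0.5 pseudo-count, and compared between
#' genotypes with a two-sided Welch t-test per feature. A feature is `up`
#' when its fold-change (mutant vs wild type) is at least `fc` and p <
#' `alpha`; `down` symmetrically; otherwise `unchanged`. A feature constant
#' within both groups gets p = 1 when the group means are equal (p = 0 when
#' they differ).
#'
#' @param cm a `count_matrix` with genotype labels `"WT"` and `"MUT"`
#'   (two or more replicates each).
#' @param min_count total-count filter (default 10).
#' @param fc fold-change threshold (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @return data.table: `id`, `type`, `log2fc`, `pvalue`, `status`
#'   (`up`/`down`/`unchanged`/`filtered`).
#' @export
differential_expression <- function(cm, min_count = 10L, fc = 2,
                                    alpha = 0.05) {
  wt <- cm$genotype == "WT"
  mut <- cm$genotype == "MUT"
  if (sum(wt) < 2L || sum(mut) < 2L)
    stop("need at least two replicates per genotype")
  counts <- cm$counts
  total <- rowSums(counts)
  logcpm <- log2(t(1e6 * t(counts) / cm$lib_size) + 0.5)
  n <- nrow(counts)
  l2fc <- rowMeans(logcpm[, mut, drop = FALSE]) -
    rowMeans(logcpm[, wt, drop = FALSE])
  pv <- rep(NA_real_, n)
  keep <- which(total >= min_count)
  for (i in keep) {
    x <- logcpm[i, mut]; y <- logcpm[i, wt]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      pv[i] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      pv[i] <- tryCatch(t.test(x, y)$p.value, error = function(e) 1)
    }
  }
  status <- rep("filtered", n)
  status[keep] <- "unchanged"
  status[keep][l2fc[keep] >= log2(fc) & pv[keep] < alpha] <- "up"
  status[keep][l2fc[keep] <= -log2(fc) & pv[keep] < alpha] <- "down"
  out <- data.table(id = rownames(counts),
                    type = cm$features$type[match(rownames(counts),
                                                  cm$features$id)],
                    log2fc = l2fc, pvalue = pv, status = status)
  out[]
}
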