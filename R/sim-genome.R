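#' Simulate a TE-rich genome with chromatin compartments
#'
#' Builds a synthetic genome whose structure mirrors a moss-like methylome
#' study system: chromosomes are partitioned into heterochromatic blocks
#' (elevated GC content, high nucleosome/H3 and H3K9me2 track values) and
#' euchromatic blocks (low GC, low track values). Transposable elements are
#' packed without overlap into both compartments according to `te_density`
#' and `frac_hetero_te`; genes are placed in euchromatin. LTR-class TEs carry
#' two terminal LTR sub-intervals flanking an internal region, and a subset
#' of LTR-class TEs is flagged "predisposed" (these later receive low
#' wild-type LTR methylation and weak basal expression, and are the true
#' upregulated set in the simulated mutant transcriptome).
#'
#' @param params a [sim_params()] object.
#' @return an object of class `GenomeBundle`: a list with
#'   * `genome`: [Biostrings::DNAStringSet] of chromosomes,
#'   * `tes`: [GenomicRanges::GRanges] with columns `te_id`, `family`,
#'     `class` (`"LTR"` or `"nonLTR"`), `compartment`, `ltr_len`,
#'     `predisposed`,
#'   * `genes`: `GRanges` with `gene_id`,
#'   * `blocks`: `GRanges` of compartment blocks,
#'   * `tracks`: data.table of 50-bp bins with `gc`, `h3`, `h3k9me2`,
#'   * `params`: the parameter set used.
#' @export
#' @examples
#' b <- simulate_genome(sim_params(seed = 1, n_chromosomes = 1,
#'                                 chrom_length = 20000))
#' length(b$tes)
simulate_genome <- function(params) {
  validate_sim_params(params)
  with_seed(params$seed, simulate_genome_impl(params))
}

simulate_genome_impl <- function(params) {
  L <- params$chrom_length
  nchrom <- params$n_chromosomes
  total <- as.numeric(L) * nchrom
  chrom_names <- paste0("chr", seq_len(nchrom))

  gc_hetero <- 0.55
  gc_eu <- 0.35
  fill_max <- 0.9
  gene_density <- 0.2

  # compartment sizing: heterochromatin holds frac_hetero_te of TE bases at
  # ~70% packing; fall back to a 30% heterochromatic genome when TE-free
  h_te_bp <- params$te_density * total * params$frac_hetero_te
  e_te_bp <- params$te_density * total * (1 - params$frac_hetero_te)
  h_frac <- if (h_te_bp > 0) min(0.75, (h_te_bp / total) / 0.7) else 0.3
  hetero_bp <- h_frac * total
  eu_bp <- total - hetero_bp
  if (h_te_bp > fill_max * hetero_bp ||
      e_te_bp + gene_density * eu_bp > fill_max * eu_bp)
    stop("infeasible packing: requested TE density ", params$te_density,
         " with frac_hetero_te ", params$frac_hetero_te,
         " cannot be placed without overlaps")

  block_len <- min(25000L, max(2500L, L %/% 4L))

  blocks <- data.table()
  for (ci in seq_len(nchrom)) {
    starts <- seq(0L, L - 1L, by = block_len)
    ends <- pmin(starts + block_len, L)
    nb <- length(starts)
    n_het <- round(h_frac * nb)
    lab <- rep("euchromatic", nb)
    if (n_het > 0)
      lab[unique(round(seq(1, nb, length.out = n_het)))] <- "heterochromatic"
    blocks <- rbind(blocks, data.table(chrom = chrom_names[ci],
                                       start = starts, end = ends,
                                       compartment = lab))
  }

  # sequence: iid bases per block at the compartment's GC level
  seqs <- vapply(chrom_names, function(cn) {
    bl <- blocks[chrom == cn]
    parts <- vapply(seq_len(nrow(bl)), function(i) {
      gc <- if (bl$compartment[i] == "heterochromatic") gc_hetero else gc_eu
      n <- bl$end[i] - bl$start[i]
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  genome <- DNAStringSet(seqs)
  names(genome) <- chrom_names

  # feature generation: lengths drawn once per compartment target, features
  # packed first-fit-decreasing into compartment blocks, then positioned by
  # stick-breaking of the leftover gap
  draw_lengths <- function(target_bp, meanlog, sdlog, lo, hi) {
    if (target_bp <= 0) return(integer(0))
    lens <- integer(0)
    while (sum(lens) < target_bp) {
      l <- as.integer(pmin(hi, pmax(lo, round(rlnorm(64, meanlog, sdlog)))))
      lens <- c(lens, l)
    }
    lens[cumsum(as.numeric(lens)) - lens < target_bp]
  }

  te_h_len <- draw_lengths(h_te_bp, log(1500), 0.45, 300, 6000)
  te_e_len <- draw_lengths(e_te_bp, log(1500), 0.45, 300, 6000)
  gene_len <- draw_lengths(gene_density * eu_bp, log(1800), 0.35, 500, 5000)

  feats <- rbind(
    data.table(type = "te", compartment = "heterochromatic", len = te_h_len),
    data.table(type = "te", compartment = "euchromatic", len = te_e_len),
    data.table(type = "gene", compartment = "euchromatic", len = gene_len))

  bl <- copy(blocks)
  bl[, capacity := as.integer(floor((end - start) * 0.92))]
  bl[, block_id := .I]
  placed <- vector("list", nrow(feats))
  if (nrow(feats) > 0) {
    setorder(feats, -len)
    for (i in seq_len(nrow(feats))) {
      cand <- bl[compartment == feats$compartment[i] & capacity >= feats$len[i]]
      if (nrow(cand) == 0) next
      bid <- cand$block_id[which.max(cand$capacity)]
      bl[block_id == bid, capacity := capacity - feats$len[i] - 50L]
      placed[[i]] <- data.table(block_id = bid, type = feats$type[i],
                                compartment = feats$compartment[i],
                                len = feats$len[i])
    }
  }
  placed <- rbindlist(placed)

  feat_pos <- data.table()
  if (nrow(placed) > 0) {
    pieces <- lapply(unique(placed$block_id), function(bid) {
      b <- bl[J(bid), on = "block_id"]
      pf <- placed[block_id == bid]
      m <- nrow(pf)
      ord <- sample.int(m)
      l <- pf$len[ord]
      gap_total <- (b$end - b$start) - sum(l)
      raw <- diff(c(0, sort(runif(m)), 1))
      gaps <- floor(raw[seq_len(m)] * gap_total)
      starts <- b$start + as.integer(cumsum(gaps)) +
        as.integer(cumsum(c(0L, l[-m])))
      data.table(chrom = b$chrom, start = starts, end = starts + l,
                 type = pf$type[ord], compartment = pf$compartment[ord])
    })
    feat_pos <- rbindlist(pieces)
  }

  mk_granges <- function(dt) {
    if (nrow(dt) == 0)
      return(GRanges(seqlengths = setNames(rep(L, nchrom), chrom_names)))
    gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end),
                  strand = sample(c("+", "-"), nrow(dt), replace = TRUE),
                  seqlengths = setNames(rep(L, nchrom), chrom_names))
    gr
  }

  tes_dt <- feat_pos[type == "te"]
  setorder(tes_dt, chrom, start)
  tes <- mk_granges(tes_dt)
  if (length(tes) > 0) {
    n_te <- length(tes)
    is_ltr <- runif(n_te) < 0.3
    fam <- character(n_te)
    fam[is_ltr] <- sample(c("RLG_Gypsy1", "RLG_Gypsy2", "RLC_Copia1"),
                          sum(is_ltr), replace = TRUE)
    fam[!is_ltr] <- sample(c("LINE_L1", "DNA_MuDR", "DNA_hAT", "SINE_tRNA"),
                           sum(!is_ltr), replace = TRUE)
    mcols(tes)$te_id <- sprintf("TE%04d", seq_len(n_te))
    mcols(tes)$family <- fam
    mcols(tes)$class <- ifelse(is_ltr, "LTR", "nonLTR")
    mcols(tes)$compartment <- tes_dt$compartment
    mcols(tes)$ltr_len <- ifelse(is_ltr, as.integer(round(0.15 * width(tes))),
                                 NA_integer_)
    predisposed <- rep(FALSE, n_te)
    ltr_idx <- which(is_ltr)
    if (params$n_upregulated_te > 0 && length(ltr_idx) > 0) {
      if (length(ltr_idx) < params$n_upregulated_te)
        warning("only ", length(ltr_idx), " LTR-class TEs available for ",
                params$n_upregulated_te, " predisposed slots")
      predisposed[sample(ltr_idx,
                         min(params$n_upregulated_te, length(ltr_idx)))] <- TRUE
    }
    mcols(tes)$predisposed <- predisposed
  } else {
    mcols(tes) <- S4Vectors::DataFrame(te_id = character(0),
                                       family = character(0),
                                       class = character(0),
                                       compartment = character(0),
                                       ltr_len = integer(0),
                                       predisposed = logical(0))
  }

  genes_dt <- feat_pos[type == "gene"]
  setorder(genes_dt, chrom, start)
  genes <- mk_granges(genes_dt)
  if (length(genes) > 0) {
    mcols(genes)$gene_id <- sprintf("G%04d", seq_along(genes))
  } else {
    mcols(genes) <- S4Vectors::DataFrame(gene_id = character(0))
  }

  tracks <- make_tracks(genome, blocks)

  bundle <- list(genome = genome, tes = tes, genes = genes,
                 blocks = GRanges(blocks$chrom,
                                  IRanges(blocks$start + 1L, blocks$end),
                                  compartment = blocks$compartment,
                                  seqlengths = setNames(rep(L, nchrom),
                                                        chrom_names)),
                 tracks = tracks, params = params)
  class(bundle) <- "GenomeBundle"
  bundle
}

# 50-bp chromatin tracks: GC measured from the realized sequence, H3 and
# H3K9me2 as compartment-level proxies in [0,1]
make_tracks <- function(genome, blocks, bin = 50L) {
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    cn <- names(genome)[ci]
    Lc <- length(genome[[ci]])
    starts <- seq(0L, Lc - 1L, by = bin)
    ends <- pmin(starts + bin, Lc)
    v <- Biostrings::Views(genome[[ci]], start = starts + 1L, end = ends)
    gc <- as.numeric(Biostrings::letterFrequency(v, "GC", as.prob = TRUE))
    bl <- blocks[chrom == cn]
    comp <- bl$compartment[findInterval(starts, bl$start)]
    het <- comp == "heterochromatic"
    h3 <- clamp01(rnorm(length(starts), ifelse(het, 0.75, 0.25), 0.08))
    k9 <- clamp01(rnorm(length(starts), ifelse(het, 0.70, 0.05),
                        ifelse(het, 0.10, 0.03)))
    out[[ci]] <- data.table(chrom = cn, start = starts, end = ends,
                            compartment = comp, gc = gc, h3 = h3,
                            h3k9me2 = k9)
  }
  rbindlist(out)
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat("GenomeBundle:", length(x$genome), "chromosome(s),",
      sum(Biostrings::width(x$genome)), "bp;",
      length(x$tes), "TEs (",
      sum(mcols(x$tes)$class == "LTR"), "LTR-class ),",
      length(x$genes), "genes\n")
  invisible(x)
}

#' LTR and internal sub-intervals of LTR-class TEs
#'
#' @param tes the `tes` GRanges of a [simulate_genome()] bundle.
#' @param part one of `"ltr"` (both terminal repeats) or `"internal"`.
#' @return a `GRanges` with `te_id`; TEs lacking LTR annotation are dropped.
#' @export
te_subintervals <- function(tes, part = c("ltr", "internal")) {
  part <- match.arg(part)
  keep <- !is.na(mcols(tes)$ltr_len) & mcols(tes)$ltr_len > 0
  tes <- tes[keep]
  if (length(tes) == 0) return(tes)
  ll <- mcols(tes)$ltr_len
  if (part == "ltr") {
    left <- GRanges(seqnames(tes), IRanges(start(tes), start(tes) + ll - 1L),
                    strand = strand(tes), te_id = mcols(tes)$te_id,
                    seqlengths = seqlengths(tes))
    right <- GRanges(seqnames(tes), IRanges(end(tes) - ll + 1L, end(tes)),
                     strand = strand(tes), te_id = mcols(tes)$te_id,
                     seqlengths = seqlengths(tes))
    out <- c(left, right)
    out[order(mcols(out)$te_id, start(out))]
  } else {
    GRanges(seqnames(tes), IRanges(start(tes) + ll, end(tes) - ll),
            strand = strand(tes), te_id = mcols(tes)$te_id,
            seqlengths = seqlengths(tes))
  }
}
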