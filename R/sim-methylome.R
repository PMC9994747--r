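#' Simulate ground-truth wild-type and mutant methylomes
#'
#' Assigns a true methylation probability to every cytosine of the genome
#' (both strands). Wild-type levels are drawn per 50-bp window from a Beta
#' distribution centred on the compartment- and context-specific mean
#' (TEs near `wt_levels`, gene bodies low CG-only, intergenic background
#' near zero, predisposed-TE LTR sub-intervals low), then jittered per
#' cytosine. The mutant methylome applies the per-context multiplicative
#' reduction everywhere; euchromatic-TE CHH cytosines in windows whose
#' wild-type CHH mean is below `chh_low_threshold` additionally gain
#' `chh_hyper_gain` on top of their reduced value — the CHH redistribution
#' signature: hyper-methylation confined to lowly methylated euchromatic TE
#' sequence while heterochromatic CHH is reduced. With `chh_hyper_gain = 0`
#' the mutant is therefore a clean per-context multiplicative reduction of
#' the wild type.
#'
#' @param bundle a [simulate_genome()] result.
#' @param params the same [sim_params()] object.
#' @return list with elements `wt` and `mutant`, each a data.table with one
#'   row per genomic cytosine: `chrom`, `pos0`, `strand`, `context`,
#'   `compartment` (`"heterochromatic TE"`, `"euchromatic TE"`, `"gene"`,
#'   `"intergenic"`) and `p` (true methylation probability). Both share an
#'   identical position set and row order.
#' @export
simulate_methylomes <- function(bundle, params) {
  validate_sim_params(params)
  with_seed(params$seed + 1000L, simulate_methylomes_impl(bundle, params))
}

simulate_methylomes_impl <- function(bundle, params) {
  cm <- context_map(bundle$genome)
  cm[, trinuc := NULL]

  gr <- GRanges(cm$chrom, IRanges(cm$pos0 + 1L, width = 1L))
  cm[, compartment := "intergenic"]
  if (length(bundle$genes) > 0) {
    hits <- findOverlaps(gr, bundle$genes)
    cm[queryHits(hits), compartment := "gene"]
  }
  if (length(bundle$tes) > 0) {
    hits <- findOverlaps(gr, bundle$tes)
    te_comp <- mcols(bundle$tes)$compartment[subjectHits(hits)]
    cm[queryHits(hits),
       compartment := ifelse(te_comp == "heterochromatic",
                             "heterochromatic TE", "euchromatic TE")]
    pred <- bundle$tes[mcols(bundle$tes)$predisposed]
    if (length(pred) > 0) {
      pl <- te_subintervals(pred, "ltr")
      cm[, pred_ltr := FALSE]
      if (length(pl) > 0)
        cm[unique(queryHits(findOverlaps(gr, pl))), pred_ltr := TRUE]
    } else cm[, pred_ltr := FALSE]
  } else cm[, pred_ltr := FALSE]

  wl <- params$wt_levels
  bg <- 0.01
  cm[, ctx_eff := fifelse(is.na(context), "CHH", context)]
  cm[, mu := bg]
  cm[compartment == "heterochromatic TE",
     mu := unname(wl[ctx_eff])]
  cm[compartment == "euchromatic TE",
     mu := fifelse(ctx_eff == "CHH", params$eu_chh_level, unname(wl[ctx_eff]))]
  cm[compartment == "gene" & ctx_eff == "CG", mu := params$gene_cg_level]
  cm[pred_ltr == TRUE, mu := 0.1]

  # one Beta draw per (window, context, mean) group, then per-cytosine jitter
  cm[, win := pos0 %/% 50L]
  grp <- cm[, .(mu = mu[1]), by = .(chrom, win, ctx_eff, mu_key = mu)]
  grp[, p_win := rbeta_mean(.N, mu_key, params$beta_concentration)]
  cm <- merge(cm, grp[, .(chrom, win, ctx_eff, mu_key, p_win)],
              by.x = c("chrom", "win", "ctx_eff", "mu"),
              by.y = c("chrom", "win", "ctx_eff", "mu_key"),
              sort = FALSE)
  cm[, p := clamp01(p_win + rnorm(.N, 0, 0.03))]
  setorder(cm, chrom, pos0, strand)

  red <- params$mutant_reduction
  cm[, p_mut := p * (1 - unname(red[ctx_eff]))]
  # CHH redistribution: euchromatic TE windows with low wild-type CHH gain
  cm[, eu_chh := compartment == "euchromatic TE" & ctx_eff == "CHH"]
  if (any(cm$eu_chh)) {
    wmean <- cm[eu_chh == TRUE, .(w_chh = mean(p)), by = .(chrom, win)]
    low <- wmean[w_chh < params$chh_low_threshold]
    if (nrow(low) > 0) {
      cm[low, on = c("chrom", "win"),
         p_mut := fifelse(eu_chh, clamp01(p_mut + params$chh_hyper_gain),
                          p_mut)]
    }
  }

  base_cols <- c("chrom", "pos0", "strand", "context", "compartment")
  wt <- cm[, c(base_cols, "p"), with = FALSE]
  mut <- cm[, c(base_cols, "p_mut"), with = FALSE]
  setnames(mut, "p_mut", "p")
  list(wt = copy(wt), mutant = copy(mut))
}

#' Write a ground-truth methylome table
#'
#' @param truth one element of [simulate_methylomes()] output.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  fwrite(truth, path, sep = "\t")
  invisible(path)
}
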