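#' Simulate gene and TE expression counts
#'
#' Draws negative-binomial read counts per feature and replicate for two
#' genotypes. Genes get moderate-to-high baseline means; most TEs are near
#' silent (methylation-silenced), while the predisposed LTR-class TEs flagged
#' by [simulate_genome()] have a small nonzero wild-type mean and are
#' multiplied by `de_fold` in the mutant — the true differentially expressed
#' set.
#'
#' @param bundle a [simulate_genome()] result.
#' @param params a [sim_params()] object (`n_reps`, `de_fold`,
#'   `nb_dispersion`).
#' @param seed RNG seed; defaults to `params$seed + 4000`.
#' @return list of class `count_matrix`:
#'   * `counts`: integer matrix, features x (2 * n_reps) replicates,
#'   * `genotype`: `"WT"`/`"MUT"` per column,
#'   * `lib_size`: column sums,
#'   * `features`: data.table (`id`, `type`, `family`, `predisposed`,
#'     `base_mean`),
#'   * `truth`: data.table of truly DE features (`id`, `fold`); empty when
#'     `de_fold = 1`.
#' @export
simulate_expression_counts <- function(bundle, params,
                                       seed = params$seed + 4000L) {
  validate_sim_params(params)
  if (params$n_reps < 2L) stop("n_reps must be >= 2")
  te <- bundle$tes
  gn <- bundle$genes
  feats <- rbind(
    if (length(gn)) data.table(id = mcols(gn)$gene_id, type = "gene",
                               family = NA_character_, predisposed = FALSE)
    else NULL,
    if (length(te)) data.table(id = mcols(te)$te_id, type = "te",
                               family = mcols(te)$family,
                               predisposed = mcols(te)$predisposed)
    else NULL)
  if (is.null(feats) || nrow(feats) == 0) stop("bundle has no features")

  with_seed(seed, {
    n <- nrow(feats)
    base <- numeric(n)
    g <- feats$type == "gene"
    base[g] <- rlnorm(sum(g), log(80), 1)
    base[!g] <- rlnorm(sum(!g), log(1), 1.2)
    base[feats$predisposed] <- rlnorm(sum(feats$predisposed), log(15), 0.3)
    feats[, base_mean := base]

    fold <- ifelse(feats$predisposed, params$de_fold, 1)
    size <- if (params$nb_dispersion > 0) 1 / params$nb_dispersion else Inf
    nrep <- params$n_reps
    draw <- function(mu) {
      if (is.finite(size)) rnbinom(length(mu), mu = mu, size = size)
      else rpois(length(mu), mu)
    }
    counts <- cbind(
      matrix(draw(rep(base, nrep)), nrow = n),
      matrix(draw(rep(base * fold, nrep)), nrow = n))
    dimnames(counts) <- list(feats$id,
                             c(paste0("WT_", seq_len(nrep)),
                               paste0("MUT_", seq_len(nrep))))
    truth <- feats[predisposed & params$de_fold != 1,
                   .(id, fold = params$de_fold)]
    out <- list(counts = counts,
                genotype = rep(c("WT", "MUT"), each = nrep),
                lib_size = colSums(counts),
                features = feats, truth = truth)
    class(out) <- "count_matrix"
    out
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "replicates (", sum(x$genotype == "WT"), "WT /",
      sum(x$genotype == "MUT"), "MUT );", nrow(x$truth),
      "truly DE feature(s)\n")
  invisible(x)
}
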