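#' Simulation parameters for the synthetic methylome study
#'
#' Constructs and validates the parameter set driving every synthetic-data
#' generator: genome geometry, TE compartment structure, per-context wild-type
#' methylation levels, the mutant's per-context reduction, the euchromatic CHH
#' hyper-methylation gain, bisulfite chemistry rates, sequencing depth, and
#' expression-count settings.
#'
#' Defaults describe a moss-like TE-rich methylome: TEs carry high symmetric
#' (CG/CHG) methylation near 0.8 and moderate CHH methylation, the mutant
#' loses about 75% of symmetric methylation but only about 25% of CHH
#' methylation, and lowly methylated euchromatic TE sequence gains CHH
#' methylation in the mutant. Bisulfite conversion is perfect and reads are
#' error-free by default so oracle tests are exact; noise is opt-in.
#'
#' @param seed integer seed; all generators are deterministic given the
#'   parameter set (identical seed implies identical output).
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param te_density fraction of the genome covered by TEs.
#' @param frac_hetero_te fraction of TE bases in the heterochromatic
#'   compartment (high GC, high H3/H3K9me2 tracks).
#' @param wt_levels named numeric of length 3 (`CG`, `CHG`, `CHH`): mean
#'   wild-type methylation of TE cytosines per context. The CHH entry applies
#'   to heterochromatic TEs; euchromatic TE CHH uses `eu_chh_level`.
#' @param mutant_reduction named numeric of length 3: per-context
#'   multiplicative methylation loss in the mutant, each in \[0,1\].
#' @param chh_hyper_gain additive CHH methylation gained in the mutant within
#'   euchromatic TE windows whose wild-type CHH mean is below
#'   `chh_low_threshold` (clipped to 1).
#' @param chh_low_threshold wild-type window-mean CHH level below which
#'   euchromatic TE cytosines are hyper- rather than hypo-methylated in the
#'   mutant. Default 0.15.
#' @param eu_chh_level mean wild-type CHH methylation of euchromatic TEs
#'   (kept below `chh_low_threshold` so the redistribution structure exists).
#' @param gene_cg_level mean wild-type gene-body CG methylation.
#' @param conversion_rate probability an unmethylated cytosine reads as T.
#' @param meth_protection probability a methylated cytosine reads as C.
#' @param read_length read length in bp (paired-end; fragments span twice
#'   this, so mates never overlap).
#' @param coverage mean fold-coverage of the bisulfite library.
#' @param seq_error per-base sequencing error probability.
#' @param n_reps expression replicates per genotype.
#' @param n_upregulated_te number of predisposed LTR-class TEs truly
#'   upregulated in the mutant.
#' @param de_fold true expression fold-change of upregulated TEs.
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param beta_concentration concentration of the per-window Beta draw around
#'   the mean methylation level.
#'
#' @return a validated list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(seed = 1, chrom_length = 50000)
#' p$wt_levels
sim_params <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 250000L,
                       te_density = 0.4,
                       frac_hetero_te = 0.7,
                       wt_levels = c(CG = 0.8, CHG = 0.8, CHH = 0.3),
                       mutant_reduction = c(CG = 0.75, CHG = 0.75, CHH = 0.25),
                       chh_hyper_gain = 0.1,
                       chh_low_threshold = 0.15,
                       eu_chh_level = 0.08,
                       gene_cg_level = 0.05,
                       conversion_rate = 1,
                       meth_protection = 1,
                       read_length = 100L,
                       coverage = 30,
                       seq_error = 0,
                       n_reps = 3L,
                       n_upregulated_te = 35L,
                       de_fold = 8,
                       nb_dispersion = 0.1,
                       beta_concentration = 20) {
  p <- list(seed = as.integer(seed),
            n_chromosomes = as.integer(n_chromosomes),
            chrom_length = as.integer(chrom_length),
            te_density = te_density,
            frac_hetero_te = frac_hetero_te,
            wt_levels = wt_levels,
            mutant_reduction = mutant_reduction,
            chh_hyper_gain = chh_hyper_gain,
            chh_low_threshold = chh_low_threshold,
            eu_chh_level = eu_chh_level,
            gene_cg_level = gene_cg_level,
            conversion_rate = conversion_rate,
            meth_protection = meth_protection,
            read_length = as.integer(read_length),
            coverage = coverage,
            seq_error = seq_error,
            n_reps = as.integer(n_reps),
            n_upregulated_te = as.integer(n_upregulated_te),
            de_fold = de_fold,
            nb_dispersion = nb_dispersion,
            beta_concentration = beta_concentration)
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(length(p$seed) == 1L, is.finite(p$seed))
  if (p$n_chromosomes < 1L || p$chrom_length < 1L)
    stop("n_chromosomes and chrom_length must be positive")
  fracs <- c(te_density = p$te_density, frac_hetero_te = p$frac_hetero_te,
             chh_hyper_gain = p$chh_hyper_gain,
             chh_low_threshold = p$chh_low_threshold,
             eu_chh_level = p$eu_chh_level, gene_cg_level = p$gene_cg_level,
             conversion_rate = p$conversion_rate,
             meth_protection = p$meth_protection, seq_error = p$seq_error,
             p$wt_levels, p$mutant_reduction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("probabilities/fractions out of [0,1]: ",
         paste(names(fracs)[bad], collapse = ", "))
  for (nm in c("wt_levels", "mutant_reduction")) {
    if (!all(c("CG", "CHG", "CHH") %in% names(p[[nm]])))
      stop(nm, " must be named with CG, CHG, CHH")
  }
  if (p$read_length < 1L || p$coverage < 0 || p$n_reps < 1L ||
      p$de_fold <= 0 || p$nb_dispersion < 0 || p$beta_concentration <= 0)
    stop("invalid read/coverage/expression parameters")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:", x$n_chromosomes, "x", x$chrom_length, "bp, TE density",
      x$te_density, "\n  wt_levels:",
      paste(names(x$wt_levels), x$wt_levels, sep = "=", collapse = " "),
      "\n  mutant_reduction:",
      paste(names(x$mutant_reduction), x$mutant_reduction, sep = "=",
            collapse = " "),
      "\n  coverage:", x$coverage, "x, read_length:", x$read_length,
      "bp, seed:", x$seed, "\n")
  invisible(x)
}
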