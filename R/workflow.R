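#' Pipeline configuration
#'
#' Collects every stage parameter with defaults, round-trips through YAML
#' unchanged, and carries the global seed through the simulation parameters.
#'
#' @param params a [sim_params()] block describing the simulated study (or
#'   `NULL` with externally supplied inputs, not yet wired).
#' @param outdir output directory.
#' @param stages named list of logical toggles: `simulate`, `align`,
#'   `methylation`, `diffmeth`, `metaprofile`, `expression`.
#' @param window_width,min_calls windowed-methylation settings.
#' @param max_mismatch,max_hits aligner settings.
#' @param min_meth matched-window methylation threshold.
#' @param n_quantiles quantile count for attribute stratification.
#' @param chrom_window chromosome-profile bin width in bp.
#' @param metaprofile_bin,max_offset meta-profile settings.
#' @param min_count,fc,alpha differential-expression filters.
#' @param write_files write intermediate files (FASTA/BED/TSV) to `outdir`;
#'   the run report is always written.
#' @return list of class `run_config`.
#' @export
run_config <- function(params = sim_params(), outdir = tempfile("methylte_"),
                       stages = list(), window_width = 50L, min_calls = 4L,
                       max_mismatch = 2L, max_hits = 10L, min_meth = 0.5,
                       n_quantiles = 5L, chrom_window = 100000L,
                       metaprofile_bin = 100L, max_offset = 2000L,
                       min_count = 10L, fc = 2, alpha = 0.05,
                       write_files = TRUE) {
  st <- list(simulate = TRUE, align = TRUE, methylation = TRUE,
             diffmeth = TRUE, metaprofile = TRUE, expression = TRUE)
  for (nm in names(stages)) st[[nm]] <- isTRUE(stages[[nm]])
  cfg <- list(params = params, outdir = outdir, stages = st,
              window_width = as.integer(window_width),
              min_calls = as.integer(min_calls),
              max_mismatch = as.integer(max_mismatch),
              max_hits = as.integer(max_hits), min_meth = min_meth,
              n_quantiles = as.integer(n_quantiles),
              chrom_window = as.integer(chrom_window),
              metaprofile_bin = as.integer(metaprofile_bin),
              max_offset = as.integer(max_offset),
              min_count = as.integer(min_count), fc = fc, alpha = alpha,
              write_files = isTRUE(write_files))
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [run_config()].
#' @param path YAML path.
#' @return `write_run_config` the path invisibly; `read_run_config` the
#'   restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$params$wt_levels <- as.list(x$params$wt_levels)
  x$params$mutant_reduction <- as.list(x$params$mutant_reduction)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  p <- x$params
  p$wt_levels <- unlist(p$wt_levels)
  p$mutant_reduction <- unlist(p$mutant_reduction)
  params <- do.call(sim_params, p)
  x$params <- NULL
  do.call(run_config, c(list(params = params), x))
}

#' Run the full methylome-comparison pipeline
#'
#' Executes simulate, align, methylation calling, differential methylation,
#' meta-profile and expression stages in dependency order, skipping disabled
#' stages, and returns (and writes) a machine-readable report: per-context
#' TE methylation reductions, matched-window medians, DE counts, the
#' upregulated-TE methylation contrast, a file manifest with MD5 hashes, the
#' seed and package version.
#'
#' @param config a [run_config()].
#' @return the report, a list (also written as `report.json` in
#'   `config$outdir`). Intermediate tables are attached in the
#'   `"intermediates"` attribute for programmatic use.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  params <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  report <- list(seed = params$seed,
                 package_version = as.character(packageVersion("methylTE")))
  inter <- list()
  manifest <- character(0)

  if (!st$simulate) stop("stage 'simulate' is required: no external inputs configured")
  logf("simulate: genome + methylomes + reads + counts")
  bundle <- simulate_genome(params)
  meth <- simulate_methylomes(bundle, params)
  reads_wt <- simulate_bisulfite_reads(bundle, meth$wt, params,
                                       seed = params$seed + 2000L)
  reads_mut <- simulate_bisulfite_reads(bundle, meth$mutant, params,
                                        seed = params$seed + 3000L)
  inter$bundle <- bundle
  inter$methylomes <- meth
  if (config$write_files) {
    manifest <- c(manifest, write_genome_bundle(bundle, config$outdir))
    tp <- file.path(config$outdir, c("truth_wt.tsv", "truth_mut.tsv"))
    write_truth(meth$wt, tp[1]); write_truth(meth$mutant, tp[2])
    manifest <- c(manifest, truth_wt = tp[1], truth_mut = tp[2])
  }

  if (st$align) {
    logf("align: three-letter alignment + pileup, both samples")
    idx <- build_converted_index(bundle)
    hits_wt <- align_reads(reads_wt, idx, config$max_mismatch,
                           config$max_hits, seed = params$seed + 11L)
    hits_mut <- align_reads(reads_mut, idx, config$max_mismatch,
                            config$max_hits, seed = params$seed + 12L)
    cx_wt <- pileup_cytosines(hits_wt, bundle)
    cx_mut <- pileup_cytosines(hits_mut, bundle)
    inter$cx <- list(wt = cx_wt, mut = cx_mut)
    report$aligned_reads <- c(wt = nrow(hits_wt), mut = nrow(hits_mut))
    report$discarded <- list(wt = as.list(attr(hits_wt, "discarded")),
                             mut = as.list(attr(hits_mut, "discarded")))
    if (config$write_files) {
      p <- file.path(config$outdir, c("cx_wt.tsv", "cx_mut.tsv"))
      write_cx(cx_wt, p[1]); write_cx(cx_mut, p[2])
      manifest <- c(manifest, cx_wt = p[1], cx_mut = p[2])
    }
  }

  if (st$methylation) {
    if (is.null(inter$cx)) stop("stage 'methylation' needs stage 'align'")
    logf("methylation: windows + per-TE parts")
    win_wt <- window_methylation(inter$cx$wt, bundle, config$window_width,
                                 min_calls = config$min_calls)
    win_mut <- window_methylation(inter$cx$mut, bundle, config$window_width,
                                  min_calls = config$min_calls)
    inter$windows <- list(wt = win_wt, mut = win_mut)
    te_parts <- rbindlist(lapply(c("whole", "internal", "ltr"), function(pt) {
      rbind(region_methylation(inter$cx$wt, bundle$tes, pt,
                               config$min_calls)[, sample := "WT"],
            region_methylation(inter$cx$mut, bundle$tes, pt,
                               config$min_calls)[, sample := "MUT"])
    }), fill = TRUE)
    inter$te_meth <- te_parts
    if (config$write_files) {
      p <- file.path(config$outdir, "te_methylation.tsv")
      fwrite(te_parts, p, sep = "\t")
      manifest <- c(manifest, te_methylation = p)
    }
  }

  if (st$diffmeth) {
    if (is.null(inter$windows)) stop("stage 'diffmeth' needs stage 'methylation'")
    logf("diffmeth: percent change, matched windows, stratification")
    win_wt <- inter$windows$wt; win_mut <- inter$windows$mut
    red <- estimate_context_reduction(win_wt, win_mut, bundle$tes)
    report$context_reduction <- setNames(as.list(red$reduction_pct),
                                         red$context)
    mw <- select_matched_windows(win_wt, win_mut, config$min_meth)
    ms <- attr(mw, "summary")
    report$matched_window_median <- if (nrow(ms) > 0)
      list(wt = ms[sample == "A", median], mut = ms[sample == "B", median])
    else list(wt = NA_real_, mut = NA_real_)
    changes <- rbindlist(lapply(c("CG", "CHG", "CHH"), function(ctx)
      window_percent_change(windows_in_regions(win_wt, bundle$tes),
                            windows_in_regions(win_mut, bundle$tes), ctx)))
    inter$changes <- changes
    # TE-window CHH change stratified by wild-type CHH level of the window
    chh <- changes[context == "CHH"]
    strat <- tryCatch(
      stratify_by_attribute(chh, chh[, .(chrom, start, value = m_a)],
                            config$n_quantiles),
      error = function(e) NULL)
    inter$chh_stratified <- strat
    if (!is.null(strat))
      report$chh_quantile_median <- strat$median
    inter$chrom_profile <- list(
      wt = chromosome_profile(inter$cx$wt, bundle, config$chrom_window),
      mut = chromosome_profile(inter$cx$mut, bundle, config$chrom_window))
    if (config$write_files) {
      p <- file.path(config$outdir,
                     c("percent_change.tsv", "matched_windows.tsv",
                       "chromosome_profile_wt.tsv",
                       "chromosome_profile_mut.tsv"))
      fwrite(changes, p[1], sep = "\t")
      fwrite(mw, p[2], sep = "\t")
      fwrite(inter$chrom_profile$wt, p[3], sep = "\t")
      fwrite(inter$chrom_profile$mut, p[4], sep = "\t")
      if (!is.null(strat)) {
        ps <- file.path(config$outdir, "chh_quantiles.tsv")
        fwrite(strat, ps, sep = "\t")
        manifest <- c(manifest, chh_quantiles = ps)
      }
      manifest <- c(manifest, percent_change = p[1], matched_windows = p[2],
                    chrom_profile_wt = p[3], chrom_profile_mut = p[4])
    }
  }

  if (st$metaprofile) {
    if (is.null(inter$cx)) stop("stage 'metaprofile' needs stage 'align'")
    logf("metaprofile: 5prime + 3prime")
    mp <- rbind(
      te_metaprofile(list(WT = inter$cx$wt, MUT = inter$cx$mut), bundle,
                     "5prime", config$metaprofile_bin, config$max_offset),
      te_metaprofile(list(WT = inter$cx$wt, MUT = inter$cx$mut), bundle,
                     "3prime", config$metaprofile_bin, config$max_offset))
    inter$metaprofile <- mp
    if (config$write_files) {
      p <- file.path(config$outdir, "metaprofile.tsv")
      fwrite(mp, p, sep = "\t")
      manifest <- c(manifest, metaprofile = p)
    }
  }

  if (st$expression) {
    logf("expression: counts + DE + family RPM + contrast")
    cmx <- simulate_expression_counts(bundle, params)
    de <- differential_expression(cmx, config$min_count, config$fc,
                                  config$alpha)
    fam <- family_rpm(cmx)
    inter$counts <- cmx
    inter$de <- de
    report$de_counts <- list(
      up_te = de[type == "te" & status == "up", .N],
      down_te = de[type == "te" & status == "down", .N],
      up_gene = de[type == "gene" & status == "up", .N],
      down_gene = de[type == "gene" & status == "down", .N],
      filtered = de[status == "filtered", .N])
    if (!is.null(inter$te_meth)) {
      contrast <- upregulated_te_methylation_contrast(
        de, inter$te_meth[sample == "WT"],
        if (!is.null(inter$changes))
          te_percent_change(inter$changes, bundle$tes) else NULL)
      inter$contrast <- contrast
      report$upregulated_ltr_effect <- contrast$tests[
        metric == "m_total_ltr", effect]
    }
    if (config$write_files) {
      p <- file.path(config$outdir, c("counts.tsv", "de.tsv",
                                      "family_rpm.tsv"))
      fwrite(as.data.table(cmx$counts, keep.rownames = "id"), p[1],
             sep = "\t")
      fwrite(de, p[2], sep = "\t")
      fwrite(fam, p[3], sep = "\t")
      manifest <- c(manifest, counts = p[1], de = p[2], family_rpm = p[3])
    }
  }

  report$manifest <- as.list(setNames(unname(md5sum(manifest)),
                                      basename(manifest)))
  rp <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logf("done")
  attr(report, "intermediates") <- inter
  report
}

# mean signed percent change per TE, averaging over its 50-bp windows
te_percent_change <- function(changes, tes, context = "total") {
  ctx <- context
  ch <- if (ctx %in% unique(changes$context)) changes[context == ctx]
        else changes
  gr <- GRanges(ch$chrom, IRanges(ch$start + 1L, ch$end))
  ov <- findOverlaps(gr, tes, ignore.strand = TRUE)
  dt <- ch[queryHits(ov)][, te_id := mcols(tes)$te_id[subjectHits(ov)]]
  dt[, .(pct_change = mean(pct_change)), by = .(id = te_id)]
}

#' Methylation contrast between upregulated and unaffected TEs
#'
#' Compares the wild-type methylation of TEs called upregulated against the
#' remaining expressed-and-tested (unaffected) TEs, for the whole element,
#' the internal sequence and the LTR sub-intervals, plus (optionally) the
#' mutant-versus-wild-type percent methylation change. Group differences are
#' summarized with a rank-based (Mann-Whitney) test and the rank-biserial
#' effect size (negative: upregulated group lower).
#'
#' @param de a [differential_expression()] table.
#' @param te_meth_wt per-TE wild-type methylation: a table from
#'   [region_methylation()] runs with a `part` column covering `whole`,
#'   `internal`, `ltr` (id column `id`).
#' @param te_changes optional per-TE percent-change table (`id`,
#'   `pct_change`).
#' @return list with `summary` (per metric and group: n, median, quartiles)
#'   and `tests` (per metric: Mann-Whitney p and rank-biserial effect).
#' @export
upregulated_te_methylation_contrast <- function(de, te_meth_wt,
                                                te_changes = NULL) {
  tes <- de[type == "te" & status != "filtered"]
  up_ids <- tes[status == "up", id]
  un_ids <- tes[status != "up", id]
  if (length(up_ids) == 0)
    warning("no upregulated TEs; summarizing the unaffected group only")

  metrics <- list()
  for (pt in intersect(c("whole", "internal", "ltr"),
                       unique(te_meth_wt$part))) {
    metrics[[paste0("m_total_", pt)]] <-
      te_meth_wt[part == pt, .(id, value = m_total)]
  }
  if (!is.null(te_changes))
    metrics$pct_change <- te_changes[, .(id, value = pct_change)]

  smry <- list(); tests <- list()
  for (mn in names(metrics)) {
    mt <- metrics[[mn]][!is.na(value)]
    gu <- mt[id %in% up_ids, value]
    gn <- mt[id %in% un_ids, value]
    sm <- rbind(
      if (length(gu) > 0)
        data.table(metric = mn, group = "upregulated", n = length(gu),
                   median = median(gu), q1 = unname(quantile(gu, 0.25)),
                   q3 = unname(quantile(gu, 0.75))) else NULL,
      if (length(gn) > 0)
        data.table(metric = mn, group = "unaffected", n = length(gn),
                   median = median(gn), q1 = unname(quantile(gn, 0.25)),
                   q3 = unname(quantile(gn, 0.75))) else NULL)
    smry[[mn]] <- sm
    if (length(gu) > 0 && length(gn) > 0) {
      wt <- suppressWarnings(wilcox.test(gu, gn))
      effect <- 2 * unname(wt$statistic) / (length(gu) * length(gn)) - 1
      tests[[mn]] <- data.table(metric = mn, p = wt$p.value, effect = effect)
    } else {
      tests[[mn]] <- data.table(metric = mn, p = NA_real_,
                                effect = NA_real_)
    }
  }
  list(summary = rbindlist(smry), tests = rbindlist(tests))
}
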