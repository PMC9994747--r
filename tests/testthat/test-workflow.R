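wf_params <- function(...) {
  args <- list(seed = 21, n_chromosomes = 1, chrom_length = 50000,
               coverage = 10, n_upregulated_te = 3)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

test_that("run_config fills defaults and round-trips through YAML", {
  cfg <- run_config(wf_params(), stages = list(expression = FALSE),
                    window_width = 100, fc = 4)
  expect_s3_class(cfg, "run_config")
  expect_true(cfg$stages$align)
  expect_false(cfg$stages$expression)
  expect_identical(cfg$window_width, 100L)
  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_identical(cfg2$stages, cfg$stages)
  expect_identical(cfg2$window_width, cfg$window_width)
  expect_identical(cfg2$fc, cfg$fc)
  expect_identical(unclass(cfg2$params)[names(cfg$params)],
                   unclass(cfg$params)[names(cfg$params)])
})

test_that("disabled prerequisite stages fail with a clear message", {
  base <- wf_params()
  expect_error(
    run_pipeline(run_config(base, outdir = withr::local_tempdir(),
                            stages = list(align = FALSE,
                                          metaprofile = FALSE,
                                          expression = FALSE))),
    "'methylation' needs stage 'align'")
  expect_error(
    run_pipeline(run_config(base, outdir = withr::local_tempdir(),
                            stages = list(methylation = FALSE,
                                          metaprofile = FALSE,
                                          expression = FALSE))),
    "'diffmeth' needs stage 'methylation'")
})

test_that("the pipeline produces a coherent report and manifest", {
  out <- withr::local_tempdir()
  rep <- suppressWarnings(
    run_pipeline(run_config(wf_params(), outdir = out)))
  expect_true(file.exists(file.path(out, "report.json")))
  disk <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(disk$seed, 21)
  expect_setequal(names(rep$context_reduction), c("CG", "CHG", "CHH"))
  # configured 75% symmetric reduction should be visible even at this size
  expect_gt(rep$context_reduction$CG, 50)
  expect_gt(rep$context_reduction$CHG, 50)
  expect_true(all(rep$aligned_reads > 0))
  inter <- attr(rep, "intermediates")
  expect_s3_class(inter$windows$wt, "data.table")
  # every manifest entry exists and hashes to its recorded MD5
  for (f in names(rep$manifest)) {
    fp <- file.path(out, f)
    expect_true(file.exists(fp))
    expect_identical(unname(tools::md5sum(fp)), rep$manifest[[f]])
  }
})

test_that("two runs with one seed are bit-identical, a new seed differs", {
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  o3 <- withr::local_tempdir()
  p <- wf_params(chrom_length = 40000)
  st <- list(metaprofile = FALSE)
  r1 <- suppressWarnings(run_pipeline(run_config(p, outdir = o1, stages = st)))
  r2 <- suppressWarnings(run_pipeline(run_config(p, outdir = o2, stages = st)))
  expect_identical(r1$manifest, r2$manifest)
  expect_identical(r1$context_reduction, r2$context_reduction)
  p2 <- wf_params(chrom_length = 40000, seed = 22)
  r3 <- suppressWarnings(run_pipeline(run_config(p2, outdir = o3,
                                                 stages = st)))
  expect_false(identical(r1$manifest[["cx_wt.tsv"]],
                         r3$manifest[["cx_wt.tsv"]]))
})

test_that("pipeline reduction equals the stage-by-stage computation", {
  out <- withr::local_tempdir()
  rep <- suppressWarnings(
    run_pipeline(run_config(wf_params(), outdir = out,
                            stages = list(metaprofile = FALSE,
                                          expression = FALSE),
                            write_files = FALSE)))
  inter <- attr(rep, "intermediates")
  red <- estimate_context_reduction(inter$windows$wt, inter$windows$mut,
                                    inter$bundle$tes)
  expect_equal(unlist(rep$context_reduction),
               setNames(red$reduction_pct, red$context))
})

test_that("upregulated-TE contrast partitions tested TEs and scores groups", {
  de <- data.table(
    id = c(paste0("te", 1:6), "g1"),
    type = c(rep("te", 6), "gene"),
    log2fc = c(3, 3, 0, 0, 0, 0, 0), pvalue = 0.01,
    status = c("up", "up", "unchanged", "unchanged", "unchanged",
               "filtered", "unchanged"))
  tm <- data.table(id = paste0("te", 1:6), part = "whole",
                   m_total = c(0.1, 0.2, 0.8, 0.9, 0.85, 0.7))
  ct <- upregulated_te_methylation_contrast(de, tm)
  sm <- ct$summary
  expect_equal(sm[group == "upregulated", n], 2L)
  expect_equal(sm[group == "unaffected", n], 3L)  # te6 filtered out
  expect_equal(sm[group == "upregulated", median], 0.15)
  tst <- ct$tests
  expect_equal(tst$effect, -1)  # complete separation, upregulated lower
  expect_warning(
    upregulated_te_methylation_contrast(de[status != "up"], tm),
    "no upregulated")
})
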