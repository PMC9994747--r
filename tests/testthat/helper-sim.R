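library(data.table)

# small shared fixtures, built once per test run

small_params <- function(...) {
  args <- list(seed = 11, n_chromosomes = 1, chrom_length = 60000,
               coverage = 20, n_upregulated_te = 3)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_params, args)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_bundle <- function() {
  fixture("small_bundle",
          function() suppressWarnings(simulate_genome(small_params())))
}

small_methylomes <- function() {
  fixture("small_meth",
          function() simulate_methylomes(small_bundle(), small_params()))
}

# aligned + piled-up records for both genotypes on the small fixture
small_cx <- function() {
  fixture("small_cx", function() {
    p <- small_params()
    b <- small_bundle()
    m <- small_methylomes()
    idx <- build_converted_index(b)
    lapply(list(wt = m$wt, mut = m$mutant), function(tr) {
      rs <- simulate_bisulfite_reads(b, tr, p,
                                     seed = p$seed + sum(tr$p > 0.5))
      pileup_cytosines(align_reads(rs, idx, seed = 7), b)
    })
  })
}

random_genome <- function(n, gc = 0.45, name = "chr1") {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
             collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# independent brute-force three-letter aligner over every position of both
# conversion modes, via Biostrings::matchPattern (mate-1 read semantics)
brute_force_hits <- function(read, genome_chr, max_mm = 2) {
  g <- as.character(genome_chr)
  g_ct <- chartr("C", "T", g)
  g_ga <- chartr("G", "A", g)
  hit_set <- function(query, subject, tmpl) {
    m <- Biostrings::matchPattern(query, Biostrings::DNAString(subject),
                                  max.mismatch = max_mm, with.indels = FALSE)
    if (length(m) == 0) return(NULL)
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(query),
                                      Biostrings::DNAString(subject),
                                      starting.at = Biostrings::start(m))
    data.table(pos0 = Biostrings::start(m) - 1L, strand = tmpl, mm = mm)
  }
  rbind(hit_set(chartr("C", "T", read), g_ct, "+"),
        hit_set(chartr("G", "A", revcomp_chr(read)), g_ga, "-"))
}
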