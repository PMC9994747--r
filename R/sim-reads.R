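#' Simulate paired-end bisulfite reads
#'
#' Samples fragments uniformly over the genome and both template strands and
#' emits directional paired-end reads. Each fragment spans twice the read
#' length, mate 1 being the first `read_length` bases of the
#' bisulfite-converted template strand (5' to 3') and mate 2 the reverse
#' complement of the last `read_length` bases, so mates never overlap. For
#' each templated cytosine an independent Bernoulli draw under its true
#' methylation probability decides the methylation state; a methylated
#' cytosine is read as C with probability `meth_protection`, an unmethylated
#' one as T with probability `conversion_rate`. Sequencing errors are applied
#' independently afterwards. Read names encode the true origin
#' (`sim<i>:<chrom>:<start0>:<strand>`) so oracle tests can recover it.
#'
#' The number of pairs is `round(coverage * genome_length /
#' (2 * read_length))`.
#'
#' @param bundle a [simulate_genome()] result.
#' @param truth one methylome of [simulate_methylomes()] (data.table with
#'   `chrom`, `pos0`, `strand`, `p`).
#' @param params a [sim_params()] object.
#' @param seed RNG seed for fragment sampling and bisulfite draws; defaults
#'   to `params$seed + 2000`.
#' @return data.table of class `bis_reads` with one row per pair: `id`,
#'   `chrom`, `start0` (fragment start), `strand` (template strand), `mate1`,
#'   `mate2` (read sequences).
#' @export
simulate_bisulfite_reads <- function(bundle, truth, params,
                                     seed = params$seed + 2000L) {
  validate_sim_params(params)
  if (params$coverage <= 0) stop("coverage must be > 0")
  genome <- bundle$genome
  lens <- Biostrings::width(genome)
  frag <- 2L * params$read_length
  if (any(frag > lens))
    stop("read_length too large: fragment (2x read length = ", frag,
         " bp) exceeds a chromosome length")
  total <- sum(as.numeric(lens))
  n_pairs <- round(params$coverage * total / (2 * params$read_length))
  if (n_pairs < 1) stop("coverage too low: zero read pairs requested")

  # per-position truth arrays; positions without a cytosine stay at 0 and
  # are never consulted
  p_plus <- lapply(lens, function(L) numeric(L))
  p_minus <- lapply(lens, function(L) numeric(L))
  names(p_plus) <- names(p_minus) <- names(genome)
  for (cn in unique(truth$chrom)) {
    tp <- truth[chrom == cn & strand == "+"]
    tm <- truth[chrom == cn & strand == "-"]
    p_plus[[cn]][tp$pos0 + 1L] <- tp$p
    p_minus[[cn]][tm$pos0 + 1L] <- tm$p
  }

  with_seed(seed, {
    wts <- (lens - frag + 1) / sum(lens - frag + 1)
    ci <- sample.int(length(genome), n_pairs, replace = TRUE, prob = wts)
    start0 <- floor(runif(n_pairs) * (lens[ci] - frag + 1))
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    res <- cpp_simulate_read_pairs(as.character(genome), p_plus, p_minus,
                                   as.integer(ci), as.integer(start0), strand,
                                   params$read_length,
                                   params$conversion_rate,
                                   params$meth_protection, params$seq_error)
    out <- data.table(id = sprintf("sim%07d:%s:%d:%s", seq_len(n_pairs),
                                   names(genome)[ci], as.integer(start0),
                                   strand),
                      chrom = names(genome)[ci],
                      start0 = as.integer(start0), strand = strand,
                      mate1 = res$mate1, mate2 = res$mate2)
    setattr(out, "class", c("bis_reads", class(out)))
    out
  })
}

#' Long-format view of a paired read set
#'
#' @param reads a `bis_reads` table (or any data.table with `id`, `mate1`,
#'   `mate2`).
#' @return data.table with `id`, `pair` (integer pair index), `mate` (1/2)
#'   and `seq`, ordered so mate 1 of each pair precedes mate 2.
#' @export
reads_long <- function(reads) {
  out <- rbind(
    data.table(id = reads$id, pair = seq_len(nrow(reads)), mate = 1L,
               seq = reads$mate1),
    data.table(id = reads$id, pair = seq_len(nrow(reads)), mate = 2L,
               seq = reads$mate2))
  setorder(out, pair, mate)
  out
}

#' Write paired reads as gzipped FASTQ
#'
#' @param reads a `bis_reads` table.
#' @param prefix output prefix; files `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz` are written with uniform Phred+33 qualities.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  for (m in 1:2) {
    s <- DNAStringSet(reads[[paste0("mate", m)]])
    names(s) <- paste0(reads$id, "/", m)
    q <- BStringSet(strrep("I", Biostrings::width(s)))
    writeXStringSet(s, paths[m], format = "fastq", compress = TRUE,
                    qualities = q)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a `bis_reads`-compatible table
#'
#' Origin fields are recovered from read names when they follow the
#' simulator's `sim<i>:<chrom>:<start0>:<strand>` convention.
#'
#' @param path1,path2 FASTQ paths (optionally gzipped).
#' @return data.table with `id`, `mate1`, `mate2` (and origin columns when
#'   parseable).
#' @export
read_fastq_pair <- function(path1, path2) {
  s1 <- readDNAStringSet(path1, format = "fastq")
  s2 <- readDNAStringSet(path2, format = "fastq")
  id <- sub("/[12]$", "", sub(" .*", "", names(s1)))
  out <- data.table(id = id, mate1 = as.character(s1),
                    mate2 = as.character(s2))
  parts <- tstrsplit(id, ":", fixed = TRUE)
  if (length(parts) == 4L && !anyNA(suppressWarnings(as.integer(parts[[3]])))) {
    out[, `:=`(chrom = parts[[2]], start0 = as.integer(parts[[3]]),
               strand = parts[[4]])]
  }
  setattr(out, "class", c("bis_reads", class(out)))
  out
}
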