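#' Build a three-letter converted genome index
#'
#' Produces both conversion modes of the genome used by bisulfite read
#' alignment: a C-to-T converted copy (plus-strand template) and a G-to-A
#' converted copy (minus-strand template), together with the seed length used
#' by the k-mer index. N bases are preserved.
#'
#' @param genome a `DNAStringSet` or `GenomeBundle`.
#' @param k seed k-mer length (default 20). Chromosomes shorter than `k`
#'   are retained but produce no seeds (a warning is logged).
#' @return list of class `converted_index` with `original`, `ct`, `ga`
#'   (character vectors), `chroms`, `lengths`, `k`.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' idx <- build_converted_index(g, k = 2)
#' idx$ct  # "ATGT"
#' idx$ga  # "ACAT"
build_converted_index <- function(genome, k = 20L) {
  genome <- first_genome(genome)
  if (length(genome) == 0) stop("empty genome")
  s <- as.character(genome)
  if (any(nchar(s) < k))
    warning("chromosome(s) shorter than k = ", k, ": indexed without seeds")
  out <- list(original = s,
              ct = chartr("C", "T", s),
              ga = chartr("G", "A", s),
              chroms = names(genome),
              lengths = setNames(nchar(s), names(genome)),
              k = as.integer(k))
  class(out) <- "converted_index"
  out
}

#' Align bisulfite reads to a converted genome
#'
#' Three-letter alignment: each read is converted under both template-strand
#' hypotheses (C-to-T against the C-to-T genome for a plus-strand template,
#' G-to-A against the G-to-A genome for a minus-strand template, with the
#' orientation appropriate to its mate) and placed ungapped end-to-end by a
#' seed-and-extend search. Hits with the minimum mismatch count are retained;
#' a read is discarded when the minimum exceeds `max_mismatch` or when more
#' than `max_hits` equally good placements exist. Among up to `max_hits`
#' ties, one placement is chosen by a seeded uniform draw from the hits
#' sorted by coordinate, and the tie multiplicity is recorded.
#'
#' @param reads a `bis_reads` table, a long table with columns `id`, `pair`,
#'   `mate`, `seq` (see [reads_long()]), or a character vector of sequences
#'   (all treated as mate 1).
#' @param index a [build_converted_index()] result.
#' @param max_mismatch maximum mismatches (default 2).
#' @param max_hits maximum number of equally good hits (default 10).
#' @param seed RNG seed for multi-hit tie-breaking.
#' @return data.table with one row per aligned read: `id`, `pair`, `mate`,
#'   `chrom`, `pos0` (0-based start), `strand` (template strand), `orient`
#'   (0 = read as given, 1 = reverse-complemented), `mismatches`,
#'   `multiplicity`, `seq`. Attribute `"discarded"` tabulates discard
#'   reasons (`no_hit`, `too_many_hits`, `too_short`).
#' @export
align_reads <- function(reads, index, max_mismatch = 2L, max_hits = 10L,
                        seed = 1L) {
  stopifnot(inherits(index, "converted_index"))
  if (is.character(reads))
    reads <- data.table(id = paste0("r", seq_along(reads)),
                        pair = seq_along(reads), mate = 1L, seq = reads)
  else if (inherits(reads, "bis_reads") || all(c("mate1", "mate2") %in%
                                               names(reads)))
    reads <- reads_long(reads)
  stopifnot(all(c("id", "mate", "seq") %in% names(reads)))
  if (!"pair" %in% names(reads)) reads[, pair := rleid(id)]

  # reads shorter than k are discarded; for the rest the seed length is
  # capped at a third of the shortest read so that with <= 2 mismatches at
  # least one of the three partition seeds is exact (pigeonhole), making the
  # seed search exhaustive over all valid placements
  len <- nchar(reads$seq)
  short <- len < index$k
  seqs <- reads$seq
  seqs[short] <- ""
  k_eff <- index$k
  if (any(!short))
    k_eff <- max(4L, min(index$k, as.integer(min(len[!short]) %/% 3L)))
  res <- with_seed(seed,
    cpp_align_reads(index$ct, index$ga, seqs, as.integer(reads$mate),
                    k_eff, as.integer(max_mismatch), as.integer(max_hits)))
  status <- attr(res, "status")
  hits <- as.data.table(res)
  out <- data.table(id = reads$id[hits$read], pair = reads$pair[hits$read],
                    mate = reads$mate[hits$read],
                    chrom = index$chroms[hits$chrom_idx],
                    pos0 = hits$pos0, strand = hits$strand,
                    orient = hits$orient, mismatches = hits$mismatches,
                    multiplicity = hits$multiplicity,
                    seq = reads$seq[hits$read])
  disc <- c(no_hit = sum(status == 1L), too_many_hits = sum(status == 2L),
            too_short = sum(status == 3L))
  setattr(out, "discarded", disc)
  out
}

#' Align a single read
#'
#' @param read a character sequence.
#' @param index a [build_converted_index()] result.
#' @param mate 1 (template-strand read), 2 (complementary mate) or 0
#'   (search all four combinations).
#' @inheritParams align_reads
#' @return a one-row data.table (see [align_reads()]), or `NULL` when the
#'   read is discarded.
#' @export
align_read <- function(read, index, mate = 1L, max_mismatch = 2L,
                       max_hits = 10L, seed = 1L) {
  rl <- data.table(id = "read", pair = 1L, mate = as.integer(mate),
                   seq = read)
  out <- align_reads(rl, index, max_mismatch, max_hits, seed)
  if (nrow(out) == 0) NULL else out
}

#' Per-cytosine pileup of aligned bisulfite reads
#'
#' Recovers the original (unconverted) read sequence in genome orientation
#' and, for each genomic cytosine on the template strand a read aligned to,
#' counts whether it was sequenced as C or as T. Read bases other than C/T at
#' a cytosine (sequencing errors) are ignored. When the two mates of a pair
#' overlap the same positions on the same template strand, mate 1 wins and
#' the overlapping mate-2 bases are not double-counted.
#'
#' @param hits an [align_reads()] result (must carry `seq`).
#' @param genome a `DNAStringSet` or `GenomeBundle`.
#' @param emit_all if `TRUE`, records for uncovered cytosines are included
#'   with zero counts.
#' @return data.table of cytosine records: `chrom`, `pos0`, `strand`,
#'   `context`, `trinuc`, `n_C`, `n_T`.
#' @export
pileup_cytosines <- function(hits, genome, emit_all = FALSE) {
  genome <- first_genome(genome)
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (nrow(hits) > 0) {
    rl <- nchar(hits$seq)
    if (any(hits$pos0 < 0 | hits$pos0 + rl > lens[hits$chrom]))
      stop("alignment beyond chromosome bounds: corrupt input")
  }
  h <- copy(hits)
  setorder(h, pair, mate)
  chrom_idx <- match(h$chrom, names(genome))
  piles <- cpp_pileup(as.character(genome), chrom_idx, h$pos0, h$strand,
                      h$orient, h$seq, h$pair, h$mate)
  cm <- context_map(genome)
  recs <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    p <- piles[[ci]]
    cn <- names(genome)[ci]
    dt <- cm[chrom == cn]
    dt[strand == "+", `:=`(n_C = p$nC_plus[pos0 + 1L],
                           n_T = p$nT_plus[pos0 + 1L])]
    dt[strand == "-", `:=`(n_C = p$nC_minus[pos0 + 1L],
                           n_T = p$nT_minus[pos0 + 1L])]
    recs[[ci]] <- dt
  }
  out <- rbindlist(recs)
  if (!emit_all) out <- out[n_C + n_T > 0]
  setorder(out, chrom, pos0, strand)
  out[]
}

#' Write cytosine records as a CX-style table
#'
#' Tab-separated: chromosome, 1-based position, strand, count methylated
#' (C), count unmethylated (T), context, trinucleotide.
#'
#' @param records a [pileup_cytosines()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cx <- function(records, path) {
  out <- records[, .(chrom, pos = pos0 + 1L, strand, n_C, n_T, context,
                     trinuc)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write per-context methylation BedGraph tracks
#'
#' One BedGraph per context (0-based half-open single-base intervals, value
#' `n_C / (n_C + n_T)`).
#'
#' @param records a [pileup_cytosines()] result.
#' @param prefix output path prefix; files `<prefix>.<context>.bedGraph`.
#' @return paths, invisibly.
#' @export
write_context_bedgraph <- function(records, prefix) {
  paths <- character(0)
  for (ctx in c("CG", "CHG", "CHH")) {
    r <- records[context == ctx & n_C + n_T > 0]
    p <- paste0(prefix, ".", ctx, ".bedGraph")
    fwrite(r[, .(chrom, pos0, end = pos0 + 1L,
                 value = n_C / (n_C + n_T))],
           p, sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
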