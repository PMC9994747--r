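#' Write a genome bundle to standard formats
#'
#' Emits the genome as FASTA, genes and TEs both as BED6+ (0-based half-open,
#' name field `family:class` for TEs) and as GFF3 (1-based closed), and the
#' chromatin tracks as fixed-step BedGraph files.
#'
#' @param bundle a [simulate_genome()] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_genome_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(outdir, "genome.fa"),
             te_bed = file.path(outdir, "tes.bed"),
             gene_bed = file.path(outdir, "genes.bed"),
             gff = file.path(outdir, "annotations.gff3"))
  writeXStringSet(bundle$genome, paths["fasta"])

  te <- bundle$tes
  te_bed <- data.table(chrom = as.character(seqnames(te)),
                       start = start(te) - 1L, end = end(te),
                       name = paste0(mcols(te)$family, ":", mcols(te)$class),
                       score = 0L, strand = as.character(strand(te)),
                       te_id = mcols(te)$te_id,
                       compartment = mcols(te)$compartment,
                       ltr_len = mcols(te)$ltr_len)
  fwrite(te_bed, paths["te_bed"], sep = "\t", col.names = FALSE)
  gn <- bundle$genes
  gene_bed <- data.table(chrom = as.character(seqnames(gn)),
                         start = start(gn) - 1L, end = end(gn),
                         name = mcols(gn)$gene_id, score = 0L,
                         strand = as.character(strand(gn)))
  fwrite(gene_bed, paths["gene_bed"], sep = "\t", col.names = FALSE)

  gff_gr <- c(
    GRanges(seqnames(te), IRanges(start(te), end(te)), strand = strand(te),
            type = "transposable_element", ID = mcols(te)$te_id,
            Name = paste0(mcols(te)$family, ":", mcols(te)$class)),
    GRanges(seqnames(gn), IRanges(start(gn), end(gn)), strand = strand(gn),
            type = "gene", ID = mcols(gn)$gene_id, Name = mcols(gn)$gene_id))
  rtracklayer::export(gff_gr, paths["gff"], format = "gff3")

  for (tr in c("gc", "h3", "h3k9me2")) {
    p <- file.path(outdir, paste0(tr, ".bedGraph"))
    gr <- GRanges(bundle$tracks$chrom,
                  IRanges(bundle$tracks$start + 1L, bundle$tracks$end),
                  score = round(bundle$tracks[[tr]], 4))
    rtracklayer::export(gr, p, format = "bedGraph")
    paths[tr] <- p
  }
  invisible(paths)
}

#' Read TE annotations from a BED6+ file written by [write_genome_bundle()]
#'
#' @param path BED path.
#' @param seqlengths optional named lengths for the resulting `GRanges`.
#' @return a `GRanges` with `te_id`, `family`, `class`, `compartment`,
#'   `ltr_len`.
#' @export
read_te_bed <- function(path, seqlengths = NULL) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "name", "score",
                            "strand", "te_id", "compartment", "ltr_len"))
  fam <- tstrsplit(dt$name, ":", fixed = TRUE)
  GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end), strand = dt$strand,
          te_id = dt$te_id, family = fam[[1]], class = fam[[2]],
          compartment = dt$compartment, ltr_len = dt$ltr_len,
          seqlengths = seqlengths)
}
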