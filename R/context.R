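#' Cytosine sequence-context assignment
#'
#' Every cytosine falls in one of three sequence contexts defined by the two
#' bases downstream on its own strand: CG, CHG or CHH, where H is A, C or T.
#' A cytosine within two bases of the chromosome end, or whose downstream
#' bases include N, has no defined context (`NA`).
#'
#' @param genome a `DNAStringSet` or `GenomeBundle`.
#' @param chrom chromosome name(s), recycled.
#' @param pos 0-based position(s) of a cytosine on `strand`'s sense
#'   (a `C` on the plus strand, a `G` base on the plus strand for minus-strand
#'   queries).
#' @param strand `"+"` or `"-"`, recycled.
#' @return character vector of `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "CGACCGTT"))
#' assign_context(g, "chr1", 0, "+")   # CG
#' assign_context(g, "chr1", 3, "+")   # CHG (H = C)
assign_context <- function(genome, chrom, pos, strand) {
  genome <- first_genome(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- character(n)
  for (cn in unique(chrom)) {
    b <- strsplit(as.character(genome[[cn]]), "", fixed = TRUE)[[1]]
    sel <- chrom == cn
    p <- pos[sel] + 1L  # 1-based
    s <- strand[sel]
    base <- b[p]
    sense <- ifelse(s == "+", base, chartr("ACGTN", "TGCAN", base))
    if (any(sense != "C", na.rm = TRUE) || anyNA(sense))
      stop("assign_context: queried base is not a cytosine on the given strand")
    out[sel] <- context_from_neighbors(b, p, s)
  }
  out
}

# shared kernel: b is the plus-strand base vector, p 1-based positions,
# s strand labels
context_from_neighbors <- function(b, p, s) {
  L <- length(b)
  n1 <- rep(NA_character_, length(p))
  n2 <- rep(NA_character_, length(p))
  plus <- s == "+"
  i1 <- ifelse(plus, p + 1L, p - 1L)
  i2 <- ifelse(plus, p + 2L, p - 2L)
  ok1 <- i1 >= 1L & i1 <= L
  ok2 <- i2 >= 1L & i2 <= L
  n1[ok1] <- b[i1[ok1]]
  n2[ok2] <- b[i2[ok2]]
  # strand-sense bases
  n1[!plus & ok1] <- chartr("ACGTN", "TGCAN", n1[!plus & ok1])
  n2[!plus & ok2] <- chartr("ACGTN", "TGCAN", n2[!plus & ok2])
  ctx <- rep(NA_character_, length(p))
  good <- !is.na(n1) & !is.na(n2) & n1 != "N" & n2 != "N"
  ctx[good & n1 == "G"] <- "CG"
  ctx[good & n1 != "G" & n2 == "G"] <- "CHG"
  ctx[good & n1 != "G" & n2 != "G"] <- "CHH"
  ctx
}

#' Genome-wide cytosine table
#'
#' Enumerates every cytosine of both strands (plus-strand `C` bases and
#' minus-strand cytosines, i.e. plus-strand `G` bases) with its sequence
#' context and strand-sense trinucleotide.
#'
#' @param genome a `DNAStringSet` or `GenomeBundle`.
#' @return data.table with columns `chrom`, `pos0` (0-based, plus-strand
#'   coordinate), `strand`, `context` (`NA` near chromosome ends or Ns) and
#'   `trinuc`.
#' @export
context_map <- function(genome) {
  genome <- first_genome(genome)
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    cn <- names(genome)[ci]
    b <- strsplit(as.character(genome[[ci]]), "", fixed = TRUE)[[1]]
    L <- length(b)
    pc <- which(b == "C")
    pg <- which(b == "G")
    ctx_p <- context_from_neighbors(b, pc, rep("+", length(pc)))
    ctx_m <- context_from_neighbors(b, pg, rep("-", length(pg)))
    tri <- function(p, plus) {
      g1 <- ifelse(plus, p + 1L, p - 1L); g2 <- ifelse(plus, p + 2L, p - 2L)
      b1 <- ifelse(g1 >= 1L & g1 <= L, b[pmax(pmin(g1, L), 1L)], "N")
      b2 <- ifelse(g2 >= 1L & g2 <= L, b[pmax(pmin(g2, L), 1L)], "N")
      if (!plus[1]) { b1 <- chartr("ACGTN", "TGCAN", b1)
                      b2 <- chartr("ACGTN", "TGCAN", b2) }
      paste0("C", b1, b2)
    }
    dt <- rbind(
      data.table(chrom = cn, pos0 = pc - 1L, strand = "+", context = ctx_p,
                 trinuc = if (length(pc)) tri(pc, rep(TRUE, length(pc)))
                          else character(0)),
      data.table(chrom = cn, pos0 = pg - 1L, strand = "-", context = ctx_m,
                 trinuc = if (length(pg)) tri(pg, rep(FALSE, length(pg)))
                          else character(0)))
    setorder(dt, pos0, strand)
    out[[ci]] <- dt
  }
  rbindlist(out)
}
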