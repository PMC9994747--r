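# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# mean Beta draw with given mean and concentration; degenerate means allowed
rbeta_mean <- function(n, mean, concentration) {
  mean <- clamp01(mean)
  a <- mean * concentration
  b <- (1 - mean) * concentration
  out <- numeric(n)
  deg <- a <= 0 | b <= 0
  out[deg] <- mean[if (length(mean) > 1) deg else 1]
  if (any(!deg)) {
    out[!deg] <- rbeta(sum(!deg),
                       if (length(a) > 1) a[!deg] else a,
                       if (length(b) > 1) b[!deg] else b)
  }
  out
}

comp_chr <- function(x) chartr("ACGTN", "TGCAN", x)

# weighted fraction with NA for empty denominators
wfrac <- function(num, den) ifelse(den > 0, num / den, NA_real_)

first_genome <- function(x) {
  if (inherits(x, "GenomeBundle")) x$genome
  else if (inherits(x, "DNAStringSet")) x
  else stop("expected a GenomeBundle or DNAStringSet")
}
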