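#' @importFrom stats rbinom rpois runif setNames rmultinom
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a plain character string
#' @noRd
revcompChr <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), ""))
}

#' All k-mers of a character sequence, with start positions as names
#' @noRd
kmersOf <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

#' Sample random DNA at a given GC fraction
#' @noRd
randDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Run an expression with a private RNG stream, restoring global state after
#' @noRd
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Genetic code, bacterial table 11 (standard codon assignments; the
# difference from table 1 lies in initiation, which is not re-coded here).
codonTable <- function() Biostrings::getGeneticCode("11")

#' Translate a nucleotide string; codons containing N become X
#' @noRd
translateChr <- function(nt) {
  n3 <- (nchar(nt) %/% 3L) * 3L
  if (n3 == 0L) return("")
  codons <- substring(nt, seq(1L, n3, 3L), seq(3L, n3, 3L))
  gc <- codonTable()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
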