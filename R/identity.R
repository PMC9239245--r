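# Fragment-based average nucleotide identity (ANI, Goris-style: 1020-bp
# query fragments, best local placement in the subject, fragments kept at
# >= 30% identity over >= 70% of their length) and reciprocal-best-hit
# average amino-acid identity (AAI), plus all-pairs identity matrices.

# k-mer position index of one strand of a genome (named character vector of
# replicon sequences); returns sorted unique k-mers with position lists
buildSeedIndex <- function(seqs, k) {
  kms <- list(); pos <- list(); repl <- list()
  for (rn in names(seqs)) {
    v <- kmersOf(seqs[[rn]], k)
    kms[[rn]] <- v
    pos[[rn]] <- seq_along(v)
    repl[[rn]] <- rep(rn, length(v))
  }
  allK <- unlist(kms, use.names = FALSE)
  p <- unlist(pos, use.names = FALSE)
  r <- unlist(repl, use.names = FALSE)
  ord <- order(allK, method = "radix")
  allK <- allK[ord]; p <- p[ord]; r <- r[ord]
  starts <- c(1L, which(allK[-1L] != allK[-length(allK)]) + 1L)
  list(uK = allK[starts], starts = starts,
       ends = c(starts[-1L] - 1L, length(allK)), pos = p, repl = r)
}

lookupSeeds <- function(idx, kms) {
  m <- match(kms, idx$uK)
  keep <- which(!is.na(m))
  if (!length(keep))
    return(list(qoff = integer(0), pos = integer(0), repl = character(0)))
  mi <- m[keep]
  cnt <- idx$ends[mi] - idx$starts[mi] + 1L
  ix <- sequence(cnt) - 1L + rep(idx$starts[mi], cnt)
  list(qoff = rep(keep, cnt), pos = idx$pos[ix], repl = idx$repl[ix])
}

# one direction of fragment-based ANI
aniOneWay <- function(qseqs, sseqs, fragmentLen, minId, minCov, k = 15L,
                      band = NULL) {
  band <- band %||% as.integer(0.2 * fragmentLen)
  fwd <- buildSeedIndex(sseqs, k)
  rcs <- lapply(sseqs, revcompChr)
  rev <- buildSeedIndex(rcs, k)
  stride <- max(1L, fragmentLen %/% 60L)
  offs <- seq(1L, fragmentLen - k + 1L, by = stride)

  ids <- numeric(0); used <- 0L; total <- 0L
  for (rn in names(qseqs)) {
    qs <- qseqs[[rn]]
    L <- nchar(qs)
    nFrag <- L %/% fragmentLen
    if (nFrag == 0L) next
    # one global seed lookup for all fragments of this replicon
    fragStart <- (seq_len(nFrag) - 1L) * fragmentLen + 1L
    gpos <- rep(fragStart, each = length(offs)) +
      rep(offs, nFrag) - 1L
    kmsAll <- substring(qs, gpos, gpos + k - 1L)
    fragId <- rep(seq_len(nFrag), each = length(offs))
    localQ <- rep(seq_along(offs), nFrag)
    hF <- lookupSeeds(fwd, kmsAll)
    hR <- lookupSeeds(rev, kmsAll)
    byFragF <- split(seq_along(hF$qoff), fragId[hF$qoff])
    byFragR <- split(seq_along(hR$qoff), fragId[hR$qoff])
    for (fi in seq_len(nFrag)) {
      total <- total + 1L
      fs <- fragStart[fi]
      frag <- substr(qs, fs, fs + fragmentLen - 1L)
      ixF <- byFragF[[as.character(fi)]]
      ixR <- byFragR[[as.character(fi)]]
      hitF <- list(qoff = localQ[hF$qoff[ixF]], pos = hF$pos[ixF],
                   repl = hF$repl[ixF])
      hitR <- list(qoff = localQ[hR$qoff[ixR]], pos = hR$pos[ixR],
                   repl = hR$repl[ixR])
      best <- pickDiagonal(hitF, hitR, offs)
      st <- NULL
      if (!is.null(best)) {
        sseq <- if (best$strand == "+") sseqs[[best$repl]]
                else rcs[[best$repl]]
        # gapless fast path on the exact diagonal
        seg <- substr(sseq, best$diag + 1L, best$diag + fragmentLen)
        h <- if (nchar(seg) == fragmentLen)
          hamShortcut(frag, seg) else NULL
        if (!is.null(h)) {
          st <- list(identity = h$identity, coverage = 1)
        } else {
          ws <- max(1L, best$diag + 1L - band)
          we <- min(nchar(sseq), best$diag + fragmentLen + band)
          win <- substr(sseq, ws, we)
          # local alignment: a fragment straddling a homology boundary
          # contributes the identity of its aligned part; the coverage
          # filter then decides whether it counts
          al <- pwAlign(frag, win, type = "local")
          st <- alnStats(al$p, al$s)
          st$coverage <- sum(al$p != "-") / fragmentLen
        }
      } else if (sum(nchar(unlist(sseqs))) <= 100000L) {
        # no seed chain: full dynamic-programming fallback, affordable on
        # small subjects; on larger genomes a homologous placement passing
        # the 30%/70% filters would have shared a seed k-mer
        bestScore <- -Inf
        for (sn in names(sseqs)) for (ss in list(sseqs[[sn]], rcs[[sn]])) {
          al <- pwAlign(frag, ss, type = "local")
          if (al$score > bestScore) {
            bestScore <- al$score
            st <- alnStats(al$p, al$s)
            st$coverage <- sum(al$p != "-") / fragmentLen
          }
        }
      }
      if (!is.null(st) && st$identity >= minId && st$coverage >= minCov) {
        ids <- c(ids, st$identity)
        used <- used + 1L
      }
    }
  }
  list(mean_identity = if (used) mean(ids) else NA_real_,
       n_used = used, n_total = total)
}

# modal (strand, diagonal) among seed hits; ties resolved toward the
# forward strand and the smaller diagonal
pickDiagonal <- function(hitF, hitR, offs) {
  tab <- list()
  addHits <- function(h, strand) {
    if (!length(h$pos)) return()
    d <- h$pos - offs[h$qoff]
    key <- paste(strand, h$repl, d %/% 30L)
    for (kk in unique(key)) {
      n <- sum(key == kk)
      dm <- min(d[key == kk])
      tab[[kk]] <<- list(n = n, strand = strand,
                         repl = h$repl[key == kk][1L], diag = dm)
    }
  }
  addHits(hitF, "+")
  addHits(hitR, "-")
  if (!length(tab)) return(NULL)
  ns <- vapply(tab, `[[`, 0, "n")
  strs <- vapply(tab, `[[`, "", "strand")
  digs <- vapply(tab, `[[`, 0, "diag")
  ord <- order(-ns, strs != "+", digs)
  tab[[ord[1L]]]
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' The query genome is chopped into non-overlapping \code{fragmentLen}-bp
#' windows (the final partial window is discarded); each fragment is placed
#' at its best seed diagonal in the subject (both strands) and aligned with
#' a banded window (band 0.2 x fragment length; full dynamic programming
#' when no seed is found). Fragments are kept iff identity >= \code{minId}\%
#' over >= \code{minCov} of their length; the one-way ANI is the mean
#' identity of kept fragments, and the reported ANI is the mean of the two
#' directions. Deterministic.
#'
#' @param bundleA,bundleB \linkS4class{GenomeBundle}s.
#' @param fragmentLen fragment length in bp (default 1020).
#' @param minId,minCov fragment filters (published cutoffs 30\% / 0.7).
#' @return \code{ANIResult} list: strainA, strainB, ani_pct,
#'   n_fragments_used, n_fragments_total, aligned_fraction, no_homology.
#' @export
computeAni <- function(bundleA, bundleB, fragmentLen = 1020L, minId = 30,
                       minCov = 0.7) {
  a <- as.character(replicons(bundleA))
  b <- as.character(replicons(bundleB))
  stopifnot(length(a) > 0L, length(b) > 0L)
  ab <- aniOneWay(a, b, fragmentLen, minId, minCov)
  ba <- aniOneWay(b, a, fragmentLen, minId, minCov)
  noHom <- ab$n_used == 0L && ba$n_used == 0L
  ani <- if (noHom) NA_real_ else
    mean(c(ab$mean_identity, ba$mean_identity), na.rm = TRUE)
  structure(list(strainA = strainId(bundleA), strainB = strainId(bundleB),
                 ani_pct = ani,
                 n_fragments_used = ab$n_used + ba$n_used,
                 n_fragments_total = ab$n_total + ba$n_total,
                 aligned_fraction = (ab$n_used + ba$n_used) /
                   max(1L, ab$n_total + ba$n_total),
                 no_homology = noHom, method = "fragment (ANIb-like)"),
            class = "ANIResult")
}

#' Reciprocal-best-hit average amino-acid identity between two genomes
#'
#' Proteins are paired by reciprocal best hit under BLOSUM62 global
#' alignment; pairs passing >= 30\% identity over >= 70\% of the shorter
#' protein contribute their identity to the mean. Deterministic.
#'
#' @param bundleA,bundleB \linkS4class{GenomeBundle}s with CDS features.
#' @param minId,minCov pair filters.
#' @return \code{AAIResult} list: strainA, strainB, aai_pct, n_pairs,
#'   no_homology.
#' @export
computeAai <- function(bundleA, bundleB, minId = 30, minCov = 0.7) {
  pa <- extractCds(bundleA); pb <- extractCds(bundleB)
  if (!nrow(pa) || !nrow(pb)) stopf("computeAai requires CDS features")
  gA <- setNames(pa$aa, pa$locus_tag)
  gB <- setNames(pb$aa, pb$locus_tag)
  gA <- gA[nchar(gA) >= 10L]; gB <- gB[nchar(gB) >= 10L]
  pr <- rbhCore(gA, gB, minIdentity = minId, minCoverage = minCov, k = 5L,
                alphabet = "aa")
  noHom <- nrow(pr) == 0L
  structure(list(strainA = strainId(bundleA), strainB = strainId(bundleB),
                 aai_pct = if (noHom) NA_real_ else mean(pr$identity_pct),
                 n_pairs = nrow(pr), no_homology = noHom),
            class = "AAIResult")
}

#' All-pairs identity matrix
#'
#' @param bundles list of >= 2 \linkS4class{GenomeBundle}s.
#' @param metric "ani" or "aai".
#' @param ... passed to \code{\link{computeAni}} / \code{\link{computeAai}}.
#' @return symmetric numeric matrix with 100 on the diagonal.
#' @export
identityMatrix <- function(bundles, metric = c("ani", "aai"), ...) {
  metric <- match.arg(metric)
  strains <- vapply(bundles, strainId, "")
  n <- length(strains)
  stopifnot(n >= 2L)
  m <- matrix(100, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- if (metric == "ani")
      computeAni(bundles[[i]], bundles[[j]], ...)$ani_pct
    else computeAai(bundles[[i]], bundles[[j]], ...)$aai_pct
    m[i, j] <- v; m[j, i] <- v
  }
  m
}

#' Write an identity matrix as TSV
#' @param m matrix from \code{\link{identityMatrix}}.
#' @param path output file.
#' @export
writeIdentityMatrix <- function(m, path) {
  write.table(cbind(strain = rownames(m), as.data.frame(m)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
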