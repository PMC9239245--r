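# Alignment utilities shared by the ortholog, variant and identity modules:
# affine-gap pairwise alignment (match +2, mismatch -3, gap open 5, extend 2
# for nucleotides; BLOSUM62, 11/1 for proteins), identity defined as
# identical columns / alignment length including internal gap columns and
# excluding terminal overhangs, N never counted as a match, and a
# center-star progressive multiple alignment with left-shifted gaps.

ntScoreMatrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      x <- matrix(-3, 5L, 5L,
                  dimnames = list(c("A", "C", "G", "T", "N"),
                                  c("A", "C", "G", "T", "N")))
      diag(x) <- 2
      x["N", ] <- 0; x[, "N"] <- 0
      m <<- x
    }
    m
  }
})

#' Global affine-gap pairwise alignment
#'
#' @param a,b sequences (character strings).
#' @param type alignment type, "global" or "global-local".
#' @param alphabet "nt" or "aa".
#' @return list with aligned character vectors \code{p}, \code{s} and
#'   \code{score}.
#' @noRd
pwAlign <- function(a, b, type = "global", alphabet = "nt") {
  if (alphabet == "nt") {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = ntScoreMatrix(), gapOpening = 5, gapExtension = 2,
      type = type)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = type)
  }
  list(p = strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
       s = strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]],
       score = Biostrings::score(al),
       substart = BiocGenerics::start(Biostrings::subject(al)))
}

#' Gapless comparison of two equal-length sequences
#'
#' For equal-length sequences whose gapless identity is high (>= 90%), the
#' gapless alignment is score-optimal under the package's scoring (a
#' mismatch at -3 is always cheaper than the compensating gap pair), so the
#' full dynamic program can be skipped. Returns NULL when the shortcut does
#' not apply.
#' @noRd
hamShortcut <- function(a, b, minPct = 90, alphabet = "nt") {
  if (nchar(a) != nchar(b) || nchar(a) == 0L) return(NULL)
  ra <- charToRaw(a); rb <- charToRaw(b)
  mism <- sum(ra != rb)
  n <- length(ra)
  if (100 * (n - mism) / n < minPct) return(NULL)
  if (alphabet == "nt") {
    nN <- sum(ra == charToRaw("N")) + sum(rb == charToRaw("N"))
    list(score = 2 * (n - mism) - 3 * mism,
         identity = 100 * max(0L, n - mism - nN) / n, coverage = 1)
  } else {
    b62 <- blosum62()
    va <- strsplit(a, "", fixed = TRUE)[[1]]
    vb <- strsplit(b, "", fixed = TRUE)[[1]]
    ok <- va %in% rownames(b62) & vb %in% rownames(b62)
    list(score = sum(b62[cbind(va[ok], vb[ok])]),
         identity = 100 * (n - mism) / n, coverage = 1)
  }
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = environment())
      m <<- get("BLOSUM62", envir = environment())
    }
    m
  }
})

#' Elementwise batched pairwise alignment (patterns[i] vs subjects[i])
#' @noRd
pwAlignVec <- function(patterns, subjects, type = "global", alphabet = "nt",
                       scoreOnly = FALSE) {
  if (alphabet == "nt") {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), Biostrings::DNAStringSet(subjects),
      substitutionMatrix = ntScoreMatrix(), gapOpening = 5,
      gapExtension = 2, type = type, scoreOnly = scoreOnly)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns), Biostrings::AAStringSet(subjects),
      substitutionMatrix = "BLOSUM62", gapOpening = 11,
      gapExtension = 1, type = type, scoreOnly = scoreOnly)
  }
  if (scoreOnly) return(al)
  ap <- as.character(Biostrings::alignedPattern(al))
  as_ <- as.character(Biostrings::alignedSubject(al))
  lapply(seq_along(ap), function(i)
    list(p = strsplit(ap[i], "", fixed = TRUE)[[1]],
         s = strsplit(as_[i], "", fixed = TRUE)[[1]],
         score = Biostrings::score(al)[i]))
}

#' Batched pairwise alignment of many patterns against one subject
#' @noRd
pwAlignSet <- function(patterns, subject, type = "global", alphabet = "nt",
                       scoreOnly = FALSE) {
  if (alphabet == "nt") {
    pat <- Biostrings::DNAStringSet(patterns)
    sub <- Biostrings::DNAString(subject)
    al <- Biostrings::pairwiseAlignment(
      pat, sub, substitutionMatrix = ntScoreMatrix(), gapOpening = 5,
      gapExtension = 2, type = type, scoreOnly = scoreOnly)
  } else {
    pat <- Biostrings::AAStringSet(patterns)
    sub <- Biostrings::AAString(subject)
    al <- Biostrings::pairwiseAlignment(
      pat, sub, substitutionMatrix = "BLOSUM62", gapOpening = 11,
      gapExtension = 1, type = type, scoreOnly = scoreOnly)
  }
  if (scoreOnly) return(al)
  ap <- as.character(Biostrings::alignedPattern(al))
  as_ <- as.character(Biostrings::alignedSubject(al))
  lapply(seq_along(ap), function(i)
    list(p = strsplit(ap[i], "", fixed = TRUE)[[1]],
         s = strsplit(as_[i], "", fixed = TRUE)[[1]],
         score = Biostrings::score(al)[i]))
}

#' Identity and coverage statistics of one pairwise alignment
#'
#' Identity: identical columns / alignment length, internal gap columns
#' included, terminal overhangs excluded, N never a match. Coverage:
#' aligned base-base columns over the shorter sequence.
#' @noRd
alnStats <- function(p, s) {
  gap <- p == "-" | s == "-"
  n <- length(p)
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- if (n - lead - trail > 0L) (lead + 1L):(n - trail) else integer(0)
  if (!length(keep)) return(list(identity = 0, coverage = 0, ncol = 0L))
  pk <- p[keep]; sk <- s[keep]
  ident <- sum(pk == sk & pk != "-" & pk != "N")
  basebase <- sum(pk != "-" & sk != "-")
  shorter <- min(sum(p != "-"), sum(s != "-"))
  list(identity = 100 * ident / length(keep),
       coverage = basebase / shorter, ncol = length(keep))
}

# ---- member-vs-center representation with left-shifted gaps --------------

# parse a member-vs-center global alignment into center coordinates:
# at[i] = member char aligned to center position i ('-' = deletion),
# ins[[i+1]] = member bases inserted after center position i (i from 0)
parseVsCenter <- function(al, cen) {
  Lc <- nchar(cen)
  at <- character(Lc)
  ins <- vector("list", Lc + 1L)
  cpos <- 0L
  for (i in seq_along(al$p)) {
    if (al$s[i] != "-") {
      cpos <- cpos + 1L
      at[cpos] <- al$p[i]
    } else {
      ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], al$p[i])
    }
  }
  cc <- strsplit(cen, "", fixed = TRUE)[[1]]
  # left-shift deletion runs while the shift swaps equal, matching bases
  r <- rle(at == "-")
  endsAt <- cumsum(r$lengths)
  for (ri in which(r$values)) {
    b <- endsAt[ri]; a <- b - r$lengths[ri] + 1L
    while (a > 1L && is.null(ins[[a]]) && at[a - 1L] != "-" &&
           at[a - 1L] == cc[a - 1L] && cc[a - 1L] == cc[b]) {
      at[b] <- at[a - 1L]
      at[a - 1L] <- "-"
      a <- a - 1L; b <- b - 1L
    }
  }
  # left-shift insertions while their last base equals the matching base left
  for (p in rev(seq_len(Lc + 1L))) {
    S <- ins[[p]]
    if (is.null(S)) next
    q <- p
    while (q > 1L && at[q - 1L] != "-" && at[q - 1L] == cc[q - 1L] &&
           S[length(S)] == at[q - 1L] && is.null(ins[[q - 1L]])) {
      S <- c(at[q - 1L], S[-length(S)])
      q <- q - 1L
    }
    if (q != p) { ins[[q]] <- S; ins[p] <- list(NULL) }
  }
  list(at = at, ins = ins)
}

#' Progressive (center-star) multiple alignment of a homology group
#'
#' Members are aligned pairwise to the longest member (ties: first) with the
#' package's affine-gap scorer, gap runs are normalized to their leftmost
#' equivalent placement, and the pairwise alignments are merged on center
#' coordinates. Deterministic.
#'
#' @param seqs named character vector of member sequences (>= 1).
#' @param alphabet "nt" or "aa".
#' @return character matrix, one row per member (input order), one aligned
#'   column per matrix column.
#' @export
alignGroup <- function(seqs, alphabet = "nt") {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) {
    m <- matrix(strsplit(seqs[[1L]], "", fixed = TRUE)[[1L]], nrow = 1L)
    rownames(m) <- names(seqs)
    return(m)
  }
  ci <- which.max(nchar(seqs))
  cen <- seqs[[ci]]
  Lc <- nchar(cen)
  others <- setdiff(seq_along(seqs), ci)
  als <- pwAlignSet(unlist(seqs[others]), cen, "global", alphabet)
  parsed <- lapply(als, parseVsCenter, cen = cen)
  insLen <- integer(Lc + 1L)
  for (pr in parsed)
    for (p in seq_len(Lc + 1L))
      if (!is.null(pr$ins[[p]]))
        insLen[p] <- max(insLen[p], length(pr$ins[[p]]))

  width <- Lc + sum(insLen)
  rowFor <- function(at, ins) {
    out <- character(width)
    k <- 0L
    for (p in seq_len(Lc + 1L)) {
      if (insLen[p] > 0L) {
        S <- ins[[p]] %||% character(0)
        out[k + seq_len(insLen[p])] <- c(S, rep("-", insLen[p] - length(S)))
        k <- k + insLen[p]
      }
      if (p <= Lc) {
        out[k + 1L] <- at[p]
        k <- k + 1L
      }
    }
    out
  }
  cc <- strsplit(cen, "", fixed = TRUE)[[1]]
  mat <- matrix("-", nrow = length(seqs), ncol = width,
                dimnames = list(names(seqs), NULL))
  mat[ci, ] <- rowFor(cc, vector("list", Lc + 1L))
  for (j in seq_along(others))
    mat[others[j], ] <- rowFor(parsed[[j]]$at, parsed[[j]]$ins)
  mat
}

#' Identity of a multiple alignment
#'
#' Columns inside any member's terminal overhang are excluded; a column
#' counts as identical when all members carry the same non-gap, non-N base.
#' @param mat character matrix from \code{\link{alignGroup}}.
#' @return percent identity in [0, 100].
#' @export
msaIdentity <- function(mat) {
  if (ncol(mat) == 0L) return(NA_real_)
  ov <- overhangMask(mat)
  keep <- !apply(ov, 2L, any)
  if (!any(keep)) return(NA_real_)
  sub <- mat[, keep, drop = FALSE]
  same <- apply(sub, 2L, function(col)
    all(col == col[1L]) && col[1L] != "-" && col[1L] != "N")
  100 * sum(same) / ncol(sub)
}

#' Multiple alignment of a homology group, with gapless fast path
#'
#' When all members have equal length and are highly similar, the gapless
#' stack is the optimal alignment and is returned directly; otherwise the
#' center-star progressive alignment is used.
#' @inheritParams alignGroup
#' @return character matrix as for \code{\link{alignGroup}}.
#' @export
groupMsa <- function(seqs, alphabet = "nt") {
  n1 <- nchar(seqs[[1L]])
  if (length(seqs) >= 2L && all(nchar(seqs) == n1)) {
    ok <- TRUE
    for (i in seq_along(seqs)[-1L]) {
      if (is.null(hamShortcut(seqs[[1L]], seqs[[i]]))) { ok <- FALSE; break }
    }
    if (ok) {
      m <- do.call(rbind, strsplit(unname(unlist(seqs)), "", fixed = TRUE))
      rownames(m) <- names(seqs)
      return(m)
    }
  }
  alignGroup(seqs, alphabet)
}

# TRUE where a cell lies in a row's leading or trailing gap run
overhangMask <- function(mat) {
  out <- matrix(FALSE, nrow(mat), ncol(mat))
  for (r in seq_len(nrow(mat))) {
    v <- mat[r, ] == "-"
    if (v[1L]) out[r, seq_len(rle(v)$lengths[1L])] <- TRUE
    n <- length(v)
    if (v[n]) {
      rl <- rle(rev(v))$lengths[1L]
      out[r, (n - rl + 1L):n] <- TRUE
    }
  }
  out
}
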