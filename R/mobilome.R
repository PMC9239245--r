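# Mobile-element detection: integrated prophages anchored at tRNA genes via
# exact duplication of the tRNA's 3'-terminal bases (attL/attR), HIP1
# octamer scan, inversion detection from unique k-mer anchors, plasmid
# homology blocks with duplicated-flank (fusion) structure, and CRISPR
# repeat-spacer arrays.

#' Find tRNA-anchored prophages by exact terminal duplication
#'
#' For each tRNA the maximal exact duplication of its 3'-terminal k bases
#' (k scanned from \code{maxAtt} down to \code{minAtt}) is sought on the
#' same strand within \code{window} bp downstream of the tRNA's 3' end. A
#' call is emitted for the largest k whose second copy yields an element of
#' at least \code{minSpan} bp (nearest qualifying copy when several). The
#' element span runs from the first base after attL through the last base
#' of attR; cargo genes inside the span are listed. Calls are sorted by
#' coordinate; deterministic.
#'
#' @param bundle a \linkS4class{GenomeBundle} with tRNA annotations.
#' @param minAtt,maxAtt duplication length bounds (bp).
#' @param window downstream search window (bp).
#' @param minSpan minimum element length (bp).
#' @return data.frame of prophage calls (possibly empty), with columns
#'   replicon, anchor_trna_locus, attL_start/attL_end, attR_start/attR_end,
#'   duplication_len, elem_start/elem_end, elem_len, cargo_locus_tags
#'   (comma-joined).
#' @export
findAttProphages <- function(bundle, minAtt = 15L, maxAtt = 200L,
                             window = 150000L, minSpan = 5000L) {
  ft <- features(bundle)
  trna <- ft[ft$kind == "tRNA"]
  out <- emptyProphageTable()
  if (!length(trna)) {
    warning("no tRNA features; prophage scan skipped")
    return(out)
  }
  reps <- as.character(replicons(bundle))
  for (i in seq_along(trna)) {
    tr <- trna[i]
    rn <- as.character(GenomeInfoDb::seqnames(tr))
    seqF <- reps[[rn]]
    plus <- as.character(BiocGenerics::strand(tr)) == "+"
    # work in gene orientation: for minus-strand tRNAs scan the reverse
    # complement and map coordinates back
    L <- nchar(seqF)
    if (plus) {
      s <- BiocGenerics::start(tr); e <- BiocGenerics::end(tr)
      g <- seqF
    } else {
      s <- L - BiocGenerics::end(tr) + 1L
      e <- L - BiocGenerics::start(tr) + 1L
      g <- revcompChr(seqF)
    }
    tlen <- e - s + 1L
    kMax <- min(maxAtt, tlen)
    if (kMax < minAtt) next
    suffix <- substr(g, e - minAtt + 1L, e)
    winEnd <- min(L, e + window)
    win <- substr(g, e + 1L, winEnd)
    hits <- gregexpr(suffix, win, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    # extend each hit leftward to the maximal duplication length
    dup <- integer(length(hits))
    for (h in seq_along(hits)) {
      kk <- minAtt
      copyEnd <- e + hits[h] + minAtt - 1L     # matches the tRNA 3' end
      while (kk < kMax) {
        gpos <- copyEnd - kk                   # one base left of the copy
        tpos <- e - kk
        if (gpos <= e) break                   # ran into the tRNA itself
        if (substr(g, gpos, gpos) != substr(g, tpos, tpos)) break
        kk <- kk + 1L
      }
      dup[h] <- kk
    }
    attREnd <- e + hits + minAtt - 1L          # end of copy in gene frame
    elemLen <- attREnd - e
    okSpan <- elemLen >= minSpan & dup >= minAtt
    if (!any(okSpan)) next
    cand <- which(okSpan)
    cand <- cand[order(-dup[cand], elemLen[cand])]
    h <- cand[1L]
    k <- dup[h]
    gAttL <- c(e - k + 1L, e)
    gAttR <- c(attREnd[h] - k + 1L, attREnd[h])
    gElem <- c(e + 1L, attREnd[h])
    back <- function(iv) if (plus) iv else sort(L - iv + 1L)
    attL <- back(gAttL); attR <- back(gAttR); elem <- back(gElem)
    inside <- ft[as.character(GenomeInfoDb::seqnames(ft)) == rn &
                   BiocGenerics::start(ft) >= elem[1L] &
                   BiocGenerics::end(ft) <= elem[2L]]
    out <- rbind(out, data.frame(
      replicon = rn, anchor_trna_locus = tr$locus_tag,
      attL_start = attL[1L], attL_end = attL[2L],
      attR_start = attR[1L], attR_end = attR[2L],
      duplication_len = k, elem_start = elem[1L], elem_end = elem[2L],
      elem_len = elem[2L] - elem[1L] + 1L,
      cargo_locus_tags = paste(inside$locus_tag, collapse = ","),
      stringsAsFactors = FALSE))
  }
  out[order(out$replicon, out$elem_start), , drop = FALSE]
}

emptyProphageTable <- function() {
  data.frame(replicon = character(0), anchor_trna_locus = character(0),
             attL_start = integer(0), attL_end = integer(0),
             attR_start = integer(0), attR_end = integer(0),
             duplication_len = integer(0), elem_start = integer(0),
             elem_end = integer(0), elem_len = integer(0),
             cargo_locus_tags = character(0), stringsAsFactors = FALSE)
}

#' Scan HIP1 octamers (GCGATCGC)
#'
#' The motif is its own reverse complement, so a single-strand scan covers
#' both strands; overlapping occurrences are counted.
#'
#' @param bundle a \linkS4class{GenomeBundle}.
#' @return list: \code{sites} (data.frame replicon, pos of each occurrence
#'   start) and \code{density} (data.frame replicon, length_bp, n_sites,
#'   per_kb).
#' @export
scanHip1 <- function(bundle) {
  reps <- as.character(replicons(bundle))
  sites <- list(); dens <- list()
  for (rn in names(reps)) {
    m <- Biostrings::matchPattern(HIP1, Biostrings::DNAString(reps[[rn]]))
    p <- BiocGenerics::start(m)
    if (length(p))
      sites[[rn]] <- data.frame(replicon = rn, pos = p,
                                stringsAsFactors = FALSE)
    dens[[rn]] <- data.frame(replicon = rn, length_bp = nchar(reps[[rn]]),
                             n_sites = length(p),
                             per_kb = 1000 * length(p) / nchar(reps[[rn]]),
                             stringsAsFactors = FALSE)
  }
  list(sites = if (length(sites)) do.call(rbind, c(sites,
         list(make.row.names = FALSE)))
       else data.frame(replicon = character(0), pos = integer(0)),
       density = do.call(rbind, c(dens, list(make.row.names = FALSE))))
}

# unique shared k-mer anchors between two sequences, both orientations
kmerAnchors <- function(sa, sb, k) {
  ka <- kmersOf(sa, k)
  kb <- kmersOf(sb, k)
  kbr <- kmersOf(revcompChr(sb), k)
  Lb <- nchar(sb)
  uniqA <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  allB <- c(kb, kbr)
  dupB <- duplicated(allB) | duplicated(allB, fromLast = TRUE)
  uniqBf <- !dupB[seq_along(kb)]
  uniqBr <- !dupB[length(kb) + seq_along(kbr)]
  mF <- match(ka, ifelse(uniqBf, kb, NA_character_))
  mR <- match(ka, ifelse(uniqBr, kbr, NA_character_))
  useF <- uniqA & !is.na(mF)
  useR <- uniqA & !is.na(mR) & !useF
  rbind(
    data.frame(posA = which(useF), posB = mF[useF],
               orient = rep("+", sum(useF)), stringsAsFactors = FALSE),
    data.frame(posA = which(useR),
               posB = Lb - (mR[useR] + k - 1L) + 1L,
               orient = rep("-", sum(useR)), stringsAsFactors = FALSE))
}

# chain anchors (sorted by posA) into collinear blocks
chainAnchors <- function(an, k, maxJump = 5000L, minAnchors = 5L) {
  if (!nrow(an)) return(NULL)
  an <- an[order(an$posA), , drop = FALSE]
  n <- nrow(an)
  if (n == 1L) {
    brk <- logical(0)
  } else {
    dA <- diff(an$posA)
    dB <- diff(an$posB)
    okDir <- ifelse(an$orient[-1L] == "+", dB > 0L, dB < 0L)
    brk <- an$orient[-1L] != an$orient[-n] | !okDir | dA > maxJump |
      abs(abs(dB) - dA) > 200L
  }
  id <- cumsum(c(1L, as.integer(brk)))
  sp <- split(seq_len(n), id)
  blocks <- lapply(sp, function(ix) {
    if (length(ix) < minAnchors) return(NULL)
    data.frame(startA = an$posA[ix[1L]],
               endA = an$posA[ix[length(ix)]] + k - 1L,
               startB = min(an$posB[ix]), endB = max(an$posB[ix]) + k - 1L,
               orient = an$orient[ix[1L]], n_anchors = length(ix),
               stringsAsFactors = FALSE)
  })
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (!length(blocks)) return(NULL)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Detect inversions between two genomes from unique k-mer anchors
#'
#' k-mers unique in both genomes become anchors; anchors are chained into
#' maximal collinear blocks; blocks whose orientation is opposite to the
#' majority (the flanking context) are reported as inversions. Boundary
#' uncertainty is the gap between adjacent anchors; \code{boundary_hip1} is
#' TRUE iff a HIP1 octamer lies within the uncertainty interval at both
#' ends.
#'
#' @param bundleA,bundleB \linkS4class{GenomeBundle}s.
#' @param k anchor k-mer size (default 21).
#' @param minLen minimum inversion length reported (bp).
#' @return data.frame of inversion blocks (possibly empty): replicon_A,
#'   replicon_B, startA, endA, startB, endB, length, boundary_hip1, plus
#'   uncertainty bounds uncLeft/uncRight in A coordinates.
#' @export
detectInversions <- function(bundleA, bundleB, k = 21L, minLen = 1000L) {
  repsA <- as.character(replicons(bundleA))
  repsB <- as.character(replicons(bundleB))
  out <- data.frame(replicon_A = character(0), replicon_B = character(0),
                    startA = integer(0), endA = integer(0),
                    startB = integer(0), endB = integer(0),
                    length = integer(0), boundary_hip1 = logical(0),
                    uncLeft_start = integer(0), uncLeft_end = integer(0),
                    uncRight_start = integer(0), uncRight_end = integer(0),
                    stringsAsFactors = FALSE)
  for (ra in names(repsA)) {
    # pair with the B replicon sharing the most unique k-mer anchors
    anchorSets <- lapply(names(repsB), function(rb)
      kmerAnchors(repsA[[ra]], repsB[[rb]], k))
    nh <- vapply(anchorSets, nrow, 0L)
    if (!length(nh) || max(nh) == 0L) next
    rb <- names(repsB)[which.max(nh)]
    an <- anchorSets[[which.max(nh)]]
    bl <- chainAnchors(an, k)
    if (is.null(bl)) next
    majority <- with(bl, {
      w <- endA - startA
      if (sum(w[orient == "+"]) >= sum(w[orient == "-"])) "+" else "-"
    })
    inv <- bl[bl$orient != majority &
                (bl$endA - bl$startA + 1L) >= minLen, , drop = FALSE]
    if (!nrow(inv)) next
    hip <- scanHip1Seq(repsA[[ra]])
    for (i in seq_len(nrow(inv))) {
      bi <- inv[i, ]
      prevEnd <- bl$endA[bl$endA < bi$startA]
      nextStart <- bl$startA[bl$startA > bi$endA]
      uncL <- c(if (length(prevEnd)) max(prevEnd) + 1L else 1L,
                bi$startA)
      uncR <- c(bi$endA,
                if (length(nextStart)) min(nextStart) - 1L
                else nchar(repsA[[ra]]))
      hipL <- any(hip >= uncL[1L] - 8L & hip <= uncL[2L])
      hipR <- any(hip >= uncR[1L] - 8L & hip <= uncR[2L])
      out <- rbind(out, data.frame(
        replicon_A = ra, replicon_B = rb, startA = bi$startA,
        endA = bi$endA, startB = bi$startB, endB = bi$endB,
        length = bi$endA - bi$startA + 1L,
        boundary_hip1 = hipL && hipR,
        uncLeft_start = uncL[1L], uncLeft_end = uncL[2L],
        uncRight_start = uncR[1L], uncRight_end = uncR[2L],
        stringsAsFactors = FALSE))
    }
  }
  out
}

scanHip1Seq <- function(s) {
  m <- gregexpr(HIP1, s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Compare two plasmids: homology blocks and duplicated-flank structure
#'
#' Shared blocks are unique-k-mer anchor chains; their total length (in A
#' coordinates) estimates the shared backbone. Gene pairs in B that are
#' reciprocal-best-hit homologs of a single adjacent pair in A and occur
#' twice in B are flagged as duplicated flanks; the inter-flank segment is
#' reported as the candidate expanded (fusion) region.
#'
#' @param bundleA,bundleB single-replicon \linkS4class{GenomeBundle}s.
#' @param k anchor k-mer size.
#' @return list: \code{blocks} (homology block table),
#'   \code{shared_length} (bp in A), \code{dup_flanks} (data.frame of
#'   duplicated flank pairs, possibly empty) and \code{expanded_region}
#'   (B-coordinate span between the flank copies, or NULL).
#' @export
comparePlasmids <- function(bundleA, bundleB, k = 21L) {
  sa <- as.character(replicons(bundleA))[[1L]]
  sb <- as.character(replicons(bundleB))[[1L]]
  an <- kmerAnchors(sa, sb, k)
  bl <- chainAnchors(an, k, minAnchors = 3L)
  shared <- 0L
  if (!is.null(bl)) {
    iv <- IRanges::reduce(IRanges::IRanges(bl$startA, bl$endA))
    shared <- sum(IRanges::width(iv))
  }

  # duplicated flank detection through gene homology
  gA <- orthoGenes(bundleA)
  gB <- orthoGenes(bundleB)
  ftA <- features(bundleA); ftB <- features(bundleB)
  dup <- data.frame(gene_A = character(0), copies_B = character(0),
                    stringsAsFactors = FALSE)
  expanded <- NULL
  if (length(gA) && length(gB)) {
    # best A hit for every B gene (many B genes may hit the same A gene)
    cand <- kmerCandidates(gB, gA, k = 12L, top = 3L)
    bestA <- rep(NA_integer_, length(gB))
    for (j in seq_along(gB)) {
      if (!length(cand[[j]])) next
      sc <- vapply(cand[[j]], function(a) {
        h <- hamShortcut(gB[[j]], gA[[a]])
        if (!is.null(h)) h$score else
          pwAlignVec(gB[[j]], gA[[a]], scoreOnly = TRUE)
      }, 0)
      best <- cand[[j]][which.max(sc)]
      st <- hamShortcut(gB[[j]], gA[[best]])
      if (is.null(st)) {
        al <- pwAlign(gB[[j]], gA[[best]])
        st <- alnStats(al$p, al$s)
      }
      if (st$identity >= 70) bestA[j] <- best
    }
    hitsPerA <- table(bestA)
    dupA <- as.integer(names(hitsPerA)[hitsPerA >= 2L])
    if (length(dupA) >= 2L) {
      ordA <- order(BiocGenerics::start(ftA))
      posInA <- match(dupA, ordA)
      # adjacent duplicated pair in A
      ordPos <- sort(match(dupA, ordA))
      adj <- which(diff(ordPos) == 1L)
      if (length(adj)) {
        aPair <- ordA[c(ordPos[adj[1L]], ordPos[adj[1L]] + 1L)]
        copies <- lapply(aPair, function(a) which(bestA == a))
        dup <- data.frame(
          gene_A = ftA$locus_tag[aPair],
          copies_B = vapply(copies, function(ix)
            paste(ftB$locus_tag[ix], collapse = ","), ""),
          stringsAsFactors = FALSE)
        # inter-flank segment in B: between the two copies of the pair
        bIdx <- sort(unique(unlist(copies)))
        if (length(bIdx) >= 4L) {
          st <- sort(BiocGenerics::start(ftB)[bIdx])
          en <- sort(BiocGenerics::end(ftB)[bIdx])
          expanded <- c(en[2L] + 1L, st[3L] - 1L)
        }
      }
    }
  }
  list(blocks = bl, shared_length = shared, dup_flanks = dup,
       expanded_region = expanded)
}

#' Find CRISPR repeat-spacer arrays by exact repeat periodicity
#'
#' Candidate repeats are k-mers occurring at least \code{minRepeats} times
#' with plausible spacing; each candidate is extended to the maximal
#' identical repeat shared by all copies, then validated: 21-50 bp repeat,
#' spacer lengths within [0.6, 2.5] x repeat length, spacers mutually
#' distinct.
#'
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param minRepeats minimum repeat copies (default 3).
#' @param k seed k-mer size.
#' @return list of array calls, each a list(replicon, start, end,
#'   repeat_seq, n_repeats, spacers).
#' @export
findCrisprArrays <- function(bundle, minRepeats = 3L, k = 21L) {
  out <- list()
  reps <- as.character(replicons(bundle))
  for (rn in names(reps)) {
    s <- reps[[rn]]
    v <- kmersOf(s, k)
    ord <- order(v, method = "radix")
    sv <- v[ord]
    starts <- c(1L, which(sv[-1L] != sv[-length(sv)]) + 1L)
    ends <- c(starts[-1L] - 1L, length(sv))
    cnt <- ends - starts + 1L
    claimed <- integer(0)
    for (ci in order(vapply(which(cnt >= minRepeats),
                            function(i) min(ord[starts[i]:ends[i]]), 0L))) {
      i <- which(cnt >= minRepeats)[ci]
      pos <- sort(ord[starts[i]:ends[i]])
      if (length(claimed) && any(pos %in% claimed)) next
      gaps <- diff(pos)
      if (any(gaps < 33L) || any(gaps > 180L)) next
      # maximal identical extension across all copies
      left <- 0L
      while (all(pos - left - 1L >= 1L) &&
             length(unique(substring(s, pos - left - 1L,
                                     pos - left - 1L))) == 1L &&
             left + k < min(gaps))
        left <- left + 1L
      right <- 0L
      while (all(pos + k + right <= nchar(s)) &&
             length(unique(substring(s, pos + k + right,
                                     pos + k + right))) == 1L &&
             k + right < min(gaps))
        right <- right + 1L
      rs <- pos - left
      rlen <- k + left + right
      if (rlen < 21L || rlen > 50L) next
      rpt <- substr(s, rs[1L], rs[1L] + rlen - 1L)
      spac <- substring(s, rs[-length(rs)] + rlen, rs[-1L] - 1L)
      slen <- nchar(spac)
      if (any(slen < 0.6 * rlen) || any(slen > 2.5 * rlen)) next
      if (anyDuplicated(spac)) next
      claimed <- c(claimed,
                   unlist(lapply(rs, function(p) p:(p + rlen - 1L))))
      out[[length(out) + 1L]] <- list(
        replicon = rn, start = rs[1L], end = rs[length(rs)] + rlen - 1L,
        repeat_seq = rpt, n_repeats = length(rs), spacers = spac)
    }
  }
  out
}

#' Write mobilome calls as TSV and BED, spacers as FASTA
#'
#' BED uses 0-based half-open coordinates per the BED standard.
#'
#' @param prophages prophage table from \code{\link{findAttProphages}}.
#' @param inversions inversion table from \code{\link{detectInversions}}.
#' @param crisprs array list from \code{\link{findCrisprArrays}}.
#' @param outDir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
writeMobilome <- function(prophages, inversions, crisprs, outDir,
                          prefix = "mobilome") {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  tsv <- file.path(outDir, paste0(prefix, "_prophages.tsv"))
  write.table(prophages, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  itsv <- file.path(outDir, paste0(prefix, "_inversions.tsv"))
  write.table(inversions, itsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  bed <- file.path(outDir, paste0(prefix, ".bed"))
  bedLines <- c(
    if (nrow(prophages))
      sprintf("%s\t%d\t%d\tprophage_%s", prophages$replicon,
              prophages$elem_start - 1L, prophages$elem_end,
              prophages$anchor_trna_locus),
    if (nrow(inversions))
      sprintf("%s\t%d\t%d\tinversion", inversions$replicon_A,
              inversions$startA - 1L, inversions$endA),
    vapply(crisprs, function(cr)
      sprintf("%s\t%d\t%d\tcrispr_array", cr$replicon, cr$start - 1L,
              cr$end), ""))
  writeLines(bedLines, bed)
  fa <- file.path(outDir, paste0(prefix, "_spacers.fasta"))
  con <- file(fa, "w")
  for (ai in seq_along(crisprs)) {
    cr <- crisprs[[ai]]
    for (si in seq_along(cr$spacers))
      writeLines(c(sprintf(">array%d_spacer%d %s:%d-%d", ai, si,
                           cr$replicon, cr$start, cr$end),
                   cr$spacers[si]), con)
  }
  close(con)
  invisible(c(tsv, itsv, bed, fa))
}
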