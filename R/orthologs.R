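# Pangenome construction: reciprocal-best-hit ortholog pairs on nucleotide
# gene sequences, single-linkage closure with strain-conflict splitting,
# core/accessory/unique classification, per-group nucleotide and amino-acid
# identity of the group alignments.

orthoKinds <- c("CDS", "tRNA", "ncRNA", "pseudogene")

# gene sequences eligible for orthology, as a named character vector
orthoGenes <- function(bundle) {
  ft <- features(bundle)
  ft <- ft[ft$kind %in% orthoKinds]
  geneSeqs(bundle, ft)
}

# k-mer candidate hits: for each query gene, subject genes sharing k-mers
kmerCandidates <- function(qry, sbj, k = 12L, top = 5L) {
  sk <- lapply(sbj, function(s) unique(kmersOf(s, k)))
  allK <- unlist(sk, use.names = FALSE)
  gene <- rep.int(seq_along(sk), lengths(sk))
  ord <- order(allK, method = "radix")
  allK <- allK[ord]; gene <- gene[ord]
  starts <- c(1L, which(allK[-1L] != allK[-length(allK)]) + 1L)
  uK <- allK[starts]
  ends <- c(starts[-1L] - 1L, length(allK))
  lapply(qry, function(s) {
    kms <- unique(kmersOf(s, k))
    m <- match(kms, uK)
    m <- m[!is.na(m)]
    if (!length(m)) return(integer(0))
    hits <- unlist(lapply(m, function(i) gene[starts[i]:ends[i]]),
                   use.names = FALSE)
    tb <- sort(table(hits), decreasing = TRUE)
    keep <- tb[tb >= 0.6 * tb[1L]]
    as.integer(names(utils::head(keep, top)))
  })
}

#' Reciprocal-best-hit ortholog pairs between two strains
#'
#' Gene-vs-gene scoring uses global affine-gap nucleotide alignment
#' (match +2, mismatch -3, gap open 5, extend 2); a k-mer prefilter
#' restricts the pairs aligned without changing best hits at the
#' divergences of interest. A pair is reported iff each gene is the other's
#' highest-scoring hit (ties broken towards the lexicographically smaller
#' locus tag) with identity >= \code{minIdentity} over >= \code{minCoverage}
#' of the shorter gene.
#'
#' @param bundleA,bundleB \linkS4class{GenomeBundle}s.
#' @param minIdentity minimum percent identity (default 70).
#' @param minCoverage minimum aligned fraction of the shorter gene (0.5).
#' @param k prefilter k-mer size.
#' @return data.frame: locus_tag_A, locus_tag_B, score, identity_pct.
#' @export
rbhPairs <- function(bundleA, bundleB, minIdentity = 70, minCoverage = 0.5,
                     k = 12L) {
  rbhCore(orthoGenes(bundleA), orthoGenes(bundleB), minIdentity,
          minCoverage, k, alphabet = "nt")
}

# generic RBH over named sequence vectors (nucleotide genes or proteins)
rbhCore <- function(gA, gB, minIdentity = 70, minCoverage = 0.5, k = 12L,
                    alphabet = "nt") {
  empty <- data.frame(locus_tag_A = character(0), locus_tag_B = character(0),
                      score = numeric(0), identity_pct = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(gA) || !length(gB)) return(empty)

  candAB <- kmerCandidates(gA, gB, k)
  candBA <- kmerCandidates(gB, gA, k)
  pairs <- unique(rbind(
    do.call(rbind, lapply(seq_along(gA), function(i)
      if (length(candAB[[i]])) data.frame(a = i, b = candAB[[i]]))),
    do.call(rbind, lapply(seq_along(gB), function(j)
      if (length(candBA[[j]])) data.frame(a = candBA[[j]], b = j)))))
  if (is.null(pairs) || !nrow(pairs)) return(empty)

  # scores for all candidate pairs: gapless shortcut where optimal,
  # one batched elementwise alignment call for the rest
  pairs$score <- NA_real_
  pairs$identity <- NA_real_
  pairs$coverage <- NA_real_
  slow <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    h <- hamShortcut(gA[[pairs$a[r]]], gB[[pairs$b[r]]],
                     alphabet = alphabet)
    if (is.null(h)) slow <- c(slow, r)
    else {
      pairs$score[r] <- h$score
      pairs$identity[r] <- h$identity
      pairs$coverage[r] <- h$coverage
    }
  }
  if (length(slow))
    pairs$score[slow] <- pwAlignVec(unlist(gA[pairs$a[slow]]),
                                    unlist(gB[pairs$b[slow]]),
                                    scoreOnly = TRUE, alphabet = alphabet)

  bestOf <- function(df, byCol, tagVec) {
    # index of best-scoring row per gene, ties to smaller partner tag
    sel <- tapply(seq_len(nrow(df)), df[[byCol]], function(ix) {
      s <- df$score[ix]
      cand <- ix[s == max(s)]
      if (length(cand) > 1L)
        cand <- cand[order(tagVec[cand])][1L]
      cand
    })
    unlist(sel)
  }
  tagsA <- names(gA); tagsB <- names(gB)
  bestA <- bestOf(pairs, "a", tagsB[pairs$b])  # per A gene
  bestB <- bestOf(pairs, "b", tagsA[pairs$a])  # per B gene
  rbh <- intersect(bestA, bestB)
  out <- pairs[rbh, , drop = FALSE]
  need <- which(is.na(out$identity))
  if (length(need)) {
    als <- pwAlignVec(unlist(gA[out$a[need]]), unlist(gB[out$b[need]]),
                      alphabet = alphabet)
    for (q in seq_along(need)) {
      st <- alnStats(als[[q]]$p, als[[q]]$s)
      out$identity[need[q]] <- st$identity
      out$coverage[need[q]] <- st$coverage
    }
  }
  out <- out[out$identity >= minIdentity & out$coverage >= minCoverage, ,
             drop = FALSE]
  out <- out[order(tagsA[out$a]), , drop = FALSE]
  data.frame(locus_tag_A = tagsA[out$a], locus_tag_B = tagsB[out$b],
             score = out$score, identity_pct = out$identity,
             stringsAsFactors = FALSE)
}

#' Build the pangenome from all pairwise RBH edges
#'
#' Groups are the single-linkage closure over all pairwise reciprocal-best-
#' hit edges, built greedily by decreasing edge score under the constraint
#' of at most one member per strain (a conflicting merge is skipped, so the
#' conflicting gene re-seeds its own group). Every gene is assigned to
#' exactly one group. Deterministic given the inputs.
#'
#' @param bundles list of >= 1 \linkS4class{GenomeBundle}s.
#' @param minIdentity,minCoverage RBH thresholds, see \code{\link{rbhPairs}}.
#' @param computeIdentities compute per-group alignment identities
#'   (nucleotide for all groups, amino acid for all-CDS groups).
#' @return a \linkS4class{Pangenome}.
#' @export
buildPangenome <- function(bundles, minIdentity = 70, minCoverage = 0.5,
                           computeIdentities = TRUE) {
  strains <- vapply(bundles, strainId, "")
  stopifnot(!anyDuplicated(strains))
  names(bundles) <- strains

  genes <- lapply(bundles, orthoGenes)
  kindOf <- lapply(bundles, function(b) {
    ft <- features(b)
    setNames(ft$kind, ft$locus_tag)
  })

  # vertices: strain-qualified gene ids
  vid <- function(s, tag) paste0(s, "|", tag)
  allV <- unlist(lapply(strains, function(s) vid(s, names(genes[[s]]))),
                 use.names = FALSE)

  edges <- list()
  if (length(strains) >= 2L)
    for (i in seq_len(length(strains) - 1L))
      for (j in (i + 1L):length(strains)) {
        pr <- rbhPairs(bundles[[i]], bundles[[j]], minIdentity, minCoverage)
        if (nrow(pr))
          edges[[length(edges) + 1L]] <- data.frame(
            va = vid(strains[i], pr$locus_tag_A),
            vb = vid(strains[j], pr$locus_tag_B),
            score = pr$score, stringsAsFactors = FALSE)
      }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(va = character(0), vb = character(0), score = numeric(0))
  edges <- edges[order(-edges$score, edges$va, edges$vb), , drop = FALSE]

  # constrained union-find
  parent <- seq_along(allV)
  names(parent) <- allV
  strainOf <- sub("\\|.*$", "", allV)
  members <- lapply(seq_along(allV), function(i) i)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(edges))) {
    ia <- find(match(edges$va[r], allV))
    ib <- find(match(edges$vb[r], allV))
    if (ia == ib) next
    if (length(intersect(strainOf[members[[ia]]],
                         strainOf[members[[ib]]]))) next
    parent[ib] <- ia
    members[[ia]] <- c(members[[ia]], members[[ib]])
    members[[ib]] <- integer(0)
  }
  roots <- vapply(seq_along(allV), find, 1L)
  comps <- split(seq_along(allV), roots)

  # deterministic group order: by (strain index, locus tag) of the first member
  repKey <- vapply(comps, function(ix) {
    s <- strainOf[ix]
    o <- order(match(s, strains), allV[ix])
    sprintf("%02d|%s", match(s[o[1L]], strains), allV[ix[o[1L]]])
  }, "")
  comps <- comps[order(repKey)]

  nS <- length(strains)
  grows <- lapply(seq_along(comps), function(g) {
    ix <- comps[[g]]
    s <- strainOf[ix]
    tag <- sub("^[^|]*\\|", "", allV[ix])
    row <- as.list(setNames(rep(NA_character_, nS), strains))
    row[s] <- tag
    kinds <- mapply(function(ss, tt) kindOf[[ss]][[tt]], s, tag)
    m <- length(ix)
    c(list(group_id = sprintf("OG%04d", g)), row,
      list(kind = names(sort(table(kinds), decreasing = TRUE))[1L],
           classification = if (m == nS) "core" else if (m == 1L) "unique"
                            else "accessory",
           n_members = m))
  })
  groups <- do.call(rbind, lapply(grows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  groups$nt_identity_pct <- NA_real_
  groups$aa_identity_pct <- NA_real_
  if (computeIdentities && nrow(groups)) {
    prot <- lapply(bundles, function(b) {
      cds <- extractCds(b)
      setNames(cds$aa, cds$locus_tag)
    })
    for (g in seq_len(nrow(groups))) {
      if (groups$n_members[g] < 2L) next
      tags <- unlist(groups[g, strains])
      tags <- tags[!is.na(tags)]
      seqs <- setNames(
        vapply(names(tags), function(s) genes[[s]][[tags[[s]]]], ""),
        names(tags))
      groups$nt_identity_pct[g] <- msaIdentity(groupMsa(seqs))
      if (groups$kind[g] == "CDS") {
        aas <- setNames(
          vapply(names(tags), function(s) prot[[s]][[tags[[s]]]], ""),
          names(tags))
        if (all(nchar(aas) > 0L))
          groups$aa_identity_pct[g] <-
            msaIdentity(groupMsa(aas, alphabet = "aa"))
      }
    }
  }
  new("Pangenome", groups = groups, strainIds = strains)
}

#' Conserved group sets feeding enrichment analysis
#'
#' @param pangenome a \linkS4class{Pangenome}.
#' @return list: \code{nt100} (group ids of multi-member groups at exactly
#'   100\% nucleotide identity) and \code{aa95} (CDS group ids at >= 95\%
#'   amino-acid identity).
#' @export
conservedSets <- function(pangenome) {
  g <- pangenomeGroups(pangenome)
  multi <- g$n_members >= 2L
  list(nt100 = g$group_id[multi & !is.na(g$nt_identity_pct) &
                            g$nt_identity_pct == 100],
       aa95 = g$group_id[multi & g$kind == "CDS" &
                           !is.na(g$aa_identity_pct) &
                           g$aa_identity_pct >= 95])
}

#' Write the pangenome table as TSV
#'
#' One row per group: group_id, per-strain locus tags, kind,
#' classification, identities.
#' @param pangenome a \linkS4class{Pangenome}.
#' @param path output file.
#' @export
writePangenomeTsv <- function(pangenome, path) {
  write.table(pangenomeGroups(pangenome), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
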