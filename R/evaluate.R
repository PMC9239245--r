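# Scoring detector output against the synthetic truth log. Every expected
# value here is derived from the truth tables alone; sequences are never
# re-inspected.

compBase <- function(x) unname(compMap[x])

#' Truth ortholog pairs of a strain panel
#'
#' Two genes are true orthologs iff they descend from the same ancestral
#' (or shared inserted) gene, identified by a stable gene id. Genes
#' involved in planted duplications are excluded, as are their extra
#' copies.
#'
#' @param truths named list of strain truth logs.
#' @return character vector of canonical "strain|gene" pair keys.
#' @export
truthOrthologPairs <- function(truths) {
  dupIds <- unique(unlist(lapply(truths, `[[`, "duplicatedGeneIds")))
  maps <- lapply(truths, function(tr) {
    gm <- tr$geneMap
    gm <- gm[!grepl("__dup$", gm$gene_id) & !(gm$gene_id %in% dupIds), ]
    gm
  })
  long <- do.call(rbind, lapply(names(maps), function(s)
    data.frame(strain = s, gene_id = maps[[s]]$gene_id,
               stringsAsFactors = FALSE)))
  pairs <- character(0)
  for (gid in unique(long$gene_id)) {
    ss <- sort(long$strain[long$gene_id == gid])
    if (length(ss) < 2L) next
    for (i in seq_len(length(ss) - 1L))
      for (j in (i + 1L):length(ss))
        pairs <- c(pairs, paste(ss[i], gid, ss[j], gid, sep = "|"))
  }
  pairs
}

#' Precision/recall of pangenome groups against truth orthology
#'
#' Pairwise co-membership: a predicted pair is any two genes of different
#' strains placed in the same homology group.
#'
#' @param pangenome a \linkS4class{Pangenome}.
#' @param truths named list of strain truth logs.
#' @return list(precision, recall, n_truth_pairs, n_pred_pairs).
#' @export
evaluateOrthologs <- function(pangenome, truths) {
  strains <- pangenomeStrains(pangenome)
  tag2gene <- lapply(truths[strains], function(tr)
    setNames(tr$geneMap$gene_id, tr$geneMap$locus_tag))
  dupIds <- unique(unlist(lapply(truths, `[[`, "duplicatedGeneIds")))
  g <- pangenomeGroups(pangenome)
  pred <- character(0)
  for (i in seq_len(nrow(g))) {
    tags <- unlist(g[i, strains])
    tags <- tags[!is.na(tags)]
    if (length(tags) < 2L) next
    ids <- vapply(names(tags), function(s) tag2gene[[s]][[tags[[s]]]], "")
    keep <- !grepl("__dup$", ids) & !(ids %in% dupIds)
    ids <- ids[keep]
    ss <- names(tags)[keep]
    if (length(ids) < 2L) next
    o <- order(ss)
    ids <- ids[o]; ss <- ss[o]
    for (a in seq_len(length(ids) - 1L))
      for (b in (a + 1L):length(ids))
        pred <- c(pred, paste(ss[a], ids[a], ss[b], ids[b], sep = "|"))
  }
  truth <- truthOrthologPairs(truths)
  tp <- length(intersect(pred, truth))
  list(precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       n_truth_pairs = length(truth), n_pred_pairs = length(pred))
}

# truth SNP events callable from group alignments: genic, gene annotated in
# >= 2 strains
callableTruthSnps <- function(truths) {
  counts <- table(unlist(lapply(truths, function(tr)
    unique(tr$geneMap$gene_id))))
  shared <- names(counts)[counts >= 2L]
  do.call(rbind, lapply(names(truths), function(s) {
    tr <- truths[[s]]
    sn <- tr$snps
    sn <- sn[!is.na(sn$gene_id) & sn$gene_id %in% shared &
               sn$gene_id %in% tr$geneMap$gene_id, , drop = FALSE]
    if (!nrow(sn)) return(NULL)
    gm <- tr$geneMap
    strand <- gm$strand[match(sn$gene_id, gm$gene_id)]
    sn$strain <- s
    sn$gene_frame_alt <- ifelse(strand == "+", sn$alt, compBase(sn$alt))
    sn
  }))
}

callableTruthIndels <- function(truths) {
  counts <- table(unlist(lapply(truths, function(tr)
    unique(tr$geneMap$gene_id))))
  shared <- names(counts)[counts >= 2L]
  do.call(rbind, lapply(names(truths), function(s) {
    tr <- truths[[s]]
    ind <- tr$indels
    ind <- ind[!is.na(ind$gene_id) & ind$gene_id %in% shared, ,
               drop = FALSE]
    if (!nrow(ind)) return(NULL)
    ind$strain <- s
    gm <- tr$geneMap
    strand <- gm$strand[match(ind$gene_id, gm$gene_id)]
    # the caller anchors indels on the base left of the run in gene
    # orientation; translate the genome-frame truth anchor accordingly
    ind$expected_pos <- ifelse(
      strand == "+", ind$pos,
      ifelse(ind$type == "deletion", ind$pos + 1L,
             ind$pos + ind$len + 1L))
    ind
  }))
}

#' Precision/recall of panel variant calls against truth
#'
#' SNPs match on (strain, replicon coordinate, allele); indels on (strain,
#' anchor coordinate, type, length). Only truth events inside genes
#' annotated in at least two strains are callable from group alignments
#' and enter the recall denominator. Effect agreement is reported over
#' matched SNPs.
#'
#' @param calls table from \code{\link{callPanelVariants}}.
#' @param truths named list of strain truth logs.
#' @return list with snp/indel precision and recall and effect agreement.
#' @export
evaluateVariants <- function(calls, truths) {
  strains <- names(truths)
  tSnp <- callableTruthSnps(truths)
  tInd <- callableTruthIndels(truths)
  tSnpKey <- if (!is.null(tSnp))
    paste(tSnp$strain, tSnp$pos, tSnp$gene_frame_alt) else character(0)
  tIndKey <- if (!is.null(tInd))
    paste(tInd$strain, tInd$expected_pos, tInd$type, tInd$len)
    else character(0)

  snpRows <- which(calls$var_type == "SNP")
  indRows <- which(calls$var_type != "SNP")

  callKeys <- function(i) {
    unlist(lapply(strains, function(s) {
      a <- calls[[paste0("allele_", s)]][i]
      p <- calls[[paste0("pos_", s)]][i]
      if (is.na(a) || is.na(p)) return(NULL)
      if (calls$var_type[i] == "SNP") paste(s, p, a)
      else {
        gl <- sum(strsplit(a, "", fixed = TRUE)[[1]] == "-")
        len <- calls$length[i]
        typ <- if (gl > 0L) "deletion" else "insertion"
        paste(s, p, typ, len)
      }
    }))
  }

  snpTp <- 0L; effAgree <- 0L; effTot <- 0L
  matchedSnpTruth <- logical(length(tSnpKey))
  for (i in snpRows) {
    ks <- callKeys(i)
    hit <- which(tSnpKey %in% ks)
    if (length(hit)) {
      snpTp <- snpTp + 1L
      matchedSnpTruth[hit] <- TRUE
      if (!is.na(calls$effect[i]) && !calls$boundary[i]) {
        effTot <- effTot + length(hit)
        effAgree <- effAgree + sum(tSnp$effect[hit] == calls$effect[i])
      }
    }
  }
  indTp <- 0L
  matchedIndTruth <- logical(length(tIndKey))
  for (i in indRows) {
    ks <- callKeys(i)
    hit <- which(tIndKey %in% ks)
    if (length(hit)) {
      indTp <- indTp + 1L
      matchedIndTruth[hit] <- TRUE
    }
  }
  list(snp_precision = if (length(snpRows)) snpTp / length(snpRows)
       else NA_real_,
       snp_recall = if (length(tSnpKey)) mean(matchedSnpTruth) else NA_real_,
       indel_precision = if (length(indRows)) indTp / length(indRows)
       else NA_real_,
       indel_recall = if (length(tIndKey)) mean(matchedIndTruth)
       else NA_real_,
       effect_agreement = if (effTot) effAgree / effTot else NA_real_,
       n_truth_snps = length(tSnpKey), n_truth_indels = length(tIndKey))
}

#' Compare prophage calls of one strain with its truth log
#'
#' @param calls table from \code{\link{findAttProphages}}.
#' @param truth the strain's truth log.
#' @return list(recall, n_false, boundary_exact).
#' @export
evaluateProphages <- function(calls, truth) {
  tr <- truth$prophages
  if (!nrow(tr))
    return(list(recall = NA_real_, n_false = nrow(calls),
                boundary_exact = NA))
  matched <- logical(nrow(tr))
  falseCalls <- 0L
  exact <- TRUE
  for (i in seq_len(nrow(calls))) {
    j <- which(tr$replicon == calls$replicon[i] &
                 tr$attL_start == calls$attL_start[i] &
                 tr$attL_end == calls$attL_end[i] &
                 tr$attR_start == calls$attR_start[i] &
                 tr$attR_end == calls$attR_end[i])
    if (length(j)) {
      matched[j] <- TRUE
      if (calls$duplication_len[i] != tr$att_len[j] ||
          calls$elem_start[i] != tr$elem_start[j] ||
          calls$elem_end[i] != tr$elem_end[j]) exact <- FALSE
    } else falseCalls <- falseCalls + 1L
  }
  list(recall = mean(matched), n_false = falseCalls,
       boundary_exact = exact && all(matched))
}

#' Compare inversion blocks with a strain's truth log
#'
#' @param blocks table from \code{\link{detectInversions}} (A = the strain
#'   carrying the inversion).
#' @param truth the strain's truth log.
#' @param tol anchor-resolution tolerance in bp.
#' @return list(recall, n_false, hip1_flagged).
#' @export
evaluateInversions <- function(blocks, truth, tol = 60L) {
  tr <- truth$inversions
  if (!nrow(tr))
    return(list(recall = NA_real_, n_false = nrow(blocks),
                hip1_flagged = NA))
  matched <- logical(nrow(tr))
  hip <- logical(nrow(tr))
  falseCalls <- 0L
  for (i in seq_len(nrow(blocks))) {
    j <- which(tr$replicon == blocks$replicon_A[i] &
                 abs(tr$start - blocks$startA[i]) <= tol &
                 abs(tr$end - blocks$endA[i]) <= tol)
    if (length(j)) {
      matched[j] <- TRUE
      hip[j] <- blocks$boundary_hip1[i]
    } else falseCalls <- falseCalls + 1L
  }
  list(recall = mean(matched), n_false = falseCalls,
       hip1_flagged = all(hip[matched]))
}

#' Compare CRISPR array calls with a strain's truth log
#'
#' @param arrays list from \code{\link{findCrisprArrays}}.
#' @param truth the strain's truth log.
#' @return list(recall, n_false, spacers_exact).
#' @export
evaluateCrispr <- function(arrays, truth) {
  tr <- truth$crisprs
  if (!nrow(tr))
    return(list(recall = NA_real_, n_false = length(arrays),
                spacers_exact = NA))
  matched <- logical(nrow(tr))
  spacersOk <- TRUE
  falseCalls <- 0L
  for (ar in arrays) {
    j <- which(tr$replicon == ar$replicon & tr$start == ar$start &
                 tr$end == ar$end)
    if (length(j)) {
      matched[j] <- TRUE
      if (!identical(ar$repeat_seq, tr$repeat_seq[j]) ||
          ar$n_repeats != tr$n_repeats[j] ||
          !identical(unname(ar$spacers),
                     unname(truth$crisprSpacers[[j]])))
        spacersOk <- FALSE
    } else falseCalls <- falseCalls + 1L
  }
  list(recall = mean(matched), n_false = falseCalls,
       spacers_exact = spacersOk && all(matched))
}
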