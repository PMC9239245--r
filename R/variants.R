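# SNP and indel calling inside homology-group alignments, with codon-aware
# effect classification against a designated reference strain, summary
# statistics (including the percent of coding SNPs that change the protein)
# and TSV/VCF export.

#' Call variants across a panel of strains from their pangenome
#'
#' Each multi-member homology group is aligned (\code{\link{groupMsa}}:
#' progressive alignment with left-shifted gaps) and polymorphic columns are
#' called: single-base columns with >= 2 allele states become SNPs, and
#' contiguous gap runs are merged into single insertion/deletion events.
#' Leading/trailing alignment overhangs (annotation-length differences) are
#' treated as missing data, not indels. Effects are classified against the
#' reference strain's reading frame.
#'
#' @param pangenome a \linkS4class{Pangenome}.
#' @param bundles named list of the \linkS4class{GenomeBundle}s used to
#'   build it.
#' @param refStrain reference strain id (default: first bundle).
#' @return data.frame of variant calls, one row per call; per-strain allele
#'   columns (\code{allele_<strain>}, alignment frame) and position columns
#'   (\code{pos_<strain>}, 1-based replicon coordinates).
#' @export
callPanelVariants <- function(pangenome, bundles,
                              refStrain = strainId(bundles[[1L]])) {
  strains <- pangenomeStrains(pangenome)
  names(bundles) <- vapply(bundles, strainId, "")
  stopifnot(refStrain %in% strains, all(strains %in% names(bundles)))
  g <- pangenomeGroups(pangenome)
  genes <- lapply(bundles[strains], orthoGenes)
  featOf <- lapply(bundles[strains], function(b) {
    ft <- features(b)
    df <- data.frame(replicon = as.character(GenomeInfoDb::seqnames(ft)),
                     start = BiocGenerics::start(ft),
                     end = BiocGenerics::end(ft),
                     strand = as.character(BiocGenerics::strand(ft)),
                     kind = ft$kind, stringsAsFactors = FALSE)
    rownames(df) <- ft$locus_tag
    df
  })

  calls <- list()
  for (gi in seq_len(nrow(g))) {
    if (g$n_members[gi] < 2L) next
    tags <- unlist(g[gi, strains])
    tags <- tags[!is.na(tags)]
    seqs <- setNames(
      vapply(names(tags), function(s) genes[[s]][[tags[[s]]]], ""),
      names(tags))
    msa <- groupMsa(seqs)
    cg <- callGroupVariants(msa, g$group_id[gi], tags, featOf, refStrain,
                            strains)
    if (!is.null(cg)) calls[[length(calls) + 1L]] <- cg
  }
  if (!length(calls))
    return(emptyVariantTable(strains))
  out <- do.call(rbind, calls)
  refPos <- out[[paste0("pos_", refStrain)]]
  out <- out[order(out$ref_replicon, refPos, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyVariantTable <- function(strains) {
  base <- data.frame(group_id = character(0), var_type = character(0),
                     column = integer(0), length = integer(0),
                     effect = character(0), aa_change = character(0),
                     ref_replicon = character(0), boundary = logical(0),
                     stringsAsFactors = FALSE)
  for (s in strains) {
    base[[paste0("allele_", s)]] <- character(0)
    base[[paste0("pos_", s)]] <- integer(0)
  }
  base
}

# variants of one group alignment
callGroupVariants <- function(msa, groupId, tags, featOf, refStrain,
                              strains) {
  nr <- nrow(msa); nc <- ncol(msa)
  if (nr < 2L || nc == 0L) return(NULL)
  ov <- overhangMask(msa)
  work <- msa
  work[ov] <- "."                      # missing data, not sequence

  gapCol <- apply(work == "-", 2L, any)
  polySnp <- !gapCol & apply(work, 2L, function(col) {
    b <- col[col != "."]
    length(unique(b)) >= 2L
  })

  # merge contiguous gap-containing columns into indel events
  events <- list()
  r <- rle(gapCol)
  ends <- cumsum(r$lengths)
  for (ri in which(r$values)) {
    to <- ends[ri]; from <- to - r$lengths[ri] + 1L
    events[[length(events) + 1L]] <- list(type = "indel", from = from,
                                          to = to)
  }
  for (cc in which(polySnp))
    events[[length(events) + 1L]] <- list(type = "SNP", from = cc, to = cc)
  if (!length(events)) return(NULL)

  # per-row mapping alignment column -> 1-based offset in member sequence
  offs <- apply(msa != "-", 1L, cumsum)      # nc x nr matrix
  refHas <- refStrain %in% rownames(msa)

  rows <- list()
  for (evn in events) {
    from <- evn$from; to <- evn$to
    alleles <- setNames(rep(NA_character_, length(strains)), strains)
    pos <- setNames(rep(NA_integer_, length(strains)), strains)
    for (s in rownames(msa)) {
      seg <- work[s, from:to]
      if (all(seg == ".")) next
      alleles[s] <- paste(msa[s, from:to], collapse = "")
      ft <- featOf[[s]][tags[[s]], ]
      # SNPs anchor on the substituted base itself; indel events anchor on
      # the base immediately left of the run in every strain
      o <- offs[from, s]
      anchorOff <- if (evn$type == "SNP" || msa[s, from] == "-") o
                   else o - 1L
      pos[s] <- if (ft$strand == "+") ft$start + anchorOff - 1L
                else ft$end - anchorOff + 1L
    }
    present <- !is.na(alleles)
    if (sum(present) < 2L) next
    if (evn$type == "SNP") {
      ab <- alleles[present]
      if (length(unique(ab)) < 2L) next
      varType <- "SNP"
      len <- 1L
    } else {
      gapped <- vapply(alleles[present], function(a) grepl("-", a), TRUE)
      if (!any(gapped) || all(gapped)) next
      refAllele <- if (refHas && present[refStrain]) alleles[refStrain]
                   else alleles[present][1L]
      varType <- if (grepl("-", refAllele)) "insertion" else "deletion"
      len <- to - from + 1L
    }
    rows[[length(rows) + 1L]] <-
      c(list(group_id = groupId, var_type = varType, column = from,
             length = len),
        as.list(setNames(alleles, paste0("allele_", strains))),
        as.list(setNames(pos, paste0("pos_", strains))))
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  # effect classification against the reference strain
  df$effect <- NA_character_
  df$aa_change <- NA_character_
  df$boundary <- FALSE
  df$ref_replicon <- NA_character_
  if (refHas) {
    ft <- featOf[[refStrain]][tags[[refStrain]], ]
    df$ref_replicon <- ft$replicon
    refSeq <- paste(msa[refStrain, msa[refStrain, ] != "-"], collapse = "")
    for (i in seq_len(nrow(df))) {
      cls <- classifyEffect(df[i, ], msa, refStrain, ft, refSeq, strains)
      df$effect[i] <- cls$effect
      df$aa_change[i] <- cls$aa_change
      df$boundary[i] <- cls$boundary
    }
  }
  df
}

#' Classify the coding effect of one variant call
#'
#' Codon-aware: the reference codon is rebuilt from the reference strain's
#' reading frame and the full mutated codon of the first differing strain
#' (including any neighbouring substitutions it carries in the same codon)
#' is mapped through the bacterial genetic code. Indels in CDS are
#' frameshift iff their length is not a multiple of three. tRNA/ncRNA and
#' pseudogene features give \code{noncoding_gene}.
#'
#' @param call one row of the variant table.
#' @param msa the group alignment matrix.
#' @param refStrain reference strain id.
#' @param ft reference feature row (replicon, start, end, strand, kind).
#' @param refSeq ungapped reference member sequence.
#' @param strains panel strain ids.
#' @return list(effect, aa_change, boundary).
#' @export
classifyEffect <- function(call, msa, refStrain, ft, refSeq, strains) {
  out <- list(effect = "intergenic", aa_change = NA_character_,
              boundary = FALSE)
  if (ft$kind %in% c("tRNA", "ncRNA", "pseudogene")) {
    out$effect <- "noncoding_gene"
    return(out)
  }
  if (ft$kind != "CDS") return(out)
  if (call$var_type %in% c("insertion", "deletion")) {
    gapLens <- vapply(strains, function(s) {
      a <- call[[paste0("allele_", s)]]
      if (is.na(a)) return(0L)
      sum(strsplit(a, "", fixed = TRUE)[[1]] == "-")
    }, 0L)
    len <- max(gapLens)
    out$effect <- if (len %% 3L) "frameshift" else "inframe_indel"
    return(out)
  }
  # SNP: locate reference offset of the column
  col <- call$column
  if (msa[refStrain, col] == "-") {
    out$effect <- "boundary"; out$boundary <- TRUE
    return(out)
  }
  o <- sum(msa[refStrain, seq_len(col)] != "-")   # 1-based offset in gene
  ci <- (o - 1L) %/% 3L                            # 0-based codon index
  nCod <- nchar(refSeq) %/% 3L
  if (o > nCod * 3L) {
    out$boundary <- TRUE
    out$effect <- "noncoding_gene"
    return(out)
  }
  refCodon <- substr(refSeq, ci * 3L + 1L, ci * 3L + 3L)
  # first strain differing from the reference at this column
  refBase <- msa[refStrain, col]
  altStrain <- NULL
  for (s in rownames(msa)) {
    if (s == refStrain) next
    a <- call[[paste0("allele_", s)]]
    if (!is.na(a) && a != "-" && a != refBase) { altStrain <- s; break }
  }
  if (is.null(altStrain)) {
    out$effect <- "synonymous"
    return(out)
  }
  # rebuild the full mutated codon from the alt strain's aligned bases
  codCols <- which(cumsum(msa[refStrain, ] != "-") %in%
                     (ci * 3L + 1L):(ci * 3L + 3L) & msa[refStrain, ] != "-")
  altCodon <- refCodon
  for (j in seq_along(codCols)) {
    ab <- msa[altStrain, codCols[j]]
    if (ab != "-" && ab != ".")
      substr(altCodon, j, j) <- ab
  }
  eff <- classifyCodonChange(refCodon, altCodon)
  out$effect <- eff
  if (eff %in% c("missense", "nonsense")) {
    gc <- codonTable()
    out$aa_change <- paste0(unname(gc[refCodon]), ci + 1L,
                            unname(gc[altCodon]))
  }
  out
}

#' Summarize a panel variant table
#'
#' \code{pct_aa_changing} is computed over SNPs located in CDS of the
#' reference strain: the percentage with effect missense or nonsense
#' (\code{NA} when there are no coding SNPs). The sharing matrix has one row
#' per strain and one column per variant, 1 iff the strain carries a
#' non-reference allele.
#'
#' @param calls variant table from \code{\link{callPanelVariants}}.
#' @param strains strain ids (derived from the table when omitted).
#' @param refStrain reference strain id (default: first strain).
#' @return list: total_snps, total_indels, pct_aa_changing, sharing_matrix.
#' @export
summarizeVariants <- function(calls, strains = NULL, refStrain = NULL) {
  if (is.null(strains))
    strains <- sub("^allele_", "",
                   grep("^allele_", colnames(calls), value = TRUE))
  if (is.null(refStrain)) refStrain <- strains[1L]
  isSnp <- calls$var_type == "SNP"
  cds <- isSnp & calls$effect %in% c("synonymous", "missense", "nonsense")
  pct <- if (any(cds))
    100 * sum(calls$effect[cds] %in% c("missense", "nonsense")) / sum(cds)
  else NA_real_
  sharing <- matrix(0L, length(strains), nrow(calls),
                    dimnames = list(strains, calls$group_id))
  if (nrow(calls)) {
    refAll <- calls[[paste0("allele_", refStrain)]]
    for (s in strains) {
      a <- calls[[paste0("allele_", s)]]
      sharing[s, ] <- as.integer(!is.na(a) & !is.na(refAll) & a != refAll)
    }
  }
  list(total_snps = sum(isSnp), total_indels = sum(!isSnp),
       pct_aa_changing = pct, sharing_matrix = sharing)
}

#' Write the variant table as TSV
#' @param calls variant table.
#' @param path output file.
#' @export
writeVariantTsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Export per-strain variants as minimal VCF v4.2 against the reference
#'
#' SNP records use the reference/alternate single bases; indels are written
#' as symbolic \code{<DEL>}/\code{<INS>} records with an END/SVLEN INFO
#' field, anchored at the reference base immediately left of the event.
#'
#' @param calls variant table from \code{\link{callPanelVariants}}.
#' @param strain strain to export.
#' @param refStrain reference strain id.
#' @param path output file.
#' @export
writeVariantVcf <- function(calls, strain, refStrain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=strainpan%s", packageVersion("strainpan")),
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Indel length\">",
               "##INFO=<ID=GROUP,Number=1,Type=String,Description=\"Homology group\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  aS <- calls[[paste0("allele_", strain)]]
  aR <- calls[[paste0("allele_", refStrain)]]
  pR <- calls[[paste0("pos_", refStrain)]]
  keep <- which(!is.na(aS) & !is.na(aR) & aS != aR & !is.na(pR))
  keep <- keep[order(calls$ref_replicon[keep], pR[keep])]
  for (i in keep) {
    if (calls$var_type[i] == "SNP") {
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGROUP=%s",
                         calls$ref_replicon[i], pR[i], aR[i], aS[i],
                         calls$group_id[i]), con)
    } else {
      sym <- if (calls$var_type[i] == "deletion") "<DEL>" else "<INS>"
      writeLines(sprintf("%s\t%d\t.\tN\t%s\t.\tPASS\tSVLEN=%d;GROUP=%s",
                         calls$ref_replicon[i], pR[i], sym,
                         calls$length[i], calls$group_id[i]), con)
    }
  }
  invisible(path)
}
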