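# Consensus pangenome annotation: start-coordinate reconciliation by
# majority vote, removal of hypothetical/pseudogene groups without
# transcription evidence, promotion of evidence-backed ncRNAs.

#' Reconcile per-strain annotations into a unified pangenome annotation
#'
#' Per group: (i) when member start coordinates disagree (detected as
#' leading-overhang differences in the group alignment), the majority start
#' is adopted (ties towards the longest open reading frame) and a
#' \code{start_adjust} action is recorded; (ii) groups annotated
#' hypothetical or pseudogene whose members have \code{transcribed = FALSE}
#' in every evidence-bearing member (and no essential member) are dropped
#' (\code{drop_unsupported}); (iii) ncRNA groups with transcription
#' evidence in any member are promoted (\code{promote_ncRNA}); all other
#' groups are kept. A group with no evidence in any member is kept with a
#' "no evidence" note. Deterministic.
#'
#' @param pangenome a \linkS4class{Pangenome}.
#' @param bundles the bundles it was built from.
#' @return list: \code{unified} (annotation table of retained groups) and
#'   \code{adjustments} (one action record per group: group_id, action,
#'   detail, affected_strains).
#' @export
reconcileAnnotations <- function(pangenome, bundles) {
  strains <- pangenomeStrains(pangenome)
  names(bundles) <- vapply(bundles, strainId, "")
  g <- pangenomeGroups(pangenome)
  genes <- lapply(bundles[strains], orthoGenes)
  meta <- lapply(bundles[strains], function(b) {
    ft <- features(b)
    df <- data.frame(product = ft$product, transcribed = ft$transcribed,
                     essential = ft$essential, categories = ft$categories,
                     kind = ft$kind, stringsAsFactors = FALSE)
    rownames(df) <- ft$locus_tag
    df
  })

  actions <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    tags <- unlist(g[i, strains])
    tags <- tags[!is.na(tags)]
    mrows <- do.call(rbind, lapply(names(tags), function(s)
      meta[[s]][tags[[s]], ]))
    hasEv <- !is.na(mrows$transcribed)
    anyEssential <- any(!is.na(mrows$essential) & mrows$essential)
    act <- "keep"; detail <- ""; affected <- ""

    # start disagreement via leading overhangs of the group alignment
    if (length(tags) >= 2L) {
      seqs <- setNames(
        vapply(names(tags), function(s) genes[[s]][[tags[[s]]]], ""),
        names(tags))
      msa <- groupMsa(seqs)
      lead <- apply(msa, 1L, function(v) {
        r <- rle(v == "-")
        if (r$values[1L]) r$lengths[1L] else 0L
      })
      if (length(unique(lead)) > 1L) {
        tb <- table(lead)
        top <- tb[tb == max(tb)]
        # tie -> smallest overhang (longest ORF)
        maj <- min(as.integer(names(top)))
        dev <- names(lead)[lead != maj]
        act <- "start_adjust"
        detail <- sprintf("start moved to majority (offsets: %s)",
                          paste(sprintf("%s=%+d", dev,
                                        lead[dev] - maj), collapse = ","))
        affected <- paste(dev, collapse = ",")
      }
    }

    hypo <- g$kind[i] == "pseudogene" ||
      any(grepl("hypothetical", mrows$product, ignore.case = TRUE))
    if (act == "keep" || act == "start_adjust") {
      if (g$kind[i] == "ncRNA" &&
          any(hasEv & mrows$transcribed)) {
        act <- "promote_ncRNA"
        detail <- sprintf("transcribed%s",
                          if (anyEssential) " and essential" else "")
      } else if ((g$kind[i] == "pseudogene" || hypo) && any(hasEv) &&
                 !any(mrows$transcribed[hasEv]) && !anyEssential) {
        act <- "drop_unsupported"
        detail <- "hypothetical/pseudogene without transcription evidence"
      } else if (!any(hasEv) && act == "keep") {
        detail <- "no evidence"
      }
    }
    actions[[i]] <- data.frame(
      group_id = g$group_id[i], action = act, detail = detail,
      affected_strains = affected, stringsAsFactors = FALSE)
  }
  adj <- do.call(rbind, actions)
  keep <- adj$action != "drop_unsupported"
  unified <- g[keep, , drop = FALSE]
  unified$action <- adj$action[keep]

  # representative product/categories/essentiality from the members
  unified$product <- NA_character_
  unified$categories <- NA_character_
  unified$essential <- FALSE
  for (i in seq_len(nrow(unified))) {
    tags <- unlist(unified[i, strains])
    tags <- tags[!is.na(tags)]
    mrows <- do.call(rbind, lapply(names(tags), function(s)
      meta[[s]][tags[[s]], ]))
    unified$product[i] <- mrows$product[1L]
    unified$categories[i] <-
      paste(sort(unique(unlist(strsplit(mrows$categories, ",")))),
            collapse = ",")
    unified$essential[i] <- any(!is.na(mrows$essential) & mrows$essential)
  }
  rownames(unified) <- NULL
  list(unified = unified, adjustments = adj)
}

#' Export the unified pangenome annotation table as TSV
#'
#' One row per retained pangenome gene: group id, per-strain locus tags,
#' kind, product, categories, essentiality, classification, identities and
#' adjustment action. Stable sort; re-export is byte-identical.
#'
#' @param unified result of \code{\link{reconcileAnnotations}}.
#' @param path output file.
#' @export
exportPangenomeTable <- function(unified, path) {
  u <- unified$unified
  u <- u[order(u$group_id), , drop = FALSE]
  write.table(u, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Export the unified annotation as GFF3 for a designated reference strain
#'
#' Features of the reference strain whose groups survived reconciliation,
#' with the adjustment action carried in the attributes.
#'
#' @param unified result of \code{\link{reconcileAnnotations}}.
#' @param bundle reference strain \linkS4class{GenomeBundle}.
#' @param path output file.
#' @export
exportReferenceGff <- function(unified, bundle, path) {
  u <- unified$unified
  ref <- strainId(bundle)
  stopifnot(ref %in% colnames(u))
  tags <- u[[ref]]
  keep <- !is.na(tags)
  ft <- features(bundle)
  ft <- ft[match(tags[keep], ft$locus_tag)]
  lines <- c("##gff-version 3",
             sprintf("%s\tstrainpan\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s;group_id=%s;action=%s",
                     as.character(GenomeInfoDb::seqnames(ft)), ft$kind,
                     BiocGenerics::start(ft), BiocGenerics::end(ft),
                     as.character(BiocGenerics::strand(ft)), ft$locus_tag,
                     ft$locus_tag, u$group_id[keep], u$action[keep]))
  writeLines(lines, path)
  invisible(path)
}
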