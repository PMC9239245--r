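#' Read a strain genome bundle from FASTA + GFF3 (+ optional evidence TSV)
#'
#' FASTA record ids must match the GFF3 seqid column. Gene features are taken
#' from GFF3 rows of type CDS, tRNA, ncRNA or pseudogene; \code{region} rows
#' carry replicon topology via the \code{Is_circular} attribute. Evidence
#' flags default to unknown (\code{NA}) when the TSV is omitted; when given,
#' the TSV (columns \code{locus_tag}, \code{transcribed}, \code{essential},
#' \code{categories} comma-joined) overrides GFF3 attributes.
#'
#' @param fastaPath multi-record FASTA, one record per replicon.
#' @param gffPath GFF3 annotation file.
#' @param evidencePath optional evidence TSV.
#' @param strainId strain label; default: FASTA file name without extension.
#' @return a validated \linkS4class{GenomeBundle}.
#' @export
loadBundle <- function(fastaPath, gffPath, evidencePath = NULL,
                       strainId = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  strainId <- strainId %||% sub("\\.(fa|fasta|fna)$", "", basename(fastaPath))

  gr <- rtracklayer::import(gffPath, format = "gff3")
  type <- as.character(gr$type)

  topo <- setNames(rep("linear", length(seqs)), names(seqs))
  reg <- gr[type == "region"]
  if (length(reg) && !is.null(reg$Is_circular)) {
    circ <- as.character(GenomeInfoDb::seqnames(reg))[
      tolower(as.character(reg$Is_circular)) == "true"]
    topo[intersect(circ, names(topo))] <- "circular"
  }

  ft <- gr[type %in% c("CDS", "tRNA", "ncRNA", "pseudogene")]
  sq <- as.character(GenomeInfoDb::seqnames(ft))
  unknown <- setdiff(unique(sq), names(seqs))
  if (length(unknown))
    stopf("GFF3 seqid not present in FASTA: %s", paste(unknown, collapse = ","))

  pick <- function(field, default) {
    v <- S4Vectors::mcols(ft)[[field]]
    if (is.null(v)) return(rep(default, length(ft)))
    if (methods::is(v, "List"))
      v <- vapply(v, function(e) paste(e, collapse = "|"), "")
    v[is.na(v)] <- default
    v
  }
  asFlag <- function(v) {
    out <- rep(NA, length(v))
    out[tolower(v) %in% c("true", "yes", "1")] <- TRUE
    out[tolower(v) %in% c("false", "no", "0")] <- FALSE
    out
  }
  lt <- pick("locus_tag", NA_character_)
  if (anyNA(lt)) stopf("GFF3 feature without locus_tag attribute")
  if (anyDuplicated(lt))
    stopf("duplicate locus_tag in GFF3: %s",
          paste(unique(lt[duplicated(lt)]), collapse = ","))

  feat <- GenomicRanges::GRanges(
    seqnames = sq,
    ranges = IRanges::IRanges(BiocGenerics::start(ft), BiocGenerics::end(ft)),
    strand = BiocGenerics::strand(ft))
  S4Vectors::mcols(feat) <- S4Vectors::DataFrame(
    locus_tag = lt,
    kind = as.character(type[type %in% c("CDS", "tRNA", "ncRNA",
                                         "pseudogene")]),
    product = pick("product", ""),
    transcribed = asFlag(pick("evidence_transcribed", "unknown")),
    essential = asFlag(pick("evidence_essential", "unknown")),
    categories = gsub("|", ",", pick("category", ""), fixed = TRUE))

  if (!is.null(evidencePath)) {
    ev <- read.delim(evidencePath, stringsAsFactors = FALSE,
                     colClasses = "character")
    i <- match(feat$locus_tag, ev$locus_tag)
    hit <- !is.na(i)
    feat$transcribed[hit] <- asFlag(ev$transcribed[i[hit]])
    feat$essential[hit] <- asFlag(ev$essential[i[hit]])
    if (!is.null(ev$categories))
      feat$categories[hit] <- ev$categories[i[hit]]
  }

  ord <- order(match(as.character(GenomeInfoDb::seqnames(feat)), names(seqs)),
               BiocGenerics::start(feat), feat$locus_tag)
  bundle <- GenomeBundle(strainId, seqs, topo, feat[ord])
  lens <- Biostrings::width(seqs)[match(as.character(
    GenomeInfoDb::seqnames(feat)), names(seqs))]
  bad <- feat$locus_tag[BiocGenerics::end(feat) > lens |
                          BiocGenerics::start(feat) < 1L]
  if (length(bad))
    stopf("feature out of replicon bounds: %s", paste(bad, collapse = ","))
  bundle
}

#' Write a GenomeBundle as FASTA + GFF3 + evidence TSV
#'
#' Guarantees the round trip \code{loadBundle(writeBundle(b))} reproduces the
#' bundle field for field. Coordinates are written 1-based inclusive;
#' circular topology is recorded on GFF3 \code{region} rows.
#'
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param outDir output directory (created if needed).
#' @param prefix file name prefix; default the strain id.
#' @return named character vector of the three paths written.
#' @export
writeBundle <- function(bundle, outDir, prefix = strainId(bundle)) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory: %s", outDir)
  fa <- file.path(outDir, paste0(prefix, ".fasta"))
  gff <- file.path(outDir, paste0(prefix, ".gff3"))
  tsv <- file.path(outDir, paste0(prefix, ".evidence.tsv"))

  Biostrings::writeXStringSet(replicons(bundle), fa, width = 80L)

  ft <- features(bundle)
  ord <- order(match(as.character(GenomeInfoDb::seqnames(ft)),
                     names(replicons(bundle))),
               BiocGenerics::start(ft), ft$locus_tag)
  ft <- ft[ord]
  flag <- function(v) ifelse(is.na(v), "unknown", ifelse(v, "true", "false"))
  attrs <- sprintf(
    "ID=%s;locus_tag=%s;product=%s;evidence_transcribed=%s;evidence_essential=%s;category=%s",
    ft$locus_tag, ft$locus_tag, gsub("[;=,\t]", " ", ft$product),
    flag(ft$transcribed), flag(ft$essential),
    gsub(",", "|", ft$categories, fixed = TRUE))
  lens <- Biostrings::width(replicons(bundle))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(replicons(bundle)), lens),
             sprintf("%s\tstrainpan\tregion\t1\t%d\t.\t+\t.\tID=region_%s;Is_circular=%s",
                     names(replicons(bundle)), lens, names(replicons(bundle)),
                     ifelse(topology(bundle) == "circular", "true", "false")),
             sprintf("%s\tstrainpan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                     as.character(GenomeInfoDb::seqnames(ft)), ft$kind,
                     BiocGenerics::start(ft), BiocGenerics::end(ft),
                     as.character(BiocGenerics::strand(ft)),
                     ifelse(ft$kind == "CDS", "0", "."), attrs))
  writeLines(lines, gff)

  ev <- data.frame(locus_tag = ft$locus_tag,
                   transcribed = flag(ft$transcribed),
                   essential = flag(ft$essential),
                   categories = ft$categories,
                   stringsAsFactors = FALSE)
  write.table(ev, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fasta = fa, gff3 = gff, evidence = tsv)
}

#' Extract CDS nucleotide and protein sequences
#'
#' Minus-strand CDSs are reverse-complemented before translation (bacterial
#' code, table 11); the terminal stop is removed. A CDS whose length is not a
#' multiple of three is translated up to the last full codon and flagged
#' (\code{frame_ok = FALSE}); an internal stop in a frame-intact CDS is
#' flagged (\code{internal_stop}), not fatal.
#'
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param kinds feature kinds to extract; default CDS only.
#' @return data.frame with locus_tag, nt, aa, frame_ok, internal_stop.
#' @export
extractCds <- function(bundle, kinds = "CDS") {
  ft <- features(bundle)
  ft <- ft[ft$kind %in% kinds]
  if (!length(ft))
    return(data.frame(locus_tag = character(0), nt = character(0),
                      aa = character(0), frame_ok = logical(0),
                      internal_stop = logical(0), stringsAsFactors = FALSE))
  nt <- geneSeqs(bundle, ft)
  aa <- vapply(nt, translateChr, "")
  frameOk <- nchar(nt) %% 3L == 0L
  hasTermStop <- frameOk & endsWith(aa, "*")
  aaTrim <- ifelse(hasTermStop, substr(aa, 1L, nchar(aa) - 1L), aa)
  data.frame(locus_tag = ft$locus_tag, nt = unname(nt), aa = unname(aaTrim),
             frame_ok = frameOk,
             internal_stop = grepl("*", aaTrim, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Stranded gene sequences for a set of features
#' @noRd
geneSeqs <- function(bundle, ft) {
  rep <- as.character(replicons(bundle))
  sq <- as.character(GenomeInfoDb::seqnames(ft))
  seqs <- substring(rep[sq], BiocGenerics::start(ft), BiocGenerics::end(ft))
  minus <- as.character(BiocGenerics::strand(ft)) == "-"
  if (any(minus)) seqs[minus] <- revcompChr(seqs[minus])
  setNames(seqs, ft$locus_tag)
}
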