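#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' GenomeBundle: one strain's replicon sequences plus gene annotations
#'
#' The canonical in-memory genome model used throughout the package. A bundle
#' holds the ordered replicon sequences of one strain (chromosome and
#' plasmids), their topology, and a \code{GRanges} of gene features carrying
#' \code{locus_tag}, \code{kind} (CDS, tRNA, ncRNA or pseudogene),
#' \code{product}, evidence flags (\code{transcribed}, \code{essential};
#' \code{NA} means unknown) and comma-joined \code{categories} labels.
#'
#' All coordinates are 1-based inclusive, the GFF3/GenBank convention; the
#' \code{GRanges} container enforces it end to end.
#'
#' @slot strainId single character label for the strain.
#' @slot replicons named \code{DNAStringSet}, one entry per replicon.
#' @slot topology named character vector, \code{"circular"} or
#'   \code{"linear"}, parallel to \code{replicons}.
#' @slot features \code{GRanges} of gene features on the replicons.
#' @exportClass GenomeBundle
setClass("GenomeBundle",
         representation(strainId = "character",
                        replicons = "DNAStringSet",
                        topology = "character",
                        features = "GRanges"))

validGenomeBundle <- function(object) {
  msgs <- character(0)
  rn <- names(object@replicons)
  if (length(object@strainId) != 1L || is.na(object@strainId))
    msgs <- c(msgs, "strainId must be a single non-NA string")
  if (is.null(rn) || anyDuplicated(rn))
    msgs <- c(msgs, "replicon ids must be present and unique")
  if (length(object@topology) != length(object@replicons) ||
      !all(object@topology %in% c("circular", "linear")))
    msgs <- c(msgs, "topology must be circular/linear, one per replicon")
  af <- Biostrings::alphabetFrequency(object@replicons, baseOnly = FALSE)
  bad <- setdiff(colnames(af)[colSums(af) > 0], c("A", "C", "G", "T", "N"))
  if (length(bad))
    msgs <- c(msgs, paste0("sequence alphabet restricted to A,C,G,T,N; found: ",
                           paste(bad, collapse = ",")))
  ft <- object@features
  if (length(ft)) {
    mc <- S4Vectors::mcols(ft)
    need <- c("locus_tag", "kind", "product", "transcribed", "essential",
              "categories")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
      msgs <- c(msgs, paste0("features missing mcols: ",
                             paste(miss, collapse = ",")))
    else {
      if (anyDuplicated(mc$locus_tag))
        msgs <- c(msgs, "locus_tag must be unique genome-wide")
      if (!all(mc$kind %in% c("CDS", "tRNA", "ncRNA", "pseudogene")))
        msgs <- c(msgs, "feature kind must be CDS/tRNA/ncRNA/pseudogene")
    }
    sq <- as.character(GenomeInfoDb::seqnames(ft))
    if (!all(sq %in% rn))
      msgs <- c(msgs, paste0("feature replicon not in bundle: ",
                             paste(unique(setdiff(sq, rn)), collapse = ",")))
    else {
      lens <- Biostrings::width(object@replicons)[match(sq, rn)]
      if (any(BiocGenerics::start(ft) < 1L) || any(BiocGenerics::end(ft) > lens))
        msgs <- c(msgs, "feature coordinates outside replicon bounds")
    }
    if (any(as.character(BiocGenerics::strand(ft)) == "*"))
      msgs <- c(msgs, "feature strand must be + or -")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("GenomeBundle", validGenomeBundle)

#' Construct a GenomeBundle
#'
#' @param strainId strain label.
#' @param replicons named \code{DNAStringSet} (or named character vector).
#' @param topology character vector of \code{"circular"}/\code{"linear"};
#'   recycled if length one.
#' @param features \code{GRanges} with the feature mcols described in
#'   \linkS4class{GenomeBundle}, or \code{NULL} for none.
#' @return a validated \linkS4class{GenomeBundle}.
#' @export
GenomeBundle <- function(strainId, replicons, topology = "linear",
                         features = NULL) {
  if (is.character(replicons))
    replicons <- Biostrings::DNAStringSet(replicons)
  if (length(topology) == 1L)
    topology <- rep(topology, length(replicons))
  names(topology) <- names(replicons)
  if (is.null(features)) {
    features <- GenomicRanges::GRanges(seqnames = character(0),
                                       ranges = IRanges::IRanges())
    S4Vectors::mcols(features) <- S4Vectors::DataFrame(
      locus_tag = character(0), kind = character(0), product = character(0),
      transcribed = logical(0), essential = logical(0),
      categories = character(0))
  }
  GenomeInfoDb::seqlevels(features) <- union(GenomeInfoDb::seqlevels(features),
                                             names(replicons))
  new("GenomeBundle", strainId = strainId, replicons = replicons,
      topology = topology, features = features)
}

#' @describeIn GenomeBundle-accessors strain label
#' @export
strainId <- function(x) x@strainId

#' Accessors for GenomeBundle
#'
#' @param x a \linkS4class{GenomeBundle}.
#' @name GenomeBundle-accessors
NULL

#' @describeIn GenomeBundle-accessors named DNAStringSet of replicons
#' @export
replicons <- function(x) x@replicons

#' @describeIn GenomeBundle-accessors replicon topology vector
#' @export
topology <- function(x) x@topology

#' @describeIn GenomeBundle-accessors feature GRanges
#' @export
features <- function(x) x@features

setMethod("show", "GenomeBundle", function(object) {
  cat("GenomeBundle:", object@strainId, "\n")
  w <- Biostrings::width(object@replicons)
  cat(sprintf("  %d replicon(s), %s bp total\n", length(w),
              format(sum(w), big.mark = ",")))
  for (i in seq_along(w))
    cat(sprintf("    %s (%s, %s bp)\n", names(object@replicons)[i],
                object@topology[i], format(w[i], big.mark = ",")))
  k <- table(S4Vectors::mcols(object@features)$kind)
  cat("  features:", paste(sprintf("%s=%d", names(k), k), collapse = " "), "\n")
})

#' Pangenome: cross-strain homology groups
#'
#' Groups are rows of the \code{groups} data.frame: \code{group_id}, one
#' locus-tag column per strain (\code{NA} where absent), \code{kind},
#' \code{classification} (core / accessory / unique), \code{n_members},
#' \code{nt_identity_pct} and \code{aa_identity_pct} (NA for non-CDS groups).
#'
#' @slot groups data.frame, one row per homology group.
#' @slot strainIds character vector of the strains compared.
#' @exportClass Pangenome
setClass("Pangenome",
         representation(groups = "data.frame", strainIds = "character"))

validPangenome <- function(object) {
  g <- object@groups
  msgs <- character(0)
  need <- c("group_id", object@strainIds, "kind", "classification",
            "n_members", "nt_identity_pct", "aa_identity_pct")
  if (length(setdiff(need, colnames(g))))
    msgs <- c(msgs, "groups table missing required columns")
  else {
    if (anyDuplicated(g$group_id)) msgs <- c(msgs, "duplicate group_id")
    m <- rowSums(!is.na(as.matrix(g[, object@strainIds, drop = FALSE])))
    if (any(m < 1L)) msgs <- c(msgs, "every group needs >= 1 member")
    if (!all(g$n_members == m)) msgs <- c(msgs, "n_members inconsistent")
    cls <- ifelse(m == length(object@strainIds), "core",
                  ifelse(m == 1L, "unique", "accessory"))
    if (!all(g$classification == cls))
      msgs <- c(msgs, "classification inconsistent with membership")
    id <- g$nt_identity_pct
    if (any(!is.na(id) & (id < 0 | id > 100)))
      msgs <- c(msgs, "nt identity outside [0,100]")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("Pangenome", validPangenome)

#' @describeIn Pangenome-accessors groups table
#' @param x a \linkS4class{Pangenome}.
#' @name Pangenome-accessors
#' @export
pangenomeGroups <- function(x) x@groups

#' @describeIn Pangenome-accessors strain ids
#' @export
pangenomeStrains <- function(x) x@strainIds

#' @describeIn Pangenome-accessors size counts: pangenome size, core size,
#'   per-strain unique counts
#' @export
pangenomeCounts <- function(x) {
  g <- x@groups
  uniq <- vapply(x@strainIds, function(s)
    sum(g$classification == "unique" & !is.na(g[[s]])), integer(1))
  list(pangenome_size = nrow(g),
       core_size = sum(g$classification == "core"),
       unique_counts = uniq)
}

setMethod("show", "Pangenome", function(object) {
  ct <- pangenomeCounts(object)
  cat("Pangenome of", length(object@strainIds), "strains:",
      ct$pangenome_size, "groups,", ct$core_size, "core\n")
  cat("  unique per strain:",
      paste(sprintf("%s=%d", names(ct$unique_counts), ct$unique_counts),
            collapse = " "), "\n")
})
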