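# Derive a strain genome from the synthetic ancestor by applying, in a fixed
# order, substitutions -> indels -> inversion -> prophage insertion ->
# plasmid events -> CRISPR array -> unique gene blocks -> annotation tweaks.
# Every sequence-touching primitive is appended to a replayable script and
# every recorded truth coordinate is kept current as later events shift the
# frame, so detectors can be scored against the log without re-inspecting
# sequence.

compMap <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Branch parameters for deriving one strain from the ancestor
#'
#' @param strainId label for the derived strain.
#' @param snpRate substitutions per site, in [0, 0.1].
#' @param indelRate indel events per site, in [0, 0.1]; lengths 1-12 bp,
#'   geometric.
#' @param pNonsyn fraction of coding substitutions drawn as amino-acid
#'   changing (missense or nonsense); the rest are synonymous.
#' @param invert optional \code{list(approxLength)}: plant one inversion
#'   bounded by planted HIP1 octamers, targeting the given length.
#' @param prophage optional \code{list(anchorTrnaIndex, elementLength,
#'   attLen = 60, nCargo, cargoCategories, elementSeed, key)}: insert a
#'   prophage immediately 3' of the anchor tRNA so that both element flanks
#'   carry an exact copy of the tRNA's terminal \code{attLen} bases. Strains
#'   given the same \code{elementSeed}/\code{key} receive an identical
#'   element.
#' @param plasmidEvents list of plasmid events, each \code{list(type =
#'   "lose"|"gain"|"fuse", ...)}; see the package vignette.
#' @param crispr optional \code{list(replicon, repeatLen, nSpacers,
#'   spacerLen, seed)}: insert a CRISPR repeat-spacer array.
#' @param uniqueGeneBlocks list of \code{list(nGenes, categories)} blocks of
#'   strain-unique genes inserted into chromosome intergenic space.
#' @param annotationTweaks \code{list(truncateStarts = data.frame(gene_id,
#'   offset), dropNcrna = FALSE)}: annotation-only changes used to exercise
#'   consensus reconciliation.
#' @param seed RNG seed for this branch.
#' @return a \code{BranchParams} list.
#' @export
branchParams <- function(strainId, snpRate = 0, indelRate = 0, pNonsyn = 0.2,
                         invert = NULL, prophage = NULL,
                         plasmidEvents = list(), crispr = NULL,
                         uniqueGeneBlocks = list(),
                         annotationTweaks = list(), seed = 1L) {
  stopifnot(snpRate >= 0, snpRate <= 0.1, indelRate >= 0, indelRate <= 0.1,
            pNonsyn >= 0, pNonsyn <= 1)
  if (!is.null(prophage)) {
    prophage$attLen <- prophage$attLen %||% 60L
    prophage$nCargo <- prophage$nCargo %||% 8L
    prophage$cargoCategories <- prophage$cargoCategories %||%
      c(mobilome = 0.7, defense = 0.2, unknown = 0.1)
    stopifnot(prophage$attLen >= 15L, prophage$elementLength >= 5000L,
              !is.null(prophage$anchorTrnaIndex))
    prophage$elementSeed <- prophage$elementSeed %||% 777L
    prophage$key <- prophage$key %||% as.character(prophage$elementSeed)
  }
  structure(list(strainId = strainId, snpRate = snpRate,
                 indelRate = indelRate, pNonsyn = pNonsyn, invert = invert,
                 prophage = prophage, plasmidEvents = plasmidEvents,
                 crispr = crispr, uniqueGeneBlocks = uniqueGeneBlocks,
                 annotationTweaks = annotationTweaks,
                 seed = as.integer(seed)),
            class = "BranchParams")
}

# ---- state primitives ----------------------------------------------------

emptyTruth <- function(strain) {
  list(strain = strain,
       snps = data.frame(replicon = character(0), pos = integer(0),
                         anc_pos = integer(0), ref = character(0),
                         alt = character(0), gene_id = character(0),
                         effect = character(0), aa_change = character(0),
                         stringsAsFactors = FALSE),
       indels = data.frame(replicon = character(0), pos = integer(0),
                           anc_pos = integer(0), len = integer(0),
                           type = character(0), seq = character(0),
                           gene_id = character(0), effect = character(0),
                           stringsAsFactors = FALSE),
       inversions = data.frame(replicon = character(0), start = integer(0),
                               end = integer(0), anc_start = integer(0),
                               anc_end = integer(0),
                               boundary_hip1 = logical(0),
                               stringsAsFactors = FALSE),
       prophages = data.frame(replicon = character(0),
                              anchor_gene_id = character(0),
                              attL_start = integer(0), attL_end = integer(0),
                              elem_start = integer(0), elem_end = integer(0),
                              attR_start = integer(0), attR_end = integer(0),
                              att_len = integer(0), elem_len = integer(0),
                              element_key = character(0),
                              stringsAsFactors = FALSE),
       crisprs = data.frame(replicon = character(0), start = integer(0),
                            end = integer(0), repeat_seq = character(0),
                            n_repeats = integer(0), stringsAsFactors = FALSE),
       crisprSpacers = list(),
       uniqueBlocks = data.frame(replicon = character(0), start = integer(0),
                                 end = integer(0), n_genes = integer(0),
                                 stringsAsFactors = FALSE),
       plasmid = list(),
       annotation = list(
         startAdjust = data.frame(gene_id = character(0),
                                  offset = integer(0),
                                  stringsAsFactors = FALSE),
         droppedNcrna = character(0)),
       duplicatedGeneIds = character(0),
       geneMap = NULL, script = list())
}

truthCoordTables <- function() {
  list(snps = "pos", indels = "pos",
       inversions = c("start", "end"),
       prophages = c("attL_start", "attL_end", "elem_start", "elem_end",
                     "attR_start", "attR_end"),
       crisprs = c("start", "end"), uniqueBlocks = c("start", "end"))
}

updateCoords <- function(state, repl, fn) {
  i <- state$feat$replicon == repl
  if (any(i)) {
    state$feat$start[i] <- fn(state$feat$start[i])
    state$feat$end[i] <- fn(state$feat$end[i])
  }
  j <- state$hip1$replicon == repl
  if (any(j)) state$hip1$pos[j] <- fn(state$hip1$pos[j])
  for (tb in names(truthCoordTables())) {
    df <- state$truth[[tb]]
    k <- df$replicon == repl
    if (any(k))
      for (col in truthCoordTables()[[tb]])
        df[[col]][k] <- fn(df[[col]][k])
    state$truth[[tb]] <- df
  }
  state
}

pushScript <- function(state, rec) {
  state$truth$script[[length(state$truth$script) + 1L]] <- rec
  state
}

opSub <- function(state, repl, pos, alt) {
  state$seqs[[repl]][pos] <- alt
  pushScript(state, list(op = "sub", replicon = repl, pos = pos,
                         alt = paste(alt, collapse = "")))
}

opDel <- function(state, repl, pos, len) {
  state$seqs[[repl]] <- state$seqs[[repl]][-(pos:(pos + len - 1L))]
  state <- pushScript(state, list(op = "del", replicon = repl, pos = pos,
                                  len = len))
  updateCoords(state, repl, function(x)
    ifelse(x >= pos + len, x - len, ifelse(x >= pos, pos - 1L, x)))
}

opIns <- function(state, repl, pos, chars) {
  state$seqs[[repl]] <- append(state$seqs[[repl]], chars, after = pos)
  state <- pushScript(state, list(op = "ins", replicon = repl, pos = pos,
                                  seq = paste(chars, collapse = "")))
  len <- length(chars)
  updateCoords(state, repl, function(x) ifelse(x > pos, x + len, x))
}

opInv <- function(state, repl, s, e) {
  v <- state$seqs[[repl]]
  seg <- rev(unname(compMap[v[s:e]]))
  v[s:e] <- seg
  state$seqs[[repl]] <- v
  state <- pushScript(state, list(op = "inv", replicon = repl, s = s, e = e))

  i <- which(state$feat$replicon == repl)
  fs <- state$feat$start[i]; fe <- state$feat$end[i]
  inside <- fs >= s & fe <= e
  cross <- (fs < s & fe >= s) | (fs <= e & fe > e)
  if (any(cross)) stopf("inversion boundary crosses a feature")
  if (any(inside)) {
    ii <- i[inside]
    ns <- s + e - state$feat$end[ii]
    ne <- s + e - state$feat$start[ii]
    state$feat$start[ii] <- ns
    state$feat$end[ii] <- ne
    state$feat$strand[ii] <- ifelse(state$feat$strand[ii] == "+", "-", "+")
  }
  j <- which(state$hip1$replicon == repl & state$hip1$pos >= s &
               state$hip1$pos <= e)
  # octamer start position reflects to s+e-(pos+7)
  state$hip1$pos[j] <- s + e - (state$hip1$pos[j] + 7L)
  k <- which(state$truth$snps$replicon == repl & state$truth$snps$pos >= s &
               state$truth$snps$pos <= e)
  if (length(k)) {
    state$truth$snps$pos[k] <- s + e - state$truth$snps$pos[k]
    state$truth$snps$ref[k] <- unname(compMap[state$truth$snps$ref[k]])
    state$truth$snps$alt[k] <- unname(compMap[state$truth$snps$alt[k]])
  }
  state
}

opDropRep <- function(state, name) {
  state$seqs[[name]] <- NULL
  state$topo <- state$topo[names(state$topo) != name]
  state$feat <- state$feat[state$feat$replicon != name, , drop = FALSE]
  state$hip1 <- state$hip1[state$hip1$replicon != name, , drop = FALSE]
  for (tb in names(truthCoordTables()))
    state$truth[[tb]] <-
      state$truth[[tb]][state$truth[[tb]]$replicon != name, , drop = FALSE]
  pushScript(state, list(op = "drop_replicon", replicon = name))
}

opAddRep <- function(state, name, chars, topo = "circular") {
  state$seqs[[name]] <- chars
  state$topo[name] <- topo
  pushScript(state, list(op = "add_replicon", replicon = name,
                         seq = paste(chars, collapse = ""), topology = topo))
}

opRenameRep <- function(state, old, new) {
  names(state$seqs)[names(state$seqs) == old] <- new
  names(state$topo)[names(state$topo) == old] <- new
  state$feat$replicon[state$feat$replicon == old] <- new
  state$hip1$replicon[state$hip1$replicon == old] <- new
  for (tb in names(truthCoordTables())) {
    df <- state$truth[[tb]]
    df$replicon[df$replicon == old] <- new
    state$truth[[tb]] <- df
  }
  pushScript(state, list(op = "rename_replicon", replicon = old, new = new))
}

#' Re-apply a strain truth log's event script to the ancestor
#'
#' Folds the recorded sequence-level operations over the ancestor replicons;
#' the result must reproduce the derived genome byte for byte.
#'
#' @param ancestor result of \code{\link{generateAncestor}}.
#' @param truth a strain truth log from \code{\link{deriveStrain}}.
#' @return named character vector of replicon sequences.
#' @export
replayTruth <- function(ancestor, truth) {
  seqs <- lapply(as.character(replicons(ancestor$bundle)),
                 function(s) strsplit(s, "", fixed = TRUE)[[1]])
  names(seqs) <- names(replicons(ancestor$bundle))
  for (rec in truth$script) {
    switch(rec$op,
      sub = { seqs[[rec$replicon]][rec$pos] <-
                strsplit(rec$alt, "", fixed = TRUE)[[1]] },
      del = { seqs[[rec$replicon]] <-
                seqs[[rec$replicon]][-(rec$pos:(rec$pos + rec$len - 1L))] },
      ins = { seqs[[rec$replicon]] <-
                append(seqs[[rec$replicon]],
                       strsplit(rec$seq, "", fixed = TRUE)[[1]],
                       after = rec$pos) },
      inv = { v <- seqs[[rec$replicon]]
              v[rec$s:rec$e] <- rev(unname(compMap[v[rec$s:rec$e]]))
              seqs[[rec$replicon]] <- v },
      drop_replicon = { seqs[[rec$replicon]] <- NULL },
      add_replicon = { seqs[[rec$replicon]] <-
                         strsplit(rec$seq, "", fixed = TRUE)[[1]] },
      rename_replicon = { names(seqs)[names(seqs) == rec$replicon] <-
                            rec$new },
      stopf("unknown script op: %s", rec$op))
  }
  vapply(seqs, paste, "", collapse = "")
}
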