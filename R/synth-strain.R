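# deriveStrain: orchestrates the fixed event order and finalizes the bundle;
# makeStudyPanel: the six-strain fixture mirroring a panel of five
# near-identical laboratory strains plus one divergent environmental isolate.

initState <- function(ancestor, strainId) {
  seqs <- lapply(as.character(replicons(ancestor$bundle)),
                 function(s) strsplit(s, "", fixed = TRUE)[[1]])
  names(seqs) <- names(replicons(ancestor$bundle))
  g <- ancestor$genes
  feat <- data.frame(gene_id = g$gene_id, replicon = g$replicon,
                     start = g$start, end = g$end, strand = g$strand,
                     kind = g$kind, product = g$product,
                     transcribed = g$transcribed, essential = g$essential,
                     categories = g$category, origin = "ancestral",
                     stringsAsFactors = FALSE)
  hip <- do.call(rbind, lapply(names(ancestor$hip1), function(r)
    if (length(ancestor$hip1[[r]]))
      data.frame(replicon = r, pos = ancestor$hip1[[r]],
                 anc_pos = ancestor$hip1[[r]], stringsAsFactors = FALSE)))
  if (is.null(hip))
    hip <- data.frame(replicon = character(0), pos = integer(0),
                      anc_pos = integer(0), stringsAsFactors = FALSE)
  list(strain = strainId, seqs = seqs,
       topo = topology(ancestor$bundle), feat = feat, hip1 = hip,
       truth = emptyTruth(strainId))
}

#' Derive one strain genome from the synthetic ancestor
#'
#' Events are applied in a fixed order (substitutions, indels, inversion,
#' prophage insertion, plasmid events, CRISPR array, unique gene blocks,
#' annotation tweaks); the returned truth log records every event with
#' coordinates in both the ancestor frame (where defined) and the derived
#' frame, plus a replayable script of sequence operations
#' (\code{\link{replayTruth}}).
#'
#' @param ancestor result of \code{\link{generateAncestor}}.
#' @param params a \code{\link{branchParams}} object.
#' @return list with \code{bundle} (\linkS4class{GenomeBundle}) and
#'   \code{truth} (strain truth log).
#' @export
deriveStrain <- function(ancestor, params) {
  stopifnot(inherits(ancestor, "AncestorGenome"),
            inherits(params, "BranchParams"))
  set.seed(params$seed)
  state <- initState(ancestor, params$strainId)

  trna <- ancestor$genes[ancestor$genes$kind == "tRNA", , drop = FALSE]
  invPlan <- NULL
  if (!is.null(params$invert))
    invPlan <- planInversion(ancestor, params$invert$approxLength,
                             avoid = trna)

  snpMask <- data.frame(replicon = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  indelMask <- snpMask
  if (!is.null(params$prophage)) {
    ai <- params$prophage$anchorTrnaIndex
    if (ai < 1L || ai > nrow(trna))
      stopf("anchor tRNA index out of range: %d (have %d tRNAs)",
            ai, nrow(trna))
    at <- trna[ai, ]
    attLen <- params$prophage$attLen
    attIv <- if (at$strand == "+")
      data.frame(replicon = at$replicon, start = at$end - attLen + 1L,
                 end = at$end, stringsAsFactors = FALSE)
    else
      data.frame(replicon = at$replicon, start = at$start,
                 end = at$start + attLen - 1L, stringsAsFactors = FALSE)
    snpMask <- rbind(snpMask, attIv)
  }
  if (!is.null(invPlan)) {
    octs <- data.frame(replicon = "chr",
                       start = c(invPlan$anc_s, invPlan$anc_e - 7L) - 2L,
                       end = c(invPlan$anc_s + 7L, invPlan$anc_e) + 2L,
                       stringsAsFactors = FALSE)
    snpMask <- rbind(snpMask, octs)
    indelMask <- rbind(indelMask,
                       data.frame(replicon = "chr",
                                  start = invPlan$anc_s - 10L,
                                  end = invPlan$anc_e + 10L,
                                  stringsAsFactors = FALSE))
  }

  state <- plantSnps(state, params$snpRate, params$pNonsyn, snpMask)
  state <- plantIndels(state, params$indelRate,
                       rbind(indelMask, snpMask))

  if (!is.null(invPlan)) {
    s <- state$hip1$pos[state$hip1$replicon == "chr" &
                          state$hip1$anc_pos == invPlan$anc_s]
    e <- state$hip1$pos[state$hip1$replicon == "chr" &
                          state$hip1$anc_pos == invPlan$anc_e - 7L] + 7L
    state <- plantInversion(state, list(s = s, e = e,
                                        anc_s = invPlan$anc_s,
                                        anc_e = invPlan$anc_e))
  }
  if (!is.null(params$prophage))
    state <- plantProphage(state, params$prophage, trna$gene_id)
  if (length(params$plasmidEvents))
    state <- plantPlasmidEvents(state, params$plasmidEvents)
  if (!is.null(params$crispr))
    state <- plantCrispr(state, params$crispr)
  if (length(params$uniqueGeneBlocks))
    state <- plantUniqueBlocks(state, params$uniqueGeneBlocks,
                               params$strainId)

  tw <- params$annotationTweaks
  if (!is.null(tw$truncateStarts) && nrow(tw$truncateStarts)) {
    for (i in seq_len(nrow(tw$truncateStarts))) {
      gidx <- which(state$feat$gene_id == tw$truncateStarts$gene_id[i])
      if (!length(gidx)) stopf("truncateStarts: unknown gene_id")
      off <- tw$truncateStarts$offset[i]
      if (state$feat$strand[gidx] == "+")
        state$feat$start[gidx] <- state$feat$start[gidx] + off
      else state$feat$end[gidx] <- state$feat$end[gidx] - off
    }
    state$truth$annotation$startAdjust <- tw$truncateStarts
  }
  if (isTRUE(tw$dropNcrna)) {
    drop <- state$feat$kind == "ncRNA"
    state$truth$annotation$droppedNcrna <- state$feat$gene_id[drop]
    state$feat <- state$feat[!drop, , drop = FALSE]
  }

  finalizeStrain(state)
}

finalizeStrain <- function(state) {
  feat <- state$feat
  ord <- order(match(feat$replicon, names(state$seqs)), feat$start,
               feat$gene_id)
  feat <- feat[ord, , drop = FALSE]
  feat$locus_tag <- sprintf("%s_%04d", state$strain, seq_len(nrow(feat)))
  seqs <- vapply(state$seqs, paste, "", collapse = "")
  ft <- GenomicRanges::GRanges(
    seqnames = factor(feat$replicon, levels = names(seqs)),
    ranges = IRanges::IRanges(feat$start, feat$end), strand = feat$strand)
  S4Vectors::mcols(ft) <- S4Vectors::DataFrame(
    locus_tag = feat$locus_tag, kind = feat$kind, product = feat$product,
    transcribed = feat$transcribed, essential = feat$essential,
    categories = feat$categories)
  bundle <- GenomeBundle(state$strain, seqs, state$topo[names(seqs)], ft)
  truth <- state$truth
  truth$geneMap <- feat[, c("gene_id", "locus_tag", "replicon", "start",
                            "end", "strand", "kind", "origin", "categories")]
  rownames(truth$geneMap) <- NULL
  truth$hip1 <- state$hip1
  class(truth) <- "StrainTruth"
  list(bundle = bundle, truth = truth)
}

# choose the HIP1 pair bounding the inversion; pairs whose span contains a
# tRNA (future prophage anchor) are excluded so anchors keep their strand
planInversion <- function(ancestor, approxLength, avoid = NULL) {
  hp <- sort(ancestor$hip1[["chr"]])
  if (length(hp) < 2L) stopf("not enough planted HIP1 octamers for inversion")
  cand <- expand.grid(i = seq_along(hp), j = seq_along(hp))
  cand <- cand[hp[cand$i] > hp[cand$j], , drop = FALSE]
  if (!is.null(avoid) && nrow(avoid)) {
    ok <- vapply(seq_len(nrow(cand)), function(r) {
      s <- hp[cand$j[r]]; e <- hp[cand$i[r]] + 7L
      av <- avoid[avoid$replicon == "chr", , drop = FALSE]
      !any(av$start >= s & av$end <= e)
    }, TRUE)
    cand <- cand[ok, , drop = FALSE]
  }
  if (!nrow(cand)) stopf("no usable HIP1 pair for inversion")
  d <- hp[cand$i] + 7L - hp[cand$j]
  best <- which.min(abs(d - approxLength))
  list(anc_s = hp[cand$j[best]], anc_e = hp[cand$i[best]] + 7L)
}

#' Generate the six-strain study panel with its truth log
#'
#' Five near-identical "laboratory" strains (pairwise divergence ~0.1%) and
#' one divergent "environmental" strain (~1.5% to the others). The
#' laboratory strains share one prophage (anchored in a tRNA, 60-bp att
#' duplication); two of them carry a HIP1-bounded chromosomal inversion; the
#' environmental strain carries a different prophage at a different tRNA,
#' loses the small plasmid, fuses the large plasmid with an expanded region
#' bounded by a duplicated flanking gene pair, gains a small plasmid with a
#' CRISPR repeat-spacer array, and carries strain-unique gene blocks
#' enriched in mobilome/defense/motility categories. Annotation
#' discrepancies (truncated start codons, an ncRNA annotated in one strain
#' only, untranscribed hypothetical genes) are planted for the consensus
#' annotation module.
#'
#' @param seed integer seed; the panel is deterministic given the seed.
#' @param config optional \code{\link{ancestorConfig}} override.
#' @return list with \code{ancestor}, \code{bundles} (named list of six
#'   \linkS4class{GenomeBundle}s, first one the reference), \code{truths}
#'   (named list of strain truth logs) and \code{params}.
#' @export
makeStudyPanel <- function(seed = 1L, config = NULL) {
  cfg <- config %||% ancestorConfig(seed = seed)
  anc <- generateAncestor(cfg)

  cdsChr <- anc$genes[anc$genes$kind == "CDS" & anc$genes$replicon == "chr" &
                        !anc$genes$unsupported, ]
  truncTargets <- cdsChr$gene_id[c(10L, 25L, 40L)]
  trunc2 <- data.frame(gene_id = truncTargets[1:2], offset = 9L,
                       stringsAsFactors = FALSE)
  trunc3 <- data.frame(gene_id = truncTargets, offset = 9L,
                       stringsAsFactors = FALSE)

  legacyPhage <- list(anchorTrnaIndex = 3L, elementLength = 12000L,
                      attLen = 60L, nCargo = 8L, elementSeed = 4242L,
                      key = "legacy")
  envPhage <- list(anchorTrnaIndex = 5L, elementLength = 18000L,
                   attLen = 60L, nCargo = 12L, elementSeed = 5151L,
                   key = "env",
                   cargoCategories = c(mobilome = 0.6, defense = 0.3,
                                       unknown = 0.1))
  labRate <- 5e-4; labIndel <- 2e-5

  mk <- function(...) branchParams(...)
  plist <- list(
    mk("LAB1", labRate, labIndel, invert = list(approxLength = 20000L),
       prophage = legacyPhage, seed = seed + 1L * 1009L),
    mk("LAB2", labRate, labIndel, invert = list(approxLength = 20000L),
       prophage = legacyPhage,
       annotationTweaks = list(truncateStarts = trunc2, dropNcrna = TRUE),
       seed = seed + 2L * 1009L),
    mk("LAB3", labRate, labIndel, prophage = legacyPhage,
       annotationTweaks = list(dropNcrna = TRUE), seed = seed + 3L * 1009L),
    mk("LAB4", labRate, labIndel, prophage = legacyPhage,
       annotationTweaks = list(truncateStarts = trunc3, dropNcrna = TRUE),
       seed = seed + 4L * 1009L),
    mk("LAB5", labRate, labIndel, prophage = legacyPhage,
       annotationTweaks = list(dropNcrna = TRUE), seed = seed + 5L * 1009L),
    mk("ENV1", 1.45e-2, 1e-4, prophage = envPhage,
       plasmidEvents = list(
         list(type = "lose", name = "pSM"),
         list(type = "fuse", name = "pLA", newName = "pMALx",
              nGenes = 15L, length = 18000L, seed = 6161L),
         list(type = "gain", name = "pMAS", length = 12000L, nGenes = 8L,
              seed = 7171L)),
       crispr = list(replicon = "pMAS", repeatLen = 32L, nSpacers = 4L,
                     spacerLen = 34L, seed = 8181L),
       uniqueGeneBlocks = list(
         list(nGenes = 20L, categories = c(mobilome = 0.5, defense = 0.3,
                                           motility = 0.2)),
         list(nGenes = 15L, categories = c(motility = 0.6, membrane = 0.2,
                                           cell_cycle = 0.2))),
       annotationTweaks = list(dropNcrna = TRUE), seed = seed + 6L * 1009L))

  out <- lapply(plist, function(p) deriveStrain(anc, p))
  names(out) <- vapply(plist, function(p) p$strainId, "")
  list(ancestor = anc,
       bundles = lapply(out, `[[`, "bundle"),
       truths = lapply(out, `[[`, "truth"),
       params = plist)
}

#' Write a strain truth log as TSV tables plus a JSON summary
#'
#' @param truth a strain truth log.
#' @param outDir output directory.
#' @return invisibly, the paths written.
#' @export
writeTruthLog <- function(truth, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character(0)
  for (tb in c("snps", "indels", "inversions", "prophages", "crisprs",
               "uniqueBlocks", "geneMap")) {
    df <- truth[[tb]]
    if (is.null(df)) next
    p <- file.path(outDir, sprintf("%s_%s.tsv", truth$strain, tb))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  js <- file.path(outDir, sprintf("%s_truth.json", truth$strain))
  jsonlite::write_json(
    list(strain = truth$strain,
         n_snps = nrow(truth$snps), n_indels = nrow(truth$indels),
         prophages = truth$prophages, inversions = truth$inversions,
         crisprs = truth$crisprs, crispr_spacers = truth$crisprSpacers,
         plasmid_events = truth$plasmid,
         annotation = truth$annotation),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, js))
}
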