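# Synthetic ancestral genome: an ORF-packed chromosome plus plasmids, with
# planted HIP1 octamers, tRNA genes, category labels and evidence flags.
# Everything downstream (strain derivation, every detector test) keys off the
# truth tables built here.

HIP1 <- "GCGATCGC"

defaultCategoryAlphabet <- function() {
  c(metabolism = 0.20, energy = 0.12, translation = 0.10,
    transcription = 0.08, membrane = 0.10, signal_transduction = 0.08,
    circadian = 0.04, motility = 0.05, defense = 0.05, cell_cycle = 0.05,
    mobilome = 0.03, unknown = 0.10)
}

#' Configuration for the synthetic ancestor genome
#'
#' Defaults describe a scaled-down freshwater cyanobacterium: one chromosome
#' plus a large and a small plasmid, ~55% GC, HIP1 octamers planted in
#' intergenic space at a per-kb rate, and COG-like category labels.
#'
#' @param chromosomeLength chromosome length, bp.
#' @param nGenes protein-coding genes on the chromosome.
#' @param nTrna tRNA genes on the chromosome.
#' @param gcFraction GC content of intergenic background in (0,1).
#' @param hip1Rate planted HIP1 octamers per kb (Poisson rate).
#' @param plasmidSpecs list of \code{list(name, length, nGenes)}.
#' @param categoryAlphabet named sampling weights for gene category labels.
#' @param nUnsupportedHypothetical planted CDS genes annotated
#'   "hypothetical protein" with no transcription evidence anywhere.
#' @param plantPseudogene plant one untranscribed pseudogene-kind gene.
#' @param plantNcrna plant one intergenic ncRNA with transcription and
#'   essentiality evidence.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return an \code{AncestorConfig} list.
#' @export
ancestorConfig <- function(chromosomeLength = 150000L, nGenes = 120L,
                           nTrna = 6L, gcFraction = 0.55, hip1Rate = 0.8,
                           plasmidSpecs = list(
                             list(name = "pLA", length = 40000L, nGenes = 28L),
                             list(name = "pSM", length = 8000L, nGenes = 5L)),
                           categoryAlphabet = defaultCategoryAlphabet(),
                           nUnsupportedHypothetical = 3L,
                           plantPseudogene = TRUE, plantNcrna = TRUE,
                           seed = 1L) {
  cfg <- list(chromosomeLength = as.integer(chromosomeLength),
              nGenes = as.integer(nGenes), nTrna = as.integer(nTrna),
              gcFraction = gcFraction, hip1Rate = hip1Rate,
              plasmidSpecs = plasmidSpecs,
              categoryAlphabet = categoryAlphabet,
              nUnsupportedHypothetical = as.integer(nUnsupportedHypothetical),
              plantPseudogene = plantPseudogene, plantNcrna = plantNcrna,
              seed = as.integer(seed))
  stopifnot(cfg$chromosomeLength > 0, cfg$nGenes >= 0, cfg$nTrna >= 0,
            cfg$hip1Rate >= 0, gcFraction > 0, gcFraction < 1)
  for (p in plasmidSpecs) stopifnot(p$length > 0, p$nGenes >= 0)
  class(cfg) <- "AncestorConfig"
  cfg
}

# sample one open reading frame: ATG + non-stop codons + stop
makeOrf <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  codons <- names(codonTable())
  sense <- codons[codonTable() != "*"]
  body <- sample(sense[sense != "ATG"], len / 3L - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# pack genes into one replicon; returns sequence string + feature rows +
# intergenic gap table + planted HIP1 positions
packReplicon <- function(name, length, geneLens, kinds, strands, gc,
                         hip1Rate, minGap = 30L) {
  n <- length(geneLens)
  slack <- length - sum(geneLens) - minGap * (n + 1L)
  if (slack < 0L)
    stopf("infeasible packing: %d genes of %d bp do not fit in %d bp (%s)",
          n, sum(geneLens), length, name)
  extra <- if (n >= 0L && slack > 0L)
    as.vector(rmultinom(1L, slack, rep(1, n + 1L))) else rep(0L, n + 1L)
  gaps <- minGap + extra

  pieces <- character(2L * n + 1L)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n + 1L)) {
    pieces[2L * i - 1L] <- randDna(gaps[i], gc)
    pos <- pos + gaps[i]
    if (i <= n) {
      g <- if (kinds[i] %in% c("CDS", "pseudogene")) makeOrf(geneLens[i])
           else randDna(geneLens[i], gc)
      if (strands[i] == "-") g <- revcompChr(g)
      pieces[2L * i] <- g
      starts[i] <- pos + 1L
      ends[i] <- pos + geneLens[i]
      pos <- pos + geneLens[i]
    }
  }
  seq <- paste(pieces, collapse = "")

  # HIP1 octamers, intergenic only, non-overlapping
  nHip <- rpois(1L, hip1Rate * length / 1000L)
  gapStarts <- c(1L, ends + 1L)
  gapEnds <- c(starts - 1L, length)
  gapOk <- (gapEnds - gapStarts + 1L) >= 10L
  hip <- integer(0)
  if (nHip > 0L && any(gapOk)) {
    cand <- unlist(lapply(which(gapOk), function(i)
      seq.int(gapStarts[i] + 1L, gapEnds[i] - 8L)))
    cand <- cand[cand >= 1L]
    tries <- 0L
    while (length(hip) < nHip && length(cand) && tries < 20L * nHip) {
      p <- sample(cand, 1L)
      if (!length(hip) || min(abs(hip - p)) >= 8L) hip <- c(hip, p)
      tries <- tries + 1L
    }
    hip <- sort(hip)
    for (p in hip) substr(seq, p, p + 7L) <- HIP1
  }
  list(seq = seq, starts = starts, ends = ends, hip1 = hip)
}

#' Generate the synthetic ancestor genome
#'
#' Deterministic given \code{config$seed}. Genes are intact ORFs (bacterial
#' code); tRNAs are 70-90 bp on the plus strand; HIP1 octamers are planted in
#' intergenic space at the configured per-kb rate; every gene carries a
#' category label and evidence flags.
#'
#' @param config an \code{\link{ancestorConfig}}.
#' @return list with \code{bundle} (a \linkS4class{GenomeBundle} for strain
#'   "ancestor"), \code{genes} (truth gene table keyed by stable
#'   \code{gene_id}), \code{hip1} (planted octamer start positions per
#'   replicon) and \code{config}.
#' @export
generateAncestor <- function(config) {
  stopifnot(inherits(config, "AncestorConfig"))
  set.seed(config$seed)

  reps <- c(list(list(name = "chr", length = config$chromosomeLength,
                      nGenes = config$nGenes, nTrna = config$nTrna)),
            lapply(config$plasmidSpecs, function(p)
              list(name = p$name, length = p$length, nGenes = p$nGenes,
                   nTrna = 0L)))

  seqs <- character(0); topo <- character(0)
  genes <- list(); hip1 <- list()
  gid <- 0L
  for (rp in reps) {
    nC <- rp$nGenes; nT <- rp$nTrna
    nNc <- if (rp$name == "chr" && config$plantNcrna) 1L else 0L
    kinds <- c(rep("CDS", nC), rep("tRNA", nT), rep("ncRNA", nNc))
    if (rp$name == "chr" && config$plantPseudogene && nC > 0L)
      kinds[nC] <- "pseudogene"
    n <- length(kinds)
    kinds <- if (n) sample(kinds) else kinds
    lens <- integer(n)
    lens[kinds %in% c("CDS", "pseudogene")] <-
      3L * sample(102:450, sum(kinds %in% c("CDS", "pseudogene")),
                  replace = TRUE)
    lens[kinds == "tRNA"] <- sample(70:90, sum(kinds == "tRNA"),
                                    replace = TRUE)
    lens[kinds == "ncRNA"] <- sample(90:150, sum(kinds == "ncRNA"),
                                     replace = TRUE)
    strands <- ifelse(kinds == "tRNA", "+",
                      sample(c("+", "-"), n, replace = TRUE))
    pk <- packReplicon(rp$name, rp$length, lens, kinds, strands,
                       config$gcFraction, config$hip1Rate)
    seqs[rp$name] <- pk$seq
    topo[rp$name] <- "circular"
    hip1[[rp$name]] <- pk$hip1
    if (n)
      genes[[rp$name]] <- data.frame(
        gene_id = sprintf("anc_%04d", gid + seq_len(n)),
        replicon = rp$name, start = pk$starts, end = pk$ends,
        strand = strands, kind = kinds, stringsAsFactors = FALSE)
    gid <- gid + n
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL

  if (!is.null(genes)) {
    n <- nrow(genes)
    genes$category <- sample(names(config$categoryAlphabet), n, replace = TRUE,
                             prob = config$categoryAlphabet)
    genes$transcribed <- runif(n) < 0.9
    genes$essential <- genes$kind == "CDS" & runif(n) < 0.2
    genes$product <- paste("putative", genes$category, "protein")
    genes$product[genes$kind == "tRNA"] <- "tRNA"
    genes$product[genes$kind == "ncRNA"] <- "noncoding RNA"
    # hypothetical annotations: only transcribed ones, except the planted
    # unsupported set below
    hypo <- which(genes$kind == "CDS" & genes$transcribed & !genes$essential)
    hypo <- utils::head(hypo, 8L)
    genes$product[hypo] <- "hypothetical protein"

    genes$unsupported <- FALSE
    cdsChr <- which(genes$kind == "CDS" & genes$replicon == "chr" &
                      !genes$essential)
    cdsChr <- setdiff(cdsChr, hypo)
    uns <- utils::head(cdsChr, config$nUnsupportedHypothetical)
    genes$product[uns] <- "hypothetical protein"
    genes$transcribed[uns] <- FALSE
    genes$essential[uns] <- FALSE
    genes$unsupported[uns] <- TRUE
    ps <- which(genes$kind == "pseudogene")
    genes$transcribed[ps] <- FALSE
    genes$essential[ps] <- FALSE
    genes$unsupported[ps] <- TRUE
    nc <- which(genes$kind == "ncRNA")
    genes$transcribed[nc] <- TRUE
    genes$essential[nc] <- TRUE
  } else {
    genes <- data.frame(gene_id = character(0), replicon = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), kind = character(0),
                        category = character(0), transcribed = logical(0),
                        essential = logical(0), product = character(0),
                        unsupported = logical(0), stringsAsFactors = FALSE)
  }

  ft <- ancestorFeatures(genes, names(seqs))
  bundle <- GenomeBundle("ancestor", seqs, topo[names(seqs)], ft)
  structure(list(bundle = bundle, genes = genes, hip1 = hip1,
                 config = config),
            class = "AncestorGenome")
}

# gene truth table -> feature GRanges (locus_tag = gene_id for the ancestor)
ancestorFeatures <- function(genes, repNames) {
  if (!nrow(genes)) return(NULL)
  ft <- GenomicRanges::GRanges(
    seqnames = factor(genes$replicon, levels = repNames),
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(ft) <- S4Vectors::DataFrame(
    locus_tag = genes$gene_id, kind = genes$kind, product = genes$product,
    transcribed = genes$transcribed, essential = genes$essential,
    categories = genes$category)
  ft
}
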