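# Shared fixtures, built once per test run and cached. The study panel and
# its derived objects are deterministic for the fixed seed below.

.fixtures <- new.env(parent = emptyenv())

panelSeed <- 42L

getPanel <- function() {
  if (is.null(.fixtures$panel))
    .fixtures$panel <- makeStudyPanel(seed = panelSeed)
  .fixtures$panel
}

getPangenome <- function() {
  if (is.null(.fixtures$pangenome))
    .fixtures$pangenome <- buildPangenome(getPanel()$bundles)
  .fixtures$pangenome
}

getPanelCalls <- function() {
  if (is.null(.fixtures$calls))
    .fixtures$calls <- callPanelVariants(getPangenome(),
                                         getPanel()$bundles)
  .fixtures$calls
}

getReconciled <- function() {
  if (is.null(.fixtures$reconciled))
    .fixtures$reconciled <- reconcileAnnotations(getPangenome(),
                                                 getPanel()$bundles)
  .fixtures$reconciled
}

# a tiny two-gene bundle for fast I/O and ortholog unit tests
tinyBundle <- function(strain = "tiny", seed = 7L) {
  withr::with_seed(seed, {
    g1 <- strainpan:::makeOrf(120L)
    g2 <- strainpan:::makeOrf(90L)
    spacer <- function(n) strainpan:::randDna(n, 0.5)
    seq <- paste0(spacer(40), g1, spacer(50), g2, spacer(40))
    ft <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(c(41L, 41L + 120L + 50L),
                              width = c(120L, 90L)),
      strand = c("+", "-"),
      locus_tag = paste0(strain, c("_g1", "_g2")),
      kind = "CDS", product = c("protein one", "protein two"),
      transcribed = c(TRUE, NA), essential = c(NA, FALSE),
      categories = c("metabolism", "motility,defense"))
    GenomeBundle(strain, c(chr = seq), "circular", ft)
  })
}
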