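# Synthetic genome generator: determinism, planted-event statistics, truth
# log replay, and the structure of planted mobile elements.

test_that("ancestor generation is deterministic given the seed", {
  cfg <- ancestorConfig(chromosomeLength = 30000L, nGenes = 15L,
                        nTrna = 2L, plasmidSpecs = list(), seed = 5L)
  a1 <- generateAncestor(cfg)
  a2 <- generateAncestor(cfg)
  expect_identical(as.character(replicons(a1$bundle)),
                   as.character(replicons(a2$bundle)))
  expect_identical(a1$genes, a2$genes)
  a3 <- generateAncestor(ancestorConfig(chromosomeLength = 30000L,
                                        nGenes = 15L, nTrna = 2L,
                                        plasmidSpecs = list(), seed = 6L))
  expect_false(identical(as.character(replicons(a1$bundle)),
                         as.character(replicons(a3$bundle))))
})

test_that("an ancestor with no genes is valid and empty", {
  cfg <- ancestorConfig(chromosomeLength = 5000L, nGenes = 0L, nTrna = 0L,
                        plasmidSpecs = list(), plantPseudogene = FALSE,
                        plantNcrna = FALSE, nUnsupportedHypothetical = 0L,
                        seed = 3L)
  a <- generateAncestor(cfg)
  expect_equal(length(features(a$bundle)), 0L)
  expect_equal(unname(Biostrings::width(replicons(a$bundle))), 5000L)
})

test_that("infeasible gene packing is a configuration error", {
  cfg <- ancestorConfig(chromosomeLength = 5000L, nGenes = 50L,
                        nTrna = 0L, plasmidSpecs = list(),
                        plantPseudogene = FALSE, plantNcrna = FALSE,
                        nUnsupportedHypothetical = 0L, seed = 3L)
  expect_error(generateAncestor(cfg), "packing")
})

test_that("planted HIP1 count on 100 kb falls in the Poisson 99% band", {
  cfg <- ancestorConfig(chromosomeLength = 100000L, nGenes = 0L,
                        nTrna = 0L, hip1Rate = 1.0, plasmidSpecs = list(),
                        plantPseudogene = FALSE, plantNcrna = FALSE,
                        nUnsupportedHypothetical = 0L, seed = 8L)
  a <- generateAncestor(cfg)
  n <- length(a$hip1[["chr"]])
  expect_gte(n, qpois(0.005, 100))
  expect_lte(n, qpois(0.995, 100))
  # planted octamers are really in the sequence
  chr <- as.character(replicons(a$bundle))[["chr"]]
  expect_true(all(substring(chr, a$hip1$chr, a$hip1$chr + 7L) ==
                    "GCGATCGC"))
})

test_that("truth SNP count matches the binomial 99% band of the rate", {
  cfg <- ancestorConfig(chromosomeLength = 100000L, nGenes = 60L,
                        nTrna = 2L, plasmidSpecs = list(), seed = 9L)
  anc <- generateAncestor(cfg)
  der <- deriveStrain(anc, branchParams("S", snpRate = 0.01, seed = 10L))
  n <- nrow(der$truth$snps)
  expect_gte(n, qbinom(0.005, 100000L, 0.01))
  expect_lte(n, qbinom(0.995, 100000L, 0.01))
})

test_that("replaying the truth script reproduces each panel strain exactly", {
  pan <- getPanel()
  for (s in c("LAB1", "ENV1")) {
    rp <- replayTruth(pan$ancestor, pan$truths[[s]])
    der <- as.character(replicons(pan$bundles[[s]]))
    expect_identical(sort(names(rp)), sort(names(der)))
    expect_identical(rp[names(der)], der)
  }
})

test_that("prophage insertion duplicates exactly the tRNA terminal bases", {
  pan <- getPanel()
  for (s in c("LAB1", "ENV1")) {
    tr <- pan$truths[[s]]$prophages
    chr <- as.character(replicons(pan$bundles[[s]]))[[tr$replicon]]
    attL <- substr(chr, tr$attL_start, tr$attL_end)
    attR <- substr(chr, tr$attR_start, tr$attR_end)
    expect_identical(attL, attR)
    expect_equal(nchar(attL), 60L)
    # exactly two occurrences genome-wide
    hits <- gregexpr(attL, chr, fixed = TRUE)[[1L]]
    expect_equal(length(hits), 2L)
    expect_equal(tr$elem_end - tr$elem_start + 1L, tr$elem_len)
  }
})

test_that("the planted inversion is bounded by HIP1 octamers", {
  pan <- getPanel()
  iv <- pan$truths$LAB1$inversions
  expect_equal(nrow(iv), 1L)
  expect_true(iv$boundary_hip1)
  chr <- as.character(replicons(pan$bundles$LAB1))[["chr"]]
  expect_identical(substr(chr, iv$start, iv$start + 7L), "GCGATCGC")
  expect_identical(substr(chr, iv$end - 7L, iv$end), "GCGATCGC")
})

test_that("an out-of-range prophage anchor is a parameter error", {
  cfg <- ancestorConfig(chromosomeLength = 30000L, nGenes = 10L,
                        nTrna = 2L, plasmidSpecs = list(), seed = 5L)
  anc <- generateAncestor(cfg)
  expect_error(
    deriveStrain(anc, branchParams(
      "S", prophage = list(anchorTrnaIndex = 9L, elementLength = 6000L),
      seed = 1L)),
    "out of range")
})

test_that("the panel carries exactly two distinct prophage elements", {
  pan <- getPanel()
  keys <- unlist(lapply(pan$truths, function(t) t$prophages$element_key))
  expect_equal(length(unique(keys)), 2L)
  expect_setequal(unique(keys), c("legacy", "env"))
})

test_that("different seeds give different panels with the same event plan", {
  p1 <- makeStudyPanel(seed = 101L)
  expect_false(identical(
    as.character(replicons(p1$bundles$LAB1))[["chr"]],
    as.character(replicons(getPanel()$bundles$LAB1))[["chr"]]))
  expect_equal(nrow(p1$truths$LAB1$prophages), 1L)
  expect_equal(nrow(p1$truths$LAB1$inversions), 1L)
  expect_equal(length(Filter(function(x) x$type == "fuse",
                             p1$truths$ENV1$plasmid)), 1L)
})
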