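# Mobile-element detectors: prophage att duplication, HIP1 scan,
# inversions, plasmid comparison, CRISPR arrays.

test_that("HIP1 scan reports every occurrence including overlaps", {
  b <- GenomeBundle("h", c(chr = "GCGATCGC"), "linear")
  s <- scanHip1(b)
  expect_equal(s$sites$pos, 1L)
  b2 <- GenomeBundle("h2", c(chr = "GCGATCGCGATCGC"), "linear")
  expect_equal(scanHip1(b2)$sites$pos, c(1L, 7L))
})

test_that("HIP1 count on random sequence matches the independent-base model", {
  gc <- 0.55
  L <- 100000L
  seq <- withr::with_seed(123L, strainpan:::randDna(L, gc))
  n <- nrow(scanHip1(GenomeBundle("r", c(chr = seq), "linear"))$sites)
  # GCGATCGC: six G/C letters, two A/T letters
  p <- (gc / 2)^6 * ((1 - gc) / 2)^2
  lambda <- (L - 7) * p
  expect_gte(n, qpois(0.005, lambda))
  expect_lte(n, qpois(0.995, lambda))
})

test_that("planted prophages are recovered with exact att boundaries", {
  pan <- getPanel()
  for (s in names(pan$bundles)) {
    calls <- findAttProphages(pan$bundles[[s]])
    ev <- evaluateProphages(calls, pan$truths[[s]])
    expect_equal(ev$recall, 1)
    expect_equal(ev$n_false, 0L)
    expect_true(ev$boundary_exact)
    expect_equal(calls$duplication_len, 60L)
    # att copies byte-identical in every emitted call
    chr <- as.character(replicons(pan$bundles[[s]]))[[calls$replicon]]
    expect_identical(substr(chr, calls$attL_start, calls$attL_end),
                     substr(chr, calls$attR_start, calls$attR_end))
  }
})

test_that("genomes without insertions or tRNAs give no prophage calls", {
  pan <- getPanel()
  expect_equal(nrow(findAttProphages(pan$ancestor$bundle)), 0L)
  noTrna <- GenomeBundle("x", c(chr = strainpan:::randDna(2000, 0.5)),
                         "linear")
  expect_warning(res <- findAttProphages(noTrna), "tRNA")
  expect_equal(nrow(res), 0L)
})

test_that("a duplication below min_att yields no call", {
  withr::local_seed(44L)
  trna <- strainpan:::randDna(80, 0.5)
  dup10 <- substr(trna, 71, 80)
  seq <- paste0(strainpan:::randDna(100, 0.5), trna,
                strainpan:::randDna(6000, 0.5), dup10,
                strainpan:::randDna(200, 0.5))
  ft <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(101L, width = 80L), strand = "+",
    locus_tag = "t1", kind = "tRNA", product = "tRNA",
    transcribed = NA, essential = NA, categories = "")
  b <- GenomeBundle("s", c(chr = seq), "linear", ft)
  expect_equal(nrow(findAttProphages(b, minSpan = 5000L)), 0L)
})

test_that("inversion detection recovers the planted HIP1-bounded inversion", {
  pan <- getPanel()
  bl <- detectInversions(pan$bundles$LAB1, pan$bundles$LAB3)
  ev <- evaluateInversions(bl, pan$truths$LAB1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$n_false, 0L)
  expect_true(ev$hip1_flagged)
  # both strains carrying the inversion: no block between them
  expect_equal(nrow(detectInversions(pan$bundles$LAB1,
                                     pan$bundles$LAB2)), 0L)
  # symmetry: swapping genomes mirrors the block
  blr <- detectInversions(pan$bundles$LAB3, pan$bundles$LAB1)
  expect_equal(nrow(blr), nrow(bl))
  expect_lte(abs(blr$startB - bl$startA), 25L)
})

test_that("identical genomes give no inversions", {
  pan <- getPanel()
  expect_equal(nrow(detectInversions(pan$bundles$LAB3,
                                     pan$bundles$LAB3)), 0L)
})

test_that("plasmid comparison finds the fusion backbone and duplicated flanks", {
  pan <- getPanel()
  sub <- function(b, r) {
    GenomeBundle(paste0(strainId(b), "_", r), replicons(b)[r], "circular",
                 features(b)[GenomeInfoDb::seqnames(features(b)) == r])
  }
  cp <- comparePlasmids(sub(pan$bundles$LAB1, "pLA"),
                        sub(pan$bundles$ENV1, "pMALx"))
  fr <- Filter(function(x) x$type == "fuse", pan$truths$ENV1$plasmid)[[1L]]
  expect_lt(abs(cp$shared_length - fr$backbone_len),
            0.05 * fr$backbone_len)
  expect_equal(nrow(cp$dup_flanks), 2L)
  expect_false(is.null(cp$expanded_region))
  expect_lt(abs(cp$expanded_region[1L] - fr$expanded_start), 50L)
  expect_lt(abs(cp$expanded_region[2L] - fr$expanded_end), 50L)
  # identical plasmids: full-length block, no duplicated flanks
  same <- comparePlasmids(sub(pan$bundles$LAB1, "pLA"),
                          sub(pan$bundles$LAB2, "pLA"))
  expect_gt(same$shared_length,
            0.98 * Biostrings::width(replicons(pan$bundles$LAB1)["pLA"]))
  expect_equal(nrow(same$dup_flanks), 0L)
  # unrelated plasmids share nothing
  rnd <- GenomeBundle("R", c(p = strainpan:::randDna(20000, 0.5)),
                      "circular")
  expect_lt(comparePlasmids(sub(pan$bundles$LAB1, "pLA"),
                            rnd)$shared_length, 500L)
})

test_that("planted CRISPR arrays are recovered exactly", {
  pan <- getPanel()
  ar <- findCrisprArrays(pan$bundles$ENV1)
  ev <- evaluateCrispr(ar, pan$truths$ENV1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$n_false, 0L)
  expect_true(ev$spacers_exact)
  expect_equal(ar[[1L]]$n_repeats, 5L)
  expect_equal(length(findCrisprArrays(pan$bundles$LAB1)), 0L)
})

test_that("tandem repeats with identical spacers are rejected", {
  withr::local_seed(45L)
  rpt <- strainpan:::randDna(32, 0.5)
  spc <- strainpan:::randDna(34, 0.5)
  arr <- paste0(rpt, spc, rpt, spc, rpt, spc, rpt)
  seq <- paste0(strainpan:::randDna(500, 0.5), arr,
                strainpan:::randDna(500, 0.5))
  b <- GenomeBundle("t", c(chr = seq), "linear")
  expect_equal(length(findCrisprArrays(b)), 0L)
  # distinct spacers: accepted
  sp <- replicate(3, strainpan:::randDna(34, 0.5))
  arr2 <- paste0(rpt, sp[1], rpt, sp[2], rpt, sp[3], rpt)
  b2 <- GenomeBundle("t2", c(chr = paste0(
    strainpan:::randDna(500, 0.5), arr2,
    strainpan:::randDna(500, 0.5))), "linear")
  found <- findCrisprArrays(b2)
  expect_equal(length(found), 1L)
  expect_equal(found[[1L]]$n_repeats, 4L)
  expect_identical(found[[1L]]$repeat_seq, rpt)
  expect_identical(unname(found[[1L]]$spacers), sp)
})

test_that("prophage detection is error-free over randomized replicates", {
  # 25 small replicate genomes: one planted prophage each plus one
  # negative control without insertion
  for (i in 1:25) {
    anc <- generateAncestor(ancestorConfig(
      chromosomeLength = 30000L, nGenes = 12L, nTrna = 3L,
      plasmidSpecs = list(), seed = 500L + i))
    pos <- deriveStrain(anc, branchParams(
      "P", snpRate = 5e-4,
      prophage = list(anchorTrnaIndex = (i %% 3L) + 1L,
                      elementLength = 6000L, attLen = 60L, nCargo = 3L,
                      elementSeed = 600L + i),
      seed = 700L + i))
    cp <- findAttProphages(pos$bundle, window = 30000L)
    ev <- evaluateProphages(cp, pos$truth)
    expect_equal(ev$recall, 1)
    expect_equal(ev$n_false, 0L)
    neg <- deriveStrain(anc, branchParams("N", snpRate = 5e-4,
                                          seed = 800L + i))
    expect_equal(nrow(findAttProphages(neg$bundle, window = 30000L)), 0L)
  }
})
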