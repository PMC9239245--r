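# Fragment-based ANI and RBH-based AAI.

aniTestPair <- function(rate, seed = 55L, L = 60000L) {
  anc <- generateAncestor(ancestorConfig(
    chromosomeLength = L, nGenes = 30L, nTrna = 2L, plasmidSpecs = list(),
    seed = seed))
  d <- deriveStrain(anc, branchParams("MUT", snpRate = rate,
                                      seed = seed + 1L))
  list(ref = anc$bundle, mut = d$bundle)
}

test_that("ANI of a genome with itself is exactly 100", {
  p <- aniTestPair(0)
  r <- computeAni(p$ref, p$ref)
  expect_identical(r$ani_pct, 100)
  expect_identical(r$aligned_fraction, 1)
})

test_that("ANI decreases monotonically with the substitution rate", {
  rates <- c(0, 0.005, 0.01, 0.02)
  anis <- vapply(rates, function(r) {
    p <- aniTestPair(r)
    computeAni(p$ref, p$mut)$ani_pct
  }, 0)
  expect_true(all(diff(anis) < 0))
  # and tracks 100 * (1 - rate) closely under uniform substitution
  expect_true(all(abs(anis - 100 * (1 - rates)) < 0.3))
})

test_that("unrelated random sequences carry the no-homology flag", {
  a <- GenomeBundle("A", c(chr = strainpan:::randDna(5000, 0.5)), "linear")
  b <- withr::with_seed(99L, GenomeBundle(
    "B", c(chr = strainpan:::randDna(5000, 0.5)), "linear"))
  r <- computeAni(a, b)
  expect_true(r$no_homology)
  expect_true(is.na(r$ani_pct))
})

test_that("AAI equals 100 on self and exceeds ANI on a diverged pair", {
  p <- aniTestPair(0.01, seed = 66L)
  aSelf <- computeAai(p$ref, p$ref)
  expect_equal(aSelf$aai_pct, 100)
  ani <- computeAni(p$ref, p$mut)$ani_pct
  aai <- computeAai(p$ref, p$mut)$aai_pct
  # synonymous substitutions vanish at the protein level
  expect_gt(aai, ani)
})

test_that("computeAai requires coding genes", {
  e <- GenomeBundle("E", c(chr = strainpan:::randDna(2000, 0.5)), "linear")
  expect_error(computeAai(e, e), "CDS")
})

test_that("the identity matrix is symmetric with a 100 diagonal", {
  p <- aniTestPair(0.005, seed = 77L)
  p$mut@strainId <- "MUT"
  m <- identityMatrix(list(p$ref, p$mut), "ani")
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 100))
  expect_lt(m[1, 2], 100)
})
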