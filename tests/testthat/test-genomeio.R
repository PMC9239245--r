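# Genome bundle I/O: validation, round trips, CDS extraction/translation.

test_that("a minimal bundle validates and rejects bad coordinates", {
  seq90 <- strainpan:::randDna(90, 0.5)
  ft <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(1, 30), strand = "+",
    locus_tag = "g1", kind = "CDS", product = "p",
    transcribed = NA, essential = NA, categories = "")
  b <- GenomeBundle("s1", c(chr = seq90), "linear", ft)
  expect_s4_class(b, "GenomeBundle")
  expect_equal(length(features(b)), 1L)
  expect_equal(unname(Biostrings::width(replicons(b))), 90L)

  bad <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(80, 100), strand = "+",
    locus_tag = "g1", kind = "CDS", product = "p",
    transcribed = NA, essential = NA, categories = "")
  expect_error(GenomeBundle("s1", c(chr = seq90), "linear", bad),
               "bounds")
  dup <- c(ft, ft)
  expect_error(GenomeBundle("s1", c(chr = seq90), "linear", dup),
               "unique")
})

test_that("load errors name the offending replicon and reject bad input", {
  b <- tinyBundle()
  d <- withr::local_tempdir()
  p <- writeBundle(b, d)
  # corrupt the GFF3 seqid
  lines <- readLines(p["gff3"])
  writeLines(gsub("^chr\t", "chrX\t", lines), p["gff3"])
  expect_error(loadBundle(p["fasta"], p["gff3"]), "chrX")
})

test_that("write/load round trip preserves every field", {
  b <- tinyBundle()
  d <- withr::local_tempdir()
  p <- writeBundle(b, d)
  b2 <- loadBundle(p["fasta"], p["gff3"], p["evidence"], strainId = "tiny")
  expect_identical(as.character(replicons(b2)), as.character(replicons(b)))
  expect_identical(unname(topology(b2)), unname(topology(b)))
  f1 <- features(b); f2 <- features(b2)
  expect_identical(BiocGenerics::start(f2), BiocGenerics::start(f1))
  expect_identical(as.character(BiocGenerics::strand(f2)),
                   as.character(BiocGenerics::strand(f1)))
  for (col in c("locus_tag", "kind", "product", "transcribed",
                "essential", "categories"))
    expect_identical(S4Vectors::mcols(f2)[[col]],
                     S4Vectors::mcols(f1)[[col]], label = col)
})

test_that("round trip holds for randomized generated genomes", {
  for (seed in c(11L, 12L)) {
    anc <- generateAncestor(ancestorConfig(
      chromosomeLength = 20000L, nGenes = 10L, nTrna = 2L,
      plasmidSpecs = list(), seed = seed))
    d <- withr::local_tempdir()
    p <- writeBundle(anc$bundle, d)
    b2 <- loadBundle(p["fasta"], p["gff3"], p["evidence"])
    expect_identical(as.character(replicons(b2)),
                     as.character(replicons(anc$bundle)))
    expect_identical(features(b2)$locus_tag,
                     features(anc$bundle)$locus_tag)
    expect_identical(features(b2)$transcribed,
                     features(anc$bundle)$transcribed)
  }
})

test_that("omitted evidence defaults to unknown", {
  b <- tinyBundle()
  d <- withr::local_tempdir()
  p <- writeBundle(b, d)
  # strip evidence attributes from the GFF3 so nothing is recorded there
  lines <- readLines(p["gff3"])
  lines <- gsub("evidence_transcribed=[a-z]+;", "evidence_transcribed=unknown;",
                lines)
  lines <- gsub("evidence_essential=[a-z]+;", "evidence_essential=unknown;",
                lines)
  writeLines(lines, p["gff3"])
  b2 <- loadBundle(p["fasta"], p["gff3"])
  expect_true(all(is.na(features(b2)$transcribed)))
  expect_true(all(is.na(features(b2)$essential)))
})

test_that("a featureless bundle writes a header-only GFF3 and reloads", {
  seq <- strainpan:::randDna(500, 0.5)
  b <- GenomeBundle("empty", c(chr = seq), "circular")
  d <- withr::local_tempdir()
  p <- writeBundle(b, d)
  b2 <- loadBundle(p["fasta"], p["gff3"])
  expect_equal(length(features(b2)), 0L)
  expect_identical(unname(topology(b2)["chr"]), "circular")
})

test_that("extractCds translates with the bacterial code and flags frames", {
  mk <- function(seqs, strands, lens, starts) {
    chr <- paste(seqs, collapse = "")
    ft <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(starts, width = lens), strand = strands,
      locus_tag = paste0("g", seq_along(seqs)), kind = "CDS",
      product = "", transcribed = NA, essential = NA, categories = "")
    GenomeBundle("t", c(chr = chr), "linear", ft)
  }
  # plus strand ATG AAA TAA -> "MK" (terminal stop removed)
  b <- mk("ATGAAATAA", "+", 9L, 1L)
  expect_identical(extractCds(b)$aa, "MK")
  # minus strand: reverse complement of the same CDS gives the same protein
  rc <- strainpan:::revcompChr("ATGAAATAA")
  b2 <- mk(rc, "-", 9L, 1L)
  expect_identical(extractCds(b2)$aa, "MK")
  # 10-bp CDS: translated to the last full codon, frame flagged
  b3 <- mk("ATGAAATAAC", "+", 10L, 1L)
  cds <- extractCds(b3)
  expect_false(cds$frame_ok)
  expect_identical(nchar(cds$aa), 3L)   # no terminal-stop trim off-frame
  # internal stop flagged, not fatal
  b4 <- mk("ATGTAAAAATAA", "+", 12L, 1L)
  expect_true(extractCds(b4)$internal_stop)
})
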