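# Group alignment, variant calling, and codon-aware effect classification.

test_that("identical members align without gap columns", {
  seqs <- setNames(rep("ATGACGTTTGGA", 3L), c("a", "b", "c"))
  m <- groupMsa(seqs)
  expect_equal(ncol(m), 12L)
  expect_false(any(m == "-"))
})

test_that("a single deletion is placed at its leftmost equivalent position", {
  # AAAG vs AAG: the deleted A could sit at columns 1-3; leftmost wins
  m <- alignGroup(c(a = "AAAG", b = "AAG"))
  expect_equal(ncol(m), 4L)
  expect_identical(unname(m["b", 1L]), "-")
  expect_identical(paste(m["b", 2:4], collapse = ""), "AAG")
  # ACGT vs ACT: single placement possible after left-shift
  m2 <- alignGroup(c(a = "ACGT", b = "ACT"))
  gapCol <- which(m2["b", ] == "-")
  expect_equal(length(gapCol), 1L)
  expect_equal(gapCol, 3L)
})

# helper: two-member CDS group aligned and called through the panel caller
callMini <- function(refNt, altNt, refStrand = "+") {
  lenR <- nchar(refNt)
  mkB <- function(strain, nt) {
    seq <- paste0(strainpan:::randDna(30, 0.5),
                  if (refStrand == "-") strainpan:::revcompChr(nt) else nt,
                  strainpan:::randDna(30, 0.5))
    ft <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(31L, width = nchar(nt)), strand = refStrand,
      locus_tag = paste0(strain, "_g1"), kind = "CDS", product = "",
      transcribed = NA, essential = NA, categories = "")
    GenomeBundle(strain, c(chr = seq), "linear", ft)
  }
  bundles <- list(mkB("REF", refNt), mkB("ALT", altNt))
  pg <- buildPangenome(bundles)
  callPanelVariants(pg, bundles, refStrain = "REF")
}

test_that("codon-aware classification matches the genetic code", {
  withr::local_seed(33L)
  base <- strainpan:::makeOrf(480L)   # 160 codons
  # codon 121 occupies nucleotides 361-363; force CGA -> CAA (R -> Q)
  refNt <- base
  substr(refNt, 361L, 363L) <- "CGA"
  altNt <- refNt
  substr(altNt, 361L, 363L) <- "CAA"
  calls <- callMini(refNt, altNt)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$effect, "missense")
  expect_identical(calls$aa_change, "R121Q")
  # third-position GGA -> GGG is synonymous
  altNt2 <- refNt
  substr(altNt2, 361L, 363L) <- "CGG"
  calls2 <- callMini(refNt, altNt2)
  expect_identical(calls2$effect, "synonymous")
  # stop gain TGG -> TGA
  refNt3 <- base
  substr(refNt3, 361L, 363L) <- "TGG"
  altNt3 <- refNt3
  substr(altNt3, 361L, 363L) <- "TGA"
  calls3 <- callMini(refNt3, altNt3)
  expect_identical(calls3$effect, "nonsense")
  expect_identical(calls3$aa_change, "W121*")
  # minus-strand genes classify identically
  calls4 <- callMini(refNt, altNt, refStrand = "-")
  expect_identical(calls4$effect, "missense")
  expect_identical(calls4$aa_change, "R121Q")
})

test_that("indels in CDS classify by length mod three and merge gap runs", {
  withr::local_seed(34L)
  base <- strainpan:::makeOrf(300L)
  # 2-bp deletion inside the CDS -> frameshift, single call of length 2
  altNt <- paste0(substr(base, 1L, 149L), substr(base, 152L, 300L))
  calls <- callMini(base, altNt)
  ind <- calls[calls$var_type != "SNP", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$length, 2L)
  expect_identical(ind$var_type, "deletion")
  expect_identical(ind$effect, "frameshift")
  # 3-bp deletion -> in-frame
  altNt3 <- paste0(substr(base, 1L, 149L), substr(base, 153L, 300L))
  calls3 <- callMini(base, altNt3)
  ind3 <- calls3[calls3$var_type != "SNP", ]
  expect_identical(ind3$effect, "inframe_indel")
})

test_that("a minority allele column becomes one SNP with strain alleles", {
  withr::local_seed(35L)
  nt <- strainpan:::makeOrf(120L)
  alt <- nt
  # synonymous-safe third position change at codon 10 (nt 30)
  substr(alt, 30L, 30L) <- setdiff(c("A", "C", "G", "T"),
                                   substr(nt, 30L, 30L))[1L]
  mkB <- function(strain, s) {
    ft <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(1L, nchar(s)), strand = "+",
      locus_tag = paste0(strain, "_g"), kind = "CDS", product = "",
      transcribed = NA, essential = NA, categories = "")
    GenomeBundle(strain, c(chr = s), "linear", ft)
  }
  bundles <- c(lapply(paste0("S", 1:5), mkB, s = nt), list(mkB("S6", alt)))
  pg <- buildPangenome(bundles)
  calls <- callPanelVariants(pg, bundles, refStrain = "S1")
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$var_type, "SNP")
  expect_identical(calls$allele_S6, substr(alt, 30L, 30L))
  expect_identical(calls$allele_S1, substr(nt, 30L, 30L))
  expect_equal(calls$pos_S6, 30L)
})

test_that("panel variant calls match the truth log", {
  ev <- evaluateVariants(getPanelCalls(), getPanel()$truths)
  expect_gte(ev$snp_precision, 0.99)
  expect_gte(ev$snp_recall, 0.99)
  expect_gte(ev$indel_precision, 0.99)
  expect_gte(ev$indel_recall, 0.99)
  expect_gte(ev$effect_agreement, 0.98)
})

test_that("effect classification agrees with whole-protein re-translation", {
  # brute-force oracle: mutate the whole CDS, re-translate, diff proteins
  withr::local_seed(36L)
  gc <- strainpan:::codonTable()
  for (rep in 1:200) {
    nt <- strainpan:::makeOrf(3L * sample(30:80, 1L))
    nCod <- nchar(nt) / 3L
    ci <- sample(seq(1L, nCod - 2L), 1L)          # 0-based internal codon
    pos <- ci * 3L + sample(0:2, 1L)              # 0-based offset
    ref <- substr(nt, pos + 1L, pos + 1L)
    altBase <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    alt <- nt
    substr(alt, pos + 1L, pos + 1L) <- altBase
    pRef <- strainpan:::translateChr(nt)
    pAlt <- strainpan:::translateChr(alt)
    oracle <- if (identical(pRef, pAlt)) "synonymous"
    else if (substr(pAlt, ci + 1L, ci + 1L) == "*") "nonsense"
    else "missense"
    refCodon <- substr(nt, ci * 3L + 1L, ci * 3L + 3L)
    altCodon <- substr(alt, ci * 3L + 1L, ci * 3L + 3L)
    expect_identical(strainpan:::classifyCodonChange(refCodon, altCodon),
                     oracle)
  }
})

test_that("variant summary statistics follow their definitions", {
  strains <- c("R", "S")
  mkRow <- function(type, effect, aS) {
    data.frame(group_id = "OG1", var_type = type, column = 1L,
               length = 1L, effect = effect, aa_change = NA,
               ref_replicon = "chr", boundary = FALSE,
               allele_R = "A", pos_R = 1L, allele_S = aS, pos_S = 1L,
               stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, c(
    lapply(1:8, function(i) mkRow("SNP", "synonymous", "G")),
    list(mkRow("SNP", "missense", "G"), mkRow("SNP", "nonsense", "G"),
         mkRow("deletion", "frameshift", "-"))))
  vs <- summarizeVariants(calls, strains, "R")
  expect_equal(vs$total_snps, 10L)
  expect_equal(vs$total_indels, 1L)
  expect_equal(vs$pct_aa_changing, 20.0)
  expect_equal(dim(vs$sharing_matrix), c(2L, 11L))
  expect_true(all(vs$sharing_matrix["S", ] == 1L))
  expect_true(all(vs$sharing_matrix["R", ] == 0L))
  # no coding SNPs -> NA
  empty <- summarizeVariants(calls[calls$var_type != "SNP", ],
                             strains, "R")
  expect_true(is.na(empty$pct_aa_changing))
})
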