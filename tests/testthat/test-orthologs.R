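# Reciprocal-best-hit orthology and pangenome construction.

test_that("self-comparison pairs every gene with itself at 100% identity", {
  b <- tinyBundle()
  pr <- rbhPairs(b, b)
  expect_equal(nrow(pr), 2L)
  expect_identical(pr$locus_tag_A, pr$locus_tag_B)
  expect_true(all(pr$identity_pct == 100))
})

test_that("a gene present in only one strain yields no pair", {
  a <- tinyBundle("A", seed = 21L)
  # strain B = strain A's first gene only
  fa <- features(a)
  b <- GenomeBundle("B", replicons(a), topology(a), fa[1L])
  pr <- rbhPairs(a, b)
  expect_equal(nrow(pr), 1L)
  expect_identical(pr$locus_tag_A, "A_g1")
  expect_false("A_g2" %in% pr$locus_tag_A)
})

test_that("empty gene sets give an empty pair list, not an error", {
  a <- tinyBundle("A")
  e <- GenomeBundle("E", c(chr = strainpan:::randDna(500, 0.5)), "linear")
  expect_equal(nrow(rbhPairs(a, e)), 0L)
})

test_that("raising the identity threshold never increases pair count", {
  pan <- getPanel()
  base <- rbhPairs(pan$bundles$LAB1, pan$bundles$ENV1, minIdentity = 70)
  ns <- vapply(c(70, 90, 98, 99.9), function(th)
    sum(base$identity_pct >= th), 0)
  expect_true(all(diff(ns) <= 0))
  strict <- rbhPairs(pan$bundles$LAB1, pan$bundles$ENV1, minIdentity = 98)
  expect_lte(nrow(strict), nrow(base))
})

test_that("two identical bundles produce an all-core pangenome", {
  a <- tinyBundle("A", seed = 31L)
  b <- GenomeBundle("B", replicons(a), topology(a), features(a))
  pg <- buildPangenome(list(a, b))
  ct <- pangenomeCounts(pg)
  expect_equal(ct$pangenome_size, 2L)
  expect_equal(ct$core_size, 2L)
  g <- pangenomeGroups(pg)
  expect_true(all(g$classification == "core"))
  expect_true(all(g$nt_identity_pct == 100))
})

test_that("panel group membership matches truth orthology", {
  ev <- evaluateOrthologs(getPangenome(), getPanel()$truths)
  expect_gte(ev$precision, 0.99)
  expect_gte(ev$recall, 0.99)
})

test_that("panel core size equals the truth count of universally retained genes", {
  pan <- getPanel()
  counts <- table(unlist(lapply(pan$truths, function(tr)
    unique(tr$geneMap$gene_id[!grepl("__dup$", tr$geneMap$gene_id)]))))
  truthCore <- sum(counts == length(pan$truths))
  expect_equal(pangenomeCounts(getPangenome())$core_size, truthCore)
})

test_that("every input gene appears in exactly one group", {
  pan <- getPanel()
  pg <- getPangenome()
  g <- pangenomeGroups(pg)
  for (s in pangenomeStrains(pg)) {
    tags <- g[[s]]
    tags <- tags[!is.na(tags)]
    expect_false(anyDuplicated(tags) > 0)
    expect_setequal(tags, features(pan$bundles[[s]])$locus_tag)
  }
  expect_equal(sum(g$n_members),
               sum(vapply(pan$bundles, function(b)
                 length(features(b)), 0L)))
})

test_that("the environmental strain's unique count covers its planted blocks", {
  pan <- getPanel()
  ct <- pangenomeCounts(getPangenome())
  planted <- sum(vapply(pan$params[[6L]]$uniqueGeneBlocks, `[[`, 0L,
                        "nGenes"))
  expect_gte(unname(ct$unique_counts["ENV1"]), planted)
})

test_that("conserved sets apply exact threshold semantics", {
  strains <- c("s1", "s2")
  g <- data.frame(group_id = c("OG1", "OG2", "OG3", "OG4"),
                  s1 = paste0("a", 1:4), s2 = paste0("b", 1:4),
                  kind = "CDS", classification = "core", n_members = 2L,
                  nt_identity_pct = c(100, 99.5, 100, 80),
                  aa_identity_pct = c(100, 96.0, 94.9, 70),
                  stringsAsFactors = FALSE)
  pg <- new("Pangenome", groups = g, strainIds = strains)
  cs <- conservedSets(pg)
  # one synonymous SNP: aa 100 but nt < 100
  expect_false("OG2" %in% cs$nt100)
  expect_true("OG2" %in% cs$aa95)
  # zero differences: both sets
  expect_true("OG1" %in% cs$nt100 && "OG1" %in% cs$aa95)
  # sub-threshold protein conservation
  expect_false("OG3" %in% cs$aa95)
  expect_false("OG4" %in% cs$nt100 || "OG4" %in% cs$aa95)
})
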