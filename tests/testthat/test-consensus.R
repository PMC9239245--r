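# Consensus pangenome annotation: majority starts, evidence-based drops,
# ncRNA promotion, stable export.

test_that("panel reconciliation recovers every planted discrepancy", {
  pan <- getPanel()
  rec <- getReconciled()
  adj <- rec$adjustments
  expect_equal(nrow(adj), nrow(pangenomeGroups(getPangenome())))

  # planted start truncations: LAB2/LAB4 on three ancestor genes
  planted <- unique(unlist(lapply(pan$truths, function(tr)
    tr$annotation$startAdjust$gene_id)))
  sa <- adj[adj$action == "start_adjust", ]
  expect_equal(nrow(sa), length(planted))
  affected <- sort(unique(unlist(strsplit(sa$affected_strains, ","))))
  expect_setequal(affected, c("LAB2", "LAB4"))

  # planted unsupported hypotheticals + pseudogene
  anc <- pan$ancestor$genes
  expect_equal(sum(adj$action == "drop_unsupported"),
               sum(anc$unsupported))
  # planted evidence-backed ncRNA
  expect_equal(sum(adj$action == "promote_ncRNA"), 1L)
})

test_that("no essential gene is ever dropped", {
  pan <- getPanel()
  rec <- getReconciled()
  dropped <- rec$adjustments$group_id[
    rec$adjustments$action == "drop_unsupported"]
  g <- pangenomeGroups(getPangenome())
  ess <- lapply(pan$bundles, function(b) {
    ft <- features(b)
    ft$locus_tag[!is.na(ft$essential) & ft$essential]
  })
  for (gid in dropped) {
    row <- g[g$group_id == gid, ]
    for (s in pangenomeStrains(getPangenome())) {
      tag <- row[[s]]
      if (!is.na(tag)) expect_false(tag %in% ess[[s]])
    }
  }
})

test_that("the unified table row count balances drops and promotions", {
  rec <- getReconciled()
  expect_equal(nrow(rec$unified),
               nrow(pangenomeGroups(getPangenome())) -
                 sum(rec$adjustments$action == "drop_unsupported"))
  expect_true(all(rec$unified$action != "drop_unsupported"))
})

test_that("export is deterministic and reference GFF3 reloads", {
  pan <- getPanel()
  rec <- getReconciled()
  d <- withr::local_tempdir()
  f1 <- file.path(d, "u1.tsv"); f2 <- file.path(d, "u2.tsv")
  exportPangenomeTable(rec, f1)
  exportPangenomeTable(rec, f2)
  expect_identical(readLines(f1), readLines(f2))
  gff <- file.path(d, "ref.gff3")
  exportReferenceGff(rec, pan$bundles$LAB1, gff)
  lines <- readLines(gff)
  expect_identical(lines[1L], "##gff-version 3")
  expect_gt(length(lines), 100L)
})

test_that("a majority start disagreement adopts the majority annotation", {
  # five members share the full-length annotation; one is truncated 9 nt
  withr::local_seed(51L)
  nt <- strainpan:::makeOrf(240L)
  mkB <- function(strain, start) {
    seq <- paste0(strainpan:::randDna(30, 0.5), nt,
                  strainpan:::randDna(30, 0.5))
    ft <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(31L + start, width = 240L - start),
      strand = "+", locus_tag = paste0(strain, "_g"), kind = "CDS",
      product = "p", transcribed = TRUE, essential = NA, categories = "")
    GenomeBundle(strain, c(chr = seq), "linear", ft)
  }
  bundles <- c(lapply(paste0("S", 1:5), mkB, start = 0L),
               list(mkB("S6", 9L)))
  pg <- buildPangenome(bundles)
  rec <- reconcileAnnotations(pg, bundles)
  expect_identical(rec$adjustments$action, "start_adjust")
  expect_identical(rec$adjustments$affected_strains, "S6")
})
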