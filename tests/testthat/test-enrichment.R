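# Fisher exact test, BH-FDR, fold enrichment.

# exhaustive enumeration oracle: all tables with the observed margins,
# probabilities from binomial coefficients
fisherOracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pObs <- probs[match(a, xs)]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

test_that("two-sided Fisher p matches enumeration on canonical tables", {
  expect_equal(fisherTwoSided(1, 1, 1, 1), 1.0)
  expect_equal(fisherTwoSided(0, 0, 0, 0), 1.0)
  expect_equal(fisherTwoSided(6, 4, 14, 76), fisherOracle(6, 4, 14, 76),
               tolerance = 1e-12)
  expect_error(fisherTwoSided(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  withr::local_seed(7L)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 20), 2)
    expect_equal(fisherTwoSided(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("BH step-up matches the hand-executed procedure", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(1.0), 1.0)
  expect_error(bhFdr(c(0.5, 1.5)), "\\[0, 1\\]")
  # hand-executed on an unsorted vector: p = (.03, .002, .20, .04, .8)
  # sorted: .002*5/1=.01, .03*5/2=.075, .04*5/3=.0667 -> min over j>=i
  # gives q_sorted = (.01, .0667, .0667, .20*5/4=.25 -> min(.25,.8)= .25, .8)
  p <- c(0.03, 0.002, 0.20, 0.04, 0.8)
  expect_equal(bhFdr(p), c(0.0666666666666667, 0.01, 0.25,
                           0.0666666666666667, 0.8),
               tolerance = 1e-12)
  # q monotone non-decreasing in sorted-p order
  withr::local_seed(8L)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bhFdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("Bonferroni discoveries are a subset of BH discoveries", {
  withr::local_seed(9L)
  for (i in 1:20) {
    p <- runif(25)^2
    bh <- bhFdr(p) <= 0.05
    bonf <- pmin(1, p * length(p)) <= 0.05
    expect_true(all(!bonf | bh))
  }
})

test_that("fold enrichment follows the printed formula", {
  categoriesOf <- as.list(rep("other", 100))
  names(categoriesOf) <- paste0("g", 1:100)
  categoriesOf[1:20] <- "target"           # Nc = 20
  geneSet <- c(paste0("g", 1:6), paste0("g", 95:98))  # Ng = 10, Ngc = 6
  res <- runGsea(geneSet, categoriesOf, "demo")
  row <- res[res$category == "target", ]
  expect_equal(row$N, 100L)
  expect_equal(row$Ng, 10L)
  expect_equal(row$Nc, 20L)
  expect_equal(row$Ngc, 6L)
  expect_equal(row$fc, 0.2)
  expect_equal(row$Egc, 2.0)
  expect_equal(row$F, 3.0)
  expect_identical(row$direction, "enriched")
})

test_that("F is 0 with no overlap and 1 at the expected overlap", {
  categoriesOf <- as.list(c(rep("cat", 50), rep("other", 50)))
  names(categoriesOf) <- paste0("g", 1:100)
  # Ngc = 0
  res0 <- runGsea(paste0("g", 51:60), categoriesOf, "none")
  expect_equal(res0$F[res0$category == "cat"], 0)
  # Ngc = Egc: Ng = 10, fc = 0.5 -> Egc = 5; pick 5 in, 5 out
  res1 <- runGsea(paste0("g", c(1:5, 51:55)), categoriesOf, "even")
  expect_equal(res1$F[res1$category == "cat"], 1)
})

test_that("empty gene sets give empty results and set errors are caught", {
  categoriesOf <- as.list(rep("x", 10))
  names(categoriesOf) <- paste0("g", 1:10)
  expect_equal(nrow(runGsea(character(0), categoriesOf)), 0L)
  expect_error(runGsea("missing", categoriesOf), "missing")
})

test_that("the environmental unique gene set is enriched in its planted categories", {
  pan <- getPanel()
  pg <- getPangenome()
  cats <- pangenomeCategories(pg, pan$bundles)
  g <- pangenomeGroups(pg)
  uniq <- g$group_id[g$classification == "unique" & !is.na(g$ENV1)]
  expect_gte(length(uniq), 30L)
  res <- runGsea(uniq, cats, "unique_ENV1")
  mob <- res[res$category == "mobilome", ]
  expect_true(mob$significant)
  expect_identical(mob$direction, "enriched")
  expect_gt(mob$F, 1)
  mot <- res[res$category == "motility", ]
  expect_true(mot$significant)
})

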