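# Gene-set enrichment over categorical metadata: fold enrichment
# F = Ngc / Egc with Egc = Ng * fc and fc = Nc / N, two-sided Fisher exact
# tests, Benjamini-Hochberg FDR control at q <= 0.05.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' P is the sum of hypergeometric probabilities, over all tables with the
#' same margins, whose probability does not exceed that of the observed
#' table (standard two-sided definition). Probabilities are computed in log
#' space from the hypergeometric mass function; a relative tolerance of
#' 1e-7 guards the comparison against rounding, as in common
#' implementations. Stable for margins up to 10,000.
#'
#' @param a,b,c,d cell counts of the table \code{rbind(c(a, b), c(c, d))}.
#' @return the two-sided p value.
#' @export
fisherTwoSided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stopf("fisherTwoSided requires non-negative integer counts")
  m <- a + c          # first column margin
  n <- b + d
  kk <- a + b         # first row margin
  if (m + n == 0L || kk == 0L || kk == m + n) return(1)
  support <- max(0L, kk - n):min(kk, m)
  logp <- stats::dhyper(support, m, n, kk, log = TRUE)
  obs <- stats::dhyper(a, m, n, kk, log = TRUE)
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param p vector of p values in [0, 1].
#' @return q values, same length and order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment against categorical metadata
#'
#' For each category touched by the genome, the fold enrichment is
#' F = Ngc / Egc with Egc = Ng * fc and fc = Nc / N, where N is the genome
#' gene total, Ng the gene-set size, Nc the category size and Ngc their
#' overlap. P values come from two-sided Fisher exact tests on the 2x2
#' table (in-set/in-category vs out); q values from Benjamini-Hochberg
#' across the categories tested for this gene set; significance is
#' q <= 0.05. Genes carrying several categories contribute to each
#' category's table independently. Categories with Nc = 0 are skipped.
#'
#' @param geneSet character vector of gene ids (subset of
#'   \code{names(categoriesOf)}).
#' @param categoriesOf named list (or comma-joined character vector) mapping
#'   every genome gene to its category labels.
#' @param geneSetId label for the gene set.
#' @param alpha significance level on q (default 0.05).
#' @return data.frame, one row per tested category: gene_set_id, category,
#'   N, Ng, Nc, Ngc, fc, Egc, F, p, q, significant, direction.
#' @export
runGsea <- function(geneSet, categoriesOf, geneSetId = "gene_set",
                    alpha = 0.05) {
  if (is.character(categoriesOf))
    categoriesOf <- strsplit(categoriesOf, ",", fixed = TRUE)
  genes <- names(categoriesOf)
  stopifnot(!is.null(genes))
  bad <- setdiff(geneSet, genes)
  if (length(bad))
    stopf("gene set members missing from metadata: %s",
          paste(utils::head(bad, 5L), collapse = ","))
  N <- length(genes)
  empty <- data.frame(gene_set_id = character(0), category = character(0),
                      N = integer(0), Ng = integer(0), Nc = integer(0),
                      Ngc = integer(0), fc = numeric(0), Egc = numeric(0),
                      F = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (!length(geneSet) || N == 0L) return(empty)
  inSet <- genes %in% geneSet
  Ng <- sum(inSet)
  cats <- sort(unique(unlist(categoriesOf, use.names = FALSE)))
  cats <- cats[!is.na(cats) & cats != ""]
  if (!length(cats)) return(empty)
  rows <- lapply(cats, function(cc) {
    inCat <- vapply(categoriesOf, function(v) cc %in% v, TRUE)
    Nc <- sum(inCat)
    if (Nc == 0L) return(NULL)
    Ngc <- sum(inSet & inCat)
    fc <- Nc / N
    Egc <- Ng * fc
    data.frame(gene_set_id = geneSetId, category = cc, N = N, Ng = Ng,
               Nc = Nc, Ngc = Ngc, fc = fc, Egc = Egc,
               F = if (Egc > 0) Ngc / Egc else NA_real_,
               p = fisherTwoSided(Ngc, Ng - Ngc, Nc - Ngc,
                                  N - Ng - Nc + Ngc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$q <- bhFdr(out$p)
  out$significant <- out$q <= alpha
  out$direction <- ifelse(out$Ngc > out$Egc, "enriched", "depleted")
  out
}

#' Category metadata of a pangenome, keyed by group id
#'
#' Collates the category labels of each group's members (union across
#' strains) for use with \code{\link{runGsea}}.
#'
#' @param pangenome a \linkS4class{Pangenome}.
#' @param bundles the bundles it was built from.
#' @return named list mapping group_id to a character vector of categories.
#' @export
pangenomeCategories <- function(pangenome, bundles) {
  strains <- pangenomeStrains(pangenome)
  names(bundles) <- vapply(bundles, strainId, "")
  catOf <- lapply(bundles[strains], function(b) {
    ft <- features(b)
    setNames(ft$categories, ft$locus_tag)
  })
  g <- pangenomeGroups(pangenome)
  out <- lapply(seq_len(nrow(g)), function(i) {
    tags <- unlist(g[i, strains])
    tags <- tags[!is.na(tags)]
    cc <- unlist(lapply(names(tags), function(s) {
      strsplit(catOf[[s]][[tags[[s]]]], ",", fixed = TRUE)[[1]]
    }), use.names = FALSE)
    sort(unique(cc[cc != ""]))
  })
  names(out) <- g$group_id
  out
}
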