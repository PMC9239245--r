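# End-to-end orchestration: validated run configuration, staged execution
# (simulate, pangenome, variants, ani, mobilome, gsea, annotate), Markdown
# summary, provenance (version, config hash, seed) in every run.

pipelineStages <- c("simulate", "pangenome", "variants", "ani", "mobilome",
                    "gsea", "annotate")

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or YAML file) with keys: \code{input}
#' (either \code{list(simulate = list(seed))} or \code{list(bundles =
#' list(list(fasta, gff3, evidence)))}), \code{reference} (strain id,
#' optional), \code{outDir}, \code{seed}, \code{stages} (subset of the
#' stage names, or "all"), \code{thresholds} (optional overrides:
#' min_identity, min_coverage, fragment_len, min_att, max_att, window,
#' min_span, alpha) and \code{logLevel}. Unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return the validated, default-filled configuration.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("input", "reference", "outDir", "seed", "stages",
             "thresholds", "logLevel")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stopf("unknown config key: %s", paste(unknown, collapse = ","))
  if (is.null(config$input))
    stopf("config key 'input' is required")
  if (is.null(config$input$simulate) && is.null(config$input$bundles))
    stopf("config key 'input' needs 'simulate' or 'bundles'")
  config$outDir <- config$outDir %||% "strainpan_out"
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% "all"
  if (identical(config$stages, "all")) config$stages <- pipelineStages
  bad <- setdiff(config$stages, pipelineStages)
  if (length(bad))
    stopf("unknown stage: %s", paste(bad, collapse = ","))
  th <- config$thresholds %||% list()
  knownTh <- c("min_identity", "min_coverage", "fragment_len", "min_att",
               "max_att", "window", "min_span", "alpha")
  badTh <- setdiff(names(th), knownTh)
  if (length(badTh))
    stopf("unknown threshold key: %s", paste(badTh, collapse = ","))
  defaults <- list(min_identity = 70, min_coverage = 0.5,
                   fragment_len = 1020L, min_att = 15L, max_att = 200L,
                   window = 150000L, min_span = 5000L, alpha = 0.05)
  config$thresholds <- utils::modifyList(defaults, th)
  config$logLevel <- config$logLevel %||% "info"
  config
}

#' Run the comparative-genomics pipeline
#'
#' Executes the configured stages in order and writes, under
#' \code{outDir}: the panel bundles and truth logs (simulate), pangenome
#' TSV, variant TSV and per-strain VCFs, ANI/AAI matrices, mobilome
#' TSV/BED plus spacer FASTA, enrichment TSV, unified annotation TSV/GFF3,
#' a Markdown summary, and \code{run_info.json} with the package version,
#' configuration hash and seed. Outputs are deterministic given the
#' configuration and seed.
#'
#' @param config configuration list or YAML path
#'   (\code{\link{validateRunConfig}}).
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(config) {
  cfg <- validateRunConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(cfg$outDir, "run.log")
  logmsg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = logFile, append = TRUE)
    if (cfg$logLevel != "quiet") message(line)
  }
  th <- cfg$thresholds
  res <- list(config = cfg)

  cfgNorm <- cfg; cfgNorm$outDir <- NULL
  tf <- tempfile()
  writeLines(utils::capture.output(utils::str(cfgNorm)), tf)
  cfgHash <- substr(unname(tools::md5sum(tf)), 1L, 12L)
  unlink(tf)

  # inputs
  if (!is.null(cfg$input$simulate) && "simulate" %in% cfg$stages) {
    logmsg("simulating study panel (seed %d)", cfg$seed)
    pan <- makeStudyPanel(seed = cfg$input$simulate$seed %||% cfg$seed)
    res$bundles <- pan$bundles
    res$truths <- pan$truths
    pdir <- file.path(cfg$outDir, "panel")
    for (s in names(pan$bundles)) {
      writeBundle(pan$bundles[[s]], pdir)
      writeTruthLog(pan$truths[[s]], file.path(pdir, "truth"))
    }
  } else if (!is.null(cfg$input$bundles)) {
    logmsg("loading %d input bundles", length(cfg$input$bundles))
    res$bundles <- lapply(cfg$input$bundles, function(bb)
      loadBundle(bb$fasta, bb$gff3, bb$evidence %||% NULL,
                 strainId = bb$strainId %||% NULL))
    names(res$bundles) <- vapply(res$bundles, strainId, "")
  } else stopf("no input available for the requested stages")
  bundles <- res$bundles
  refStrain <- cfg$reference %||% strainId(bundles[[1L]])

  if ("pangenome" %in% cfg$stages) {
    logmsg("building pangenome (%d strains)", length(bundles))
    res$pangenome <- buildPangenome(bundles,
                                    minIdentity = th$min_identity,
                                    minCoverage = th$min_coverage)
    writePangenomeTsv(res$pangenome, file.path(cfg$outDir, "pangenome.tsv"))
    ct <- pangenomeCounts(res$pangenome)
    logmsg("pangenome: %d groups, %d core", ct$pangenome_size, ct$core_size)
  }
  if ("variants" %in% cfg$stages) {
    if (is.null(res$pangenome)) stopf("variants stage needs pangenome")
    logmsg("calling variants (reference %s)", refStrain)
    res$variants <- callPanelVariants(res$pangenome, bundles, refStrain)
    writeVariantTsv(res$variants, file.path(cfg$outDir, "variants.tsv"))
    for (s in setdiff(names(bundles), refStrain))
      writeVariantVcf(res$variants, s, refStrain,
                      file.path(cfg$outDir,
                                sprintf("variants_%s.vcf", s)))
    res$variantSummary <- summarizeVariants(res$variants,
                                            names(bundles), refStrain)
    logmsg("variants: %d SNPs, %d indels, %.1f%% aa-changing",
           res$variantSummary$total_snps, res$variantSummary$total_indels,
           res$variantSummary$pct_aa_changing %||% NA)
  }
  if ("ani" %in% cfg$stages) {
    logmsg("computing ANI / AAI matrices")
    res$ani <- identityMatrix(bundles, "ani",
                              fragmentLen = th$fragment_len)
    res$aai <- identityMatrix(bundles, "aai")
    writeIdentityMatrix(res$ani, file.path(cfg$outDir, "ani_matrix.tsv"))
    writeIdentityMatrix(res$aai, file.path(cfg$outDir, "aai_matrix.tsv"))
  }
  if ("mobilome" %in% cfg$stages) {
    logmsg("scanning mobilome")
    res$prophages <- do.call(rbind, lapply(names(bundles), function(s) {
      pc <- findAttProphages(bundles[[s]], minAtt = th$min_att,
                             maxAtt = th$max_att, window = th$window,
                             minSpan = th$min_span)
      if (nrow(pc)) cbind(strain = s, pc) else NULL
    }))
    res$hip1 <- lapply(bundles, scanHip1)
    res$crisprs <- lapply(bundles, findCrisprArrays)
    res$inversions <- do.call(rbind, lapply(
      setdiff(names(bundles), refStrain), function(s) {
        bl <- detectInversions(bundles[[refStrain]], bundles[[s]])
        if (nrow(bl)) cbind(strainA = refStrain, strainB = s, bl) else NULL
      }))
    writeMobilome(res$prophages %||% emptyProphageTable(),
                  res$inversions %||%
                    detectInversions(bundles[[1L]], bundles[[1L]]),
                  do.call(c, unname(res$crisprs)), cfg$outDir)
  }
  if ("gsea" %in% cfg$stages) {
    if (is.null(res$pangenome)) stopf("gsea stage needs pangenome")
    logmsg("gene-set enrichment")
    cats <- pangenomeCategories(res$pangenome, bundles)
    g <- pangenomeGroups(res$pangenome)
    sets <- list()
    for (s in names(bundles))
      sets[[paste0("unique_", s)]] <-
        g$group_id[g$classification == "unique" & !is.na(g[[s]])]
    cs <- conservedSets(res$pangenome)
    sets$conserved_nt100 <- cs$nt100
    sets$conserved_aa95 <- cs$aa95
    res$enrichment <- do.call(rbind, lapply(names(sets), function(nm)
      if (length(sets[[nm]]))
        runGsea(sets[[nm]], cats, geneSetId = nm, alpha = th$alpha)))
    write.table(res$enrichment, file.path(cfg$outDir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("annotate" %in% cfg$stages) {
    if (is.null(res$pangenome)) stopf("annotate stage needs pangenome")
    logmsg("reconciling annotations")
    res$consensus <- reconcileAnnotations(res$pangenome, bundles)
    exportPangenomeTable(res$consensus,
                         file.path(cfg$outDir, "unified_annotation.tsv"))
    exportReferenceGff(res$consensus, bundles[[refStrain]],
                       file.path(cfg$outDir, "unified_reference.gff3"))
  }

  info <- list(tool = "strainpan",
               version = as.character(packageVersion("strainpan")),
               config_hash = unname(cfgHash), seed = cfg$seed,
               reference = refStrain, stages = cfg$stages)
  jsonlite::write_json(info, file.path(cfg$outDir, "run_info.json"),
                       auto_unbox = TRUE)
  writeRunSummary(res, info, file.path(cfg$outDir, "summary.md"))
  logmsg("done")
  invisible(res)
}

writeRunSummary <- function(res, info, path) {
  ln <- c(sprintf("# strainpan run summary"),
          "",
          sprintf("- tool: strainpan %s", info$version),
          sprintf("- config hash: %s", info$config_hash),
          sprintf("- seed: %d", info$seed),
          sprintf("- reference strain: %s", info$reference),
          sprintf("- strains: %s", paste(names(res$bundles),
                                         collapse = ", ")),
          "")
  if (!is.null(res$pangenome)) {
    ct <- pangenomeCounts(res$pangenome)
    ln <- c(ln, "## Pangenome", "",
            sprintf("- %d homology groups, %d core",
                    ct$pangenome_size, ct$core_size),
            sprintf("- unique per strain: %s",
                    paste(sprintf("%s=%d", names(ct$unique_counts),
                                  ct$unique_counts), collapse = ", ")), "")
  }
  if (!is.null(res$variantSummary)) {
    vs <- res$variantSummary
    ln <- c(ln, "## Variants", "",
            sprintf("- %d SNPs, %d indels", vs$total_snps, vs$total_indels),
            sprintf("- %.1f%% of coding SNPs change the protein",
                    vs$pct_aa_changing), "")
  }
  if (!is.null(res$ani)) {
    ln <- c(ln, "## Identity", "",
            sprintf("- mean off-diagonal ANI: %.2f%%",
                    mean(res$ani[upper.tri(res$ani)])),
            sprintf("- mean off-diagonal AAI: %.2f%%",
                    mean(res$aai[upper.tri(res$aai)])), "")
  }
  if (!is.null(res$prophages)) {
    ln <- c(ln, "## Mobilome", "",
            sprintf("- %d prophage call(s)",
                    if (is.null(res$prophages)) 0L else nrow(res$prophages)),
            sprintf("- %d inversion block(s)",
                    if (is.null(res$inversions)) 0L
                    else nrow(res$inversions)),
            sprintf("- %d CRISPR array(s)",
                    sum(lengths(res$crisprs))), "")
  }
  if (!is.null(res$enrichment)) {
    sig <- res$enrichment[res$enrichment$significant, , drop = FALSE]
    ln <- c(ln, "## Enrichment", "",
            sprintf("- %d significant gene-set x category result(s)",
                    nrow(sig)),
            if (nrow(sig))
              sprintf("  - %s: %s (F=%.2f, q=%.3g)", sig$gene_set_id,
                      sig$category, sig$F, sig$q), "")
  }
  if (!is.null(res$consensus)) {
    tab <- table(res$consensus$adjustments$action)
    ln <- c(ln, "## Annotation consensus", "",
            sprintf("- %s: %d", names(tab), as.integer(tab)), "")
  }
  writeLines(ln, path)
  invisible(path)
}
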