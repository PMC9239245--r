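# Event planting for deriveStrain: substitutions with a controlled
# nonsynonymous fraction, left-normalized indels, the HIP1-bounded inversion,
# tRNA-anchored prophage insertion, plasmid gain/loss/fusion, CRISPR arrays
# and strain-unique gene blocks.

classifyCodonChange <- function(refCodon, altCodon) {
  gc <- codonTable()
  aaR <- unname(gc[refCodon]); aaA <- unname(gc[altCodon])
  if (identical(aaR, aaA)) "synonymous"
  else if (identical(aaA, "*")) "nonsense"
  else "missense"
}

# stranded gene characters from the current state
geneChars <- function(state, row) {
  v <- state$seqs[[row$replicon]][row$start:row$end]
  if (row$strand == "-") rev(unname(compMap[v])) else v
}

inIntervals <- function(pos, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv)))
    out <- out | (pos >= iv$start[i] & pos <= iv$end[i])
  out
}

plantSnps <- function(state, rate, pNonsyn, masks) {
  if (rate <= 0) return(state)
  gc <- codonTable()
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (repl in names(state$seqs)) {
    L <- length(state$seqs[[repl]])
    fi <- which(state$feat$replicon == repl)
    mrepl <- masks[masks$replicon == repl, , drop = FALSE]
    for (fidx in fi) {
      f <- state$feat[fidx, ]
      len <- f$end - f$start + 1L
      n <- rbinom(1L, len, rate)
      if (n == 0L) next
      if (f$kind == "CDS") {
        nCod <- len %/% 3L
        if (nCod < 3L) next
        internal <- seq.int(1L, nCod - 2L)   # 0-based codon indices
        n <- min(n, length(internal))
        chosen <- if (length(internal) == 1L) internal
                  else sample(internal, n)
        spare <- setdiff(internal, chosen)
        if (length(spare) > 1L) spare <- sample(spare)
        gchars <- geneChars(state, f)
        ci_i <- 0L
        while (ci_i < length(chosen)) {
          ci_i <- ci_i + 1L
          ci <- chosen[ci_i]
          codon <- paste(gchars[ci * 3L + 1:3], collapse = "")
          cand <- expand.grid(p = 0:2, b = bases,
                              stringsAsFactors = FALSE)
          refB <- substring(codon, cand$p + 1L, cand$p + 1L)
          cand <- cand[refB != cand$b, ]
          altCodon <- vapply(seq_len(nrow(cand)), function(i) {
            ac <- codon
            substr(ac, cand$p[i] + 1L, cand$p[i] + 1L) <- cand$b[i]
            ac
          }, "")
          cls <- vapply(altCodon, classifyCodonChange, "",
                        refCodon = codon)
          wantNonsyn <- runif(1L) < pNonsyn
          pool <- if (wantNonsyn) which(cls != "synonymous")
                  else which(cls == "synonymous")
          if (!length(pool)) {
            # codon cannot yield the target class (e.g. ATG/TGG have no
            # synonymous alternative): swap in a different codon so the
            # configured nonsynonymous fraction is unbiased
            if (length(spare)) {
              chosen[ci_i] <- spare[1L]
              spare <- spare[-1L]
              ci_i <- ci_i - 1L
              next
            }
            pool <- seq_along(cls)
          }
          pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
          pInC <- cand$p[pick]
          genePos <- ci * 3L + pInC            # 0-based offset in gene
          gpos <- if (f$strand == "+") f$start + genePos
                  else f$end - genePos
          if (inIntervals(gpos, mrepl)) next
          geneRef <- substr(codon, pInC + 1L, pInC + 1L)
          geneAlt <- cand$b[pick]
          eff <- cls[pick]
          aaCh <- if (eff == "synonymous") NA_character_ else
            paste0(unname(gc[codon]), ci + 1L,
                   unname(gc[altCodon[pick]]))
          rows[[length(rows) + 1L]] <- data.frame(
            replicon = repl, pos = gpos, anc_pos = gpos,
            ref = if (f$strand == "+") geneRef else unname(compMap[geneRef]),
            alt = if (f$strand == "+") geneAlt else unname(compMap[geneAlt]),
            gene_id = f$gene_id, effect = eff, aa_change = aaCh,
            stringsAsFactors = FALSE)
        }
      } else {
        # tRNA / ncRNA / pseudogene: random substitutions, noncoding effect
        cand <- seq.int(f$start, f$end)
        cand <- cand[!inIntervals(cand, mrepl)]
        if (!length(cand)) next
        n <- min(n, length(cand))
        pos <- if (length(cand) == 1L) cand else sample(cand, n)
        for (p in pos) {
          ref <- state$seqs[[repl]][p]
          alt <- sample(setdiff(bases, ref), 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            replicon = repl, pos = p, anc_pos = p, ref = ref, alt = alt,
            gene_id = f$gene_id, effect = "noncoding_gene",
            aa_change = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    # intergenic space
    geneMask <- rep(FALSE, L)
    for (fidx in fi)
      geneMask[state$feat$start[fidx]:state$feat$end[fidx]] <- TRUE
    inter <- which(!geneMask)
    inter <- inter[!inIntervals(inter, mrepl)]
    n <- rbinom(1L, L - sum(geneMask), rate)
    n <- min(n, length(inter))
    if (n > 0L) {
      pos <- sample(inter, n)
      ref <- state$seqs[[repl]][pos]
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      rows[[length(rows) + 1L]] <- data.frame(
        replicon = repl, pos = pos, anc_pos = pos, ref = ref,
        alt = unname(alt), gene_id = NA_character_, effect = "intergenic",
        aa_change = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(state)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  state$truth$snps <- df
  for (repl in unique(df$replicon)) {
    i <- df$replicon == repl
    state <- opSub(state, repl, df$pos[i], df$alt[i])
  }
  state
}

plantIndels <- function(state, rate, masks) {
  if (rate <= 0) return(state)
  rows <- list()
  for (repl in names(state$seqs)) {
    L <- length(state$seqs[[repl]])
    n <- rbinom(1L, L, rate)
    if (n == 0L) next
    v <- state$seqs[[repl]]
    fi <- which(state$feat$replicon == repl)
    fstart <- state$feat$start[fi]; fend <- state$feat$end[fi]
    fkind <- state$feat$kind[fi]; fids <- state$feat$gene_id[fi]
    mrepl <- masks[masks$replicon == repl, , drop = FALSE]
    snpPos <- state$truth$snps$pos[state$truth$snps$replicon == repl]
    placed <- integer(0)
    got <- 0L; tries <- 0L
    while (got < n && tries < 300L * n) {
      tries <- tries + 1L
      pos <- sample.int(L - 30L, 1L) + 10L
      len <- min(12L, stats::rgeom(1L, 0.4) + 1L)
      type <- sample(c("insertion", "deletion"), 1L)
      lo <- pos; hi <- if (type == "deletion") pos + len - 1L else pos
      if (hi > L - 10L) next
      if (any(inIntervals(lo:hi, mrepl))) next
      hitLo <- which(fstart <= lo & fend >= lo)
      hitHi <- which(fstart <= hi & fend >= hi)
      if (!identical(hitLo, hitHi)) next       # crosses a feature boundary
      gene <- NA_character_; eff <- "intergenic"
      if (length(hitLo)) {
        if (fkind[hitLo] != "CDS") next        # keep tRNA/ncRNA intact
        if (lo < fstart[hitLo] + 30L || hi > fend[hitLo] - 30L) next
        gene <- fids[hitLo]
        eff <- if (len %% 3L) "frameshift" else "inframe_indel"
      }
      if (length(snpPos) && min(abs(snpPos - pos)) <= 20L) next
      if (length(placed) && min(abs(placed - pos)) < 50L) next
      if (type == "deletion") {
        # reject deletions whose placement is ambiguous in either
        # orientation (minus-strand genes normalize in gene frame)
        if (v[pos - 1L] == v[pos + len - 1L]) next   # left-shiftable
        if (v[pos] == v[pos + len]) next             # right-shiftable
        content <- paste(v[pos:(pos + len - 1L)], collapse = "")
      } else {
        ok <- FALSE
        for (k in 1:10) {
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          if (ins[len] != v[pos] && ins[1L] != v[pos + 1L]) { ok <- TRUE; break }
        }
        if (!ok) next
        content <- paste(ins, collapse = "")
      }
      placed <- c(placed, pos)
      rows[[length(rows) + 1L]] <- data.frame(
        replicon = repl,
        pos = if (type == "deletion") pos else pos,
        anc_pos = pos, len = len, type = type, seq = content,
        gene_id = gene, effect = eff, stringsAsFactors = FALSE)
      got <- got + 1L
    }
  }
  if (!length(rows)) return(state)
  df <- do.call(rbind, rows)
  df <- df[order(df$replicon, df$anc_pos), , drop = FALSE]
  rownames(df) <- NULL
  # anchor convention: pos is the base immediately left of the event run in
  # the derived frame (deletion: gap opens after pos-1 -> store pos-1;
  # insertion: run occupies pos+1..pos+len -> store pos)
  state$truth$indels <- df
  for (i in seq_len(nrow(df))) {
    r <- state$truth$indels[i, ]
    if (r$type == "deletion") {
      state <- opDel(state, r$replicon, r$pos, r$len)
    } else {
      state <- opIns(state, r$replicon, r$pos,
                     strsplit(r$seq, "", fixed = TRUE)[[1]])
    }
  }
  state
}

plantInversion <- function(state, plan) {
  s <- plan$s; e <- plan$e
  state <- opInv(state, "chr", s, e)
  state$truth$inversions <- rbind(state$truth$inversions, data.frame(
    replicon = "chr", start = s, end = e, anc_start = plan$anc_s,
    anc_end = plan$anc_e, boundary_hip1 = TRUE, stringsAsFactors = FALSE))
  state
}

# choose the HIP1 pair bounding the inversion (ancestor frame)
planInversion <- function(ancestor, approxLength) {
  hp <- ancestor$hip1[["chr"]]
  if (length(hp) < 2L) stopf("not enough planted HIP1 octamers for inversion")
  d <- outer(hp, hp, "-")
  d[upper.tri(d, diag = TRUE)] <- NA    # d[i,j] = hp[i]-hp[j], i>j
  best <- which.min(abs(d - approxLength))
  i <- row(d)[best]; j <- col(d)[best]
  list(anc_s = hp[j], anc_e = hp[i] + 7L)
}

# build a gene-packed insert; returns chars + local feature table
buildGeneInsert <- function(nGenes, categories, idFmt, lenRange = 100:300,
                            product = "hypothetical protein", gc = 0.5,
                            minGap = 25L) {
  lens <- 3L * sample(lenRange, nGenes, replace = TRUE)
  total <- sum(lens) + minGap * (nGenes + 1L) + 200L
  pk <- packReplicon("insert", total, lens,
                     rep("CDS", nGenes),
                     sample(c("+", "-"), nGenes, replace = TRUE),
                     gc, hip1Rate = 0)
  cats <- sample(names(categories), nGenes, replace = TRUE,
                 prob = categories)
  list(chars = strsplit(pk$seq, "", fixed = TRUE)[[1]],
       feat = data.frame(gene_id = sprintf(idFmt, seq_len(nGenes)),
                         start = pk$starts, end = pk$ends,
                         strand = rep("+", nGenes), kind = "CDS",
                         product = product, transcribed = TRUE,
                         essential = FALSE, categories = cats,
                         stringsAsFactors = FALSE))
}

addFeatures <- function(state, repl, local, offset) {
  if (!nrow(local$feat)) return(state)
  add <- data.frame(gene_id = local$feat$gene_id, replicon = repl,
                    start = local$feat$start + offset,
                    end = local$feat$end + offset,
                    strand = local$feat$strand, kind = local$feat$kind,
                    product = local$feat$product,
                    transcribed = local$feat$transcribed,
                    essential = local$feat$essential,
                    categories = local$feat$categories,
                    origin = "inserted", stringsAsFactors = FALSE)
  state$feat <- rbind(state$feat, add)
  state
}

plantProphage <- function(state, pp, trnaIds) {
  if (pp$anchorTrnaIndex < 1L || pp$anchorTrnaIndex > length(trnaIds))
    stopf("anchor tRNA index out of range: %d (have %d tRNAs)",
          pp$anchorTrnaIndex, length(trnaIds))
  anchor <- trnaIds[pp$anchorTrnaIndex]
  f <- state$feat[state$feat$gene_id == anchor, ]
  if (f$strand != "+")
    stopf("prophage anchor tRNA must be on the plus strand")
  attLen <- pp$attLen
  attSeq <- state$seqs[[f$replicon]][(f$end - attLen + 1L):f$end]
  cargoLen <- pp$elementLength - attLen
  local <- withLocalSeed(pp$elementSeed, {
    ins <- buildGeneInsert(pp$nCargo, pp$cargoCategories,
                           paste0("ph", pp$key, "_%03d"),
                           product = "phage protein")
    # pad or trim filler to the requested cargo length
    if (length(ins$chars) < cargoLen) {
      ins$chars <- c(ins$chars,
                     strsplit(randDna(cargoLen - length(ins$chars), 0.5),
                              "", fixed = TRUE)[[1]])
    } else if (length(ins$chars) > cargoLen) {
      if (max(ins$feat$end) > cargoLen)
        stopf("prophage cargo genes do not fit element length %d",
              pp$elementLength)
      ins$chars <- ins$chars[seq_len(cargoLen)]
    }
    ins
  })
  p <- f$end
  # the planted duplication must be maximal: the base left of the att copy
  # may not match the tRNA base left of its terminal window, or a detector
  # scanning for the maximal exact duplication would rightly call one base
  # more than planted
  guardPos <- length(local$chars)
  tGuard <- state$seqs[[f$replicon]][f$end - attLen]
  if (local$chars[guardPos] == tGuard)
    local$chars[guardPos] <- setdiff(c("A", "C", "G", "T"), tGuard)[1L]
  chars <- c(local$chars, attSeq)
  state <- opIns(state, f$replicon, p, chars)
  state <- addFeatures(state, f$replicon, local, p)
  elemLen <- length(chars)
  state$truth$prophages <- rbind(state$truth$prophages, data.frame(
    replicon = f$replicon, anchor_gene_id = anchor,
    attL_start = f$end - attLen + 1L, attL_end = f$end,
    elem_start = p + 1L, elem_end = p + elemLen,
    attR_start = p + elemLen - attLen + 1L, attR_end = p + elemLen,
    att_len = attLen, elem_len = elemLen, element_key = pp$key,
    stringsAsFactors = FALSE))
  state
}

plantPlasmidEvents <- function(state, events) {
  for (evp in events) {
    if (evp$type == "lose") {
      lost <- state$feat$gene_id[state$feat$replicon == evp$name]
      state <- opDropRep(state, evp$name)
      state$truth$plasmid[[length(state$truth$plasmid) + 1L]] <-
        list(type = "lose", name = evp$name, gene_ids = lost)
    } else if (evp$type == "gain") {
      local <- withLocalSeed(evp$seed, {
        ins <- buildGeneInsert(evp$nGenes,
                               evp$categories %||%
                                 c(cell_cycle = 0.5, defense = 0.3,
                                   signal_transduction = 0.2),
                               paste0("g", evp$name, "_%03d"),
                               product = "plasmid protein")
        if (length(ins$chars) < evp$length)
          ins$chars <- c(ins$chars,
                         strsplit(randDna(evp$length - length(ins$chars),
                                          0.5), "", fixed = TRUE)[[1]])
        ins
      })
      state <- opAddRep(state, evp$name, local$chars)
      state <- addFeatures(state, evp$name, local, 0L)
      state$truth$plasmid[[length(state$truth$plasmid) + 1L]] <-
        list(type = "gain", name = evp$name,
             gene_ids = local$feat$gene_id)
    } else if (evp$type == "fuse") {
      state <- fusePlasmid(state, evp)
    } else stopf("unknown plasmid event type: %s", evp$type)
  }
  state
}

fusePlasmid <- function(state, evp) {
  repl <- evp$name
  if (!repl %in% names(state$seqs)) stopf("no such plasmid: %s", repl)
  fi <- which(state$feat$replicon == repl & state$feat$kind == "CDS")
  fi <- fi[order(state$feat$start[fi])]
  pair <- NULL
  for (i in seq_len(length(fi) - 1L)) {
    gap <- state$feat$start[fi[i + 1L]] - state$feat$end[fi[i]] - 1L
    nxt <- if (i + 2L <= length(fi))
      state$feat$start[fi[i + 2L]] - state$feat$end[fi[i + 1L]] - 1L
      else length(state$seqs[[repl]]) - state$feat$end[fi[i + 1L]]
    if (gap >= 20L && nxt >= 40L) { pair <- fi[i + 0:1]; break }
  }
  if (is.null(pair)) stopf("no adjacent gene pair with room for fusion")
  a <- state$feat[pair[1L], ]; b <- state$feat[pair[2L], ]
  backboneLen <- length(state$seqs[[repl]])
  p <- b$end + 10L
  dupChars <- state$seqs[[repl]][a$start:b$end]
  local <- withLocalSeed(evp$seed, {
    buildGeneInsert(evp$nGenes,
                    evp$categories %||%
                      c(metabolism = 0.5, cell_cycle = 0.3, membrane = 0.2),
                    paste0("x", evp$newName, "_%03d"),
                    product = "plasmid protein")
  })
  if (!is.null(evp$length) && length(local$chars) < evp$length)
    local$chars <- c(local$chars,
                     strsplit(randDna(evp$length - length(local$chars), 0.5),
                              "", fixed = TRUE)[[1]])
  expLen <- length(local$chars)
  chars <- c(local$chars, dupChars)
  state <- opIns(state, repl, p, chars)
  state <- addFeatures(state, repl, local, p)
  # duplicate copies of the flanking pair
  dupFeat <- data.frame(
    gene_id = paste0(c(a$gene_id, b$gene_id), "__dup"), replicon = repl,
    start = p + expLen + (c(a$start, b$start) - a$start) + 1L,
    end = p + expLen + (c(a$end, b$end) - a$start) + 1L,
    strand = c(a$strand, b$strand), kind = "CDS",
    product = c(a$product, b$product), transcribed = TRUE,
    essential = FALSE, categories = c(a$categories, b$categories),
    origin = "dup_flank", stringsAsFactors = FALSE)
  state$feat <- rbind(state$feat, dupFeat)
  state$truth$duplicatedGeneIds <-
    union(state$truth$duplicatedGeneIds, c(a$gene_id, b$gene_id))
  newName <- evp$newName %||% paste0(repl, "F")
  state <- opRenameRep(state, repl, newName)
  state$truth$plasmid[[length(state$truth$plasmid) + 1L]] <-
    list(type = "fuse", name = newName, source = repl,
         backbone_len = backboneLen, flank_ids = c(a$gene_id, b$gene_id),
         dup_ids = dupFeat$gene_id,
         expanded_start = p + 1L, expanded_end = p + expLen,
         expanded_gene_ids = local$feat$gene_id)
  state
}

plantCrispr <- function(state, cr) {
  repl <- cr$replicon
  if (!repl %in% names(state$seqs)) stopf("no such replicon: %s", repl)
  arr <- withLocalSeed(cr$seed %||% 99L, {
    rpt <- randDna(cr$repeatLen, 0.5)
    spacers <- character(cr$nSpacers)
    while (anyDuplicated(spacers) || any(spacers == ""))
      spacers <- vapply(seq_len(cr$nSpacers),
                        function(i) randDna(cr$spacerLen, 0.5), "")
    list(rpt = rpt, spacers = spacers,
         seq = paste0(rpt, paste0(spacers, rpt, collapse = "")))
  })
  # largest intergenic gap
  fi <- which(state$feat$replicon == repl)
  L <- length(state$seqs[[repl]])
  bounds <- sort(c(0L, state$feat$start[fi] - 1L, state$feat$end[fi], L))
  gs <- bounds[seq(1L, length(bounds), 2L)]
  ge <- bounds[seq(2L, length(bounds), 2L)]
  sz <- ge - gs
  k <- which.max(sz)
  need <- nchar(arr$seq) + 20L
  if (sz[k] < need) stopf("no intergenic gap fits the CRISPR array")
  p <- gs[k] + (sz[k] - nchar(arr$seq)) %/% 2L
  state <- opIns(state, repl, p, strsplit(arr$seq, "", fixed = TRUE)[[1]])
  state$truth$crisprs <- rbind(state$truth$crisprs, data.frame(
    replicon = repl, start = p + 1L, end = p + nchar(arr$seq),
    repeat_seq = arr$rpt, n_repeats = cr$nSpacers + 1L,
    stringsAsFactors = FALSE))
  state$truth$crisprSpacers[[nrow(state$truth$crisprs)]] <- arr$spacers
  state
}

plantUniqueBlocks <- function(state, blocks, strain) {
  for (bi in seq_along(blocks)) {
    bl <- blocks[[bi]]
    local <- buildGeneInsert(bl$nGenes, bl$categories,
                             paste0(strain, "_u", bi, "_%03d"))
    fi <- which(state$feat$replicon == "chr")
    L <- length(state$seqs[["chr"]])
    ss <- sort(state$feat$start[fi]); ee <- sort(state$feat$end[fi])
    gs <- c(0L, ee); ge <- c(ss - 1L, L)
    sz <- ge - gs
    # keep clear of planted prophage / CRISPR spans and earlier blocks
    keepOut <- rbind(
      state$truth$prophages[state$truth$prophages$replicon == "chr",
                            c("elem_start", "elem_end")],
      setNames(state$truth$uniqueBlocks[
        state$truth$uniqueBlocks$replicon == "chr", c("start", "end")],
        c("elem_start", "elem_end")))
    clear <- vapply(seq_along(sz), function(i) {
      if (!nrow(keepOut)) return(TRUE)
      !any(keepOut$elem_start <= ge[i] & keepOut$elem_end >= gs[i] + 1L)
    }, TRUE)
    ok <- which(sz >= 60L & clear)
    if (!length(ok)) stopf("no intergenic gap for unique block")
    k <- ok[sample.int(length(ok), 1L)]
    p <- gs[k] + sz[k] %/% 2L
    n <- length(local$chars)
    state <- opIns(state, "chr", p, local$chars)
    state <- addFeatures(state, "chr", local, p)
    state$truth$uniqueBlocks <- rbind(state$truth$uniqueBlocks, data.frame(
      replicon = "chr", start = p + 1L, end = p + n,
      n_genes = bl$nGenes, stringsAsFactors = FALSE))
  }
  state
}
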