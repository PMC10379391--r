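#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the simulator in one validated list. Defaults
#' give a small vertebrate-like panel: eight species on a fixed topology
#' with primate-to-fish divergences, a 2 kb locus, HKY-style substitutions
#' (equal base frequencies, transition/transversion rate ratio `kappa`,
#' optional CpG transition multiplier), rare 1-bp indels, a catalog in
#' which benign variants are planted shared far more often than pathogenic
#' ones, and an ancient cohort with terminal-deamination damage.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical
#'   outputs.
#' @param tree newick string with branch lengths (expected substitutions
#'   per site).
#' @param refSpecies name of the reference (human) tip.
#' @param length root sequence length in bp.
#' @param kappa transition/transversion rate ratio of the substitution
#'   model.
#' @param cpgMult extra multiplier on the transition rate at CpG-context
#'   sites (spontaneous deamination hotspots); 1 disables it.
#' @param indelRate 1-bp indel events per site per unit branch length.
#' @param maf list: `strandFlipProb` (probability a non-reference species
#'   is emitted on the '-' strand), `blockLen` (approximate reference
#'   length of one MAF block).
#' @param catalog list: `nPV`, `nBV`, `sharedFracPV`, `sharedFracBV`
#'   (fraction of each class planted at sites where at least one species
#'   carries the alternate allele), `nVUS` (uncertain rows, excluded by
#'   the catalog filter), `nDel`, `nDup` (1-bp indel variants, planted
#'   where the alignment supports them).
#' @param ancient list: `nSamples`, `coverage` (mean fold-coverage),
#'   `readLen`, `baseError`, `deamRate` (per-base C>T probability inside
#'   the damage window), `damageWindow` (bases from the read 5' terminus),
#'   `dateRange` (years BP, carriers dated uniformly), `locations`
#'   (labels), `carrierProb` (probability a sample carries at least one
#'   catalog variant).
#' @return a list of class `"SimConfig"`.
#' @export
simConfig <- function(
    seed = 1L,
    tree = paste0("((human:0.01,(rhesus:0.04,bushbaby:0.07):0.03):0.09,",
                  "((mouse:0.2,rat:0.2):0.15,(dog:0.18,",
                  "(chicken:0.5,zebrafish:0.9):0.15):0.05):0.05);"),
    refSpecies = "human",
    length = 2000L,
    kappa = 4,
    cpgMult = 1,
    indelRate = 0.003,
    maf = list(),
    catalog = list(),
    ancient = list()) {
  dflt <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    seed = as.integer(seed), tree = tree, refSpecies = refSpecies,
    length = as.integer(length), kappa = kappa, cpgMult = cpgMult,
    indelRate = indelRate,
    maf = dflt(maf, list(strandFlipProb = 0.3, blockLen = 500L)),
    catalog = dflt(catalog, list(nPV = 30L, nBV = 60L,
                                 sharedFracPV = 0.15, sharedFracBV = 0.9,
                                 nVUS = 5L, nDel = 2L, nDup = 2L)),
    ancient = dflt(ancient, list(
      nSamples = 12L, coverage = 8, readLen = 60L, baseError = 0.002,
      deamRate = 0.2, damageWindow = 2L, dateRange = c(270, 48426),
      locations = c("Anatolia", "Steppe", "Iberia", "TianShan",
                    "Levant", "Britain"),
      carrierProb = 0.5)))
  stopifnot(cfg$length > 0L, cfg$kappa > 0, cfg$cpgMult >= 1,
            cfg$indelRate >= 0,
            cfg$ancient$deamRate >= 0, cfg$ancient$deamRate <= 1)
  class(cfg) <- "SimConfig"
  cfg
}

#' Read a simulator configuration from YAML
#'
#' The YAML holds any subset of the [simConfig()] arguments (nested
#' `maf`, `catalog`, `ancient` sections included); unspecified fields
#' take the defaults.
#'
#' @param path path to a YAML file.
#' @param seed optional seed overriding the file's value.
#' @return a `"SimConfig"` list.
#' @export
readSimConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  known <- names(formals(simConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    pvStop(paste("unknown simulator config fields:",
                 paste(bad, collapse = ", ")), "inputError")
  do.call(simConfig, y)
}

BASES <- c("A", "C", "G", "T")

## K80 transition probabilities for branch length t (expected
## substitutions per site) and rate ratio kappa: the rate matrix is
## normalized to one substitution per site per unit t.
k80Probs <- function(t, kappa) {
  a <- kappa / (kappa + 2); b <- 1 / (kappa + 2)
  e1 <- exp(-4 * b * t); e2 <- exp(-2 * (a + b) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)   # each of the two transversions
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

## Substitute one sequence along a branch. CpG-context sites (C followed
## by G, or G preceded by C, in the parent) use kappa * cpgMult.
substituteBranch <- function(bases, t, kappa, cpgMult) {
  n <- length(bases)
  if (n == 0L || t <= 0) return(bases)
  cpg <- rep(FALSE, n)
  if (cpgMult > 1 && n > 1L) {
    cpg[-n] <- bases[-n] == "C" & bases[-1L] == "G"
    cpg[-1L] <- cpg[-1L] | (bases[-1L] == "G" & bases[-n] == "C")
  }
  pN <- k80Probs(t, kappa)
  pC <- if (any(cpg)) k80Probs(t, kappa * cpgMult) else pN
  u <- stats::runif(n)
  out <- bases
  pTsEnd <- ifelse(cpg, pC["same"] + pC["ts"], pN["same"] + pN["ts"])
  pSame <- ifelse(cpg, pC["same"], pN["same"])
  pTv1End <- pTsEnd + ifelse(cpg, pC["tv"], pN["tv"])
  isTs <- u >= pSame & u < pTsEnd
  isTv1 <- u >= pTsEnd & u < pTv1End
  isTv2 <- u >= pTv1End
  out[isTs] <- TRANSITION[bases[isTs]]
  out[isTv1] <- vapply(bases[isTv1], function(b) TRANSVERSIONS[[b]][1L],
                       "")
  out[isTv2] <- vapply(bases[isTv2], function(b) TRANSVERSIONS[[b]][2L],
                       "")
  out
}

## Apply Poisson 1-bp indels along a branch. Sequences are kept as
## (keys, bases): keys are real numbers defining global column order, so
## the true multiple alignment can be reassembled exactly.
indelBranch <- function(keys, bases, t, rate) {
  nEv <- stats::rpois(1L, rate * t * length(bases))
  for (e in seq_len(nEv)) {
    n <- length(bases)
    if (n < 2L) break
    if (stats::runif(1) < 0.5) {            # deletion
      i <- sample.int(n, 1L)
      keys <- keys[-i]; bases <- bases[-i]
    } else {                                # insertion
      i <- sample.int(n + 1L, 1L) - 1L      # insert after position i
      lo <- if (i == 0L) keys[1L] - 1 else keys[i]
      hi <- if (i == n) keys[n] + 1 else keys[i + 1L]
      k <- stats::runif(1L, lo, hi)
      keys <- append(keys, k, after = i)
      bases <- append(bases, sample(BASES, 1L), after = i)
    }
  }
  list(keys = keys, bases = bases)
}

#' Evolve sequences along a phylogeny with known true alignment
#'
#' Draws a random root sequence and evolves it along the configured
#' newick tree under the HKY-style substitution model (equal base
#' frequencies; transition bias `kappa`, optionally elevated at CpG
#' sites) with rare 1-bp indels. Every residue carries a persistent
#' column key, so the returned per-species sequences come with their true
#' column-level multiple alignment.
#'
#' @param cfg a [simConfig()] list.
#' @return a list of class `"EvolvedAlignment"`: `species`, `matrix`
#'   (species x alignment-column character matrix, `-` for gaps),
#'   `refSpecies`, `refSeq` (ungapped reference string), `refCols`
#'   (alignment column of each reference base).
#' @export
evolveSequences <- function(cfg) {
  set.seed(cfg$seed)
  tree <- tryCatch(ape::read.tree(text = cfg$tree), error = function(e) NULL)
  if (is.null(tree) || is.null(tree$edge.length))
    pvStop("malformed newick tree (branch lengths required)",
           "newickParseError")
  root <- ape::Ntip(tree) + 1L
  rootSeq <- sample(BASES, cfg$length, replace = TRUE)
  seqs <- list()
  seqs[[root]] <- list(keys = as.numeric(seq_len(cfg$length)),
                       bases = rootSeq)
  tree <- stats::reorder(tree)   # cladewise: parents before children
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
    t <- tree$edge.length[i]
    s <- seqs[[par]]
    b <- substituteBranch(s$bases, t, cfg$kappa, cfg$cpgMult)
    seqs[[child]] <- indelBranch(s$keys, b, t, cfg$indelRate)
  }
  tips <- seq_len(ape::Ntip(tree))
  species <- tree$tip.label
  if (!cfg$refSpecies %in% species)
    pvStop(paste0("reference species '", cfg$refSpecies,
                  "' is not a tip of the tree"), "inputError")
  allKeys <- sort(unique(unlist(lapply(seqs[tips], `[[`, "keys"))))
  mat <- matrix("-", nrow = length(species), ncol = length(allKeys),
                dimnames = list(species, NULL))
  for (i in tips) {
    s <- seqs[[i]]
    mat[species[i], match(s$keys, allKeys)] <- s$bases
  }
  refCols <- which(mat[cfg$refSpecies, ] != "-")
  structure(list(species = species, matrix = mat,
                 refSpecies = cfg$refSpecies,
                 refSeq = paste(mat[cfg$refSpecies, refCols],
                                collapse = ""),
                 refCols = refCols),
            class = "EvolvedAlignment")
}

#' Emit an evolved alignment as MAF text
#'
#' Splits the true alignment into blocks at randomized reference
#' positions and writes UCSC-dialect MAF. Each non-reference species is,
#' with probability `strandFlipProb`, annotated on the `-` strand: the
#' aligned text is unchanged (it is the alignment frame), the row's
#' source is the reverse complement of the species' evolved sequence and
#' the start offset is expressed strand-relatively, exactly as MAF
#' prescribes. Species with no aligned base in a block get no row there.
#'
#' @param evo an `EvolvedAlignment` from [evolveSequences()].
#' @param cfg the [simConfig()] used (controls `maf$strandFlipProb`,
#'   `maf$blockLen` and the seed).
#' @param path optional output file.
#' @return list of class `"MafEmission"`: `lines` (MAF text),
#'   `strand` (named per-species strand), `sources` (named per-species
#'   forward source sequences implied by the strand annotation).
#' @export
emitMaf <- function(evo, cfg, path = NULL) {
  set.seed(cfg$seed + 1L)
  mat <- evo$matrix
  species <- rownames(mat)
  ref <- evo$refSpecies
  refLen <- length(evo$refCols)
  flip <- stats::setNames(stats::runif(length(species)) <
                            cfg$maf$strandFlipProb, species)
  flip[ref] <- FALSE

  nBlocks <- max(1L, ceiling(refLen / cfg$maf$blockLen))
  cuts <- if (nBlocks > 1L)
    sort(sample(seq_len(refLen - 1L), nBlocks - 1L)) else integer()
  bounds <- c(0L, cuts, refLen)            # ref-position block bounds

  rowSeq <- apply(mat, 1L, function(ch) paste(ch, collapse = ""))
  ungapped <- vapply(rowSeq, function(s)
    gsub("-", "", s, fixed = TRUE), "")
  srcSize <- nchar(ungapped)
  sources <- ifelse(flip[species],
                    vapply(ungapped, revCompStr, ""), ungapped)
  names(sources) <- species

  lines <- "##maf version=1"
  ncolTot <- ncol(mat)
  for (b in seq_len(length(bounds) - 1L)) {
    a0 <- bounds[b]; b0 <- bounds[b + 1L]
    colStart <- if (b == 1L) 1L else evo$refCols[a0 + 1L]
    colEnd <- if (b0 < refLen) evo$refCols[b0 + 1L] - 1L else ncolTot
    lines <- c(lines, "a score=0.000000")
    ord <- c(ref, setdiff(species, ref))
    for (sp in ord) {
      txt <- substr(rowSeq[sp], colStart, colEnd)
      size <- nchar(gsub("-", "", txt, fixed = TRUE))
      if (size == 0L) next
      fwdStart <- nchar(gsub("-", "",
                             substr(rowSeq[sp], 1L, colStart - 1L),
                             fixed = TRUE))
      strand <- if (flip[sp]) "-" else "+"
      lines <- c(lines, paste("s", paste0(sp, ".chr1"), fwdStart, size,
                              strand, srcSize[sp], txt))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  structure(list(lines = lines,
                 strand = stats::setNames(ifelse(flip, "-", "+"), species),
                 sources = sources),
            class = "MafEmission")
}

## Sharing truth for one planted variant, computed directly on the true
## alignment matrix (independent of the MAF parsing/indexing path).
truthCall <- function(evo, pos, kind, refBase, altBase, k = 3L) {
  mat <- evo$matrix
  refChars <- strsplit(evo$refSeq, "")[[1]]
  others <- setdiff(rownames(mat), evo$refSpecies)
  out <- stats::setNames(rep("no_alignment", length(others)), others)
  if (kind == "SNV") {
    col <- evo$refCols[pos + 1L]
    for (sp in others) {
      ch <- mat[sp, col]
      out[sp] <- if (ch %in% c("-", "N")) "no_alignment"
                 else if (ch == altBase) "shared" else "not_shared"
    }
    return(out)
  }
  ## indels: homopolymer run around the site, then flank check
  b <- if (kind == "del1") refBase else altBase
  lo <- pos; hi <- pos
  if (kind == "del1") {
    while (lo > 0L && refChars[lo] == b) lo <- lo - 1L
    while (hi + 2L <= length(refChars) && refChars[hi + 2L] == b)
      hi <- hi + 1L
  } else {
    lo <- pos; hi <- pos
    while (hi + 2L <= length(refChars) && refChars[hi + 2L] == b)
      hi <- hi + 1L
    hi <- hi + 1L   # far flank base beyond the run
  }
  flankLo <- lo - k; flankHi <- hi + k
  if (flankLo < 0L || flankHi >= length(refChars)) {
    out[] <- "no_alignment"; return(out)
  }
  for (sp in others) {
    flanks <- c(flankLo:(lo - 1L), (hi + 1L):flankHi)
    fc <- mat[sp, evo$refCols[flanks + 1L]]
    rc <- refChars[flanks + 1L]
    if (any(fc %in% c("-", "N"))) { out[sp] <- "no_alignment"; next }
    if (any(fc != rc)) { out[sp] <- "not_shared"; next }
    if (kind == "del1") {
      runCols <- evo$refCols[(lo:hi) + 1L]
      spRun <- mat[sp, runCols]
      if (any(spRun == "N")) out[sp] <- "no_alignment"
      else if (any(spRun == "-") &&
               all(spRun[spRun != "-"] ==
                   refChars[(lo:hi) + 1L][spRun != "-"]))
        out[sp] <- "shared"
      else out[sp] <- "not_shared"
    } else {
      c1 <- evo$refCols[pos + 1L]; c2 <- evo$refCols[hi + 1L]
      if (c2 - c1 < 2L) { out[sp] <- "not_shared"; next }
      inner <- setdiff(seq(c1, c2), evo$refCols)
      innerRef <- setdiff(seq(c1 + 1L, c2 - 1L), inner)
      spInner <- mat[sp, innerRef]
      if (length(innerRef) &&
          (any(spInner %in% c("-", "N")))) { out[sp] <- "no_alignment"; next }
      if (length(innerRef) &&
          any(spInner != mat[evo$refSpecies, innerRef])) {
        out[sp] <- "not_shared"; next
      }
      out[sp] <- if (length(inner) && any(mat[sp, inner] == b))
        "shared" else "not_shared"
    }
  }
  out
}

#' Plant a variant catalog with known sharing truth
#'
#' Places SNVs (and optionally clean 1-bp indels) on the reference
#' sequence of an evolved alignment. For each class, a configured
#' fraction is planted at sites where at least one non-reference species
#' carries the chosen alternate allele ("shared"); the rest at sites
#' where no species does. Uncertain-significance decoy rows are added to
#' exercise the catalog filter. The per-species sharing truth of every
#' planted variant is computed directly from the true alignment.
#'
#' @param cfg a [simConfig()] list.
#' @param evo an `EvolvedAlignment` from [evolveSequences()].
#' @return a list: `table` (raw variant table for [buildCatalog()]),
#'   `truth` (variant x species matrix of sharing calls, catalog rows
#'   only), `transcript` (the single-exon plus-strand
#'   \linkS4class{TranscriptModel} covering the locus), `planted`
#'   (data.frame with `hgvs_c, pos, ref, alt, kind, var_class`).
#' @export
plantCatalog <- function(cfg, evo) {
  set.seed(cfg$seed + 2L)
  refChars <- strsplit(evo$refSeq, "")[[1]]
  refLen <- length(refChars)
  mat <- evo$matrix
  others <- setdiff(rownames(mat), evo$refSpecies)
  cs <- cfg$catalog
  tm <- TranscriptModel("sim_tx", "sim_ref", "+", 0L, refLen, 0L, refLen)

  avail <- sample(seq_len(refLen) - 1L)    # shuffled 0-based positions
  used <- logical(refLen)
  planted <- list()
  pickSnv <- function(wantShared, cls) {
    for (p in avail) {
      if (used[p + 1L]) next
      col <- evo$refCols[p + 1L]
      spBases <- mat[others, col]
      spBases <- spBases[!spBases %in% c("-", "N")]
      refB <- refChars[p + 1L]
      diffB <- setdiff(unique(spBases), refB)
      if (wantShared) {
        if (!length(diffB)) next
        alt <- if (length(diffB) == 1L) diffB else sample(diffB, 1L)
      } else {
        cand <- setdiff(BASES, c(refB, unique(spBases)))
        if (!length(cand)) next
        alt <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
      used[p + 1L] <<- TRUE
      return(data.frame(hgvs_c = paste0("c.", p + 1L, refB, ">", alt),
                        pos = p, ref = refB, alt = alt, kind = "SNV",
                        var_class = cls, stringsAsFactors = FALSE))
    }
    pvStop(paste0("cannot plant a ", if (wantShared) "shared" else
                  "non-shared", " ", cls,
                  " SNV on this alignment; lower the requested fraction ",
                  "or counts"), "generationError")
  }
  for (cls in c("PV", "BV")) {
    nCls <- if (cls == "PV") cs$nPV else cs$nBV
    frac <- if (cls == "PV") cs$sharedFracPV else cs$sharedFracBV
    nShared <- round(frac * nCls)
    for (i in seq_len(nCls))
      planted[[length(planted) + 1L]] <- pickSnv(i <= nShared, cls)
  }
  ## clean 1-bp indels: deletions where >=1 species is gapped, insertions
  ## where >=1 species has an extra base; only outside homopolymers so
  ## left-normalization is the identity
  pickIndel <- function(kind, nWant) {
    got <- 0L
    for (p in avail) {
      if (got >= nWant) break
      if (used[p + 1L] || p < 4L || p > refLen - 5L) next
      refB <- refChars[p + 1L]
      if (p > 0L && refChars[p] == refB) next
      if (refChars[p + 2L] == refB) next
      if (kind == "del1") {
        col <- evo$refCols[p + 1L]
        if (!any(mat[others, col] == "-")) next
        tr <- truthCall(evo, p, "del1", refB, NA)
        if (!any(tr == "shared")) next
        used[p + 1L] <<- TRUE; got <- got + 1L
        planted[[length(planted) + 1L]] <<- data.frame(
          hgvs_c = paste0("c.", p + 1L, "del", refB), pos = p,
          ref = refB, alt = "", kind = "del1", var_class = "PV",
          stringsAsFactors = FALSE)
      } else {
        c1 <- evo$refCols[p + 1L]; c2 <- evo$refCols[p + 2L]
        if (c2 - c1 < 2L) next                 # no insertion columns here
        gapCols <- (c1 + 1L):(c2 - 1L)
        insBases <- unique(as.vector(mat[others, gapCols, drop = FALSE]))
        insBases <- setdiff(insBases, c("-", "N"))
        insBases <- setdiff(insBases,
                            c(refB, refChars[p + 2L]))  # keep normalization trivial
        if (!length(insBases)) next
        bIns <- insBases[1L]
        used[p + 1L] <<- TRUE; got <- got + 1L
        planted[[length(planted) + 1L]] <<- data.frame(
          hgvs_c = paste0("c.", p + 1L, "_", p + 2L, "ins", bIns),
          pos = p, ref = "", alt = bIns, kind = "ins1", var_class = "PV",
          stringsAsFactors = FALSE)
      }
    }
    got
  }
  gotDel <- if (cs$nDel > 0L) pickIndel("del1", cs$nDel) else 0L
  gotDup <- if (cs$nDup > 0L) pickIndel("ins1", cs$nDup) else 0L
  if (gotDel < cs$nDel || gotDup < cs$nDup)
    warning("planted only ", gotDel, " deletions and ", gotDup,
            " insertions; the alignment offers no further clean sites")

  pl <- do.call(rbind, planted)
  truth <- t(vapply(seq_len(nrow(pl)), function(i)
    truthCall(evo, pl$pos[i], pl$kind[i], pl$ref[i], pl$alt[i]),
    character(length(others))))
  rownames(truth) <- pl$hgvs_c

  sig <- ifelse(pl$var_class == "PV",
                sample(c("Pathogenic", "Likely pathogenic"), nrow(pl),
                       replace = TRUE),
                sample(c("Benign", "Likely benign"), nrow(pl),
                       replace = TRUE))
  cons <- sample(c("nonsynonymous SNV", "synonymous SNV", "stopgain",
                   "intron"), nrow(pl), replace = TRUE)
  tab <- data.frame(name = pl$hgvs_c, protein = NA_character_,
                    significance = sig, consequence = cons,
                    stringsAsFactors = FALSE)
  if (cs$nVUS > 0L) {
    vusPos <- sample(which(!used), cs$nVUS) - 1L
    vus <- data.frame(
      name = paste0("c.", vusPos + 1L, refChars[vusPos + 1L], ">",
                    vapply(refChars[vusPos + 1L], function(b)
                      sample(setdiff(BASES, b), 1L), "")),
      protein = NA_character_,
      significance = "Uncertain significance",
      consequence = "nonsynonymous SNV", stringsAsFactors = FALSE)
    tab <- rbind(tab, vus)
  }
  tab <- tab[sample(nrow(tab)), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, truth = truth, transcript = tm, planted = pl)
}

#' Simulate ancient-sample pileups with deamination damage
#'
#' Draws a dated, located cohort; plants catalog SNVs as carried alleles
#' in randomly chosen samples; and samples reads at the configured
#' coverage with sequencing error and post-mortem damage: within
#' `damageWindow` bases of a read's 5' terminus each C is read as T with
#' probability `deamRate` (on reverse-orientation reads this appears as
#' G>A at the reference-frame right end of the aligned span). Carried
#' alleles are present on every read of the sample (presence/absence
#' genotypes; diploidy is not modeled).
#'
#' @param cfg a [simConfig()] list.
#' @param evo an `EvolvedAlignment` (supplies the reference sequence).
#' @param planted data.frame of catalog SNVs (`hgvs_c, pos, ref, alt,
#'   kind`) from [plantCatalog()]; indel rows are ignored.
#' @return list: `pileup` (long observation table, see [readPileup()]),
#'   `samples` (metadata), `truthCarriers` (data.frame `sample_id,
#'   hgvs_c, pos, alt`), `damageEvents` (data.frame `sample_id, pos`).
#' @export
simulateAncient <- function(cfg, evo, planted) {
  set.seed(cfg$seed + 3L)
  ac <- cfg$ancient
  refChars <- strsplit(evo$refSeq, "")[[1]]
  L <- length(refChars)
  RL <- ac$readLen
  if (RL >= L) pvStop("read length must be below the region length",
                      "inputError")
  snvs <- planted[planted$kind == "SNV", , drop = FALSE]

  ids <- sprintf("anc%02d", seq_len(ac$nSamples))
  samples <- data.frame(
    sample_id = ids,
    date_bp = round(stats::runif(ac$nSamples, ac$dateRange[1L],
                                 ac$dateRange[2L])),
    location = sample(ac$locations, ac$nSamples, replace = TRUE),
    lat = round(stats::runif(ac$nSamples, -35, 65), 3),
    lon = round(stats::runif(ac$nSamples, -10, 120), 3),
    source_ref = "synthetic cohort", stringsAsFactors = FALSE)

  truth <- list(); piles <- list(); dmg <- list()
  for (s in seq_len(ac$nSamples)) {
    personal <- refChars
    if (nrow(snvs) && stats::runif(1) < ac$carrierProb) {
      idx <- sample(nrow(snvs), min(nrow(snvs), sample(1:2, 1L)))
      ## keep planted carrier sites away from the region edges so the
      ## nominal coverage applies
      idx <- idx[snvs$pos[idx] >= RL & snvs$pos[idx] < L - RL]
      if (length(idx)) {
        personal[snvs$pos[idx] + 1L] <- snvs$alt[idx]
        truth[[s]] <- data.frame(sample_id = ids[s],
                                 hgvs_c = snvs$hgvs_c[idx],
                                 pos = snvs$pos[idx],
                                 alt = snvs$alt[idx],
                                 stringsAsFactors = FALSE)
      }
    }
    nReads <- stats::rpois(1L, ac$coverage * L / RL)
    if (nReads == 0L) next
    starts <- sample(0:(L - RL), nReads, replace = TRUE)
    rev <- stats::rbinom(nReads, 1L, 0.5)
    pos <- rep(starts, each = RL) + 0:(RL - 1L)
    j <- rep.int(0:(RL - 1L), nReads)
    rv <- rep(rev, each = RL)
    base <- personal[pos + 1L]
    dist5 <- ifelse(rv == 1L, RL - 1L - j, j)
    ## terminal deamination
    cand <- dist5 <= ac$damageWindow &
      ((rv == 0L & base == "C") | (rv == 1L & base == "G"))
    hit <- cand & stats::runif(length(base)) < ac$deamRate
    base[hit & rv == 0L] <- "T"
    base[hit & rv == 1L] <- "A"
    if (any(hit))
      dmg[[length(dmg) + 1L]] <- data.frame(sample_id = ids[s],
                                            pos = pos[hit],
                                            stringsAsFactors = FALSE)
    ## sequencing error
    err <- stats::runif(length(base)) < ac$baseError
    if (any(err))
      base[err] <- vapply(base[err], function(b)
        sample(setdiff(BASES, b), 1L), "")
    qual <- pmin(41L, pmax(2L, as.integer(round(stats::rnorm(
      length(base), 35, 3)))))
    piles[[length(piles) + 1L]] <- data.frame(
      sample_id = ids[s], pos = pos, base = base, qual = qual,
      dist5 = dist5, dist3 = RL - 1L - dist5, reverse = rv,
      stringsAsFactors = FALSE)
  }
  list(pileup = if (length(piles)) do.call(rbind, piles) else
         data.frame(sample_id = character(), pos = integer(),
                    base = character(), qual = integer(),
                    dist5 = integer(), dist3 = integer(),
                    reverse = integer()),
       samples = samples,
       truthCarriers = if (length(truth)) do.call(rbind, truth) else
         data.frame(sample_id = character(), hgvs_c = character(),
                    pos = integer(), alt = character()),
       damageEvents = if (length(dmg)) do.call(rbind, dmg) else
         data.frame(sample_id = character(), pos = integer()))
}

#' Run the full synthetic study and write every pipeline input
#'
#' Orchestrates [evolveSequences()], [emitMaf()], [plantCatalog()] and
#' [simulateAncient()] and writes their outputs to `dir`: `alignment.maf`,
#' `reference.fa`, `variants.tsv`, `samples.tsv`, `pileup.tsv`,
#' `clades.yaml` and `truth.json`. With a fixed `cfg$seed` the outputs
#' are byte-identical across runs.
#'
#' @param cfg a [simConfig()] list.
#' @param dir output directory (created if needed).
#' @param clades optional named list assigning the simulated species to
#'   clades; defaults to a two-clade mammal/non-mammal split of the
#'   default tree's tips (reference excluded).
#' @return (invisibly) a list with the generated objects and file paths.
#' @export
simulateStudy <- function(cfg, dir, clades = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  evo <- evolveSequences(cfg)
  emission <- emitMaf(evo, cfg, file.path(dir, "alignment.maf"))
  plant <- plantCatalog(cfg, evo)
  anc <- simulateAncient(cfg, evo, plant$planted)

  ref <- Biostrings::DNAStringSet(evo$refSeq)
  names(ref) <- "sim_ref"
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fa"))
  utils::write.table(plant$table, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(transcript_id = "sim_tx", chrom = "sim_ref", strand = "+",
         exons = list(c(0L, nchar(evo$refSeq))),
         cds = c(0L, nchar(evo$refSeq))),
    file.path(dir, "transcript.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(anc$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(anc$pileup, file.path(dir, "pileup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(clades)) {
    sp <- setdiff(evo$species, evo$refSpecies)
    mam <- intersect(sp, c("rhesus", "bushbaby", "mouse", "rat", "dog"))
    clades <- list(Mammals = mam, NonMammals = setdiff(sp, mam))
    clades <- clades[vapply(clades, length, 0L) > 0L]
  }
  yaml::write_yaml(clades, file.path(dir, "clades.yaml"))
  jsonlite::write_json(
    list(sharing = list(variant = rownames(plant$truth),
                        species = colnames(plant$truth),
                        calls = plant$truth),
         carriers = anc$truthCarriers,
         strand = as.list(emission$strand)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(list(cfg = cfg, evo = evo, emission = emission,
                 plant = plant, ancient = anc, clades = clades,
                 dir = dir,
                 paths = stats::setNames(
                   file.path(dir, c("alignment.maf", "reference.fa",
                                    "variants.tsv", "transcript.json",
                                    "samples.tsv", "pileup.tsv",
                                    "clades.yaml", "truth.json")),
                   c("maf", "reference", "variants", "transcript",
                     "samples", "pileup", "clades", "truth"))))
}
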