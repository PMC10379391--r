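#' Score cross-species sharing of a single SNV
#'
#' A species shares a human SNV iff its aligned base equals the human
#' alternate allele exactly; showing the human reference allele or any
#' third base is `not_shared`; a gap, `N` or missing alignment is
#' `no_alignment`.
#'
#' @param alt the human alternate allele (forward strand, single base).
#' @param state a species base state as returned by [getBase()].
#' @return `"shared"`, `"not_shared"` or `"no_alignment"`.
#' @export
isSharedSnv <- function(alt, state) {
  if (state %in% c("gap", "N", "absent")) "no_alignment"
  else if (state == alt) "shared"
  else "not_shared"
}

## Fetch the aligned characters of `species` and of the reference for a run
## of reference positions [lo, hi], all of which must fall in one block.
## Returns NULL if not fully covered by a single block.
speciesRun <- function(maf, species, lo, hi) {
  a <- mafLocate(maf, lo); b <- mafLocate(maf, hi)
  if (is.null(a) || is.null(b) || a$i != b$i) return(NULL)
  blk <- maf@blocks[[a$i]]
  r <- match(species, blk$species)
  if (is.na(r)) return(NA)
  cols <- blk$colMap[(lo - maf@refStarts[a$i] + 1L):
                     (hi - maf@refStarts[a$i] + 1L)]
  ref <- toupper(strsplit(blk$text[blk$refRow], "")[[1]])
  sp <- toupper(strsplit(blk$text[r], "")[[1]])
  list(blk = a$i, cols = cols, ref = ref, sp = sp)
}

## Check the k flanking reference-base positions on each side of
## [lo, hi]: returns "ok", "no_alignment" (insufficient columns in the
## block, or species gap/N in a flank) or "not_shared" (flank mismatch).
checkFlanks <- function(maf, species, lo, hi, k) {
  run <- speciesRun(maf, species, lo - k, hi + k)
  if (is.null(run)) return("no_alignment")
  if (!is.list(run)) return("no_alignment")     # species absent from block
  flankCols <- c(run$cols[seq_len(k)], run$cols[(length(run$cols) - k + 1L):
                                                length(run$cols)])
  s <- run$sp[flankCols]; r <- run$ref[flankCols]
  if (any(s %in% c("-", "N"))) return("no_alignment")
  if (any(s != r)) return("not_shared")
  "ok"
}

#' Score cross-species sharing of a 1-bp indel
#'
#' A species shares a human 1-bp deletion iff it shows a gap aligned to the
#' deleted reference base (any base of the homopolymer run containing it —
#' catalog indels are left-normalized) and the `k` nearest reference bases
#' on each side of the run align cleanly (species base present and equal to
#' the reference). A duplication/insertion is shared iff the species
#' carries an extra copy of the inserted base in a column where the
#' reference row is gapped, immediately after the anchor (within the run of
#' the inserted base), under the same flank rule. Insufficient flanks —
#' block edge, species gap or `N` in a flank column — give
#' `no_alignment`; a flank mismatch gives `not_shared`. Raising `k` can
#' therefore only downgrade a call, never turn `not_shared` into
#' `shared`.
#'
#' @param variant one catalog row (list or single-row data.frame) with
#'   `pos`, `ref`, `alt`, `kind`.
#' @param maf a \linkS4class{MafAlignment}.
#' @param species species name.
#' @param k flank width in reference bases (default 3).
#' @return `"shared"`, `"not_shared"` or `"no_alignment"`.
#' @export
isSharedIndel <- function(variant, maf, species, k = 3L) {
  pos <- as.integer(variant$pos)
  kind <- variant$kind
  if (!kind %in% c("del1", "dup1", "ins1"))
    pvStop("isSharedIndel needs an indel variant", "inputError")

  refAt <- function(p) {
    loc <- mafLocate(maf, p)
    if (is.null(loc)) return(NA_character_)
    blk <- maf@blocks[[loc$i]]
    toupper(substr(blk$text[blk$refRow], loc$col, loc$col))
  }

  if (kind == "del1") {
    b <- toupper(variant$ref)
    ## homopolymer run of the deleted base containing pos
    lo <- pos; hi <- pos
    while (!is.na(refAt(lo - 1L)) && refAt(lo - 1L) == b) lo <- lo - 1L
    while (!is.na(refAt(hi + 1L)) && refAt(hi + 1L) == b) hi <- hi + 1L
    fl <- checkFlanks(maf, species, lo, hi, k)
    if (fl != "ok") return(fl)
    run <- speciesRun(maf, species, lo, hi)
    spRun <- run$sp[run$cols]
    refRun <- run$ref[run$cols]
    if (any(spRun == "N")) return("no_alignment")
    if (any(spRun == "-")) {
      ## the non-gapped part of the run must still match the reference
      if (all(spRun[spRun != "-"] == refRun[spRun != "-"])) "shared"
      else "not_shared"
    } else "not_shared"
  } else {
    b <- toupper(variant$alt)
    ## run of the inserted base following the (left-normalized) anchor
    lo <- pos + 1L; hi <- pos
    while (!is.na(refAt(hi + 1L)) && refAt(hi + 1L) == b) hi <- hi + 1L
    ## flank region: anchor side [pos], far side [hi + 1]
    fl <- checkFlanks(maf, species, pos, hi + 1L, k)
    if (fl != "ok") return(fl)
    run <- speciesRun(maf, species, pos, hi + 1L)
    ## run reference bases (between anchor and far flank) must match
    inner <- run$cols[-c(1L, length(run$cols))]
    if (length(inner)) {
      if (any(run$sp[inner] %in% c("-", "N"))) return("no_alignment")
      if (any(run$sp[inner] != run$ref[inner])) return("not_shared")
    }
    ## inserted columns: reference gapped between anchor column and the
    ## column after the run
    first <- run$cols[1L]; last <- run$cols[length(run$cols)]
    if (last - first < 2L) return("not_shared")  # no room for a gap column
    cols <- (first + 1L):(last - 1L)
    gapCols <- cols[!(cols %in% run$cols)]
    if (length(gapCols) && any(run$sp[gapCols] == b)) "shared"
    else "not_shared"
  }
}

#' Project a catalog through a MAF alignment into a SharingMatrix
#'
#' Fills one cell per (variant, species) pair: SNVs via [getBase()] and
#' [isSharedSnv()], 1-bp indels via [isSharedIndel()]. The reference
#' species is excluded from the columns.
#'
#' @param catalog a \linkS4class{VariantCatalog} or its `variants`
#'   data.frame.
#' @param maf a \linkS4class{MafAlignment}.
#' @param species species to score; default all non-reference species in
#'   `maf`.
#' @param flank indel flank width `k` passed to [isSharedIndel()].
#' @return a \linkS4class{SharingMatrix}.
#' @export
computeSharing <- function(catalog, maf, species = NULL, flank = 3L) {
  v <- if (is(catalog, "VariantCatalog")) variants(catalog) else catalog
  if (is.null(species))
    species <- setdiff(mafSpecies(maf), maf@refSpecies)
  if (maf@refSpecies %in% species)
    pvStop("the reference species cannot be scored against itself",
           "inputError")
  m <- matrix("no_alignment", nrow = nrow(v), ncol = length(species),
              dimnames = list(v$hgvs_c, species))
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "SNV") {
      for (s in species)
        m[i, s] <- isSharedSnv(v$alt[i], getBase(maf, v$pos[i], s))
    } else {
      for (s in species)
        m[i, s] <- isSharedIndel(v[i, ], maf, s, k = flank)
    }
  }
  new("SharingMatrix", calls = m, varClass = v$var_class)
}

#' Restrict a SharingMatrix to one variant class
#'
#' @param sm a \linkS4class{SharingMatrix}.
#' @param class `"PV"` or `"BV"`.
#' @return a \linkS4class{SharingMatrix} with only that class's rows.
#' @export
subsetSharing <- function(sm, class) {
  keep <- variantClass(sm) == class
  new("SharingMatrix", calls = sm@calls[keep, , drop = FALSE],
      varClass = sm@varClass[keep])
}

#' Read a clade map from YAML
#'
#' The YAML maps clade names to species lists. Species sets must be
#' disjoint.
#'
#' @param path path to a YAML file.
#' @return named list of character vectors.
#' @export
readCladeMap <- function(path) {
  cl <- yaml::read_yaml(path)
  cl <- lapply(cl, as.character)
  all <- unlist(cl)
  if (anyDuplicated(all))
    pvStop("clade species sets must be disjoint", "cladeError")
  cl
}

#' Summarize a SharingMatrix per species, per clade and per variant
#'
#' Per-species sharing rate is the number of shared variants divided by
#' the total number of variants in the matrix (i.e. the full PV or BV
#' catalog size): `no_alignment` cells are excluded from the numerator but
#' not the denominator. Also reported: per-variant counts of sharing
#' species, and the overall fraction of variants shared with at least one
#' species.
#'
#' @param sm a \linkS4class{SharingMatrix}.
#' @param clades optional named list mapping clade name to species vector;
#'   must be disjoint and cover every matrix species.
#' @return a list with data.frames `species`, `variants`, optionally
#'   `clades`, and a list `overall` with `n_variants`,
#'   `n_variants_shared`, `variant_shared_pct`, `n_species_sharing`.
#' @export
sharingSummary <- function(sm, clades = NULL) {
  m <- sharingCalls(sm)
  nVar <- nrow(m)
  spDf <- data.frame(
    species = colnames(m),
    shared = colSums(m == "shared"),
    not_shared = colSums(m == "not_shared"),
    no_alignment = colSums(m == "no_alignment"),
    row.names = NULL, stringsAsFactors = FALSE)
  spDf$rate <- if (nVar) spDf$shared / nVar else 0
  varDf <- data.frame(
    hgvs_c = rownames(m), var_class = variantClass(sm),
    n_species_shared = rowSums(m == "shared"),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(species = spDf, variants = varDf)
  if (!is.null(clades)) {
    missing <- setdiff(colnames(m), unlist(clades))
    if (length(missing))
      pvStop(paste("species not covered by any clade:",
                   paste(missing, collapse = ", ")), "cladeError")
    spDf$clade <- NA_character_
    for (cl in names(clades))
      spDf$clade[spDf$species %in% clades[[cl]]] <- cl
    out$species <- spDf
    out$clades <- do.call(rbind, lapply(names(clades), function(cl) {
      sub <- spDf[!is.na(spDf$clade) & spDf$clade == cl, , drop = FALSE]
      data.frame(clade = cl, n_species = nrow(sub),
                 species_sharing = sum(sub$shared > 0),
                 total_shared = sum(sub$shared),
                 mean_rate = if (nrow(sub)) mean(sub$rate) else 0,
                 stringsAsFactors = FALSE)
    }))
  }
  nShared <- sum(varDf$n_species_shared > 0)
  out$overall <- list(
    n_variants = nVar, n_variants_shared = nShared,
    variant_shared_pct = if (nVar) round(100 * nShared / nVar, 1) else 0,
    n_species_sharing = sum(spDf$shared > 0))
  out
}

#' Write / read a SharingMatrix as TSV
#'
#' Cells are encoded `S` (shared), `N` (not shared), `.` (no alignment);
#' the first column is the variant key, the second its PV/BV class. This
#' TSV is the machine-readable equivalent of a variant-by-species sharing
#' heatmap.
#'
#' @param sm a \linkS4class{SharingMatrix}.
#' @param path file path.
#' @return `writeSharingMatrix` returns `path` invisibly;
#'   `readSharingMatrix` returns a \linkS4class{SharingMatrix}.
#' @export
writeSharingMatrix <- function(sm, path) {
  m <- sharingCalls(sm)
  enc <- matrix(c(shared = "S", not_shared = "N",
                  no_alignment = ".")[m], nrow = nrow(m),
                dimnames = dimnames(m))
  df <- data.frame(variant = rownames(m), var_class = variantClass(sm),
                   enc, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSharingMatrix
#' @export
readSharingMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$variant
  dec <- c(S = "shared", N = "not_shared", "." = "no_alignment")
  m2 <- matrix(dec[m], nrow = nrow(m), dimnames = dimnames(m))
  new("SharingMatrix", calls = m2, varClass = df$var_class)
}
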