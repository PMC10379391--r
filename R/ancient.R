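#' Read ancient-sample metadata
#'
#' TSV with columns `sample_id`, `date_bp` (years before present, point
#' estimate, > 0), `location`, and optionally `lat`, `lon`, `source_ref`.
#'
#' @param path path to a TSV file.
#' @return a data.frame.
#' @export
readSampleMeta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "date_bp", "location")
  if (!all(need %in% names(df)))
    pvStop(paste("sample metadata lacks columns:",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "inputError")
  if (any(df$date_bp <= 0))
    pvStop("date_bp must be positive", "inputError")
  df
}

#' Read per-sample pileup observations
#'
#' A samtools-mpileup-like long TSV, one row per base observation, with
#' columns `sample_id`, `pos` (0-based reference position), `base`
#' (A/C/G/T/N, reference forward strand), `qual` (phred base quality),
#' `dist5`, `dist3` (distance of the observation from the read's 5' / 3'
#' terminus, in the read's own orientation, 0-based) and `reverse`
#' (0/1, read maps to the reverse strand).
#'
#' @param path path to a TSV file.
#' @return a data.frame.
#' @export
readPileup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pos", "base", "qual", "dist5", "dist3", "reverse")
  if (!all(need %in% names(df)))
    pvStop(paste("pileup lacks columns:",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "inputError")
  if (any(df$dist5 < 0) || any(df$dist3 < 0))
    pvStop("read-end distances must be >= 0", "inputError")
  if (!all(df$base %in% c("A", "C", "G", "T", "N")))
    pvStop("pileup bases must be A/C/G/T/N", "inputError")
  df
}

#' Call variants from one sample's pileup by explicit thresholds
#'
#' A transparent threshold caller standing in for a full mapping/GATK
#' pipeline: at each position, observations with base quality below
#' `minBaseQual` are discarded; a non-reference base supported by at least
#' `minAltDepth` remaining observations is emitted as a call. Positions
#' with post-filter depth below `minDepth` are still reported (ancient
#' data are sparse) but flagged `low_depth`. Diploid genotype states are
#' not modeled: a call means presence of the alternate allele.
#'
#' @param pileup data.frame of one sample's observations (see
#'   [readPileup()]; the `sample_id` column is optional here).
#' @param reference forward-strand reference sequence (plain character)
#'   for the region.
#' @param refStart 0-based position of `reference[1]`.
#' @param minBaseQual minimum base quality q (default 20).
#' @param minAltDepth minimum alt-supporting observations a (default 2).
#' @param minDepth depth d below which calls are flagged `low_depth`
#'   (default 3).
#' @return data.frame with columns `pos, ref, alt, depth, alt_depth,
#'   low_depth, damage_suspect` (the last all `FALSE`; see
#'   [flagDamage()]).
#' @export
callVariants <- function(pileup, reference, refStart = 0L,
                         minBaseQual = 20L, minAltDepth = 2L,
                         minDepth = 3L) {
  empty <- data.frame(pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_depth = integer(), low_depth = logical(),
                      damage_suspect = logical(), stringsAsFactors = FALSE)
  if (!nrow(pileup)) return(empty)
  if (any(pileup$pos < refStart) ||
      any(pileup$pos >= refStart + nchar(reference)))
    pvStop("pileup positions fall outside the reference sequence",
           "inputError")
  p <- pileup[pileup$qual >= minBaseQual & pileup$base != "N", ,
              drop = FALSE]
  if (!nrow(p)) return(empty)
  refv <- strsplit(toupper(reference), "")[[1]]
  p$refBase <- refv[p$pos - refStart + 1L]
  depth <- table(p$pos)
  altObs <- p[p$base != p$refBase, , drop = FALSE]
  if (!nrow(altObs)) return(empty)
  cnt <- stats::aggregate(list(alt_depth = altObs$base),
                          by = list(pos = altObs$pos, alt = altObs$base),
                          FUN = length)
  cnt <- cnt[cnt$alt_depth >= minAltDepth, , drop = FALSE]
  if (!nrow(cnt)) return(empty)
  cnt$depth <- as.integer(depth[as.character(cnt$pos)])
  cnt$ref <- refv[cnt$pos - refStart + 1L]
  cnt$low_depth <- cnt$depth < minDepth
  cnt$damage_suspect <- FALSE
  cnt <- cnt[order(cnt$pos, cnt$alt), , drop = FALSE]
  rownames(cnt) <- NULL
  cnt[, c("pos", "ref", "alt", "depth", "alt_depth", "low_depth",
          "damage_suspect")]
}

#' Flag calls compatible with terminal cytosine-deamination damage
#'
#' Post-mortem deamination converts cytosines near the 5' terminus of an
#' ancient read to uracil, read as T; on reverse-orientation reads the
#' same lesion appears as G>A in the reference frame. A C>T call is
#' flagged `damage_suspect` iff EVERY supporting observation is on a
#' forward read within `window` bases of its 5' end; a G>A call iff every
#' supporting observation is on a reverse read within `window` bases of
#' its (read-frame) 5' end. One interior or opposite-orientation
#' supporting read rescues the call. Other substitutions are never
#' flagged.
#'
#' @param calls data.frame from [callVariants()].
#' @param pileup the same sample's pileup observations.
#' @param window damage window w in bases (default 2, must be >= 1).
#' @param minBaseQual the quality threshold used for calling.
#' @return `calls` with `damage_suspect` updated.
#' @export
flagDamage <- function(calls, pileup, window = 2L, minBaseQual = 20L) {
  if (window < 1L) pvStop("damage window must be >= 1", "inputError")
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    ref <- calls$ref[i]; alt <- calls$alt[i]
    if (!((ref == "C" && alt == "T") || (ref == "G" && alt == "A")))
      next
    sup <- pileup[pileup$pos == calls$pos[i] & pileup$base == alt &
                  pileup$qual >= minBaseQual, , drop = FALSE]
    if (!nrow(sup)) next
    if (ref == "C" && alt == "T") {
      suspect <- all(sup$reverse == 0 & sup$dist5 <= window)
    } else {
      suspect <- all(sup$reverse == 1 & sup$dist5 <= window)
    }
    calls$damage_suspect[i] <- suspect
  }
  calls
}

#' Intersect per-sample calls with the variant catalog
#'
#' Matches calls against catalog SNVs on `(pos, ref, alt)` (both sides use
#' the same left-normalized conventions; catalog indels have no pileup
#' counterpart and never match). One carrier record is produced per
#' (sample, matching catalog variant). By default, `damage_suspect` calls
#' matching a PV are dropped and logged, the conservative choice for the
#' class where a false C>T would manufacture a carrier.
#'
#' @param calls data.frame of calls with a `sample_id` column (rbind of
#'   per-sample [callVariants()]/[flagDamage()] output).
#' @param catalog a \linkS4class{VariantCatalog} or its variants
#'   data.frame.
#' @param samples sample metadata (see [readSampleMeta()]).
#' @param dropDamagedPV drop damage-suspect PV matches (default TRUE).
#' @return list with `carriers` (data.frame `sample_id, hgvs_c, var_class,
#'   date_bp, date_open, location, cds_anchor, domain, consequence`) and
#'   `dropped` (damage-suspect matches that were excluded).
#' @export
intersectCatalog <- function(calls, catalog, samples,
                             dropDamagedPV = TRUE) {
  v <- if (is(catalog, "VariantCatalog")) variants(catalog) else catalog
  empty <- data.frame(sample_id = character(), hgvs_c = character(),
                      var_class = character(), date_bp = numeric(),
                      date_open = logical(), location = character(),
                      cds_anchor = integer(), domain = character(),
                      consequence = character(), stringsAsFactors = FALSE)
  if (!nrow(calls) || !nrow(v))
    return(list(carriers = empty, dropped = empty))
  key <- function(pos, ref, alt) paste(pos, ref, alt, sep = ":")
  vi <- match(key(calls$pos, calls$ref, calls$alt),
              key(v$pos, v$ref, v$alt))
  hit <- !is.na(vi)
  if (!any(hit)) return(list(carriers = empty, dropped = empty))
  si <- match(calls$sample_id[hit], samples$sample_id)
  if (anyNA(si))
    pvStop("calls reference samples missing from the metadata",
           "inputError")
  rec <- data.frame(
    sample_id = calls$sample_id[hit],
    hgvs_c = v$hgvs_c[vi[hit]],
    var_class = v$var_class[vi[hit]],
    date_bp = samples$date_bp[si],
    date_open = if (is.null(samples$date_open)) FALSE
                else as.logical(samples$date_open[si]),
    location = samples$location[si],
    cds_anchor = v$cds_anchor[vi[hit]],
    domain = v$domain[vi[hit]],
    consequence = v$consequence[vi[hit]],
    stringsAsFactors = FALSE)
  suspect <- calls$damage_suspect[hit]
  dropped <- empty
  if (dropDamagedPV) {
    bad <- suspect & rec$var_class == "PV"
    dropped <- rec[bad, , drop = FALSE]
    rec <- rec[!bad, , drop = FALSE]
  }
  rownames(rec) <- NULL; rownames(dropped) <- NULL
  list(carriers = rec, dropped = dropped)
}
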