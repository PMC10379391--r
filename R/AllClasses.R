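#' @import methods
#' @importFrom IRanges IRanges start end width
NULL

## Error helpers: all package errors carry a condition class so callers and
## tests can discriminate parse failures from by-design exclusions.
pvStop <- function(msg, class) {
  stop(structure(class = c(class, "pvError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' TranscriptModel: exon structure and CDS bounds of one transcript
#'
#' Holds the genomic exon structure, strand and CDS bounds of a single
#' transcript, the context needed to convert HGVS cDNA (c.) positions to
#' genomic coordinates and back. Genomic coordinates are 0-based half-open
#' throughout the package; exons are stored as an \linkS4class{IRanges}
#' (1-based closed, the Bioconductor convention) and converted at the
#' interface.
#'
#' @slot transcriptId transcript accession, e.g. a RefSeq NM_ id.
#' @slot chrom chromosome / sequence name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons `IRanges` of exons in genomic order, sorted, non-overlapping.
#' @slot cdsStart,cdsEnd 0-based half-open CDS bounds in transcript
#'   (spliced, 5'-to-3') coordinates.
#'
#' @seealso [TranscriptModel()], [cdsToGenomic()], [genomicToCds()]
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  slots = c(transcriptId = "character", chrom = "character",
            strand = "character", exons = "IRanges",
            cdsStart = "integer", cdsEnd = "integer"))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "at least one exon required")
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex), strictly = TRUE))
      msg <- c(msg, "exons must be sorted by genomic start")
    if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping and separated by introns")
  }
  tot <- sum(width(ex))
  if (!(object@cdsStart >= 0L && object@cdsStart < object@cdsEnd &&
        object@cdsEnd <= tot))
    msg <- c(msg, "need 0 <= cdsStart < cdsEnd <= total exonic length")
  if (length(msg)) msg else TRUE
})

#' HgvsChange: one parsed HGVS cDNA change
#'
#' Result of [parseHgvsC()]. Only single-nucleotide events are representable:
#' SNVs, 1-bp deletions, 1-bp duplications and 1-bp insertions. The cDNA
#' anchor stays 1-based (HGVS convention); `intronOffset` is the signed
#' offset of intron-adjacent changes (e.g. `c.211+1`, `c.49-1`) and
#' `NA` for exonic changes.
#'
#' @slot raw the input string.
#' @slot kind one of `"SNV"`, `"del1"`, `"dup1"`, `"ins1"`.
#' @slot cdsAnchor 1-based CDS position of the anchor base.
#' @slot intronOffset signed integer or `NA`.
#' @slot refBase,altBase single bases on the transcript strand, or `NA`
#'   (e.g. `c.595del` states no base; an insertion has no ref).
#' @exportClass HgvsChange
setClass("HgvsChange",
  slots = c(raw = "character", kind = "character", cdsAnchor = "integer",
            intronOffset = "integer", refBase = "character",
            altBase = "character"))

setValidity("HgvsChange", function(object) {
  msg <- character()
  if (!object@kind %in% c("SNV", "del1", "dup1", "ins1"))
    msg <- c(msg, "kind must be SNV/del1/dup1/ins1")
  if (object@cdsAnchor < 1L) msg <- c(msg, "cdsAnchor must be >= 1")
  if (!is.na(object@intronOffset) && object@intronOffset == 0L)
    msg <- c(msg, "intronOffset must be non-zero when present")
  if (object@kind == "SNV") {
    if (is.na(object@refBase) || is.na(object@altBase))
      msg <- c(msg, "SNV needs both ref and alt base")
    else if (object@refBase == object@altBase)
      msg <- c(msg, "SNV ref and alt must differ")
  }
  if (length(msg)) msg else TRUE
})

#' VariantCatalog: cleaned variant catalog plus exclusion log
#'
#' Built by [buildCatalog()]. `variants` has one row per retained variant
#' with genomic coordinates on the reference forward strand; `exclusions`
#' logs every dropped input row with a machine-readable reason code, so that
#' `nrow(variants) + nrow(exclusions)` always equals the input row count.
#'
#' @slot variants data.frame with columns `hgvs_c, protein, chrom, pos, ref,
#'   alt, kind, cds_anchor, intron_offset, var_class, consequence, domain`.
#'   `pos` is 0-based. For `del1` rows `alt` is `""`; for `dup1`/`ins1`
#'   rows `ref` is `""` and `pos` is the base after which material is
#'   inserted.
#' @slot exclusions data.frame with columns `row, hgvs_c, reason`.
#' @slot transcript the \linkS4class{TranscriptModel} used for mapping.
#' @exportClass VariantCatalog
setClass("VariantCatalog",
  slots = c(variants = "data.frame", exclusions = "data.frame",
            transcript = "TranscriptModel"))

setValidity("VariantCatalog", function(object) {
  v <- object@variants
  need <- c("hgvs_c", "chrom", "pos", "ref", "alt", "kind", "cds_anchor",
            "intron_offset", "var_class", "consequence", "domain")
  if (!all(need %in% names(v)))
    return(paste("variants lacks columns:",
                 paste(setdiff(need, names(v)), collapse = ", ")))
  if (nrow(v) && !all(v$var_class %in% c("PV", "BV")))
    return("var_class must be PV or BV (VUS are never stored)")
  snv <- v$kind == "SNV"
  if (any(snv) && any(v$ref[snv] == v$alt[snv]))
    return("SNV rows must have ref != alt")
  TRUE
})

#' MafAlignment: indexed multiple alignment in MAF form
#'
#' Parsed from MAF text by [readMaf()]. Blocks are indexed by reference
#' coordinate so that [getBase()] resolves any covered reference position to
#' its alignment column by binary search. Only 's' rows are used; 'e'/'i'/'q'
#' status lines are ignored. Blocks must not overlap on the reference.
#'
#' @slot blocks list; each element holds the species vector, per-row
#'   strand-relative starts, sizes, strands, source sizes and aligned texts
#'   of one block, plus a precomputed reference offset -> column map.
#' @slot refSpecies name of the reference species (its rows are on '+').
#' @slot species all species seen, reference first.
#' @slot refStarts,refEnds 0-based half-open reference span of each block.
#' @exportClass MafAlignment
setClass("MafAlignment",
  slots = c(blocks = "list", refSpecies = "character", species = "character",
            refStarts = "integer", refEnds = "integer"))

#' SharingMatrix: variant-by-species cross-species sharing calls
#'
#' Produced by [computeSharing()]. Each cell is one of `"shared"`,
#' `"not_shared"`, `"no_alignment"`; the reference species is excluded.
#'
#' @slot calls character matrix, rownames = variant keys (HGVS c.),
#'   colnames = species.
#' @slot varClass per-variant `"PV"`/`"BV"` vector, parallel to rows.
#' @exportClass SharingMatrix
setClass("SharingMatrix",
  slots = c(calls = "matrix", varClass = "character"))

setValidity("SharingMatrix", function(object) {
  ok <- c("shared", "not_shared", "no_alignment")
  if (length(object@calls) && !all(object@calls %in% ok))
    return("cells must be shared/not_shared/no_alignment")
  if (length(object@varClass) != nrow(object@calls))
    return("varClass must be parallel to matrix rows")
  TRUE
})

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId, "on", object@chrom,
      paste0("(", object@strand, ")"), "\n  exons:", length(object@exons),
      " spliced length:", sum(width(object@exons)),
      " CDS:", object@cdsStart, "-", object@cdsEnd, "\n")
})

setMethod("show", "HgvsChange", function(object) {
  cat("HgvsChange", object@raw, "[", object@kind, "] anchor",
      object@cdsAnchor,
      if (!is.na(object@intronOffset))
        paste0("offset ", sprintf("%+d", object@intronOffset)) else "",
      "\n")
})

setMethod("show", "VariantCatalog", function(object) {
  v <- object@variants
  cat("VariantCatalog:", nrow(v), "variants (",
      sum(v$var_class == "PV"), "PV /", sum(v$var_class == "BV"), "BV ),",
      nrow(object@exclusions), "rows excluded\n")
})

setMethod("show", "MafAlignment", function(object) {
  cat("MafAlignment:", length(object@blocks), "blocks,",
      length(object@species), "species (reference:", object@refSpecies,
      ")\n  reference span:", min(object@refStarts), "-",
      max(object@refEnds), "\n")
})

setMethod("show", "SharingMatrix", function(object) {
  m <- object@calls
  cat("SharingMatrix:", nrow(m), "variants x", ncol(m), "species\n",
      " shared cells:", sum(m == "shared"),
      " no_alignment:", sum(m == "no_alignment"), "\n")
})

## ---- accessors -------------------------------------------------------------

#' Accessors for PaleoVar classes
#'
#' `variants()` and `exclusions()` return the kept / dropped rows of a
#' catalog; `sharingCalls()` the character matrix of a
#' \linkS4class{SharingMatrix}; `variantClass()` its per-variant PV/BV
#' labels; `mafSpecies()` the species of a \linkS4class{MafAlignment}.
#'
#' @param x a PaleoVar object.
#' @return the corresponding slot content.
#' @name accessors
#' @aliases variants exclusions sharingCalls variantClass mafSpecies
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setGeneric("sharingCalls", function(x) standardGeneric("sharingCalls"))
#' @rdname accessors
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))
#' @rdname accessors
#' @export
setGeneric("mafSpecies", function(x) standardGeneric("mafSpecies"))

#' @rdname accessors
setMethod("variants", "VariantCatalog", function(x) x@variants)
#' @rdname accessors
setMethod("exclusions", "VariantCatalog", function(x) x@exclusions)
#' @rdname accessors
setMethod("sharingCalls", "SharingMatrix", function(x) x@calls)
#' @rdname accessors
setMethod("variantClass", "SharingMatrix", function(x) x@varClass)
#' @rdname accessors
setMethod("mafSpecies", "MafAlignment", function(x) x@species)
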