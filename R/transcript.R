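#' Construct a TranscriptModel
#'
#' @param transcriptId transcript accession.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds 0-based half-open genomic exon intervals,
#'   sorted by genomic start.
#' @param cdsStart,cdsEnd 0-based half-open CDS bounds in spliced
#'   transcript coordinates (5' to 3' on the transcript strand).
#' @return a \linkS4class{TranscriptModel}.
#' @examples
#' tm <- TranscriptModel("tx1", "chrT", "+", 1000, 1200, 10, 190)
#' @export
TranscriptModel <- function(transcriptId, chrom, strand,
                            exonStarts, exonEnds, cdsStart, cdsEnd) {
  new("TranscriptModel", transcriptId = transcriptId, chrom = chrom,
      strand = strand,
      exons = IRanges::IRanges(start = as.integer(exonStarts) + 1L,
                               end = as.integer(exonEnds)),
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

#' Read a TranscriptModel from a JSON file
#'
#' Schema: an object with fields `transcript_id`, `chrom`, `strand`,
#' `exons` (array of `[start, end)` 0-based pairs) and `cds` (`[start,
#' end)` transcript offsets).
#'
#' @param path path to a JSON file.
#' @return a \linkS4class{TranscriptModel}.
#' @export
readTranscriptModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- matrix(as.integer(unlist(j$exons)), ncol = 2, byrow = TRUE)
  TranscriptModel(j$transcript_id, j$chrom, j$strand,
                  ex[, 1], ex[, 2], j$cds[1], j$cds[2])
}

## internal geometry helpers -------------------------------------------------

exonStarts0 <- function(tm) start(tm@exons) - 1L
exonEnds0 <- function(tm) end(tm@exons)

compBase <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

## reverse-complement of a plain character string
revCompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## spliced transcript offset (0-based) -> genomic position (0-based).
transcriptToGenomic <- function(tm, tOff) {
  s0 <- exonStarts0(tm); e0 <- exonEnds0(tm)
  w <- e0 - s0
  ord <- if (tm@strand == "+") seq_along(w) else rev(seq_along(w))
  cw <- c(0L, cumsum(w[ord]))
  if (tOff < 0L || tOff >= sum(w))
    pvStop("transcript offset outside transcript", "rangeError")
  i <- findInterval(tOff, cw, rightmost.closed = FALSE)  # exon index in tx order
  gi <- ord[i]
  l <- tOff - cw[i]
  if (tm@strand == "+") s0[gi] + l else e0[gi] - 1L - l
}

## genomic position (0-based) -> spliced transcript offset, or NA if intronic
genomicToTranscript <- function(tm, gpos) {
  s0 <- exonStarts0(tm); e0 <- exonEnds0(tm)
  w <- e0 - s0
  ord <- if (tm@strand == "+") seq_along(w) else rev(seq_along(w))
  cw <- c(0L, cumsum(w[ord]))
  hit <- which(gpos >= s0 & gpos < e0)
  if (!length(hit)) return(NA_integer_)
  i <- match(hit, ord)
  if (tm@strand == "+") cw[i] + (gpos - s0[hit])
  else cw[i] + (e0[hit] - 1L - gpos)
}

#' Convert a 1-based CDS anchor (plus intron offset) to a genomic position
#'
#' Core coordinate arithmetic behind [mapToGenomic()]: the anchor is the
#' 1-based CDS position; a non-`NA` `intronOffset` walks into the adjacent
#' intron in transcript direction (`+k` past the donor side of the anchor's
#' exon, `-k` before its acceptor side), exactly the HGVS `c.211+1` /
#' `c.49-1` convention.
#'
#' @param tm a \linkS4class{TranscriptModel}.
#' @param cdsAnchor 1-based CDS position.
#' @param intronOffset signed integer or `NA`.
#' @return 0-based genomic position of the addressed base.
#' @export
cdsToGenomic <- function(tm, cdsAnchor, intronOffset = NA_integer_) {
  tOff <- tm@cdsStart + as.integer(cdsAnchor) - 1L
  if (cdsAnchor < 1L || tOff >= tm@cdsEnd)
    pvStop(paste0("CDS anchor ", cdsAnchor, " beyond CDS"), "rangeError")
  g <- transcriptToGenomic(tm, tOff)
  k <- intronOffset
  if (is.na(k)) return(g)

  s0 <- exonStarts0(tm); e0 <- exonEnds0(tm)
  gi <- which(g >= s0 & g < e0)
  n <- length(s0)
  ## identify the intron the offset walks into (in genomic coordinates)
  down <- (tm@strand == "+") == (k > 0L)  # genomically downstream?
  if (down) {
    if (gi == n || g != e0[gi] - 1L)
      pvStop(paste0("no intron after anchor in ", tm@transcriptId),
             "rangeError")
    intronLen <- s0[gi + 1L] - e0[gi]
    if (abs(k) > intronLen)
      pvStop("intron offset beyond intron length", "rangeError")
    g + abs(k)
  } else {
    if (gi == 1L || g != s0[gi])
      pvStop(paste0("no intron before anchor in ", tm@transcriptId),
             "rangeError")
    intronLen <- s0[gi] - e0[gi - 1L]
    if (abs(k) > intronLen)
      pvStop("intron offset beyond intron length", "rangeError")
    g - abs(k)
  }
}

#' Invert the cDNA-to-genomic mapping
#'
#' Returns the `(cdsAnchor, intronOffset)` pair addressing a genomic
#' position. Exonic positions get `intronOffset = NA`; intronic positions
#' are expressed relative to the nearest exon end (HGVS convention: the 5'
#' half of an intron is `+k` past the previous exon, the 3' half `-k`
#' before the next; the midpoint of an odd-length gap goes to `+`).
#'
#' @param tm a \linkS4class{TranscriptModel}.
#' @param gpos 0-based genomic position within the transcript span.
#' @return list with `cdsAnchor` and `intronOffset`.
#' @export
genomicToCds <- function(tm, gpos) {
  tOff <- genomicToTranscript(tm, gpos)
  if (!is.na(tOff))
    return(list(cdsAnchor = tOff - tm@cdsStart + 1L,
                intronOffset = NA_integer_))
  s0 <- exonStarts0(tm); e0 <- exonEnds0(tm)
  if (gpos < s0[1L] || gpos >= e0[length(e0)])
    pvStop("position outside transcript span", "rangeError")
  i <- max(which(e0 <= gpos))            # intron between exon i and i+1
  dLeft <- gpos - (e0[i] - 1L)           # distance from last base of exon i
  dRight <- s0[i + 1L] - gpos            # distance to first base of exon i+1
  leftAnchorG <- e0[i] - 1L
  rightAnchorG <- s0[i + 1L]
  ## "+" side belongs to the transcript-upstream exon
  if (tm@strand == "+") {
    if (dLeft <= dRight)
      anchorG <- leftAnchorG
    else anchorG <- rightAnchorG
    off <- if (dLeft <= dRight) dLeft else -dRight
  } else {
    if (dRight <= dLeft)
      anchorG <- rightAnchorG
    else anchorG <- leftAnchorG
    off <- if (dRight <= dLeft) dRight else -dLeft
  }
  tA <- genomicToTranscript(tm, anchorG)
  list(cdsAnchor = tA - tm@cdsStart + 1L, intronOffset = as.integer(off))
}

refBaseAt <- function(reference, refStart, pos) {
  i <- pos - refStart + 1L
  if (i < 1L || i > nchar(reference))
    pvStop("position outside reference sequence", "rangeError")
  toupper(substr(reference, i, i))
}

## Left-normalize a 1-bp indel against the reference (VCF convention):
## a deletion slides to the leftmost base of the homopolymer run containing
## it; an insertion anchor slides left past any run of the inserted base.
normalizeIndel1 <- function(pos, base, kind, reference, refStart) {
  if (is.null(reference) || is.na(base)) return(pos)
  if (kind == "del1") {
    while (pos - 1L >= refStart &&
           refBaseAt(reference, refStart, pos - 1L) == base)
      pos <- pos - 1L
  } else {  # dup1 / ins1: pos is the base AFTER which material is inserted
    while (pos >= refStart &&
           refBaseAt(reference, refStart, pos) == base)
      pos <- pos - 1L
  }
  pos
}

#' Map a parsed HGVS change onto forward-strand genomic coordinates
#'
#' Converts an \linkS4class{HgvsChange} to `(chrom, pos, ref, alt)` on the
#' reference-genome forward strand. For minus-strand transcripts the alleles
#' are complemented. Insertions and duplications are anchored at the base
#' AFTER which material is inserted (`ref = ""`); deletions at the deleted
#' base (`alt = ""`). When a reference sequence is supplied, stated
#' reference alleles are checked against it, missing deletion bases are
#' filled in, and 1-bp indels are left-normalized (VCF convention).
#'
#' @param change an \linkS4class{HgvsChange}.
#' @param tm a \linkS4class{TranscriptModel}.
#' @param reference optional reference sequence (plain character) covering
#'   the region, forward strand.
#' @param refStart 0-based genomic position of the first base of
#'   `reference`.
#' @return list with `chrom`, `pos` (0-based), `ref`, `alt`, `kind`.
#' @export
mapToGenomic <- function(change, tm, reference = NULL, refStart = 0L) {
  g <- cdsToGenomic(tm, change@cdsAnchor, change@intronOffset)
  minus <- tm@strand == "-"
  txBase <- function(b) if (minus) compBase(b) else b

  if (change@kind == "SNV") {
    ref <- txBase(change@refBase); alt <- txBase(change@altBase)
    if (!is.null(reference)) {
      actual <- refBaseAt(reference, refStart, g)
      if (actual != ref)
        warning("HGVS reference allele ", change@raw, " disagrees with the ",
                "reference sequence (", ref, " vs ", actual, ")")
    }
    return(list(chrom = tm@chrom, pos = g, ref = ref, alt = alt,
                kind = "SNV"))
  }
  if (change@kind == "del1") {
    ref <- if (!is.na(change@refBase)) txBase(change@refBase)
           else if (!is.null(reference)) refBaseAt(reference, refStart, g)
           else "N"
    if (!is.null(reference) && !is.na(change@refBase)) {
      actual <- refBaseAt(reference, refStart, g)
      if (actual != ref)
        warning("deleted base in ", change@raw,
                " disagrees with the reference sequence")
      ref <- actual
    }
    pos <- normalizeIndel1(g, ref, "del1", reference, refStart)
    if (!is.null(reference)) ref <- refBaseAt(reference, refStart, pos)
    return(list(chrom = tm@chrom, pos = pos, ref = ref, alt = "",
                kind = "del1"))
  }
  ## dup1 / ins1: inserted after the anchor base in transcript space;
  ## in genomic forward space that is after g on '+', after g-1 on '-'.
  insBase <- change@altBase
  if (change@kind == "dup1" && is.na(insBase)) {
    insBase <- if (!is.null(reference)) {
      b <- refBaseAt(reference, refStart, g)
      if (minus) compBase(b) else b   # report in transcript frame first
    } else NA_character_
  }
  alt <- if (is.na(insBase)) "N" else txBase(insBase)
  pos <- if (minus) g - 1L else g
  pos <- normalizeIndel1(pos, alt, change@kind, reference, refStart)
  list(chrom = tm@chrom, pos = pos, ref = "", alt = alt,
       kind = change@kind)
}
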