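## Shared fixtures and independent oracles. Oracles deliberately
## re-derive results by brute force rather than calling the code paths
## they check.

## -- toy transcripts ---------------------------------------------------------

## plus-strand two-exon gene on a 400 bp region: exons [50,150) and
## [250,350), CDS = transcript offsets [10, 190)
toyPlusTranscript <- function() {
  TranscriptModel("toy_plus", "chrT", "+",
                  exonStarts = c(50L, 250L), exonEnds = c(150L, 350L),
                  cdsStart = 10L, cdsEnd = 190L)
}

## the same gene mirrored onto the minus strand of a region of length L:
## interval [s, e) maps to [L - e, L - s)
toyMinusTranscript <- function(L = 400L) {
  TranscriptModel("toy_minus", "chrT", "-",
                  exonStarts = L - c(350L, 150L), exonEnds = L - c(250L, 50L),
                  cdsStart = 10L, cdsEnd = 190L)
}

randomRegion <- function(L = 400L, seed = 42L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

revCompOracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## Brute-force transcript->genome coordinate table: row i gives the
## genomic position of spliced transcript offset i-1 (0-based), obtained
## by enumerating every exonic base, independent of the package
## arithmetic.
coordTableOracle <- function(exonStarts, exonEnds, strand) {
  g <- unlist(mapply(function(s, e) s:(e - 1L), exonStarts, exonEnds,
                     SIMPLIFY = FALSE))
  if (strand == "-") g <- rev(g)
  g
}

## -- MAF oracles -------------------------------------------------------------

## Naive full-scan projection: walks every block and column of raw MAF
## lines, counting reference bases, without any index.
naiveGetBase <- function(lines, refSpecies, pos, species) {
  lines <- lines[!grepl("^#", lines)]
  grp <- cumsum(grepl("^a( |$)", lines))
  sRows <- grepl("^s ", lines)
  for (g in unique(grp[sRows])) {
    rows <- lines[sRows & grp == g]
    parts <- lapply(strsplit(rows, "[ \t]+"), function(p) p[nzchar(p)])
    sp <- sub("\\..*$", "", vapply(parts, `[[`, "", 2L))
    dup <- duplicated(sp)
    parts <- parts[!dup]; sp <- sp[!dup]
    ri <- match(refSpecies, sp)
    if (is.na(ri)) next
    refStart <- as.integer(parts[[ri]][3L])
    refSize <- as.integer(parts[[ri]][4L])
    if (pos < refStart || pos >= refStart + refSize) next
    refText <- strsplit(parts[[ri]][7L], "")[[1]]
    seen <- -1L; col <- NA_integer_
    for (cidx in seq_along(refText)) {
      if (refText[cidx] != "-") {
        seen <- seen + 1L
        if (refStart + seen == pos) { col <- cidx; break }
      }
    }
    si <- match(species, sp)
    if (is.na(si)) return("absent")
    ch <- toupper(strsplit(parts[[si]][7L], "")[[1]][col])
    return(if (ch == "-") "gap" else if (ch == "N") "N" else ch)
  }
  "absent"
}

## a small hand-written MAF with a gap, a soft-masked base and a second
## species missing from the second block
handMafLines <- function() {
  c("##maf version=1",
    "a score=1.0",
    "s hum.chr1 100 10 + 1000 ACGTAC-GTAC",
    "s spA.chr2  40 11 +  500 ACTTACGGTAC",
    "s spB.chr3  10 10 +  300 gCGTAC-GTAt",
    "",
    "a score=2.0",
    "s hum.chr1 110  5 + 1000 AAA-CC",
    "s spA.chr2  51  6 +  500 AAATCC",
    "")
}

## -- cohort helpers ----------------------------------------------------------

expandCarrierOracle <- function(tbl) {
  ## independent carrier expansion used to cross-check totals
  sum(tbl$carrier_number)
}

## exhaustive Mann-Whitney two-sided p over all rank assignments
enumMwuOracle <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); n <- length(r)
  mu <- na * length(b) / 2
  Uobs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  Us <- apply(sets, 2L, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
}

## small, fast simulation configuration for tests
testSimConfig <- function(seed = 1L, ...) {
  simConfig(seed = seed, length = 1000L,
            catalog = list(nPV = 15L, nBV = 30L, nVUS = 3L,
                           nDel = 0L, nDup = 0L),
            ancient = list(nSamples = 8L, coverage = 8, readLen = 50L),
            ...)
}
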