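#' Parse an HGVS cDNA change restricted to single-base events
#'
#' Parses an HGVS `c.` string into an \linkS4class{HgvsChange}. Only events
#' touching a single base pair are representable: substitutions
#' (`c.3G>A`, `c.2996+264T>C`), 1-bp deletions (`c.103delC`, `c.595del`),
#' 1-bp duplications (`c.173dupT`) and 1-bp insertions (`c.100_101insA`).
#' Anything spanning more than one base (`c.100_102del`, `c.425del5`) raises
#' an error of class `"hgvsExcludedError"`: such variants are excluded from
#' the catalog by design, not malformed. Strings that cannot be read at all
#' raise `"hgvsParseError"`. UTR-anchored changes (`c.-12...`, `c.*45...`)
#' are not supported and raise a parse error.
#'
#' @param raw an HGVS cDNA string beginning with `"c."`.
#' @return an \linkS4class{HgvsChange}.
#' @examples
#' parseHgvsC("c.3G>A")
#' parseHgvsC("c.2996+264T>C")
#' parseHgvsC("c.103delC")
#' @export
parseHgvsC <- function(raw) {
  if (length(raw) != 1L || !is.character(raw) || !startsWith(raw, "c."))
    pvStop(paste0("not an HGVS cDNA string: ", raw), "hgvsParseError")
  body <- sub("^c\\.", "", raw)

  newChange <- function(kind, anchor, offset, ref, alt) {
    new("HgvsChange", raw = raw, kind = kind,
        cdsAnchor = as.integer(anchor),
        intronOffset = if (is.na(offset) || !nzchar(offset)) NA_integer_
                       else as.integer(offset),
        refBase = ref, altBase = alt)
  }
  pos <- "([0-9]+)([+-][0-9]+)?"   # exonic anchor with optional intron offset

  m <- regmatches(body, regexec(paste0("^", pos, "([ACGT])>([ACGT])$"), body))[[1]]
  if (length(m)) {
    if (m[4] == m[5])
      pvStop(paste0("ref equals alt in ", raw), "hgvsParseError")
    return(newChange("SNV", m[2], m[3], m[4], m[5]))
  }
  m <- regmatches(body, regexec(paste0("^", pos, "del([ACGT])?$"), body))[[1]]
  if (length(m))
    return(newChange("del1", m[2], m[3],
                     if (nzchar(m[4])) m[4] else NA_character_, NA_character_))
  m <- regmatches(body, regexec(paste0("^", pos, "dup([ACGT])?$"), body))[[1]]
  if (length(m))
    return(newChange("dup1", m[2], m[3], NA_character_,
                     if (nzchar(m[4])) m[4] else NA_character_))
  m <- regmatches(body,
         regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$", body))[[1]]
  if (length(m)) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    if (b != a + 1L)
      pvStop(paste0("insertion anchors must be adjacent in ", raw),
             "hgvsParseError")
    if (nchar(m[4]) > 1L)
      pvStop(paste0("multi-base insertion excluded by design: ", raw),
             "hgvsExcludedError")
    return(newChange("ins1", a, NA_character_, NA_character_, m[4]))
  }
  ## multi-base spans: recognized but excluded by design
  if (grepl(paste0("^", pos, "_[0-9]+([+-][0-9]+)?(del|dup|ins|delins)"),
            body) ||
      grepl(paste0("^", pos, "(del|dup)[0-9]+$"), body) ||
      grepl(paste0("^", pos, "delins"), body))
    pvStop(paste0("event spans more than one base pair: ", raw),
           "hgvsExcludedError")
  pvStop(paste0("unparseable HGVS cDNA string: ", raw), "hgvsParseError")
}

#' Classify a ClinVar clinical-significance string
#'
#' Maps a ClinVar significance label onto the two classes the analysis
#' keeps: `"Pathogenic"` and `"Likely pathogenic"` become `"PV"`;
#' `"Benign"` and `"Likely benign"` become `"BV"`. Matching is
#' case-insensitive and exact on the canonical strings; the combined
#' ClinVar forms `"Pathogenic/Likely pathogenic"` and
#' `"Benign/Likely benign"` map to their class. Everything else —
#' uncertain significance, conflicting interpretations, risk factors,
#' free text — returns `"excluded"` (a valid outcome, not an error).
#'
#' @param sig character vector of significance strings.
#' @return character vector over `"PV"`, `"BV"`, `"excluded"`.
#' @examples
#' classifySignificance(c("Pathogenic", "Likely benign",
#'                        "Uncertain significance"))
#' @export
classifySignificance <- function(sig) {
  s <- tolower(trimws(sig))
  out <- rep("excluded", length(s))
  out[s %in% c("pathogenic", "likely pathogenic",
               "pathogenic/likely pathogenic")] <- "PV"
  out[s %in% c("benign", "likely benign", "benign/likely benign")] <- "BV"
  out
}
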