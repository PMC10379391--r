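#' Construct a domain map over cDNA coordinates
#'
#' A DomainMap is an ordered set of named, non-overlapping 1-based cDNA
#' intervals used to place each variant into a protein domain.
#'
#' @param domain character vector of domain names.
#' @param start,end 1-based inclusive cDNA bounds.
#' @return a `data.frame` of class `"DomainMap"` with columns
#'   `domain, start, end`, sorted by `start`.
#' @examples
#' DomainMap(c("coiled-coil", "WD40"), c(25, 2557), c(132, 3561))
#' @export
DomainMap <- function(domain, start, end) {
  df <- data.frame(domain = as.character(domain),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$start > df$end))
    pvStop("domain intervals must have start <= end", "domainError")
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)]))
    pvStop("domain intervals must be non-overlapping", "domainError")
  rownames(df) <- NULL
  class(df) <- c("DomainMap", "data.frame")
  df
}

#' Read a DomainMap from JSON or YAML
#'
#' The file holds an array of objects with fields `domain`, `start`,
#' `end` (1-based cDNA).
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return a DomainMap.
#' @export
readDomainMap <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x)) DomainMap(x$domain, x$start, x$end)
  else DomainMap(vapply(x, `[[`, "", "domain"),
                 vapply(x, function(e) as.integer(e$start), 0L),
                 vapply(x, function(e) as.integer(e$end), 0L))
}

#' PALB2 domain map used by the packaged examples
#'
#' cDNA intervals for the coiled-coil, ETGE, ChAM and WD40 domains of
#' PALB2 (NM_024675-frame, 1-based). The exact nucleotide boundaries are a
#' synthetic reconstruction: they agree with the published residue ranges of
#' the domains and with the domain labels of every variant in the packaged
#' ancient-carrier table, but are not an authoritative annotation.
#'
#' @return a DomainMap with four domains.
#' @examples
#' palb2Domains()
#' @export
palb2Domains <- function() {
  DomainMap(c("coiled-coil", "ETGE", "ChAM", "WD40"),
            c(25L, 205L, 1183L, 2557L),
            c(132L, 222L, 1338L, 3561L))
}

#' Assign a protein domain to a parsed cDNA change
#'
#' The anchor position decides: an anchor inside a domain interval gets
#' that domain; intron-offset variants use their (nearest) exonic anchor;
#' anything else is `"none"`.
#'
#' @param change an \linkS4class{HgvsChange} (or anything with a
#'   `cdsAnchor` slot), or an integer anchor vector.
#' @param dm a DomainMap.
#' @return character vector of domain labels.
#' @export
assignDomain <- function(change, dm) {
  anchor <- if (is(change, "HgvsChange")) change@cdsAnchor
            else as.integer(change)
  vapply(anchor, function(a) {
    hit <- which(dm$start <= a & a <= dm$end)
    if (length(hit)) dm$domain[hit[1L]] else "none"
  }, character(1))
}
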