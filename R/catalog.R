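#' Read a ClinVar-style variant table
#'
#' Expects a TSV with columns `name` (HGVS c. string), `protein`,
#' `significance` and `consequence`. Extra columns are kept but ignored by
#' [buildCatalog()].
#'
#' @param path path to a tab-separated file with a header line.
#' @return a data.frame.
#' @export
readVariantTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("name", "significance")
  if (!all(need %in% names(df)))
    pvStop(paste("variant table lacks columns:",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "inputError")
  if (is.null(df$protein)) df$protein <- NA_character_
  if (is.null(df$consequence)) df$consequence <- NA_character_
  df
}

#' Build a clean variant catalog from a raw variant table
#'
#' Applies, in order: the clinical-significance filter (only pathogenic /
#' likely pathogenic and benign / likely benign rows are kept, see
#' [classifySignificance()]), the single-base-pair span filter (see
#' [parseHgvsC()]), and the cDNA-to-genomic coordinate mapping (see
#' [mapToGenomic()]). Every excluded row is logged with a reason code:
#' `significance_excluded`, `span_gt_1bp`, `parse_error` or `map_error` —
#' the number of kept plus excluded rows always equals the input row count.
#' Duplicate `(pos, ref, alt)` entries with conflicting PV/BV class are a
#' hard error; concordant duplicates are collapsed to the first occurrence
#' (logged as `duplicate`).
#'
#' @param rows data.frame with columns `name`, `significance` and
#'   optionally `protein`, `consequence` (see [readVariantTable()]).
#' @param tm a \linkS4class{TranscriptModel}.
#' @param dm a DomainMap, or `NULL` for no domain assignment.
#' @param reference optional forward-strand reference sequence (character)
#'   used to verify stated alleles and left-normalize 1-bp indels.
#' @param refStart 0-based genomic position of `reference[1]`.
#' @return a \linkS4class{VariantCatalog}.
#' @examples
#' tm <- TranscriptModel("tx", "chrT", "+", 0, 300, 0, 300)
#' rows <- data.frame(name = c("c.3G>A", "c.5T>C"),
#'                    significance = c("Pathogenic", "Uncertain significance"))
#' buildCatalog(rows, tm)
#' @export
buildCatalog <- function(rows, tm, dm = NULL, reference = NULL,
                         refStart = 0L) {
  n <- nrow(rows)
  keep <- vector("list", n)
  excl <- vector("list", n)
  cls <- classifySignificance(rows$significance)
  for (i in seq_len(n)) {
    nm <- rows$name[i]
    if (cls[i] == "excluded") {
      excl[[i]] <- data.frame(row = i, hgvs_c = nm,
                              reason = "significance_excluded")
      next
    }
    ch <- tryCatch(parseHgvsC(nm), pvError = function(e) e)
    if (inherits(ch, "pvError")) {
      reason <- if (inherits(ch, "hgvsExcludedError")) "span_gt_1bp"
                else "parse_error"
      excl[[i]] <- data.frame(row = i, hgvs_c = nm, reason = reason)
      next
    }
    gm <- tryCatch(mapToGenomic(ch, tm, reference, refStart),
                   pvError = function(e) e)
    if (inherits(gm, "pvError")) {
      excl[[i]] <- data.frame(row = i, hgvs_c = nm, reason = "map_error")
      next
    }
    keep[[i]] <- data.frame(
      hgvs_c = nm,
      protein = if (is.null(rows$protein)) NA_character_ else rows$protein[i],
      chrom = gm$chrom, pos = gm$pos, ref = gm$ref, alt = gm$alt,
      kind = gm$kind, cds_anchor = ch@cdsAnchor,
      intron_offset = ch@intronOffset, var_class = cls[i],
      consequence = if (is.null(rows$consequence)) NA_character_
                    else rows$consequence[i],
      domain = if (is.null(dm)) "none" else assignDomain(ch, dm),
      stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, keep[!vapply(keep, is.null, TRUE)])
  e <- do.call(rbind, excl[!vapply(excl, is.null, TRUE)])
  if (is.null(v))
    v <- data.frame(hgvs_c = character(), protein = character(),
                    chrom = character(), pos = integer(), ref = character(),
                    alt = character(), kind = character(),
                    cds_anchor = integer(), intron_offset = integer(),
                    var_class = character(), consequence = character(),
                    domain = character(), stringsAsFactors = FALSE)
  if (is.null(e))
    e <- data.frame(row = integer(), hgvs_c = character(),
                    reason = character(), stringsAsFactors = FALSE)

  ## duplicate (pos, ref, alt): conflicting class is a hard error,
  ## concordant duplicates collapse to the first occurrence
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      if (length(unique(v$var_class[idx])) > 1L)
        pvStop(paste0("conflicting PV/BV class for duplicate variant ", k),
               "catalogConflictError")
    }
    dup <- duplicated(key)
    e <- rbind(e, data.frame(row = NA_integer_, hgvs_c = v$hgvs_c[dup],
                             reason = "duplicate"))
    v <- v[!dup, , drop = FALSE]
  }
  rownames(v) <- NULL; rownames(e) <- NULL
  new("VariantCatalog", variants = v, exclusions = e, transcript = tm)
}

#' Write / read a catalog as TSV
#'
#' The catalog TSV carries the `variants` table of a
#' \linkS4class{VariantCatalog} verbatim (`pos` 0-based; empty `ref`/`alt`
#' encode the 1-bp indel conventions). `readCatalogTable()` restores the
#' data.frame; the transcript model is not serialized.
#'
#' @param catalog a \linkS4class{VariantCatalog}.
#' @param path output path.
#' @return `writeCatalog` returns `path` invisibly; `readCatalogTable`
#'   returns a data.frame.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.table(variants(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalogTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = c(ref = "character",
                                         alt = "character"))
  df$ref[is.na(df$ref)] <- ""
  df$alt[is.na(df$alt)] <- ""
  df
}
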