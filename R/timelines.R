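#' Build per-variant carrier timelines
#'
#' Groups carrier records by variant and dates each variant by its oldest
#' carrier ("arisen time", a lower bound on the variant's age). Censored
#' dates (e.g. "older than 10,000 BP") carry `date_open = TRUE` and a
#' numeric floor in `date_bp`; if the oldest carrier is censored the
#' timeline's `arisen_open` is `TRUE`. Carriers with unknown dates (`NA`)
#' never define the arisen time. Timelines are sorted by carrier count
#' (descending), then cDNA anchor (ascending). Variants with no carriers
#' yield no timeline.
#'
#' @param records carrier data.frame as produced by [intersectCatalog()]
#'   or [carriersFromTable()]: columns `sample_id, hgvs_c, date_bp` and
#'   optionally `date_open, var_class, location, cds_anchor, domain,
#'   consequence, protein`.
#' @return data.frame with one row per variant: `hgvs_c, protein,
#'   consequence, domain, var_class, carrier_count, arisen_time_bp,
#'   arisen_open`, plus a list-column `carriers` holding each variant's
#'   carrier records.
#' @examples
#' rec <- data.frame(sample_id = paste0("s", 1:4), hgvs_c = "c.3256C>T",
#'                   date_bp = c(9860, 4475, 2175, 1450))
#' buildTimelines(rec)$arisen_time_bp
#' @export
buildTimelines <- function(records) {
  if (!nrow(records))
    return(data.frame(hgvs_c = character(), protein = character(),
                      consequence = character(), domain = character(),
                      var_class = character(), carrier_count = integer(),
                      arisen_time_bp = numeric(), arisen_open = logical(),
                      carriers = I(list()), stringsAsFactors = FALSE))
  if (is.null(records$date_open)) records$date_open <- FALSE
  opt <- function(col) if (is.null(records[[col]]))
    rep(NA_character_, nrow(records)) else records[[col]]
  records$protein <- opt("protein")
  records$consequence <- opt("consequence")
  records$domain <- opt("domain")
  records$var_class <- opt("var_class")
  if (is.null(records$cds_anchor))
    records$cds_anchor <- vapply(records$hgvs_c, function(h)
      tryCatch(parseHgvsC(h)@cdsAnchor, error = function(e) NA_integer_),
      integer(1))

  grp <- split(records, records$hgvs_c)
  tl <- do.call(rbind, lapply(grp, function(g) {
    dated <- !is.na(g$date_bp)
    arisen <- if (any(dated)) max(g$date_bp[dated]) else NA_real_
    open <- if (any(dated))
      any(g$date_open[dated] & g$date_bp[dated] == arisen) else NA
    data.frame(hgvs_c = g$hgvs_c[1L], protein = g$protein[1L],
               consequence = g$consequence[1L], domain = g$domain[1L],
               var_class = g$var_class[1L],
               carrier_count = nrow(g),
               arisen_time_bp = arisen, arisen_open = open,
               cds_anchor = g$cds_anchor[1L], stringsAsFactors = FALSE)
  }))
  tl$carriers <- I(unname(grp))
  tl <- tl[order(-tl$carrier_count, tl$cds_anchor), , drop = FALSE]
  rownames(tl) <- NULL
  tl$cds_anchor <- NULL
  tl
}

#' Summarize an ancient-carrier cohort
#'
#' Counts distinct variants and total carriers, splits carriers at a
#' recency cutoff (default 10,000 years BP), and breaks variants down by
#' mutation type, domain and carrier multiplicity. Temporal percentages
#' are computed on carriers; type/domain percentages on variants. A
#' carrier counts as within the cutoff unless its date exceeds it — a
#' censored date whose floor reaches the cutoff counts as outside; a
#' carrier with an unknown date counts as within (in a Table-1-style
#' input only the oldest carrier of each variant is dated, and only that
#' carrier can lie beyond the cutoff).
#'
#' @param timelines output of [buildTimelines()].
#' @param cutoffBP recency cutoff in years BP (default 10000).
#' @return a list of counts: `n_variants`, `n_carriers`,
#'   `carriers_within_cutoff`, `pct_within_cutoff`, `oldest_bp`,
#'   `oldest_open`, `youngest_bp`, `mutation_types` (named vector),
#'   `domains` (named vector), `multi_carrier_variants`,
#'   `carrier_count_table` (named vector).
#' @export
cohortSummary <- function(timelines, cutoffBP = 10000) {
  if (!nrow(timelines))
    return(list(n_variants = 0L, n_carriers = 0L,
                carriers_within_cutoff = 0L, pct_within_cutoff = NA_real_,
                oldest_bp = NA_real_, oldest_open = NA,
                youngest_bp = NA_real_,
                mutation_types = integer(), domains = integer(),
                multi_carrier_variants = 0L,
                carrier_count_table = integer()))
  carriers <- do.call(rbind, lapply(timelines$carriers, function(g)
    g[, c("date_bp", "date_open"), drop = FALSE]))
  nCar <- nrow(carriers)
  outside <- (!is.na(carriers$date_bp)) &
    (carriers$date_bp > cutoffBP |
       (carriers$date_open & carriers$date_bp >= cutoffBP))
  dated <- carriers[!is.na(carriers$date_bp), , drop = FALSE]
  oldestIdx <- which.max(dated$date_bp)
  list(
    n_variants = nrow(timelines),
    n_carriers = nCar,
    carriers_within_cutoff = sum(!outside),
    pct_within_cutoff = round(100 * sum(!outside) / nCar, 1),
    oldest_bp = dated$date_bp[oldestIdx],
    oldest_open = dated$date_open[oldestIdx],
    youngest_bp = min(dated$date_bp),
    mutation_types = table2vec(timelines$consequence),
    domains = table2vec(timelines$domain),
    multi_carrier_variants = sum(timelines$carrier_count >= 2L),
    carrier_count_table = table2vec(timelines$carrier_count))
}

table2vec <- function(x) {
  t <- table(x, useNA = "no")
  stats::setNames(as.integer(t), names(t))
}

#' Read a Table-1-shaped ancient-carrier table
#'
#' TSV columns: `carrier_number`, `cdna`, `protein`, `mutation_type`,
#' `domain` (`-` means none) and `arisen_time_bp`, where a leading `>`
#' marks a censored ("older than") date. This is the timeline-only input
#' format: per-carrier dates beyond the oldest are not recorded.
#'
#' @param path path to a TSV file.
#' @return data.frame with numeric `arisen_time_bp` and logical
#'   `arisen_open`.
#' @export
readCarrierTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("carrier_number", "cdna", "mutation_type", "domain",
            "arisen_time_bp")
  if (!all(need %in% names(df)))
    pvStop(paste("carrier table lacks columns:",
                 paste(setdiff(need, names(df)), collapse = ", ")),
           "inputError")
  raw <- gsub(",", "", df$arisen_time_bp)
  df$arisen_open <- grepl("^>", raw)
  df$arisen_time_bp <- as.numeric(sub("^>", "", raw))
  df$carrier_number <- as.integer(df$carrier_number)
  df$domain[df$domain %in% c("-", "")] <- "none"
  if (is.null(df$protein)) df$protein <- NA_character_
  df$protein[df$protein %in% c("-", "")] <- NA_character_
  df
}

#' Expand a Table-1-shaped carrier table into carrier records
#'
#' Each table row becomes `carrier_number` carrier records for its
#' variant: the oldest carrier gets the arisen date (with its censoring
#' flag); the remaining carriers are undated (`NA`), since a
#' Table-1-style source only dates the oldest carrier.
#'
#' @param tbl data.frame from [readCarrierTable()].
#' @return carrier records suitable for [buildTimelines()].
#' @export
carriersFromTable <- function(tbl) {
  do.call(rbind, lapply(seq_len(nrow(tbl)), function(i) {
    n <- tbl$carrier_number[i]
    data.frame(
      sample_id = paste0("tab", i, ".", seq_len(n)),
      hgvs_c = tbl$cdna[i],
      protein = tbl$protein[i],
      var_class = "PV",
      date_bp = c(tbl$arisen_time_bp[i], rep(NA_real_, n - 1L)),
      date_open = c(tbl$arisen_open[i], rep(FALSE, n - 1L)),
      location = NA_character_,
      domain = tbl$domain[i],
      consequence = tbl$mutation_type[i],
      stringsAsFactors = FALSE)
  }))
}

#' Packaged ancient PALB2 pathogenic-variant carrier table
#'
#' The 50 PALB2 pathogenic variants observed in ancient human genomes,
#' with carrier counts, mutation types, domains and the date of the
#' oldest carrier (years BP; two entries are censored "older than
#' 10,000"). Ships as a plain TSV under `extdata`.
#'
#' @return data.frame as from [readCarrierTable()].
#' @examples
#' tbl <- palb2AncientCarriers()
#' sum(tbl$carrier_number)
#' @export
palb2AncientCarriers <- function() {
  readCarrierTable(system.file("extdata", "palb2_ancient_pv_carriers.tsv",
                               package = "PaleoVar", mustWork = TRUE))
}

#' Write timelines as a Table-1-shaped TSV
#'
#' @param timelines output of [buildTimelines()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTimelines <- function(timelines, path) {
  out <- data.frame(
    carrier_number = timelines$carrier_count,
    cdna = timelines$hgvs_c,
    protein = ifelse(is.na(timelines$protein), "-", timelines$protein),
    mutation_type = timelines$consequence,
    domain = ifelse(timelines$domain %in% c(NA, "none"), "-",
                    timelines$domain),
    arisen_time_bp = ifelse(timelines$arisen_open,
                            paste0(">", timelines$arisen_time_bp),
                            as.character(timelines$arisen_time_bp)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
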