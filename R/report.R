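## Stage runners behind the command-line interface. Each writes its
## outputs under `out` with fixed file names so that `assembleReport()`
## and re-runs are deterministic.

runCatalogStage <- function(variantsPath, transcriptPath, out,
                            domainsPath = NULL, referencePath = NULL) {
  rows <- readVariantTable(variantsPath)
  tm <- readTranscriptModel(transcriptPath)
  dm <- if (!is.null(domainsPath)) readDomainMap(domainsPath) else NULL
  ref <- NULL
  if (!is.null(referencePath)) {
    dna <- Biostrings::readDNAStringSet(referencePath)
    ref <- as.character(dna[[1L]])
  }
  cat <- buildCatalog(rows, tm, dm, reference = ref)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  writeCatalog(cat, file.path(out, "catalog.tsv"))
  utils::write.table(exclusions(cat), file.path(out, "exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat
}

runCrossspeciesStage <- function(catalogPath, mafPath, refSpecies, out,
                                 cladesPath = NULL, flank = 3L) {
  v <- readCatalogTable(catalogPath)
  maf <- readMaf(mafPath, refSpecies)
  clades <- if (!is.null(cladesPath)) readCladeMap(cladesPath) else NULL
  sm <- computeSharing(v, maf, flank = flank)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  writeSharingMatrix(sm, file.path(out, "sharing_matrix.tsv"))
  for (cls in intersect(c("PV", "BV"), unique(v$var_class))) {
    su <- sharingSummary(subsetSharing(sm, cls), clades)
    utils::write.table(su$species,
                       file.path(out, paste0("species_summary_", cls,
                                             ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(su$clades))
      utils::write.table(su$clades,
                         file.path(out, paste0("clade_summary_", cls,
                                               ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sm
}

runAncientStage <- function(catalogPath, pileupPath, samplesPath,
                            referencePath, out, minBaseQual = 20L,
                            minAltDepth = 2L, minDepth = 3L,
                            window = 2L, cutoffBP = 10000) {
  v <- readCatalogTable(catalogPath)
  pile <- readPileup(pileupPath)
  samples <- readSampleMeta(samplesPath)
  ref <- as.character(Biostrings::readDNAStringSet(referencePath)[[1L]])
  calls <- do.call(rbind, lapply(split(pile, pile$sample_id), function(p) {
    cl <- callVariants(p, ref, minBaseQual = minBaseQual,
                       minAltDepth = minAltDepth, minDepth = minDepth)
    cl <- flagDamage(cl, p, window = window, minBaseQual = minBaseQual)
    if (nrow(cl)) cl$sample_id <- p$sample_id[1L]
    cl
  }))
  if (is.null(calls))
    calls <- data.frame(sample_id = character(), pos = integer(),
                        ref = character(), alt = character(),
                        depth = integer(), alt_depth = integer(),
                        low_depth = logical(), damage_suspect = logical())
  res <- intersectCatalog(calls, v, samples)
  tl <- buildTimelines(res$carriers)
  finishTimelineStage(tl, res$carriers, out, cutoffBP,
                      dropped = res$dropped)
}

runTimelineOnlyStage <- function(carriersPath, out, cutoffBP = 10000) {
  tbl <- readCarrierTable(carriersPath)
  rec <- carriersFromTable(tbl)
  tl <- buildTimelines(rec)
  finishTimelineStage(tl, rec, out, cutoffBP)
}

finishTimelineStage <- function(tl, carriers, out, cutoffBP,
                                dropped = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(carriers, file.path(out, "carriers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeTimelines(tl, file.path(out, "timelines.tsv"))
  if (!is.null(dropped) && nrow(dropped))
    utils::write.table(dropped, file.path(out, "dropped_damage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- cohortSummary(tl, cutoffBP)
  jsonlite::write_json(summ, file.path(out, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(timelines = tl, summary = summ)
}

runStatsStage <- function(pvPath, bvPath, outPath,
                          mode = "auto") {
  readSu <- function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE)
    list(species = df,
         overall = list(n_variants = NA_integer_))
  }
  res <- compareSharing(readSu(pvPath), readSu(bvPath), mode = mode)
  jsonlite::write_json(res, outPath, auto_unbox = TRUE, digits = NA)
  res
}

#' Merge stage outputs into a single cross-checked report
#'
#' Reads whatever stage outputs exist under `dir` (catalog, sharing
#' summaries, timelines, cohort summary, rate-comparison test) and writes
#' `report.json` plus a short markdown digest `report.md`. Totals are
#' cross-checked against each other (carrier sums, exclusion
#' partitions), not recomputed; inconsistencies are listed in the
#' report's `checks` section.
#'
#' @param dir directory holding stage outputs.
#' @return (invisibly) the report list.
#' @export
assembleReport <- function(dir) {
  rep <- list(); checks <- list()
  p <- function(...) file.path(dir, ...)
  if (file.exists(p("catalog.tsv"))) {
    cat <- readCatalogTable(p("catalog.tsv"))
    rep$catalog <- list(
      n_variants = nrow(cat),
      n_pv = sum(cat$var_class == "PV"),
      n_bv = sum(cat$var_class == "BV"))
    if (file.exists(p("exclusions.tsv"))) {
      ex <- utils::read.delim(p("exclusions.tsv"))
      rep$catalog$n_excluded <- nrow(ex)
      rep$catalog$exclusion_reasons <- table2vec(ex$reason)
    }
  }
  for (cls in c("PV", "BV")) {
    f <- p(paste0("species_summary_", cls, ".tsv"))
    if (!file.exists(f)) next
    su <- utils::read.delim(f, stringsAsFactors = FALSE)
    nVar <- if (!is.null(rep$catalog))
      rep$catalog[[tolower(paste0("n_", tolower(cls)))]] else NA
    rep$sharing[[cls]] <- list(
      n_species_sharing = sum(su$shared > 0),
      max_species_shared = max(su$shared),
      mean_rate = mean(su$rate))
    if (file.exists(p("sharing_matrix.tsv"))) {
      sm <- readSharingMatrix(p("sharing_matrix.tsv"))
      smc <- subsetSharing(sm, cls)
      ov <- sharingSummary(smc)$overall
      rep$sharing[[cls]]$n_variants <- ov$n_variants
      rep$sharing[[cls]]$n_variants_shared <- ov$n_variants_shared
      rep$sharing[[cls]]$variant_shared_pct <- ov$variant_shared_pct
      ## cross-check: matrix column sums equal the summary table
      agree <- isTRUE(all.equal(
        sort(stats::setNames(colSums(sharingCalls(smc) == "shared"),
                             colnames(sharingCalls(smc)))[su$species]),
        sort(stats::setNames(as.integer(su$shared), su$species))))
      checks[[paste0("sharing_summary_consistent_", cls)]] <- agree
    }
  }
  if (file.exists(p("timelines.tsv"))) {
    tl <- readCarrierTable(p("timelines.tsv"))
    names(tl)[names(tl) == "cdna"] <- "cdna"
    rep$ancient <- list(n_variants = nrow(tl),
                        n_carriers = sum(tl$carrier_number))
    if (file.exists(p("cohort_summary.json"))) {
      cs <- jsonlite::read_json(p("cohort_summary.json"),
                                simplifyVector = TRUE)
      rep$ancient$summary <- cs
      checks$timeline_carrier_total_consistent <-
        isTRUE(cs$n_carriers == sum(tl$carrier_number))
      checks$timeline_variant_total_consistent <-
        isTRUE(cs$n_variants == nrow(tl))
    }
    if (file.exists(p("carriers.tsv"))) {
      ca <- utils::read.delim(p("carriers.tsv"))
      checks$carrier_rows_match_timelines <-
        isTRUE(nrow(ca) == sum(tl$carrier_number))
    }
  }
  if (file.exists(p("stats.json")))
    rep$rate_comparison <- jsonlite::read_json(p("stats.json"),
                                               simplifyVector = TRUE)
  rep$checks <- checks
  jsonlite::write_json(rep, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  md <- c("# Variant archaeology report", "")
  if (!is.null(rep$catalog))
    md <- c(md, sprintf("- Catalog: %d variants (%d PV, %d BV), %s excluded",
                        rep$catalog$n_variants, rep$catalog$n_pv,
                        rep$catalog$n_bv,
                        if (is.null(rep$catalog$n_excluded)) "?"
                        else rep$catalog$n_excluded))
  for (cls in names(rep$sharing))
    md <- c(md, sprintf(
      "- %s sharing: %s of %s variants (%s%%) shared with >=1 of the %d sharing species",
      cls, rep$sharing[[cls]]$n_variants_shared,
      rep$sharing[[cls]]$n_variants,
      rep$sharing[[cls]]$variant_shared_pct,
      rep$sharing[[cls]]$n_species_sharing))
  if (!is.null(rep$ancient))
    md <- c(md, sprintf(
      "- Ancient cohort: %d variants in %d carriers; %s%% of carriers within the recency cutoff",
      rep$ancient$n_variants, rep$ancient$n_carriers,
      if (is.null(rep$ancient$summary)) "?"
      else rep$ancient$summary$pct_within_cutoff))
  if (!is.null(rep$rate_comparison))
    md <- c(md, sprintf(
      "- PV vs BV per-species sharing rates: U = %s, p = %.3g (%s)",
      rep$rate_comparison$U, rep$rate_comparison$p,
      if (isTRUE(rep$rate_comparison$significant)) "significant"
      else "not significant"))
  bad <- names(checks)[!vapply(checks, isTRUE, TRUE)]
  md <- c(md, "", if (length(bad))
    paste("Consistency checks FAILED:", paste(bad, collapse = ", "))
    else "All consistency checks passed.")
  writeLines(md, p("report.md"))
  invisible(rep)
}

cliUsage <- function() {
  message(paste(
    "usage: paleovar <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate      --out DIR [--seed N] [--length N] [--config YAML]",
    "  catalog       --variants TSV --transcript JSON --out DIR",
    "                [--domains JSON|YAML] [--reference FASTA]",
    "  crossspecies  --catalog TSV --maf MAF --ref-species NAME --out DIR",
    "                [--clades YAML] [--flank N]",
    "  ancient       --catalog TSV --pileup TSV --samples TSV",
    "                --reference FASTA --out DIR [--qual N]",
    "                [--alt-depth N] [--depth N] [--window N] [--cutoff N]",
    "  ancient       --timeline-only --carriers TSV --out DIR [--cutoff N]",
    "  stats         --pv TSV --bv TSV --out JSON [--mode auto|exact|normal]",
    "  report        --dir DIR",
    sep = "\n"))
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate`, `catalog`,
#' `crossspecies`, `ancient`, `stats`, `report`). Returns an exit
#' status instead of calling `quit()`, so it is testable in-process: 0 on
#' success, 1 on input errors (missing files, malformed inputs), 2 on
#' usage errors (unknown subcommand or flag). A thin Rscript wrapper
#' under `inst/cli/` forwards `commandArgs()` and exits with the
#' returned status.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cliUsage(); return(invisible(2L)) }
  sub <- args[1L]; rest <- args[-1L]
  known <- list(
    simulate = c("out", "seed", "length", "config"),
    catalog = c("variants", "transcript", "out", "domains", "reference"),
    crossspecies = c("catalog", "maf", "ref-species", "out", "clades",
                     "flank"),
    ancient = c("catalog", "pileup", "samples", "reference", "out",
                "qual", "alt-depth", "depth", "window", "cutoff",
                "carriers", "timeline-only"),
    stats = c("pv", "bv", "out", "mode"),
    report = c("dir"))
  if (!sub %in% names(known)) { cliUsage(); return(invisible(2L)) }
  ## parse --flag value pairs (--timeline-only is boolean)
  flags <- list(); i <- 1L
  while (i <= length(rest)) {
    f <- rest[i]
    if (!startsWith(f, "--")) { cliUsage(); return(invisible(2L)) }
    nm <- substring(f, 3L)
    if (!nm %in% known[[sub]]) { cliUsage(); return(invisible(2L)) }
    if (nm == "timeline-only") { flags[[nm]] <- TRUE; i <- i + 1L }
    else {
      if (i == length(rest)) { cliUsage(); return(invisible(2L)) }
      flags[[nm]] <- rest[i + 1L]; i <- i + 2L
    }
  }
  need <- function(nms) {
    miss <- setdiff(nms, names(flags))
    if (length(miss))
      pvStop(paste("missing required flag(s):",
                   paste0("--", miss, collapse = ", ")), "inputError")
  }
  mustExist <- function(nms) {
    for (nm in nms)
      if (!file.exists(flags[[nm]]))
        pvStop(paste0("input file not found: ", flags[[nm]]),
               "inputError")
  }
  status <- tryCatch({
    switch(sub,
      simulate = {
        need("out")
        cfg <- if (!is.null(flags$config)) {
          mustExist("config")
          readSimConfig(flags$config,
                        seed = if (is.null(flags$seed)) NULL
                               else as.integer(flags$seed))
        } else simConfig(
          seed = if (is.null(flags$seed)) 1L else as.integer(flags$seed),
          length = if (is.null(flags$length)) 2000L
                   else as.integer(flags$length))
        simulateStudy(cfg, flags$out)
      },
      catalog = {
        need(c("variants", "transcript", "out"))
        mustExist(intersect(c("variants", "transcript", "domains",
                              "reference"), names(flags)))
        runCatalogStage(flags$variants, flags$transcript, flags$out,
                        flags$domains, flags$reference)
      },
      crossspecies = {
        need(c("catalog", "maf", "ref-species", "out"))
        mustExist(intersect(c("catalog", "maf", "clades"), names(flags)))
        runCrossspeciesStage(flags$catalog, flags$maf,
                             flags[["ref-species"]], flags$out,
                             flags$clades,
                             flank = if (is.null(flags$flank)) 3L
                                     else as.integer(flags$flank))
      },
      ancient = {
        cutoff <- if (is.null(flags$cutoff)) 10000
                  else as.numeric(flags$cutoff)
        if (isTRUE(flags[["timeline-only"]])) {
          need(c("carriers", "out")); mustExist("carriers")
          runTimelineOnlyStage(flags$carriers, flags$out, cutoff)
        } else {
          need(c("catalog", "pileup", "samples", "reference", "out"))
          mustExist(c("catalog", "pileup", "samples", "reference"))
          runAncientStage(
            flags$catalog, flags$pileup, flags$samples, flags$reference,
            flags$out,
            minBaseQual = if (is.null(flags$qual)) 20L
                          else as.integer(flags$qual),
            minAltDepth = if (is.null(flags[["alt-depth"]])) 2L
                          else as.integer(flags[["alt-depth"]]),
            minDepth = if (is.null(flags$depth)) 3L
                       else as.integer(flags$depth),
            window = if (is.null(flags$window)) 2L
                     else as.integer(flags$window),
            cutoffBP = cutoff)
        }
      },
      stats = {
        need(c("pv", "bv", "out")); mustExist(c("pv", "bv"))
        runStatsStage(flags$pv, flags$bv, flags$out,
                      mode = if (is.null(flags$mode)) "auto"
                             else flags$mode)
      },
      report = {
        need("dir")
        if (!dir.exists(flags$dir))
          pvStop(paste0("directory not found: ", flags$dir), "inputError")
        assembleReport(flags$dir)
      })
    0L
  }, pvError = function(e) { message("error: ", conditionMessage(e)); 1L },
     error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
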