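mkObs <- function(pos, base, qual = 30L, dist5 = 20L, dist3 = 20L,
                  reverse = 0L, sample_id = "s1") {
  n <- length(pos)
  data.frame(sample_id = rep_len(sample_id, n), pos = pos,
             base = rep_len(base, n), qual = rep_len(qual, n),
             dist5 = rep_len(dist5, n), dist3 = rep_len(dist3, n),
             reverse = rep_len(reverse, n), stringsAsFactors = FALSE)
}

test_that("the threshold caller emits calls per its explicit rules", {
  ref <- paste(rep("ACGT", 25), collapse = "")   # 100 bp
  ## empty pileup: no calls
  expect_identical(nrow(callVariants(mkObs(integer(), character()), ref)),
                   0L)
  ## five concordant high-quality alt reads: clean call
  p <- mkObs(rep(8L, 5L), rep("T", 5L))          # ref at 8 is A
  cl <- callVariants(p, ref)
  expect_identical(cl$alt_depth, 5L)
  expect_identical(cl$depth, 5L)
  expect_false(cl$low_depth)
  ## a single alt observation is below the alt-depth floor
  expect_identical(nrow(callVariants(mkObs(8L, "T"), ref)), 0L)
  ## low-quality support does not count
  lowq <- mkObs(rep(8L, 3L), rep("T", 3L), qual = 10L)
  expect_identical(nrow(callVariants(lowq, ref)), 0L)
  ## two alt reads pass but depth 2 < 3 flags low_depth
  two <- mkObs(rep(8L, 2L), rep("T", 2L))
  cl2 <- callVariants(two, ref)
  expect_identical(cl2$alt_depth, 2L)
  expect_true(cl2$low_depth)
  ## positions outside the reference are an input error
  expect_error(callVariants(mkObs(500L, "T"), ref), class = "inputError")
})

test_that("damage flags require exclusively terminal, orientation-consistent support", {
  ref <- paste(rep("C", 40), collapse = "")
  ## C>T with all support within 2 of the 5' end on forward reads
  term <- mkObs(rep(5L, 3L), rep("T", 3L), dist5 = c(0L, 1L, 2L))
  cl <- flagDamage(callVariants(term, ref), term)
  expect_true(cl$damage_suspect)
  ## one interior observation rescues the call
  mix <- mkObs(rep(5L, 3L), rep("T", 3L), dist5 = c(0L, 1L, 30L))
  expect_false(flagDamage(callVariants(mix, ref), mix)$damage_suspect)
  ## non-transition calls are never flagged
  ag <- mkObs(rep(5L, 3L), rep("A", 3L), dist5 = 0L)
  expect_false(flagDamage(callVariants(ag, ref), ag)$damage_suspect)
  ## G>A is suspect only when every support is on reverse reads
  refG <- paste(rep("G", 40), collapse = "")
  ga <- mkObs(rep(5L, 3L), rep("A", 3L), dist5 = 1L, reverse = 1L)
  expect_true(flagDamage(callVariants(ga, refG), ga)$damage_suspect)
  gaFwd <- mkObs(rep(5L, 3L), rep("A", 3L), dist5 = 1L, reverse = 0L)
  expect_false(flagDamage(callVariants(gaFwd, refG), gaFwd)$damage_suspect)
})

test_that("catalog intersection matches on normalized coordinates only", {
  tm <- TranscriptModel("t", "chrT", "+", 0L, 100L, 0L, 100L)
  ref <- paste(rep("ACGT", 25), collapse = "")
  rows <- data.frame(name = c("c.9A>T", "c.21A>G"),
                     significance = c("Pathogenic", "Benign"),
                     stringsAsFactors = FALSE)
  catg <- buildCatalog(rows, tm, reference = ref)
  samples <- data.frame(sample_id = "s1", date_bp = 4000,
                        location = "Steppe", stringsAsFactors = FALSE)
  p <- mkObs(rep(8L, 4L), rep("T", 4L))
  calls <- callVariants(p, ref)
  calls$sample_id <- "s1"
  res <- intersectCatalog(calls, catg, samples)
  expect_identical(nrow(res$carriers), 1L)
  expect_identical(res$carriers$hgvs_c, "c.9A>T")
  expect_identical(res$carriers$date_bp, 4000)
  ## a call at a position absent from the catalog matches nothing
  calls2 <- callVariants(mkObs(rep(12L, 4L), rep("C", 4L)), ref)
  calls2$sample_id <- "s1"
  expect_identical(nrow(intersectCatalog(calls2, catg,
                                         samples)$carriers), 0L)
  ## damage-suspect PV matches are dropped and logged by default
  calls3 <- calls
  calls3$damage_suspect <- TRUE
  res3 <- intersectCatalog(calls3, catg, samples)
  expect_identical(nrow(res3$carriers), 0L)
  expect_identical(nrow(res3$dropped), 1L)
  res4 <- intersectCatalog(calls3, catg, samples, dropDamagedPV = FALSE)
  expect_identical(nrow(res4$carriers), 1L)
})

test_that("timelines date variants by their oldest carrier", {
  rec <- data.frame(sample_id = paste0("s", 1:4), hgvs_c = "c.3256C>T",
                    date_bp = c(9860, 4475, 2175, 1450),
                    stringsAsFactors = FALSE)
  tl <- buildTimelines(rec)
  expect_identical(tl$arisen_time_bp, 9860)
  expect_identical(tl$carrier_count, 4L)
  ## a single carrier dates the variant directly
  one <- buildTimelines(data.frame(sample_id = "s9", hgvs_c = "c.49-1G>A",
                                   date_bp = 689))
  expect_identical(one$arisen_time_bp, 689)
  ## permuting carriers changes nothing
  for (i in 1:3) {
    perm <- rec[sample(nrow(rec)), ]
    expect_identical(buildTimelines(perm)$arisen_time_bp, 9860)
  }
  ## ordering: carrier count desc, then cDNA anchor asc
  rec2 <- rbind(rec,
                data.frame(sample_id = c("a1", "a2"), hgvs_c = "c.212-1G>A",
                           date_bp = c(2275, 100)),
                data.frame(sample_id = c("b1", "b2"), hgvs_c = "c.211+1G>A",
                           date_bp = c(10050, 100)))
  tl2 <- buildTimelines(rec2)
  expect_identical(tl2$hgvs_c,
                   c("c.3256C>T", "c.211+1G>A", "c.212-1G>A"))
})

test_that("timeline invariants hold on a synthetic cohort", {
  cfg <- testSimConfig(seed = 101L)
  evo <- evolveSequences(cfg)
  plant <- suppressWarnings(plantCatalog(cfg, evo))
  anc <- simulateAncient(cfg, evo, plant$planted)
  catg <- buildCatalog(plant$table, plant$transcript,
                       reference = evo$refSeq)
  calls <- do.call(rbind, lapply(split(anc$pileup, anc$pileup$sample_id),
    function(p) {
      cl <- flagDamage(callVariants(p, evo$refSeq), p)
      if (nrow(cl)) cl$sample_id <- p$sample_id[1L]
      cl
    }))
  res <- intersectCatalog(calls, catg, anc$samples)
  tl <- buildTimelines(res$carriers)
  ## carrier totals are conserved
  expect_identical(sum(tl$carrier_count), nrow(res$carriers))
  ## arisen time bounds every carrier date and is attained
  for (i in seq_len(nrow(tl))) {
    d <- tl$carriers[[i]]$date_bp
    expect_true(all(d[!is.na(d)] <= tl$arisen_time_bp[i]))
    expect_true(tl$arisen_time_bp[i] %in% d)
  }
})

test_that("cohort summaries split carriers at the recency cutoff", {
  tbl <- palb2AncientCarriers()
  tl <- buildTimelines(carriersFromTable(tbl))
  s <- cohortSummary(tl, cutoffBP = 10000)
  expect_identical(s$n_carriers, 71L)
  expect_identical(s$carriers_within_cutoff, 64L)
  expect_equal(s$pct_within_cutoff, 90.1)
  ## all carriers newer than the cutoff: 100%
  rec <- data.frame(sample_id = c("x1", "x2"), hgvs_c = "c.9A>T",
                    date_bp = c(500, 900))
  expect_equal(cohortSummary(buildTimelines(rec))$pct_within_cutoff, 100)
  ## empty input gives a defined empty summary
  s0 <- cohortSummary(buildTimelines(rec[0, ]))
  expect_identical(s0$n_variants, 0L)
  expect_identical(s0$n_carriers, 0L)
})

test_that("censored 'older than' dates keep their floor and flag", {
  tbl <- palb2AncientCarriers()
  open <- tbl[tbl$arisen_open, ]
  expect_identical(nrow(open), 2L)
  expect_true(all(open$arisen_time_bp == 10000))
  tl <- buildTimelines(carriersFromTable(tbl))
  expect_identical(sum(tl$arisen_open), 2L)
  ## the censored floor never beats the genuine maximum
  expect_identical(max(tl$arisen_time_bp), 32895)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTimelines(tl, f)
  back <- readCarrierTable(f)
  expect_identical(sum(back$arisen_open), 2L)
})
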