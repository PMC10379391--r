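test_that("SNV sharing requires the species to carry the alternate allele", {
  expect_identical(isSharedSnv("T", "T"), "shared")
  expect_identical(isSharedSnv("T", "C"), "not_shared")   # matches REF
  expect_identical(isSharedSnv("T", "G"), "not_shared")   # third base
  expect_identical(isSharedSnv("T", "gap"), "no_alignment")
  expect_identical(isSharedSnv("T", "N"), "no_alignment")
  expect_identical(isSharedSnv("T", "absent"), "no_alignment")
})

test_that("deletion sharing needs an aligned gap with clean flanks", {
  ## hum: ACGTACGTACGT (12 bp); spDel lacks the T at position 3;
  ## spSame aligns every base; spMis has a mismatched flank
  lines <- c("a",
             "s hum.chr1 0 12 + 100 ACGTACGTACGT",
             "s spDel.c  0 11 + 100 ACG-ACGTACGT",
             "s spSame.c 0 12 + 100 ACGTACGTACGT",
             "s spMis.c  0 12 + 100 AGGTACGTACGT")
  maf <- readMaf(lines, "hum")
  v <- list(pos = 3L, ref = "T", alt = "", kind = "del1")
  expect_identical(isSharedIndel(v, maf, "spDel", k = 3L), "shared")
  expect_identical(isSharedIndel(v, maf, "spSame", k = 3L), "not_shared")
  expect_identical(isSharedIndel(v, maf, "spMis", k = 3L), "not_shared")
  ## near the block edge the flank requirement cannot be met
  vEdge <- list(pos = 1L, ref = "C", alt = "", kind = "del1")
  expect_identical(isSharedIndel(vEdge, maf, "spDel", k = 3L),
                   "no_alignment")
})

test_that("insertion sharing needs the extra base where the reference is gapped", {
  ## spIns carries an extra T after hum position 3 (hum gapped there)
  lines <- c("a",
             "s hum.chr1 0 12 + 100 ACGT-ACGTACGT",
             "s spIns.c  0 13 + 100 ACGTTACGTACGT",
             "s spNo.c   0 12 + 100 ACGT-ACGTACGT")
  maf <- readMaf(lines, "hum")
  v <- list(pos = 3L, ref = "", alt = "T", kind = "ins1")
  expect_identical(isSharedIndel(v, maf, "spIns", k = 3L), "shared")
  expect_identical(isSharedIndel(v, maf, "spNo", k = 3L), "not_shared")
})

test_that("raising the indel flank width never upgrades a call", {
  rankOf <- c(no_alignment = 0L, not_shared = 1L, shared = 2L)
  cfg <- simConfig(seed = 77L, length = 800L, indelRate = 0.01,
                   maf = list(blockLen = 800L, strandFlipProb = 0.2))
  evo <- evolveSequences(cfg)
  em <- emitMaf(evo, cfg)
  maf <- readMaf(em$lines, "human")
  refChars <- strsplit(evo$refSeq, "")[[1]]
  species <- setdiff(evo$species, "human")
  set.seed(3)
  positions <- sample(5:(nchar(evo$refSeq) - 10L), 40L)
  for (p in positions) {
    v <- list(pos = p, ref = refChars[p + 1L], alt = "", kind = "del1")
    for (sp in species) {
      calls <- vapply(1:5, function(k)
        isSharedIndel(v, maf, sp, k = k), "")
      ## monotone non-increasing in the sharing order as k grows
      expect_true(all(diff(rankOf[calls] == 2L) <= 0),
                  info = paste(sp, p))
      ## not_shared never becomes shared
      firstNS <- match("not_shared", calls)
      if (!is.na(firstNS))
        expect_false("shared" %in% calls[firstNS:5],
                     info = paste(sp, p))
    }
  }
})

test_that("per-species call counts always partition the catalog", {
  cfg <- testSimConfig(seed = 19L)
  evo <- evolveSequences(cfg)
  em <- emitMaf(evo, cfg)
  maf <- readMaf(em$lines, "human")
  plant <- suppressWarnings(plantCatalog(cfg, evo))
  catg <- buildCatalog(plant$table, plant$transcript,
                       reference = evo$refSeq)
  sm <- computeSharing(catg, maf)
  m <- sharingCalls(sm)
  n <- nrow(variants(catg))
  for (sp in colnames(m))
    expect_identical(sum(m[, sp] %in% c("shared", "not_shared",
                                        "no_alignment")), n)
})

test_that("strand annotation of species rows does not change the matrix", {
  base <- list(seed = 57L, length = 900L)
  cfgPlus <- simConfig(seed = base$seed, length = base$length,
                       maf = list(strandFlipProb = 0, blockLen = 300L),
                       catalog = list(nDel = 0L, nDup = 0L))
  cfgMinus <- simConfig(seed = base$seed, length = base$length,
                        maf = list(strandFlipProb = 1, blockLen = 300L),
                        catalog = list(nDel = 0L, nDup = 0L))
  evo <- evolveSequences(cfgPlus)
  emP <- emitMaf(evo, cfgPlus)
  emM <- emitMaf(evo, cfgMinus)
  expect_true(all(emP$strand[setdiff(evo$species, "human")] == "+"))
  expect_true(all(emM$strand[setdiff(evo$species, "human")] == "-"))
  plant <- suppressWarnings(plantCatalog(cfgPlus, evo))
  catg <- buildCatalog(plant$table, plant$transcript,
                       reference = evo$refSeq)
  smP <- computeSharing(catg, readMaf(emP$lines, "human"))
  smM <- computeSharing(catg, readMaf(emM$lines, "human"))
  expect_identical(sharingCalls(smP), sharingCalls(smM))
})

test_that("summaries report rates over the full catalog denominator", {
  ## all-shared and all-not-shared corner cases
  m <- matrix("shared", 4, 3,
              dimnames = list(paste0("v", 1:4), paste0("s", 1:3)))
  sm <- new("SharingMatrix", calls = m, varClass = rep("PV", 4))
  su <- sharingSummary(sm)
  expect_true(all(su$species$rate == 1))
  m[] <- "not_shared"
  su0 <- sharingSummary(new("SharingMatrix", calls = m,
                            varClass = rep("PV", 4)))
  expect_true(all(su0$species$rate == 0))
  expect_identical(su0$overall$n_variants_shared, 0L)
  ## no_alignment stays in the denominator
  m[] <- "no_alignment"; m[1, 1] <- "shared"
  suNA <- sharingSummary(new("SharingMatrix", calls = m,
                             varClass = rep("PV", 4)))
  expect_equal(suNA$species$rate[suNA$species$species == "s1"], 1 / 4)
})

test_that("clade summaries require full species coverage", {
  m <- matrix("shared", 2, 3,
              dimnames = list(c("v1", "v2"), c("s1", "s2", "s3")))
  sm <- new("SharingMatrix", calls = m, varClass = c("PV", "PV"))
  good <- sharingSummary(sm, clades = list(A = c("s1", "s2"), B = "s3"))
  expect_identical(good$clades$n_species, c(2L, 1L))
  expect_error(sharingSummary(sm, clades = list(A = "s1")),
               class = "cladeError")
})

test_that("the sharing-matrix TSV round-trips", {
  cfg <- testSimConfig(seed = 23L)
  evo <- evolveSequences(cfg)
  maf <- readMaf(emitMaf(evo, cfg)$lines, "human")
  plant <- suppressWarnings(plantCatalog(cfg, evo))
  catg <- buildCatalog(plant$table, plant$transcript,
                       reference = evo$refSeq)
  sm <- computeSharing(catg, maf)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSharingMatrix(sm, f)
  back <- readSharingMatrix(f)
  expect_identical(sharingCalls(back), sharingCalls(sm))
  expect_identical(variantClass(back), variantClass(sm))
})
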