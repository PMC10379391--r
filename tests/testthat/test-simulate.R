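test_that("zero branch lengths leave every species identical to the root", {
  cfg <- simConfig(seed = 2L, length = 300L,
                   tree = "((human:0,rhesus:0):0,(mouse:0,dog:0):0);",
                   indelRate = 0)
  evo <- evolveSequences(cfg)
  expect_identical(ncol(evo$matrix), 300L)
  for (sp in evo$species)
    expect_identical(paste(evo$matrix[sp, ], collapse = ""), evo$refSeq)
})

test_that("a malformed newick string is a parse error", {
  expect_error(
    suppressWarnings(evolveSequences(simConfig(tree = "((a:0.1,b"))),
    class = "newickParseError")
  ## branch lengths are required
  expect_error(
    suppressWarnings(evolveSequences(simConfig(tree = "(human,rhesus);"))),
    class = "newickParseError")
})

test_that("pairwise divergence matches the substitution model within 3 sigma", {
  ## two taxa separated by total branch length 0.3: under the
  ## rate-normalized K80 model the expected fraction of differing sites
  ## is 1 - pSame(0.3)
  t <- 0.3; kappa <- 4; L <- 4000L
  a <- kappa / (kappa + 2); b <- 1 / (kappa + 2)
  pSame <- 0.25 + 0.25 * exp(-4 * b * t) + 0.5 * exp(-2 * (a + b) * t)
  pDiff <- 1 - pSame
  cfg <- simConfig(seed = 8L, length = L, kappa = kappa,
                   tree = "(human:0.15,rhesus:0.15);", indelRate = 0)
  evo <- evolveSequences(cfg)
  nDiff <- sum(evo$matrix["human", ] != evo$matrix["rhesus", ])
  expect_lt(abs(nDiff - L * pDiff), 3 * sqrt(L * pDiff * (1 - pDiff)))
})

test_that("a fixed seed reproduces every simulated object exactly", {
  cfg <- testSimConfig(seed = 5L)
  e1 <- evolveSequences(cfg); e2 <- evolveSequences(cfg)
  expect_identical(e1, e2)
  m1 <- emitMaf(e1, cfg); m2 <- emitMaf(e2, cfg)
  expect_identical(m1$lines, m2$lines)
  p1 <- suppressWarnings(plantCatalog(cfg, e1))
  p2 <- suppressWarnings(plantCatalog(cfg, e2))
  expect_identical(p1, p2)
  a1 <- simulateAncient(cfg, e1, p1$planted)
  a2 <- simulateAncient(cfg, e2, p2$planted)
  expect_identical(a1, a2)
})

test_that("strand flips are controlled by their probability", {
  cfg0 <- simConfig(seed = 4L, length = 400L,
                    maf = list(strandFlipProb = 0, blockLen = 200L))
  em0 <- emitMaf(evolveSequences(cfg0), cfg0)
  sLines <- grep("^s ", em0$lines, value = TRUE)
  strands <- vapply(strsplit(sLines, " +"), `[[`, "", 5L)
  expect_true(all(strands == "+"))
})

test_that("a reference-only alignment projects every species as absent", {
  cfg <- simConfig(seed = 6L, length = 300L, indelRate = 0)
  evo <- evolveSequences(cfg)
  solo <- evo
  solo$matrix <- evo$matrix["human", , drop = FALSE]
  solo$species <- "human"
  em <- emitMaf(solo, cfg)
  maf <- readMaf(em$lines, "human")
  for (p in c(0L, 150L, 299L))
    expect_identical(getBase(maf, p, "rhesus"), "absent")
  expect_identical(getBase(maf, 10L, "human"),
                   substr(evo$refSeq, 11L, 11L))
})

test_that("deamination damage is terminal and orientation-specific", {
  mismatchRates <- function(cfg) {
    evo <- evolveSequences(cfg)
    anc <- simulateAncient(cfg, evo,
                           data.frame(hgvs_c = character(),
                                      pos = integer(), ref = character(),
                                      alt = character(),
                                      kind = character()))
    p <- anc$pileup
    refChars <- strsplit(evo$refSeq, "")[[1]]
    p$refBase <- refChars[p$pos + 1L]
    fwdC <- p[p$reverse == 0L & p$refBase == "C", ]
    term <- fwdC$dist5 <= cfg$ancient$damageWindow
    c(xTerm = sum(fwdC$base[term] == "T"), nTerm = sum(term),
      xInt = sum(fwdC$base[!term] == "T"), nInt = sum(!term))
  }
  ## damage off: terminal and interior C>T rates agree within binomial
  ## error (both are sequencing error / 3)
  cfg0 <- simConfig(seed = 12L, length = 800L,
                    ancient = list(nSamples = 6L, coverage = 10,
                                   deamRate = 0, baseError = 0.01,
                                   carrierProb = 0, readLen = 50L))
  r0 <- mismatchRates(cfg0)
  pt <- suppressWarnings(
    stats::prop.test(c(r0[["xTerm"]], r0[["xInt"]]),
                     c(r0[["nTerm"]], r0[["nInt"]])))
  expect_gt(pt$p.value, 0.001)
  ## damage on: terminal C>T far exceeds interior
  cfgD <- simConfig(seed = 12L, length = 800L,
                    ancient = list(nSamples = 6L, coverage = 10,
                                   deamRate = 0.3, baseError = 0.01,
                                   carrierProb = 0, readLen = 50L))
  rD <- mismatchRates(cfgD)
  expect_gt(rD[["xTerm"]] / rD[["nTerm"]] - rD[["xInt"]] / rD[["nInt"]],
            0.15)
  ## reverse reads mirror the lesion as reference-frame G>A
  evoD <- evolveSequences(cfgD)
  ancD <- simulateAncient(cfgD, evoD,
                          data.frame(hgvs_c = character(),
                                     pos = integer(), ref = character(),
                                     alt = character(),
                                     kind = character()))
  pD <- ancD$pileup
  refChars <- strsplit(evoD$refSeq, "")[[1]]
  pD$refBase <- refChars[pD$pos + 1L]
  revG <- pD[pD$reverse == 1L & pD$refBase == "G", ]
  termGA <- mean(revG$base[revG$dist5 <= cfgD$ancient$damageWindow] == "A")
  intGA <- mean(revG$base[revG$dist5 > cfgD$ancient$damageWindow] == "A")
  expect_gt(termGA - intGA, 0.15)
})

test_that("huge coverage with no noise recovers planted genotypes exactly", {
  cfg <- simConfig(seed = 21L, length = 500L,
                   catalog = list(nPV = 8L, nBV = 8L, nVUS = 0L,
                                  nDel = 0L, nDup = 0L),
                   ancient = list(nSamples = 4L, coverage = 30,
                                  baseError = 0, deamRate = 0,
                                  carrierProb = 1, readLen = 50L))
  evo <- evolveSequences(cfg)
  plant <- plantCatalog(cfg, evo)
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
  found <- sort(paste(res$carriers$sample_id, res$carriers$hgvs_c))
  truth <- sort(paste(anc$truthCarriers$sample_id,
                      anc$truthCarriers$hgvs_c))
  expect_identical(found, truth)
})
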