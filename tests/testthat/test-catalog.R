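test_that("significance and span filters apply in order, with a full log", {
  tm <- toyPlusTranscript()
  rows <- data.frame(
    name = c("c.5A>G", "c.7T>C", "c.20_22del"),
    significance = c("Pathogenic", "Uncertain significance", "Benign"),
    stringsAsFactors = FALSE)
  cat <- buildCatalog(rows, tm)
  expect_identical(nrow(variants(cat)), 1L)
  expect_identical(variants(cat)$var_class, "PV")
  ex <- exclusions(cat)
  expect_identical(nrow(ex), 2L)
  expect_setequal(ex$reason, c("significance_excluded", "span_gt_1bp"))
})

test_that("an empty table yields an empty catalog without error", {
  cat <- buildCatalog(data.frame(name = character(),
                                 significance = character()),
                      toyPlusTranscript())
  expect_identical(nrow(variants(cat)), 0L)
  expect_identical(nrow(exclusions(cat)), 0L)
})

test_that("kept plus excluded rows always partition the input", {
  tm <- toyPlusTranscript()
  set.seed(9)
  sigs <- c("Pathogenic", "Benign", "Likely benign",
            "Uncertain significance", "not provided")
  for (rep in 1:5) {
    n <- sample(3:12, 1L)
    rows <- data.frame(
      name = sample(c("c.5A>G", "c.50C>T", "c.100_102del", "garbage",
                      "c.90+1G>A", "c.9000A>T"), n, replace = TRUE),
      significance = sample(sigs, n, replace = TRUE),
      stringsAsFactors = FALSE)
    ## avoid duplicate-collapse interplay: tag names unique per row by
    ## class assignment only; duplicates of the same name share class
    rows$significance <- ifelse(
      duplicated(rows$name),
      rows$significance[match(rows$name, rows$name)],
      rows$significance)
    cat <- buildCatalog(rows, tm)
    expect_identical(nrow(variants(cat)) + nrow(exclusions(cat)),
                     nrow(rows))
  }
})

test_that("mapped positions of valid rows match the coordinate-table oracle", {
  tm <- toyPlusTranscript()
  g <- coordTableOracle(c(50L, 250L), c(150L, 350L), "+")
  anchors <- c(1L, 17L, 90L, 91L, 180L)
  rows <- data.frame(name = paste0("c.", anchors, "A>G"),
                     significance = "Pathogenic",
                     stringsAsFactors = FALSE)
  cat <- buildCatalog(rows, tm)
  expect_identical(variants(cat)$pos, g[10L + anchors])
})

test_that("round-trip through the inverse mapping holds for all entries", {
  tm <- toyMinusTranscript()
  anchors <- seq(2L, 178L, by = 11L)
  rows <- data.frame(name = paste0("c.", anchors, "G>T"),
                     significance = "Benign", stringsAsFactors = FALSE)
  v <- variants(buildCatalog(rows, tm))
  for (i in seq_len(nrow(v))) {
    back <- genomicToCds(tm, v$pos[i])
    expect_identical(back$cdsAnchor, v$cds_anchor[i])
  }
})

test_that("conflicting classes at one genomic variant are a hard error", {
  tm <- toyPlusTranscript()
  rows <- data.frame(name = c("c.5A>G", "c.5A>G"),
                     significance = c("Pathogenic", "Benign"),
                     stringsAsFactors = FALSE)
  expect_error(buildCatalog(rows, tm), class = "catalogConflictError")
  ## concordant duplicates collapse and are logged
  rows2 <- data.frame(name = c("c.5A>G", "c.5A>G"),
                      significance = c("Pathogenic", "Likely pathogenic"),
                      stringsAsFactors = FALSE)
  cat <- buildCatalog(rows2, tm)
  expect_identical(nrow(variants(cat)), 1L)
  expect_identical(exclusions(cat)$reason, "duplicate")
})

test_that("a minus-strand build mirrors the plus-strand catalog", {
  L <- 400L
  region <- randomRegion(L)
  tmP <- toyPlusTranscript()
  tmM <- toyMinusTranscript(L)
  regionM <- revCompOracle(region)
  gP <- coordTableOracle(c(50L, 250L), c(150L, 350L), "+")
  anchors <- c(3L, 40L, 90L, 125L, 179L)
  ## state each variant's ref base from the plus-strand region so both
  ## builds describe the same molecular change
  refBases <- substring(region, gP[10L + anchors] + 1L,
                        gP[10L + anchors] + 1L)
  altBases <- vapply(refBases, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1L], "")
  rowsP <- data.frame(name = paste0("c.", anchors, refBases, ">", altBases),
                      significance = "Pathogenic", stringsAsFactors = FALSE)
  ## the cDNA names are representation-independent: the same strings
  ## describe the gene whichever strand the locus is stored on
  comp <- function(x) chartr("ACGT", "TGCA", x)
  vP <- variants(buildCatalog(rowsP, tmP, reference = region))
  vM <- variants(buildCatalog(rowsP, tmM, reference = regionM))
  expect_identical(vM$pos, L - 1L - vP$pos)
  expect_identical(vM$ref, comp(vP$ref))
  expect_identical(vM$alt, comp(vP$alt))
})
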