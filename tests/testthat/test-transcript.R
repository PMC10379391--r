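test_that("plus-strand CDS anchors map by direct arithmetic", {
  ## single exon [1000,1200), CDS starts at transcript offset 10:
  ## c.3 sits at genomic 1000 + 10 + 2 = 1012
  tm <- TranscriptModel("t1", "chrT", "+", 1000L, 1200L, 10L, 190L)
  gm <- mapToGenomic(parseHgvsC("c.3G>A"), tm)
  expect_identical(gm$pos, 1012L)
  expect_identical(gm$ref, "G")
  expect_identical(gm$alt, "A")
})

test_that("+1 intron offsets land on the first intronic base", {
  ## two exons; CDS position 211 is the last base of exon 1
  ## (cdsStart 0, exon1 width 211), so c.211+1 is the first intron base
  tm <- TranscriptModel("t2", "chrT", "+", c(100L, 500L),
                        c(311L, 700L), 0L, 411L)
  gm <- mapToGenomic(parseHgvsC("c.211+1G>A"), tm)
  expect_identical(gm$pos, 311L)
  ## and c.212-1 is the last intronic base before exon 2
  gm2 <- mapToGenomic(parseHgvsC("c.212-1G>A"), tm)
  expect_identical(gm2$pos, 499L)
})

test_that("minus-strand mapping equals the exhaustive coordinate-table oracle", {
  L <- 400L
  tm <- toyMinusTranscript(L)
  g <- coordTableOracle(exonStarts = L - c(350L, 150L),
                        exonEnds = L - c(250L, 50L), strand = "-")
  cdsLen <- 190L - 10L
  for (anchor in c(1L, 2L, 57L, 100L, 101L, cdsLen)) {
    expectPos <- g[10L + anchor]          # cdsStart 10, 1-based table
    gm <- mapToGenomic(parseHgvsC(paste0("c.", anchor, "G>A")), tm)
    expect_identical(gm$pos, expectPos, info = paste("anchor", anchor))
    ## alleles are reverse-complemented onto the forward strand
    expect_identical(gm$ref, "C")
    expect_identical(gm$alt, "T")
  }
})

test_that("cdsToGenomic and genomicToCds are mutually inverse", {
  for (tm in list(toyPlusTranscript(), toyMinusTranscript())) {
    for (anchor in seq(1L, 180L, by = 7L)) {
      g <- cdsToGenomic(tm, anchor)
      back <- genomicToCds(tm, g)
      expect_identical(back$cdsAnchor, anchor)
      expect_identical(back$intronOffset, NA_integer_)
    }
    ## intron offsets within the nearer half of the 100 bp intron;
    ## with cdsStart 10 and 100 bp exons the donor-side anchor is CDS
    ## position 90 and the acceptor-side anchor 91
    for (off in c(1L, 10L, 49L)) {
      g <- cdsToGenomic(tm, 90L, off)
      back <- genomicToCds(tm, g)
      expect_identical(back$cdsAnchor, 90L)
      expect_identical(back$intronOffset, off)
      g2 <- cdsToGenomic(tm, 91L, -off)
      back2 <- genomicToCds(tm, g2)
      expect_identical(back2$cdsAnchor, 91L)
      expect_identical(back2$intronOffset, -off)
    }
  }
})

test_that("out-of-range anchors and offsets raise range errors", {
  tm <- toyPlusTranscript()
  expect_error(cdsToGenomic(tm, 500L), class = "rangeError")
  expect_error(cdsToGenomic(tm, 0L), class = "rangeError")
  ## offset beyond the 100 bp intron
  expect_error(cdsToGenomic(tm, 90L, 101L), class = "rangeError")
  ## anchor not adjacent to an intron cannot take an offset
  expect_error(cdsToGenomic(tm, 50L, 1L), class = "rangeError")
})

test_that("indel anchoring and left-normalization follow VCF convention", {
  ## region with a homopolymer: positions 20..23 are TTTT
  seqch <- rep("A", 60)
  seqch[21:24] <- "T"
  region <- paste(seqch, collapse = "")
  tm <- TranscriptModel("t", "chrT", "+", 0L, 60L, 0L, 60L)
  ## deleting the last T of the run (c.24delT) normalizes to the first
  del <- mapToGenomic(parseHgvsC("c.24delT"), tm, reference = region)
  expect_identical(del$pos, 20L)
  expect_identical(del$alt, "")
  ## duplicating a T anchors before the run
  dup <- mapToGenomic(parseHgvsC("c.23dupT"), tm, reference = region)
  expect_identical(dup$pos, 19L)
  expect_identical(dup$ref, "")
  expect_identical(dup$alt, "T")
  ## inserting a base different from its left neighbour does not shift
  ins <- mapToGenomic(parseHgvsC("c.30_31insG"), tm, reference = region)
  expect_identical(ins$pos, 29L)
})
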