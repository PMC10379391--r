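#' Read and index a multiple alignment in MAF format
#'
#' Parses UCSC-dialect MAF text (the `##maf` header is optional). Only `s`
#' rows are used; `e`/`i`/`q` status lines and comments are ignored. The
#' species of a row is the part of its source name before the first `.`.
#' If a species appears twice in one block the first row wins and a warning
#' is issued. Blocks are indexed by the coordinates of the reference
#' species, whose rows must be on the `+` strand; blocks overlapping on the
#' reference raise an indexing error.
#'
#' @param x path to a MAF file, or a character vector of MAF lines.
#' @param refSpecies name of the reference species.
#' @return a \linkS4class{MafAlignment}.
#' @examples
#' maf <- readMaf(c("a score=0",
#'                  "s hg.chr1 0 4 + 4 ACGT",
#'                  "s sp.chr5 2 4 + 10 ACTT"), refSpecies = "hg")
#' getBase(maf, 2, "sp")
#' @export
readMaf <- function(x, refSpecies) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else x
  lines <- lines[!grepl("^#", lines)]
  isA <- grepl("^a( |$)", lines)
  isS <- grepl("^s ", lines)
  grp <- cumsum(isA)
  blocks <- list()
  for (g in unique(grp[isS])) {
    rows <- lines[isS & grp == g]
    f <- lapply(strsplit(rows, "[ \t]+"), function(p) p[nzchar(p)])
    src <- vapply(f, `[[`, "", 2L)
    species <- sub("\\..*$", "", src)
    if (anyDuplicated(species)) {
      warning("species ", paste(unique(species[duplicated(species)]),
                                collapse = ", "),
              " duplicated in one MAF block; first row wins")
      keep <- !duplicated(species)
      f <- f[keep]; src <- src[keep]; species <- species[keep]
    }
    text <- vapply(f, `[[`, "", 7L)
    blk <- list(species = species, src = src,
                start = as.integer(vapply(f, `[[`, "", 3L)),
                size = as.integer(vapply(f, `[[`, "", 4L)),
                strand = vapply(f, `[[`, "", 5L),
                srcSize = as.integer(vapply(f, `[[`, "", 6L)),
                text = text)
    if (length(unique(nchar(text))) != 1L)
      pvStop("MAF block rows have unequal aligned lengths", "mafParseError")
    ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
    if (any(ungapped != blk$size))
      pvStop("MAF row size disagrees with ungapped text length",
             "mafParseError")
    r <- match(refSpecies, species)
    if (is.na(r))
      pvStop(paste0("reference species ", refSpecies,
                    " missing from a MAF block"), "mafParseError")
    if (blk$strand[r] != "+")
      pvStop("reference species row must be on the '+' strand",
             "mafParseError")
    blk$refRow <- r
    ## column (1-based) of the j-th reference base in the block
    chars <- strsplit(text[r], "")[[1]]
    blk$colMap <- which(chars != "-")
    blocks[[length(blocks) + 1L]] <- blk
  }
  if (!length(blocks))
    pvStop("no alignment blocks found", "mafParseError")
  refStarts <- vapply(blocks, function(b) b$start[b$refRow], 0L)
  refEnds <- refStarts + vapply(blocks, function(b) b$size[b$refRow], 0L)
  o <- order(refStarts)
  blocks <- blocks[o]; refStarts <- refStarts[o]; refEnds <- refEnds[o]
  if (length(blocks) > 1L && any(refStarts[-1L] < refEnds[-length(refEnds)]))
    pvStop("MAF blocks overlap on the reference", "mafIndexError")
  species <- unique(c(refSpecies,
                      unlist(lapply(blocks, `[[`, "species"))))
  new("MafAlignment", blocks = blocks, refSpecies = refSpecies,
      species = species, refStarts = refStarts, refEnds = refEnds)
}

## Locate a reference position: list(block index, column) or NULL.
mafLocate <- function(maf, pos) {
  i <- findInterval(pos, maf@refStarts)
  if (i < 1L || pos >= maf@refEnds[i]) return(NULL)
  blk <- maf@blocks[[i]]
  list(i = i, col = blk$colMap[pos - maf@refStarts[i] + 1L])
}

## Raw aligned character of a species at (block, col): "-", base, or NA if
## the species has no row in the block.
mafChar <- function(blk, species, col) {
  r <- match(species, blk$species)
  if (is.na(r)) return(NA_character_)
  toupper(substr(blk$text[r], col, col))
}

#' Project one reference position onto a species
#'
#' Returns the base a species shows in the alignment column of a reference
#' position, reported in the reference forward-strand frame. MAF stores the
#' aligned text of every row in alignment orientation (for `-` strand rows
#' the text is the reverse complement of the source), so the printed column
#' character is already in the reference frame; strand and start fields
#' only matter for recovering source coordinates. Soft-masked (lower-case)
#' bases are uppercased. The state is one of the bases `A/C/G/T`, `"N"`,
#' `"gap"` (the species row has `-` in that column) or `"absent"` (no
#' block covers the position, or the species has no row in the covering
#' block).
#'
#' @param maf a \linkS4class{MafAlignment}.
#' @param pos 0-based reference position.
#' @param species species name.
#' @return a single character state.
#' @export
getBase <- function(maf, pos, species) {
  loc <- mafLocate(maf, pos)
  if (is.null(loc)) return("absent")
  ch <- mafChar(maf@blocks[[loc$i]], species, loc$col)
  if (is.na(ch)) "absent"
  else if (ch == "-") "gap"
  else if (ch == "N") "N"
  else ch
}
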