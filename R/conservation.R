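#' Percent identity between two intron sequences
#'
#' Global end-free (semi-global) pairwise nucleotide alignment; terminal
#' overhangs are not penalized and are excluded from the identity
#' denominator. Percent identity is matches over alignment columns of the
#' aligned region, scored with conventional nucleotide defaults (match +1,
#' mismatch -1, gap open -2, gap extend -1). To make the measure exactly
#' symmetric in its two arguments (equal-scoring alignments could otherwise
#' be tie-broken differently), the pair is ordered canonically before
#' aligning.
#'
#' @param seq_a,seq_b Nucleotide sequences (character or `DNAString`).
#' @param threshold Percent identity at or above which the pair is classified
#'   `highly_conserved` (default 70, the conservation band reported for
#'   placental domesticated-gene introns).
#' @param match,mismatch,gap_open,gap_ext Alignment scores (penalties
#'   positive).
#' @return One-row `data.frame`: `percent_identity`, `aligned_length`
#'   (alignment columns), `classification`.
#' @export
intron_identity <- function(seq_a, seq_b, threshold = 70,
                            match = 1, mismatch = -1,
                            gap_open = 2, gap_ext = 1) {
  a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("intron_identity requires two nonempty sequences")
  # canonical order => symmetry by construction
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_ext)
  pa <- as.character(Biostrings::alignedPattern(aln))
  ncols <- nchar(pa)
  pid <- if (ncols == 0L) 0 else 100 * Biostrings::nmatch(aln) / ncols
  data.frame(percent_identity = pid, aligned_length = ncols,
             classification = if (pid >= threshold) "highly_conserved"
                              else "not_highly_conserved",
             stringsAsFactors = FALSE)
}

#' Repeat occupancy of an intron
#'
#' Intersects repeat annotations with the intron interval, merges overlapping
#' repeat pieces (never double-counting), and reports the masked fraction and
#' per-class subtotals. Repeats must be given in the same coordinate system
#' as the intron (0-based half-open).
#'
#' @param intron_chrom,intron_start,intron_end Intron interval.
#' @param repeats `data.frame` with columns `chrom`, `start`, `end`,
#'   `repeat_class` (as from [read_repeat_annotations()]).
#' @return List: `intron_length`, `masked_nt`, `masked_fraction`,
#'   `repeat_classes` (named numeric, merged nt per class).
#' @export
repeat_occupancy <- function(intron_chrom, intron_start, intron_end,
                             repeats) {
  if (intron_end <= intron_start) stop("intron interval has no width")
  if (nrow(repeats) > 0 && any(repeats$end < repeats$start))
    stop("negative-width repeat interval")
  len <- intron_end - intron_start
  hit <- repeats[repeats$chrom == intron_chrom &
                 repeats$end > intron_start &
                 repeats$start < intron_end, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(list(intron_length = len, masked_nt = 0, masked_fraction = 0,
                repeat_classes = stats::setNames(numeric(0), character(0))))
  s <- pmax(hit$start, intron_start); e <- pmin(hit$end, intron_end)
  merged_width <- function(s, e) {
    ir <- IRanges::reduce(IRanges::IRanges(start = s + 1, end = e))
    sum(IRanges::width(ir))
  }
  masked <- merged_width(s, e)
  classes <- vapply(split(seq_along(s), hit$repeat_class), function(i)
    merged_width(s[i], e[i]), numeric(1))
  list(intron_length = len, masked_nt = masked,
       masked_fraction = masked / len, repeat_classes = classes)
}

#' Read repeat annotations from BED or RepeatMasker .out
#'
#' Format is auto-detected: RepeatMasker `.out` by its banner/column shape,
#' otherwise tab-separated BED. Intervals are normalized to 0-based half-open
#' (RepeatMasker prints 1-based closed query coordinates); the repeat
#' class/family column is preserved (BED uses the name field, column 4).
#'
#' @param path Annotation file.
#' @param format `"auto"`, `"bed"` or `"rmout"`.
#' @return `data.frame`: `chrom`, `start`, `end`, `strand`, `repeat_class`.
#' @export
read_repeat_annotations <- function(path, format = c("auto", "bed", "rmout")) {
  format <- match.arg(format)
  lines <- readLines(path)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      repeat_class = character(0), stringsAsFactors = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty)
  if (format == "auto") {
    first <- trimws(lines[[1L]])
    format <- if (grepl("^SW|^score\\s+div", first) ||
                  grepl("perc perc|divg", first) ||
                  (!grepl("\t", lines[[1L]]) &&
                   length(strsplit(first, "\\s+")[[1L]]) >= 11))
      "rmout" else "bed"
  }
  if (format == "bed") {
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(f, length, integer(1)) < 3L)
    if (length(bad))
      stop("unrecognized BED line ", bad[1L], ": ", lines[bad[1L]])
    data.frame(
      chrom = vapply(f, `[`, character(1), 1L),
      start = as.numeric(vapply(f, `[`, character(1), 2L)),
      end = as.numeric(vapply(f, `[`, character(1), 3L)),
      strand = vapply(f, function(x)
        if (length(x) >= 6L && x[[6L]] %in% c("+", "-")) x[[6L]] else "+",
        character(1)),
      repeat_class = vapply(f, function(x)
        if (length(x) >= 4L) x[[4L]] else "repeat", character(1)),
      stringsAsFactors = FALSE)
  } else {
    # skip the two banner lines + blank; data rows are whitespace-separated
    dat <- lines[!grepl("^\\s*(SW|score|perc)", lines)]
    f <- strsplit(trimws(dat), "\\s+")
    bad <- which(vapply(f, length, integer(1)) < 11L)
    if (length(bad))
      stop("unrecognized RepeatMasker line: ", dat[bad[1L]])
    data.frame(
      chrom = vapply(f, `[`, character(1), 5L),
      start = as.numeric(vapply(f, `[`, character(1), 6L)) - 1,
      end = as.numeric(vapply(f, `[`, character(1), 7L)),
      strand = ifelse(vapply(f, `[`, character(1), 9L) == "C", "-", "+"),
      repeat_class = vapply(f, `[`, character(1), 11L),
      stringsAsFactors = FALSE)
  }
}
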