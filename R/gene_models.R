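#' Construct a genomic interval
#'
#' Coordinates are 0-based half-open throughout the package; GFF3 I/O converts
#' from/to the 1-based closed convention at the boundary.
#'
#' @param chrom Chromosome/contig identifier.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A one-row `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

.norm_intervals <- function(df, what, gene_id) {
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$end <= df$start))
    stop(what, " intervals with end <= start in gene ", gene_id)
  if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
    stop(what, " intervals overlap in gene ", gene_id)
  rownames(df) <- NULL
  df[, c("start", "end"), drop = FALSE]
}

#' Construct a single-transcript gene model
#'
#' Exons and CDS intervals are stored sorted by genomic coordinate; all
#' transcription-order quantities (intron ordinal, region offset, phase) are
#' derived on demand respecting `strand`.
#'
#' @param gene_id,species_id Identifiers.
#' @param chrom Chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with `start`,`end` (0-based half-open).
#' @param cds Optional `data.frame` with `start`,`end`; every CDS interval
#'   must fall inside the exon union. A summed CDS length that is not a
#'   multiple of 3 raises a warning (annotation oddity), not an error.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, species_id, chrom, strand, exons,
                             cds = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- .norm_intervals(exons, "exon", gene_id)
  if (nrow(exons) == 0L) stop("gene ", gene_id, " has no exons")
  cds <- .norm_intervals(cds, "CDS", gene_id)
  if (nrow(cds) > 0L) {
    # each cds interval must be contained in some exon
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(inside))
      stop("CDS outside exons in gene ", gene_id)
    cdslen <- sum(cds$end - cds$start)
    if (cdslen %% 3 != 0)
      warning("gene ", gene_id, ": CDS length ", cdslen,
              " is not a multiple of 3 (remainder ", cdslen %% 3, ")")
  }
  structure(list(gene_id = as.character(gene_id),
                 species_id = as.character(species_id),
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, cds = cds),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$gene_id, " (", x$species_id, ") ",
      x$chrom, ":", min(x$exons$start), "-", max(x$exons$end), " [", x$strand,
      "] ", nrow(x$exons), " exon(s), ",
      if (nrow(x$cds)) paste0(sum(x$cds$end - x$cds$start), " nt CDS")
      else "noncoding", "\n", sep = "")
  invisible(x)
}

# Exon lengths in transcription order, plus cumulative map.
.tx_layout <- function(t) {
  ex <- t$exons
  if (t$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  len <- ex$end - ex$start
  list(exons_tx = ex, len = len, cum = cumsum(len), total = sum(len))
}

# Genomic position -> transcript coordinate of the first/last coding base.
# Returns c(cds_tx_start, cds_tx_end): transcript offsets (0-based) of the
# first coding nt and one past the last coding nt. NULL for noncoding.
.cds_tx_span <- function(t) {
  if (nrow(t$cds) == 0L) return(NULL)
  lay <- .tx_layout(t)
  ex <- lay$exons_tx
  # transcript offset of a genomic position p inside exon i
  g2t <- function(p) {
    for (i in seq_len(nrow(ex))) {
      if (p >= ex$start[i] && p <= ex$end[i]) {
        before <- if (i > 1L) lay$cum[i - 1L] else 0
        if (t$strand == "+") return(before + (p - ex$start[i]))
        return(before + (ex$end[i] - p))
      }
    }
    stop("position ", p, " not exonic in gene ", t$gene_id)
  }
  if (t$strand == "+") {
    c(g2t(min(t$cds$start)), g2t(max(t$cds$end)))
  } else {
    c(g2t(max(t$cds$end)), g2t(min(t$cds$start)))
  }
}

#' Extract introns from a transcript model
#'
#' One intron per gap between consecutive exons, reported in transcription
#' order. Each intron is classified into 5' UTR, CDS or 3' UTR (or
#' `noncoding` for transcripts without CDS), given its region offset (number
#' of region nucleotides strictly 5' of the intron) and, for CDS introns, its
#' phase. Exon gaps shorter than `min_length` nucleotides are treated as
#' annotation artifacts and dropped with a warning: a real intron must at
#' least accommodate its donor and acceptor dinucleotides.
#'
#' @param t A `transcript_model`.
#' @param min_length Minimum retained intron length (default 4 nt).
#' @return A `data.frame` with one row per intron: `gene_id`, `species_id`,
#'   `ordinal`, `chrom`, `start`, `end`, `strand`, `length`, `region_class`,
#'   `region_offset`, `phase` (NA for non-CDS introns).
#' @export
extract_introns <- function(t, min_length = 4L) {
  stopifnot(inherits(t, "transcript_model"))
  empty <- data.frame(gene_id = character(0), species_id = character(0),
                      ordinal = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), length = numeric(0),
                      region_class = character(0), region_offset = numeric(0),
                      phase = integer(0), stringsAsFactors = FALSE)
  ex <- t$exons  # genomic order
  if (nrow(ex) < 2L) return(empty)
  gap_start <- ex$end[-nrow(ex)]
  gap_end <- ex$start[-1L]
  keep <- (gap_end - gap_start) >= min_length
  if (any(!keep))
    warning("gene ", t$gene_id, ": dropped ", sum(!keep),
            " exon gap(s) shorter than ", min_length, " nt")
  gap_start <- gap_start[keep]; gap_end <- gap_end[keep]
  if (length(gap_start) == 0L) return(empty)
  # transcription order
  o <- if (t$strand == "+") order(gap_start) else order(-gap_start)
  gap_start <- gap_start[o]; gap_end <- gap_end[o]
  lay <- .tx_layout(t)
  span <- .cds_tx_span(t)
  n <- length(gap_start)
  res <- empty[rep(1L, 0L), ]
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    # exonic nt strictly 5' of this intron = sum of tx-ordered exon lengths
    # up to the exon immediately 5' of the gap
    if (t$strand == "+") {
      idx5 <- which(lay$exons_tx$end == gap_start[k])
    } else {
      idx5 <- which(lay$exons_tx$start == gap_end[k])
    }
    p <- lay$cum[idx5]
    cls <- .classify_at(p, span)
    phase <- NA_integer_
    offset <- switch(cls,
      noncoding = p,
      UTR5 = p,
      CDS = p - span[1L],
      UTR3 = p - span[2L])
    if (cls == "CDS") phase <- as.integer((p - span[1L]) %% 3)
    rows[[k]] <- data.frame(gene_id = t$gene_id, species_id = t$species_id,
                            ordinal = k, chrom = t$chrom,
                            start = gap_start[k], end = gap_end[k],
                            strand = t$strand,
                            length = gap_end[k] - gap_start[k],
                            region_class = cls, region_offset = offset,
                            phase = phase, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# p = exonic nt strictly 5' of the intron (transcript coordinate of the gap);
# span = c(cds_tx_start, cds_tx_end) or NULL.
# Boundary rule: CDS only if >= 1 coding nt on each side of the intron.
.classify_at <- function(p, span) {
  if (is.null(span)) return("noncoding")
  if (p - span[1L] > 0 && span[2L] - p > 0) return("CDS")
  if (p <= span[1L]) return("UTR5")
  "UTR3"
}

#' Classify one intron of a transcript
#'
#' Region rule, in transcription direction: `UTR5` when the intron lies 5' of
#' the first coding nucleotide, `CDS` when at least one coding nucleotide
#' flanks it on each side, `UTR3` otherwise. An intron sitting exactly on a
#' UTR/CDS boundary is assigned to the adjacent UTR. Transcripts without an
#' annotated CDS yield the distinct marker `"noncoding"` with a warning.
#'
#' @param t A `transcript_model`.
#' @param intron_start,intron_end Genomic 0-based half-open intron
#'   coordinates (must be an exon gap of `t`).
#' @return One of `"UTR5"`, `"CDS"`, `"UTR3"`, `"noncoding"`.
#' @export
classify_intron <- function(t, intron_start, intron_end) {
  introns <- suppressWarnings(extract_introns(t))
  hit <- which(introns$start == intron_start & introns$end == intron_end)
  if (length(hit) != 1L)
    stop("interval [", intron_start, ", ", intron_end,
         ") is not an intron of gene ", t$gene_id)
  if (nrow(t$cds) == 0L)
    warning("gene ", t$gene_id,
            " has no CDS; introns classified 'noncoding', not 5' UTR")
  introns$region_class[hit]
}

#' Phase of a CDS intron
#'
#' The number of coding nucleotides strictly 5' of the intron, mod 3.
#' Calling this on an intron that is not in the CDS is a contract violation.
#'
#' @inheritParams classify_intron
#' @return Integer 0, 1 or 2.
#' @export
cds_phase <- function(t, intron_start, intron_end) {
  introns <- extract_introns(t)
  hit <- which(introns$start == intron_start & introns$end == intron_end)
  if (length(hit) != 1L)
    stop("interval is not an intron of gene ", t$gene_id)
  if (introns$region_class[hit] != "CDS")
    stop("cds_phase called on a ", introns$region_class[hit],
         " intron of gene ", t$gene_id)
  introns$phase[hit]
}

#' Region lengths of a transcript
#'
#' @param t A `transcript_model`.
#' @return Named numeric vector `c(UTR5=, CDS=, UTR3=)` in nucleotides
#'   (all-zero CDS/UTRs for noncoding transcripts, whose full exonic length is
#'   reported as `noncoding`).
#' @export
region_lengths <- function(t) {
  lay <- .tx_layout(t)
  span <- .cds_tx_span(t)
  if (is.null(span))
    return(c(UTR5 = 0, CDS = 0, UTR3 = 0, noncoding = lay$total))
  c(UTR5 = span[1L], CDS = span[2L] - span[1L], UTR3 = lay$total - span[2L],
    noncoding = 0)
}

#' Pooled intron densities over a gene set
#'
#' Intron density of a region is the number of introns per kilobase of that
#' region (CDS or 5' UTR). The primary figure is pooled: total introns across
#' the set divided by total region kilobases. Per-gene densities are returned
#' alongside for transparency; averaging them is left to the caller.
#'
#' @param genes List of `transcript_model` objects.
#' @return A list with `pooled` (one-row `data.frame`: `n_introns_cds`,
#'   `n_introns_utr5`, `kb_cds`, `kb_utr5`, `density_cds`, `density_utr5`) and
#'   `per_gene` (`data.frame`, one row per gene).
#' @export
gene_set_density <- function(genes) {
  per <- lapply(genes, function(t) {
    introns <- suppressWarnings(extract_introns(t))
    rl <- region_lengths(t)
    data.frame(gene_id = t$gene_id, species_id = t$species_id,
               n_introns_cds = sum(introns$region_class == "CDS"),
               n_introns_utr5 = sum(introns$region_class == "UTR5"),
               kb_cds = rl[["CDS"]] / 1000, kb_utr5 = rl[["UTR5"]] / 1000,
               stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(gene_id = character(0), species_id = character(0),
               n_introns_cds = integer(0), n_introns_utr5 = integer(0),
               kb_cds = numeric(0), kb_utr5 = numeric(0))
  dens1 <- function(n, kb) {
    if (kb > 0) return(n / kb)
    if (n > 0) stop("nonzero intron count over zero region length")
    warning("zero region length and zero introns: density reported as 0")
    0
  }
  n_cds <- sum(per$n_introns_cds); n_utr5 <- sum(per$n_introns_utr5)
  kb_cds <- sum(per$kb_cds); kb_utr5 <- sum(per$kb_utr5)
  pooled <- data.frame(
    n_introns_cds = n_cds, n_introns_utr5 = n_utr5,
    kb_cds = kb_cds, kb_utr5 = kb_utr5,
    density_cds = dens1(n_cds, kb_cds),
    density_utr5 = dens1(n_utr5, kb_utr5))
  per$density_cds <- ifelse(per$kb_cds > 0, per$n_introns_cds / per$kb_cds, 0)
  per$density_utr5 <- ifelse(per$kb_utr5 > 0,
                             per$n_introns_utr5 / per$kb_utr5, 0)
  list(pooled = pooled, per_gene = per)
}
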