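#' Read per-species gene structures from GFF3 or BED12
#'
#' One transcript is retained per gene: the transcript with the longest
#' summed CDS, ties broken by longest total exon length, then lexicographic
#' transcript id. Minus-strand models are normalized so that all
#' transcription-order quantities follow transcription.
#'
#' @param path A GFF3 (`gene`/`mRNA`/`exon`/`CDS` features) or BED12 file.
#' @param species_id Species identifier attached to every model.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return Named list of `transcript_model` objects (names = gene ids).
#' @export
read_gene_structures <- function(path, species_id,
                                 format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bed", "bed12")) "bed12" else "gff3"
  }
  if (format == "gff3") .read_gff3(path, species_id) else
    .read_bed12(path, species_id)
}

.read_gff3 <- function(path, species_id) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$Parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  df$ID <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(tx) == 0L) {
    # flat file: exon/CDS parented directly by gene ids
    tx <- unique(parts[, c("Parent", "seqnames", "strand"), drop = FALSE])
    tx$ID <- tx$Parent
    tx$gene <- tx$Parent
  } else {
    tx$gene <- ifelse(is.na(tx$Parent), tx$ID, tx$Parent)
  }
  models <- list()
  for (g in unique(tx$gene)) {
    cand <- tx[tx$gene == g, , drop = FALSE]
    built <- lapply(seq_len(nrow(cand)), function(i) {
      tid <- cand$ID[i]
      p <- parts[parts$Parent == tid, , drop = FALSE]
      ex <- p[p$type == "exon", , drop = FALSE]
      cd <- p[p$type == "CDS", , drop = FALSE]
      if (nrow(ex) == 0L) ex <- cd  # CDS-only annotation
      if (nrow(ex) == 0L) return(NULL)
      transcript_model(
        gene_id = g, species_id = species_id,
        chrom = as.character(ex$seqnames[1L]),
        strand = as.character(ex$strand[1L]),
        exons = data.frame(start = ex$start - 1, end = ex$end),
        cds = if (nrow(cd)) data.frame(start = cd$start - 1, end = cd$end))
    })
    built <- Filter(Negate(is.null), built)
    if (length(built) == 0L) next
    models[[g]] <- .pick_transcript(built, cand$ID[!is.na(cand$ID)])
  }
  models
}

# longest CDS, then longest exon sum, then lexicographic transcript id
.pick_transcript <- function(built, ids) {
  cdslen <- vapply(built, function(t) sum(t$cds$end - t$cds$start), numeric(1))
  exlen <- vapply(built, function(t) sum(t$exons$end - t$exons$start),
                  numeric(1))
  ids <- if (length(ids) == length(built)) ids else as.character(seq_along(built))
  o <- order(-cdslen, -exlen, ids)
  built[[o[1L]]]
}

.read_bed12 <- function(path, species_id) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED parse error in ", path, ": ",
                                          conditionMessage(e)))
  models <- list()
  for (i in seq_along(gr)) {
    x <- gr[i]
    name <- if (!is.null(x$name)) x$name else paste0("bed_", i)
    chromStart <- GenomicRanges::start(x) - 1  # back to 0-based
    bl <- if (!is.null(x$blocks)) x$blocks[[1L]] else NULL
    if (is.null(bl) || length(bl) == 0L) {
      exons <- data.frame(start = chromStart, end = GenomicRanges::end(x))
    } else {
      # blocks are 1-based relative to chromStart
      exons <- data.frame(start = chromStart + IRanges::start(bl) - 1,
                          end = chromStart + IRanges::end(bl))
    }
    cds <- NULL
    if (!is.null(x$thick)) {
      ts <- IRanges::start(x$thick) - 1; te <- IRanges::end(x$thick)
      if (te > ts) {  # thickStart == thickEnd encodes a noncoding entry
        s <- pmax(exons$start, ts); e <- pmin(exons$end, te)
        keep <- e > s
        if (any(keep)) cds <- data.frame(start = s[keep], end = e[keep])
      }
    }
    models[[name]] <- transcript_model(
      gene_id = name, species_id = species_id,
      chrom = as.character(GenomicRanges::seqnames(x)),
      strand = as.character(GenomicRanges::strand(x)),
      exons = exons, cds = cds)
  }
  models
}

#' Write transcript models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features with `ID`/`Parent`
#' attributes; coordinates converted to the 1-based closed GFF3 convention.
#' Reading the file back with [read_gene_structures()] reproduces the models.
#'
#' @param models List of `transcript_model` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_structures <- function(models, path) {
  lines <- "##gff-version 3"
  for (t in models) {
    span <- c(min(t$exons$start) + 1, max(t$exons$end))
    gid <- t$gene_id; tid <- paste0(gid, ".t1")
    row9 <- function(type, s, e, id = NULL, parent = NULL) {
      attrs <- c(if (!is.null(id)) paste0("ID=", id),
                 if (!is.null(parent)) paste0("Parent=", parent))
      paste(t$chrom, "introgain", type, s, e, ".", t$strand, ".",
            paste(attrs, collapse = ";"), sep = "\t")
    }
    lines <- c(lines,
               row9("gene", span[1], span[2], id = gid),
               row9("mRNA", span[1], span[2], id = tid, parent = gid),
               vapply(seq_len(nrow(t$exons)), function(i)
                 row9("exon", t$exons$start[i] + 1, t$exons$end[i],
                      parent = tid), character(1)),
               if (nrow(t$cds))
                 vapply(seq_len(nrow(t$cds)), function(i)
                   row9("CDS", t$cds$start[i] + 1, t$cds$end[i],
                        parent = tid), character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models as BED12
#'
#' @inheritParams write_gene_structures
#' @return `path`, invisibly.
#' @export
write_gene_structures_bed12 <- function(models, path) {
  lines <- vapply(models, function(t) {
    cs <- min(t$exons$start); ce <- max(t$exons$end)
    if (nrow(t$cds)) {
      ts <- min(t$cds$start); te <- max(t$cds$end)
    } else {
      ts <- cs; te <- cs
    }
    sizes <- paste0(paste(t$exons$end - t$exons$start, collapse = ","), ",")
    starts <- paste0(paste(t$exons$start - cs, collapse = ","), ",")
    paste(t$chrom, cs, ce, t$gene_id, 0, t$strand, ts, te, "0",
          nrow(t$exons), sizes, starts, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
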