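#' Construct a region alignment
#'
#' A multiple alignment of one gene region (5' UTR, CDS or 3' UTR) across the
#' species of an ortholog group, used to carry intron positions into a common
#' coordinate system. Rows must be equal-width gapped strings; `-` and `.`
#' are gap characters.
#'
#' @param family_id Ortholog-group identifier.
#' @param region_class `"UTR5"`, `"CDS"` or `"UTR3"`.
#' @param rows Named character vector, `species_id -> gapped sequence`.
#' @param alphabet `"nucleotide"` or `"protein"`. Protein rows hold the
#'   translated CDS; one residue spans three coding nucleotides.
#' @return An object of class `region_alignment`.
#' @export
region_alignment <- function(family_id, region_class, rows,
                             alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  region_class <- match.arg(region_class, c("UTR5", "CDS", "UTR3"))
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("alignment rows have unequal widths in family ", family_id)
  structure(list(family_id = family_id, region_class = region_class,
                 rows = rows, alphabet = alphabet, width = w),
            class = "region_alignment")
}

#' Read an aligned FASTA into a region alignment
#'
#' @param path Aligned FASTA file.
#' @param family_id,region_class,alphabet Passed to [region_alignment()].
#' @return A `region_alignment`.
#' @export
read_region_alignment <- function(path, family_id, region_class,
                                  alphabet = "nucleotide") {
  ss <- Biostrings::readBStringSet(path)
  region_alignment(family_id, region_class,
                   stats::setNames(as.character(ss), names(ss)), alphabet)
}

#' Write a region alignment as aligned FASTA
#'
#' @param aln A `region_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_region_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.is_gap <- function(chars) chars == "-" | chars == "."

# ungapped index -> alignment column for one row; index 0 -> column 0
.gapmap_column <- function(row, ungapped_index) {
  if (ungapped_index == 0L) return(0L)
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  pos <- which(!.is_gap(chars))
  if (ungapped_index > length(pos))
    stop("ungapped index ", ungapped_index, " beyond row length ",
         length(pos))
  pos[ungapped_index]
}

#' Project an intron position into alignment coordinates
#'
#' The intron's insertion point sits after `region_offset` region
#' nucleotides. For nucleotide alignments the reported column is the column
#' of the nucleotide immediately 5' of the insertion point; for protein
#' alignments of the CDS it is the column of the residue containing the
#' insertion point (phase 1/2) or immediately preceding it (phase 0). The
#' projection maps through the species' own ungapped index, so it can never
#' land on a gap in that species' row.
#'
#' @param aln A `region_alignment`.
#' @param species_id Row to project through.
#' @param region_offset Region nucleotides strictly 5' of the intron.
#' @param phase CDS intron phase (0/1/2); `NA` for UTR introns.
#' @return List with `column` (integer; 0 means "before the first region
#'   position") and `phase`.
#' @export
project_intron <- function(aln, species_id, region_offset, phase = NA) {
  stopifnot(inherits(aln, "region_alignment"))
  if (!species_id %in% names(aln$rows))
    stop("species ", species_id, " has no row in family ", aln$family_id)
  row <- aln$rows[[species_id]]
  if (aln$alphabet == "protein") {
    if (is.na(phase)) stop("protein projection requires a CDS phase")
    residue <- ceiling(region_offset / 3)
    column <- tryCatch(.gapmap_column(row, residue),
                       error = function(e)
                         stop("projection error in family ", aln$family_id,
                              ", species ", species_id, ": ",
                              conditionMessage(e)))
  } else {
    column <- tryCatch(.gapmap_column(row, region_offset),
                       error = function(e)
                         stop("projection error in family ", aln$family_id,
                              ", species ", species_id, ": ",
                              conditionMessage(e)))
  }
  list(column = as.integer(column),
       phase = if (is.na(phase)) NA_integer_ else as.integer(phase))
}

#' Cluster projected introns into homologous intron sites
#'
#' Two introns belong to one site iff they share the region class, have equal
#' phase (CDS sites), and their alignment columns differ by at most `slack`
#' columns. With the default `slack = 0` this is an exact partition by
#' `(region, column, phase)`; with `slack > 0` merging is single-linkage,
#' scanning columns left to right, to tolerate small intron sliding. Species
#' not carrying an intron at a site are scored `absent` when their row covers
#' the site's column with gap-free sequence over a flanking window, and
#' `unknown` otherwise (missing rows, assembly gaps).
#'
#' @param aln A `region_alignment` (provides rows for absent/unknown calls).
#' @param projections `data.frame` with columns `species_id`, `ordinal`,
#'   `column`, `phase`, `length` (intron length, nt).
#' @param slack Maximum column distance merged into one site (default 0).
#' @param flank Gap-free columns required on the site's flanks to call a
#'   species `absent` rather than `unknown` (default 10).
#' @param species All species of the ortholog group; defaults to the
#'   alignment's rows.
#' @return List of `intron_site` objects: `family_id`, `region_class`,
#'   `column`, `phase`, `states` (named chr: present/absent/unknown),
#'   `lengths` (named numeric, present species only).
#' @export
cluster_sites <- function(aln, projections, slack = 0L, flank = 10L,
                          species = NULL) {
  stopifnot(inherits(aln, "region_alignment"))
  if (is.null(species)) species <- names(aln$rows)
  if (nrow(projections) == 0L) return(list())
  pr <- projections
  pr$phase_key <- ifelse(is.na(pr$phase), -1L, pr$phase)
  sites <- list()
  for (ph in sort(unique(pr$phase_key))) {
    sub <- pr[pr$phase_key == ph, , drop = FALSE]
    sub <- sub[order(sub$column, sub$species_id), , drop = FALSE]
    # left-to-right single linkage on columns
    grp <- cumsum(c(1L, diff(sub$column) > slack))
    for (g in unique(grp)) {
      m <- sub[grp == g, , drop = FALSE]
      if (anyDuplicated(m$species_id))
        stop("two introns from species ",
             m$species_id[duplicated(m$species_id)][1L],
             " cluster into one site in family ", aln$family_id,
             "; deduplicate annotations upstream")
      col <- min(m$column)
      states <- stats::setNames(rep("unknown", length(species)), species)
      states[m$species_id] <- "present"
      for (s in setdiff(species, m$species_id)) {
        if (s %in% names(aln$rows) &&
            .covers_column(aln$rows[[s]], col, flank))
          states[s] <- "absent"
      }
      sites[[length(sites) + 1L]] <- structure(
        list(family_id = aln$family_id, region_class = aln$region_class,
             column = col,
             phase = if (ph < 0L) NA_integer_ else as.integer(ph),
             states = states,
             lengths = stats::setNames(m$length, m$species_id)),
        class = "intron_site")
    }
  }
  # deterministic order: by column then phase
  ord <- order(vapply(sites, `[[`, integer(1), "column"),
               vapply(sites, function(s) ifelse(is.na(s$phase), -1L, s$phase),
                      integer(1)))
  sites[ord]
}

# TRUE when the row has no gap character in the window of `flank` columns on
# each side of `col` (clamped to the alignment), i.e. the species' sequence
# demonstrably covers the site.
.covers_column <- function(row, col, flank) {
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  lo <- max(1L, col - flank + 1L); hi <- min(length(chars), col + flank)
  if (col == 0L) lo <- 1L
  !any(.is_gap(chars[lo:hi]))
}

#' Presence/absence/unknown matrix of intron sites
#'
#' @param sites List of `intron_site` objects.
#' @param species_order Column order of the matrix.
#' @return Character matrix (`"P"`/`"A"`/`"U"`), rows named
#'   `site_<region>_<column>_p<phase>`, with attributes `region_class`,
#'   `column`, `phase` carrying the site keys.
#' @export
site_matrix <- function(sites, species_order) {
  m <- matrix(character(0), nrow = 0, ncol = length(species_order),
              dimnames = list(NULL, species_order))
  if (length(sites) == 0L) {
    attr(m, "region_class") <- character(0)
    attr(m, "column") <- integer(0)
    attr(m, "phase") <- integer(0)
    return(m)
  }
  code <- c(present = "P", absent = "A", unknown = "U")
  rows <- t(vapply(sites, function(s) {
    st <- rep("U", length(species_order))
    names(st) <- species_order
    known <- intersect(names(s$states), species_order)
    st[known] <- code[s$states[known]]
    st
  }, character(length(species_order))))
  rownames(rows) <- vapply(sites, function(s)
    paste0("site_", s$region_class, "_", s$column, "_p",
           ifelse(is.na(s$phase), "NA", s$phase)), character(1))
  colnames(rows) <- species_order
  attr(rows, "region_class") <- vapply(sites, `[[`, character(1),
                                       "region_class")
  attr(rows, "column") <- vapply(sites, `[[`, integer(1), "column")
  attr(rows, "phase") <- vapply(sites, function(s)
    ifelse(is.na(s$phase), NA_integer_, s$phase), integer(1))
  rows
}

#' Recover intron-site states from a site matrix
#'
#' Lossless inverse of [site_matrix()] for the state component.
#'
#' @param m Matrix from [site_matrix()].
#' @return List of named state vectors (present/absent/unknown).
#' @export
matrix_states <- function(m) {
  decode <- c(P = "present", A = "absent", U = "unknown")
  lapply(seq_len(nrow(m)), function(i)
    stats::setNames(decode[m[i, ]], colnames(m)))
}
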