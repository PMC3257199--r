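.extdata <- function(file) {
  p <- system.file("extdata", file, package = "introgain")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' Packaged species tree
#'
#' Chordate species tree with named ancestral nodes (Chordata,
#' Gnathostomata, Tetrapoda, Amniota, Mammalia, Theria, Eutheria,
#' Boreoeutheria, Atlantogenata and the four placental superorders), two
#' representative species per placental superorder, and branch lengths in
#' units of 100 My.
#'
#' @return An `ape::phylo`.
#' @export
fixture_species_tree <- function() {
  read_species_tree(.extdata("species_tree.nwk"))
}

.read_fixture_tsv <- function(file) {
  utils::read.delim(.extdata(file), comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Packaged domesticated-gene survey metadata
#'
#' Transcriptions of the published survey of TE-derived domesticated genes
#' with de novo gained introns: 36 DNA-transposon-derived families (with
#' origin-route annotations driving the eligibility filter) and 27
#' retroelement-derived genes.
#'
#' @param class `"DNA_transposon"`, `"retroelement"` or `"both"`.
#' @return `data.frame` with columns `gene`, `te_group`, `progenitor_class`,
#'   `origin_route`, `exclusion_flag`, `introns_min`, `introns_max`,
#'   `location`.
#' @export
fixture_gene_metadata <- function(class = c("both", "DNA_transposon",
                                            "retroelement")) {
  class <- match.arg(class)
  dna <- .read_fixture_tsv("dna_transposon_genes.tsv")
  retro <- .read_fixture_tsv("retroelement_genes.tsv")
  out <- switch(class, DNA_transposon = dna, retroelement = retro,
                both = rbind(dna, retro))
  out$family_id <- out$gene
  out
}

#' Packaged origin-timing table
#'
#' @return `data.frame`: `gene`, `progenitor_class`, `origin_node` for the 33
#'   families whose origin LCA the survey places on the tree.
#' @export
fixture_origins <- function() {
  .read_fixture_tsv("origins.tsv")
}

#' Packaged intron-position-conservation table
#'
#' @return `data.frame`: `gene` plus one column per placental superorder with
#'   values `present`/`incomplete`/`unknown`.
#' @export
fixture_conservation <- function() {
  .read_fixture_tsv("conservation_table.tsv")
}

#' Derive the per-gene three-state presence matrix from origin nodes
#'
#' Mechanical derivation: a gene whose origin is placed at node N is present
#' in every sampled species under N and absent outside N. Superorder cells
#' recorded `incomplete`/`unknown` in the conservation table censor that
#' superorder's representative species to `unknown`. This is the derivation
#' rule stated in the fixture provenance comments; the survey does not print
#' per-species genome checks.
#'
#' @param tree Species tree (default the packaged one).
#' @param origins Origin table (default the packaged one).
#' @param conservation Conservation table (default the packaged one).
#' @return Character matrix, genes x species, values
#'   `"present"`/`"absent"`/`"unknown"`.
#' @export
fixture_presence_matrix <- function(tree = fixture_species_tree(),
                                    origins = fixture_origins(),
                                    conservation = fixture_conservation()) {
  species <- tree$tip.label
  m <- matrix("absent", nrow = nrow(origins), ncol = length(species),
              dimnames = list(origins$gene, species))
  for (i in seq_len(nrow(origins))) {
    node <- .node_id(tree, origins$origin_node[i])
    m[i, .tips_under(tree, node)] <- "present"
  }
  superorders <- setdiff(names(conservation), "gene")
  for (j in seq_len(nrow(conservation))) {
    g <- conservation$gene[j]
    if (!g %in% rownames(m)) next
    for (so in superorders) {
      if (conservation[[so]][j] %in% c("incomplete", "unknown", "?"))
        m[g, .tips_under(tree, .node_id(tree, so))] <- "unknown"
    }
  }
  m
}

#' Emit the packaged fixture bundle to a directory
#'
#' Writes the species tree (newick), the gene metadata TSVs, the origin
#' table, the conservation table, and the mechanically derived three-state
#' presence matrix (TSV, P/A/U coded) to `dir`.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
package_paper_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  src <- c(species_tree = "species_tree.nwk",
           dna_transposon_genes = "dna_transposon_genes.tsv",
           retroelement_genes = "retroelement_genes.tsv",
           origins = "origins.tsv",
           conservation = "conservation_table.tsv")
  out <- file.path(dir, src)
  for (i in seq_along(src)) file.copy(.extdata(src[[i]]), out[[i]],
                                      overwrite = TRUE)
  pm <- fixture_presence_matrix()
  code <- c(present = "P", absent = "A", unknown = "U")
  pm_df <- data.frame(gene = rownames(pm),
                      apply(pm, 2L, function(x) code[x]),
                      check.names = FALSE, stringsAsFactors = FALSE)
  pm_path <- file.path(dir, "presence_matrix.tsv")
  con <- file(pm_path, "w")
  writeLines(c("# Three-state gene presence matrix (P/A/U), derived",
               "# mechanically from origins.tsv: present in every species",
               "# under the origin node, absent outside, unknown where the",
               "# conservation table records incomplete/unknown cells."), con)
  suppressWarnings(utils::write.table(pm_df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  invisible(c(out, presence_matrix = pm_path))
}

#' Read a P/A/U presence matrix TSV
#'
#' @param path TSV written by [package_paper_fixtures()] (first column
#'   `gene`, one column per species, values P/A/U).
#' @return Character matrix of `present`/`absent`/`unknown` states.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  decode <- c(P = "present", A = "absent", U = "unknown")
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[] <- decode[m]
  rownames(m) <- df[[1L]]
  m
}
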