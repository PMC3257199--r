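#' Positional bias of gained introns
#'
#' Counts introns per region class. Accepts either an intron table (from
#' [extract_introns()]; counted directly) or fixture gene metadata (with
#' `location` strings and `introns_min`/`introns_max` ranges; per-region
#' intron counts are then reported as min/max bounds and per-region gene
#' lists are attached). In fixture metadata, a location like `UTR5/CDS`
#' means introns in both regions; `UTR5|CDS` records source ambiguity and
#' contributes to both regions' gene lists but only to the `max` bound of
#' each region's intron count.
#'
#' @param x Intron `data.frame` (column `region_class`) or fixture metadata
#'   (`location`, `introns_min`, `introns_max`).
#' @return For intron tables: `data.frame` with `region_class`, `n`,
#'   `fraction`. For metadata: `data.frame` with `region_class`, `n_genes`,
#'   and attribute `genes` (named list of gene ids per region).
#' @export
positional_bias_table <- function(x) {
  regions <- c("UTR5", "CDS", "UTR3")
  if ("region_class" %in% names(x)) {
    n <- vapply(regions, function(r) sum(x$region_class == r), integer(1))
    extra <- sum(!x$region_class %in% regions)
    tot <- sum(n) + extra
    return(data.frame(region_class = regions, n = n,
                      fraction = if (tot > 0) n / tot else rep(0, 3L),
                      row.names = NULL))
  }
  if (!"location" %in% names(x))
    stop("expected an intron table or fixture metadata")
  hit <- lapply(regions, function(r) grepl(r, x$location, fixed = TRUE))
  names(hit) <- regions
  out <- data.frame(region_class = regions,
                    n_genes = vapply(hit, sum, integer(1)), row.names = NULL)
  attr(out, "genes") <- lapply(hit, function(h) x$gene[h])
  out
}

#' Pipeline run configuration
#'
#' @param input_dir Directory holding the inputs: either a fixture bundle
#'   written by [package_paper_fixtures()] (fixture mode) or a simulation
#'   directory written by [write_simulation()] (structure mode, detected by
#'   the presence of per-species `.gff3` files).
#' @param out_dir Output directory for the report bundle.
#' @param slack Column slack for [cluster_sites()].
#' @param identity_threshold Percent-identity threshold for
#'   `highly_conserved` classification.
#' @param seed Seed recorded in the log (stages are deterministic given the
#'   inputs).
#' @return List of class `run_config`; errors if `input_dir` is missing or
#'   empty.
#' @export
run_config <- function(input_dir, out_dir, slack = 0L,
                       identity_threshold = 70, seed = 1L) {
  if (!dir.exists(input_dir) || length(list.files(input_dir)) == 0L)
    stop("input directory missing or empty: ", input_dir)
  stopifnot(slack >= 0, identity_threshold >= 0, identity_threshold <= 100)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 slack = as.integer(slack),
                 identity_threshold = identity_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
}

#' Run the composite analysis pipeline
#'
#' Fixture mode (bundle from [package_paper_fixtures()]): places every
#' family's origin from the three-state presence matrix, tallies origins and
#' intron-gain ranges per tree node, applies the eligibility filter, and
#' summarizes positional bias. Structure mode (directory from
#' [write_simulation()]): reads per-species gene structures, extracts
#' introns, projects them through the family region alignments, clusters
#' homologous sites, places each site's gain by Dollo parsimony, and tallies
#' gains per node. Both modes write per-stage TSVs, a versioned JSON summary
#' and a run log (timestamps confined to the log; TSV/JSON outputs are
#' byte-reproducible).
#'
#' @param config A `run_config`.
#' @return The summary list, invisibly (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = log,
                               append = TRUE)
  cat("", file = log)
  logline("introgain ",
          as.character(utils::packageVersion("introgain")),
          " | seed ", config$seed, " | config ", .config_hash(config))
  logline("started ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mode <- if (length(list.files(config$input_dir,
                                pattern = "\\.gff3$")) > 0L)
    "structures" else "fixtures"
  logline("mode: ", mode)
  summary <- tryCatch(
    if (mode == "fixtures") .run_fixture_mode(config, logline)
    else .run_structure_mode(config, logline),
    error = function(e) {
      writeLines("FAILED", file.path(config$out_dir, "FAILED"))
      logline("FAILED: ", conditionMessage(e))
      stop(e)
    })
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("finished ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  invisible(summary)
}

.run_fixture_mode <- function(config, logline) {
  ind <- config$input_dir
  tree <- read_species_tree(file.path(ind, "species_tree.nwk"))
  pm <- read_presence_matrix(file.path(ind, "presence_matrix.tsv"))
  meta <- rbind(
    utils::read.delim(file.path(ind, "dna_transposon_genes.tsv"),
                      comment.char = "#", stringsAsFactors = FALSE),
    utils::read.delim(file.path(ind, "retroelement_genes.tsv"),
                      comment.char = "#", stringsAsFactors = FALSE))
  meta$family_id <- meta$gene
  logline("stage origin-placement: ", nrow(pm), " families")
  origins <- do.call(rbind, lapply(rownames(pm), function(g) {
    pl <- place_gene_origin(tree, pm[g, ])
    data.frame(family_id = g, origin_node = pl$label,
               stringsAsFactors = FALSE)
  }))
  origins <- merge(origins,
                   meta[, c("family_id", "progenitor_class", "introns_min",
                            "introns_max")],
                   by = "family_id", all.x = TRUE, sort = TRUE)
  .write_tsv(origins, file.path(config$out_dir, "origins_placed.tsv"),
             "Dollo origin placement per family from the presence matrix")
  ev <- data.frame(family_id = origins$family_id,
                   node_label = origins$origin_node,
                   gains_min = origins$introns_min,
                   gains_max = origins$introns_max)
  tally <- tally_gains(ev, tree)
  by_class <- lapply(split(ev, origins$progenitor_class), tally_gains,
                     tree = tree)
  .write_tsv(tally, file.path(config$out_dir, "node_tally.tsv"),
             "families originating and intron-gain ranges per tree node")
  elig <- filter_eligible(meta)
  .write_tsv(elig, file.path(config$out_dir, "eligibility.tsv"),
             "origin-route eligibility for gain timing")
  bias <- positional_bias_table(meta)
  .write_tsv(bias, file.path(config$out_dir, "positional_bias.tsv"),
             "genes with gained introns per region class")
  logline("stage tally: ", nrow(tally), " nodes")
  eut <- origins$origin_node == "Eutheria"
  list(schema_version = "1.0", mode = "fixtures", seed = config$seed,
       n_families = nrow(origins),
       n_eutheria_origin = sum(eut),
       n_eutheria_origin_by_class = as.list(
         table(origins$progenitor_class[eut])),
       eligibility = list(
         n_considered = nrow(elig), n_eligible = sum(elig$eligible),
         n_eligible_by_class = lapply(
           split(elig$eligible, meta$progenitor_class), sum)),
       node_tally = tally,
       node_tally_by_class = lapply(by_class, identity),
       positional_bias = bias)
}

.run_structure_mode <- function(config, logline) {
  ind <- config$input_dir
  tree <- read_species_tree(file.path(ind, "species_tree.nwk"))
  gff <- list.files(ind, pattern = "\\.gff3$", full.names = TRUE)
  models <- list()  # family -> species -> transcript_model
  for (p in gff) {
    sp <- sub("\\.gff3$", "", basename(p))
    for (t in read_gene_structures(p, sp)) models[[t$gene_id]][[sp]] <- t
  }
  logline("stage extract: ", length(models), " families, ",
          length(gff), " species")
  introns <- do.call(rbind, unlist(lapply(models, function(fm)
    lapply(fm, extract_introns)), recursive = FALSE))
  rownames(introns) <- NULL
  .write_tsv(introns, file.path(config$out_dir, "introns.tsv"),
             "extracted introns, transcription order, 0-based half-open")
  dens <- gene_set_density(unlist(models, recursive = FALSE,
                                  use.names = FALSE))
  scen_rows <- list(); site_rows <- list()
  for (fam in names(models)) {
    sp_here <- names(models[[fam]])
    presence <- stats::setNames(
      ifelse(tree$tip.label %in% sp_here, "present", "unknown"),
      tree$tip.label)
    origin <- place_gene_origin(tree, presence)
    fam_introns <- introns[introns$gene_id == fam, , drop = FALSE]
    for (rg in unique(fam_introns$region_class)) {
      aln_path <- file.path(ind, paste0(fam, "_", rg, ".aln.fa"))
      if (!file.exists(aln_path)) next
      aln <- read_region_alignment(aln_path, fam, rg)
      sub <- fam_introns[fam_introns$region_class == rg, , drop = FALSE]
      proj <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        pr <- project_intron(aln, sub$species_id[i], sub$region_offset[i],
                             sub$phase[i])
        data.frame(species_id = sub$species_id[i], ordinal = sub$ordinal[i],
                   column = pr$column, phase = pr$phase,
                   length = sub$length[i], stringsAsFactors = FALSE)
      }))
      sites <- cluster_sites(aln, proj, slack = config$slack,
                             species = sp_here)
      for (s in sites) {
        gl <- place_site_gain(tree, s$states, origin_node = origin$node)
        sid <- paste0(fam, "_", rg, "_c", s$column,
                      ifelse(is.na(s$phase), "", paste0("_p", s$phase)))
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          family_id = fam, site_id = sid, region_class = rg,
          column = s$column, phase = s$phase,
          n_present = sum(s$states == "present"),
          n_absent = sum(s$states == "absent"),
          n_unknown = sum(s$states == "unknown"),
          stringsAsFactors = FALSE)
        scen_rows[[length(scen_rows) + 1L]] <- data.frame(
          family_id = fam, site_id = sid,
          origin_node = origin$label, gain_node = gl$gain_label,
          loss_branches = paste(gl$loss_branches, collapse = ";"),
          n_losses = gl$n_losses, stringsAsFactors = FALSE)
      }
    }
  }
  sites_df <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame()
  scen_df <- if (length(scen_rows)) do.call(rbind, scen_rows) else
    data.frame(family_id = character(0), site_id = character(0),
               origin_node = character(0), gain_node = character(0),
               loss_branches = character(0), n_losses = integer(0))
  .write_tsv(sites_df, file.path(config$out_dir, "sites.tsv"),
             "homologous intron sites and three-state tallies")
  .write_tsv(scen_df, file.path(config$out_dir, "scenarios.tsv"),
             "Dollo gain node and loss branches per site")
  logline("stage time-gains: ", nrow(scen_df), " sites")
  ev <- data.frame(family_id = scen_df$family_id,
                   node_label = scen_df$gain_node)
  tally <- tally_gains(ev, tree)
  .write_tsv(tally, file.path(config$out_dir, "node_tally.tsv"),
             "intron gains per tree node")
  bias <- positional_bias_table(introns)
  qs <- if (nrow(introns)) stats::quantile(introns$length,
                                           c(0.25, 0.5, 0.75)) else
    stats::setNames(rep(NA_real_, 3L), c("25%", "50%", "75%"))
  list(schema_version = "1.0", mode = "structures", seed = config$seed,
       n_families = length(models), n_introns = nrow(introns),
       n_sites = nrow(sites_df),
       densities = dens$pooled,
       positional_bias = bias,
       intron_size_quantiles = as.list(qs),
       node_tally = tally)
}
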