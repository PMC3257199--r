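#' Read a rooted species tree with named internal nodes
#'
#' The tree is the scaffold onto which gene origins and intron gains are
#' placed; internal labels name ancestral clades (e.g. Chordata,
#' Gnathostomata, Tetrapoda, Amniota, Theria, Eutheria, Boreoeutheria and the
#' four placental superorders).
#'
#' @param path Newick file.
#' @return An `ape::phylo` object, validated for rootedness and unique
#'   labels.
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_species_tree(tree)
  tree
}

#' Validate a species tree
#'
#' @param tree An `ape::phylo`.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  labs <- c(tree$tip.label,
            tree$node.label[!is.na(tree$node.label) & tree$node.label != ""])
  if (anyDuplicated(labs))
    stop("duplicate labels in species tree: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  invisible(tree)
}

# label (tip or internal) -> node number
.node_id <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (!is.na(j)) return(ape::Ntip(tree) + j)
  stop("node '", label, "' not found in species tree")
}

# node number -> label ("" if unlabeled internal)
.node_label <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  lab <- tree$node.label[node - nt]
  if (is.null(lab) || is.na(lab)) "" else lab
}

.children <- function(tree, node) {
  tree$edge[tree$edge[, 1L] == node, 2L]
}

.tips_under <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

.mrca <- function(tree, tips) {
  tips <- unique(tips)
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# TRUE iff `desc` equals `anc` or lies in anc's clade
.is_descendant <- function(tree, desc, anc) {
  if (desc == anc) return(TRUE)
  nt <- ape::Ntip(tree)
  if (anc <= nt) return(FALSE)
  desc_tips <- .tips_under(tree, desc)
  all(desc_tips %in% .tips_under(tree, anc))
}

#' Origin-route eligibility filter for gain-timing
#'
#' Domesticated genes can arise by three routes: domestication of the whole
#' TE coding unit, fusion of the TE as a 3'-terminal exon of a host gene, and
#' exon shuffling of the TE's DNA-binding domain into a host gene. Only the
#' whole-TE route guarantees an unambiguously intronless ancestral structure,
#' so fusion- and shuffle-route families are excluded from gain timing.
#' Retroelement-derived families are whole-TE by default (fusion is
#' essentially absent in that class); documented exceptions are excluded via
#' an explicit metadata flag.
#'
#' @param groups `data.frame` with columns `family_id`, `progenitor_class`
#'   (`retroelement`/`DNA_transposon`), `origin_route` (`whole_TE`/
#'   `fusion_3prime`/`DBD_shuffle`), and optionally `exclusion_flag`
#'   (logical).
#' @return `data.frame`: `family_id`, `origin_route`, `eligible`, `reason`.
#' @export
filter_eligible <- function(groups) {
  need <- c("family_id", "progenitor_class", "origin_route")
  if (!all(need %in% names(groups)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  bad <- is.na(groups$origin_route) | groups$origin_route == ""
  if (any(bad))
    stop("missing origin_route for family ",
         paste(groups$family_id[bad], collapse = ", "))
  flag <- if ("exclusion_flag" %in% names(groups))
    isTRUE_vec(groups$exclusion_flag) else rep(FALSE, nrow(groups))
  eligible <- groups$origin_route == "whole_TE" & !flag
  reason <- ifelse(flag, "excluded by metadata flag (documented exception)",
            ifelse(groups$origin_route == "whole_TE",
                   "whole-TE origin: ancestral structure intronless",
                   paste0(groups$origin_route,
                          " route: fused/shuffled exons excluded from ",
                          "intron-gain inference")))
  data.frame(family_id = groups$family_id,
             origin_route = groups$origin_route,
             eligible = eligible, reason = reason,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Place a gene's origin on the species tree
#'
#' The origin is the most recent common ancestor of all species in which the
#' gene is present; `unknown` states are uninformative and `absent` states
#' never pull the node. A gene present in a single species is reported at
#' that terminal leaf (origin on its terminal branch).
#'
#' @param tree Species tree (`phylo`).
#' @param presence Named character vector, species -> `present`/`absent`/
#'   `unknown`.
#' @return List: `node` (ape node number), `label` (clade name, or the tip
#'   label for terminal origins).
#' @export
place_gene_origin <- function(tree, presence) {
  pres <- names(presence)[presence == "present"]
  if (length(pres) == 0L)
    stop("no species with state 'present'; cannot place gene origin")
  missing <- setdiff(pres, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  node <- .mrca(tree, pres)
  list(node = node, label = .node_label(tree, node))
}

#' Dollo placement of one intron-site gain
#'
#' Under the known-intronless ancestor, each homologous intron site is gained
#' exactly once; the gain node is the MRCA of the species presenting the
#' intron, and losses are charged to the stem branches of the maximal
#' all-absent subtrees below the gain node. `unknown` leaves never force a
#' loss and never pull the MRCA (equivalent to pruning them per site), so the
#' returned loss count is the minimum compatible with a single gain.
#'
#' @param tree Species tree (`phylo`).
#' @param states Named character vector, species -> `present`/`absent`/
#'   `unknown`.
#' @param origin_node Optional ape node number of the family's gene origin;
#'   present species outside its clade raise an orthology-conflict error.
#' @return List: `gain_node`, `gain_label`, `loss_branches` (character vector
#'   of child-node labels identifying the lost stems), `n_losses`.
#' @export
place_site_gain <- function(tree, states, origin_node = NULL) {
  pres <- names(states)[states == "present"]
  if (length(pres) == 0L) stop("site has no present species")
  if (!is.null(origin_node)) {
    clade <- .tips_under(tree, origin_node)
    out <- setdiff(pres, clade)
    if (length(out))
      stop("orthology conflict: species ", paste(out, collapse = ", "),
           " present outside the gene-origin clade")
  }
  gain <- .mrca(tree, pres)
  losses <- character(0)
  # recurse: a child subtree with no present leaves but >= 1 informative
  # absent leaf is a maximal all-absent subtree -> one loss on its stem
  walk <- function(node) {
    for (ch in .children(tree, node)) {
      tips <- .tips_under(tree, ch)
      st <- states[intersect(tips, names(states))]
      if (any(st == "present", na.rm = TRUE)) {
        if (ch > ape::Ntip(tree)) walk(ch)
      } else if (any(st == "absent", na.rm = TRUE)) {
        lab <- .node_label(tree, ch)
        losses <<- c(losses,
                     if (nzchar(lab)) lab else paste0("node_", ch))
      }
      # all-unknown subtree: uninformative, no loss
    }
  }
  if (gain > ape::Ntip(tree)) walk(gain)
  list(gain_node = gain, gain_label = .node_label(tree, gain),
       loss_branches = losses, n_losses = length(losses))
}

#' Tally gene origins and intron gains per tree node
#'
#' @param events `data.frame` with columns `family_id`, `node_label` (origin
#'   or gain node, by clade/tip label) and optionally `gains_min`,
#'   `gains_max` (per-family intron-gain counts, carrying ranges such as
#'   "2-6" from literature fixtures; rows with NA counts contribute to the
#'   family tally but not to the gain sums). Without those columns each row
#'   counts as one resolved gain.
#' @param tree Species tree; fixes the node order of the output.
#' @return `data.frame`: `node`, `n_families_originating`,
#'   `n_intron_gains_min`, `n_intron_gains_max`, for every node label seen in
#'   `events`, ordered root-to-tips along the tree.
#' @export
tally_gains <- function(events, tree) {
  if (nrow(events) == 0L)
    return(data.frame(node = character(0), n_families_originating = integer(0),
                      n_intron_gains_min = numeric(0),
                      n_intron_gains_max = numeric(0)))
  gmin <- if ("gains_min" %in% names(events)) events$gains_min else
    rep(1, nrow(events))
  gmax <- if ("gains_max" %in% names(events)) events$gains_max else gmin
  labs <- unique(events$node_label)
  # order labels by tree depth (root first), unknown labels last
  depth <- vapply(labs, function(l) {
    id <- tryCatch(.node_id(tree, l), error = function(e) NA_integer_)
    if (is.na(id)) return(Inf)
    length(.ancestors(tree, id))
  }, numeric(1))
  labs <- labs[order(depth, labs)]
  out <- lapply(labs, function(l) {
    i <- events$node_label == l
    data.frame(node = l,
               n_families_originating = length(unique(events$family_id[i])),
               n_intron_gains_min = sum(gmin[i], na.rm = TRUE),
               n_intron_gains_max = sum(gmax[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.ancestors <- function(tree, node) {
  anc <- integer(0)
  root <- ape::Ntip(tree) + 1L
  while (node != root) {
    node <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (length(node) == 0L) break
    anc <- c(anc, node)
  }
  anc
}

#' Flag genes whose CDS intron count exceeds a family baseline
#'
#' For gene families with a reconstructible ancestral intron complement
#' (e.g. KRAB/SCAN zinc-finger genes carrying 1-3 ancestral coding introns),
#' a count above the baseline maximum most probably represents newly gained
#' introns.
#'
#' @param n_cds_introns Observed CDS intron count(s).
#' @param baseline_min,baseline_max Ancestral-count range (min <= max).
#' @return `data.frame`: `n_cds_introns`, `flag` (TRUE iff count >
#'   `baseline_max`), `excess` (count - max, floored at 0).
#' @export
flag_excess_introns <- function(n_cds_introns, baseline_min, baseline_max) {
  if (any(baseline_min > baseline_max))
    stop("baseline_min must be <= baseline_max")
  excess <- pmax(0L, n_cds_introns - baseline_max)
  data.frame(n_cds_introns = n_cds_introns, flag = excess > 0L,
             excess = excess)
}
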