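# Shared toy builders and independent brute-force oracles. The oracles scan
# nucleotide-by-nucleotide or enumerate exhaustively; they share no code with
# the implementation paths they check.

toy_tree5 <- function() {
  ape::read.tree(text = "((A:1,B:1)AB:1,(C:1,(D:1,E:1)DE:1)CDE:1)R;")
}

# random toy transcript on the plus or minus strand
random_transcript <- function(n_exons, strand = "+", with_cds = TRUE,
                              gene_id = "g") {
  starts <- cumsum(c(10, sample(20:80, 2 * n_exons - 1, replace = TRUE)))
  ex <- data.frame(start = starts[seq(1, by = 2, length.out = n_exons)],
                   end = starts[seq(2, by = 2, length.out = n_exons)])
  cds <- NULL
  if (with_cds) {
    # CDS spans a random sub-interval of the exon union, trimmed to exons
    lo <- sample(ex$start[1]:(ex$end[n_exons] - 2), 1)
    hi <- sample((lo + 1):ex$end[n_exons], 1)
    s <- pmax(ex$start, lo); e <- pmin(ex$end, hi)
    keep <- e > s
    if (any(keep)) cds <- data.frame(start = s[keep], end = e[keep])
  }
  suppressWarnings(
    transcript_model(gene_id, "sp", "chr", strand, ex, cds))
}

# Oracle 1: introns as runs of non-exonic positions between sorted exon
# boundaries, via a per-nucleotide occupancy scan.
oracle_intron_gaps <- function(t) {
  span <- min(t$exons$start):(max(t$exons$end) - 1)
  exonic <- rep(FALSE, length(span))
  for (i in seq_len(nrow(t$exons)))
    exonic[span >= t$exons$start[i] & span < t$exons$end[i]] <- TRUE
  r <- rle(exonic)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  gaps <- which(!r$values)
  data.frame(start = span[starts[gaps]], end = span[ends[gaps]] + 1)
}

# Oracle 2: per-nucleotide region map in transcription order; classify an
# intron sitting after p exonic nucleotides by counting coding nucleotides on
# each side.
oracle_region_map <- function(t) {
  pos <- integer(0)  # genomic positions of exonic nt, transcription order
  ex <- t$exons[order(t$exons$start), , drop = FALSE]
  if (t$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  for (i in seq_len(nrow(ex))) {
    p <- ex$start[i]:(ex$end[i] - 1)
    if (t$strand == "-") p <- rev(p)
    pos <- c(pos, p)
  }
  coding <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(t$cds)))
    coding[pos >= t$cds$start[i] & pos < t$cds$end[i]] <- TRUE
  coding
}

oracle_classify <- function(coding, p) {
  left <- sum(coding[seq_len(p)])
  right <- sum(coding[-seq_len(p)])
  if (left > 0 && right > 0) return("CDS")
  if (left == 0 && right > 0) return("UTR5")
  if (right == 0 && left > 0) return("UTR3")
  "UTR5"  # unreachable for transcripts with coding sequence
}

oracle_phase <- function(coding, p) sum(coding[seq_len(p)]) %% 3

# Oracle 3: exhaustive single-gain Dollo search. For each candidate gain node
# covering all present tips, try loss-branch subsets of increasing size until
# one reproduces the observed states (unknown tips unconstrained); among
# minimal-loss placements pick the most recent node (fewest tips).
oracle_dollo <- function(tree, states) {
  nt <- ape::Ntip(tree)
  all_nodes <- seq_len(nt + tree$Nnode)
  tips_under <- lapply(all_nodes, function(n)
    if (n <= nt) tree$tip.label[n] else ape::extract.clade(tree, n)$tip.label)
  pres <- names(states)[states == "present"]
  abs_ <- names(states)[states == "absent"]
  best <- NULL
  for (g in all_nodes) {
    if (!all(pres %in% tips_under[[g]])) next
    # edges fully inside the clade of g
    below <- which(vapply(seq_len(nrow(tree$edge)), function(i)
      all(tips_under[[tree$edge[i, 2]]] %in% tips_under[[g]]) &&
        tree$edge[i, 1] != tree$edge[i, 2] &&
        (tree$edge[i, 1] == g ||
           all(tips_under[[tree$edge[i, 1]]] %in% tips_under[[g]])),
      logical(1)))
    found <- NULL
    for (k in 0:length(below)) {
      combs <- if (k == 0) list(integer(0)) else
        utils::combn(below, k, simplify = FALSE)
      for (S in combs) {
        dead <- unique(unlist(lapply(S, function(i)
          tips_under[[tree$edge[i, 2]]])))
        realized <- setdiff(tips_under[[g]], dead)
        if (all(pres %in% realized) && !any(abs_ %in% realized)) {
          found <- k; break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      cand <- list(gain = g, losses = found,
                   size = length(tips_under[[g]]))
      if (is.null(best) || cand$losses < best$losses ||
          (cand$losses == best$losses && cand$size < best$size))
        best <- cand
    }
  }
  best
}
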