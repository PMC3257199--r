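test_that("eligibility retains whole-TE families and names the exclusion reason", {
  meta <- data.frame(
    family_id = c("w1", "f1", "d1", "x1", "r1"),
    progenitor_class = c(rep("DNA_transposon", 4), "retroelement"),
    origin_route = c("whole_TE", "fusion_3prime", "DBD_shuffle",
                     "whole_TE", "whole_TE"),
    exclusion_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  el <- filter_eligible(meta)
  expect_equal(el$eligible, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_match(el$reason[2], "fusion")
  expect_match(el$reason[3], "DBD_shuffle")
  expect_match(el$reason[4], "metadata flag")
  meta$origin_route[1] <- NA
  expect_error(filter_eligible(meta), "missing origin_route for family w1")
})

test_that("the packaged DNA-transposon survey yields 11 eligible of 36", {
  meta <- fixture_gene_metadata("DNA_transposon")
  expect_equal(nrow(meta), 36L)
  el <- filter_eligible(meta)
  expect_equal(sum(el$eligible), 11L)
  expect_setequal(el$family_id[el$eligible],
                  c("POGK", "ZBED1", "ZNF862", "Buster3", "PRKRIR", "THAP9",
                    "HARBI1", "NAIF1", "PGBD1", "PGBD2", "PGBD5"))
})

test_that("gene origin is the MRCA of present species; unknowns uninformative", {
  tree <- fixture_species_tree()
  st <- setNames(rep("absent", length(tree$tip.label)), tree$tip.label)
  # presence across all four placental superorders, absent in marsupials and
  # monotremes -> Eutheria
  st[c("human", "cow", "sloth", "elephant")] <- "present"
  expect_equal(place_gene_origin(tree, st)$label, "Eutheria")
  # human + zebrafish -> Gnathostomata (the HARBI1-type pattern)
  st2 <- setNames(rep("absent", length(tree$tip.label)), tree$tip.label)
  st2[c("human", "zebrafish")] <- "present"
  expect_equal(place_gene_origin(tree, st2)$label, "Gnathostomata")
  # censoring a superorder to unknown does not move the node
  st[c("cow", "dog")] <- "unknown"
  expect_equal(place_gene_origin(tree, st)$label, "Eutheria")
  # single present species reports the terminal leaf
  st3 <- setNames(rep("absent", length(tree$tip.label)), tree$tip.label)
  st3["mouse"] <- "present"
  expect_equal(place_gene_origin(tree, st3)$label, "mouse")
  expect_error(place_gene_origin(tree, st3[st3 == "absent"]), "present")
})

test_that("Dollo site placement: worked 5-leaf cases", {
  tree <- toy_tree5()
  st <- c(A = "present", B = "present", C = "absent", D = "present",
          E = "absent")
  g <- place_site_gain(tree, st)
  expect_equal(g$gain_label, "R")
  expect_setequal(g$loss_branches, c("C", "E"))
  # all descendants present: gain at the MRCA, zero losses
  st2 <- c(A = "present", B = "present", C = "absent", D = "absent",
           E = "absent")
  g2 <- place_site_gain(tree, st2)
  expect_equal(g2$gain_label, "AB")
  expect_equal(g2$n_losses, 0L)
  # terminal-only presence: gain on the terminal branch
  st3 <- c(A = "present", B = "absent", C = "absent", D = "absent",
           E = "absent")
  g3 <- place_site_gain(tree, st3)
  expect_equal(g3$gain_label, "A")
  expect_equal(g3$n_losses, 0L)
  # unknowns never force losses
  st4 <- c(A = "present", B = "unknown", C = "unknown", D = "present",
           E = "unknown")
  g4 <- place_site_gain(tree, st4)
  expect_equal(g4$gain_label, "R")
  expect_equal(g4$n_losses, 0L)
  # a present species outside the gene-origin clade is an orthology conflict
  cde <- ape::getMRCA(tree, c("C", "D", "E"))
  expect_error(place_site_gain(tree, st, origin_node = cde),
               "orthology conflict")
})

test_that("converting absent to present never moves the gain node tipward", {
  tree <- toy_tree5()
  set.seed(31)
  for (rep in 1:50) {
    st <- setNames(sample(c("present", "absent", "unknown"), 5,
                          replace = TRUE), tree$tip.label)
    if (!any(st == "present") || !any(st == "absent")) next
    g0 <- place_site_gain(tree, st)
    flip <- sample(names(st)[st == "absent"], 1)
    st[flip] <- "present"
    g1 <- place_site_gain(tree, st)
    tips0 <- if (g0$gain_node <= 5) tree$tip.label[g0$gain_node] else
      ape::extract.clade(tree, g0$gain_node)$tip.label
    tips1 <- if (g1$gain_node <= 5) tree$tip.label[g1$gain_node] else
      ape::extract.clade(tree, g1$gain_node)$tip.label
    expect_true(all(tips0 %in% tips1))
    # no present leaf ever sits under a loss branch
    for (lb in g1$loss_branches) {
      lt <- if (lb %in% tree$tip.label) lb else
        ape::extract.clade(tree, introgain:::.node_id(tree, lb))$tip.label
      expect_false(any(st[lt] == "present"))
    }
  }
})

test_that("per-node tallies carry family counts and min/max gain ranges", {
  tree <- fixture_species_tree()
  ev <- data.frame(family_id = c("a", "b", "c"),
                   node_label = c("Eutheria", "Eutheria", "Theria"),
                   gains_min = c(1, 2, 5), gains_max = c(1, 6, 5))
  tl <- tally_gains(ev, tree)
  expect_equal(tl$node, c("Theria", "Eutheria"))  # root-to-tips order
  eu <- tl[tl$node == "Eutheria", ]
  expect_equal(eu$n_families_originating, 2L)
  expect_equal(eu$n_intron_gains_min, 3)
  expect_equal(eu$n_intron_gains_max, 7)
  expect_equal(nrow(tally_gains(ev[0, ], tree)), 0L)
  # NA ranges count the family but not the gain sums
  ev2 <- rbind(ev, data.frame(family_id = "d", node_label = "Eutheria",
                              gains_min = NA, gains_max = NA))
  tl2 <- tally_gains(ev2, tree)
  expect_equal(tl2[tl2$node == "Eutheria", "n_families_originating"], 3L)
  expect_equal(tl2[tl2$node == "Eutheria", "n_intron_gains_max"], 7)
})

test_that("excess-intron screen flags counts above the family baseline", {
  r <- flag_excess_introns(c(2, 5, 0, 3), 1, 2)
  expect_equal(r$flag, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$excess, c(0, 3, 0, 1))
  expect_error(flag_excess_introns(1, 3, 2), "baseline_min")
  # KRAB-ZNF-type screen: ancestral 1-2 coding introns; deviations flagged
  counts <- c(1, 2, 2, 6, 4, 1)
  expect_equal(flag_excess_introns(counts, 1, 2)$flag,
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("species tree I/O validates labels and round-trips", {
  tree <- fixture_species_tree()
  expect_true(ape::is.rooted(tree))
  need <- c("Chordata", "Gnathostomata", "Tetrapoda", "Amniota", "Theria",
            "Eutheria", "Boreoeutheria", "Euarchontoglires",
            "Laurasiatheria", "Xenarthra", "Afrotheria")
  expect_true(all(need %in% tree$node.label))
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  back <- read_species_tree(f)
  expect_equal(back$tip.label, tree$tip.label)
  expect_equal(back$node.label, tree$node.label)
  f2 <- tempfile(fileext = ".nwk")
  ape::write.tree(back, f2)
  expect_identical(readLines(f), readLines(f2))
  bad <- tree; bad$node.label[2] <- bad$tip.label[1]
  expect_error(validate_species_tree(bad), "duplicate")
})
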