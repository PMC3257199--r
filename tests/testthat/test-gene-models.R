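test_that("interval and transcript validation reject malformed input", {
  expect_error(genomic_interval("chr1", 10, 10), "start < end")
  expect_error(genomic_interval("chr1", -1, 5), "start < end")
  expect_error(genomic_interval("chr1", 0, 5, "x"), "strand")
  expect_error(transcript_model("g", "sp", "chr", "+",
                                exons = data.frame(start = c(0, 50),
                                                   end = c(60, 100))),
               "overlap")
  expect_error(transcript_model("g", "sp", "chr", "+",
                                exons = data.frame(start = 0, end = 100),
                                cds = data.frame(start = 90, end = 150)),
               "CDS outside exons")
  expect_warning(transcript_model("g", "sp", "chr", "+",
                                  exons = data.frame(start = 0, end = 100),
                                  cds = data.frame(start = 10, end = 21)),
                 "not a multiple of 3")
})

test_that("single-exon and noncoding degenerate cases behave", {
  t1 <- transcript_model("g1", "sp", "chr", "+",
                         exons = data.frame(start = 0, end = 300))
  expect_equal(nrow(extract_introns(t1)), 0L)
  t2 <- transcript_model("g2", "sp", "chr", "+",
                         exons = data.frame(start = c(0, 400),
                                            end = c(100, 500)))
  i2 <- extract_introns(t2)
  expect_equal(i2$region_class, "noncoding")
  expect_warning(cls <- classify_intron(t2, 100, 400), "no CDS")
  expect_equal(cls, "noncoding")
})

test_that("extract_introns matches a brute-force occupancy scan", {
  set.seed(11)
  for (rep in 1:30) {
    strand <- sample(c("+", "-"), 1)
    t <- random_transcript(5, strand)
    got <- extract_introns(t, min_length = 1L)
    want <- oracle_intron_gaps(t)
    # genomic order for comparison
    got <- got[order(got$start), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(nrow(got), nrow(t$exons) - 1L)
    # length partition: introns + exons = genomic span
    expect_equal(sum(got$length) + sum(t$exons$end - t$exons$start),
                 max(t$exons$end) - min(t$exons$start))
  }
})

test_that("classification and phase match per-nucleotide oracles", {
  set.seed(12)
  n_checked <- 0L
  for (rep in 1:100) {
    t <- random_transcript(sample(3:6, 1), sample(c("+", "-"), 1))
    if (nrow(t$cds) == 0) next
    coding <- oracle_region_map(t)
    introns <- extract_introns(t, min_length = 1L)
    lay_tot <- cumsum(rep(1, length(coding)))
    for (k in seq_len(nrow(introns))) {
      # exonic nt 5' of intron k in transcription order
      p <- introns$region_offset[k] +
        switch(introns$region_class[k],
               UTR5 = 0, noncoding = 0,
               CDS = min(which(coding)) - 1L,
               UTR3 = max(which(coding)))
      expect_equal(introns$region_class[k], oracle_classify(coding, p))
      if (introns$region_class[k] == "CDS") {
        expect_equal(introns$phase[k], oracle_phase(coding, p))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 20L)
})

test_that("boundary introns go to the adjacent UTR; interior introns to CDS", {
  # intron exactly at the 5'UTR/CDS boundary: coding only on the 3' side
  t <- transcript_model("g", "sp", "chr", "+",
                        exons = data.frame(start = c(0, 200),
                                           end = c(100, 350)),
                        cds = data.frame(start = 200, end = 350))
  expect_equal(classify_intron(t, 100, 200), "UTR5")
  # one codon into the CDS on the 5' exon: coding on both sides
  t2 <- transcript_model("g", "sp", "chr", "+",
                         exons = data.frame(start = c(0, 200),
                                            end = c(100, 347)),
                         cds = data.frame(start = c(97, 200),
                                          end = c(100, 347)))
  expect_equal(classify_intron(t2, 100, 200), "CDS")
  expect_equal(cds_phase(t2, 100, 200), 0L)
  expect_error(cds_phase(t, 100, 200), "UTR5 intron")
})

test_that("phase counts coding nucleotides mod 3", {
  mk <- function(cds_start) transcript_model(
    "g", "sp", "chr", "+",
    exons = data.frame(start = c(0, 200), end = c(100, 500)),
    cds = data.frame(start = c(cds_start, 200), end = c(100, 400 + cds_start)))
  expect_equal(cds_phase(mk(97), 100, 200), 0L)   # one codon before intron
  expect_equal(cds_phase(mk(96), 100, 200), 1L)   # 4 coding nt, 4 mod 3
  expect_equal(cds_phase(mk(95), 100, 200), 2L)   # 5 coding nt
})

test_that("gene emulating human ZCCHC16 yields two huge 5'UTR introns", {
  # 3 exons, CDS confined to the last exon, 5'UTR exon gaps of 47.8 kb and
  # 323.3 kb
  t <- transcript_model("ZCCHC16_like", "human", "chrX", "+",
                        exons = data.frame(start = c(0, 48000, 371400),
                                           end = c(200, 48100, 372000)),
                        cds = data.frame(start = 371500, end = 371998))
  i <- extract_introns(t)
  expect_equal(i$region_class, c("UTR5", "UTR5"))
  expect_equal(i$length, c(47800, 323300))
  # mouse ortholog carries 6 introns, again all 5' UTR
  starts <- c(0, cumsum(rep(c(100, 2000), 6)))
  ex <- data.frame(start = starts[seq(1, 13, 2)],
                   end = starts[seq(1, 13, 2)] + 100)
  ex <- rbind(ex, data.frame(start = max(ex$end) + 5000,
                             end = max(ex$end) + 5600))
  tm <- transcript_model("ZCCHC16_like", "mouse", "chrX", "+", ex,
                         cds = data.frame(start = max(ex$start) + 50,
                                          end = max(ex$start) + 500))
  im <- extract_introns(tm)
  expect_equal(nrow(im), 7L)  # 6 small 5'UTR gaps + the pre-CDS gap
  expect_true(all(im$region_class == "UTR5"))
})

test_that("gene emulating NYNRIN carries introns on both sides of the start codon", {
  t <- transcript_model("NYNRIN_like", "human", "chr14", "+",
                        exons = data.frame(start = c(0, 200, 400, 600),
                                           end = c(100, 300, 500, 700)),
                        cds = data.frame(start = c(250, 400, 600),
                                         end = c(300, 500, 699)))
  i <- extract_introns(t)
  expect_equal(i$region_class, c("UTR5", "CDS", "CDS"))
})

test_that("pooled densities follow total introns over total kilobases", {
  mk <- function(id, n_introns, cds_nt) {
    # n_introns CDS introns inside a cds_nt coding sequence
    exon_nt <- cds_nt / (n_introns + 1)
    starts <- seq(0, by = exon_nt + 100, length.out = n_introns + 1)
    transcript_model(id, "sp", "chr", "+",
                     data.frame(start = starts, end = starts + exon_nt),
                     data.frame(start = starts, end = starts + exon_nt))
  }
  d1 <- suppressWarnings(gene_set_density(list(mk("a", 1, 999))))
  expect_equal(d1$pooled$density_cds, 1 / 0.999)
  # pooled, not averaged: (2+0) introns / (0.5+1.5) kb = 1.0
  d2 <- suppressWarnings(gene_set_density(list(mk("a", 2, 501),
                                               mk("b", 0, 1500))))
  expect_equal(d2$pooled$density_cds, 2 / (0.501 + 1.5))
  expect_equal(d2$pooled$n_introns_cds, 2)
  # empty set: all-zero with a warning
  # one warning per zero/zero region (CDS and 5'UTR)
  expect_warning(expect_warning(gene_set_density(list()),
                                "zero region length"),
                 "zero region length")
  d0 <- suppressWarnings(gene_set_density(list()))
  expect_equal(d0$pooled$density_cds, 0)
  expect_equal(d0$pooled$density_utr5, 0)
})

test_that("densities are invariant under reordering and split/merge pooling", {
  set.seed(13)
  genes <- replicate(8, random_transcript(4), simplify = FALSE)
  genes <- Filter(function(t) nrow(t$cds) > 0, genes)
  d <- suppressWarnings(gene_set_density(genes))
  d_rev <- suppressWarnings(gene_set_density(rev(genes)))
  expect_equal(d$pooled$density_cds, d_rev$pooled$density_cds)
  # split into halves, recompute pooled from raw totals
  h1 <- suppressWarnings(gene_set_density(genes[1:3]))$pooled
  h2 <- suppressWarnings(gene_set_density(genes[-(1:3)]))$pooled
  expect_equal((h1$n_introns_cds + h2$n_introns_cds) /
                 (h1$kb_cds + h2$kb_cds),
               d$pooled$density_cds)
})

test_that("GFF3 and BED12 readers reproduce hand-converted coordinates", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t101\t900\t.\t+\t.\tID=gA",
           "chr1\tsrc\tmRNA\t101\t900\t.\t+\t.\tID=gA.t1;Parent=gA",
           "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=gA.t1",
           "chr1\tsrc\texon\t301\t500\t.\t+\t.\tParent=gA.t1",
           "chr1\tsrc\texon\t601\t900\t.\t+\t.\tParent=gA.t1",
           "chr1\tsrc\tCDS\t351\t500\t.\t+\t.\tParent=gA.t1",
           "chr1\tsrc\tCDS\t601\t751\t.\t+\t.\tParent=gA.t1")
  f <- tempfile(fileext = ".gff3"); writeLines(gff, f)
  m <- suppressWarnings(read_gene_structures(f, "human"))
  expect_named(m, "gA")
  # 1-based closed GFF3 -> 0-based half-open
  expect_equal(m$gA$exons$start, c(100, 300, 600))
  expect_equal(m$gA$exons$end, c(200, 500, 900))
  expect_equal(m$gA$cds$start, c(350, 600))
  expect_equal(m$gA$cds$end, c(500, 751))
  expect_equal(m$gA$species_id, "human")
  # BED12 writer/reader agree with the GFF3 route
  fb <- tempfile(fileext = ".bed")
  write_gene_structures_bed12(m, fb)
  mb <- suppressWarnings(read_gene_structures(fb, "human"))
  expect_equal(mb$gA$exons, m$gA$exons)
  expect_equal(mb$gA$cds, m$gA$cds)
})

test_that("single-exon gene without CDS parses to a bare model", {
  gff <- c("##gff-version 3",
           "chr2\tsrc\tgene\t11\t110\t.\t-\t.\tID=gB",
           "chr2\tsrc\tmRNA\t11\t110\t.\t-\t.\tID=gB.t1;Parent=gB",
           "chr2\tsrc\texon\t11\t110\t.\t-\t.\tParent=gB.t1")
  f <- tempfile(fileext = ".gff3"); writeLines(gff, f)
  m <- read_gene_structures(f, "sp")
  expect_equal(nrow(m$gB$exons), 1L)
  expect_equal(nrow(m$gB$cds), 0L)
})

test_that("one transcript per gene: longest CDS, then exon sum, then id", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=g",
           "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=g.tB;Parent=g",
           "chr1\tsrc\texon\t1\t1000\t.\t+\t.\tParent=g.tB",
           "chr1\tsrc\tCDS\t1\t300\t.\t+\t.\tParent=g.tB",
           "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=g.tA;Parent=g",
           "chr1\tsrc\texon\t1\t1000\t.\t+\t.\tParent=g.tA",
           "chr1\tsrc\tCDS\t1\t150\t.\t+\t.\tParent=g.tA")
  f <- tempfile(fileext = ".gff3"); writeLines(gff, f)
  m <- read_gene_structures(f, "sp")
  expect_equal(sum(m$g$cds$end - m$g$cds$start), 300)
})
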