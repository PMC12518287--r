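# small in-code genome + annotation fixture
write_genome_gff <- function(dir) {
  genome_fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  set.seed(404)
  contig <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  writeLines(c(">chr1", contig), genome_fa)
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t1500\t.\t+\t.\tID=geneP",
    "chr1\ttest\tgene\t501\t1000\t.\t-\t.\tID=geneM",
    "chr1\ttest\tgene\t100\t400\t.\t+\t.\tID=geneT"), gff)
  list(genome = genome_fa, gff = gff, contig = contig)
}

test_that("upstream extraction follows strand-aware coordinate rules", {
  dir <- withr::local_tempdir()
  fx <- write_genome_gff(dir)
  prom <- extract_upstream(fx$gff, fx$genome, length = 500)

  # + strand gene at 1001: promoter = genomic 501..1000
  p_plus <- prom[prom$gene_id == "geneP", ]
  expect_equal(p_plus$sequence, substr(fx$contig, 501, 1000))
  expect_false(p_plus$truncated)

  # - strand gene ending at 1000: reverse complement of 1001..1500
  p_minus <- prom[prom$gene_id == "geneM", ]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(fx$contig, 1001, 1500))))
  expect_equal(p_minus$sequence, rc)

  # + strand gene at 100: truncated 99 nt promoter
  p_tr <- prom[prom$gene_id == "geneT", ]
  expect_equal(p_tr$length, 99L)
  expect_true(p_tr$truncated)
})

test_that("AT content excludes N from the denominator", {
  expect_equal(at_content("ATAT"), 1)
  expect_equal(at_content("GCGC"), 0)
  expect_equal(at_content("ATGC"), 0.5)
  expect_equal(at_content("ATGCNN"), 0.5)
  expect_error(at_content("NNN"), "all N")
  expect_error(at_content(""), "empty")
  # complement symmetry: AT content is complement-invariant, and
  # s + reverse complement keeps the same AT fraction
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(at_content(s), at_content(rc))
})

test_that("positional AT profiles track the background composition", {
  prom <- data.frame(gene_id = "g1",
                     sequence = paste(rep("A", 500), collapse = ""),
                     strand = "+", length = 500, truncated = FALSE)
  prof <- positional_at_profile(prom, window = 1)
  expect_equal(prof$at_fraction, rep(1, 500))
  expect_equal(range(prof$position), c(-500, -1))

  # alternating AT is A or T at every site
  prom2 <- prom; prom2$sequence <- paste(rep(c("A", "T"), 250),
                                         collapse = "")
  expect_equal(positional_at_profile(prom2, window = 1)$at_fraction,
               rep(1, 500))

  # binomial check on generated backgrounds
  gp <- generate_promoters(500, 500, at_fraction = 0.6, seed = 8)
  prof3 <- positional_at_profile(gp$promoters, window = 1)
  expect_equal(mean(prof3$at_fraction), 0.6, tolerance = 0.02)
})

test_that("IUPAC scanning reports both strands in promoter coordinates", {
  lib <- data.frame(family = "WRKY", motif_id = "wbox",
                    consensus = "TTGACC")
  prom <- data.frame(gene_id = "g1", sequence = "AAATTGACCAA",
                     strand = "+", length = 11, truncated = FALSE)
  h <- scan_motifs(prom, lib)
  expect_equal(nrow(h), 1L)
  # match begins at string position 4 of an 11 nt region: -(11) + 4 - 1
  expect_equal(h$start, 4 - 11 - 1)
  expect_equal(h$strand, "+")
  expect_equal(h$start + 6, h$end + 1)

  # reverse-complement consensus hits the minus strand at the same spot
  lib_rc <- data.frame(family = "WRKY", motif_id = "wbox_rc",
                       consensus = "GGTCAA")
  h_rc <- scan_motifs(prom, lib_rc)
  expect_equal(nrow(h_rc), 1L)
  expect_equal(h_rc$start, h$start)
  expect_equal(h_rc$strand, "-")

  # degenerate letters match their degeneracy class
  lib_deg <- data.frame(family = "WRKY", motif_id = "wboxY",
                        consensus = "TTGACY")
  expect_equal(nrow(scan_motifs(prom, lib_deg)), 1L)
  expect_error(scan_motifs(prom, data.frame(family = "x", motif_id = "x",
                                            consensus = "TTQACC")),
               "IUPAC")
})

test_that("scanning a reverse-complemented promoter mirrors hits", {
  set.seed(12)
  seqs <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  lib <- data.frame(family = "f", motif_id = "m", consensus = "GGNCCC")
  fwd <- data.frame(gene_id = "g", sequence = seqs, strand = "+",
                    length = 200, truncated = FALSE)
  rc <- fwd
  rc$sequence <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqs)))
  h1 <- scan_motifs(fwd, lib)
  h2 <- scan_motifs(rc, lib)
  expect_equal(nrow(h1), nrow(h2))
  if (nrow(h1)) {
    # positions mirror: leftmost base i maps to L - i - w + 1 in string
    # coordinates, strands swap
    w <- 6L
    pos1 <- sort(h1$start + 200 + 1)
    pos2 <- sort(200 - (h2$start + 200 + 1) - w + 2)
    expect_equal(pos1, pos2)
    expect_equal(sort(table(h1$strand)), sort(table(h2$strand)),
                 ignore_attr = TRUE)
  }
})

test_that("scanner output equals planted ground truth on clean
          backgrounds", {
  pm <- rbind(planted_motif("WRKY", "TTGACC", 2),
              planted_motif("ERF", "GCCGCC", 1))
  gp <- generate_promoters(20, 300, at_fraction = 0.5, planted = pm,
                           seed = 23)
  lib <- data.frame(family = c("WRKY", "ERF"),
                    motif_id = c("wbox", "gccbox"),
                    consensus = c("TTGACC", "GCCGCC"))
  hits <- scan_motifs(gp$promoters, lib)
  got <- hits[order(hits$gene_id, hits$family, hits$start),
              c("gene_id", "family", "start", "strand")]
  want <- gp$truth[order(gp$truth$gene_id, gp$truth$family,
                         gp$truth$start),
                   c("gene_id", "family", "start", "strand")]
  rownames(got) <- rownames(want) <- NULL
  # strand of a palindromic placement is ambiguous; compare positions
  # per family and gene, then strands where the motif is not its own
  # reverse complement at the realized site
  expect_equal(got[, c("gene_id", "family", "start")],
               want[, c("gene_id", "family", "start")])
})

test_that("PWM scanning honours the relative score threshold", {
  pwm <- matrix(c(0.97, 0.01, 0.01, 0.01,
                  0.01, 0.97, 0.01, 0.01,
                  0.01, 0.01, 0.97, 0.01,
                  0.01, 0.01, 0.01, 0.97), 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  lib <- data.frame(family = "toy", motif_id = "acgt",
                    consensus = NA_character_)
  lib$pwm <- list(pwm)
  prom <- data.frame(gene_id = "g1", sequence = "TTACGTTT", strand = "+",
                     length = 8, truncated = FALSE)
  h <- scan_motifs(prom, lib, pwm_threshold = 0.8)
  expect_gte(nrow(h), 1L)
  expect_true(any(h$start + 8 + 1 == 3 & h$strand == "+"))
})

test_that("family summaries agree with a direct recount", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    family = c("WRKY", "WRKY", "ERF"),
    motif_id = "m", start = -50L, end = -45L, strand = "+", score = 1)
  fs <- family_summary(hits, universe = c("g1", "g2"))
  wrky <- fs[fs$family == "WRKY", ]
  expect_equal(wrky$pct_genes_with_site, 50)
  expect_equal(wrky$mean_sites_per_gene, 1)  # 2 sites over 2 genes
  erf <- fs[fs$family == "ERF", ]
  expect_equal(erf$pct_genes_with_site, 50)
  expect_equal(erf$mean_sites_per_gene, 0.5)

  # a library family with no hits is still reported with zeros
  fs2 <- family_summary(hits, universe = c("g1", "g2"),
                        families = c("WRKY", "ERF", "TBP"))
  expect_equal(fs2$pct_genes_with_site[fs2$family == "TBP"], 0)

  # grouped summaries split the universe
  grouping <- c(g1 = "anoxia", g2 = "control")
  fs3 <- family_summary(hits, c("g1", "g2"), grouping = grouping)
  expect_equal(fs3$pct_genes_with_site[fs3$family == "WRKY" &
                                         fs3$group == "anoxia"], 100)
  expect_equal(fs3$pct_genes_with_site[fs3$family == "WRKY" &
                                         fs3$group == "control"], 0)

  # random planted counts: summaries equal direct recounts
  set.seed(55)
  genes <- paste0("g", 1:30)
  nh <- rpois(30, 1.2)
  rh <- data.frame(gene_id = rep(genes, nh), family = "F",
                   motif_id = "m", start = -10L, end = -5L,
                   strand = "+", score = 1)
  fs4 <- family_summary(rh, genes)
  expect_equal(fs4$pct_genes_with_site, 100 * mean(nh > 0))
  expect_equal(fs4$mean_sites_per_gene, mean(nh))

  expect_error(family_summary(hits, character()), "universe")
  expect_error(family_summary(hits, "g1"), "outside")
})

test_that("positional hit histograms bin upstream starts", {
  hits <- data.frame(gene_id = "g", family = "F", motif_id = "m",
                     start = c(-400L, -399L), end = c(-395L, -394L),
                     strand = "+", score = 1)
  hp <- positional_hit_profile(hits, bin_width = 50)
  expect_equal(sum(hp$count), 2L)
  expect_equal(hp$count[hp$bin_start == -400], 2L)
  empty <- positional_hit_profile(hits[0, ], bin_width = 50)
  expect_true(all(empty$count == 0L))
  expect_equal(nrow(empty), 10L)

  # planted tri-modal positions are recovered as the modal bins
  set.seed(66)
  starts <- c(round(rnorm(40, -375, 5)), round(rnorm(40, -225, 5)),
              round(rnorm(40, -75, 5)))
  starts <- pmin(pmax(starts, -500L), -7L)
  hits3 <- data.frame(gene_id = "g", family = "F", motif_id = "m",
                      start = as.integer(starts), end = 0L, strand = "+",
                      score = 1)
  hp3 <- positional_hit_profile(hits3, bin_width = 50)
  top3 <- hp3$bin_start[order(hp3$count, decreasing = TRUE)][1:3]
  expect_setequal(top3, c(-400L, -250L, -100L))
  expect_equal(sum(hp3$count), length(starts))
})

test_that("promoter splitting preserves sequence and coordinates", {
  seqs <- paste(rep(c("A", "C"), 250), collapse = "")
  prom <- data.frame(gene_id = "g", sequence = seqs, strand = "+",
                     length = 500, truncated = FALSE)
  halves <- split_promoter(prom)
  expect_equal(paste0(halves$distal$sequence, halves$proximal$sequence),
               seqs)
  expect_equal(attr(halves$distal, "coordinates"), c(-500L, -251L))
  expect_equal(attr(halves$proximal, "coordinates"), c(-250L, -1L))
  short <- prom; short$length <- 499L
  short$sequence <- substr(seqs, 1, 499)
  expect_error(split_promoter(short), "500")
})

test_that("total hits equal the histogram sum on generated data", {
  pm <- planted_motif("WRKY", "TTGACC", 1)
  gp <- generate_promoters(15, 500, at_fraction = 0.4, planted = pm,
                           seed = 31)
  lib <- data.frame(family = "WRKY", motif_id = "wbox",
                    consensus = "TTGACC")
  hits <- scan_motifs(gp$promoters, lib)
  hp <- positional_hit_profile(hits, bin_width = 50)
  expect_equal(sum(hp$count), nrow(hits))
})
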