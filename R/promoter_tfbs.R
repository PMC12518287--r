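# Upstream-region extraction, AT-content profiling, motif scanning and
# per-family binding-site summaries.
#
# Upstream coordinates are 1-based negative offsets relative to the
# annotated gene start: position -1 is adjacent to the start, -500 is
# the distal end of a full-length promoter. A hit's `start` is the
# coordinate of its leftmost base in the promoter frame, so
# start + motif length <= 0 always holds.

#' Extract upstream promoter regions
#'
#' For a + strand gene starting at genomic position s the promoter is
#' genomic \[s - length, s - 1\]; for a - strand gene ending at e it is
#' the reverse complement of genomic \[e + 1, e + length\]. Regions
#' truncated by a contig edge are returned shorter and flagged.
#'
#' @param genes GFF3 file path or a `GRanges` of gene records (1-based
#'   inclusive coordinates, strand annotated, gene ids in `ID`, `Name`
#'   or `gene_id`).
#' @param genome FASTA file path or a named `DNAStringSet` of contigs.
#' @param length Promoter length in nt (default 500).
#' @return A promoter data frame: `gene_id`, `sequence`, `strand`,
#'   `length`, `truncated`.
#' @export
extract_upstream <- function(genes, genome, length = 500L) {
  if (is.character(genes)) genes <- rtracklayer::import(genes)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!is.null(genes$type)) {
    gsel <- genes[as.character(genes$type) == "gene"]
    if (base::length(gsel)) genes <- gsel
  }
  ids <- genes$ID %||% genes$Name %||% genes$gene_id
  if (is.null(ids)) stop("gene records carry no ID/Name/gene_id attribute")
  chroms <- as.character(GenomicRanges::seqnames(genes))
  missing_chr <- setdiff(chroms, names(genome))
  if (base::length(missing_chr))
    stop("contig(s) absent from genome: ",
         paste(unique(missing_chr), collapse = ", "))
  out <- lapply(seq_along(genes), function(i) {
    chrom <- genome[[chroms[i]]]
    clen <- base::length(chrom)
    strand <- as.character(GenomicRanges::strand(genes))[i]
    if (strand == "+") {
      s <- GenomicRanges::start(genes)[i]
      from <- max(1L, s - length); to <- s - 1L
      if (to < from)
        return(data.frame(gene_id = ids[i], sequence = "", strand = strand,
                          length = 0L, truncated = TRUE))
      seq <- as.character(Biostrings::subseq(chrom, from, to))
    } else {
      e <- GenomicRanges::end(genes)[i]
      from <- e + 1L; to <- min(clen, e + length)
      if (to < from)
        return(data.frame(gene_id = ids[i], sequence = "", strand = strand,
                          length = 0L, truncated = TRUE))
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(chrom, from, to)))
    }
    data.frame(gene_id = ids[i], sequence = seq, strand = strand,
               length = nchar(seq), truncated = nchar(seq) < length)
  })
  do.call(rbind, out)
}

#' AT content of a sequence
#'
#' (A + T) / (length - N); ambiguous N bases are excluded from the
#' denominator.
#'
#' @param sequence DNA string(s) over A, C, G, T, N.
#' @return AT fraction(s) in \[0, 1\].
#' @export
at_content <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    if (!nzchar(s)) stop("empty sequence")
    chars <- strsplit(s, "")[[1L]]
    denom <- sum(chars != "N")
    if (denom == 0L) stop("sequence is all N")
    sum(chars %in% c("A", "T")) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Positional AT profile over upstream coordinates
#'
#' Per-coordinate fraction of A/T across promoters (full-length ones
#' only), optionally smoothed with a centered moving average.
#'
#' @param promoters Promoter data frame (see [extract_upstream()]).
#' @param window Moving-average width in nt (default 10; 1 = raw).
#' @return Data frame with `position` (-L..-1) and `at_fraction`.
#' @export
positional_at_profile <- function(promoters, window = 10L) {
  stopifnot(nrow(promoters) >= 1L)
  L <- max(promoters$length)
  full <- promoters$sequence[promoters$length == L]
  if (!length(full)) stop("no full-length promoters")
  mat <- do.call(rbind, strsplit(toupper(full), ""))
  prof <- colMeans(mat == "A" | mat == "T")
  if (window > 1L) {
    half <- window %/% 2L
    prof <- vapply(seq_along(prof), function(i) {
      idx <- max(1L, i - half):min(length(prof), i + half)
      mean(prof[idx])
    }, numeric(1))
  }
  data.frame(position = seq(-L, -1L), at_fraction = prof)
}

#' Build or read a motif library
#'
#' A motif library maps transcription-factor families to motifs, each
#' given as an IUPAC consensus or a position-weight matrix. The TSV
#' format has columns `family`, `motif_id`, `consensus`.
#'
#' @param path TSV file path.
#' @return Data frame with `family`, `motif_id`, `consensus` and an
#'   optional list column `pwm` (4 x width probability matrices with
#'   rows A, C, G, T).
#' @export
read_motif_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "motif_id", "consensus") %in% names(lib)))
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(lib$consensus))
  if (any(bad))
    stop("invalid IUPAC consensus: ", paste(lib$consensus[bad],
                                            collapse = ", "))
  lib$consensus <- toupper(lib$consensus)
  lib
}

#' @rdname read_motif_library
#' @details `default_motif_library()` returns a small curated set of
#'   published plant consensus elements (W-box for WRKY, GCC-box for
#'   ERF, TATA box for TBP, and core sites for MYB, TCP, SBP and bZIP),
#'   sufficient for the family-level summaries; users supply their own
#'   TSV for larger scans.
#' @export
default_motif_library <- function() {
  read_motif_library(system.file("extdata", "motif_library.tsv",
                                 package = "digeflow", mustWork = TRUE))
}

scan_one <- function(subject_chr, pattern_chr, L) {
  subj <- Biostrings::DNAString(subject_chr)
  fwd <- Biostrings::matchPattern(pattern_chr, subj, fixed = FALSE)
  rc <- revcomp_chr(pattern_chr)
  rev <- Biostrings::matchPattern(rc, subj, fixed = FALSE)
  w <- nchar(pattern_chr)
  pos <- c(Biostrings::start(fwd), Biostrings::start(rev))
  data.frame(
    pos = pos,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    width = rep(w, length(pos))
  )
}

#' Scan promoters for motif hits
#'
#' IUPAC consensi are matched exactly against their degeneracy classes
#' on both strands; PWM entries are matched where the log-odds score
#' reaches `pwm_threshold` of the maximal achievable score. Overlapping
#' hits are all reported. Minus-strand hits are reported at the
#' coordinate of their leftmost base in the promoter frame.
#'
#' @param promoters Promoter data frame (see [extract_upstream()]).
#' @param library Motif library (see [read_motif_library()]).
#' @param pwm_threshold Fraction of the maximal PWM score required for a
#'   hit (default 0.8).
#' @return Hit data frame: `gene_id`, `family`, `motif_id`, `start`,
#'   `end` (upstream coordinates), `strand`, `score`.
#' @export
scan_motifs <- function(promoters, library, pwm_threshold = 0.8) {
  has_pwm <- !is.null(library$pwm)
  hits <- list()
  for (g in seq_len(nrow(promoters))) {
    L <- promoters$length[g]
    if (L < 1L) next
    seq_chr <- promoters$sequence[g]
    for (m in seq_len(nrow(library))) {
      pwm <- if (has_pwm) library$pwm[[m]] else NULL
      if (is.null(pwm)) {
        cons <- toupper(library$consensus[m])
        if (grepl("[^ACGTRYSWKMBDHVN]", cons))
          stop("invalid IUPAC letter in consensus: ", cons)
        if (nchar(cons) > L) next
        h <- scan_one(seq_chr, cons, L)
        score <- rep(1, nrow(h))
      } else {
        subj <- Biostrings::DNAString(seq_chr)
        sc <- log2(pmax(pwm, 1e-3) / 0.25)
        thr <- pwm_threshold * sum(apply(sc, 2L, max))
        fwd <- Biostrings::matchPWM(sc, subj, min.score = thr,
                                    with.score = TRUE)
        rev <- Biostrings::matchPWM(Biostrings::reverseComplement(sc),
                                    subj, min.score = thr,
                                    with.score = TRUE)
        h <- data.frame(
          pos = c(Biostrings::start(fwd), Biostrings::start(rev)),
          strand = rep(c("+", "-"), c(length(fwd), length(rev))),
          width = ncol(sc))
        score <- c(S4Vectors::mcols(fwd)$score %||% numeric(),
                   S4Vectors::mcols(rev)$score %||% numeric())
      }
      if (!nrow(h)) next
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = promoters$gene_id[g],
        family = library$family[m], motif_id = library$motif_id[m],
        start = h$pos - L - 1L, end = h$pos + h$width - 1L - L - 1L,
        strand = h$strand, score = score)
    }
  }
  if (!length(hits))
    return(data.frame(gene_id = character(), family = character(),
                      motif_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$gene_id, out$family, out$start), , drop = FALSE]
}

#' Per-family binding-site summaries
#'
#' For each family (and optionally each condition group) over the gene
#' universe: the percentage of genes with at least one site and the
#' mean number of sites per gene (zeros included).
#'
#' @param hits Hit data frame from [scan_motifs()].
#' @param universe Character vector of all gene ids under study.
#' @param grouping Optional named character vector mapping gene_id to a
#'   condition label; summaries are then computed per group.
#' @param families Families to report (default: those in `hits`);
#'   families without hits are reported with zeros.
#' @return Data frame: `family`, optional `group`,
#'   `pct_genes_with_site`, `mean_sites_per_gene`, `n_genes`.
#' @export
family_summary <- function(hits, universe, grouping = NULL,
                           families = NULL) {
  if (!length(universe)) stop("empty universe")
  stray <- setdiff(unique(hits$gene_id), universe)
  if (length(stray))
    stop("hit gene(s) outside universe: ", paste(stray, collapse = ", "))
  families <- families %||% sort(unique(hits$family))
  groups <- if (is.null(grouping)) list(all = universe)
            else split(universe, grouping[universe])
  out <- list()
  for (gname in names(groups)) {
    genes <- groups[[gname]]
    for (fam in families) {
      counts <- vapply(genes, function(g)
        sum(hits$family == fam & hits$gene_id == g), integer(1))
      row <- data.frame(family = fam,
                        pct_genes_with_site = 100 * mean(counts > 0),
                        mean_sites_per_gene = mean(counts),
                        n_genes = length(genes))
      if (!is.null(grouping)) row <- cbind(group = gname, row)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Histogram of hit positions over the upstream region
#'
#' @param hits Hit data frame from [scan_motifs()].
#' @param bin_width Bin width in nt (default 50); bins cover
#'   \[-500, -451\] ... \[-50, -1\].
#' @param region_length Upstream region length (default 500).
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @export
positional_hit_profile <- function(hits, bin_width = 50L,
                                   region_length = 500L) {
  starts <- seq(-region_length, -1L, by = bin_width)
  ends <- starts + bin_width - 1L
  count <- vapply(seq_along(starts), function(i)
    sum(hits$start >= starts[i] & hits$start <= ends[i]), integer(1))
  data.frame(bin_start = starts, bin_end = ends, count = count)
}

#' Split a full-length promoter into distal and proximal halves
#'
#' @param promoter One-row promoter data frame of length 500.
#' @return A list of two one-row promoter data frames: `distal`
#'   (coordinates -500..-251) and `proximal` (-250..-1), with a
#'   `coordinates` attribute on each.
#' @export
split_promoter <- function(promoter) {
  if (nrow(promoter) != 1L) stop("one promoter at a time")
  if (promoter$length != 500L)
    stop("split requires a full 500 nt promoter, got ", promoter$length)
  halves <- list(
    distal = substr(promoter$sequence, 1L, 250L),
    proximal = substr(promoter$sequence, 251L, 500L)
  )
  coords <- list(distal = c(-500L, -251L), proximal = c(-250L, -1L))
  lapply(stats::setNames(names(halves), names(halves)), function(h) {
    df <- data.frame(gene_id = promoter$gene_id, sequence = halves[[h]],
                     strand = promoter$strand, length = 250L,
                     truncated = FALSE)
    attr(df, "coordinates") <- coords[[h]]
    df
  })
}
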