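# Seeded generators emulating the study design: spot-intensity tables
# with planted trajectory groups, promoter sequences with planted
# family-labeled motifs, and MS1 peak lists with contaminant masses.
#
# All generators are pure functions of (parameters, seed); the seed is
# mandatory because downstream recovery tests rely on reproducibility.

# Condition multipliers of the log2 effect for the four trajectory
# groups (control, anoxia, reaeration). Groups 1 and 3 carry the
# anoxia-initiated change into re-aeration, so anoxic and re-aerated
# samples resemble each other, as observed on the real gels.
TRAJECTORY_PATTERNS <- rbind(
  `1` = c(1, -0.5, -1),   # continuing decline
  `2` = c(0, 1, -1),      # anoxia-specific peak
  `3` = c(-1, 0.5, 1),    # continuing accumulation
  `4` = c(0, -1, 1)       # re-aeration recovery
)
colnames(TRAJECTORY_PATTERNS) <- CONDITIONS

#' Default per-group trajectory specifications
#'
#' @param base_log2 Baseline log2 intensity (default 10, i.e. raw
#'   fluorescence around 1000 arbitrary units).
#' @param effect_log2 Condition shift magnitude in log2 units (default
#'   2, a four-fold change between the extreme conditions).
#' @param noise_sd Replicate noise standard deviation on the log2 scale
#'   (default 0.3).
#' @return Data frame with one row per trajectory group: `group`,
#'   `base_log2`, `effect_log2`, `noise_sd`.
#' @export
trajectory_specs <- function(base_log2 = 10, effect_log2 = 2,
                             noise_sd = 0.3) {
  stopifnot(effect_log2 > 0, noise_sd >= 0)
  data.frame(group = 1:4, base_log2 = base_log2,
             effect_log2 = effect_log2, noise_sd = noise_sd)
}

#' Build the standard experimental design
#'
#' Three conditions x `n_rep` biological replicates for one organ, the
#' layout of one organ's gel series.
#'
#' @param organ `"shoot"` or `"root"`.
#' @param n_rep Replicates per condition (default 3).
#' @return A [sample_sheet()].
#' @export
make_design <- function(organ = "shoot", n_rep = 3L) {
  cond <- rep(CONDITIONS, each = n_rep)
  rep_id <- rep(seq_len(n_rep), times = length(CONDITIONS))
  sample_sheet(
    sample_id = sprintf("%s_%s_r%d", organ, cond, rep_id),
    organ = organ, condition = cond, replicate = rep_id
  )
}

#' Generate a spot table with planted trajectory groups
#'
#' Raw intensities are 2^(base + pattern x effect + Normal(0, sd)) per
#' replicate, where the pattern is the group-specific condition
#' multiplier vector; the log-normal model mirrors the log2 transform
#' applied to fluorescence intensities downstream.
#'
#' @param n_spots_per_group Integer (recycled over the 4 groups) or
#'   length-4 vector of spots per trajectory group.
#' @param design A [sample_sheet()] covering the three conditions.
#' @param specs Per-group specification from [trajectory_specs()].
#' @param seed Integer random seed (required).
#' @return A list with `table` (raw-scale [spot_table()]) and `groups`
#'   (named integer vector of true group labels per spot).
#' @export
generate_spot_table <- function(n_spots_per_group, design,
                                specs = trajectory_specs(), seed) {
  if (missing(seed)) stop("seed is required for reproducibility")
  design <- validate_sample_sheet(design)
  if (!all(CONDITIONS %in% design$condition))
    stop("design must cover all three conditions")
  n_per <- rep_len(as.integer(n_spots_per_group), 4L)
  stopifnot(all(n_per >= 0L), sum(n_per) >= 1L)
  set.seed(seed)
  groups <- rep(1:4, n_per)
  n_spots <- length(groups)
  cond_idx <- match(design$condition, CONDITIONS)
  m <- matrix(NA_real_, n_spots, nrow(design))
  for (i in seq_len(n_spots)) {
    sp <- specs[specs$group == groups[i], ]
    mu <- sp$base_log2 +
      sp$effect_log2 * TRAJECTORY_PATTERNS[groups[i], cond_idx]
    m[i, ] <- 2^(mu + stats::rnorm(nrow(design), 0, sp$noise_sd))
  }
  rownames(m) <- sprintf("SSP%03d", seq_len(n_spots))
  colnames(m) <- design$sample_id
  names(groups) <- rownames(m)
  list(table = spot_table(m, design), groups = groups)
}

#' Specification of a motif to plant in synthetic promoters
#'
#' @param family Transcription-factor family label (e.g. `"WRKY"`).
#' @param consensus IUPAC consensus string over
#'   A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @param copies_per_gene Non-negative number of copies per gene.
#' @param condition_group Optional condition label attached to genes
#'   carrying this motif.
#' @return A one-row data frame.
#' @export
planted_motif <- function(family, consensus, copies_per_gene = 1L,
                          condition_group = NA_character_) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGTRYSWKMBDHVN]", consensus))
    stop("invalid IUPAC letter in consensus: ", consensus)
  data.frame(family = family, consensus = consensus,
             copies_per_gene = as.integer(copies_per_gene),
             condition_group = condition_group)
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# Draw one concrete realization of an IUPAC consensus.
realize_consensus <- function(consensus) {
  letters_ <- strsplit(consensus, "")[[1L]]
  paste(vapply(letters_, function(l) {
    opts <- strsplit(IUPAC_MAP[[l]], "")[[1L]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Generate promoter sequences with planted motifs
#'
#' Backgrounds are i.i.d. with P(A) = P(T) = at_fraction / 2 and
#' P(C) = P(G) = (1 - at_fraction) / 2. Each planted motif copy is
#' realized from its IUPAC consensus, inserted on a random strand at a
#' random non-overlapping position (rejection sampling with a retry
#' cap), and recorded in the ground-truth table. When
#' `clean_background = TRUE` (default) background segments that happen
#' to match a planted consensus on either strand are resampled so that
#' the ground truth is exactly the set of matches.
#'
#' @param n_genes Number of promoters.
#' @param length Promoter length in nt (default 500).
#' @param at_fraction Background AT fraction in (0, 1).
#' @param planted Data frame of [planted_motif()] rows (may be empty or
#'   `NULL`).
#' @param seed Integer random seed (required).
#' @param max_retry Retry cap for rejection sampling (default 200).
#' @param clean_background Purge chance background matches (default
#'   `TRUE`).
#' @return A list with `promoters` (data frame gene_id, sequence,
#'   strand, length, truncated) and `truth` (data frame gene_id, family,
#'   consensus, start in upstream coordinates, strand).
#' @export
generate_promoters <- function(n_genes, length = 500L, at_fraction,
                               planted = NULL, seed, max_retry = 200L,
                               clean_background = TRUE) {
  if (missing(seed)) stop("seed is required for reproducibility")
  stopifnot(at_fraction > 0, at_fraction < 1, n_genes >= 1L)
  if (!is.null(planted) && nrow(planted)) {
    per_gene <- sum(nchar(planted$consensus) * planted$copies_per_gene)
    if (per_gene > length)
      stop("total planted motif length (", per_gene,
           ") exceeds promoter length (", length, ")")
  }
  set.seed(seed)
  probs <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
             G = (1 - at_fraction) / 2, T = at_fraction / 2)
  draw_bg <- function(n) sample(names(probs), n, replace = TRUE,
                                prob = probs)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  seqs <- character(n_genes)
  truth <- list()
  for (g in seq_len(n_genes)) {
    chars <- draw_bg(length)
    occupied <- logical(length)
    if (!is.null(planted) && nrow(planted)) {
      for (pi in seq_len(nrow(planted))) {
        w <- nchar(planted$consensus[pi])
        for (copy in seq_len(planted$copies_per_gene[pi])) {
          placed <- FALSE
          for (try in seq_len(max_retry)) {
            pos <- sample.int(length - w + 1L, 1L)
            if (!any(occupied[pos:(pos + w - 1L)])) {
              realized <- realize_consensus(planted$consensus[pi])
              strand <- sample(c("+", "-"), 1L)
              ins <- if (strand == "+") realized else revcomp_chr(realized)
              chars[pos:(pos + w - 1L)] <- strsplit(ins, "")[[1L]]
              occupied[pos:(pos + w - 1L)] <- TRUE
              truth[[length(truth) + 1L]] <- data.frame(
                gene_id = gene_ids[g], family = planted$family[pi],
                consensus = planted$consensus[pi],
                start = pos - length - 1L, strand = strand)
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("could not place motif ", planted$consensus[pi],
                 " without overlap after ", max_retry, " tries")
        }
      }
    }
    seqs[g] <- paste(chars, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(gene_id = character(), family = character(),
                           consensus = character(), start = integer(),
                           strand = character())
  promoters <- data.frame(gene_id = gene_ids, sequence = seqs,
                          strand = "+", length = length,
                          truncated = FALSE)
  if (clean_background && nrow(truth))
    promoters$sequence <- purge_chance_matches(
      promoters$sequence, unique(planted$consensus), truth, length,
      probs, max_retry)
  list(promoters = promoters, truth = truth)
}

# Resample background letters wherever a planted consensus matches the
# sequence (either strand) at a position not recorded in the truth
# table, so scanners see exactly the planted sites.
purge_chance_matches <- function(seqs, consensi, truth, len, probs,
                                 max_retry) {
  pats <- c(consensi, vapply(consensi, revcomp_chr, character(1)))
  for (g in seq_along(seqs)) {
    planted_here <- truth[truth$gene_id == sprintf("gene%04d", g), ]
    planted_pos <- planted_here$start + len + 1L
    for (try in seq_len(max_retry)) {
      dirty <- FALSE
      subj <- Biostrings::DNAString(seqs[g])
      for (pat in pats) {
        hits <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
        spurious <- setdiff(Biostrings::start(hits), planted_pos)
        for (s in spurious) {
          w <- nchar(pat)
          span <- s:(s + w - 1L)
          # only touch background letters outside planted sites
          prot <- unlist(lapply(seq_len(nrow(planted_here)), function(i)
            planted_pos[i]:(planted_pos[i] +
                              nchar(planted_here$consensus[i]) - 1L)))
          editable <- setdiff(span, prot)
          if (!length(editable)) next
          chars <- strsplit(seqs[g], "")[[1L]]
          chars[editable] <- sample(names(probs), length(editable),
                                    replace = TRUE, prob = probs)
          seqs[g] <- paste(chars, collapse = "")
          dirty <- TRUE
        }
      }
      if (!dirty) break
    }
  }
  seqs
}

#' Generate a synthetic MS1 peak list
#'
#' Union of the tryptic peptide monoisotopic masses of a target protein
#' and an optional contaminant (e.g. the protease itself), plus
#' uniformly distributed noise peaks over the instrument scan window
#' 700-3500 Da.
#'
#' @param sequence Target protein sequence.
#' @param contaminant Optional contaminant protein sequence.
#' @param noise_peaks Number of uniform noise peaks (default 0).
#' @param seed Integer random seed (required).
#' @param missed_cleavages Passed to [tryptic_digest()] (default 2).
#' @return A list with `peaks` (sorted m/z values), `target_masses`,
#'   `contaminant_masses`.
#' @export
generate_peaklist <- function(sequence, contaminant = NULL,
                              noise_peaks = 0L, seed,
                              missed_cleavages = 2L) {
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(seed)
  window <- c(700, 3500)
  in_window <- function(x) x[x >= window[1L] & x <= window[2L]]
  target <- in_window(peptide_masses(
    tryptic_digest(sequence, missed_cleavages)))
  contam <- if (!is.null(contaminant) && nzchar(contaminant))
    in_window(peptide_masses(tryptic_digest(contaminant, missed_cleavages)))
  else numeric()
  noise <- if (noise_peaks > 0L) stats::runif(noise_peaks, window[1L],
                                              window[2L]) else numeric()
  list(peaks = sort(unique(c(target, contam, noise))),
       target_masses = sort(unique(target)),
       contaminant_masses = sort(unique(contam)))
}
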