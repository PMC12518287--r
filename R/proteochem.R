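# Sequence-derived physicochemistry: molecular weight, isoelectric
# point, residue composition and positional density, Rf-calibrated mass
# estimation, in-silico trypsin digestion and autolysis-peak filtering.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue (monomer) masses in Da; peptide mass = sum(residues) + water.
AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
             V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
             I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
             K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
             F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
AA_AVG  <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
             V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
             I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
             K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
             F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528
PROTON <- 1.007276
CARBAMIDOMETHYL <- 57.02146  # fixed Cys modification
MET_OXIDATION <- 15.99491    # variable Met modification

#' Amino-acid mass table
#'
#' Residue masses used throughout the package, with the water mass added
#' per peptide and the fixed cysteine carbamidomethylation shift applied
#' to peptide-level monoisotopic masses.
#'
#' @return A list with elements `mono`, `average` (named numeric vectors
#'   over the 20 residues), `water` (named mono/average), and
#'   `fixed_mods` (`C` carbamidomethylation shift in Da).
#' @export
aa_mass_table <- function() {
  list(mono = AA_MONO[AA_LETTERS], average = AA_AVG[AA_LETTERS],
       water = c(mono = WATER_MONO, average = WATER_AVG),
       fixed_mods = c(C = CARBAMIDOMETHYL))
}

# pKa sets for the Henderson-Hasselbalch net-charge model.
PKA_SETS <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  bjellqvist = c(Nterm = 7.5, Cterm = 3.55, C = 9.0, D = 4.05, E = 4.45,
                 H = 5.98, K = 10.0, R = 12.0, Y = 10.0)
)

#' Side-chain and terminal pKa values
#'
#' @param set `"emboss"` (default) or `"bjellqvist"`.
#' @return Named numeric vector of pKa values for the N- and C-termini
#'   and the ionizable side chains (C, D, E, H, K, R, Y).
#' @export
pka_table <- function(set = c("emboss", "bjellqvist")) {
  PKA_SETS[[match.arg(set)]]
}

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", chars[bad[1L]],
                 bad[1L]))
  chars
}

#' Protein or peptide molecular weight
#'
#' Sum of residue masses plus one water. The fixed cysteine
#' carbamidomethylation used for peptide-fingerprint masses is applied
#' only when requested (monoisotopic peptide use).
#'
#' @param sequence Amino-acid string.
#' @param kind `"average"` (protein-level, default) or `"monoisotopic"`.
#' @param carbamidomethyl Apply the +57.02146 Da fixed Cys modification.
#' @return Mass in Da.
#' @examples
#' compute_mw("GG")                          # 132.12 Da
#' compute_mw("G", kind = "monoisotopic")    # 75.03 Da
#' @export
compute_mw <- function(sequence, kind = c("average", "monoisotopic"),
                       carbamidomethyl = FALSE) {
  kind <- match.arg(kind)
  chars <- check_sequence(sequence)
  masses <- if (kind == "monoisotopic") AA_MONO else AA_AVG
  water <- if (kind == "monoisotopic") WATER_MONO else WATER_AVG
  m <- sum(masses[chars]) + water
  if (carbamidomethyl) m <- m + CARBAMIDOMETHYL * sum(chars == "C")
  unname(m)
}

# Net charge at a given pH: positive groups (N-terminus, H, K, R) carry
# 1/(1+10^(pH-pKa)); negative groups (C-terminus, C, D, E, Y) carry
# -1/(1+10^(pKa-pH)).
net_charge <- function(counts, pH, pka) {
  pos <- c(Nterm = 1, counts[c("H", "K", "R")])
  names(pos) <- c("Nterm", "H", "K", "R")
  neg <- c(Cterm = 1, counts[c("C", "D", "E", "Y")])
  names(neg) <- c("Cterm", "C", "D", "E", "Y")
  sum(pos / (1 + 10^(pH - pka[names(pos)]))) -
    sum(neg / (1 + 10^(pka[names(neg)] - pH)))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge of the
#' sequence is zero, by bisection on \[0, 14\].
#'
#' @param sequence Amino-acid string.
#' @param pka_set `"emboss"` (default) or `"bjellqvist"`.
#' @param tol Bisection tolerance in pH units (default 1e-3).
#' @return pI in pH units.
#' @examples
#' compute_pI("GG")   # (8.6 + 3.6) / 2 = 6.1 with the EMBOSS set
#' @export
compute_pI <- function(sequence, pka_set = c("emboss", "bjellqvist"),
                       tol = 1e-3) {
  pka <- pka_table(match.arg(pka_set))
  chars <- check_sequence(sequence)
  counts <- vapply(c("H", "K", "R", "C", "D", "E", "Y"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  # Z is strictly decreasing in pH; termini guarantee a sign change.
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Residue composition with a between-organ comparison
#'
#' Per-protein residue fractions (summing to 1) and, when both organs
#' are represented by at least two proteins, a per-residue Welch t-test
#' between the organ groups with Benjamini-Hochberg adjustment.
#'
#' @param records A [protein_records()] table.
#' @return A list with `fractions` (proteins x 20 residues matrix) and
#'   `comparison` (per-residue t statistic, raw and BH-adjusted p), the
#'   latter `NULL` when only one organ is present.
#' @export
aa_composition <- function(records) {
  fr <- t(vapply(records$sequence, function(s) {
    chars <- check_sequence(s)
    vapply(AA_LETTERS, function(a) mean(chars == a), numeric(1))
  }, numeric(length(AA_LETTERS))))
  rownames(fr) <- records$accession
  organs <- records$organ
  comparison <- NULL
  tab <- table(organs[!is.na(organs)])
  if (length(tab) == 2L && all(tab >= 2L)) {
    grp <- split(seq_len(nrow(fr)), organs)
    comparison <- do.call(rbind, lapply(AA_LETTERS, function(a) {
      x <- fr[grp[[1L]], a]; y <- fr[grp[[2L]], a]
      if (stats::var(x) + stats::var(y) == 0) {
        # degenerate: constant within groups; significance is decided
        # by whether the group means coincide
        eq <- isTRUE(all.equal(mean(x), mean(y)))
        return(data.frame(residue = a,
                          statistic = if (eq) 0 else sign(mean(x) -
                                                            mean(y)) * Inf,
                          p_raw = if (eq) 1 else 0))
      }
      tt <- stats::t.test(x, y)
      data.frame(residue = a, statistic = unname(tt$statistic),
                 p_raw = tt$p.value)
    }))
    comparison$p_adj <- stats::p.adjust(comparison$p_raw, method = "BH")
  }
  list(fractions = fr, comparison = comparison)
}

#' Positional density of a residue along a sequence
#'
#' Each residue position i is mapped to the relative coordinate
#' (i - 0.5) / length; within each of `n_bins` equal bins over \[0, 1\]
#' the fraction of residues equal to `residue` is reported.
#'
#' @param sequence Amino-acid string.
#' @param residue Single residue letter (e.g. `"K"` for lysine).
#' @param n_bins Number of bins (default 20).
#' @return Numeric vector of per-bin target-residue fractions; bins with
#'   no residues are 0.
#' @export
positional_density <- function(sequence, residue, n_bins = 20L) {
  stopifnot(n_bins >= 1L)
  chars <- check_sequence(sequence)
  rel <- (seq_along(chars) - 0.5) / length(chars)
  bin <- pmin(floor(rel * n_bins) + 1L, n_bins)
  dens <- numeric(n_bins)
  for (b in unique(bin)) dens[b] <- mean(chars[bin == b] == residue)
  dens
}

#' Estimate molecular weight from gel migration
#'
#' Linear interpolation in (Rf, log10 MW) space against a protein-ladder
#' calibration. Rf values outside the anchor range are linearly
#' extrapolated and flagged with a warning.
#'
#' @param rf Relative migration distance(s) in \[0, 1\].
#' @param ladder Data frame with columns `rf` (strictly increasing) and
#'   `mw_kda` (strictly decreasing), at least two anchors.
#' @return Estimated MW in kDa, with attribute `extrapolated` (logical).
#' @export
mw_from_rf <- function(rf, ladder) {
  if (nrow(ladder) < 2L) stop("ladder needs at least two anchor points")
  if (any(diff(ladder$rf) <= 0) || any(diff(ladder$mw_kda) >= 0))
    stop("ladder anchors must have strictly increasing Rf and decreasing MW")
  extrap <- rf < min(ladder$rf) | rf > max(ladder$rf)
  if (any(extrap))
    warning("Rf value(s) outside calibration range; extrapolating")
  # approx() with rule = 2 would clamp; extrapolate linearly by hand.
  logmw <- log10(ladder$mw_kda)
  slope_lo <- (logmw[2L] - logmw[1L]) / (ladder$rf[2L] - ladder$rf[1L])
  n <- nrow(ladder)
  slope_hi <- (logmw[n] - logmw[n - 1L]) / (ladder$rf[n] - ladder$rf[n - 1L])
  out <- stats::approx(ladder$rf, logmw, xout = rf, rule = 2)$y
  lo <- rf < ladder$rf[1L]; hi <- rf > ladder$rf[n]
  out[lo] <- logmw[1L] + slope_lo * (rf[lo] - ladder$rf[1L])
  out[hi] <- logmw[n] + slope_hi * (rf[hi] - ladder$rf[n])
  structure(10^out, extrapolated = extrap)
}

#' Pearson congruence of predicted and observed values
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 3).
#' @return A list with `r` and two-sided t-based `p`.
#' @export
congruence <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3L)
    stop("need equal-length vectors of at least 3 values")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("zero variance in input")
  ct <- stats::cor.test(predicted, observed, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' In-silico trypsin digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and
#' enumerates all peptides spanning up to `missed_cleavages` internal
#' cleavage sites, ordered by start position.
#'
#' @param sequence Amino-acid string.
#' @param missed_cleavages Maximum internal missed cleavage sites
#'   (default 2).
#' @return Character vector of peptides.
#' @examples
#' tryptic_digest("AKGR", missed_cleavages = 0)  # "AK", "GR"
#' tryptic_digest("AKPGR", missed_cleavages = 0) # "AKPGR" (KP suppressed)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 2L) {
  stopifnot(missed_cleavages >= 0L)
  chars <- check_sequence(sequence)
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)  # fragment i = (bounds[i]+1) .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  peptides <- character(0)
  starts <- integer(0)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + missed_cleavages)) {
      peptides <- c(peptides,
                    paste(chars[(bounds[i] + 1L):bounds[j + 1L]],
                          collapse = ""))
      starts <- c(starts, bounds[i] + 1L)
    }
  }
  peptides[order(starts, nchar(peptides))]
}

#' Monoisotopic peptide masses for MS1 fingerprints
#'
#' @param peptides Character vector of peptides.
#' @param protonated Report singly protonated \[M+H\]+ masses
#'   (+1.007276 Da); default `FALSE`.
#' @param carbamidomethyl Apply the fixed Cys modification (default
#'   `TRUE`, matching MALDI sample preparation with iodoacetamide).
#' @param met_oxidation Additionally emit, for each Met-containing
#'   peptide, variants with 1..n oxidized methionines (+15.99491 Da
#'   each); default `FALSE`.
#' @return Numeric vector of masses in Da (unsorted variants appended
#'   after the base masses when `met_oxidation = TRUE`).
#' @export
peptide_masses <- function(peptides, protonated = FALSE,
                           carbamidomethyl = TRUE, met_oxidation = FALSE) {
  base <- vapply(peptides, compute_mw, numeric(1), kind = "monoisotopic",
                 carbamidomethyl = carbamidomethyl)
  out <- base
  if (met_oxidation) {
    nmet <- vapply(strsplit(peptides, ""), function(x) sum(x == "M"),
                   integer(1))
    for (i in which(nmet > 0L))
      out <- c(out, base[i] + MET_OXIDATION * seq_len(nmet[i]))
  }
  if (protonated) out <- out + PROTON
  unname(out)
}

#' Remove protease autolysis peaks from a peak list
#'
#' Drops every m/z value lying within `tolerance_da` of any contaminant
#' (e.g. trypsin self-digestion) mass.
#'
#' @param peaks Numeric m/z values.
#' @param contaminant_masses Numeric contaminant m/z values.
#' @param tolerance_da Matching half-window in Da (default 0.8, the MS1
#'   peptide tolerance).
#' @return A list with `peaks` (survivors) and `removed` (data frame of
#'   removed peak, matched contaminant mass and their distance).
#' @export
filter_autolysis <- function(peaks, contaminant_masses,
                             tolerance_da = 0.8) {
  stopifnot(tolerance_da > 0)
  if (!length(contaminant_masses))
    return(list(peaks = peaks,
                removed = data.frame(peak = numeric(),
                                     contaminant = numeric(),
                                     delta = numeric())))
  nearest <- vapply(peaks, function(p)
    contaminant_masses[which.min(abs(contaminant_masses - p))], numeric(1))
  hit <- abs(peaks - nearest) <= tolerance_da
  list(peaks = peaks[!hit],
       removed = data.frame(peak = peaks[hit], contaminant = nearest[hit],
                            delta = peaks[hit] - nearest[hit]))
}
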