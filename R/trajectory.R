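# Classification of per-spot condition trajectories (control -> anoxia
# -> re-aeration) into four abundance groups, and the
# condition-of-maximum label used for promoter grouping.
#
# Group 1: abundance decreases through anoxia and re-aeration.
# Group 2: peak during anoxia, drop after re-aeration (anoxia-specific).
# Group 3: rise starting in anoxia, peak in re-aeration ("continuing").
# Group 4: drop in anoxia, recovery/accumulation after re-aeration
#          (re-aeration-specific).

#' Per-condition mean intensities
#'
#' Arithmetic mean over replicates within each condition, missing
#' values dropped pairwise. A spot with zero observations in any
#' condition raises an error naming the spot.
#'
#' @param table A normalized [spot_table()].
#' @return Data frame with `id`, `mean_control`, `mean_anoxia`,
#'   `mean_reaeration`.
#' @export
condition_means <- function(table) {
  stopifnot(inherits(table, "spot_table"))
  cond <- factor(table$sheet$condition, levels = CONDITIONS)
  out <- lapply(seq_len(nrow(table$matrix)), function(i) {
    y <- table$matrix[i, ]
    mns <- vapply(CONDITIONS, function(cc) {
      v <- y[cond == cc & is.finite(y)]
      if (!length(v))
        stop("spot ", table$spot_ids[i], " has no observation in condition ",
             cc)
      mean(v)
    }, numeric(1))
    data.frame(id = table$spot_ids[i], mean_control = mns[["control"]],
               mean_anoxia = mns[["anoxia"]],
               mean_reaeration = mns[["reaeration"]])
  })
  do.call(rbind, out)
}

# Tolerant strict comparison on the (positive) intensity scale:
# x exceeds y only when it does so by more than a relative delta.
gt_rel <- function(x, y, delta) x > y * (1 + delta)

#' Classify a condition trajectory into one of four groups
#'
#' Decision rule (total over finite triples, scale-free): anoxia a
#' strict maximum of the three condition means gives group 2; a strict
#' minimum gives group 4; otherwise a non-increasing profile
#' C >= A >= R gives group 1, and everything else group 3. Strictness
#' uses the relative tolerance `delta` (x exceeds y only when
#' x > y (1 + delta)), so changes smaller than `delta` count as flat.
#'
#' @param mean_C,mean_A,mean_R Numeric vectors of condition means
#'   (positive scale, e.g. normalized log2 intensities).
#' @param delta Relative tolerance (default 0.05).
#' @return Integer vector of groups in 1..4.
#' @examples
#' classify_trajectory(10, 5, 2)   # 1: continuing decline
#' classify_trajectory(5, 10, 2)   # 2: anoxia-specific peak
#' classify_trajectory(2, 5, 10)   # 3: continuing accumulation
#' classify_trajectory(10, 2, 9)   # 4: re-aeration recovery
#' @export
classify_trajectory <- function(mean_C, mean_A, mean_R, delta = 0.05) {
  stopifnot(length(mean_C) == length(mean_A),
            length(mean_A) == length(mean_R))
  if (any(!is.finite(c(mean_C, mean_A, mean_R))))
    stop("condition means must be finite")
  a_max <- gt_rel(mean_A, mean_C, delta) & gt_rel(mean_A, mean_R, delta)
  a_min <- gt_rel(mean_C, mean_A, delta) & gt_rel(mean_R, mean_A, delta)
  nonincr <- !gt_rel(mean_A, mean_C, delta) & !gt_rel(mean_R, mean_A, delta)
  ifelse(a_max, 2L, ifelse(a_min, 4L, ifelse(nonincr, 1L, 3L)))
}

#' Condition with the maximal mean intensity
#'
#' Ties are broken by the priority order control > anoxia > reaeration.
#'
#' @inheritParams classify_trajectory
#' @return Character vector over `control`, `anoxia`, `reaeration`.
#' @export
condition_of_max <- function(mean_C, mean_A, mean_R) {
  m <- cbind(mean_C, mean_A, mean_R)
  CONDITIONS[apply(m, 1L, which.max)]
}

#' Call trajectories for every spot of a table
#'
#' @param table A normalized [spot_table()].
#' @param delta Relative tolerance passed to [classify_trajectory()].
#' @return Data frame with id, the three condition means, `group`,
#'   `max_condition`, `delta`.
#' @export
call_trajectories <- function(table, delta = 0.05) {
  cm <- condition_means(table)
  cm$group <- classify_trajectory(cm$mean_control, cm$mean_anoxia,
                                  cm$mean_reaeration, delta = delta)
  cm$max_condition <- condition_of_max(cm$mean_control, cm$mean_anoxia,
                                       cm$mean_reaeration)
  cm$delta <- delta
  cm
}

#' Published condition profiles of the annotated significant proteins
#'
#' Qualitative condition-mean encodings of the 21 significantly changed,
#' annotated proteins reported for rice shoots (13) and roots (8) under
#' control, anoxia and re-aeration. Each published verbal description
#' ("gradually declined from control to re-aeration", "reached a peak in
#' anoxic conditions", and so on) is rendered as a representative triple
#' of relative intensities; the absolute scale is arbitrary, only the
#' ordering pattern matters for [classify_trajectory()].
#'
#' @return Data frame with `protein`, `organ`, `mean_control`,
#'   `mean_anoxia`, `mean_reaeration`.
#' @export
annotated_profiles <- function() {
  # Profile archetypes on an arbitrary positive scale.
  declining <- c(10, 6, 3)        # continual decline
  anoxia_peak <- c(5, 10, 2)      # peak in anoxia, drop afterwards
  rising <- c(2, 5, 10)           # gradual rise to re-aeration
  rising_late <- c(2, 8, 10)      # strong accumulation in both stresses
  recovery <- c(8, 4, 10)         # anoxic dip, re-aeration peak
  shoot <- rbind(
    `RuBisCO small subunit` = declining,
    `fructose-bisphosphate aldolase` = declining,
    `phosphoribulokinase` = declining,
    `sedoheptulose-1,7-bisphosphatase` = declining,
    `RuBisCO large subunit` = anoxia_peak,
    `heat shock cognate 70 kDa protein 2` = anoxia_peak,
    `20 kDa chaperonin, chloroplastic X1` = rising,
    `oxygen-evolving enhancer protein 1` = rising,
    `oxygen-evolving enhancer protein 2` = rising,
    `photosynthetic NDH subunit 5` = rising,
    `stromal 70 kDa heat shock protein` = rising,
    `transketolase` = rising,
    `2-Cys peroxiredoxin BAS1` = recovery
  )
  root <- rbind(
    `fructose-bisphosphate aldolase 3` = declining,
    `peroxidase P7` = declining,
    `Prb1` = anoxia_peak,
    `acidic PR-1 pathogenesis-related protein` = rising_late,
    `glucan endo-1,3-beta-glucosidase 3 X2` = rising_late,
    `cysteine-rich receptor-like kinase 6` = rising_late,
    `chitinase 2` = rising_late,
    `alpha-L-arabinofuranosidase 1 X3` = recovery
  )
  out <- data.frame(
    protein = c(rownames(shoot), rownames(root)),
    organ = rep(c("shoot", "root"), c(nrow(shoot), nrow(root))),
    rbind(shoot, root), row.names = NULL
  )
  names(out)[3:5] <- c("mean_control", "mean_anoxia", "mean_reaeration")
  out
}
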