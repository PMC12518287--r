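# Per-spot significance frameworks: normalization, Kruskal-Wallis,
# random-intercept mixed model (REML), empirical-Bayes moderated F,
# p-value adjustment, selection and Fisher over-representation.

#' Log2-transform and average technical duplicates
#'
#' Zero intensities are replaced by half the smallest positive value in
#' their column (and flagged) before taking log2; columns sharing a
#' sample id (technical duplicates of the same sample) are averaged on
#' the log scale. Spots with no finite value in any sample are dropped
#' with a warning.
#'
#' @param table A raw-scale [spot_table()].
#' @return A log2-scale [spot_table()] with `log_transformed = TRUE` and
#'   attribute `zero_replaced` (count of replaced zeros).
#' @export
log2_and_average <- function(table) {
  stopifnot(inherits(table, "spot_table"))
  if (table$log_transformed) stop("table is already log2-transformed")
  m <- table$matrix
  nzero <- 0L
  for (j in seq_len(ncol(m))) {
    z <- which(!is.na(m[, j]) & m[, j] == 0)
    if (length(z)) {
      pos <- m[, j][!is.na(m[, j]) & m[, j] > 0]
      if (!length(pos)) stop("column ", colnames(m)[j],
                             " has no positive intensity")
      m[z, j] <- min(pos) / 2
      nzero <- nzero + length(z)
    }
  }
  if (nzero) message(nzero, " zero intensit", if (nzero == 1) "y" else "ies",
                     " replaced by half the column minimum before log2")
  lm2 <- log2(m)
  # Average technical duplicate columns of the same sample on log scale.
  ids <- colnames(lm2)
  if (anyDuplicated(ids)) {
    uniq <- unique(ids)
    lm2 <- do.call(cbind, lapply(uniq, function(s)
      rowMeans(lm2[, ids == s, drop = FALSE], na.rm = TRUE)))
    lm2[is.nan(lm2)] <- NA_real_
    rownames(lm2) <- rownames(m)
    colnames(lm2) <- uniq
  }
  allmiss <- rowSums(is.finite(lm2)) == 0L
  if (any(allmiss)) {
    warning(sum(allmiss), " spot(s) with no usable intensity excluded: ",
            paste(utils::head(rownames(lm2)[allmiss], 5), collapse = ", "))
    lm2 <- lm2[!allmiss, , drop = FALSE]
  }
  out <- spot_table(lm2, table$sheet, log_transformed = TRUE)
  attr(out, "zero_replaced") <- nzero
  out
}

#' Quantile normalization of a log2 spot table
#'
#' Forces every sample column to the common empirical distribution (the
#' mean of the column order statistics), preserving within-column ranks.
#' Missing values are handled by rank interpolation over the observed
#' entries (the standard microarray-style scheme from limma).
#'
#' @param table A log2-scale [spot_table()].
#' @return The table with `normalized = TRUE`.
#' @export
quantile_normalize <- function(table) {
  stopifnot(inherits(table, "spot_table"))
  if (!table$log_transformed)
    stop("quantile normalization expects a log2-transformed table")
  m <- limma::normalizeQuantiles(table$matrix, ties = TRUE)
  dimnames(m) <- dimnames(table$matrix)
  spot_table(m, table$sheet, log_transformed = TRUE, normalized = TRUE)
}

#' Kruskal-Wallis test for one spot
#'
#' Rank-sum H statistic with tie correction and the chi-square
#' approximation on k - 1 degrees of freedom (via [stats::kruskal.test]).
#' When all observations are identical the statistic is undefined; the
#' result is flagged `degenerate` with p = 1.
#'
#' @param values List of per-condition numeric replicate vectors, or a
#'   numeric vector accompanied by `groups`.
#' @param groups Optional grouping factor when `values` is a vector.
#' @return A list with `statistic`, `p`, `df`, `degenerate`.
#' @export
kruskal_test <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- factor(rep(seq_along(values), lengths(values)))
    values <- unlist(values, use.names = FALSE)
  }
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2L) stop("need at least two conditions")
  if (length(unique(values)) == 1L)
    return(list(statistic = NA_real_, p = 1, df = nlevels(groups) - 1L,
                degenerate = TRUE))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

# Profile REML log-likelihood for a single random intercept: y = Xb + Zu + e,
# u ~ N(0, lambda * sigma2), V(lambda) = I + lambda ZZ'. Returns the REML
# criterion up to a constant.
reml_profile <- function(lambda, y, X, Z) {
  n <- length(y); p <- ncol(X)
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - p)
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            (n - p) * log(s2))
}

#' Random-intercept mixed-model test for one spot
#'
#' Fits condition as a fixed effect and a single random intercept (e.g.
#' biological replicate or gel batch) by restricted maximum likelihood,
#' profiling the variance ratio lambda = sigma_b^2 / sigma_e^2 with
#' golden-section/parabolic search on log(lambda) (tolerance 1e-8) and
#' an explicit comparison against the lambda = 0 boundary. The condition
#' effect is tested with a Wald F statistic; when the variance component
#' is estimated at zero the test reduces exactly to the one-way ANOVA F.
#'
#' @param values Numeric intensities.
#' @param condition Condition factor (>= 2 levels).
#' @param random_id Grouping factor for the random intercept.
#' @return A list with `statistic` (F), `p`, `df` (num, den), `lambda`
#'   (variance ratio estimate), `sigma2_e`, `sigma2_b`.
#' @export
mixed_model_test <- function(values, condition, random_id) {
  keep <- is.finite(values)
  values <- values[keep]
  condition <- droplevels(factor(condition[keep]))
  random_id <- droplevels(factor(random_id[keep]))
  k <- nlevels(condition); b <- nlevels(random_id)
  if (k < 2L) stop("need at least two conditions")
  n <- length(values)
  if (n <= k) stop("not enough observations for a mixed model")
  # Non-identifiable when the random factor is confounded with condition.
  if (all(table(condition, random_id) <= 1L) && b <= k &&
      identical(as.integer(condition), as.integer(random_id)))
    stop("random factor is confounded with condition; model not identifiable")
  X <- stats::model.matrix(~condition)
  Z <- stats::model.matrix(~random_id - 1)
  obj <- function(u) reml_profile(exp(u), values, X, Z)
  opt <- stats::optimize(obj, interval = c(-15, 15), maximum = TRUE,
                         tol = 1e-8)
  lambda <- exp(opt$maximum)
  if (reml_profile(0, values, X, Z) >= opt$objective || lambda < 1e-6)
    lambda <- 0
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% values))
  r <- values - X %*% beta
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - ncol(X))
  Cmat <- s2 * solve(XtViX)
  idx <- 2:k
  Fstat <- drop(t(beta[idx]) %*% solve(Cmat[idx, idx, drop = FALSE],
                                       beta[idx])) / (k - 1)
  ddf <- if (lambda > 0) max(n - k - (b - 1L), 1L) else n - k
  list(statistic = Fstat,
       p = stats::pf(Fstat, k - 1, ddf, lower.tail = FALSE),
       df = c(num = k - 1, den = ddf),
       lambda = lambda, sigma2_e = s2, sigma2_b = lambda * s2)
}

# Invert the trigamma function by Newton iteration (tolerance 1e-8,
# capped at 100 iterations), as needed for moment matching of log
# residual variances to a scaled inverse chi-square prior.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(100L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

#' Estimate the variance-moderation prior
#'
#' Moment matching of log residual variances to a scaled inverse
#' chi-square distribution: the prior degrees of freedom `d0` solve
#' trigamma(d0/2) = var(e) - trigamma(d/2) with
#' e = log(s^2) - digamma(d/2) + log(d/2), and the prior variance is
#' s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)). When the empirical
#' spread of the log variances is no larger than expected under a common
#' variance, `d0` is infinite and s0^2 is the pooled mean variance.
#'
#' @param s2 Per-spot residual variances.
#' @param df Residual degrees of freedom (scalar or per-spot).
#' @return A list with `d0` and `s0_sq`.
#' @export
fit_moderation_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2L) stop("need at least two positive variances")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # spread of log variances no larger than sampling noise: common
    # variance, estimated by the pooled mean
    d0 <- Inf
    s0 <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0)
}

#' Empirical-Bayes moderated F test across all spots
#'
#' Fits the one-way condition model to every spot, shrinks per-spot
#' residual variances toward the moment-matched prior,
#' s2_post = (d0 s0^2 + d s^2) / (d0 + d), and tests the condition
#' effect with F = MS_between / s2_post on (k - 1, d + d0) degrees of
#' freedom.
#'
#' @param table A normalized [spot_table()].
#' @param d0_override Optional fixed prior degrees of freedom (e.g.
#'   `Inf` to force s2_post = s0^2 everywhere).
#' @return A list with `prior` (`d0`, `s0_sq`) and `results`, a data
#'   frame of spot_id, statistic, p_raw, s2, s2_post.
#' @export
moderated_test <- function(table, d0_override = NULL) {
  stopifnot(inherits(table, "spot_table"))
  m <- table$matrix
  cond <- factor(table$sheet$condition, levels = CONDITIONS)
  cond <- droplevels(cond)
  k <- nlevels(cond)
  if (k < 2L) stop("need at least two conditions")
  if (!anyNA(m)) {
    # fast path: closed-form one-way sums of squares for complete data
    G <- stats::model.matrix(~cond - 1)
    ng <- colSums(G)
    GM <- (m %*% G) %*% diag(1 / ng, length(ng))
    gm <- rowSums(m) / ncol(m)
    msb <- rowSums(sweep((GM - gm)^2, 2L, ng, `*`)) / (k - 1)
    d <- ncol(m) - k
    s2 <- (rowSums(m^2) - rowSums(sweep(GM^2, 2L, ng, `*`))) / d
    s2 <- pmax(s2, 0)
    st <- cbind(msb = msb, s2 = s2, d = d, k = k)
  } else {
  stats_list <- lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    keep <- is.finite(y)
    yi <- y[keep]; ci <- droplevels(cond[keep])
    d <- length(yi) - nlevels(ci)
    if (d < 1L || nlevels(ci) < 2L)
      return(c(msb = NA_real_, s2 = NA_real_, d = d, k = nlevels(ci)))
    gm <- tapply(yi, ci, mean)
    ng <- tabulate(ci)
    msb <- sum(ng * (gm - mean(yi))^2) / (nlevels(ci) - 1)
    s2 <- sum((yi - gm[ci])^2) / d
    c(msb = msb, s2 = s2, d = d, k = nlevels(ci))
  })
  st <- do.call(rbind, stats_list)
  }
  usable <- is.finite(st[, "s2"]) & st[, "s2"] > 0
  if (any(!usable))
    warning(sum(!usable),
            " spot(s) without positive residual variance (fewer than 1",
            " residual df or constant replicates) excluded")
  prior <- fit_moderation_prior(st[usable, "s2"], st[usable, "d"])
  if (!is.null(d0_override)) prior$d0 <- d0_override
  d0 <- prior$d0; s0 <- prior$s0_sq
  d <- st[usable, "d"]
  s2 <- st[usable, "s2"]
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2))
             else (d0 * s0 + d * s2) / (d0 + d)
  Fmod <- st[usable, "msb"] / s2_post
  df2 <- d + d0
  kk <- st[usable, "k"]
  p <- stats::pf(Fmod, kk - 1, df2, lower.tail = FALSE)
  list(prior = prior,
       results = data.frame(spot_id = table$spot_ids[usable],
                            statistic = Fmod, p_raw = p,
                            s2 = s2, s2_post = s2_post,
                            df_num = kk - 1, df_den = df2,
                            row.names = NULL))
}

#' Adjust p-values for multiple testing
#'
#' Step-up Benjamini-Hochberg (`"BH"`; the paper-era alias `"FDR"` names
#' the same procedure and is accepted) or step-down Holm (`"Holm"`),
#' with monotonicity enforced and values capped at 1.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param method `"BH"` (default), `"FDR"` (alias of BH) or `"Holm"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "FDR", "Holm")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "Holm") "holm" else "BH")
}

#' Run a significance framework over every spot
#'
#' Applies one of the three per-spot tests to a normalized table and
#' attaches adjusted p-values.
#'
#' @param table A normalized [spot_table()].
#' @param method `"moderated"` (default), `"kruskal"` or `"mixed"`.
#' @param adjustment `"BH"` (default) or `"Holm"`.
#' @param random_factor Sheet column used as the random intercept for
#'   the mixed model (default `"replicate"`; `"gel_id"` is the common
#'   alternative).
#' @return A data frame with spot_id, statistic, p_raw, p_adj, method,
#'   adjustment.
#' @export
spot_tests <- function(table, method = c("moderated", "kruskal", "mixed"),
                       adjustment = c("BH", "Holm"),
                       random_factor = "replicate") {
  method <- match.arg(method)
  adjustment <- match.arg(adjustment)
  stopifnot(inherits(table, "spot_table"))
  cond <- factor(table$sheet$condition, levels = CONDITIONS)
  if (method == "moderated") {
    res <- moderated_test(table)$results[, c("spot_id", "statistic", "p_raw")]
  } else {
    rid <- table$sheet[[random_factor]]
    rows <- lapply(seq_len(nrow(table$matrix)), function(i) {
      y <- table$matrix[i, ]
      r <- if (method == "kruskal") kruskal_test(y, cond)
           else mixed_model_test(y, cond, rid)
      data.frame(spot_id = table$spot_ids[i],
                 statistic = r$statistic, p_raw = r$p)
    })
    res <- do.call(rbind, rows)
  }
  res$p_adj <- adjust_pvalues(res$p_raw, adjustment)
  res$method <- method
  res$adjustment <- adjustment
  res
}

#' Select significantly different spots
#'
#' @param results Data frame from [spot_tests()] (needs `spot_id`,
#'   `p_adj`).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return Character vector of spot ids, ordered by p_adj then spot_id.
#' @export
select_significant <- function(results, alpha = 0.05) {
  stopifnot(all(c("spot_id", "p_adj") %in% names(results)))
  hit <- results[!is.na(results$p_adj) & results$p_adj < alpha, ]
  hit$spot_id[order(hit$p_adj, hit$spot_id)]
}

#' Fisher over-representation test
#'
#' One-sided (greater) Fisher exact test of whether `hits` are enriched
#' for `category_members` within `universe`; equivalent to the
#' hypergeometric upper tail.
#'
#' @param hits Character vector, subset of `universe`.
#' @param category_members Character vector, subset of `universe`.
#' @param universe Character vector of all items.
#' @return A list with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
overrepresentation_test <- function(hits, category_members, universe) {
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(hits, universe)))
    stop("hits outside the universe")
  if (length(setdiff(category_members, universe)))
    stop("category members outside the universe")
  a <- length(intersect(hits, category_members))
  b <- length(setdiff(hits, category_members))
  cc <- length(setdiff(category_members, hits))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(hit = c("yes", "no"),
                                category = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
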