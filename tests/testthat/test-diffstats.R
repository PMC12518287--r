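test_that("log2 transform averages technical duplicates on the log scale", {
  sheet <- toy_sheet(1L)  # three samples, one per condition
  # duplicate a sample column: intensities 2 and 4 -> log2 mean 1.5
  m <- matrix(c(2, 4, 8, 16), 1, 4,
              dimnames = list("SSP1", c(sheet$sample_id[1],
                                        sheet$sample_id[1],
                                        sheet$sample_id[2:3])))
  tab <- structure(list(spot_ids = "SSP1", matrix = m, sheet = sheet,
                        log_transformed = FALSE, normalized = FALSE),
                   class = "spot_table")
  lt <- log2_and_average(tab)
  expect_equal(unname(lt$matrix[1, ]), c(1.5, 3, 4))
  expect_true(lt$log_transformed)

  # simple values: 8 -> 3, 1 -> 0
  tab2 <- toy_table(matrix(c(8, 1, 2, 4, 16, 32, 64, 128, 256), 1, 9))
  expect_equal(log2_and_average(tab2)$matrix[1, 1:2],
               c(3, 0), ignore_attr = TRUE)

  # zeros are replaced by half the smallest positive value in the column
  m3 <- matrix(c(0, 4, rep(2, 16)), 9, 2,
               dimnames = list(NULL, NULL), byrow = FALSE)
  m3 <- matrix(2, 2, 9); m3[1, 1] <- 0; m3[2, 1] <- 4
  tab3 <- toy_table(m3)
  expect_message(l3 <- log2_and_average(tab3), "replaced")
  expect_equal(l3$matrix[1, 1], log2(2), ignore_attr = TRUE)
})

test_that("quantile normalization equalizes column distributions", {
  sheet <- toy_sheet(1L)
  m <- matrix(c(1, 2, 3, 2, 4, 6, 1, 2, 3), 3, 3,
              dimnames = list(c("a", "b", "c"), sheet$sample_id))
  qn <- quantile_normalize(toy_table(m, sheet, log2 = TRUE))
  # hand oracle: mean of column order statistics (1+2+1, 2+4+2, 3+6+3)/3
  expect_equal(unname(qn$matrix[, 2]), c(4 / 3, 8 / 3, 4))
  expect_equal(unname(qn$matrix[, 1]), unname(qn$matrix[, 3]))
  # all columns share the same sorted values and mean
  sorted <- apply(qn$matrix, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # idempotence
  expect_equal(quantile_normalize(qn)$matrix, qn$matrix)
  # two identical columns are left unchanged
  m2 <- matrix(c(1, 5, 9), 3, 9, dimnames = list(c("a", "b", "c"), NULL))
  qn2 <- quantile_normalize(toy_table(m2, log2 = TRUE))
  expect_equal(unname(qn2$matrix), unname(m2))
  expect_error(quantile_normalize(toy_table(m2)), "log2")
})

test_that("Kruskal-Wallis H matches the rank-sum formula by hand", {
  # groups [1,2],[3,4],[5,6]: ranks 1..6, R = 3, 7, 11
  # H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 4.5714...
  kt <- kruskal_test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kt$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(round(kt$statistic, 3), 4.571)
  expect_equal(kt$p, pchisq(kt$statistic, 2, lower.tail = FALSE))

  # symmetric identical groups give H = 0
  expect_equal(kruskal_test(list(1:3, 1:3, 1:3))$statistic, 0)

  # H depends only on pooled ranks, not within-group order
  a <- kruskal_test(list(c(5, 1), c(2, 9), c(7, 3)))
  b <- kruskal_test(list(c(1, 5), c(9, 2), c(3, 7)))
  expect_equal(a$statistic, b$statistic)

  # degenerate all-identical data is flagged with p = 1
  deg <- kruskal_test(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("mixed model reduces to one-way ANOVA when the variance
          component is zero and is location invariant", {
  cond <- rep(CONDITIONS <- c("control", "anoxia", "reaeration"), each = 3)
  blk <- rep(1:3, 3)
  # data with no block structure at all
  set.seed(2)
  found_zero <- FALSE
  for (i in 1:10) {
    y <- rnorm(9)
    mm <- mixed_model_test(y, cond, blk)
    if (mm$lambda == 0) {
      found_zero <- TRUE
      av <- anova(lm(y ~ factor(cond)))
      expect_equal(mm$statistic, av$`F value`[1], tolerance = 1e-8)
      expect_equal(mm$p, av$`Pr(>F)`[1], tolerance = 1e-8)
      break
    }
  }
  expect_true(found_zero)

  # location invariance
  y <- rnorm(9) + rnorm(3)[blk]
  m1 <- mixed_model_test(y, cond, blk)
  m2 <- mixed_model_test(y + 100, cond, blk)
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-6)
  expect_equal(m1$p, m2$p, tolerance = 1e-6)

  expect_error(mixed_model_test(c(1, 2, 3), CONDITIONS, 1:3),
               "identifiable|observations")
})

test_that("mixed-model REML matches the nlme likelihood oracle and
          recovers a planted variance ratio", {
  skip_if_not_installed("nlme")
  cond <- rep(c("control", "anoxia", "reaeration"), each = 3)
  blk <- factor(rep(1:3, 3))
  set.seed(31)
  checked <- 0L
  for (i in 1:20) {
    y <- as.numeric(rnorm(9, sd = 0.3) + rnorm(3, sd = 1)[blk])
    mm <- mixed_model_test(y, cond, blk)
    if (mm$lambda == 0) next
    fit <- nlme::lme(y ~ cond, random = ~ 1 | blk, method = "REML")
    vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)[, 1]))
    expect_equal(mm$lambda, vc[1] / vc[2], tolerance = 1e-3)
    expect_equal(mm$p, anova(fit)["cond", "p-value"], tolerance = 1e-5)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)

  # planted sigma_b = 1, sigma_e = 0.1: true ratio 100; the median
  # estimate over 200 seeds must land within 50% of the truth
  set.seed(99)
  lams <- replicate(200, {
    y <- as.numeric(rnorm(9, sd = 0.1) + rnorm(3, sd = 1)[blk])
    mixed_model_test(y, cond, blk)$lambda
  })
  expect_gt(median(lams), 50)
  expect_lt(median(lams), 150)
})

test_that("moderation prior and moderated F match limma's independent
          implementation on a toy table", {
  sheet <- toy_sheet()
  set.seed(5)
  m <- matrix(rnorm(9 * 5, 10, 1), 5, 9,
              dimnames = list(paste0("s", 1:5), sheet$sample_id))
  tab <- spot_table(m, sheet, log_transformed = TRUE, normalized = TRUE)
  mt <- moderated_test(tab)

  cond <- factor(sheet$condition, levels = c("control", "anoxia",
                                             "reaeration"))
  fit <- limma::eBayes(limma::lmFit(m, model.matrix(~cond)))
  expect_equal(mt$prior$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(mt$prior$s0_sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(mt$results$s2_post, unname(fit$s2.post), tolerance = 1e-10)
  tt <- limma::topTable(fit, coef = 2:3, number = Inf, sort.by = "none")
  expect_equal(mt$results$statistic, tt$F, tolerance = 1e-10)
  expect_equal(mt$results$p_raw, tt$P.Value, tolerance = 1e-10)

  # s2_post lies between the observed and prior variances
  lo <- pmin(mt$results$s2, mt$prior$s0_sq)
  hi <- pmax(mt$results$s2, mt$prior$s0_sq)
  expect_true(all(mt$results$s2_post >= lo - 1e-12 &
                    mt$results$s2_post <= hi + 1e-12))
})

test_that("degenerate moderation limits behave as the formulas dictate", {
  sheet <- toy_sheet()
  # identical residual variance everywhere -> d0 = Inf and the
  # moderated F equals the ordinary F with inflated denominator df
  base <- c(1, 2, 3)
  m <- rbind(s1 = c(base, base + 1, base + 2),
             s2 = c(base, base, base) + 5,
             s3 = c(base, base + 3, base + 1))
  colnames(m) <- sheet$sample_id
  tab <- spot_table(m, sheet, log_transformed = TRUE, normalized = TRUE)
  mt <- moderated_test(tab)
  expect_equal(mt$prior$d0, Inf)
  cond <- factor(sheet$condition, c("control", "anoxia", "reaeration"))
  f_ord <- vapply(1:3, function(i)
    anova(lm(m[i, ] ~ cond))$`F value`[1], numeric(1))
  # equal variances: s2_post = s0_sq = s2, so the moderated F equals
  # the ordinary F, now tested with infinite denominator df
  expect_equal(unique(round(mt$results$s2, 10)), 1)
  expect_equal(mt$results$s2_post, rep(mt$prior$s0_sq, 3),
               tolerance = 1e-10)
  expect_equal(mt$results$statistic, f_ord, tolerance = 1e-8)
  expect_equal(mt$results$df_den, rep(Inf, 3))

  # d0 override at Inf forces s2_post = s0_sq for every spot
  set.seed(8)
  m2 <- matrix(rnorm(9 * 4, 10), 4, 9,
               dimnames = list(paste0("r", 1:4), sheet$sample_id))
  tab2 <- spot_table(m2, sheet, log_transformed = TRUE, normalized = TRUE)
  mt2 <- moderated_test(tab2, d0_override = Inf)
  expect_equal(mt2$results$s2_post,
               rep(mt2$prior$s0_sq, 4), tolerance = 1e-12)
})

test_that("p-value adjustment reproduces hand-computed BH and Holm", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "Holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(numeric()), numeric())
  expect_error(adjust_pvalues(1.2), "0, 1")
  # FDR is an alias of BH
  set.seed(3); p <- runif(20)
  expect_equal(adjust_pvalues(p, "FDR"), adjust_pvalues(p, "BH"))
  # BH-adjusted values are non-decreasing in raw-p rank order
  padj <- adjust_pvalues(p, "BH")
  expect_true(all(diff(padj[order(p)]) >= -1e-15))
})

test_that("significant-spot selection is thresholded and stably ordered", {
  res <- data.frame(spot_id = c("b", "a", "c"),
                    p_adj = c(0.01, 0.01, 0.2))
  expect_equal(select_significant(res, alpha = 0.05), c("a", "b"))
  expect_equal(select_significant(res, alpha = 1), c("a", "b", "c"))
  expect_equal(select_significant(res, alpha = 0.001), character())
})

test_that("Fisher over-representation equals the hypergeometric tail", {
  # 2x2 table a=3, b=1, c=1, d=5: enumeration oracle over the
  # hypergeometric distribution of the top-left cell
  universe <- as.character(1:10)
  hits <- universe[1:4]            # a + b = 4
  category <- universe[c(1:3, 5)]  # a + c = 4, overlap a = 3
  ot <- overrepresentation_test(hits, category, universe)
  tail_p <- sum(vapply(3:4, function(x)
    choose(4, x) * choose(6, 4 - x) / choose(10, 4), numeric(1)))
  expect_equal(ot$p, tail_p, tolerance = 1e-12)
  expect_equal(as.vector(ot$table), c(3, 1, 1, 5))

  # hits = category = universe -> p = 1
  expect_equal(overrepresentation_test(universe, universe, universe)$p, 1)
  # disjoint hits and category -> p = 1 under the greater alternative
  expect_equal(
    overrepresentation_test(universe[1:3], universe[4:6], universe)$p, 1)
  expect_error(overrepresentation_test("a", "a", character()), "universe")
  expect_error(overrepresentation_test("z", "a", letters[1:5]), "universe")
})

test_that("spot_tests attaches adjusted p-values for every framework", {
  set.seed(12)
  sim <- generate_spot_table(3, make_design(),
                             trajectory_specs(noise_sd = 0.2), seed = 12)
  norm <- quantile_normalize(log2_and_average(sim$table))
  for (meth in c("moderated", "kruskal", "mixed")) {
    res <- spot_tests(norm, method = meth)
    expect_equal(nrow(res), 12L)
    expect_true(all(res$p_adj >= res$p_raw - 1e-12))
    expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
    expect_equal(unique(res$method), meth)
  }
})
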