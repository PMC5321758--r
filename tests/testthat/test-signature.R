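sig8 <- c("AREG", "DUSP4", "DUSP6", "FOSL1", "LAMB3", "LAMC2", "PHLDA1", "SPRY4")

test_that("geometric-mean score equals the geometric mean of linear values", {
  # all genes at log2 value v => score 2^v
  em <- toy_expression(matrix(6, nrow = 8, ncol = 3, dimnames = NULL),
                       genes = sig8)
  st <- geometric_mean_score(em, sig8)
  expect_equal(unname(st$scores), rep(2^6, 3))

  # linear values 2 and 8 => geometric mean 4
  em2 <- toy_expression(rbind(c(1, 1), c(3, 3)), genes = c("A", "B"))
  st2 <- geometric_mean_score(em2, c("A", "B"))
  expect_equal(unname(st2$scores), c(4, 4))
})

test_that("scaling one of k genes by c scales the score by c^(1/k)", {
  set.seed(64)
  em <- toy_expression(matrix(rnorm(40, 7), 4, 10),
                       genes = c("A", "B", "C", "D"))
  base <- geometric_mean_score(em, c("A", "B", "C", "D"))$scores
  v2 <- em$values
  v2["B", ] <- v2["B", ] + log2(3)   # multiply linear values by 3
  st2 <- geometric_mean_score(expression_matrix(v2, em$phenotype),
                              c("A", "B", "C", "D"))$scores
  expect_equal(unname(st2 / base), rep(3^(1 / 4), 10), tolerance = 1e-12)
})

test_that("geometric-mean score ignores sample and signature gene order", {
  set.seed(65)
  em <- toy_expression(matrix(rnorm(30, 7), 3, 10), genes = c("A", "B", "C"))
  a <- geometric_mean_score(em, c("A", "B", "C"))$scores
  b <- geometric_mean_score(em, c("C", "A", "B"))$scores
  expect_identical(a, b)
  perm <- sample(colnames(em$values))
  em_perm <- expression_matrix(em$values[, perm], em$phenotype[perm])
  c_ <- geometric_mean_score(em_perm, c("A", "B", "C"))$scores
  expect_equal(c_[names(a)], a)
})

test_that("missing signature genes renormalize under a coverage floor", {
  set.seed(66)
  em <- toy_expression(matrix(rnorm(40, 7), 4, 10),
                       genes = c("AREG", "DUSP4", "DUSP6", "FOSL1"))
  expect_warning(st <- geometric_mean_score(em, c(sig8[1:4], "ABSENT"),
                                            min_coverage = 0.5),
                 "renormalized")
  expect_setequal(st$genes_used, sig8[1:4])
  expect_error(geometric_mean_score(em, sig8, min_coverage = 0.75),
               "coverage")
  expect_error(geometric_mean_score(em, c("NOPE1", "NOPE2")), "no signature gene")
})

test_that("z-summation standardizes per gene and sums to zero over samples", {
  set.seed(67)
  em <- toy_expression(matrix(rnorm(50, 7), 5, 10),
                       genes = sprintf("Z%d", 1:5))
  st <- zsum_score(em, c("Z1", "Z3", "Z5"))
  expect_equal(sum(st$scores), 0, tolerance = 1e-10)
  one <- zsum_score(em, "Z2")
  z <- (em$values["Z2", ] - mean(em$values["Z2", ])) / sd(em$values["Z2", ])
  expect_equal(unname(one$scores), unname(z), tolerance = 1e-12)

  v <- em$values; v["Z4", ] <- 5
  expect_warning(st2 <- zsum_score(expression_matrix(v, em$phenotype),
                                   c("Z1", "Z4")), "zero-variance")
  expect_equal(st2$genes_used, "Z1")
})

test_that("zsum and geometric-mean scores agree monotonically on planted data", {
  p <- simulation_params(n_genes = 300, n_planted = 8, n_per_group = 15,
                         n_systems = 1, n_cohorts = 1, seed = 31)
  sim <- simulate_multi_cohort(p)
  em <- sim$cohorts[[1]]
  g <- geometric_mean_score(em, sim$truth)$scores
  z <- zsum_score(em, sim$truth)$scores
  expect_gt(cor(g, z[names(g)], method = "spearman"), 0.8)
})

test_that("the score t-test matches direct pooled-variance evaluation", {
  # degenerate: identical score distributions
  same <- geometric_mean_score(
    toy_expression(rbind(c(1, 2, 1, 2)), genes = "A",
                   labels = c("KRAS_mut", "KRAS_mut", "KRAS_wt", "KRAS_wt")), "A")
  res_same <- score_group_ttest(same, c(S01 = "KRAS_mut", S02 = "KRAS_mut",
                                        S03 = "KRAS_wt", S04 = "KRAS_wt"))
  expect_equal(res_same$t, 0)
  expect_equal(res_same$p_value, 1)

  # textbook two-group instance vs the closed-form pooled t; a one-gene
  # geometric-mean score is just the linear expression 2^log2value
  a <- c(5.1, 6.2, 7.3, 5.9); b <- c(4.0, 4.8, 5.2, 4.4)
  emt <- toy_expression(rbind(c(a, b)), genes = "A",
                        labels = rep(c("KRAS_mut", "KRAS_wt"), each = 4))
  stt <- geometric_mean_score(emt, "A")
  lab <- emt$phenotype
  res <- score_group_ttest(stt, lab)
  sp2 <- (3 * var(2^a) + 3 * var(2^b)) / 6
  t_manual <- (mean(2^a) - mean(2^b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), 6), tolerance = 1e-10)
})

test_that("signature scores separate mutant from wild type on planted data", {
  p <- simulation_params(n_genes = 500, n_planted = 8, n_per_group = 12,
                         n_systems = 1, n_cohorts = 1, seed = 41)
  sim <- simulate_multi_cohort(p)
  em <- sim$cohorts[[1]]
  st <- geometric_mean_score(em, sim$truth)
  res <- score_group_ttest(st, em$phenotype)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$group_means["KRAS_mut"], res$group_means["KRAS_wt"])
})

test_that("the logistic classifier is calibrated under the null", {
  set.seed(91)
  reject <- 0
  for (i in 1:100) {
    sc <- rnorm(200)
    st <- geometric_mean_score(toy_expression(rbind(sc), genes = "A"), "A")
    lab <- setNames(sample(rep(c("mut", "wt"), each = 100)),
                    names(st$scores))
    fit <- fit_status_classifier(st, lab)
    if (fit$wald_p <= 0.05) reject <- reject + 1
  }
  expect_lte(reject, 10)   # >=90% of null fits non-significant
})

test_that("separation is flagged and label flips mirror the slope", {
  sc <- c(-2, -1, 1, 2)
  em <- toy_expression(rbind(sc), genes = "A")
  st <- zsum_score(em, "A")
  lab <- setNames(c("a", "a", "b", "b"), names(st$scores))
  fit <- fit_status_classifier(st, lab)
  expect_true(fit$separation)

  sc2 <- c(-1, 1, -1, 1, -0.5, 0.5)
  st2 <- zsum_score(toy_expression(rbind(sc2), genes = "A"), "A")
  lab2 <- setNames(c("a", "b", "a", "b", "b", "a"), names(st2$scores))
  f1 <- fit_status_classifier(st2, lab2)
  lab_flip <- setNames(ifelse(lab2 == "a", "b", "a"), names(lab2))
  f2 <- fit_status_classifier(st2, lab_flip)
  expect_equal(f1$slope, -f2$slope, tolerance = 1e-6)
})

test_that("AUC matches the concordant-pair oracle and its symmetries", {
  set.seed(92)
  sc <- round(rnorm(30), 1)   # rounding forces some ties
  y <- rbinom(30, 1, 0.5)
  st <- zsum_score(toy_expression(rbind(rnorm(30)), genes = "A"), "A")
  st$scores[] <- sc
  lab <- setNames(ifelse(y == 1, "pos", "neg"), names(st$scores))
  res <- roc_auc(st, lab)
  # brute-force pair counting with half-credit ties
  pos <- sc[y == 1]; neg <- sc[y == 0]
  conc <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(res$auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)

  st_neg <- st; st_neg$scores <- -st$scores
  expect_equal(roc_auc(st, lab)$auc + roc_auc(st_neg, lab)$auc, 1)

  # perfect separation and all-tied degeneracies
  st$scores[] <- ifelse(y == 1, 2, 1)
  expect_equal(roc_auc(st, lab)$auc, 1.0)
  st$scores[] <- 1
  expect_equal(roc_auc(st, lab)$auc, 0.5)
})

test_that("classifier slope is positive whenever training AUC exceeds 0.5", {
  set.seed(93)
  for (i in 1:10) {
    sc <- rnorm(80)
    y <- rbinom(80, 1, plogis(1.2 * sc))
    st <- zsum_score(toy_expression(rbind(rnorm(80)), genes = "A"), "A")
    st$scores[] <- sc
    lab <- setNames(ifelse(y == 1, "b_pos", "a_neg"), names(st$scores))
    if (length(unique(lab)) < 2) next
    auc <- roc_auc(st, lab)$auc
    fit <- fit_status_classifier(st, lab)
    if (auc > 0.5) expect_gt(fit$slope, 0)
  }
})
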