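test_that("expression floor filter applies the strict more-than rule", {
  em <- toy_expression(rbind(c(4, 4, 6, 6),    # exactly 50% low: retained
                             c(1, 1, 1, 9),    # 75% low: removed
                             c(6, 6, 6, 6)))
  filt <- filter_low_expression(em, floor = 5, max_low_fraction = 0.5)
  expect_equal(rownames(filt$values), c("GENE01", "GENE03"))

  # knockdown configuration uses floor 4
  em2 <- toy_expression(rbind(c(3.9, 3.9, 3.9, 8), c(5, 5, 5, 5)))
  filt2 <- filter_low_expression(em2, floor = 4, max_low_fraction = 0.5)
  expect_equal(rownames(filt2$values), "GENE02")

  all_low <- filter_low_expression(toy_expression(rbind(c(1, 1, 1, 1))),
                                   floor = 5)
  expect_equal(nrow(all_low$values), 0)
})

test_that("d0 = 0 reduces the moderated t to the ordinary pooled t", {
  em <- random_expression(40, 5, seed = 11, heteroscedastic = TRUE)
  de <- moderated_de(em, d0 = 0)
  mut <- em$values[, em$phenotype[colnames(em$values)] == "KRAS_mut"]
  wt <- em$values[, em$phenotype[colnames(em$values)] == "KRAS_wt"]
  t_plain <- vapply(seq_len(nrow(em$values)), function(g)
    unname(t.test(mut[g, ], wt[g, ], var.equal = TRUE)$statistic), numeric(1))
  expect_equal(de$t_mod, t_plain, tolerance = 1e-10)
})

test_that("d0 = Inf shares one variance so |t| ranks like |log2fc|", {
  em <- random_expression(40, 5, seed = 12, heteroscedastic = TRUE)
  de <- moderated_de(em, d0 = Inf)
  expect_equal(order(-abs(de$t_mod)), order(-abs(de$log2fc)))
})

test_that("moderated statistics match a direct closed-form evaluation", {
  em <- random_expression(50, 4, seed = 3, heteroscedastic = TRUE,
                          effect_rows = 1:5, effect = 2)
  de <- moderated_de(em)
  hp <- attr(de, "hyperparams")

  # independent evaluation of the closed forms, given the fitted
  # hyperparameters
  mut <- em$values[, 1:4]; wt <- em$values[, 5:8]
  lfc <- rowMeans(mut) - rowMeans(wt)
  d <- 6
  s2 <- (rowSums((mut - rowMeans(mut))^2) +
         rowSums((wt - rowMeans(wt))^2)) / d
  stilde2 <- (hp$d0 * hp$s0_sq + d * s2) / (hp$d0 + d)
  vg <- 1 / 4 + 1 / 4
  t_exp <- lfc / sqrt(stilde2 * vg)
  df_tot <- hp$d0 + d
  p_exp <- 2 * pt(-abs(t_exp), df_tot)
  r <- (vg + hp$v0) / vg
  b_exp <- log(hp$p_prior / (1 - hp$p_prior)) - log(r) / 2 +
    (1 + df_tot) / 2 * log((t_exp^2 + df_tot) / (t_exp^2 / r + df_tot))

  expect_equal(de$log2fc, unname(lfc), tolerance = 1e-12)
  expect_equal(de$t_mod, unname(t_exp), tolerance = 1e-10)
  expect_equal(de$p_value, unname(p_exp), tolerance = 1e-10)
  expect_equal(de$b_stat, unname(b_exp), tolerance = 1e-10)
})

test_that("moderated t and p agree with the limma reference", {
  em <- random_expression(200, 5, seed = 17, heteroscedastic = TRUE,
                          effect_rows = 1:10, effect = 1.5)
  de <- moderated_de(em)
  design <- cbind(intercept = 1,
                  mut = as.numeric(em$phenotype[colnames(em$values)] == "KRAS_mut"))
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  hp <- attr(de, "hyperparams")
  expect_equal(hp$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(hp$s0_sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(de$t_mod, unname(fit$t[, "mut"]), tolerance = 1e-10)
  expect_equal(de$p_value, unname(fit$p.value[, "mut"]), tolerance = 1e-10)
})

test_that("the cross-system candidate rule counts strict passes per system", {
  de1 <- fake_de(c("A", "B", "C"), log2fc = c(2.0, 1.0, 1.5),
                 b_stat = c(1, 1, 1))
  de2 <- fake_de(c("A", "B", "C"), log2fc = c(0.2, 2.0, 1.4),
                 b_stat = c(1, 1, -0.5))
  de3 <- fake_de(c("A", "B"), log2fc = c(3.0, 2.0), b_stat = c(2, 1))
  sel <- select_cross_system_candidates(list(de1, de2, de3))
  # A passes in systems 1 and 3; B's log2fc of exactly 1.0 fails the strict
  # cutoff in system 1 but passes in 2 and 3; C passes only in system 1
  # (absent B-pass in 2, absent entirely from 3)
  expect_setequal(as.character(sel), c("A", "B"))
  expect_error(select_cross_system_candidates(list(de1), min_systems = 2))
})

test_that("the knockdown signature rule uses linear FC < 0.5 and B > 0", {
  de <- fake_de(c("IN", "OUT_FC", "OUT_B"),
                log2fc = c(-1.1, -0.9, -2.0), b_stat = c(0.2, 5, -0.1))
  expect_equal(select_knockdown_signature(de), "IN")
})

test_that("statistics are location invariant and monotone in effect size", {
  em <- random_expression(30, 4, seed = 5, heteroscedastic = TRUE)
  de <- moderated_de(em)
  shifted <- expression_matrix(em$values + 3.7, em$phenotype)
  de2 <- moderated_de(shifted)
  expect_equal(de$log2fc, de2$log2fc, tolerance = 1e-12)
  expect_equal(de$t_mod, de2$t_mod, tolerance = 1e-10)
  expect_equal(de$b_stat, de2$b_stat, tolerance = 1e-10)

  # same residuals, larger |group separation| => |t| cannot decrease
  v <- em$values
  mut_cols <- em$phenotype[colnames(v)] == "KRAS_mut"
  diff1 <- mean(v[1, mut_cols]) - mean(v[1, !mut_cols])
  v2 <- v
  v2[1, mut_cols] <- v2[1, mut_cols] + sign(diff1) * 2
  de_b <- moderated_de(expression_matrix(v2, em$phenotype))
  expect_gte(abs(de_b$t_mod[1]), abs(de$t_mod[1]))
})

test_that("B is an increasing function of t^2 at fixed hyperparameters", {
  em <- random_expression(100, 5, seed = 19, heteroscedastic = TRUE,
                          effect_rows = 1:5, effect = 2)
  de <- moderated_de(em)
  o <- order(de$t_mod^2)
  expect_true(all(diff(de$b_stat[o]) >= -1e-12))
})

test_that("null p-values are uniform in a planted-null simulation", {
  p <- simulation_params(n_genes = 2000, planted_log2fc = 0, seed = 7,
                         n_systems = 1, n_cohorts = 0)
  sim <- simulate_multi_cohort(p)
  de <- moderated_de(sim$systems[[1]])
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})
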