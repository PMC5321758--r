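# Stage 1: expression floor filtering, empirical-Bayes moderated two-group
# differential expression with the B log-odds statistic, and the
# cross-system candidate / knockdown-signature selection rules.
#
# Model per gene g: log2fc_g = mean(group A) - mean(group B); residual
# variance s2_g on d degrees of freedom; hierarchical prior
# s2_g ~ s0^2 * d0 / chisq(d0) estimated by moment matching on log s2;
# posterior variance stilde2 = (d0*s0^2 + d*s2)/(d0 + d); moderated
# t = log2fc / (stilde * sqrt(1/nA + 1/nB)) on d0 + d df. B is the log
# posterior odds of differential expression under a two-component mixture
# with prior proportion p_prior and prior effect variance v0 estimated from
# the top-ranked genes.

#' Remove genes below an expression floor
#'
#' A gene is dropped when its expression is below `floor` in strictly more
#' than `max_low_fraction` of all samples (both conditions pooled); a gene
#' low in exactly that fraction is retained. Gene order is preserved.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param floor Expression floor (log2 units); the headline configuration
#'   uses 5 for discovery arrays and 4 for the knockdown arrays.
#' @param max_low_fraction Maximum tolerated fraction of low samples, in
#'   (0, 1].
#' @return Filtered `ExpressionMatrix` (possibly with zero rows).
#' @export
filter_low_expression <- function(matrix, floor = 5, max_low_fraction = 0.5) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            max_low_fraction > 0, max_low_fraction <= 1)
  low_frac <- rowMeans(matrix$values < floor)
  keep <- low_frac <= max_low_fraction
  expression_matrix(matrix$values[keep, , drop = FALSE], matrix$phenotype)
}

# Newton inversion of the trigamma function (used by the moment-matching
# estimate of the prior degrees of freedom).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Moment matching of log residual variances to a scaled F / chi-square
# hierarchy: returns prior df d0 and prior variance s0^2.
fit_variance_prior <- function(s2, d) {
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Quantile-matching estimate of the prior variance v0 of a true effect
# (in units of the unscaled coefficient variance), from the genes with the
# largest |t|.
estimate_v0 <- function(tstat, v_unscaled, df, p_prior, top_fraction) {
  g <- length(tstat)
  ntarget <- ceiling(top_fraction * g)
  if (ntarget < 1) return(0)
  p <- max(ntarget / g, p_prior)
  t2 <- sort(tstat^2, decreasing = TRUE)[seq_len(ntarget)]
  r <- seq_len(ntarget)
  p0 <- 2 * stats::pt(sqrt(t2), df, lower.tail = FALSE)
  ptarget <- ((r - 0.5) / g - (1 - p) * p0) / p
  v0 <- numeric(ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df, lower.tail = FALSE)
    v0[pos] <- v_unscaled * (t2[pos] / qtarget^2 - 1)
  }
  max(mean(v0), 0)
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' @param matrix An `ExpressionMatrix` with a phenotype map covering all
#'   samples used.
#' @param group_a,group_b Phenotype labels of the contrast; `log2fc` is
#'   oriented `group_a - group_b` (mutant minus wild type in the headline
#'   use).
#' @param p_prior Prior proportion of differentially expressed genes used in
#'   the B log-odds (default 0.01, the method's conventional default).
#' @param v0_top_fraction Fraction of top genes by |t| used to estimate the
#'   prior effect variance (default 0.1).
#' @param d0,s0_sq Optional overrides of the estimated prior df / prior
#'   variance (mainly for the shrinkage-limit checks: `d0 = 0` gives the
#'   ordinary pooled-variance t, `d0 = Inf` fully shared variance).
#' @return Object of class `DEResult`: data frame with columns `gene`,
#'   `log2fc`, `t_mod`, `df_total`, `p_value`, `b_stat` and attribute
#'   `hyperparams` (list `d0`, `s0_sq`, `p_prior`, `v0`, `df_residual`,
#'   `v_unscaled`).
#' @export
moderated_de <- function(matrix, group_a = "KRAS_mut", group_b = "KRAS_wt",
                         p_prior = 0.01, v0_top_fraction = 0.1,
                         d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.null(matrix$phenotype))
    stop("matrix has no phenotype labels", call. = FALSE)
  ia <- colnames(matrix$values) %in%
    names(matrix$phenotype)[matrix$phenotype == group_a]
  ib <- colnames(matrix$values) %in%
    names(matrix$phenotype)[matrix$phenotype == group_b]
  na <- sum(ia); nb <- sum(ib)
  if (na < 2 || nb < 2)
    stop("need >=2 samples per group (", group_a, ": ", na, ", ",
         group_b, ": ", nb, ")", call. = FALSE)
  A <- matrix$values[, ia, drop = FALSE]
  B <- matrix$values[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  log2fc <- ma - mb
  d <- na + nb - 2
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  s2 <- (ssa + ssb) / d
  if (all(s2 == 0))
    stop("degenerate fit: zero residual variance for every gene", call. = FALSE)
  if (any(s2 == 0)) {
    warning(sprintf("%d gene(s) with zero residual variance floored at machine epsilon",
                    sum(s2 == 0)), call. = FALSE)
    s2 <- pmax(s2, .Machine$double.eps)
  }
  prior <- fit_variance_prior(s2, d)
  if (!is.null(d0)) prior$d0 <- d0
  if (!is.null(s0_sq)) prior$s0_sq <- s0_sq
  stilde2 <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2))
             else (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  v_unscaled <- 1 / na + 1 / nb
  t_mod <- log2fc / sqrt(stilde2 * v_unscaled)
  df_total <- min(prior$d0 + d, 1e6)
  p_value <- 2 * stats::pt(-abs(t_mod), df = df_total)
  v0 <- estimate_v0(t_mod, v_unscaled, df_total, p_prior, v0_top_fraction)
  r <- (v_unscaled + v0) / v_unscaled
  t2 <- t_mod^2
  kernel <- if (df_total > 1e6 / 2)
    t2 * (1 - 1 / r) / 2
  else
    (1 + df_total) / 2 * log((t2 + df_total) / (t2 / r + df_total))
  b_stat <- log(p_prior / (1 - p_prior)) - log(r) / 2 + kernel
  out <- data.frame(gene = rownames(matrix$values), log2fc = log2fc,
                    t_mod = t_mod, df_total = df_total, p_value = p_value,
                    b_stat = b_stat, row.names = NULL)
  structure(out,
            hyperparams = list(d0 = prior$d0, s0_sq = prior$s0_sq,
                               p_prior = p_prior, v0 = v0,
                               df_residual = d, v_unscaled = v_unscaled),
            contrast = c(group_a, group_b), n_per_group = c(na, nb),
            class = c("DEResult", "data.frame"))
}

#' Cross-system candidate selection rule
#'
#' A gene is selected when it satisfies `b_stat > b_min` and
#' `log2fc > logfc_min` (both strict) in at least `min_systems` of the
#' supplied per-system results; a gene absent from a system counts as not
#' passing there.
#'
#' @param results List of `DEResult` objects, one per experimental system.
#' @param logfc_min log2 fold-change cutoff (default 1).
#' @param b_min B log-odds cutoff (default 0).
#' @param min_systems Minimum number of systems a gene must pass in.
#' @return Character vector of selected gene symbols (sorted), with
#'   attribute `n_passing` giving each selected gene's system count.
#' @export
select_cross_system_candidates <- function(results, logfc_min = 1, b_min = 0,
                                           min_systems = 2) {
  stopifnot(length(results) >= min_systems)
  passing <- lapply(results, function(de) {
    stopifnot(inherits(de, "DEResult"))
    de$gene[de$b_stat > b_min & de$log2fc > logfc_min]
  })
  counts <- table(unlist(passing))
  sel <- sort(as.character(names(counts)[counts >= min_systems]))
  structure(sel, n_passing = as.integer(counts[sel]))
}

#' Knockdown-signature selection rule
#'
#' Selects genes downregulated upon knockdown: linear fold change below
#' `fc_max` (i.e. `log2fc < log2(fc_max)`) and `b_stat > b_min`.
#'
#' @param result A `DEResult` from a knockdown-vs-control contrast
#'   (log2fc oriented target minus control).
#' @param fc_max Linear fold-change ceiling (default 0.5).
#' @param b_min B log-odds cutoff (default 0).
#' @return Character vector of selected gene symbols (sorted).
#' @export
select_knockdown_signature <- function(result, fc_max = 0.5, b_min = 0) {
  stopifnot(inherits(result, "DEResult"), fc_max > 0)
  sort(result$gene[result$log2fc < log2(fc_max) & result$b_stat > b_min])
}
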