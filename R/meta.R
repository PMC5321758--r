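# Standardized-mean-difference meta-analysis across cohorts and
# hypergeometric over-representation of a gene list in annotation
# categories, with Benjamini-Hochberg adjustment.

#' Hedges' g standardized mean difference for one study
#'
#' `d = (mean_case - mean_control) / s_pooled`; the small-sample correction
#' `J = 1 - 3 / (4(n1 + n2 - 2) - 1)` gives `g = J d` with sampling variance
#' `var_g = J^2 * ((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param mean_case,sd_case,n_case Case-arm summary statistics.
#' @param mean_control,sd_control,n_control Control-arm summary statistics.
#' @param study_id Study label.
#' @param correct Apply the Hedges correction (default); `FALSE` gives
#'   Cohen's d.
#' @return One-row data frame of class `StudyEffect`: `study_id`, `g`,
#'   `var_g`, `n_case`, `n_control`.
#' @export
hedges_g <- function(mean_case, sd_case, n_case, mean_control, sd_control,
                     n_control, study_id = "study", correct = TRUE) {
  if (n_case < 2 || n_control < 2)
    stop("each arm needs n >= 2", call. = FALSE)
  if (sd_case <= 0 || sd_control <= 0)
    stop("arm standard deviations must be positive", call. = FALSE)
  n <- n_case + n_control
  s_pooled <- sqrt(((n_case - 1) * sd_case^2 + (n_control - 1) * sd_control^2) /
                   (n - 2))
  d <- (mean_case - mean_control) / s_pooled
  j <- if (correct) 1 - 3 / (4 * (n - 2) - 1) else 1
  g <- j * d
  var_g <- j^2 * (n / (n_case * n_control) + d^2 / (2 * n))
  structure(data.frame(study_id = study_id, g = g, var_g = var_g,
                       n_case = n_case, n_control = n_control),
            class = c("StudyEffect", "data.frame"))
}

#' Pool standardized mean differences across studies
#'
#' Fixed effect: inverse-variance weights. Random effects: DerSimonian-Laird
#' `tau^2 = max(0, (Q - df) / C)` added to every study variance, with
#' `C = sum(w) - sum(w^2)/sum(w)` computed from the fixed-effect weights.
#' The 95% CI is `pooled +/- 1.96 se`.
#'
#' @param effects Data frame with columns `g` and `var_g` (rows bindable
#'   from [hedges_g()] output), >= 2 studies.
#' @param model `"random"` (default) or `"fixed"`.
#' @return List with `pooled`, `se`, `ci_lower`, `ci_upper`, `q`, `tau_sq`,
#'   `k`, `model`.
#' @export
pool_smd <- function(effects, model = c("random", "fixed")) {
  model <- match.arg(model)
  stopifnot(nrow(effects) >= 2, all(c("g", "var_g") %in% names(effects)),
            all(effects$var_g > 0))
  w <- 1 / effects$var_g
  fixed <- sum(w * effects$g) / sum(w)
  q <- sum(w * (effects$g - fixed)^2)
  k <- nrow(effects)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau_sq <- max(0, (q - (k - 1)) / cc)
  if (model == "fixed") {
    pooled <- fixed
    se <- sqrt(1 / sum(w))
  } else {
    ws <- 1 / (effects$var_g + tau_sq)
    pooled <- sum(ws * effects$g) / sum(ws)
    se <- sqrt(1 / sum(ws))
  }
  list(pooled = pooled, se = se,
       ci_lower = pooled - 1.96 * se, ci_upper = pooled + 1.96 * se,
       q = q, tau_sq = tau_sq, k = k, model = model)
}

#' Hypergeometric over-representation of a gene list
#'
#' For each category: with universe size `N`, category size `K` (after
#' intersection with the universe), query size `n` and overlap `k`, the
#' enrichment p-value is the inclusive upper tail `P(X >= k)` of
#' `Hypergeometric(N, K, n)`. q-values are Benjamini-Hochberg adjusted.
#'
#' @param query Character vector of gene symbols (must lie in `universe`).
#' @param categories A `GeneSetCollection` of annotation categories.
#' @param universe Character vector of background gene symbols.
#' @return Data frame with one row per category: `category`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`.
#' @export
hypergeom_enrich <- function(query, categories, universe) {
  stopifnot(inherits(categories, "GeneSetCollection"))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(toupper(query))
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "),
         call. = FALSE)
  n <- length(query); n_univ <- length(universe)
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], universe)
    kk <- length(intersect(cat_genes, query))
    bigk <- length(cat_genes)
    p <- stats::phyper(kk - 1, bigk, n_univ - bigk, n, lower.tail = FALSE)
    data.frame(category = nm, k = kk, K = bigk, n = n, N = n_univ,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return q-values in the same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}
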