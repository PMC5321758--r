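# Stage 2: preranked gene-set enrichment. Weighted Kolmogorov-Smirnov
# running-sum enrichment score, gene-resampling permutation significance,
# leading-edge extraction, and the leading-edge recurrence filter that
# distils a core signature out of many cohort-level enrichment runs.

#' Rank genes by log2 fold change
#'
#' Descending metric order; ties broken by ascending lexicographic gene
#' symbol so the ranking is deterministic regardless of input row order.
#'
#' @param de A `DEResult` (or any data frame with `gene` and `log2fc`).
#' @return Object of class `RankedList`: list with `genes` and `metric`.
#' @export
rank_by_logfc <- function(de) {
  stopifnot(nrow(de) >= 1, all(c("gene", "log2fc") %in% names(de)))
  o <- order(-de$log2fc, de$gene)
  structure(list(genes = de$gene[o], metric = de$log2fc[o]),
            class = "RankedList")
}

#' Construct a ranked list directly from genes and metric values
#' @param genes Unique gene symbols.
#' @param metric Ranking metric (one value per gene).
#' @return A `RankedList` (sorted descending by metric, symbol tie-break).
#' @export
ranked_list <- function(genes, metric) {
  stopifnot(length(genes) == length(metric), !anyDuplicated(genes))
  rank_by_logfc(data.frame(gene = as.character(genes), log2fc = metric))
}

# Enrichment score from hit ranks only. The running sum is piecewise
# monotone between hits, so its extreme positive deviation is attained at a
# hit position and its extreme negative deviation just before a hit; both
# are evaluated in O(|set|) after locating the hits.
es_from_hits <- function(hit_ranks, metric, weight_p, n) {
  r <- sort(hit_ranks)
  nh <- length(r)
  w <- abs(metric[r])^weight_p
  nr <- sum(w)
  if (nr == 0) stop("all hit weights are zero; enrichment score undefined",
                    call. = FALSE)
  cum <- cumsum(w) / nr
  miss_scale <- 1 / (n - nh)
  k <- seq_len(nh)
  pos_dev <- cum - (r - k) * miss_scale
  neg_dev <- c(0, cum[-nh]) - (r - k) * miss_scale
  mx <- max(pos_dev); mn <- min(neg_dev, 0)
  if (mx >= -mn) mx else mn
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Computes the running sum `P_hit(i) - P_miss(i)` where hits are weighted
#' by `|metric|^weight_p` (normalized to 1 over the set) and misses
#' uniformly, and returns its signed maximum deviation. `weight_p = 0`
#' reduces to the classical unweighted KS form.
#'
#' @param ranked A `RankedList`.
#' @param gene_set Character vector of gene symbols.
#' @param weight_p Weighting exponent (default 1).
#' @return Object of class `GseaResult` with `es`, `running_sum` (per-rank
#'   deviations), `hit_ranks`, and `leading_edge`/`nes`/`p_value` unset.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(inherits(ranked, "RankedList"))
  n <- length(ranked$genes)
  hit <- toupper(ranked$genes) %in% toupper(gene_set)
  nh <- sum(hit)
  if (nh == 0) stop("gene set not represented in the ranked list", call. = FALSE)
  if (nh == n) stop("gene set covers the whole ranked list; miss probability undefined",
                    call. = FALSE)
  w <- numeric(n)
  w[hit] <- abs(ranked$metric[hit])^weight_p
  nr <- sum(w)
  if (nr == 0) stop("all hit weights are zero; enrichment score undefined",
                    call. = FALSE)
  p_hit <- cumsum(w) / nr
  p_miss <- cumsum(!hit) / (n - nh)
  rs <- p_hit - p_miss
  i_max <- which.max(rs); i_min <- which.min(rs)
  es <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  structure(list(es = es, nes = NA_real_, p_value = NA_real_,
                 leading_edge = NULL, running_sum = rs,
                 hit_ranks = which(hit), n = n, weight_p = weight_p),
            class = "GseaResult")
}

#' Leading-edge subset of a gene set
#'
#' For a positive enrichment score: set members at ranks up to (and
#' including) the running-sum maximum; for a negative score: members at
#' ranks at or after the running-sum minimum.
#'
#' @param result A `GseaResult` computed on `ranked` and `gene_set`.
#' @param ranked The `RankedList` used.
#' @param gene_set The gene set used.
#' @return Character vector of leading-edge genes in rank order.
#' @export
leading_edge <- function(result, ranked, gene_set) {
  stopifnot(inherits(result, "GseaResult"), inherits(ranked, "RankedList"))
  rs <- result$running_sum
  hits <- result$hit_ranks
  if (result$es >= 0) {
    peak <- which.max(rs)
    ranked$genes[hits[hits <= peak]]
  } else {
    trough <- which.min(rs)
    ranked$genes[hits[hits >= trough]]
  }
}

#' Preranked GSEA with gene-resampling permutation significance
#'
#' The null distribution is built from `n_perm` random gene sets of the same
#' size drawn from the ranked list. The p-value uses the same-sign null with
#' a +1 pseudo-count, `p = (1 + #{|ES_null| >= |ES|, same sign}) /
#' (1 + #{same-sign nulls})`, and `NES = ES / mean(|same-sign null ES|)`.
#'
#' @param ranked A `RankedList`.
#' @param gene_set Character vector of gene symbols.
#' @param n_perm Number of permutations (>= 100 recommended for reported
#'   p-values; default 1000).
#' @param seed Integer RNG seed.
#' @param weight_p Weighting exponent (default 1).
#' @return A `GseaResult` with `es`, `nes`, `p_value`, `leading_edge`,
#'   `running_sum`, `hit_ranks` and the vector of null scores (`null_es`).
#' @export
gsea_permutation <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                             weight_p = 1) {
  stopifnot(n_perm >= 1)
  obs <- enrichment_score(ranked, gene_set, weight_p)
  obs$leading_edge <- leading_edge(obs, ranked, gene_set)
  n <- obs$n
  nh <- length(obs$hit_ranks)
  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_perm), function(i)
    es_from_hits(sample.int(n, nh), ranked$metric, weight_p, n),
    numeric(1))
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  obs$p_value <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  obs$nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  obs$null_es <- null_es
  obs
}

#' @export
print.GseaResult <- function(x, ...) {
  cat(sprintf("GseaResult: ES=%.4f NES=%s p=%s hits=%d/%d\n", x$es,
              ifelse(is.na(x$nes), "NA", sprintf("%.3f", x$nes)),
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value)),
              length(x$hit_ranks), x$n))
  if (!is.null(x$leading_edge))
    cat("leading edge:", paste(utils::head(x$leading_edge, 12), collapse = ", "),
        if (length(x$leading_edge) > 12) "..." else "", "\n")
  invisible(x)
}

#' Leading-edge recurrence filter
#'
#' Keeps the genes present in strictly more than `min_fraction` of the
#' supplied leading edges (e.g. a gene in 5 of 9 edges passes the default
#' >50% rule; one in exactly 3 of 6 does not).
#'
#' @param edges List (length >= 2) of leading-edge gene vectors.
#' @param min_fraction Recurrence threshold (strict), default 0.5.
#' @return Character vector of recurrent genes (sorted), with attribute
#'   `recurrence` giving each gene's fraction.
#' @export
leading_edge_recurrence <- function(edges, min_fraction = 0.5) {
  stopifnot(length(edges) >= 2, min_fraction > 0, min_fraction <= 1)
  counts <- table(unlist(lapply(edges, unique)))
  frac <- as.numeric(counts) / length(edges)
  names(frac) <- names(counts)
  sel <- sort(as.character(names(frac)[frac > min_fraction]))
  structure(sel, recurrence = unname(frac[sel]))
}
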