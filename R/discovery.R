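# The discovery workflow: per-system moderated differential expression ->
# cross-system candidate intersection -> per-cohort preranked enrichment ->
# leading-edge recurrence -> core signature -> per-cohort signature scores.
# The pipeline halts with an explicit status (rather than an error) when an
# intermediate gene set comes up empty, so partial reports remain usable.

#' Pipeline configuration
#'
#' Central home of every tunable threshold of the discovery workflow.
#'
#' @param expression_floor Expression floor (log2 units; default 5).
#' @param floor_max_fraction Maximum tolerated fraction of low samples per
#'   gene (default 0.5; a gene below the floor in strictly more than this
#'   fraction is dropped).
#' @param logfc_min,b_min Candidate-rule cutoffs (strict; defaults 1 and 0).
#' @param min_systems Minimum systems a candidate must pass in (default 2).
#' @param recurrence_min_fraction Leading-edge recurrence threshold
#'   (strict; default 0.5).
#' @param gsea_weight GSEA weighting exponent (default 1).
#' @param n_perm GSEA permutations per cohort (default 1000).
#' @param scoring_method `"geometric_mean"` or `"zsum"`.
#' @param survival_quantile Dichotomization quantile for survival
#'   stratification (default 0.5).
#' @param p_prior Prior proportion of differential genes for the B
#'   statistic (default 0.01).
#' @param seed Integer seed governing every stochastic stage.
#' @return Validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(expression_floor = 5, floor_max_fraction = 0.5,
                            logfc_min = 1, b_min = 0, min_systems = 2,
                            recurrence_min_fraction = 0.5, gsea_weight = 1,
                            n_perm = 1000,
                            scoring_method = c("geometric_mean", "zsum"),
                            survival_quantile = 0.5, p_prior = 0.01,
                            seed = 1) {
  scoring_method <- match.arg(scoring_method)
  stopifnot(floor_max_fraction > 0, floor_max_fraction <= 1,
            recurrence_min_fraction > 0, recurrence_min_fraction <= 1,
            survival_quantile > 0, survival_quantile < 1,
            n_perm >= 1, min_systems >= 1,
            p_prior > 0, p_prior < 1)
  structure(list(expression_floor = expression_floor,
                 floor_max_fraction = floor_max_fraction,
                 logfc_min = logfc_min, b_min = b_min,
                 min_systems = min_systems,
                 recurrence_min_fraction = recurrence_min_fraction,
                 gsea_weight = gsea_weight, n_perm = n_perm,
                 scoring_method = scoring_method,
                 survival_quantile = survival_quantile,
                 p_prior = p_prior, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the cross-system signature discovery workflow
#'
#' Stage 1 filters and tests each discovery system
#' ([filter_low_expression()], [moderated_de()]) and intersects the
#' per-system hits ([select_cross_system_candidates()]). Stage 2 ranks each
#' validation cohort by log2 fold change and runs preranked enrichment of
#' the candidate set ([gsea_permutation()]); the per-cohort leading edges
#' feed the recurrence filter ([leading_edge_recurrence()]) to yield the
#' core signature. Stage 3 scores every cohort sample on the core
#' signature.
#'
#' @param config A [pipeline_config()].
#' @param systems List of `ExpressionMatrix` discovery systems (phenotypes
#'   labelled `group_a`/`group_b`).
#' @param cohorts List of `ExpressionMatrix` validation cohorts.
#' @param group_a,group_b Phenotype labels of the contrast.
#' @return Object of class `DiscoveryReport`: list with `status`
#'   (`"ok"` or an explanatory halt status), `systems_de`, `candidates`,
#'   `gsea`, `leading_edges`, `core_signature`, `scores`, `config`.
#' @export
run_discovery <- function(config, systems, cohorts,
                          group_a = "KRAS_mut", group_b = "KRAS_wt") {
  stopifnot(inherits(config, "PipelineConfig"),
            length(systems) >= 1, length(cohorts) >= 1)
  for (em in c(systems, cohorts)) {
    stopifnot(inherits(em, "ExpressionMatrix"))
    if (is.null(em$phenotype) ||
        !all(c(group_a, group_b) %in% em$phenotype))
      stop("every matrix needs phenotype labels for both contrast groups",
           call. = FALSE)
  }
  report <- list(status = "ok", systems_de = NULL, candidates = character(),
                 gsea = NULL, leading_edges = NULL,
                 core_signature = character(), scores = NULL,
                 config = config)
  class(report) <- "DiscoveryReport"
  if (length(systems) < config$min_systems) {
    report$status <- "intersection rule unsatisfiable"
    return(report)
  }
  report$systems_de <- lapply(systems, function(em) {
    filtered <- filter_low_expression(em, config$expression_floor,
                                      config$floor_max_fraction)
    if (nrow(filtered$values) == 0) return(NULL)
    moderated_de(filtered, group_a, group_b, p_prior = config$p_prior)
  })
  if (any(vapply(report$systems_de, is.null, logical(1)))) {
    report$status <- "all genes removed by expression filter"
    return(report)
  }
  report$candidates <- select_cross_system_candidates(
    report$systems_de, config$logfc_min, config$b_min, config$min_systems)
  if (length(report$candidates) == 0) {
    report$status <- "no candidates from intersection rule"
    return(report)
  }
  report$gsea <- vector("list", length(cohorts))
  report$leading_edges <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    filtered <- filter_low_expression(cohorts[[i]], config$expression_floor,
                                      config$floor_max_fraction)
    de <- moderated_de(filtered, group_a, group_b, p_prior = config$p_prior)
    ranked <- rank_by_logfc(de)
    res <- tryCatch(
      gsea_permutation(ranked, report$candidates, n_perm = config$n_perm,
                       seed = config$seed + i, weight_p = config$gsea_weight),
      error = function(e) NULL)
    report$gsea[[i]] <- res
    report$leading_edges[[i]] <- if (is.null(res)) character() else res$leading_edge
  }
  if (length(report$leading_edges) >= 2) {
    report$core_signature <- leading_edge_recurrence(
      report$leading_edges, config$recurrence_min_fraction)
  } else {
    report$core_signature <- unique(unlist(report$leading_edges))
  }
  if (length(report$core_signature) == 0) {
    report$status <- "no recurrent leading-edge genes"
    return(report)
  }
  scorer <- if (config$scoring_method == "geometric_mean") geometric_mean_score
            else zsum_score
  report$scores <- lapply(cohorts, function(em)
    scorer(em, report$core_signature, signature_name = "core_signature"))
  report
}

#' @export
print.DiscoveryReport <- function(x, ...) {
  cat("DiscoveryReport\n")
  cat("  status:        ", x$status, "\n")
  cat("  systems:       ", length(x$systems_de), "\n")
  cat("  candidates:    ", length(x$candidates), "\n")
  cat("  core signature:", length(x$core_signature),
      if (length(x$core_signature))
        paste0("(", paste(utils::head(x$core_signature, 8), collapse = ", "),
               if (length(x$core_signature) > 8) ", ..." else "", ")")
      else "", "\n")
  invisible(x)
}

#' Serialize a discovery report to JSON and TSV tables
#'
#' Writes `report.json` (status, thresholds, candidate and core gene lists,
#' per-cohort enrichment statistics) plus per-system DE TSVs, a per-cohort
#' GSEA summary TSV and per-cohort score TSVs into `dir`.
#'
#' @param report A `DiscoveryReport`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_discovery_report <- function(report, dir) {
  stopifnot(inherits(report, "DiscoveryReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(report$systems_de)) {
    de <- report$systems_de[[i]]
    if (is.null(de)) next
    utils::write.table(de, file.path(dir, sprintf("de_system%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gsea_tab <- NULL
  if (!is.null(report$gsea)) {
    gsea_tab <- do.call(rbind, lapply(seq_along(report$gsea), function(i) {
      g <- report$gsea[[i]]
      if (is.null(g)) return(NULL)
      data.frame(cohort = i, es = g$es, nes = g$nes, p_value = g$p_value,
                 n_leading_edge = length(g$leading_edge),
                 leading_edge = paste(g$leading_edge, collapse = ","))
    }))
    if (!is.null(gsea_tab))
      utils::write.table(gsea_tab, file.path(dir, "gsea_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$scores)) {
    for (i in seq_along(report$scores)) {
      st <- report$scores[[i]]
      utils::write.table(
        data.frame(sample_id = names(st$scores), score = unname(st$scores)),
        file.path(dir, sprintf("scores_cohort%d.tsv", i)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  json <- list(status = report$status,
               config = unclass(report$config),
               candidates = as.character(report$candidates),
               core_signature = as.character(report$core_signature),
               gsea = if (is.null(gsea_tab)) NULL else
                 gsea_tab[, c("cohort", "es", "nes", "p_value")])
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
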