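# Stage 3a: per-sample signature scores, group comparison, the logistic
# status classifier and ROC/AUC evaluation.

score_table <- function(scores, method, signature_name, genes_used) {
  structure(list(scores = scores, method = method,
                 signature = signature_name, genes_used = genes_used),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat(sprintf("ScoreTable (%s, signature '%s', %d genes, %d samples)\n",
              x$method, x$signature, length(x$genes_used), length(x$scores)))
  invisible(x)
}

check_signature_coverage <- function(matrix, genes, min_coverage) {
  genes <- unique(toupper(genes))
  present <- intersect(genes, rownames(matrix$values))
  if (length(present) == 0)
    stop("no signature gene present in the matrix", call. = FALSE)
  cov <- length(present) / length(genes)
  if (cov < min_coverage)
    stop(sprintf("signature coverage %.2f below minimum %.2f", cov, min_coverage),
         call. = FALSE)
  if (length(present) < length(genes))
    warning(sprintf("%d of %d signature genes absent; score renormalized over %d genes",
                    length(genes) - length(present), length(genes),
                    length(present)), call. = FALSE)
  present
}

#' Geometric-mean signature score
#'
#' Per sample, `2 ^ mean(log2 values over the present signature genes)` --
#' identical to the geometric mean of the linear-scale values. Missing
#' genes are excluded with the exponent renormalized (warning), subject to
#' a minimum-coverage fraction.
#'
#' @param matrix An `ExpressionMatrix` (log2 scale).
#' @param genes Signature gene symbols.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present (default 0.75).
#' @param signature_name Label stored in the result.
#' @return A `ScoreTable` (named per-sample scores, linear scale).
#' @export
geometric_mean_score <- function(matrix, genes, min_coverage = 0.75,
                                 signature_name = "signature") {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  present <- check_signature_coverage(matrix, genes, min_coverage)
  sc <- 2^colMeans(matrix$values[present, , drop = FALSE])
  score_table(sc, "geometric_mean", signature_name, present)
}

#' z-summation signature score
#'
#' Each gene is standardized across samples (mean 0, sd 1); the score is the
#' sum of standardized values over the signature genes. Zero-variance genes
#' are excluded with a warning.
#'
#' @inheritParams geometric_mean_score
#' @return A `ScoreTable`.
#' @export
zsum_score <- function(matrix, genes, min_coverage = 0.75,
                       signature_name = "signature") {
  stopifnot(inherits(matrix, "ExpressionMatrix"), ncol(matrix$values) >= 2)
  present <- check_signature_coverage(matrix, genes, min_coverage)
  sub <- matrix$values[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance gene(s) excluded from z-summation",
                    sum(sds == 0)), call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(sub) == 0) stop("no gene with non-zero variance", call. = FALSE)
  }
  z <- (sub - rowMeans(sub)) / sds
  score_table(colSums(z), "zsum", signature_name, rownames(sub))
}

#' Two-sample t-test on signature scores
#'
#' Two-sided pooled-variance Student t between the two phenotype groups.
#'
#' @param scores A `ScoreTable`.
#' @param labels Named phenotype map (sample id -> group label) with exactly
#'   two groups among the scored samples.
#' @return List with `t`, `p_value`, `group_means`, `df`.
#' @export
score_group_ttest <- function(scores, labels) {
  stopifnot(inherits(scores, "ScoreTable"))
  lab <- labels[names(scores$scores)]
  if (any(is.na(lab))) stop("labels missing for some scored samples", call. = FALSE)
  groups <- unique(lab)
  if (length(groups) != 2)
    stop("need exactly two non-empty groups, got ", length(groups), call. = FALSE)
  a <- scores$scores[lab == groups[1]]
  b <- scores$scores[lab == groups[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("need >=2 samples per group", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       group_means = stats::setNames(c(mean(a), mean(b)), groups),
       df = unname(tt$parameter))
}

#' Single-feature logistic status classifier
#'
#' Logistic regression of binary status on the signature score, fit by
#' iteratively reweighted least squares. Complete separation is detected
#' (diverging slope / fitted probabilities pinned at 0 or 1) and reported as
#' a flagged fit rather than an error.
#'
#' @param scores A `ScoreTable`.
#' @param labels Named binary map (sample id -> label); the second level of
#'   `factor(labels)` is coded 1.
#' @return List with `intercept`, `slope`, `fitted`, `separation` flag,
#'   `wald_p` (slope), and the positive-class label.
#' @export
fit_status_classifier <- function(scores, labels) {
  stopifnot(inherits(scores, "ScoreTable"))
  lab <- labels[names(scores$scores)]
  if (any(is.na(lab))) stop("labels missing for some scored samples", call. = FALSE)
  f <- factor(lab)
  if (nlevels(f) != 2) stop("both classes must be present", call. = FALSE)
  y <- as.integer(f) - 1L
  x <- as.numeric(scores$scores)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (!separation && abs(cf[2]) > 1e3) separation <- TRUE
  sm <- summary(fit)$coefficients
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       fitted = stats::setNames(fit$fitted.values, names(scores$scores)),
       separation = separation,
       wald_p = unname(sm[2, 4]),
       positive_class = levels(f)[2])
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties contributing 1/2;
#' ROC points from a threshold sweep over the unique scores (rule:
#' positive when score > threshold).
#'
#' @param scores A `ScoreTable` (higher score = more positive-like).
#' @param labels Named binary map; the second factor level is the positive
#'   class.
#' @return List with `auc` and a data frame `roc` of (`fpr`, `tpr`) points.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(inherits(scores, "ScoreTable"))
  lab <- labels[names(scores$scores)]
  if (any(is.na(lab))) stop("labels missing for some scored samples", call. = FALSE)
  f <- factor(lab)
  if (nlevels(f) != 2) stop("both classes must be present", call. = FALSE)
  y <- as.integer(f) - 1L
  x <- as.numeric(scores$scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(x)   # midranks: ties contribute 1/2 to the AUC
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(x))
  roc <- data.frame(
    threshold = c(-Inf, thr),
    tpr = vapply(c(-Inf, thr), function(t) mean(x[y == 1] > t), numeric(1)),
    fpr = vapply(c(-Inf, thr), function(t) mean(x[y == 0] > t), numeric(1)))
  list(auc = auc, roc = roc, positive_class = levels(f)[2])
}
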