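# Survival analysis: Kaplan-Meier estimation, Mantel-Cox log-rank testing,
# multivariate Cox proportional hazards (Efron ties) and signature-based
# high/low stratification. Model fitting is delegated to the survival
# package; this module defines the validated table type, the stratification
# rule and tidy result surfaces.

#' Construct a validated survival table
#'
#' @param df Data frame with required columns `sample_id`, `time` (> 0) and
#'   `event` (0 = censored, 1 = event), plus optional covariates `age`
#'   (years), `sex` (binary coded), `stage` (ordinal numeric), `status`
#'   (e.g. `"KRAS_mut"`/`"KRAS_wt"`) and `score` (real signature score).
#' @return Object of class `SurvivalTable` (a data frame) with attribute
#'   `covariates_present` listing which optional columns are available.
#' @export
survival_table <- function(df) {
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  bad_e <- which(!df$event %in% c(0, 1))
  if (length(bad_t))
    stop("non-positive or missing time at row(s): ",
         paste(utils::head(bad_t, 10), collapse = ", "), call. = FALSE)
  if (length(bad_e))
    stop("event must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_e, 10), collapse = ", "), call. = FALSE)
  optional <- c("age", "sex", "stage", "status", "score")
  present <- intersect(optional, names(df))
  structure(as.data.frame(df), covariates_present = present,
            class = c("SurvivalTable", "data.frame"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param table A `SurvivalTable`.
#' @return Data frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (the product-limit estimate
#'   S(t)).
#' @export
km_estimate <- function(table) {
  stopifnot(inherits(table, "SurvivalTable"), nrow(table) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Mantel-Cox log-rank test between two groups
#'
#' At each distinct event time the expected events per group come from the
#' hypergeometric mean and the variance from the hypergeometric variance;
#' the statistic is chi-square with 1 df.
#'
#' @param table A `SurvivalTable`.
#' @param group Vector of two group labels, one per row of `table` (or the
#'   name of a column of `table`).
#' @return List with `chisq`, `p_value`, and a per-group data frame of
#'   observed and expected event counts.
#' @export
logrank_test <- function(table, group) {
  stopifnot(inherits(table, "SurvivalTable"))
  if (is.character(group) && length(group) == 1 && group %in% names(table))
    group <- table[[group]]
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  if (sum(table$event) == 0)
    stop("no events observed; log-rank test undefined", call. = FALSE)
  d <- data.frame(time = table$time, event = table$event, g = group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  list(chisq = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       groups = data.frame(group = levels(droplevels(group)),
                           n = as.vector(sd_$n),
                           observed = as.vector(sd_$obs),
                           expected = as.vector(sd_$exp)))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial likelihood maximized with the Efron tie correction. Absent or
#' constant covariates are rejected; non-convergence or an infinite
#' coefficient (monotone likelihood / separation) is reported as a flagged
#' fit rather than an error.
#'
#' @param table A `SurvivalTable`.
#' @param covariates Character vector of column names to include (e.g.
#'   `c("score", "age", "sex", "stage")`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `CoxFit`: list with a coefficient data frame
#'   (`beta`, `hr`, `ci_lower`, `ci_upper`, `p_value` per covariate), the
#'   model log partial likelihood, iteration count and a `flagged` logical
#'   with `flag_reason`.
#' @export
cox_fit <- function(table, covariates, ties = c("efron", "breslow")) {
  stopifnot(inherits(table, "SurvivalTable"))
  ties <- match.arg(ties)
  if (sum(table$event) < 1) stop("Cox fit needs >=1 event", call. = FALSE)
  miss <- setdiff(covariates, names(table))
  if (length(miss))
    stop("covariate(s) absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- table[, covariates, drop = FALSE]
  for (cv in covariates) {
    x <- X[[cv]]
    if (!is.numeric(x)) x <- as.numeric(as.factor(x)) - 1
    if (length(unique(x)) < 2)
      stop("covariate is constant: ", cv, call. = FALSE)
    X[[cv]] <- x
  }
  d <- cbind(data.frame(time = table$time, event = table$event), X)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  flagged <- FALSE; reason <- NA_character_
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|converge|beta may be infinite",
                conditionMessage(w))) {
        flagged <<- TRUE; reason <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  co <- data.frame(covariate = covariates,
                   beta = unname(stats::coef(fit)),
                   se = unname(s$coefficients[, "se(coef)"]),
                   hr = unname(exp(stats::coef(fit))),
                   ci_lower = unname(exp(stats::coef(fit) - 1.96 * s$coefficients[, "se(coef)"])),
                   ci_upper = unname(exp(stats::coef(fit) + 1.96 * s$coefficients[, "se(coef)"])),
                   p_value = unname(s$coefficients[, "Pr(>|z|)"]))
  structure(list(coefficients = co,
                 loglik = fit$loglik[2],
                 score_test = unname(s$sctest["test"]),
                 iterations = fit$iter,
                 flagged = flagged, flag_reason = reason,
                 ties = ties),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties)%s\n", x$ties,
              if (x$flagged) " [FLAGGED]" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Dichotomize patients by signature score
#'
#' Labels each patient `"high"` when the score strictly exceeds the
#' within-stratum quantile threshold (ties at the threshold go to `"low"`).
#' When `stratify_by_status = TRUE` the threshold is computed separately
#' within each mutation-status group, mirroring the genotype-stratified
#' Kaplan-Meier panels.
#'
#' @param table A `SurvivalTable` with a `score` column.
#' @param quantile Dichotomization quantile in (0, 1); default median split.
#' @param stratify_by_status Compute thresholds within each `status` group?
#' @return Character vector (`"high"`/`"low"`), one per row.
#' @export
stratify_by_score <- function(table, quantile = 0.5, stratify_by_status = FALSE) {
  stopifnot(inherits(table, "SurvivalTable"))
  if (!"score" %in% names(table)) stop("table has no `score` column", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("`quantile` must be in (0, 1)", call. = FALSE)
  split_one <- function(sc) {
    if (length(unique(sc)) < 2)
      stop("cannot stratify: scores are constant", call. = FALSE)
    thr <- stats::quantile(sc, probs = quantile, names = FALSE, type = 7)
    ifelse(sc > thr, "high", "low")
  }
  if (stratify_by_status) {
    if (!"status" %in% names(table))
      stop("stratified split requested but no `status` column", call. = FALSE)
    out <- character(nrow(table))
    for (st in unique(table$status)) {
      idx <- which(table$status == st)
      out[idx] <- split_one(table$score[idx])
    }
    out
  } else {
    split_one(table$score)
  }
}
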