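# Synthetic-data generators emulating the statistical structure the pipeline
# assumes: multiple cohorts sharing a planted set of genotype-associated
# genes, censored survival linked to a signature score, and median-effect
# dose-response curves. All generators are pure functions of their parameters
# (including the seed).

#' Simulation parameters for the multi-cohort expression generator
#'
#' Defaults describe the study conditions under which the pipeline is
#' exercised: 2000 genes of which 20 carry a +1.5 log2 shift in mutant
#' samples, Gaussian log2-scale noise of sd 0.5, 10 samples per genotype
#' group, three discovery systems and four validation cohorts whose planted
#' effect is attenuated to model cross-dataset heterogeneity.
#'
#' @param n_genes Total genes.
#' @param n_planted Number of planted genotype-associated genes.
#' @param planted_log2fc Planted mutant-minus-wild-type shift (log2 units).
#' @param noise_sd Gaussian noise sd (log2 units).
#' @param n_per_group Samples per phenotype group per matrix (>= 2).
#' @param n_systems Discovery systems.
#' @param n_cohorts Validation cohorts.
#' @param cohort_effect_attenuation Multiplier in (0, 1] applied to the
#'   planted effect in cohorts.
#' @param baseline_mean Mean per-gene baseline expression (log2 units).
#' @param seed Integer RNG seed.
#' @return Validated list of class `SimulationParams`.
#' @export
simulation_params <- function(n_genes = 2000, n_planted = 20,
                              planted_log2fc = 1.5, noise_sd = 0.5,
                              n_per_group = 10, n_systems = 3, n_cohorts = 4,
                              cohort_effect_attenuation = 0.7,
                              baseline_mean = 7, seed = 7) {
  stopifnot(n_planted <= n_genes, noise_sd > 0, n_per_group >= 2,
            n_systems >= 1, n_cohorts >= 0,
            cohort_effect_attenuation > 0, cohort_effect_attenuation <= 1)
  structure(list(n_genes = n_genes, n_planted = n_planted,
                 planted_log2fc = planted_log2fc, noise_sd = noise_sd,
                 n_per_group = n_per_group, n_systems = n_systems,
                 n_cohorts = n_cohorts,
                 cohort_effect_attenuation = cohort_effect_attenuation,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "SimulationParams")
}

sim_gene_names <- function(n) sprintf("G%05d", seq_len(n))

sim_one_matrix <- function(prefix, baselines, planted, effect, noise_sd,
                           n_per_group, group_a = "KRAS_mut",
                           group_b = "KRAS_wt") {
  n_genes <- length(baselines)
  n <- 2 * n_per_group
  vals <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n) + baselines
  vals[planted, seq_len(n_per_group)] <-
    vals[planted, seq_len(n_per_group)] + effect
  sids <- c(sprintf("%s_MUT_%02d", prefix, seq_len(n_per_group)),
            sprintf("%s_WT_%02d", prefix, seq_len(n_per_group)))
  dimnames(vals) <- list(names(baselines), sids)
  pheno <- stats::setNames(rep(c(group_a, group_b), each = n_per_group), sids)
  expression_matrix(vals, pheno)
}

#' Simulate multiple discovery systems and validation cohorts
#'
#' Every matrix shares the same gene universe and per-gene baselines. Planted
#' genes are shifted by `planted_log2fc` in mutant samples of the discovery
#' systems and by `planted_log2fc * cohort_effect_attenuation` in the
#' cohorts; non-planted genes are exchangeable between groups.
#'
#' @param params A [simulation_params()] object.
#' @return List with `systems` (list of `ExpressionMatrix`), `cohorts`
#'   (list of `ExpressionMatrix`) and `truth` (planted gene symbols).
#' @export
simulate_multi_cohort <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  genes <- sim_gene_names(params$n_genes)
  baselines <- stats::setNames(
    stats::rnorm(params$n_genes, mean = params$baseline_mean, sd = 1), genes)
  planted <- sort(sample.int(params$n_genes, params$n_planted))
  # keep planted genes comfortably above the expression floor so discovery
  # power reflects the effect size, not the filter
  baselines[planted] <- pmax(baselines[planted], params$baseline_mean - 1)
  systems <- lapply(seq_len(params$n_systems), function(i)
    sim_one_matrix(sprintf("SYS%d", i), baselines, planted,
                   params$planted_log2fc, params$noise_sd, params$n_per_group))
  cohorts <- if (params$n_cohorts > 0)
    lapply(seq_len(params$n_cohorts), function(i)
      sim_one_matrix(sprintf("COH%d", i), baselines, planted,
                     params$planted_log2fc * params$cohort_effect_attenuation,
                     params$noise_sd, params$n_per_group))
  else list()
  list(systems = systems, cohorts = cohorts, truth = genes[planted])
}

#' Simulate censored survival times linked to a signature score
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(beta * (score - mean(score)))`; censoring times are
#' independent exponentials with rate `censor_rate` (no censoring when 0).
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param beta Log-hazard per unit of (centered) score.
#' @param baseline_rate Baseline event rate (> 0), events per time unit.
#' @param censor_rate Censoring rate (>= 0).
#' @param seed Integer RNG seed.
#' @return A [survival_table()] carrying the scores.
#' @export
simulate_survival <- function(scores, beta, baseline_rate = 0.1,
                              censor_rate = 0.02, seed = 1) {
  stopifnot(baseline_rate > 0, censor_rate >= 0)
  set.seed(as.integer(seed))
  n <- length(scores)
  if (is.null(names(scores))) names(scores) <- sprintf("P%04d", seq_len(n))
  hz <- baseline_rate * exp(beta * (scores - mean(scores)))
  t_event <- stats::rexp(n, rate = hz)
  t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else rep(Inf, n)
  survival_table(data.frame(sample_id = names(scores),
                            time = pmin(t_event, t_cens),
                            event = as.numeric(t_event <= t_cens),
                            score = as.numeric(scores)))
}

#' Simulate a single-drug dose-response curve from the median-effect equation
#'
#' Fractions affected follow `fa/(1-fa) = (D/Dm)^m`, optionally perturbed by
#' Gaussian noise on the logit scale and clamped to (0.001, 0.999).
#'
#' @param m Median-effect slope (> 0).
#' @param dm Median-effect dose (> 0), the dose giving 50% effect.
#' @param doses Positive dose vector.
#' @param fa_noise_sd Gaussian sd on logit(fa); 0 for noise-free curves.
#' @param seed Integer RNG seed (ignored when `fa_noise_sd = 0`).
#' @param drug Drug identifier.
#' @return Object of class `DoseResponse`: list with `drug`, `doses`, `fa`.
#' @export
simulate_dose_response <- function(m, dm, doses, fa_noise_sd = 0, seed = 1,
                                   drug = "drug") {
  stopifnot(m > 0, dm > 0, all(doses > 0))
  lg <- m * (log10(doses) - log10(dm))   # logit10 of fa
  if (fa_noise_sd > 0) {
    set.seed(as.integer(seed))
    lg <- lg + stats::rnorm(length(doses), sd = fa_noise_sd)
  }
  fa <- 10^lg / (1 + 10^lg)
  fa <- pmin(pmax(fa, 0.001), 0.999)
  structure(list(drug = drug, doses = as.numeric(doses), fa = fa),
            class = "DoseResponse")
}

#' Simulate a knockdown-versus-control expression experiment
#'
#' Two groups (`sh_target` vs `sh_control`); `n_down` genes are shifted by
#' the (negative) `down_log2fc` in the target group, emulating the
#' transcriptional footprint of silencing a transcription factor.
#'
#' @param params A [simulation_params()] (uses `n_genes`, `noise_sd`,
#'   `n_per_group`, `baseline_mean`, `seed`).
#' @param n_down Number of downregulated genes.
#' @param down_log2fc Negative log2 shift applied in the target group.
#' @return List with `matrix` (`ExpressionMatrix`) and `truth` (gene symbols).
#' @export
simulate_knockdown_experiment <- function(params, n_down = 45,
                                          down_log2fc = -1.5) {
  stopifnot(inherits(params, "SimulationParams"), down_log2fc <= 0,
            n_down <= params$n_genes)
  set.seed(params$seed)
  genes <- sim_gene_names(params$n_genes)
  baselines <- stats::setNames(
    stats::rnorm(params$n_genes, mean = params$baseline_mean, sd = 1), genes)
  down <- sort(sample.int(params$n_genes, n_down))
  baselines[down] <- pmax(baselines[down], params$baseline_mean - 1)
  em <- sim_one_matrix("KD", baselines, down, down_log2fc, params$noise_sd,
                       params$n_per_group, group_a = "sh_target",
                       group_b = "sh_control")
  # relabel sample ids to match the contrast
  sids <- c(sprintf("KD_SH_%02d", seq_len(params$n_per_group)),
            sprintf("KD_CTRL_%02d", seq_len(params$n_per_group)))
  colnames(em$values) <- sids
  names(em$phenotype) <- sids
  list(matrix = expression_matrix(em$values, em$phenotype),
       truth = genes[down])
}
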