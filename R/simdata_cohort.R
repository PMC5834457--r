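#' Parameters for a simulated patient cohort
#'
#' Defines the generative model for a TMA cohort: a true case-level stromal
#' inflammation (SI) fraction per patient, two per-core SI targets (case SI
#' plus heterogeneity noise, reflecting intratumoral heterogeneity between
#' the two cores sampled per case), clinical covariates, a PD-L1 tumor
#' proportion score with a point mass at 0.00 and a weak rank association
#' with SI, and overall survival drawn from a proportional-hazards model with
#' exponential baseline whose log-hazard is linear in true SI, stage, age,
#' vascular invasion, and a PD-L1-by-SI interaction.
#'
#' Default log hazard ratios follow the magnitudes reported for a multivariate
#' lung squamous cell carcinoma model: HR 0.32 per unit SI, 1.59 per stage
#' unit, 1.04 per year of age, 1.84 for vascular invasion, no interaction.
#'
#' @param n_cases Number of patients (>= 2).
#' @param log_hr_si Log hazard ratio per unit of SI proportion (default
#'   `log(0.32)`: higher inflammation, lower hazard).
#' @param log_hr_stage,log_hr_age,log_hr_vascular Log hazard ratios per stage
#'   unit, per year of age, and for the presence of vascular invasion.
#' @param log_hr_interaction Log hazard ratio of the PD-L1-high-by-SI product
#'   term (0 = no effect modification).
#' @param baseline_hazard Baseline event rate, events/month.
#' @param censoring_rate Independent exponential censoring rate, events/month.
#' @param si_mean,si_sd Mean and SD of the true case SI; realized as a Beta
#'   distribution with these moments so SI stays in `[0, 1]` without clipping.
#' @param core_heterogeneity_sd SD of per-core SI around the case SI
#'   (Gaussian, clipped to `[0, 1]`).
#' @param si_pdl1_rho Target Spearman correlation between SI and PD-L1,
#'   in `(-1, 1)`.
#' @param pdl1_zero_mass Probability that a case's PD-L1 proportion is
#'   exactly 0.00 (the "PD-L1 low" stratum).
#' @param seed Integer seed.
#' @return Object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_cases = 200L,
                              log_hr_si = log(0.32),
                              log_hr_stage = log(1.59),
                              log_hr_age = log(1.04),
                              log_hr_vascular = log(1.84),
                              log_hr_interaction = 0,
                              baseline_hazard = 0.015,
                              censoring_rate = 0.008,
                              si_mean = 0.25,
                              si_sd = 0.20,
                              core_heterogeneity_sd = 0.20,
                              si_pdl1_rho = 0.20,
                              pdl1_zero_mass = 0.60,
                              seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 2)
    stop("'n_cases' must be >= 2", call. = FALSE)
  if (baseline_hazard <= 0 || censoring_rate <= 0)
    stop("'baseline_hazard' and 'censoring_rate' must be > 0", call. = FALSE)
  if (si_pdl1_rho <= -1 || si_pdl1_rho >= 1)
    stop("'si_pdl1_rho' must be in (-1, 1)", call. = FALSE)
  stopifnot_scalar01(pdl1_zero_mass, "pdl1_zero_mass")
  if (si_sd^2 >= si_mean * (1 - si_mean))
    stop("'si_sd' too large for a Beta distribution with mean 'si_mean'", call. = FALSE)
  structure(as.list(environment()), class = "cohort_sim_params")
}

# Beta shape parameters matching a given mean and SD.
beta_moments <- function(m, s) {
  nu <- m * (1 - m) / s^2 - 1
  c(a = m * nu, b = (1 - m) * nu)
}

# PD-L1 marginal: point mass at 0 with probability p0, else a Beta(0.8, 4)
# quantile of the conditional uniform (small proportions dominate).
pdl1_from_uniform <- function(u, p0) {
  q <- pmax((u - p0) / max(1 - p0, 1e-12), 0)
  ifelse(u <= p0, 0, stats::qbeta(q, 0.8, 4))
}

# Latent Gaussian-copula correlation that yields the target Spearman rho
# between SI and the zero-inflated PD-L1 score. The point mass at 0 ties the
# lower tail of the PD-L1 ranks and attenuates the achievable correlation;
# we invert the attenuation by a deterministic Monte-Carlo root-find.
calibrate_latent_rho <- function(target, p0, n = 40000L) {
  if (target == 0 || p0 >= 1) return(0)
  with_seed(742001L, {
    e0 <- stats::rnorm(n); e1 <- stats::rnorm(n)
    u0 <- stats::pnorm(e0)
    spearman_at <- function(r) {
      u <- stats::pnorm(r * e0 + sqrt(1 - r^2) * e1)
      # large-n Spearman with midranks for the tied zeros
      s <- ifelse(u <= p0, p0 / 2, u)
      stats::cor(u0, s)
    }
    hi <- spearman_at(0.999)
    if (abs(target) >= abs(hi)) {
      warning(sprintf(
        "target si_pdl1_rho %.2f exceeds the maximum achievable %.2f given pdl1_zero_mass; using the maximum",
        target, hi))
      return(sign(target) * 0.999)
    }
    stats::uniroot(function(r) spearman_at(r) - target,
                   interval = c(-0.999, 0.999), tol = 1e-4)$root
  })
}

#' Simulate a TMA cohort
#'
#' Draws the case table (true SI, per-core SI targets, covariates, PD-L1,
#' censored survival) and the per-core image-simulation parameters whose
#' inflammatory density equals each core's SI target.
#'
#' @param params A [cohort_sim_params()] object.
#' @param image_template An [image_sim_params()] object used as template for
#'   the per-core image parameters; its `stromal_inflammation_density` and
#'   `seed` are overridden per core.
#' @return List of class `cohort_sim` with:
#'   \describe{
#'     \item{cases}{data.frame with columns `case_id`, `core1_path`,
#'       `core2_path` (NA until images are written), `time_months`, `event`,
#'       `stage`, `age`, `vascular_invasion`, `pleural_invasion`, `grade`,
#'       `pdl1`, `true_si`, `si_core1_true`, `si_core2_true`.}
#'     \item{image_params}{list of per-case lists with elements `core1` and
#'       `core2`, each an `image_sim_params`.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' ch <- generate_cohort(cohort_sim_params(n_cases = 50, seed = 3))
#' head(ch$cases)
#' @export
generate_cohort <- function(params = cohort_sim_params(),
                            image_template = image_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  with_seed(params$seed, {
    n <- as.integer(params$n_cases)
    sh <- beta_moments(params$si_mean, params$si_sd)

    # SI and PD-L1 through a Gaussian copula with calibrated latent correlation
    r_lat <- calibrate_latent_rho(params$si_pdl1_rho, params$pdl1_zero_mass)
    z_si <- stats::rnorm(n)
    z_p <- r_lat * z_si + sqrt(1 - r_lat^2) * stats::rnorm(n)
    true_si <- stats::qbeta(stats::pnorm(z_si), sh["a"], sh["b"])
    pdl1 <- pdl1_from_uniform(stats::pnorm(z_p), params$pdl1_zero_mass)

    # per-core SI targets: case SI + heterogeneity noise, clipped to [0, 1]
    si_core1 <- pmin(pmax(true_si + stats::rnorm(n, 0, params$core_heterogeneity_sd), 0), 1)
    si_core2 <- pmin(pmax(true_si + stats::rnorm(n, 0, params$core_heterogeneity_sd), 0), 1)

    stage <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.30, 0.25, 0.10))
    age <- round(pmin(pmax(stats::rnorm(n, 67, 9), 40), 90))
    vascular <- stats::rbinom(n, 1, 0.35)
    pleural <- stats::rbinom(n, 1, 0.40)
    grade <- sample(1:3, n, replace = TRUE, prob = c(0.20, 0.60, 0.20))

    lp <- params$log_hr_si * true_si +
      params$log_hr_stage * (stage - 2) +
      params$log_hr_age * (age - 65) +
      params$log_hr_vascular * vascular +
      params$log_hr_interaction * true_si * (pdl1 > 0)
    t_event <- stats::rexp(n, rate = params$baseline_hazard * exp(lp))
    t_cens <- stats::rexp(n, rate = params$censoring_rate)
    time_months <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    if (sum(event) == 0L)
      warning("all cases censored; survival analyses will not be possible")

    cases <- data.frame(
      case_id = sprintf("case_%04d", seq_len(n)),
      core1_path = NA_character_, core2_path = NA_character_,
      time_months = time_months, event = event,
      stage = stage, age = age,
      vascular_invasion = vascular, pleural_invasion = pleural,
      grade = grade, pdl1 = pdl1, true_si = true_si,
      si_core1_true = si_core1, si_core2_true = si_core2,
      stringsAsFactors = FALSE
    )

    image_params <- lapply(seq_len(n), function(i) {
      mk <- function(core, dens) {
        p <- image_template
        p$stromal_inflammation_density <- dens
        p$seed <- as.integer(sub_seed(params$seed, 1000L + 2L * i + core))
        p
      }
      list(core1 = mk(0L, si_core1[i]), core2 = mk(1L, si_core2[i]))
    })

    structure(list(cases = cases, image_params = image_params, params = params),
              class = "cohort_sim")
  })
}

#' Write a simulated case table as TSV
#'
#' @param cohort A `cohort_sim` object or its `cases` data.frame.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- if (inherits(cohort, "cohort_sim")) cohort$cases else cohort
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a gene-expression matrix linked to SI
#'
#' The first `n_linked` genes are linear in the case SI score with unit
#' Gaussian noise; the remaining genes are independent noise. Used as
#' substrate for the SI-expression correlation screen.
#'
#' @param n_genes Total number of genes.
#' @param n_linked Number of SI-linked genes (`<= n_genes`).
#' @param effect_sd Slope of the linked genes on standardized SI (in noise-SD
#'   units); larger values give stronger correlations.
#' @param case_si Numeric vector of case SI scores (one per case).
#' @param seed Integer seed.
#' @return Numeric matrix genes x cases, rownames `gene_0001...`, with
#'   attribute `linked_genes` naming the linked set.
#' @export
simulate_expression <- function(n_genes, n_linked, effect_sd, case_si, seed = 1L) {
  if (n_linked > n_genes) stop("'n_linked' must be <= 'n_genes'", call. = FALSE)
  n_cases <- length(case_si)
  with_seed(seed, {
    expr <- matrix(stats::rnorm(n_genes * n_cases), n_genes, n_cases)
    si_std <- if (stats::sd(case_si) > 0) as.numeric(scale(case_si)) else case_si * 0
    if (n_linked > 0)
      expr[seq_len(n_linked), ] <- expr[seq_len(n_linked), , drop = FALSE] +
        matrix(effect_sd * si_std, n_linked, n_cases, byrow = TRUE)
    rownames(expr) <- sprintf("gene_%04d", seq_len(n_genes))
    colnames(expr) <- sprintf("case_%04d", seq_len(n_cases))
    attr(expr, "linked_genes") <- rownames(expr)[seq_len(n_linked)]
    expr
  })
}
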