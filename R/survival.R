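# The downstream survival battery: cohort filtering, Kaplan-Meier median
# splits, univariate/multivariate proportional-hazards models, the
# PD-L1-by-SI interaction, and the delta-value heterogeneity subgroups.
# All fits go through the survival package with the Breslow tie convention.

#' Filter a cohort for survival analysis
#'
#' Removes cases that survived less than `min_months` after surgery
#' (immediate post-operative deaths carry no biomarker information).
#'
#' @param cohort data.frame with at least `time_months`.
#' @param min_months Exclusion threshold in months (default 1).
#' @return The filtered data.frame with attribute `n_removed`; errors if no
#'   cases remain.
#' @export
filter_cohort <- function(cohort, min_months = 1) {
  stopifnot("time_months" %in% names(cohort))
  keep <- cohort$time_months >= min_months
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no cases remain after the survival-time filter", call. = FALSE)
  message(sprintf("excluded %d case(s) with survival < %g month(s)", sum(!keep), min_months))
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Shared coxph wrapper: Breslow ties, convergence flagged, never stochastic.
fit_cph <- function(formula, data, ties = "breslow") {
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = ties),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  list(fit = fit, warning = warn)
}

# Turn a coxph fit into a model-report data.frame (one row per variable).
cph_report <- function(fit, model_type, warning = NULL) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- data.frame(
    variable = rownames(co),
    hr = co[, "exp(coef)"],
    ci_lower = ci[, "lower .95"],
    ci_upper = ci[, "upper .95"],
    p = co[, "Pr(>|z|)"],
    model = model_type,
    n = s$n,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("si_model_report", "data.frame"),
            converged = is.null(warning), warning = warning)
}

#' @export
print.si_model_report <- function(x, ...) {
  cat(sprintf("Proportional-hazards model report (%s, n = %d)\n",
              x$model[1], x$n[1]))
  if (!is.null(attr(x, "warning")))
    cat("  [flag] ", attr(x, "warning"), "\n")
  df <- data.frame(variable = x$variable,
                   `HR (95% CI)` = sprintf("%.2f (%.2f-%.2f)", x$hr, x$ci_lower, x$ci_upper),
                   `p` = signif(x$p, 2), check.names = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier analysis by median SI split
#'
#' Dichotomizes the cohort at the median SI score (high = strictly greater
#' than the median, low = at or below it), estimates the two product-limit
#' survival curves, and compares them with the log-rank test.
#'
#' @param cohort data.frame with `time_months`, `event` and the SI column.
#' @param si_col Name of the SI column (default `"si"`).
#' @return Object of class `si_km`: list with `fit` (a `survfit`), `logrank_p`,
#'   `group_sizes`, `median_survival` (months per group), `median_si`.
#' @export
km_by_median_si <- function(cohort, si_col = "si") {
  si <- cohort[[si_col]]
  ok <- !is.na(si) & !is.na(cohort$time_months) & !is.na(cohort$event)
  d <- cohort[ok, , drop = FALSE]
  si <- si[ok]
  if (length(unique(si)) < 2L)
    stop("all SI scores are equal; no median split possible", call. = FALSE)
  med <- stats::median(si)
  group <- factor(ifelse(si > med, "high", "low"), levels = c("low", "high"))
  if (any(table(group) < 2L))
    stop("fewer than 2 cases in a median-split group", call. = FALSE)
  d$si_group <- group
  fit <- survival::survfit(survival::Surv(time_months, event) ~ si_group, data = d)
  lr <- survival::survdiff(survival::Surv(time_months, event) ~ si_group, data = d)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  med_surv <- summary(fit)$table[, "median"]
  structure(list(fit = fit, logrank_p = p,
                 group_sizes = table(group),
                 median_survival = med_surv,
                 median_si = med),
            class = "si_km")
}

#' @export
print.si_km <- function(x, ...) {
  cat("Kaplan-Meier by median SI split\n")
  cat(sprintf("  median SI: %.3f; groups low/high: %d/%d\n",
              x$median_si, x$group_sizes["low"], x$group_sizes["high"]))
  ms <- x$median_survival
  cat(sprintf("  median survival (months) low/high: %.1f/%.1f\n", ms[1], ms[2]))
  cat(sprintf("  log-rank p = %.3g\n", x$logrank_p))
  invisible(x)
}

#' Univariate proportional-hazards model
#'
#' @param cohort data.frame with `time_months`, `event` and the variable.
#' @param variable Column name of the covariate (numeric or 0/1 coded;
#'   ordinal variables enter linearly).
#' @return One-row `si_model_report` (HR per unit, 95% CI, p, n).
#' @export
cph_univariate <- function(cohort, variable) {
  x <- cohort[[variable]]
  ok <- !is.na(x) & !is.na(cohort$time_months) & !is.na(cohort$event)
  d <- cohort[ok, , drop = FALSE]
  if (length(unique(d[[variable]])) < 2L)
    stop(sprintf("variable '%s' is constant", variable), call. = FALSE)
  if (sum(d$event) < 3L)
    stop("fewer than 3 events", call. = FALSE)
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~", variable))
  res <- fit_cph(f, d)
  rep <- cph_report(res$fit, "univariate", res$warning)
  rep$variable <- variable
  rep
}

#' Multivariate proportional-hazards model
#'
#' Joint model over the standard covariate set, fitted on complete cases,
#' with the report ordered by p-value (most significant first). Warns when
#' complete cases fall below 10 per covariate; flags aliased (collinear)
#' covariates.
#'
#' @param cohort data.frame with `time_months`, `event` and the covariates.
#' @param variables Covariate names; default
#'   `c("stage", "age", "vascular_invasion", "si", "pleural_invasion", "grade")`.
#' @return `si_model_report` with one row per covariate and attribute
#'   `n_complete`.
#' @export
cph_multivariate <- function(cohort,
                             variables = c("stage", "age", "vascular_invasion",
                                           "si", "pleural_invasion", "grade")) {
  stopifnot(all(variables %in% names(cohort)))
  keep <- stats::complete.cases(cohort[, c("time_months", "event", variables)])
  d <- cohort[keep, , drop = FALSE]
  if (nrow(d) < 10L * length(variables))
    warning(sprintf("only %d complete cases for %d covariates (guideline: >= %d)",
                    nrow(d), length(variables), 10L * length(variables)))
  X <- as.matrix(d[, variables, drop = FALSE])
  aliased <- qr(cbind(1, X))$rank < ncol(X) + 1L
  if (aliased) warning("collinear covariates detected; estimates may be unstable")
  f <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                               paste(variables, collapse = " + ")))
  res <- fit_cph(f, d)
  rep <- cph_report(res$fit, "multivariate", res$warning)
  rep <- rep[order(rep$p), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "n_complete") <- nrow(d)
  attr(rep, "collinear") <- aliased
  class(rep) <- c("si_model_report", "data.frame")
  rep
}

#' PD-L1-by-SI interaction analysis
#'
#' Tests whether PD-L1 expression modifies the prognostic value of SI: fits
#' a proportional-hazards model with SI, the PD-L1 stratum indicator, and
#' their product term, and runs a median-SI-split Kaplan-Meier analysis
#' within each PD-L1 stratum (median taken within stratum by default).
#'
#' @param cohort data.frame with `time_months`, `event`, `si`,
#'   `pdl1_stratum` (factor `"low"`/`"high"`).
#' @param global_median Use the cohort-wide median SI for the per-stratum
#'   splits instead of the within-stratum median (default FALSE).
#' @return Object of class `si_interaction`: list with `model`
#'   (`si_model_report` incl. the product term), `interaction_p`, and
#'   `stratum_km` (named list of `si_km` or NULL where a stratum lacks
#'   events).
#' @export
interaction_model <- function(cohort, global_median = FALSE) {
  stopifnot(all(c("si", "pdl1_stratum") %in% names(cohort)))
  ok <- !is.na(cohort$si) & !is.na(cohort$pdl1_stratum) &
    !is.na(cohort$time_months) & !is.na(cohort$event)
  d <- cohort[ok, , drop = FALSE]
  d$pdl1_high <- as.integer(d$pdl1_stratum == "high")
  if (length(unique(d$pdl1_high)) < 2L)
    stop("both PD-L1 strata must be non-empty", call. = FALSE)
  res <- fit_cph(survival::Surv(time_months, event) ~ si * pdl1_high, d)
  rep <- cph_report(res$fit, "interaction", res$warning)
  ip <- rep$p[rep$variable == "si:pdl1_high"]
  med_global <- stats::median(d$si)
  km <- lapply(c(low = "low", high = "high"), function(st) {
    ds <- d[d$pdl1_stratum == st, , drop = FALSE]
    if (sum(ds$event) == 0L) {
      warning(sprintf("PD-L1 %s stratum has no events; its KM analysis is skipped", st))
      return(NULL)
    }
    if (global_median) {
      grp <- factor(ifelse(ds$si > med_global, "high", "low"), levels = c("low", "high"))
      if (length(unique(grp)) < 2L || any(table(grp) < 2L)) return(NULL)
      ds$si_group <- grp
      fit <- survival::survfit(survival::Surv(time_months, event) ~ si_group, data = ds)
      lr <- survival::survdiff(survival::Surv(time_months, event) ~ si_group, data = ds)
      structure(list(fit = fit,
                     logrank_p = stats::pchisq(lr$chisq, 1, lower.tail = FALSE),
                     group_sizes = table(grp),
                     median_survival = summary(fit)$table[, "median"],
                     median_si = med_global), class = "si_km")
    } else {
      tryCatch(km_by_median_si(ds), error = function(e) NULL)
    }
  })
  structure(list(model = rep, interaction_p = ip, stratum_km = km),
            class = "si_interaction")
}

#' @export
print.si_interaction <- function(x, ...) {
  cat("PD-L1 x SI interaction analysis\n")
  cat(sprintf("  interaction p = %.3g\n", x$interaction_p))
  for (st in names(x$stratum_km)) {
    k <- x$stratum_km[[st]]
    if (is.null(k)) {
      cat(sprintf("  PD-L1 %s stratum: KM skipped\n", st))
    } else {
      cat(sprintf("  PD-L1 %s stratum: median-SI-split log-rank p = %.3g (n = %d)\n",
                  st, k$logrank_p, sum(k$group_sizes)))
    }
  }
  invisible(x)
}

#' Delta-value heterogeneity subgroup analysis
#'
#' Within the delta-low (homogeneous) and delta-high (heterogeneous)
#' subgroups, reports the univariate SI hazard ratio and the paired-core
#' Spearman correlation — checking whether intratumoral heterogeneity
#' erodes the prognostic value of the score.
#'
#' @param cohort data.frame with `time_months`, `event`, `si`, `delta`,
#'   `si_core1`, `si_core2`.
#' @return data.frame, one row per subgroup: `subgroup`, `n`, `n_events`,
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `paired_core_rho`.
#' @export
subgroup_analysis <- function(cohort) {
  stopifnot(all(c("si", "delta", "si_core1", "si_core2") %in% names(cohort)))
  strata <- split_by_median(cohort$delta)
  out <- lapply(c("low", "high"), function(st) {
    ds <- cohort[!is.na(strata) & strata == st, , drop = FALSE]
    rho <- spearman_or_na(ds$si_core1, ds$si_core2, warn = FALSE)
    if (sum(ds$event, na.rm = TRUE) < 3L || length(unique(ds$si)) < 2L) {
      return(data.frame(subgroup = st, n = nrow(ds),
                        n_events = sum(ds$event, na.rm = TRUE),
                        hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, paired_core_rho = rho,
                        stringsAsFactors = FALSE))
    }
    rep <- cph_univariate(ds, "si")
    data.frame(subgroup = st, n = nrow(ds), n_events = sum(ds$event),
               hr = rep$hr, ci_lower = rep$ci_lower, ci_upper = rep$ci_upper,
               p = rep$p, paired_core_rho = rho, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export Kaplan-Meier curves as a data.frame
#'
#' @param km An `si_km` object.
#' @return data.frame: `time`, `survival`, `n_risk`, `group`.
#' @export
km_curves <- function(km) {
  stopifnot(inherits(km, "si_km"))
  s <- summary(km$fit)
  data.frame(time = s$time, survival = s$surv, n_risk = s$n.risk,
             group = sub("^si_group=", "", as.character(s$strata)),
             stringsAsFactors = FALSE)
}
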