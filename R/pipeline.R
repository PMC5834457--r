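# End-to-end pipeline: simulate -> segment -> extract -> screen -> score ->
# survival, with a validated config, seeded substreams per stage, and a
# manifest of every output file.

#' Build a pipeline run configuration
#'
#' @param n_cases Number of simulated cases.
#' @param image Image-simulation template, an [image_sim_params()].
#' @param cohort Cohort-simulation parameters, a [cohort_sim_params()];
#'   its `n_cases` and `seed` are overridden by this config.
#' @param n_train_images Cores used to train the compartment classifier.
#' @param target_size Superpixel size in pixels.
#' @param n_perm Permutations for the feature screen.
#' @param fdr FDR threshold for the screen.
#' @param seed Master seed; every stage derives its own substream.
#' @param write_images Write PNG cores and TIFF masks to the run directory
#'   (default FALSE: masks are kept in memory only).
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(n_cases = 60L,
                       image = image_sim_params(),
                       cohort = cohort_sim_params(),
                       n_train_images = 2L,
                       target_size = 8,
                       n_perm = 200L,
                       fdr = 0.05,
                       seed = 1L,
                       write_images = FALSE) {
  structure(list(n_cases = as.integer(n_cases), image = image, cohort = cohort,
                 n_train_images = as.integer(n_train_images),
                 target_size = target_size, n_perm = as.integer(n_perm),
                 fdr = fdr, seed = as.integer(seed),
                 write_images = isTRUE(write_images)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A `run_config` (or plain list with the same fields).
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_run_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$n_cases) && length(config$n_cases) == 1 && config$n_cases >= 2,
      "n_cases: must be a single integer >= 2")
  chk(is.numeric(config$fdr) && length(config$fdr) == 1 &&
        config$fdr > 0 && config$fdr < 1,
      "fdr: must lie in (0, 1)")
  chk(is.numeric(config$n_perm) && config$n_perm >= 100,
      "n_perm: must be >= 100")
  chk(is.numeric(config$target_size) && config$target_size >= 5,
      "target_size: must be >= 5 pixels")
  chk(is.numeric(config$n_train_images) && config$n_train_images >= 1,
      "n_train_images: must be >= 1")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed: must be a single integer")
  chk(inherits(config$image, "image_sim_params"),
      "image: must be an image_sim_params object")
  chk(inherits(config$cohort, "cohort_sim_params"),
      "cohort: must be a cohort_sim_params object")
  v
}

#' Run the full pipeline
#'
#' Simulates a cohort with paired TMA cores, trains the epithelium/stroma
#' classifier on ground-truth-labeled superpixels from the first training
#' cores, segments every core, audits accuracy against ground truth,
#' extracts the 1,536-feature table per core, averages cores to cases,
#' screens the features against survival, computes the SI scores and
#' delta-values, and fits the survival battery. All tables are written as
#' TSV under `outdir`, with a JSON manifest recording seeds and MD5
#' checksums of every output.
#'
#' @param config A valid [run_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `cohort`, `audit`,
#'   `features_core1`, `features_core2`, `features_case`, `screen`, `scores`,
#'   `analysis_table`, `km`, `univariate`, `multivariate`, `interaction`,
#'   `subgroups`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  viol <- validate_run_config(config)
  if (length(viol) > 0L)
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, ...) message(sprintf("[%s] %s", stage, sprintf(...)))

  # -- stage 1: cohort ------------------------------------------------------
  cp <- config$cohort
  cp$n_cases <- config$n_cases
  cp$seed <- as.integer(sub_seed(config$seed, 1L))
  sim <- tryCatch(generate_cohort(cp, image_template = config$image),
                  error = function(e) stop("stage 'simulate' failed: ",
                                           conditionMessage(e), call. = FALSE))
  cases <- sim$cases
  n <- nrow(cases)
  log_msg("simulate", "%d cases, %d events", n, sum(cases$event))

  # -- stage 2: render cores ------------------------------------------------
  cores <- vector("list", n)
  for (i in seq_len(n)) {
    cores[[i]] <- tryCatch(
      list(core1 = generate_tma_image(sim$image_params[[i]]$core1),
           core2 = generate_tma_image(sim$image_params[[i]]$core2)),
      error = function(e) stop(sprintf("stage 'render' failed at case %s: %s",
                                       cases$case_id[i], conditionMessage(e)),
                               call. = FALSE))
    if (config$write_images) {
      p1 <- write_tma_image(cores[[i]]$core1, file.path(outdir, paste0(cases$case_id[i], "_core1")))
      p2 <- write_tma_image(cores[[i]]$core2, file.path(outdir, paste0(cases$case_id[i], "_core2")))
      cases$core1_path[i] <- p1[["image"]]
      cases$core2_path[i] <- p2[["image"]]
    }
  }
  log_msg("render", "%d cores rendered", 2L * n)

  # -- stage 3: classifier --------------------------------------------------
  k <- min(config$n_train_images, n)
  ex <- lapply(seq_len(k), function(i)
    training_examples_from_truth(cores[[i]]$core1, target_size = config$target_size))
  model <- train_compartment_classifier(
    do.call(rbind, lapply(ex, `[[`, "descriptors")),
    unlist(lapply(ex, `[[`, "labels")))
  log_msg("train", "classifier resubstitution accuracy %.3f",
          model$resubstitution_accuracy)

  # -- stage 4: segment + audit + features ----------------------------------
  catalogue <- build_catalogue()
  seg1 <- vector("list", n); seg2 <- vector("list", n)
  audit <- vector("list", 2L * n)
  F1 <- matrix(NA_real_, n, nrow(catalogue), dimnames = list(cases$case_id, catalogue$name))
  F2 <- F1
  for (i in seq_len(n)) {
    seg1[[i]] <- segment_tma(cores[[i]]$core1$image, model, target_size = config$target_size)
    seg2[[i]] <- segment_tma(cores[[i]]$core2$image, model, target_size = config$target_size)
    a1 <- suppressWarnings(audit_accuracy(seg1[[i]], cores[[i]]$core1$truth))
    a2 <- suppressWarnings(audit_accuracy(seg2[[i]], cores[[i]]$core2$truth))
    audit[[2L * i - 1L]] <- data.frame(image_id = paste0(cases$case_id[i], "_core1"),
                                       spx_audited = a1$n_superpixels_audited,
                                       spx_accuracy = a1$superpixel_accuracy,
                                       nuclei_audited = a1$n_nuclei_audited,
                                       nuclei_accuracy = a1$nucleus_accuracy)
    audit[[2L * i]] <- data.frame(image_id = paste0(cases$case_id[i], "_core2"),
                                  spx_audited = a2$n_superpixels_audited,
                                  spx_accuracy = a2$superpixel_accuracy,
                                  nuclei_audited = a2$n_nuclei_audited,
                                  nuclei_accuracy = a2$nucleus_accuracy)
    F1[i, ] <- extract_features(cores[[i]]$core1$image, seg1[[i]], catalogue)
    F2[i, ] <- extract_features(cores[[i]]$core2$image, seg2[[i]], catalogue)
  }
  audit <- do.call(rbind, audit)
  Fcase <- F1
  for (j in seq_len(ncol(F1))) Fcase[, j] <- case_average(F1[, j], F2[, j])
  log_msg("features", "feature tables: %d x %d", nrow(Fcase), ncol(Fcase))

  # -- stage 5: screen ------------------------------------------------------
  keep <- cases$time_months >= 1
  screen <- sam_fdr(Fcase[keep, , drop = FALSE],
                    cases$time_months[keep], cases$event[keep],
                    n_perm = config$n_perm, threshold = config$fdr,
                    seed = as.integer(sub_seed(config$seed, 5L)))
  log_msg("screen", "%d hits at FDR < %g", sum(screen$hit, na.rm = TRUE), config$fdr)

  # -- stage 6: scores ------------------------------------------------------
  scores <- score_cohort(seg1, seg2, cases$case_id)
  scores$pdl1 <- cases$pdl1
  scores$pdl1_stratum <- pdl1_stratum(cases$pdl1)
  log_msg("score", "computed SI: mean %.3f (true mean %.3f)",
          mean(scores$si_case, na.rm = TRUE), mean(cases$true_si))

  # -- stage 7: survival battery -------------------------------------------
  tab <- data.frame(cases[, c("case_id", "time_months", "event", "stage", "age",
                              "vascular_invasion", "pleural_invasion", "grade")],
                    si = scores$si_case, si_core1 = scores$si_core1,
                    si_core2 = scores$si_core2, delta = scores$delta,
                    pdl1_stratum = scores$pdl1_stratum,
                    stringsAsFactors = FALSE)
  tab <- suppressMessages(filter_cohort(tab))
  km <- tryCatch(km_by_median_si(tab), error = function(e) NULL)
  uni <- do.call(rbind, lapply(
    c("si", "stage", "age", "vascular_invasion", "pleural_invasion", "grade"),
    function(v) tryCatch(as.data.frame(cph_univariate(tab, v)),
                         error = function(e) NULL)))
  multi <- tryCatch(suppressWarnings(cph_multivariate(tab)), error = function(e) NULL)
  inter <- tryCatch(suppressWarnings(interaction_model(tab)), error = function(e) NULL)
  sub <- tryCatch(suppressWarnings(subgroup_analysis(tab)), error = function(e) NULL)
  log_msg("survive", "survival battery complete")

  # -- outputs --------------------------------------------------------------
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(cases, "cohort.tsv"),
    wt(audit, "audit.tsv"),
    write_feature_table(F1, file.path(outdir, "features_core1.tsv"), catalogue),
    write_feature_table(F2, file.path(outdir, "features_core2.tsv"), catalogue),
    write_feature_table(Fcase, file.path(outdir, "features_case.tsv"), catalogue),
    write_screen_tsv(screen, file.path(outdir, "screen.tsv")),
    wt(scores, "scores.tsv"))
  if (!is.null(uni)) paths <- c(paths, wt(uni, "cph_univariate.tsv"))
  if (!is.null(multi)) paths <- c(paths, wt(as.data.frame(multi), "cph_multivariate.tsv"))
  if (!is.null(sub)) paths <- c(paths, wt(sub, "subgroups.tsv"))
  if (!is.null(km)) paths <- c(paths, wt(km_curves(km), "km_curves.tsv"))

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("siscreen")),
    master_seed = config$seed,
    stage_seeds = list(cohort = cp$seed, screen = as.integer(sub_seed(config$seed, 5L))),
    n_cases = n,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_msg("manifest", "%d files written to %s", length(files) + 1L, outdir)

  invisible(list(cohort = cases, audit = audit,
                 features_core1 = F1, features_core2 = F2, features_case = Fcase,
                 screen = screen, scores = scores, analysis_table = tab,
                 km = km, univariate = uni, multivariate = multi,
                 interaction = inter, subgroups = sub, manifest = manifest))
}
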