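#' Derive deterministic child seeds from one root seed
#'
#' Every stage of the pipeline draws from its own child seed, so each stage
#' is independently reproducible while the whole run remains a pure
#' function of the root seed. Derivation: seed the generator with the root
#' seed and draw `n` integers.
#'
#' @param seed Root seed (integer).
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Pipeline run configuration
#'
#' Bundles everything a full phantom-to-metrics run depends on; a run is a
#' pure function of `(config, seed)`. The configuration is a plain list and
#' round-trips through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param n_subjects Simulated kidneys.
#' @param n_per_class Scans per class per subject.
#' @param seed Root seed.
#' @param width,depth Scan size in pixels.
#' @param noise_floor Additive background intensity.
#' @param roi A [roi_spec()].
#' @param phenotypes Named list of [tissue_phenotype()]s.
#' @param positive Positive class for the two-class threshold analysis.
#' @param subject_jitter Per-subject relative jitter on `mu`.
#' @param out_dir Optional output directory for artifacts (CSV/JSON); `NULL`
#'   keeps the run in memory.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `oct_run_config`.
#' @export
oct_run_config <- function(n_subjects = 3, n_per_class = 20, seed = 7,
                           width = 240L, depth = 320L, noise_floor = 0,
                           roi = roi_spec(), phenotypes = default_phenotypes(),
                           positive = "tumor", subject_jitter = 0.15,
                           out_dir = NULL, log_level = c("info", "quiet")) {
  structure(list(n_subjects = n_subjects, n_per_class = n_per_class,
                 seed = seed, width = as.integer(width),
                 depth = as.integer(depth), noise_floor = noise_floor,
                 roi = roi, phenotypes = phenotypes, positive = positive,
                 subject_jitter = subject_jitter, out_dir = out_dir,
                 log_level = match.arg(log_level)),
            class = "oct_run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config An [oct_run_config()].
#' @param path YAML file path.
#' @return `path` (write) or the restored `oct_run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "oct_run_config"))
  x <- unclass(config)
  x$roi <- unclass(x$roi)
  x$phenotypes <- lapply(x$phenotypes, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  phen <- lapply(x$phenotypes, function(p) do.call(tissue_phenotype, p))
  oct_run_config(n_subjects = x$n_subjects, n_per_class = x$n_per_class,
                 seed = x$seed, width = x$width, depth = x$depth,
                 noise_floor = x$noise_floor,
                 roi = do.call(roi_spec, x$roi), phenotypes = phen,
                 positive = x$positive, subject_jitter = x$subject_jitter,
                 out_dir = x$out_dir, log_level = x$log_level)
}

run_log <- function(config, fmt, ...) {
  if (config$log_level != "quiet") message(sprintf(fmt, ...))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full phantom-to-metrics pipeline
#'
#' Executes, in order: phantom generation, per-image attenuation
#' estimation, subject-rotating cross-testing of the Gaussian classifier
#' (both the multi-class likelihood rule and, if configured, the two-class
#' tumor-vs-normal threshold), and the pooled metrics report. Each stage
#' runs on its own child seed derived from the root seed, so re-running
#' with an identical configuration reproduces all numeric outputs
#' bit-exactly. If `config$out_dir` is set, the manifest, attenuation
#' table, metrics (JSON/CSV) and a file manifest with MD5 checksums are
#' written there.
#'
#' @param config An [oct_run_config()].
#' @return Object of class `oct_run_report`: list with `config`, `mu_table`,
#'   `split_plan`, `crosstest` (multi-class [cross_test_attenuation()]
#'   result), `crosstest_binary` (two-class, when `positive` set),
#'   `pooled_metrics`, `tumor_vs_normal_auc`, `abstentions`, per-stage
#'   `timings` (seconds), and `files` (path + MD5) when artifacts were
#'   written.
#' @examples
#' \donttest{
#' rep <- run_pipeline(oct_run_config(n_subjects = 3, n_per_class = 6,
#'                                    log_level = "quiet"))
#' rep$pooled_metrics
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "oct_run_config"))
  seeds <- derive_seeds(config$seed, 4L)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  dataset <- with_stage("phantom",
    generate_phantom_dataset(config$phenotypes, config$n_subjects,
                             config$n_per_class, seed = seeds[1],
                             subject_jitter = config$subject_jitter,
                             width = config$width, depth = config$depth,
                             noise_floor = config$noise_floor))
  timings["phantom"] <- tic() - t0
  run_log(config, "phantom: %d scans rendered", nrow(dataset$manifest))

  t0 <- tic()
  mu_table <- with_stage("attenuation", dataset_mu(dataset, roi = config$roi))
  timings["attenuation"] <- tic() - t0
  run_log(config, "attenuation: %d/%d images computable",
          sum(mu_table$valid), nrow(mu_table))

  t0 <- tic()
  plan <- with_stage("split", make_split_plan(unique(mu_table$subject_id),
                                              seed = seeds[2]))
  ct <- with_stage("crosstest", cross_test_attenuation(mu_table, plan))
  ct_bin <- NULL; auc <- NA_real_
  if (!is.null(config$positive)) {
    ct_bin <- with_stage("crosstest",
                         cross_test_attenuation(mu_table, plan,
                                                positive = config$positive))
    pool <- with_stage("classification",
      one_vs_rest_pool(mu_table, config$positive,
                       max(1L, config$n_per_class %/%
                             (length(config$phenotypes) - 2L)),
                       seed = seeds[3]))
    auc <- roc_auc(pool$positives, pool$negatives)$auc
  }
  timings["classification"] <- tic() - t0

  t0 <- tic()
  pooled_metrics <- with_stage("evaluation", metrics_report(ct$pooled))
  timings["evaluation"] <- tic() - t0
  run_log(config, "evaluation: %d abstentions routed out of the matrix",
          sum(ct$abstentions))

  files <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(manifest = file.path(config$out_dir, "manifest.csv"),
               mu = file.path(config$out_dir, "mu.csv"),
               metrics_csv = file.path(config$out_dir, "metrics.csv"),
               metrics_json = file.path(config$out_dir, "metrics.json"))
    utils::write.csv(dataset$manifest, paths["manifest"], row.names = FALSE)
    utils::write.csv(mu_table, paths["mu"], row.names = FALSE)
    utils::write.csv(as.data.frame(pooled_metrics), paths["metrics_csv"],
                     row.names = FALSE)
    jsonlite::write_json(
      list(pooled = as.data.frame(pooled_metrics),
           tumor_vs_normal_auc = auc,
           abstentions = as.list(ct$abstentions)),
      paths["metrics_json"], auto_unbox = TRUE, digits = NA)
    files <- data.frame(path = unname(paths),
                        md5 = unname(tools::md5sum(paths)),
                        stringsAsFactors = FALSE)
  }

  structure(list(config = config, mu_table = mu_table, split_plan = plan,
                 crosstest = ct, crosstest_binary = ct_bin,
                 pooled_metrics = pooled_metrics,
                 tumor_vs_normal_auc = auc,
                 abstentions = ct$abstentions,
                 timings = timings, files = files),
            class = "oct_run_report")
}

#' @export
print.oct_run_report <- function(x, ...) {
  cat(sprintf("OCT attenuation pipeline run (seed %d)\n", x$config$seed))
  cat(sprintf("  %d subjects x %d scans/class, %d x %d px scans\n",
              x$config$n_subjects, x$config$n_per_class,
              x$config$width, x$config$depth))
  cat(sprintf("  computable attenuation: %d/%d images; abstentions: %d\n",
              sum(x$mu_table$valid), nrow(x$mu_table), sum(x$abstentions)))
  if (!is.na(x$tumor_vs_normal_auc))
    cat(sprintf("  tumor-vs-normal pooled AUC: %.4f\n", x$tumor_vs_normal_auc))
  cat("\nPooled held-out multi-class metrics:\n")
  print(x$pooled_metrics)
  invisible(x)
}
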