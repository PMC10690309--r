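# shared fixtures: everything is generated in code, at reduced scan sizes
# (the ROI defaults of 200 x 250 px still fit)

small_width <- 220L
small_depth <- 320L

quick_scan <- function(phenotype, seed = 1, speckle = "exponential", ...) {
  render_bscan(phenotype, seed = seed, width = small_width,
               depth = small_depth, speckle = speckle, ...)
}

quick_dataset <- function(n_subjects = 3, n_per_class = 4, seed = 11, ...) {
  generate_phantom_dataset(n_subjects = n_subjects, n_per_class = n_per_class,
                           seed = seed, width = small_width,
                           depth = small_depth, ...)
}

# hand-built gaussian_model without going through data
gm <- function(mean, sd, label = "g", n = 100L) {
  structure(list(mean = mean, sd = sd, n = n, label = label),
            class = "gaussian_model")
}

# mu table shaped like dataset_mu() output, from explicit per-class draws
synthetic_mu_table <- function(subjects, class_means, n_per, sd = 0.3,
                               seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject_id = subjects, label = names(class_means),
                      rep = seq_len(n_per), stringsAsFactors = FALSE)
  rows$mu <- stats::rnorm(nrow(rows), unlist(class_means[rows$label]), sd)
  rows$valid <- TRUE
  rows$n_valid_columns <- 200L
  rows$scan_id <- sprintf("%s_%s_%d", rows$subject_id, rows$label, rows$rep)
  rows[, c("scan_id", "subject_id", "label", "mu", "n_valid_columns", "valid")]
}
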