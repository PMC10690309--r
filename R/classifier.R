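#' Fit a Gaussian to a sample of attenuation coefficients
#'
#' Moment fit: sample mean and sample standard deviation (n-1 denominator).
#'
#' @param values Numeric sample (mm^-1); non-finite values are rejected.
#' @param label Class name attached to the fit.
#' @return Object of class `gaussian_model`: list with `mean`, `sd`, `n`,
#'   `label`.
#' @export
fit_gaussian <- function(values, label = "sample") {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("fit error: need at least 2 finite samples for '", label, "'")
  s <- stats::sd(values)
  if (s <= 0)
    stop("fit error: zero variance in '", label, "'")
  structure(list(mean = mean(values), sd = s, n = length(values),
                 label = label),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model> %s: N(%.4f, %.4f^2), n = %d\n",
              x$label, x$mean, x$sd, x$n))
  invisible(x)
}

#' Crossing point of two fitted normal densities
#'
#' Solves \eqn{\phi(x; m_1, s_1) = \phi(x; m_2, s_2)}. With equal standard
#' deviations the unique crossing is the midpoint of the means. With unequal
#' standard deviations the log-density equality is a quadratic in \eqn{x};
#' the decision-relevant root is the one lying between the two means
#' (tie-break: the root nearer the midpoint, should both qualify
#' numerically).
#'
#' @param a,b `gaussian_model` objects with different means.
#' @return The threshold in mm^-1.
#' @examples
#' a <- fit_gaussian(c(0.9, 1.1), "low");  a$mean <- 1; a$sd <- 0.5
#' b <- fit_gaussian(c(2.9, 3.1), "high"); b$mean <- 3; b$sd <- 0.5
#' intersection_threshold(a, b)  # 2
#' @export
intersection_threshold <- function(a, b) {
  stopifnot(inherits(a, "gaussian_model"), inherits(b, "gaussian_model"))
  m1 <- a$mean; s1 <- a$sd; m2 <- b$mean; s2 <- b$sd
  if (m1 == m2 && s1 == s2)
    stop("no-threshold error: identical distributions")
  if (m1 == m2)
    stop("no-threshold error: equal means")
  if (s1 == s2)
    return((m1 + m2) / 2)
  # log phi_a(x) = log phi_b(x)  <=>  A x^2 + B x + C = 0
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) - log(s1 / s2)
  disc <- B^2 - 4 * A * C
  if (disc < 0)
    stop("no-threshold error: densities do not cross")
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  lo <- min(m1, m2); hi <- max(m1, m2)
  mid <- (m1 + m2) / 2
  between <- roots >= lo & roots <= hi
  cand <- if (any(between)) roots[between] else roots
  cand[which.min(abs(cand - mid))]
}

#' Gaussian attenuation classifier
#'
#' The core fitted model of the package. Class-conditional normal
#' distributions are fitted (by moments) to the per-image attenuation
#' coefficients of each tissue class. When a `positive` class is named, the
#' remaining classes are additionally pooled into a single "rest" group and
#' a two-class decision threshold is placed at the crossing point of the two
#' fitted densities — the rule used to separate tumor from normal renal
#' tissue. Multi-class prediction assigns the nearest class by Gaussian
#' likelihood under equal priors.
#'
#' Images whose attenuation coefficient is not computable (e.g. signal-free
#' pelvis scans) are counted as abstentions at fit time and predicted as
#' `NA` — they are reported, never silently dropped.
#'
#' @param formula Model formula of the form `mu ~ label`.
#' @param data data.frame holding the attenuation coefficients and class
#'   labels (e.g. the output of [dataset_mu()]).
#' @param positive Optional name of the positive class; enables the
#'   two-class crossing-point threshold rule.
#' @return Object of class `atten_classifier` with components `classes`
#'   (named list of [fit_gaussian()] models), `positive`, `rest` (pooled
#'   negatives model, two-class mode only), `threshold`, `positive_high`
#'   (whether the positive class sits on the high-mu side), `data`,
#'   `n_abstain`, `call`.
#' @seealso [predict.atten_classifier()], [roc_auc()]
#' @examples
#' d <- data.frame(mu = c(rnorm(50, 2, .3), rnorm(50, 8, .5)),
#'                 label = rep(c("cortex", "tumor"), each = 50))
#' fit <- atten_classifier(mu ~ label, d, positive = "tumor")
#' coef(fit)
#' @export
atten_classifier <- function(formula = mu ~ label, data, positive = NULL) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  mu <- mf[[1L]]
  lab <- as.character(mf[[2L]])
  if (!is.numeric(mu)) stop("response must be numeric (mm^-1)")

  abstain <- !is.finite(mu)
  n_abstain <- sum(abstain)
  mu_f <- mu[!abstain]; lab_f <- lab[!abstain]
  classes_present <- sort(unique(lab_f))
  if (length(classes_present) < 2L)
    stop("need at least two classes with computable attenuation")
  if (!is.null(positive) && !positive %in% classes_present)
    stop("positive class '", positive, "' has no computable attenuation values")

  models <- lapply(classes_present,
                   function(cl) fit_gaussian(mu_f[lab_f == cl], cl))
  names(models) <- classes_present

  rest <- NULL; threshold <- NA_real_; positive_high <- NA
  if (!is.null(positive)) {
    rest <- fit_gaussian(mu_f[lab_f != positive], "rest")
    threshold <- intersection_threshold(models[[positive]], rest)
    positive_high <- models[[positive]]$mean > rest$mean
  }

  structure(
    list(classes = models, positive = positive, rest = rest,
         threshold = threshold, positive_high = positive_high,
         data = data.frame(mu = mu, label = lab, stringsAsFactors = FALSE),
         n_abstain = n_abstain, call = match.call()),
    class = "atten_classifier")
}

#' @export
print.atten_classifier <- function(x, ...) {
  cat("Gaussian attenuation classifier\n")
  for (m in x$classes)
    cat(sprintf("  %-8s N(%.4f, %.4f^2)  n = %d\n", m$label, m$mean, m$sd, m$n))
  if (!is.null(x$positive))
    cat(sprintf("  threshold (%s vs rest): %.4f mm^-1, %s above\n",
                x$positive, x$threshold,
                if (x$positive_high) x$positive else "rest"))
  if (x$n_abstain > 0)
    cat(sprintf("  %d abstentions (attenuation not computable)\n", x$n_abstain))
  invisible(x)
}

#' @export
coef.atten_classifier <- function(object, ...) {
  out <- unlist(lapply(object$classes,
                       function(m) c(mean = m$mean, sd = m$sd)))
  if (!is.null(object$positive))
    out <- c(out, threshold = object$threshold)
  out
}

#' @export
summary.atten_classifier <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$classes, function(m)
    data.frame(label = m$label, mean = m$mean, sd = m$sd, n = m$n)))
  rownames(tab) <- NULL
  roc <- NULL
  if (!is.null(object$positive)) {
    d <- object$data[is.finite(object$data$mu), ]
    roc <- roc_auc(d$mu[d$label == object$positive],
                   d$mu[d$label != object$positive])
  }
  structure(list(classes = tab, positive = object$positive,
                 threshold = object$threshold,
                 training_auc = if (!is.null(roc)) roc$auc else NA_real_,
                 n_abstain = object$n_abstain),
            class = "summary.atten_classifier")
}

#' @export
print.summary.atten_classifier <- function(x, ...) {
  cat("Gaussian attenuation classifier\n\nClass-conditional fits:\n")
  print(x$classes, row.names = FALSE)
  if (!is.null(x$positive))
    cat(sprintf("\nThreshold (%s vs rest): %.4f mm^-1; training AUC %.4f\n",
                x$positive, x$threshold, x$training_auc))
  if (x$n_abstain > 0)
    cat(sprintf("Abstentions: %d\n", x$n_abstain))
  invisible(x)
}

#' Predict tissue classes from attenuation coefficients
#'
#' Two-class mode (model fitted with `positive`): values on the positive
#' class's side of the crossing-point threshold get the positive label, the
#' others `"rest"`; a value exactly at the threshold goes to the
#' higher-mean class (documented tie-break). Multi-class mode: nearest class
#' by Gaussian log-likelihood under equal priors; exact likelihood ties go
#' to the class with the higher mean. Non-finite attenuation values abstain
#' and are returned as `NA`; their count is attached as attribute
#' `n_abstain`.
#'
#' @param object An [atten_classifier()].
#' @param newdata Numeric vector of attenuation coefficients, or a
#'   data.frame with a `mu` column. Defaults to the training data.
#' @param type `"class"` for labels, `"multiclass"` to force the
#'   likelihood rule even when a threshold is available.
#' @param ... Unused.
#' @return Character vector of class labels (`NA` = abstain) with attribute
#'   `n_abstain`.
#' @export
predict.atten_classifier <- function(object, newdata = NULL,
                                     type = c("class", "multiclass"), ...) {
  type <- match.arg(type)
  mu <- if (is.null(newdata)) object$data$mu
        else if (is.data.frame(newdata)) newdata$mu
        else newdata
  if (!is.numeric(mu)) stop("'newdata' must supply numeric attenuation values")
  out <- rep(NA_character_, length(mu))
  ok <- is.finite(mu)

  if (type == "class" && !is.null(object$positive)) {
    hi_label <- if (object$positive_high) object$positive else "rest"
    lo_label <- if (object$positive_high) "rest" else object$positive
    # tie-break: exactly-at-threshold goes to the higher-mean class
    out[ok] <- ifelse(mu[ok] >= object$threshold, hi_label, lo_label)
  } else {
    mods <- object$classes
    ll <- vapply(mods, function(m)
      stats::dnorm(mu[ok], m$mean, m$sd, log = TRUE), numeric(sum(ok)))
    ll <- matrix(ll, nrow = sum(ok))
    means <- vapply(mods, `[[`, numeric(1), "mean")
    pick <- apply(ll, 1L, function(r) {
      best <- which(r == max(r))
      if (length(best) > 1L) best <- best[which.max(means[best])]
      best
    })
    out[ok] <- names(mods)[pick]
  }
  attr(out, "n_abstain") <- sum(!ok)
  out
}

#' @export
residuals.atten_classifier <- function(object, ...) {
  means <- vapply(object$classes, `[[`, numeric(1), "mean")
  object$data$mu - unname(means[object$data$label])
}

#' Simulate attenuation coefficients from the fitted class models
#'
#' Draws `nsim` values per fitted class from its class-conditional normal,
#' returning a data.frame shaped like the training input — useful for
#' parametric-bootstrap checks of the threshold rule.
#'
#' @param object An [atten_classifier()].
#' @param nsim Draws per class.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return data.frame with columns `mu`, `label`.
#' @export
simulate.atten_classifier <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(object$classes, function(m)
    data.frame(mu = stats::rnorm(nsim, m$mean, m$sd), label = m$label,
               stringsAsFactors = FALSE)))
}

#' Plot the fitted class densities and decision threshold
#'
#' @param x An [atten_classifier()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.atten_classifier <- function(x, ...) {
  means <- vapply(x$classes, `[[`, numeric(1), "mean")
  sds <- vapply(x$classes, `[[`, numeric(1), "sd")
  rng <- range(means - 4 * sds, means + 4 * sds)
  grid <- seq(rng[1], rng[2], length.out = 512)
  dens <- vapply(x$classes, function(m) stats::dnorm(grid, m$mean, m$sd),
                 numeric(length(grid)))
  graphics::matplot(grid, dens, type = "l", lty = 1,
                    col = seq_along(x$classes),
                    xlab = expression(mu ~ (mm^-1)), ylab = "density", ...)
  if (!is.null(x$positive))
    graphics::abline(v = x$threshold, lty = 2)
  graphics::legend("topright", legend = names(x$classes), lty = 1,
                   col = seq_along(x$classes), bty = "n")
  invisible(x)
}

#' ROC curve and AUC for a two-group attenuation comparison
#'
#' Sweeps the decision threshold over the pooled sample values (positives
#' assumed to sit on the high-mu side) and computes the AUC by the
#' rank (Mann-Whitney) statistic, counting ties one half.
#'
#' @param positives,negatives Numeric attenuation samples; must be nonempty
#'   after removing non-finite values.
#' @return Object of class `roc_result`: list with `thresholds`, `tpr`,
#'   `fpr` (both nondecreasing along the sweep, with endpoints (0,0) and
#'   (1,1)) and `auc` in `[0, 1]`.
#' @examples
#' roc_auc(c(5, 6, 7), c(1, 2, 3))$auc  # 1: perfect separation
#' @export
roc_auc <- function(positives, negatives) {
  positives <- positives[is.finite(positives)]
  negatives <- negatives[is.finite(negatives)]
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both groups must be nonempty")
  np <- length(positives); nn <- length(negatives)
  r <- rank(c(positives, negatives))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  thr <- c(Inf, sort(unique(c(positives, negatives)), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(positives >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(negatives >= t), numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d operating points)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Build a balanced tumor-vs-normal sample pool
#'
#' For the pooled two-class comparison the positives are all images of the
#' positive class, and the negatives are an equal-sized pool drawn by
#' sampling the same number of images from each normal class within each
#' subject (e.g. 2,500 images x 4 normal classes x 5 subjects matches
#' 50,000 positives). Reproducible from `seed`.
#'
#' @param mu_table data.frame with columns `subject_id`, `label`, `mu`,
#'   `valid` (as from [dataset_mu()]); only valid rows are pooled.
#' @param positive_class Name of the positive class.
#' @param per_class_subsample Images drawn per normal class per subject.
#' @param seed Optional seed.
#' @return List with numeric vectors `positives` and `negatives`.
#' @export
one_vs_rest_pool <- function(mu_table, positive_class, per_class_subsample,
                             seed = NULL) {
  stopifnot(all(c("subject_id", "label", "mu") %in% names(mu_table)))
  if (per_class_subsample < 1)
    stop("'per_class_subsample' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if ("valid" %in% names(mu_table)) mu_table <- mu_table[mu_table$valid, ]
  pos <- mu_table$mu[mu_table$label == positive_class]
  if (length(pos) == 0L) stop("no images of positive class '", positive_class, "'")
  negtab <- mu_table[mu_table$label != positive_class, ]
  neg <- c()
  for (sid in sort(unique(negtab$subject_id))) {
    for (cl in sort(unique(negtab$label))) {
      v <- negtab$mu[negtab$subject_id == sid & negtab$label == cl]
      if (length(v) < per_class_subsample)
        stop(sprintf("insufficient images: %d < %d for %s/%s",
                     length(v), per_class_subsample, sid, cl))
      neg <- c(neg, v[sample.int(length(v), per_class_subsample)])
    }
  }
  list(positives = pos, negatives = neg)
}

#' Persist a fitted classifier as JSON / restore it
#'
#' Stores the class-conditional means, standard deviations, sample sizes,
#' the positive class and the crossing-point threshold; enough to classify
#' new attenuation values, not the training data.
#'
#' @param object An [atten_classifier()].
#' @param path JSON file path.
#' @return `path` (write) or a reduced `atten_classifier` (read).
#' @export
write_classifier_json <- function(object, path) {
  stopifnot(inherits(object, "atten_classifier"))
  x <- list(
    classes = lapply(object$classes, function(m)
      list(mean = m$mean, sd = m$sd, n = m$n, label = m$label)),
    positive = object$positive,
    rest = if (!is.null(object$rest))
      list(mean = object$rest$mean, sd = object$rest$sd, n = object$rest$n),
    threshold = object$threshold,
    positive_high = object$positive_high)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  x <- jsonlite::read_json(path)
  classes <- lapply(x$classes, function(m)
    structure(list(mean = m$mean, sd = m$sd, n = as.integer(m$n),
                   label = m$label), class = "gaussian_model"))
  names(classes) <- vapply(classes, `[[`, character(1), "label")
  rest <- if (!is.null(x$rest))
    structure(list(mean = x$rest$mean, sd = x$rest$sd,
                   n = as.integer(x$rest$n), label = "rest"),
              class = "gaussian_model")
  structure(
    list(classes = classes, positive = x$positive, rest = rest,
         threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
         positive_high = if (is.null(x$positive_high)) NA else x$positive_high,
         data = NULL, n_abstain = 0L, call = NULL),
    class = "atten_classifier")
}

#' Export ROC operating points as CSV
#'
#' @param roc A [roc_auc()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.csv(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                              fpr = roc$fpr), path, row.names = FALSE)
  invisible(path)
}
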