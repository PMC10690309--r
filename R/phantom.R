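#' Tissue phenotype: generative parameters for one renal tissue class
#'
#' A `tissue_phenotype` bundles the parameters that drive the synthetic
#' B-scan renderer for one tissue class: the Beer-Lambert pair (`i0`, `mu`)
#' governing the mean depth decay \eqn{I(z) = I_0 e^{-2\mu z}}, plus texture
#' parameters that reproduce the qualitative appearance of each renal tissue
#' type under a forward-viewing endoscopic OCT probe (striped calyx, dark fat
#' with bright adipocyte dots, signal-free pelvis).
#'
#' @param name Tissue label, one of `"cortex"`, `"medulla"`, `"calyx"`,
#'   `"fat"`, `"pelvis"`, `"tumor"` (other labels are allowed for custom
#'   phantoms).
#' @param mu Attenuation coefficient in mm^-1 (decay rate of the mean
#'   intensity with physical depth; must be >= 0).
#' @param i0 Mean backscatter intensity at the tissue surface, arbitrary
#'   units; must be > 0 when `has_tissue_signal`.
#' @param surface_row Depth-pixel row (1-based) of the tissue surface; decay
#'   starts there. Rows between the instrument surface band and this row hold
#'   only the noise floor.
#' @param stripe_period_px Depth period, in pixels, of a sinusoidal
#'   modulation of `mu` (calyx strata); 0 disables striping.
#' @param stripe_contrast Relative amplitude of the `mu` modulation, in
#'   `[0, 1)`.
#' @param dot_density Expected number of bright circular inclusions per mm^2
#'   of tissue area (adipocytes in fat); 0 disables.
#' @param dot_intensity_gain Multiplicative brightness of the inclusions.
#' @param dot_radius_px Inclusion radius in pixels.
#' @param has_tissue_signal `FALSE` for the pelvis, which is an empty
#'   urine-collecting space: nothing is rendered below the instrument surface
#'   band except the noise floor.
#' @return An object of class `tissue_phenotype`.
#' @seealso [default_phenotypes()], [render_bscan()]
#' @export
tissue_phenotype <- function(name, mu, i0 = 100, surface_row = 6L,
                             stripe_period_px = 0, stripe_contrast = 0,
                             dot_density = 0, dot_intensity_gain = 1,
                             dot_radius_px = 3L,
                             has_tissue_signal = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("'mu' must be a single nonnegative number (mm^-1)")
  if (has_tissue_signal && (!is.numeric(i0) || length(i0) != 1L || i0 <= 0))
    stop("'i0' must be > 0 when the phenotype carries tissue signal")
  if (stripe_contrast < 0 || stripe_contrast >= 1)
    stop("'stripe_contrast' must lie in [0, 1)")
  if (surface_row < 1)
    stop("'surface_row' must be a positive row index")
  if (dot_density < 0) stop("'dot_density' must be >= 0")
  structure(
    list(name = name, mu = as.numeric(mu), i0 = as.numeric(i0),
         surface_row = as.integer(surface_row),
         stripe_period_px = as.numeric(stripe_period_px),
         stripe_contrast = as.numeric(stripe_contrast),
         dot_density = as.numeric(dot_density),
         dot_intensity_gain = as.numeric(dot_intensity_gain),
         dot_radius_px = as.integer(dot_radius_px),
         has_tissue_signal = isTRUE(has_tissue_signal)),
    class = "tissue_phenotype")
}

#' @export
print.tissue_phenotype <- function(x, ...) {
  cat(sprintf("<tissue_phenotype> %s: mu = %.3g mm^-1, i0 = %.3g%s\n",
              x$name, x$mu, x$i0,
              if (!x$has_tissue_signal) " (no tissue signal)" else ""))
  invisible(x)
}

#' Default phenotypes for the six renal tissue classes
#'
#' Simulator defaults chosen to mirror the qualitative ordering seen on
#' endoscopic OCT of ex-vivo kidney: tumor is the brightest and attenuates
#' fastest (shallowest imaging depth), medulla penetrates deeper than cortex,
#' calyx shows alternating bright/dark strata, fat is darkest with sparse
#' bright adipocyte dots, and the pelvis carries no tissue signal below the
#' instrument surface. The numeric values are free simulator parameters, not
#' measurements.
#'
#' @return Named list of six [tissue_phenotype()] objects.
#' @export
default_phenotypes <- function() {
  list(
    cortex  = tissue_phenotype("cortex",  mu = 2.5, i0 = 120),
    medulla = tissue_phenotype("medulla", mu = 1.5, i0 = 100),
    calyx   = tissue_phenotype("calyx",   mu = 3.0, i0 = 110,
                               stripe_period_px = 40, stripe_contrast = 0.5),
    fat     = tissue_phenotype("fat",     mu = 2.0, i0 = 40,
                               dot_density = 10, dot_intensity_gain = 6),
    pelvis  = tissue_phenotype("pelvis",  mu = 0, i0 = 1,
                               has_tissue_signal = FALSE),
    tumor   = tissue_phenotype("tumor",   mu = 8.0, i0 = 250)
  )
}

# Mean (noiseless) depth profile of one A-scan for a phenotype.
# Row 1 is the shallowest pixel; decay starts at phenotype$surface_row with
# intensity i0 there. Striped phenotypes modulate mu sinusoidally in depth and
# the decay exponent is the cumulative depth integral of the modulated mu.
mean_depth_profile <- function(phenotype, depth, axial_pitch_mm, noise_floor) {
  prof <- rep(noise_floor, depth)
  if (!phenotype$has_tissue_signal) return(prof)
  s <- phenotype$surface_row
  if (s > depth) return(prof)
  k <- 0:(depth - s)                       # pixels below the tissue surface
  if (phenotype$stripe_period_px > 0 && phenotype$stripe_contrast > 0) {
    mu_k <- phenotype$mu *
      (1 + phenotype$stripe_contrast * sin(2 * pi * k / phenotype$stripe_period_px))
    integral <- c(0, cumsum(mu_k[-length(mu_k)]))  # left Riemann sum, pixels
    decay <- exp(-2 * integral * axial_pitch_mm)
  } else {
    decay <- exp(-2 * phenotype$mu * k * axial_pitch_mm)
  }
  prof[s:depth] <- phenotype$i0 * decay + noise_floor
  prof
}

#' Render one synthetic OCT B-scan
#'
#' Draws a labelled B-scan whose mean intensity follows the Beer-Lambert
#' decay \eqn{I(z) = I_0 e^{-2\mu (z - z_s)}} below the tissue surface, with
#' per-pixel intensities drawn as fully developed speckle: exponentially
#' distributed with that mean. The instrument (GRIN lens) surface appears as
#' a saturated bright band in the top rows, as on the real probe. Calyx-style
#' phenotypes modulate \eqn{\mu} sinusoidally in depth; fat-style phenotypes
#' superpose bright circular inclusions; pelvis-style phenotypes emit only
#' the surface band plus the noise floor.
#'
#' @param phenotype A [tissue_phenotype()].
#' @param noise_floor Additive mean background intensity (>= 0).
#' @param seed Optional integer seed; if supplied the scan is reproducible
#'   bit-for-bit.
#' @param width,depth Image size in pixels (lateral A-scans x depth samples).
#'   Defaults match the probe output: 650 x 1050 px at 2 um/px, a
#'   1.30 mm x 2.10 mm field of view.
#' @param lateral_pitch_mm,axial_pitch_mm Physical pixel pitch in mm.
#' @param speckle Speckle model: `"exponential"` (fully developed, unit-mean
#'   multiplicative), `"gamma"` (partially averaged speckle with shape
#'   `gamma_shape`), or `"none"` (noiseless mean image).
#' @param gamma_shape Shape parameter (number of incoherently averaged looks)
#'   for `speckle = "gamma"`.
#' @param surface_intensity Intensity of the saturated instrument-surface
#'   band.
#' @param surface_band_rows Rows occupied by the instrument-surface band.
#' @param axial_blur_sigma_px Optional Gaussian blur (sd, pixels) applied
#'   along depth to emulate the finite axial point-spread function; 0 (the
#'   default) disables it.
#' @param subject_id Optional identifier of the simulated kidney.
#' @return Object of class `bscan`: a list with `pixels` (depth x lateral
#'   matrix, nonnegative), pitches, `subject_id`, `label`, `seed`.
#' @examples
#' ph <- default_phenotypes()$cortex
#' sc <- render_bscan(ph, seed = 1, width = 80, depth = 300)
#' dim(sc$pixels)
#' @export
render_bscan <- function(phenotype, noise_floor = 0, seed = NULL,
                         width = 650L, depth = 1050L,
                         lateral_pitch_mm = 0.002, axial_pitch_mm = 0.002,
                         speckle = c("exponential", "gamma", "none"),
                         gamma_shape = 4,
                         surface_intensity = 1000,
                         surface_band_rows = 1:3,
                         axial_blur_sigma_px = 0,
                         subject_id = NA_character_) {
  stopifnot(inherits(phenotype, "tissue_phenotype"))
  speckle <- match.arg(speckle)
  if (lateral_pitch_mm <= 0 || axial_pitch_mm <= 0)
    stop("invalid geometry: pixel pitches must be positive")
  if (noise_floor < 0) stop("'noise_floor' must be >= 0")
  if (phenotype$surface_row > depth)
    stop("invalid geometry: 'surface_row' beyond image depth")
  if (!is.null(seed)) set.seed(seed)

  prof <- mean_depth_profile(phenotype, depth, axial_pitch_mm, noise_floor)
  m <- matrix(prof, nrow = depth, ncol = width)

  if (phenotype$has_tissue_signal && phenotype$dot_density > 0) {
    area_mm2 <- (width * lateral_pitch_mm) *
      ((depth - phenotype$surface_row + 1) * axial_pitch_mm)
    n_dots <- stats::rpois(1, phenotype$dot_density * area_mm2)
    if (n_dots > 0) {
      cz <- sample.int(depth - phenotype$surface_row + 1L, n_dots, replace = TRUE) +
        phenotype$surface_row - 1L
      cx <- sample.int(width, n_dots, replace = TRUE)
      r <- phenotype$dot_radius_px
      off <- expand.grid(dz = -r:r, dx = -r:r)
      off <- off[off$dz^2 + off$dx^2 <= r^2, ]
      for (d in seq_len(n_dots)) {
        zz <- cz[d] + off$dz
        xx <- cx[d] + off$dx
        ok <- zz >= phenotype$surface_row & zz <= depth & xx >= 1 & xx <= width
        m[cbind(zz[ok], xx[ok])] <- m[cbind(zz[ok], xx[ok])] *
          phenotype$dot_intensity_gain
      }
    }
  }

  px <- switch(speckle,
    none = m,
    exponential = m * matrix(stats::rexp(length(m)), nrow = depth),
    gamma = m * matrix(stats::rgamma(length(m), shape = gamma_shape,
                                     rate = gamma_shape), nrow = depth))

  if (axial_blur_sigma_px > 0) {
    half <- ceiling(3 * axial_blur_sigma_px)
    kern <- stats::dnorm(-half:half, sd = axial_blur_sigma_px)
    kern <- kern / sum(kern)
    px <- apply(px, 2, function(col) {
      padded <- c(rep(col[1], half), col, rep(col[length(col)], half))
      stats::convolve(padded, rev(kern), type = "filter")
    })
  }

  # Saturated instrument-surface band: deterministic, overwrites speckle.
  px[surface_band_rows, ] <- surface_intensity

  structure(
    list(pixels = px,
         lateral_pitch_mm = lateral_pitch_mm,
         axial_pitch_mm = axial_pitch_mm,
         subject_id = subject_id,
         label = phenotype$name,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %s: %d x %d px (%.2f x %.2f mm), subject %s\n",
              x$label, ncol(x$pixels), nrow(x$pixels),
              ncol(x$pixels) * x$lateral_pitch_mm,
              nrow(x$pixels) * x$axial_pitch_mm,
              as.character(x$subject_id)))
  invisible(x)
}

#' Generate a labelled phantom dataset of synthetic B-scans
#'
#' Emulates a multi-subject ex-vivo study: for each simulated kidney the
#' per-class phenotype parameters are drawn once (the attenuation coefficient
#' is jittered uniformly within `+/- subject_jitter` of the class default, so
#' cross-testing splits see genuine between-subject variance), then the
#' requested number of scans per class is rendered, each with its own child
#' seed. Each scan additionally receives an independent Gaussian jitter on
#' `mu` (`scan_jitter`, relative sd) emulating within-class tissue
#' heterogeneity across imaging sites — on real tissue the per-image
#' attenuation spread is far larger than the estimator noise alone. The
#' manifest records every parameter and seed, so any scan can be re-rendered
#' bit-exactly with [scan_from_manifest()].
#'
#' @param phenotypes Named list of [tissue_phenotype()] objects (defaults to
#'   the six renal classes from [default_phenotypes()]).
#' @param n_subjects Number of simulated kidneys (>= 2).
#' @param n_per_class Scans per class per subject.
#' @param seed Root seed; the dataset is fully reproducible from it.
#' @param subject_jitter Relative half-width of the per-subject uniform
#'   jitter on `mu` (default 0.15, i.e. +/- 15 percent).
#' @param scan_jitter Relative standard deviation of the per-scan Gaussian
#'   jitter on `mu` (default 0.05; multipliers are truncated at zero).
#' @param ... Passed to [render_bscan()] (e.g. `width`, `depth`,
#'   `noise_floor`, `speckle`).
#' @return Object of class `phantom_dataset`: list with `scans` (list of
#'   `bscan`) and `manifest` (data.frame with one row per scan: `scan_id`,
#'   `subject_id`, `label`, `seed`, `mu`, `i0`, `surface_row`,
#'   `stripe_period_px`, `stripe_contrast`, `dot_density`). Render geometry
#'   is kept in `attr(, "geometry")`.
#' @examples
#' ds <- generate_phantom_dataset(n_subjects = 2, n_per_class = 2, seed = 1,
#'                                width = 60, depth = 200)
#' nrow(ds$manifest)
#' @export
generate_phantom_dataset <- function(phenotypes = default_phenotypes(),
                                     n_subjects = 5, n_per_class = 10,
                                     seed = 1, subject_jitter = 0.15,
                                     scan_jitter = 0.05, ...) {
  if (length(phenotypes) == 0)
    stop("configuration error: empty tissue class list")
  if (!all(vapply(phenotypes, inherits, logical(1), "tissue_phenotype")))
    stop("'phenotypes' must be a list of tissue_phenotype objects")
  if (n_subjects < 2) stop("'n_subjects' must be >= 2")
  if (n_per_class < 1) stop("'n_per_class' must be >= 1")

  set.seed(seed)
  classes <- vapply(phenotypes, `[[`, character(1), "name")
  n_total <- n_subjects * length(phenotypes) * n_per_class

  # Subject-level parameter draws first, then one child seed per scan; the
  # draw order is fixed so the whole dataset is a pure function of `seed`.
  jit <- matrix(stats::runif(n_subjects * length(phenotypes),
                             1 - subject_jitter, 1 + subject_jitter),
                nrow = n_subjects)
  scan_jit <- pmax(0, stats::rnorm(n_total, 1, scan_jitter))
  scan_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  scans <- vector("list", n_total)
  rows <- vector("list", n_total)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("K%d", s)
    for (ci in seq_along(phenotypes)) {
      ph <- phenotypes[[ci]]
      ph_s <- ph
      ph_s$mu <- ph$mu * jit[s, ci]
      for (r in seq_len(n_per_class)) {
        idx <- idx + 1L
        ph_r <- ph_s
        ph_r$mu <- ph_s$mu * scan_jit[idx]
        sc <- render_bscan(ph_r, seed = scan_seeds[idx], subject_id = sid, ...)
        scans[[idx]] <- sc
        rows[[idx]] <- data.frame(
          scan_id = sprintf("%s_%s_%03d", sid, ph$name, r),
          subject_id = sid, label = ph$name, seed = scan_seeds[idx],
          mu = ph_r$mu, i0 = ph_r$i0, surface_row = ph_r$surface_row,
          stripe_period_px = ph_s$stripe_period_px,
          stripe_contrast = ph_s$stripe_contrast,
          dot_density = ph_s$dot_density,
          dot_intensity_gain = ph_s$dot_intensity_gain,
          dot_radius_px = ph_s$dot_radius_px,
          has_tissue_signal = ph_s$has_tissue_signal,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  out <- structure(list(scans = scans, manifest = manifest),
                   class = "phantom_dataset")
  attr(out, "geometry") <- list(...)
  attr(out, "root_seed") <- seed
  out
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d scans: %d subjects x %d classes\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              length(unique(x$manifest$label))))
  print(table(x$manifest$label))
  invisible(x)
}

#' Re-render one scan from a dataset manifest row
#'
#' The manifest stores every generative parameter plus the per-scan seed;
#' re-rendering reproduces the stored pixels bit-exactly.
#'
#' @param dataset A `phantom_dataset`.
#' @param i Row index into `dataset$manifest`.
#' @return A `bscan`.
#' @export
scan_from_manifest <- function(dataset, i) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  mr <- dataset$manifest[i, ]
  ph <- tissue_phenotype(mr$label, mu = mr$mu, i0 = mr$i0,
                         surface_row = mr$surface_row,
                         stripe_period_px = mr$stripe_period_px,
                         stripe_contrast = mr$stripe_contrast,
                         dot_density = mr$dot_density,
                         dot_intensity_gain = mr$dot_intensity_gain,
                         dot_radius_px = mr$dot_radius_px,
                         has_tissue_signal = mr$has_tissue_signal)
  args <- c(list(phenotype = ph, seed = mr$seed, subject_id = mr$subject_id),
            attr(dataset, "geometry"))
  do.call(render_bscan, args)
}

#' Write a B-scan as 16-bit grayscale TIFF
#'
#' Intensities (nonnegative floats) are divided by a fixed documented
#' `scale`, clipped to `[0, 1]` and quantised to 16 bits. The scale is fixed
#' per file set so images remain mutually comparable; the attenuation
#' estimator itself is scale-invariant.
#'
#' @param scan A `bscan`.
#' @param path Output file path.
#' @param scale Intensity corresponding to the 16-bit full scale.
#' @return `path`, invisibly.
#' @export
write_bscan_tiff <- function(scan, path, scale = 1024) {
  stopifnot(inherits(scan, "bscan"), scale > 0)
  img <- pmin(scan$pixels / scale, 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF back into a `bscan`
#'
#' Inverse of [write_bscan_tiff()] up to 16-bit quantisation.
#'
#' @param path TIFF file path.
#' @param scale Intensity of the 16-bit full scale used when writing.
#' @param lateral_pitch_mm,axial_pitch_mm Physical pixel pitch.
#' @param subject_id,label Optional metadata to attach.
#' @return A `bscan`.
#' @export
read_bscan_tiff <- function(path, scale = 1024,
                            lateral_pitch_mm = 0.002, axial_pitch_mm = 0.002,
                            subject_id = NA_character_, label = NA_character_) {
  img <- tiff::readTIFF(path)
  structure(
    list(pixels = img * scale,
         lateral_pitch_mm = lateral_pitch_mm, axial_pitch_mm = axial_pitch_mm,
         subject_id = subject_id, label = label, seed = NA_integer_),
    class = "bscan")
}

#' Write a phantom dataset to disk (TIFFs + CSV manifest)
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if missing).
#' @param scale Intensity full scale passed to [write_bscan_tiff()].
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir, scale = 1024) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$scans)) {
    write_bscan_tiff(dataset$scans[[i]],
                     file.path(dir, paste0(dataset$manifest$scan_id[i], ".tiff")),
                     scale = scale)
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
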