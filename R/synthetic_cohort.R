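# Reproducible synthetic slide cohorts with the sparse-lesion structure the
# slide-representation pipeline assumes: each slide is a variable-size bag of
# small RGB texture patches; positive slides carry a minority of
# "lesion"-textured patches (high-frequency oriented stripes) among
# "background"-textured ones (low-frequency blobs), and survival times follow
# a proportional-hazards model driven by the lesion burden.

#' Specification of a synthetic slide cohort
#'
#' @param n_slides_pos,n_slides_neg number of positive / negative slides.
#' @param patches_per_slide integer range `c(min, max)` of patches per slide
#'   (a single value gives a fixed count).
#' @param lesion_fraction fraction of a positive slide's patches carrying
#'   lesion texture. A single value in `(0, 1]` gives every positive slide
#'   the same fraction; a length-2 range draws a per-slide fraction
#'   uniformly, producing a lesion-burden gradient across the cohort (used
#'   for survival studies).
#' @param patch_size pixels per patch side.
#' @param texture_params list of texture descriptors, see Details.
#' @param hazard_coef log-hazard per unit lesion burden (burden = fraction of
#'   lesion patches in the slide).
#' @param baseline_scale baseline mean survival in months.
#' @param censoring_rate expected fraction of censored slides, in `[0, 1)`.
#' @param n_classes number of classes; with more than 2, positive slides are
#'   assigned subtypes that differ in lesion stripe orientation.
#' @param seed single integer driving every random draw.
#'
#' @details `texture_params` fields (all intensities in `[0, 1]` units):
#' `bg_base` background base intensity; `bg_blob_amp` amplitude of the
#' low-frequency blob field; `bg_blob_sigma` blob smoothing radius in pixels;
#' `lesion_base` lesion base intensity; `lesion_amp` range `c(lo, hi)` of the
#' per-patch stripe amplitude; `lesion_freq` range of stripe frequency in
#' cycles/pixel; `lesion_severity` range of the per-patch severity scaling
#' intensity/amplitude/tint from background-like to fully lesional;
#' `noise_sd` per-pixel Gaussian noise; `artifact_rate` range of the
#' per-slide fraction of background patches replaced by low-severity
#' lesion-textured "inflammation" artifacts (still labelled background);
#' `artifact_severity` their maximum severity; `slide_jitter_sd`
#' per-slide brightness offset emulating scan-to-scan variation.
#'
#' @return a validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_slides_pos, n_slides_neg,
                        patches_per_slide = c(12L, 48L),
                        lesion_fraction = 0.1, patch_size = 64L,
                        texture_params = list(), hazard_coef = 2,
                        baseline_scale = 24, censoring_rate = 0.3,
                        n_classes = 2L, seed = 1L) {
  tp <- utils::modifyList(list(bg_base = 0.80, bg_blob_amp = 0.15,
                               bg_blob_sigma = 8, lesion_base = 0.60,
                               lesion_amp = c(0.03, 0.30),
                               lesion_freq = c(0.15, 0.35),
                               lesion_severity = c(0.1, 1),
                               noise_sd = 0.05,
                               artifact_rate = c(0, 0.3),
                               artifact_severity = 0.35,
                               slide_jitter_sd = 0.03),
                          texture_params)
  if (length(patches_per_slide) == 1) patches_per_slide <- rep(patches_per_slide, 2)
  spec <- list(n_slides_pos = as.integer(n_slides_pos),
               n_slides_neg = as.integer(n_slides_neg),
               patches_per_slide = as.integer(patches_per_slide),
               lesion_fraction = as.numeric(lesion_fraction),
               patch_size = as.integer(patch_size), texture_params = tp,
               hazard_coef = as.numeric(hazard_coef),
               baseline_scale = as.numeric(baseline_scale),
               censoring_rate = as.numeric(censoring_rate),
               n_classes = as.integer(n_classes), seed = as.integer(seed))
  if (spec$n_slides_pos < 0) stop("invalid spec: n_slides_pos must be >= 0")
  if (spec$n_slides_neg < 0) stop("invalid spec: n_slides_neg must be >= 0")
  if (spec$patches_per_slide[1] < 1 ||
      spec$patches_per_slide[2] < spec$patches_per_slide[1])
    stop("invalid spec: patches_per_slide must be an increasing range with min >= 1")
  lf <- spec$lesion_fraction
  if (!length(lf) %in% 1:2 || any(lf <= 0) || any(lf > 1) ||
      (length(lf) == 2 && lf[2] < lf[1]))
    stop("invalid spec: lesion_fraction must lie in (0, 1]")
  if (spec$patch_size < 8) stop("invalid spec: patch_size must be >= 8")
  if (spec$censoring_rate < 0 || spec$censoring_rate >= 1)
    stop("invalid spec: censoring_rate must be in [0, 1)")
  if (spec$baseline_scale <= 0) stop("invalid spec: baseline_scale must be > 0")
  if (spec$n_classes < 2) stop("invalid spec: n_classes must be >= 2")
  structure(spec, class = "cohort_spec")
}

# Gaussian blur of a matrix by separable band-matrix filtering with
# replicate-normalised edges (kernel truncated at 3 sigma).
blur_band <- function(m, sigma) {
  n <- nrow(m)
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  make_band <- function(sz) {
    b <- matrix(0, sz, sz)
    for (i in seq_len(sz)) {
      j <- i + offs
      ok <- j >= 1 & j <= sz
      b[i, j[ok]] <- w[ok] / sum(w[ok])
    }
    b
  }
  br <- make_band(nrow(m))
  bc <- make_band(ncol(m))
  br %*% m %*% t(bc)
}

# background texture: low-frequency blobs + noise, lightly tinted (H&E-like
# pale pink). A fraction of background patches is replaced by a LOW-severity
# draw from the lesion texture model (severity <= artifact_severity) while
# keeping the background label: the analogue of inflammation or fibrosis,
# which genuinely overlaps weak lesions and therefore scores an
# intermediate probability. The artifact rate is a per-slide quantity
# (inflammation is a slide-level condition), drawn from the artifact_rate
# range, which gives naive mean pooling a slide-level nuisance to contend
# with. All draws come from the current RNG stream.
make_bg_patch <- function(size, tp, jitter, artifact_rate) {
  if (artifact_rate > 0 && stats::runif(1) < artifact_rate) {
    sev <- stats::runif(1, 0, tp$artifact_severity)
    return(make_lesion_patch(size, tp, jitter, sev = sev))
  }
  field <- blur_band(matrix(stats::rnorm(size^2), size), tp$bg_blob_sigma)
  s <- stats::sd(field)
  if (s > 0) field <- field / s
  amp <- stats::runif(1, 0.4, 1) * tp$bg_blob_amp
  base <- tp$bg_base + jitter
  g <- base - amp * (field - min(field)) / max(1e-8, diff(range(field)))
  tint <- c(1.0, 0.88, 0.94)
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3)
    img[, , ch] <- g * tint[ch] + stats::rnorm(size^2, sd = tp$noise_sd)
  pmin(pmax(img, 0), 1)
}

# lesion texture: high-frequency oriented stripes + noise, darker purple
# tint. A per-patch severity in lesion_severity interpolates intensity
# shift, stripe amplitude and tint from background-like (faint lesions that
# overlap with background artifacts) to fully lesional.
make_lesion_patch <- function(size, tp, jitter, theta = NULL, sev = NULL) {
  if (is.null(theta)) theta <- stats::runif(1, 0, pi)
  freq <- stats::runif(1, tp$lesion_freq[1], tp$lesion_freq[2])
  if (is.null(sev))
    sev <- stats::runif(1, tp$lesion_severity[1], tp$lesion_severity[2])
  amp <- tp$lesion_amp[1] + sev * (tp$lesion_amp[2] - tp$lesion_amp[1])
  phase <- stats::runif(1, 0, 2 * pi)
  xy <- outer(seq_len(size) * cos(theta), rep(1, size)) +
        outer(rep(1, size), seq_len(size) * sin(theta))
  stripes <- sin(2 * pi * freq * xy + phase)
  base <- tp$bg_base - sev * (tp$bg_base - tp$lesion_base) + jitter
  g <- base + amp * stripes
  bg_tint <- c(1.0, 0.88, 0.94)
  ls_tint <- c(0.80, 0.68, 0.95)
  tint <- bg_tint + sev * (ls_tint - bg_tint)
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3)
    img[, , ch] <- g * tint[ch] + stats::rnorm(size^2, sd = tp$noise_sd)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic slide cohort
#'
#' Produces `n_slides_pos + n_slides_neg` slides. Each positive slide carries
#' `round(f * n_patches)` lesion patches (at least one), where `f` is the
#' slide's lesion fraction; negative slides carry none. Patch counts are
#' drawn uniformly from `patches_per_slide`. Identical spec and seed
#' reproduce byte-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return list of slides; each slide is an `hm_slide` list with `slide_id`,
#'   `patches` (list of `img` `(size, size, 3)` in `[0,1]`, 0-based
#'   `grid_row`, `grid_col`), `label` (0 = negative, otherwise the class
#'   index), and logical `patch_truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  tp <- spec$texture_params
  n_total <- spec$n_slides_pos + spec$n_slides_neg
  positive <- rep(c(TRUE, FALSE), c(spec$n_slides_pos, spec$n_slides_neg))
  n_subtypes <- spec$n_classes - 1L
  slides <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    rng <- spec$patches_per_slide
    n_patches <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    jitter <- stats::rnorm(1, sd = tp$slide_jitter_sd)
    ar <- tp$artifact_rate
    artifact_rate <- if (length(ar) == 2) stats::runif(1, ar[1], ar[2]) else ar
    truth <- rep(FALSE, n_patches)
    label <- 0L
    theta <- NULL
    if (positive[s]) {
      lf <- spec$lesion_fraction
      f <- if (length(lf) == 2) stats::runif(1, lf[1], lf[2]) else lf
      n_lesion <- max(1L, round(f * n_patches))
      truth[sample.int(n_patches, min(n_lesion, n_patches))] <- TRUE
      label <- if (n_subtypes > 1) ((s - 1L) %% n_subtypes) + 1L else 1L
      # subtype-specific stripe orientation keeps subtypes separable
      if (n_subtypes > 1) theta <- (label - 1) * pi / n_subtypes + pi / 12
    }
    ncol_g <- as.integer(ceiling(sqrt(n_patches)))
    patches <- vector("list", n_patches)
    for (p in seq_len(n_patches)) {
      img <- if (truth[p]) make_lesion_patch(spec$patch_size, tp, jitter, theta)
             else make_bg_patch(spec$patch_size, tp, jitter, artifact_rate)
      patches[[p]] <- list(img = img,
                           grid_row = (p - 1L) %/% ncol_g,
                           grid_col = (p - 1L) %% ncol_g)
    }
    slides[[s]] <- structure(list(slide_id = sprintf("S%04d", s),
                                  patches = patches, label = label,
                                  time = NULL, event = NULL,
                                  patch_truth = truth),
                             class = "hm_slide")
  }
  slides
}

#' Attach proportional-hazards survival outcomes to a cohort
#'
#' Survival times are exponential with rate
#' `exp(hazard_coef * burden) / baseline_scale`, where `burden` is the
#' slide's fraction of lesion patches. Censoring is independent of the
#' covariate: a single global exponential censoring rate is solved so the
#' expected censored fraction equals `censoring_rate`.
#'
#' @param slides output of [generate_cohort()] (requires `patch_truth`).
#' @param spec the governing [cohort_spec()].
#' @return the slides with `time` (months) and `event` (0/1) filled in.
#' @export
generate_survival <- function(slides, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(vapply(slides, function(s) is.null(s$patch_truth), TRUE)))
    stop("slides lack patch_truth; survival generation needs lesion flags")
  set.seed(spec$seed + 1L)
  burden <- vapply(slides, function(s) mean(s$patch_truth), 0)
  lambda <- exp(spec$hazard_coef * burden) / spec$baseline_scale
  t_event <- stats::rexp(length(slides), rate = lambda)
  if (spec$censoring_rate > 0) {
    mu <- stats::uniroot(function(m) mean(m / (m + lambda)) - spec$censoring_rate,
                         interval = c(1e-10, 1e6 * max(lambda)))$root
    t_cens <- stats::rexp(length(slides), rate = mu)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, length(slides))
  }
  for (i in seq_along(slides)) {
    slides[[i]]$time <- time[i]
    slides[[i]]$event <- event[i]
  }
  slides
}

#' Write a cohort to disk as per-slide patch directories plus a manifest
#'
#' Patches are written as `r{row}_c{col}.png` inside one directory per
#' slide; the manifest TSV has columns `slide_id`, `path`, `label`, `time`,
#' `event`, `n_patches` with empty strings for missing values.
#'
#' @param slides list of slides.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(slides, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(slides, function(s) {
    sdir <- file.path(dir, s$slide_id)
    dir.create(sdir, showWarnings = FALSE)
    for (p in s$patches)
      png::writePNG(p$img, file.path(sdir, sprintf("r%d_c%d.png",
                                                   p$grid_row, p$grid_col)))
    data.frame(slide_id = s$slide_id, path = s$slide_id,
               label = s$label %||% NA, time = s$time %||% NA,
               event = s$event %||% NA, n_patches = length(s$patches))
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.tsv`.
#' @return list of `hm_slide` objects (without `patch_truth`).
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    sdir <- file.path(dir, manifest$path[i])
    files <- sort(list.files(sdir, pattern = "^r\\d+_c\\d+\\.png$"))
    patches <- lapply(files, function(f) {
      rc <- as.integer(regmatches(f, gregexpr("\\d+", f))[[1]][1:2])
      img <- png::readPNG(file.path(sdir, f))
      list(img = img, grid_row = rc[1], grid_col = rc[2])
    })
    structure(list(slide_id = manifest$slide_id[i], patches = patches,
                   label = manifest$label[i] %||% NA,
                   time = if ("time" %in% names(manifest)) manifest$time[i] else NULL,
                   event = if ("event" %in% names(manifest)) manifest$event[i] else NULL,
                   patch_truth = NULL),
              class = "hm_slide")
  })
}
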