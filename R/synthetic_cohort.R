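# Synthetic two-phase cohorts with planted habitats, Tim-3 labels, IHC
# fields and survival times: the ground-truth test surface for the pipeline.

#' Specification of a synthetic cohort
#'
#' Defines the study conditions a generated cohort emulates: tumor geometry,
#' per-habitat two-phase intensity structure, where the Tim-3 signal lives,
#' and the clinical/survival model. Defaults emulate a 102-patient HCC-like
#' cohort with three concentric habitat shells whose class signal lives in
#' habitat 2 of the arterial phase — predominantly as a texture change
#' (longer noise correlation length, mildly larger noise sd) plus a small
#' mean shift that is volume-compensated in the other habitats so the
#' whole-ROI mean carries no signal.
#'
#' @param n_patients cohort size.
#' @param volume_shape voxels per axis (length 3).
#' @param spacing_mm voxel spacing (mm).
#' @param tumor_radius_range min/max tumor radius (mm).
#' @param n_habitats_true number of planted habitats (default 3).
#' @param habitat_intensity_means list with `ACE` and `VCE` numeric vectors of
#'   per-habitat mean HU (core to rim); must be pairwise distinct per phase.
#' @param habitat_texture_scale per-habitat correlation length of the smoothed
#'   intensity noise, in voxels.
#' @param noise_sd marginal sd of the smoothed intensity noise (HU).
#' @param between_patient_sd between-patient biological variability (HU):
#'   each patient draws a global per-phase enhancement offset with this sd
#'   (shared by all habitats, emulating contrast-timing/physiology
#'   differences) plus an independent per-habitat deviation with half this sd.
#' @param signal_features list `(habitat = , phase = )` naming where the
#'   Tim-3 signal is planted.
#' @param effect_size mean HU shift in the signal habitat/phase for
#'   Tim-3-high patients (compensated elsewhere so the whole-ROI mean is
#'   unchanged).
#' @param texture_effect fractional increase of noise sd in the signal
#'   habitat/phase for Tim-3-high patients.
#' @param texture_scale_effect fractional increase of the noise correlation
#'   length in the signal habitat/phase for Tim-3-high patients: a pure
#'   texture signal that leaves the voxel-intensity histogram unchanged, so
#'   only spatial (texture-matrix) features can see it.
#' @param noise_sd_dispersion between-patient dispersion of the noise level:
#'   each patient's noise sd is multiplied by a log-normal factor with this
#'   log-sd (scanner dose / reconstruction variability).
#' @param shell_frac_jitter per-patient Gaussian jitter (sd, in radius
#'   fractions) on the habitat shell boundaries (tumor-geometry variability).
#' @param class_balance fraction of Tim-3-high patients, in (0, 1).
#' @param survival_hr hazard ratio of Tim-3-high vs low overall survival.
#' @param median_os_low median OS of the Tim-3-low group (months).
#' @param censor_rate fraction of patients censored.
#' @param recurrence_rate marginal probability of recurrence.
#' @param geometry `"shells"` (concentric, perturbed) or `"blobs"`.
#' @param shell_fracs habitat boundary radii as fractions of the tumor
#'   radius (length `n_habitats_true - 1`); `NULL` for defaults.
#' @param boundary_perturbation relative amplitude of the smooth random
#'   perturbation applied to the radial distance field.
#' @param background_hu intensity outside the tumor.
#' @param seed integer seed; with `patient_index` it fully determines each
#'   patient.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 102L,
                        volume_shape = c(48L, 48L, 48L),
                        spacing_mm = c(1, 1, 1),
                        tumor_radius_range = c(9, 14),
                        n_habitats_true = 3L,
                        habitat_intensity_means = list(
                          ACE = c(30, 80, 130), VCE = c(40, 65, 90)),
                        habitat_texture_scale = c(1, 1, 1),
                        noise_sd = 12,
                        between_patient_sd = 6,
                        signal_features = list(habitat = 2L, phase = "ACE"),
                        effect_size = 2,
                        texture_effect = 0.15,
                        texture_scale_effect = 0.5,
                        noise_sd_dispersion = 0.2,
                        shell_frac_jitter = 0.05,
                        class_balance = 0.5,
                        survival_hr = 2.2,
                        median_os_low = 40,
                        censor_rate = 0.5,
                        recurrence_rate = 0.6,
                        geometry = c("shells", "blobs"),
                        shell_fracs = NULL,
                        boundary_perturbation = 0.05,
                        background_hu = -80,
                        seed = 1L) {
  geometry <- match.arg(geometry)
  k <- as.integer(n_habitats_true)
  if (k < 1L) stop("n_habitats_true must be >= 1")
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must be in (0, 1)")
  }
  for (rate in c(censor_rate, recurrence_rate)) {
    if (rate < 0 || rate > 1) stop("rates must lie in [0, 1]")
  }
  for (ph in c("ACE", "VCE")) {
    mu <- habitat_intensity_means[[ph]]
    if (length(mu) != k) stop("need one ", ph, " mean per habitat")
    if (anyDuplicated(mu)) stop(ph, " habitat means must be pairwise distinct")
  }
  if (length(habitat_texture_scale) == 1L) {
    habitat_texture_scale <- rep(habitat_texture_scale, k)
  }
  if (is.null(shell_fracs)) {
    shell_fracs <- if (k == 3L) c(0.42, 0.74) else
      (seq_len(k - 1L) / k)^(1 / 3)
  }
  if (k > 1L && length(shell_fracs) != k - 1L) {
    stop("shell_fracs must have n_habitats_true - 1 entries")
  }
  structure(list(
    n_patients = as.integer(n_patients), volume_shape = as.integer(volume_shape),
    spacing_mm = as.numeric(spacing_mm),
    tumor_radius_range = as.numeric(tumor_radius_range),
    n_habitats_true = k, habitat_intensity_means = habitat_intensity_means,
    habitat_texture_scale = as.numeric(habitat_texture_scale),
    noise_sd = noise_sd, between_patient_sd = between_patient_sd,
    signal_features = signal_features, effect_size = effect_size,
    texture_effect = texture_effect,
    texture_scale_effect = texture_scale_effect,
    noise_sd_dispersion = noise_sd_dispersion,
    shell_frac_jitter = shell_frac_jitter, class_balance = class_balance,
    survival_hr = survival_hr, median_os_low = median_os_low,
    censor_rate = censor_rate, recurrence_rate = recurrence_rate,
    geometry = geometry, shell_fracs = as.numeric(shell_fracs),
    boundary_perturbation = boundary_perturbation,
    background_hu = background_hu, seed = as.integer(seed)),
    class = "cohort_spec")
}

# unit-sd spatially correlated noise field
correlated_noise <- function(dm, scale_vox) {
  correlated_noise_fft(dm, scale_vox)
}

#' Generate one synthetic patient
#'
#' Places a perturbed ellipsoidal tumor in the volume, partitions it into
#' contiguous habitats (concentric shells by default), and fills each habitat
#' with its per-phase mean plus spatially smoothed Gaussian noise. For
#' Tim-3-high patients the configured mean/texture shift is applied only in
#' the designated signal habitat and phase, with a volume-weighted opposite
#' shift in the remaining habitats so the whole-ROI mean is unchanged.
#' Deterministic given `(spec$seed, patient_index)`.
#'
#' @param spec a [cohort_spec()].
#' @param patient_index 1-based patient index.
#' @param tim3_class `"low"`, `"high"`, or `NULL` to draw from
#'   `spec$class_balance`.
#' @return A `synthetic_patient`: two [image_volume()]s (raw HU), a
#'   [roi_mask()], the ground-truth habitat label array (`true_habitats`),
#'   the Tim-3 class, replicate IHC fields with their mean H-score, and
#'   survival fields.
#' @export
generate_patient <- function(spec, patient_index, tim3_class = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed((spec$seed %% 1000003L) * 2011L + as.integer(patient_index))
  dm <- spec$volume_shape
  sp <- spec$spacing_mm
  k <- spec$n_habitats_true
  if (is.null(tim3_class)) {
    tim3_class <- if (runif(1) < spec$class_balance) "high" else "low"
  }
  r <- runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
  half_extent <- min((dm - 1) * sp) / 2
  r_max <- r * (1 + 3 * spec$boundary_perturbation)
  if (r_max > half_extent - 1) {
    stop(sprintf("tumor radius %.1f mm does not fit in the volume", r))
  }
  center <- (dm - 1) * sp / 2 + runif(3, -1, 1)
  ax <- lapply(1:3, function(i) (seq_len(dm[i]) - 1) * sp[i] - center[i])
  d <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  eta <- correlated_noise(dm, 3)
  d_pert <- d * (1 + spec$boundary_perturbation * eta)
  roi <- d_pert <= r
  if (spec$geometry == "shells") {
    fr <- spec$shell_fracs
    if (spec$shell_frac_jitter > 0 && length(fr)) {
      fr <- sort(pmin(pmax(fr + rnorm(length(fr), 0, spec$shell_frac_jitter),
                           0.15), 0.92))
    }
    lab <- array(1L, dm)
    for (b in r * fr) lab <- lab + (d_pert > b)
  } else {
    # blobs: nearest of k seed points inside the tumor, perturbed metric
    seeds <- matrix(runif(3 * k, -0.6 * r, 0.6 * r), ncol = 3)
    dist_k <- vapply(seq_len(k), function(j) {
      dj <- sqrt(outer(outer((ax[[1]] - seeds[j, 1])^2,
                             (ax[[2]] - seeds[j, 2])^2, `+`),
                       (ax[[3]] - seeds[j, 3])^2, `+`))
      as.vector(dj * (1 + spec$boundary_perturbation * eta))
    }, numeric(prod(dm)))
    lab <- array(max.col(-dist_k, ties.method = "first"), dm)
  }
  true_habitats <- array(0L, dm)
  true_habitats[roi] <- lab[roi]
  vox_per_hab <- tabulate(true_habitats[roi], k)
  # per-patient biological offsets: a global per-phase enhancement shift
  # (contrast timing / physiology, shared by all habitats) plus a smaller
  # independent per-habitat deviation
  offsets <- matrix(rnorm(2, 0, spec$between_patient_sd), nrow = 2, ncol = k,
                    dimnames = list(c("ACE", "VCE"), NULL)) +
    matrix(rnorm(2 * k, 0, spec$between_patient_sd / 2), nrow = 2)
  sig_h <- spec$signal_features$habitat
  sig_ph <- spec$signal_features$phase
  shift <- matrix(0, nrow = 2, ncol = k, dimnames = list(c("ACE", "VCE"), NULL))
  if (tim3_class == "high" && spec$effect_size != 0 && k > 1L) {
    # volume-weighted compensation in the other habitats nulls the
    # whole-ROI mean shift exactly
    shift[sig_ph, sig_h] <- spec$effect_size
    others <- setdiff(seq_len(k), sig_h)
    shift[sig_ph, others] <- -spec$effect_size * vox_per_hab[sig_h] /
      sum(vox_per_hab[others])
  }
  vols <- list()
  for (ph in c("ACE", "VCE")) {
    vals <- array(spec$background_hu, dm)
    mu <- spec$habitat_intensity_means[[ph]]
    # one noise field per distinct correlation length, shared by habitats;
    # a per-patient log-normal factor disperses the overall noise level.
    # Tim-3-high patients get a longer correlation length (and mildly larger
    # sd) in the signal habitat/phase: a subregion-specific texture signal.
    sc_h <- spec$habitat_texture_scale
    if (tim3_class == "high" && ph == sig_ph) {
      sc_h[sig_h] <- sc_h[sig_h] * (1 + spec$texture_scale_effect)
    }
    fields <- list()
    noise_scale <- exp(rnorm(1, 0, spec$noise_sd_dispersion))
    if (spec$noise_sd > 0) {
      for (sc in unique(sc_h)) {
        fields[[as.character(sc)]] <- correlated_noise(dm, sc)
      }
    }
    for (h in seq_len(k)) {
      sel <- roi & true_habitats == h
      m <- mu[h] + offsets[ph, h] + shift[ph, h]
      if (spec$noise_sd > 0) {
        nz <- fields[[as.character(sc_h[h])]]
        s <- spec$noise_sd * noise_scale
        if (tim3_class == "high" && h == sig_h && ph == sig_ph) {
          s <- s * (1 + spec$texture_effect)
        }
        vals[sel] <- m + s * nz[sel]
      } else {
        vals[sel] <- m
      }
    }
    vols[[ph]] <- image_volume(vals, sp, phase = ph)
  }
  ihc <- lapply(1:3, function(i) generate_ihc_field(tim3_class = tim3_class))
  hs <- h_score(ihc)
  rate <- log(2) / spec$median_os_low
  if (tim3_class == "high") rate <- rate * spec$survival_hr
  os <- rexp(1, rate)
  rec <- rbinom(1, 1, spec$recurrence_rate)
  structure(list(
    patient_id = sprintf("P%03d", as.integer(patient_index)),
    ace_volume = vols$ACE, vce_volume = vols$VCE,
    roi = roi_mask(array(as.integer(roi), dm), sp),
    true_habitats = true_habitats, tim3_class = tim3_class,
    ihc_fields = ihc, h_score = hs,
    os_months = os, os_event = 1L, recurrence_flag = rec),
    class = "synthetic_patient")
}

#' Generate a full synthetic cohort
#'
#' Class labels honor `class_balance` exactly up to rounding; survival times
#' are exponential with the configured hazard ratio; a fixed fraction of
#' patients is censored uniformly before their event time. With `dir` set,
#' per-patient NIfTI volumes (`ace`, `vce`, `roi`, `habitats_true`) and a
#' `clinical.csv` are written.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @return `list(patients = , clinical = )`; `clinical` has columns
#'   patient_id, tim3_class, h_score, os_months, os_event, recurrence.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  cols <- c("patient_id", "tim3_class", "h_score", "os_months", "os_event",
            "recurrence")
  if (n == 0L) {
    clin <- as.data.frame(setNames(
      list(character(), character(), numeric(), numeric(), integer(),
           integer()), cols))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
    }
    return(list(patients = list(), clinical = clin))
  }
  set.seed(spec$seed)
  n_high <- round(n * spec$class_balance)
  classes <- sample(c(rep("high", n_high), rep("low", n - n_high)))
  patients <- lapply(seq_len(n), function(i) {
    generate_patient(spec, i, tim3_class = classes[i])
  })
  # censoring: a fixed fraction, censored uniformly before the event
  set.seed(spec$seed + 99991L)
  n_cens <- floor(spec$censor_rate * n)
  cens_idx <- if (n_cens > 0) sample(n, n_cens) else integer(0)
  for (i in cens_idx) {
    patients[[i]]$os_months <- runif(1, 0, patients[[i]]$os_months)
    patients[[i]]$os_event <- 0L
  }
  clin <- data.frame(
    patient_id = vapply(patients, `[[`, "", "patient_id"),
    tim3_class = vapply(patients, `[[`, "", "tim3_class"),
    h_score = vapply(patients, `[[`, 0, "h_score"),
    os_months = vapply(patients, `[[`, 0, "os_months"),
    os_event = vapply(patients, function(p) as.integer(p$os_event), 0L),
    recurrence = vapply(patients, function(p) as.integer(p$recurrence_flag),
                        0L))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in patients) {
      pd <- file.path(dir, p$patient_id)
      dir.create(pd, showWarnings = FALSE)
      write_volume(p$ace_volume, file.path(pd, "ace.nii.gz"))
      write_volume(p$vce_volume, file.path(pd, "vce.nii.gz"))
      write_volume(p$roi, file.path(pd, "roi.nii.gz"))
      ht <- p$roi
      ht$labels <- p$true_habitats
      img <- nifti_with_geometry(ht$labels, ht$spacing, ht$origin, "uint8")
      RNifti::writeNifti(img, file.path(pd, "habitats_true.nii.gz"))
    }
    write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  }
  list(patients = patients, clinical = clin)
}

#' Draw an IHC field of four staining-category percentages
#'
#' Draws (High Positive, Positive, Low Positive, Negative) percentages from a
#' Dirichlet distribution whose concentration depends on the Tim-3 class, so
#' that the expected H-score of the high class exceeds the 92.3 cutpoint and
#' that of the low class falls below it. Percentages always sum to 100.
#'
#' @param seed optional integer seed.
#' @param tim3_class `"low"` or `"high"`.
#' @param concentration optional length-4 Dirichlet parameters overriding the
#'   class defaults (high: 5,4,2,1; low: 1,2,3,6).
#' @return An [ihc_field()].
#' @export
generate_ihc_field <- function(seed = NULL, tim3_class = c("low", "high"),
                               concentration = NULL) {
  tim3_class <- match.arg(tim3_class)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(concentration)) {
    concentration <- if (tim3_class == "high") c(5, 4, 2, 1) else c(1, 2, 3, 6)
  }
  g <- rgamma(4, shape = concentration, rate = 1)
  p <- 100 * g / sum(g)
  ihc_field(p[1], p[2], p[3], p[4])
}
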