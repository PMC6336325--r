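#' Phantom parcellation for synthetic subjects
#'
#' Builds a deterministic spherical "brain" with a concentric/sector
#' parcellation: a posterior-fossa slab split into cerebellar grey matter
#' (the reference region) and brainstem, a subcortical core (putamen,
#' caudate, thalamus), a white-matter shell, and `n_cortical_regions`
#' angular cortical sectors. Labels partition the brain mask; 0 is
#' background.
#'
#' @param shape integer length-3 grid size, each dimension >= 16.
#' @param n_cortical_regions number of cortical sectors (>= 3).
#' @param voxel_size_mm isotropic voxel size in millimetres.
#' @return A [pet_atlas()].
#' @export
make_phantom_atlas <- function(shape = c(32L, 32L, 32L),
                               n_cortical_regions = 4L,
                               voxel_size_mm = 4) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("grid too small: each dimension must be at least 16")
  if (n_cortical_regions < 3L) stop("need at least 3 cortical regions")
  ctr <- (shape + 1) / 2
  R <- 0.42 * min(shape)
  ax <- seq_len(shape[1L]) - ctr[1L]
  ay <- seq_len(shape[2L]) - ctr[2L]
  az <- seq_len(shape[3L]) - ctr[3L]
  dx <- array(ax, shape)
  dy <- array(rep(ay, each = shape[1L]), shape)
  dz <- array(rep(az, each = shape[1L] * shape[2L]), shape)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  brain <- r <= R

  labels <- array(0L, shape)
  fossa <- brain & dz < -0.55 * R
  stem <- fossa & sqrt(dx^2 + dy^2) < 0.18 * R
  labels[fossa] <- 1L            # cerebellum_gm
  labels[stem] <- 2L             # brainstem
  rest <- brain & !fossa
  core <- rest & r < 0.35 * R
  labels[core & dx > 0] <- 3L    # putamen
  labels[core & dx <= 0 & dy > 0] <- 4L   # caudate
  labels[core & dx <= 0 & dy <= 0] <- 5L  # thalamus
  wm <- rest & r >= 0.35 * R & r < 0.7 * R
  labels[wm] <- 6L               # white_matter
  cortex <- rest & r >= 0.7 * R
  ang <- atan2(dy, dx)           # (-pi, pi]
  sector <- pmin(1L + as.integer(floor((ang + pi) / (2 * pi) *
                                         n_cortical_regions)),
                 n_cortical_regions)
  labels[cortex] <- 6L + sector[cortex]

  cort_names <- c("frontal_cortex", "parietal_cortex", "temporal_cortex",
                  "occipital_cortex",
                  if (n_cortical_regions > 4L)
                    paste0("cortical_", 5:n_cortical_regions))
  cort_names <- cort_names[seq_len(n_cortical_regions)]
  tab <- data.frame(
    label = seq_len(6L + n_cortical_regions),
    name = c("cerebellum_gm", "brainstem", "putamen", "caudate",
             "thalamus", "white_matter", cort_names),
    tissue_class = c("reference", "other", "subcortical", "subcortical",
                     "subcortical", "white_matter",
                     rep("cortical", n_cortical_regions)),
    is_reference = c(TRUE, rep(FALSE, 5L + n_cortical_regions)),
    stringsAsFactors = FALSE)
  pet_atlas(labels, tab, voxel_size_mm)
}

#' Feng-style arterial input and reference-tissue kinetics
#'
#' Parameters of the simulated tracer delivery: a tri-exponential Feng
#' plasma input \eqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} +
#' A_2 e^{-\lambda_2 t} + A_3 e^{-\lambda_3 t}} (t in minutes) feeding a
#' one-tissue reference region \eqn{dC_R/dt = K_1 C_p - k_2' C_R}.
#'
#' @param A1,A2,A3 Feng amplitudes (activity units).
#' @param lambda1,lambda2,lambda3 Feng decay constants (1/min).
#' @param K1_ref reference-region influx constant (mL/min/mL).
#' @param k2_ref reference-region efflux constant k2' (1/min).
#' @param scale global activity scale applied to the input.
#' @return A list of class `input_spec`.
#' @export
feng_input_spec <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                            lambda1 = 4.134, lambda2 = 0.1191,
                            lambda3 = 0.0104, K1_ref = 0.35,
                            k2_ref = 0.13, scale = 0.25) {
  structure(list(A1 = A1, A2 = A2, A3 = A3, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3,
                 K1_ref = K1_ref, k2_ref = k2_ref, scale = scale),
            class = "input_spec")
}

feng_plasma <- function(t_min, sp) {
  sp$scale * ((sp$A1 * t_min - sp$A2 - sp$A3) * exp(-sp$lambda1 * t_min) +
                sp$A2 * exp(-sp$lambda2 * t_min) +
                sp$A3 * exp(-sp$lambda3 * t_min))
}

#' Simulate a reference-region time-activity curve
#'
#' Convolves the Feng plasma input with one-tissue reference kinetics on a
#' fine uniform grid and averages the resulting curve over the frame
#' schedule. The call is noiseless and deterministic; `seed` is accepted for
#' interface symmetry but unused.
#'
#' @param schedule a [frame_schedule()].
#' @param input_spec a [feng_input_spec()].
#' @param seed ignored (the curve is deterministic).
#' @param dt_s fine-grid step in seconds.
#' @return A [tac()] with attribute `fine` (list `t_min`, `value`) holding
#'   the underlying fine-grid curve.
#' @export
simulate_reference_tac <- function(schedule, input_spec = feng_input_spec(),
                                   seed = NULL, dt_s = 1) {
  stopifnot(inherits(schedule, "frame_schedule"))
  t_min <- fine_grid_min(schedule, dt_s)
  cp <- feng_plasma(t_min, input_spec)
  cr <- input_spec$K1_ref * exp_conv(cp, t_min, input_spec$k2_ref)
  out <- tac_from_schedule(schedule, frame_average(cr, t_min, schedule))
  attr(out, "fine") <- list(t_min = t_min, value = cr)
  out
}

#' Regional kinetic ground truth
#'
#' The generator's truth: per-region true `R1` and `BPnd`, the global
#' reference efflux `k2_prime_true`, the linear flow-metabolism coupling
#' mapping R1 to FDG uptake, and the noise scales. The reference region must
#' have `R1 = 1` and `BPnd = 0`.
#'
#' @param regions data.frame with columns `name`, `R1` (> 0), `BPnd` (>= 0).
#' @param reference_name name of the reference region in `regions`.
#' @param k2_prime_true reference efflux constant (1/min).
#' @param coupling_slope,coupling_offset FDG = slope * R1 + offset (+ jitter).
#' @param noise_scale PIB TAC noise: coefficient of variation at the TAC
#'   peak (0 = noiseless).
#' @param fdg_noise_sd voxel noise SD of the FDG image (reference units).
#' @param region_jitter_sd per-region metabolic offset SD on FDG.
#' @param input_spec a [feng_input_spec()]; its `k2_ref` is overridden by
#'   `k2_prime_true`.
#' @param group optional group label carried along ("PIB+" / "PIB-").
#' @return An object of class `region_kinetic_spec`.
#' @export
region_kinetic_spec <- function(regions, reference_name = "cerebellum_gm",
                                k2_prime_true = 0.13,
                                coupling_slope = 1.4,
                                coupling_offset = -0.3,
                                noise_scale = 0.05,
                                fdg_noise_sd = 0.02,
                                region_jitter_sd = 0.03,
                                input_spec = feng_input_spec(),
                                group = NA_character_) {
  stopifnot(is.data.frame(regions),
            all(c("name", "R1", "BPnd") %in% names(regions)))
  if (any(regions$R1 <= 0)) stop("true R1 must be positive")
  if (any(regions$BPnd < 0)) stop("true BPnd must be nonnegative")
  i <- match(reference_name, regions$name)
  if (is.na(i)) stop("reference region missing from the regional truth table")
  if (abs(regions$R1[i] - 1) > 1e-12 || regions$BPnd[i] != 0)
    stop("reference region must have R1 = 1 and BPnd = 0")
  if (k2_prime_true <= 0) stop("k2_prime_true must be positive")
  input_spec$k2_ref <- k2_prime_true
  structure(list(regions = regions, reference_name = reference_name,
                 k2_prime_true = k2_prime_true,
                 coupling_slope = coupling_slope,
                 coupling_offset = coupling_offset,
                 noise_scale = noise_scale, fdg_noise_sd = fdg_noise_sd,
                 region_jitter_sd = region_jitter_sd,
                 input_spec = input_spec, group = group),
            class = "region_kinetic_spec")
}

# Template truth for a phantom atlas. Cortical R1 sits in [0.8, 1.0] with
# region-specific means; PIB+ subjects get elevated cortical BPnd and a
# fractional cortical R1 reduction.
#' @rdname region_kinetic_spec
#' @param atlas a `pet_atlas` naming the regions to cover.
#' @param cortical_bpnd_pos mean cortical BPnd of PIB+ subjects.
#' @param cortical_bpnd_neg near-zero cortical BPnd of PIB- subjects.
#' @param cortical_r1_reduction fractional cortical R1 reduction in PIB+.
#' @param ... further arguments passed to `region_kinetic_spec`.
#' @export
default_kinetic_spec <- function(atlas, group = c("PIB-", "PIB+"),
                                 cortical_bpnd_pos = 1.5,
                                 cortical_bpnd_neg = 0.1,
                                 cortical_r1_reduction = 0.05, ...) {
  group <- match.arg(group)
  pos <- group == "PIB+"
  base_r1 <- c(cerebellum_gm = 1, brainstem = 0.85, putamen = 1.13,
               caudate = 0.70, thalamus = 1.00, white_matter = 0.75,
               frontal_cortex = 0.92, parietal_cortex = 0.93,
               temporal_cortex = 0.90, occipital_cortex = 0.95)
  base_bp <- c(cerebellum_gm = 0, brainstem = 0.1,
               putamen = if (pos) 1.3 else 0.1,
               caudate = if (pos) 1.0 else 0.1,
               thalamus = if (pos) 0.6 else 0.1,
               white_matter = 0.4,
               frontal_cortex = NA, parietal_cortex = NA,
               temporal_cortex = NA, occipital_cortex = NA)
  nm <- atlas$table$name
  cls <- atlas$table$tissue_class
  R1 <- ifelse(nm %in% names(base_r1), base_r1[nm],
               ifelse(cls == "cortical", 0.92, 0.9))
  bp <- ifelse(cls == "cortical",
               if (pos) cortical_bpnd_pos else cortical_bpnd_neg,
               ifelse(nm %in% names(base_bp) & !is.na(base_bp[nm]),
                      base_bp[nm], 0.1))
  if (pos) R1[cls == "cortical"] <- R1[cls == "cortical"] *
      (1 - cortical_r1_reduction)
  ref <- nm[atlas$table$is_reference]
  R1[nm == ref] <- 1; bp[nm == ref] <- 0
  region_kinetic_spec(
    data.frame(name = nm, R1 = as.numeric(R1), BPnd = as.numeric(bp),
               stringsAsFactors = FALSE),
    reference_name = ref, group = group, ...)
}

#' Simulate one synthetic subject
#'
#' Generates a dynamic PIB scan (per-voxel SRTM forward curves with
#' `k2 = R1 * k2_prime_true`, plus Gaussian noise whose SD scales as
#' `sqrt(mean activity / frame duration)`, normalized so `noise_scale` is the
#' coefficient of variation at the TAC peak) and a static FDG image coupled
#' linearly to the true R1 volume with per-region metabolic jitter and voxel
#' noise. The truth is retained alongside the data.
#'
#' @param atlas a `pet_atlas`.
#' @param spec a [region_kinetic_spec()] covering every atlas region.
#' @param schedule a [frame_schedule()].
#' @param seed integer seed; the subject is reproducible from (spec, seed).
#' @param subject_id identifier string.
#' @return An object of class `subject_data`: `dynamic_pib`, `static_fdg`,
#'   `truth` (regions, `k2_prime_true`, true `R1_map`), `group`, `seed`.
#' @export
simulate_subject <- function(atlas, spec, schedule = pib_frame_schedule(),
                             seed = 1, subject_id = "sub-01") {
  stopifnot(inherits(atlas, "pet_atlas"),
            inherits(spec, "region_kinetic_spec"))
  nm <- atlas$table$name
  if (!all(nm %in% spec$regions$name))
    stop("spec does not cover all atlas regions")
  reg <- spec$regions[match(nm, spec$regions$name), ]
  ref_tac <- simulate_reference_tac(schedule, spec$input_spec)
  Fn <- n_frames(schedule)
  region_tacs <- t(vapply(seq_len(nrow(reg)), function(i) {
    srtm_forward(ref_tac, reg$R1[i], reg$R1[i] * spec$k2_prime_true,
                 reg$BPnd[i], schedule)$value
  }, numeric(Fn)))

  dims <- dim(atlas$labels)
  lab_vec <- as.vector(atlas$labels)
  idx <- match(lab_vec, atlas$table$label)    # NA for background
  inside <- !is.na(idx)
  V <- length(lab_vec)
  M <- matrix(0, V, Fn)
  M[inside, ] <- region_tacs[idx[inside], ]
  r1_vec <- numeric(V)
  r1_vec[inside] <- reg$R1[idx[inside]]

  with_local_seed(seed, {
    if (spec$noise_scale > 0) {
      peak <- max(region_tacs)
      dur_min <- frame_duration_s(schedule) / 60
      pk_dur <- dur_min[which.max(apply(region_tacs, 2, max))]
      sd_rf <- spec$noise_scale * peak *
        sqrt(pmax(region_tacs, 0) / peak * (pk_dur / rep(dur_min,
                                                         each = nrow(reg))))
      sd_vox <- matrix(0, V, Fn)
      sd_vox[inside, ] <- sd_rf[idx[inside], ]
      M <- M + matrix(stats::rnorm(V * Fn), V, Fn) * sd_vox
    }
    fdg <- numeric(V)
    jit <- stats::rnorm(nrow(reg), 0, spec$region_jitter_sd)
    jit[reg$name == spec$reference_name] <- 0
    fdg[inside] <- spec$coupling_slope * r1_vec[inside] +
      spec$coupling_offset + jit[idx[inside]]
    if (spec$fdg_noise_sd > 0)
      fdg[inside] <- fdg[inside] +
        stats::rnorm(sum(inside), 0, spec$fdg_noise_sd)
  })

  structure(list(
    dynamic_pib = dynamic_image(array(M, c(dims, Fn)), atlas$voxel_size_mm,
                                schedule),
    static_fdg = static_image(array(10 * fdg, dims), atlas$voxel_size_mm),
    truth = list(regions = reg, k2_prime_true = spec$k2_prime_true,
                 R1_map = static_image(array(r1_vec, dims),
                                       atlas$voxel_size_mm)),
    group = spec$group, subject_id = subject_id, seed = seed),
    class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject_data> %s (%s), seed %s\n",
              x$subject_id, x$group, format(x$seed)))
  invisible(x)
}

#' Simulate a two-group cohort
#'
#' Draws `n_pos` PIB+ and `n_neg` PIB- subjects from the group templates
#' (elevated cortical BPnd and fractionally reduced cortical R1 in PIB+,
#' near-zero cortical BPnd in PIB-), with between-subject lognormal jitter on
#' the regional R1 and BPnd truths. Default sizes are 15 + 15.
#'
#' @param n_pos,n_neg group sizes (>= 1).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param atlas a `pet_atlas`; default [make_phantom_atlas()] at 32^3, 4 mm.
#' @param schedule a [frame_schedule()].
#' @param r1_jitter_sdlog,bpnd_jitter_sdlog between-subject lognormal SDs.
#' @param ... template arguments forwarded to [default_kinetic_spec()]
#'   (e.g. `noise_scale`, `cortical_bpnd_pos`, `cortical_r1_reduction`).
#' @return An object of class `pet_cohort`: list with `subjects` (list of
#'   `subject_data`), `atlas`, `schedule`, `seed`.
#' @export
simulate_cohort <- function(n_pos = 15, n_neg = 15, seed = 1,
                            atlas = make_phantom_atlas(),
                            schedule = pib_frame_schedule(),
                            r1_jitter_sdlog = 0.05,
                            bpnd_jitter_sdlog = 0.25, ...) {
  if (n_pos < 1L || n_neg < 1L) stop("group sizes must be at least 1")
  groups <- c(rep("PIB+", n_pos), rep("PIB-", n_neg))
  n <- length(groups)
  subjects <- with_local_seed(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      tmpl <- default_kinetic_spec(atlas, group = groups[i], ...)
      reg <- tmpl$regions
      ref <- reg$name == tmpl$reference_name
      reg$R1 <- reg$R1 * exp(stats::rnorm(nrow(reg), 0, r1_jitter_sdlog))
      reg$BPnd <- reg$BPnd * exp(stats::rnorm(nrow(reg), 0,
                                              bpnd_jitter_sdlog))
      reg$R1[ref] <- 1; reg$BPnd[ref] <- 0
      tmpl$regions <- reg
      simulate_subject(atlas, tmpl, schedule, seed = subject_seeds[i],
                       subject_id = sprintf("sub-%02d", i))
    })
  })
  structure(list(subjects = subjects, atlas = atlas, schedule = schedule,
                 seed = seed), class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("<pet_cohort> %d subjects (%d PIB+, %d PIB-), seed %d\n",
              length(g), sum(g == "PIB+"), sum(g == "PIB-"), x$seed))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' Writes a BIDS-like layout: one directory per subject holding the dynamic
#' PIB NIfTI with its JSON timing sidecar, the static FDG NIfTI and a truth
#' TSV, plus the atlas volume/table and a participants TSV at the top level.
#'
#' @param cohort a `pet_cohort`.
#' @param dir output directory.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `pet_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.nii.gz"),
              file.path(dir, "atlas_labels.tsv"))
  parts <- data.frame(
    subject = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    group = vapply(cohort$subjects, `[[`, character(1), "group"),
    seed = vapply(cohort$subjects, function(s) as.integer(s$seed),
                  integer(1)))
  utils::write.table(parts, file.path(dir, "participants.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    write_dynamic_image(s$dynamic_pib, file.path(sd, "pib.nii.gz"),
                        file.path(sd, "pib.json"))
    write_static_image(s$static_fdg, file.path(sd, "fdg.nii.gz"))
    tr <- s$truth$regions
    tr$k2_prime_true <- s$truth$k2_prime_true
    utils::write.table(tr, file.path(sd, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.nii.gz"),
                      file.path(dir, "atlas_labels.tsv"))
  parts <- utils::read.table(file.path(dir, "participants.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(parts)), function(i) {
    sd <- file.path(dir, parts$subject[i])
    dyn <- read_dynamic_image(file.path(sd, "pib.nii.gz"),
                              file.path(sd, "pib.json"))
    fdg <- read_static_image(file.path(sd, "fdg.nii.gz"))
    tr <- utils::read.table(file.path(sd, "truth.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    structure(list(dynamic_pib = dyn, static_fdg = fdg,
                   truth = list(regions = tr[, c("name", "R1", "BPnd")],
                                k2_prime_true = tr$k2_prime_true[1L],
                                R1_map = NULL),
                   group = parts$group[i], subject_id = parts$subject[i],
                   seed = parts$seed[i]),
              class = "subject_data")
  })
  structure(list(subjects = subjects, atlas = atlas,
                 schedule = subjects[[1L]]$dynamic_pib$schedule,
                 seed = NA_integer_), class = "pet_cohort")
}
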