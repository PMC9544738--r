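#' Synthetic cohort parameters
#'
#' Defines the study conditions the generator emulates: per subject, one or
#' two ~5-min rest runs (150 volumes at TR 2 s) and two 207-volume task
#' runs on a shared toy grid, with an 8-parcel ACC atlas (one dACC per
#' hemisphere), four physics parcels inside a fronto-parietal search mask,
#' and a subject-specific rigid displacement of the physics-responsive voxel
#' set that is shared between rest connectivity targets and task activation
#' — the planted fingerprint.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param grid_dims Grid size, 3 integers (>= 20 each).
#' @param voxel_size_mm Voxel size in mm.
#' @param tr_s TR in seconds.
#' @param n_rest_volumes Volumes per rest run (150 = 5 min at TR 2 s).
#' @param rest_runs_per_subject 1 or 2.
#' @param seed_coupling Mixing weight `a` of the dACC latent into planted
#'   voxels (unitless).
#' @param activation_beta Task response amplitude at planted voxels.
#' @param noise_sd AR(1) innovation SD `sigma`.
#' @param ar1_phi AR(1) coefficient in [0, 1); stationary initialization.
#' @param displacement_sd_mm SD of the per-subject spatial offset of the
#'   physics-responsive voxels (per axis, before rounding to voxels and
#'   clamping to the parcel margins).
#' @param motion_spike_rate Probability per volume of a > 2 mm motion spike.
#' @param master_seed Integer master seed; the cohort is bit-reproducible
#'   given this value.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 8, grid_dims = c(20, 20, 20),
                          voxel_size_mm = c(3, 3, 3.5), tr_s = 2,
                          n_rest_volumes = 150, rest_runs_per_subject = 2,
                          seed_coupling = 0.5, activation_beta = 1,
                          noise_sd = 1, ar1_phi = 0.3,
                          displacement_sd_mm = 6, motion_spike_rate = 0.01,
                          master_seed = 1L) {
  stopifnot(n_subjects >= 2, seed_coupling >= 0, noise_sd > 0,
            ar1_phi >= 0, ar1_phi < 1,
            rest_runs_per_subject %in% c(1L, 2L))
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      grid_dims = as.integer(grid_dims),
      voxel_size_mm = as.numeric(voxel_size_mm),
      tr_s = tr_s,
      n_rest_volumes = as.integer(n_rest_volumes),
      rest_runs_per_subject = as.integer(rest_runs_per_subject),
      seed_coupling = seed_coupling,
      activation_beta = activation_beta,
      noise_sd = noise_sd,
      ar1_phi = ar1_phi,
      displacement_sd_mm = displacement_sd_mm,
      motion_spike_rate = motion_spike_rate,
      master_seed = as.integer(master_seed)
    ),
    class = "cohort_params"
  )
}

box_idx <- function(d, xr, yr, zr) {
  arr <- array(FALSE, dim = d)
  arr[xr, yr, zr] <- TRUE
  arr
}

# proportional box layout; exact classic layout at the 20^3 default grid
atlas_layout <- function(d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  mid <- floor(nx / 2)
  ystart <- round(ny * c(0.10, 0.30, 0.50, 0.70))
  acc_z <- round(nz * 0.40):round(nz * 0.50)
  acc <- list()
  for (h in c("L", "R")) {
    xr <- if (h == "L") (mid - 1):mid else (mid + 1):(mid + 2)
    for (k in 1:4) {
      acc[[paste0(h, k)]] <- list(x = xr, y = ystart[k]:(ystart[k] + 2), z = acc_z)
    }
  }
  pz <- round(nz * 0.65):round(nz * 0.90)
  phys <- list(
    frontal_L  = list(x = 2:(mid - 1), y = 2:round(ny * 0.45), z = pz),
    frontal_R  = list(x = (mid + 2):(nx - 1), y = 2:round(ny * 0.45), z = pz),
    parietal_L = list(x = 2:(mid - 1), y = round(ny * 0.60):(ny - 1), z = pz),
    parietal_R = list(x = (mid + 2):(nx - 1), y = round(ny * 0.60):(ny - 1), z = pz)
  )
  list(
    acc = acc,
    phys = phys,
    search_z = (min(pz) - 1):nz,
    wm = list(x = round(nx * 0.15):round(nx * 0.25),
              y = round(ny * 0.15):round(ny * 0.25),
              z = round(nz * 0.10):round(nz * 0.20)),
    vent = list(x = round(nx * 0.75):round(nx * 0.85),
                y = round(ny * 0.15):round(ny * 0.25),
                z = round(nz * 0.10):round(nz * 0.20))
  )
}

#' Build the toy parcel atlas
#'
#' Deterministic given the parameters: eight ACC parcels near the midline
#' (four per hemisphere, the second of each designated dACC), four physics
#' parcels (frontal and parietal in each hemisphere, >= 200 voxels each) in
#' a dorsal slab, a fronto-parietal search mask containing the physics
#' parcels, and white-matter and ventricle compartments. Each physics parcel
#' records a central "core" sub-box and the per-axis margins available for
#' subject-specific displacement (attributes `physics_cores`,
#' `displacement_margin_vox`).
#'
#' @param params A [cohort_params()].
#' @return A `parcel_atlas`.
#' @export
make_atlas <- function(params = cohort_params()) {
  d <- params$grid_dims
  if (any(d < 20)) {
    stop("grid too small: need at least 20 voxels per axis to place all parcels",
         call. = FALSE)
  }
  lay <- atlas_layout(d)
  labels <- array(0L, dim = d)
  rows <- list()
  add <- function(id, name, role, b) {
    labels[b$x, b$y, b$z] <<- id
    rows[[length(rows) + 1]] <<- tibble::tibble(label_id = id, name = name, role = role)
  }
  acc_names <- names(lay$acc)
  for (i in seq_along(lay$acc)) {
    h <- substr(acc_names[i], 1, 1)
    k <- as.integer(substr(acc_names[i], 2, 2))
    role <- if (k == 2) "acc_dacc" else "acc_other"
    nm <- if (k == 2) paste0("dACC_", h) else sprintf("ACC%d_%s", k, h)
    add(i, nm, role, lay$acc[[i]])
  }
  # search mask first so physics labels overwrite it inside the slab
  search <- array(FALSE, dim = d)
  search[, , lay$search_z] <- TRUE
  labels[search & labels == 0L] <- 21L
  rows[[length(rows) + 1]] <- tibble::tibble(label_id = 21L,
                                             name = "frontoparietal_search",
                                             role = "searchmask")
  phys_ids <- c(frontal_L = 11L, frontal_R = 12L, parietal_L = 13L, parietal_R = 14L)
  cores <- list()
  margins <- NULL
  for (nm in names(lay$phys)) {
    b <- lay$phys[[nm]]
    add(phys_ids[[nm]], paste0("physics_", nm), "physics", b)
    lens <- c(length(b$x), length(b$y), length(b$z))
    m <- pmax(1L, floor(lens / 4))
    core <- list(x = (min(b$x) + m[1]):(max(b$x) - m[1]),
                 y = (min(b$y) + m[2]):(max(b$y) - m[2]),
                 z = (min(b$z) + m[3]):(max(b$z) - m[3]))
    cores[[nm]] <- core
    margins <- if (is.null(margins)) m else pmin(margins, m)
  }
  add(31L, "white_matter", "wm", lay$wm)
  add(32L, "ventricles", "ventricle", lay$vent)

  atlas <- parcel_atlas(labels, dplyr::bind_rows(rows),
                        voxel_size_mm = params$voxel_size_mm)
  n_phys <- vapply(phys_ids, function(id) sum(labels == id), numeric(1))
  stopifnot(all(n_phys >= 200))
  attr(atlas, "physics_cores") <- cores
  attr(atlas, "displacement_margin_vox") <- as.integer(margins)
  # fixed control set for the colour condition: slab below the physics boxes
  ctrl <- array(FALSE, dim = d)
  zc <- min(lay$search_z)
  ctrl[round(d[1] * 0.25):round(d[1] * 0.75),
       round(d[2] * 0.25):round(d[2] * 0.75), zc] <- TRUE
  attr(atlas, "control_voxels") <- ctrl
  atlas
}

#' Subject profile
#'
#' A subject's identity in the generator: their rigid integer-voxel
#' displacement of the physics-responsive voxel set (shared between rest
#' and task, bounded so the displaced cores stay inside the physics
#' parcels) and per-run noise seeds.
#'
#' @param subject_id Subject identifier.
#' @param displacement_vox Length-3 integer displacement in voxels.
#' @param rest_seeds,task_seeds Integer seeds, one per run.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, displacement_vox, rest_seeds,
                            task_seeds) {
  structure(
    list(subject_id = subject_id,
         displacement_vox = as.integer(displacement_vox),
         rest_seeds = as.integer(rest_seeds),
         task_seeds = as.integer(task_seeds)),
    class = "subject_profile"
  )
}

# logical array of this subject's planted voxels: each physics core shifted
# by the subject displacement (clamped at construction, so always inside)
planted_voxels <- function(atlas, displacement_vox) {
  d <- dim(atlas$labels)
  out <- array(FALSE, dim = d)
  for (core in attr(atlas, "physics_cores")) {
    out[core$x + displacement_vox[1],
        core$y + displacement_vox[2],
        core$z + displacement_vox[3]] <- TRUE
  }
  out
}

# stationary AR(1) series matrix (T x n), unit innovation SD unless scaled
ar1_matrix <- function(n_t, n_series, phi, innov_sd = 1) {
  x <- matrix(rnorm(n_t * n_series), n_t, n_series) * innov_sd
  if (phi > 0) {
    x[1, ] <- x[1, ] / sqrt(1 - phi^2)
    for (t in 2:n_t) x[t, ] <- phi * x[t - 1, ] + x[t, ]
  }
  x
}

# unit-stationary-variance AR(1) latent (vector length T)
ar1_latent <- function(n_t, phi) {
  drop(ar1_matrix(n_t, 1, phi, innov_sd = sqrt(1 - phi^2)))
}

simulate_motion <- function(n_t, spike_rate) {
  base <- vapply(1:6, function(i) {
    cumsum(rnorm(n_t, sd = 0.02))
  }, numeric(n_t))
  colnames(base) <- c("roll", "pitch", "yaw", "dS", "dP", "dL")
  spikes <- which(stats::runif(n_t - 1) < spike_rate) + 1L
  for (s in spikes) {
    col <- sample(4:6, 1)  # translation step > 2 mm
    base[s:n_t, col] <- base[s:n_t, col] + sample(c(-1, 1), 1) * stats::runif(1, 2.3, 4)
  }
  motion_table(base)
}

#' Simulate one resting-state run
#'
#' Every voxel carries stationary AR(1) Gaussian noise (coefficient
#' `ar1_phi`, innovation SD `noise_sd`). The dACC voxels additionally share
#' a unit-variance latent series s(t); the subject's displaced
#' physics-core voxels carry `a * s(t)`; white-matter and ventricle voxels
#' carry their own shared unit-variance confound series, which also leak
#' with weight `0.2 * a` into all brain voxels. The other ACC parcels get
#' independent latents so their connectivity goes elsewhere. Motion is
#' smooth low-amplitude noise with translation steps > 2 mm at the spike
#' rate. Fully reproducible from the profile's run seed.
#'
#' @param profile A [subject_profile()].
#' @param atlas A [make_atlas()] atlas.
#' @param params A [cohort_params()].
#' @param run Run number (indexes `profile$rest_seeds`).
#' @return List with `vol` (a `volume_series`) and `motion` (a
#'   `motion_table`).
#' @export
simulate_rest_run <- function(profile, atlas, params, run = 1L) {
  withr_seed(profile$rest_seeds[run], {
    d <- params$grid_dims
    n_t <- params$n_rest_volumes
    n_vox <- prod(d)
    a <- params$seed_coupling
    phi <- params$ar1_phi

    y <- ar1_matrix(n_t, n_vox, phi, innov_sd = params$noise_sd)
    s <- ar1_latent(n_t, phi)
    w_wm <- ar1_latent(n_t, phi)
    w_vent <- ar1_latent(n_t, phi)

    dacc <- which(atlas_mask(atlas, roles = "acc_dacc"))
    y[, dacc] <- y[, dacc] + s
    # distinct latents for the non-seed ACC parcels
    for (id in atlas$table$label_id[atlas$table$role == "acc_other"]) {
      sel <- which(atlas$labels == id)
      y[, sel] <- y[, sel] + ar1_latent(n_t, phi)
    }
    planted <- which(planted_voxels(atlas, profile$displacement_vox))
    y[, planted] <- y[, planted] + a * s

    wm <- which(atlas_mask(atlas, roles = "wm"))
    vent <- which(atlas_mask(atlas, roles = "ventricle"))
    y[, wm] <- y[, wm] + w_wm
    y[, vent] <- y[, vent] + w_vent
    brain <- setdiff(seq_len(n_vox), c(wm, vent))
    y[, brain] <- y[, brain] + outer(0.2 * a * (w_wm + w_vent), rep(1, length(brain)))

    vol <- volume_series(array(t(y), dim = c(d, n_t)),
                         voxel_size_mm = params$voxel_size_mm, tr_s = params$tr_s)
    list(vol = vol, motion = simulate_motion(n_t, params$motion_spike_rate))
  })
}

#' Simulate one task run
#'
#' The subject's displaced physics-core voxels respond with amplitude
#' `activation_beta` to the HRF-convolved physics-cue regressor only; a
#' fixed disjoint control voxel set responds to the colour-cue regressor;
#' all voxels carry additive AR(1) noise.
#'
#' @param profile A [subject_profile()].
#' @param atlas A [make_atlas()] atlas.
#' @param design A [build_block_design()] (total duration must be a
#'   multiple of the TR).
#' @param params A [cohort_params()].
#' @param run Run number (indexes `profile$task_seeds`).
#' @return List with `vol`, `motion`, and the regressor matrix `X` used to
#'   plant the signal.
#' @export
simulate_task_run <- function(profile, atlas, design, params, run = 1L) {
  if (abs(design$total_duration_s / params$tr_s -
          round(design$total_duration_s / params$tr_s)) > 1e-9) {
    stop("design duration is not a whole number of TRs", call. = FALSE)
  }
  withr_seed(profile$task_seeds[run], {
    d <- params$grid_dims
    X <- convolve_design(design)
    n_t <- nrow(X)
    y <- ar1_matrix(n_t, prod(d), params$ar1_phi, innov_sd = params$noise_sd)
    planted <- which(planted_voxels(atlas, profile$displacement_vox))
    ctrl <- which(attr(atlas, "control_voxels"))
    b <- params$activation_beta
    y[, planted] <- y[, planted] + b * X[, "physics_cue"]
    y[, ctrl] <- y[, ctrl] + b * X[, "colour_cue"]
    vol <- volume_series(array(t(y), dim = c(d, n_t)),
                         voxel_size_mm = params$voxel_size_mm, tr_s = params$tr_s)
    list(vol = vol, motion = simulate_motion(n_t, params$motion_spike_rate),
         X = X)
  })
}

#' Generate a full synthetic cohort
#'
#' Subject displacements are drawn i.i.d. Gaussian per axis (SD
#' `displacement_sd_mm`), rounded to whole voxels and clamped to the atlas
#' displacement margins; the same displacement drives that subject's rest
#' connectivity targets and task activation, which is the planted
#' fingerprint the analysis should recover. Bit-identical given
#' `master_seed`.
#'
#' @param params A [cohort_params()].
#' @param tasks Generate the two task runs per subject (disable for
#'   rest-only analyses such as split-half reliability).
#' @return A list of class `cohort`: `params`, `atlas`, `design`, and
#'   `subjects` — per subject a list with `profile`, `rest` (list of
#'   run lists) and `task` (list of run lists).
#' @export
make_cohort <- function(params = cohort_params(), tasks = TRUE) {
  atlas <- make_atlas(params)
  margin <- attr(atlas, "displacement_margin_vox")
  profiles <- withr_seed(params$master_seed, {
    lapply(seq_len(params$n_subjects), function(i) {
      disp_mm <- rnorm(3, sd = params$displacement_sd_mm)
      disp <- round(disp_mm / params$voxel_size_mm)
      disp <- pmin(margin, pmax(-margin, disp))
      subject_profile(
        subject_id = sprintf("sub%02d", i),
        displacement_vox = disp,
        rest_seeds = sample.int(.Machine$integer.max - 1L, params$rest_runs_per_subject),
        task_seeds = sample.int(.Machine$integer.max - 1L, 2L)
      )
    })
  })
  design <- build_block_design(seed = params$master_seed)
  subjects <- lapply(profiles, function(pr) {
    rest <- lapply(seq_len(params$rest_runs_per_subject), function(r) {
      simulate_rest_run(pr, atlas, params, run = r)
    })
    task <- if (tasks) lapply(1:2, function(r) {
      simulate_task_run(pr, atlas, design, params, run = r)
    }) else list()
    list(profile = pr, rest = rest, task = task)
  })
  structure(list(params = params, atlas = atlas, design = design,
                 subjects = subjects),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, grid %s, %d rest run(s) + 2 task runs each\n",
              x$params$n_subjects, paste(x$params$grid_dims, collapse = "x"),
              x$params$rest_runs_per_subject))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per-subject NIfTI runs and motion TSVs, the atlas (NIfTI + label TSV),
#' the design events TSV, and a YAML manifest recording parameters, seeds
#' and true displacements.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("writing a cohort manifest requires the yaml package", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas"))
  write_design_events(cohort$design, file.path(dir, "design_events.tsv"))
  manifest <- list(params = unclass(cohort$params), subjects = list())
  for (sub in cohort$subjects) {
    id <- sub$profile$subject_id
    for (r in seq_along(sub$rest)) {
      write_volume(sub$rest[[r]]$vol, file.path(dir, sprintf("%s_rest%d.nii.gz", id, r)))
      write_motion(sub$rest[[r]]$motion, file.path(dir, sprintf("%s_rest%d_motion.tsv", id, r)))
    }
    for (r in seq_along(sub$task)) {
      write_volume(sub$task[[r]]$vol, file.path(dir, sprintf("%s_task%d.nii.gz", id, r)))
      write_motion(sub$task[[r]]$motion, file.path(dir, sprintf("%s_task%d_motion.tsv", id, r)))
    }
    manifest$subjects[[id]] <- list(
      displacement_vox = sub$profile$displacement_vox,
      rest_seeds = sub$profile$rest_seeds,
      task_seeds = sub$profile$task_seeds
    )
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
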