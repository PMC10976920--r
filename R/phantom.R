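#' Configuration for a synthetic chest phantom
#'
#' The phantom emulates the class-conditional texture structure the pipeline
#' assumes: a fibrotic class carrying high-frequency reticular walls and
#' honeycomb micro-cysts concentrated toward the lung base and outer rind,
#' and a non-fibrotic class carrying smooth ground-glass intensity elevation.
#' Lungs are two half-ellipsoids mirrored about the mid-sagittal plane with a
#' fixed 4-voxel gap, guaranteeing left/right separability.
#'
#' @param grid_shape voxels per axis, each at least 32 (default 96^3).
#' @param spacing_mm voxel spacing in mm (default 1 isotropic).
#' @param class_label "fibrotic" or "non_fibrotic".
#' @param parenchyma_hu mean lung intensity in HU (default -850).
#' @param air_hu background intensity (default -1000).
#' @param noise_sd_hu additive Gaussian noise SD (default 20).
#' @param ggo_amplitude_hu,ggo_scale_mm ground-glass blob strength and
#'   smoothness; applied only to the non-fibrotic class.
#' @param reticular_amplitude_hu,reticular_period_mm sinusoidal septal-wall
#'   lattice for the fibrotic class.
#' @param cyst_radius_mm,cyst_density honeycomb micro-cyst radius and number
#'   per mm^3 of lung (fibrotic class).
#' @param basal_gradient,peripheral_gradient weighting of fibrotic texture
#'   toward the lung base and rind, in `[0, 1]`; 0 = uniform.
#' @param seed RNG seed; identical config and seed give bit-identical output.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 96), spacing_mm = c(1, 1, 1),
                           class_label = c("fibrotic", "non_fibrotic"),
                           parenchyma_hu = -850, air_hu = -1000, noise_sd_hu = 20,
                           ggo_amplitude_hu = 120, ggo_scale_mm = 12,
                           reticular_amplitude_hu = 250, reticular_period_mm = 6,
                           cyst_radius_mm = 3, cyst_density = 5e-5,
                           basal_gradient = 0.7, peripheral_gradient = 0.7,
                           seed = 1L) {
  class_label <- match.arg(class_label)
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(length(grid_shape) == 3, length(spacing_mm) == 3, all(spacing_mm > 0))
  if (any(grid_shape < 32)) stop("grid_shape must be at least 32 voxels per axis")
  amps <- c(noise_sd_hu, ggo_amplitude_hu, reticular_amplitude_hu, cyst_density,
            cyst_radius_mm, ggo_scale_mm, reticular_period_mm)
  if (any(amps < 0)) stop("amplitudes and scales must be non-negative")
  if (basal_gradient < 0 || basal_gradient > 1 ||
      peripheral_gradient < 0 || peripheral_gradient > 1)
    stop("gradients must lie in [0, 1]")
  structure(list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 class_label = class_label, parenchyma_hu = parenchyma_hu,
                 air_hu = air_hu, noise_sd_hu = noise_sd_hu,
                 ggo_amplitude_hu = ggo_amplitude_hu, ggo_scale_mm = ggo_scale_mm,
                 reticular_amplitude_hu = reticular_amplitude_hu,
                 reticular_period_mm = reticular_period_mm,
                 cyst_radius_mm = cyst_radius_mm, cyst_density = cyst_density,
                 basal_gradient = basal_gradient,
                 peripheral_gradient = peripheral_gradient,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# deterministic sub-seed streams so that component geometry does not depend
# on amplitude parameter values
sub_seed <- function(seed, k) as.integer((abs(seed) * 48271 + k * 69621) %% 2147483587L + 1L)

#' Generate a synthetic chest phantom
#'
#' Builds the volume, its ground-truth lung mask (with left/right labels) and
#' the class label from a [phantom_config()]. Fibrotic texture amplitude
#' increases toward the basal third and the peripheral rind according to the
#' gradient parameters.
#'
#' @param config a [phantom_config()].
#' @return list with elements `volume` (`fg_volume`), `mask` (`fg_mask`) and
#'   `class_label`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape; sp <- config$spacing_mm
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  X <- nx * sp[1]; Y <- ny * sp[2]; Z <- nz * sp[3]
  xs <- (seq_len(nx) - 0.5) * sp[1]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]

  # soft-tissue thorax inside an air background, with two mirrored
  # ellipsoidal lungs separated by a 4-voxel mid-sagittal gap
  a <- 0.19 * X; b <- 0.30 * Y; cc <- 0.38 * Z
  gap <- 2 * sp[1]
  xc_l <- X / 2 - gap - a; xc_r <- X / 2 + gap + a
  yc <- Y / 2; zc <- Z / 2
  ell <- function(xc, ax, ay, az) {
    ex <- ((xs - xc) / ax)^2; ey <- ((ys - yc) / ay)^2; ez <- ((zs - zc) / az)^2
    outer(outer(ex, ey, "+"), ez, "+") <= 1
  }
  body <- ell(X / 2, 0.48 * X, 0.43 * Y, 0.49 * Z)
  # guarantee a tissue shell of at least 2.5 mm between lung and outside air
  bdist <- array(cpp_edt(body, d, sp), d)
  shell_ok <- bdist > 2.5
  left <- ell(xc_l, a, b, cc) & shell_ok
  right <- ell(xc_r, a, b, cc) & shell_ok
  if (sum(left) < 500 || sum(right) < 500)
    stop("grid too small to contain two lungs with at least 500 voxels each")
  mask <- left | right
  lung <- array(0L, d); lung[left] <- 1L; lung[right] <- 2L

  vol <- array(config$air_hu, d)
  vol[body] <- 40                        # soft tissue
  vol[mask] <- config$parenchyma_hu

  # basal/peripheral weight field for the fibrotic texture
  zany <- apply(mask, 3, any)
  zmin <- min(zs[zany]); zmax <- max(zs[zany])
  bfrac <- (zmax - zs) / max(zmax - zmin, 1e-9)          # 1 at base, 0 at apex
  wb <- (1 - config$basal_gradient) + config$basal_gradient * pmin(pmax(bfrac, 0), 1)
  dist <- array(cpp_edt(mask, d, sp), d)
  dmax <- max(dist[mask])
  pfrac <- 1 - dist / max(dmax, 1e-9)                    # 1 at rind, 0 centrally
  wp <- (1 - config$peripheral_gradient) + config$peripheral_gradient * pfrac
  wfield <- sweep(wp, 3, wb, "*")

  if (config$class_label == "fibrotic") {
    p <- max(config$reticular_period_mm, 2 * max(sp))
    lat <- outer(outer(abs(sin(pi * xs / p)), abs(sin(pi * ys / p)), "*"),
                 abs(sin(pi * zs / p)), "*")
    walls <- mask & (lat > 0.4)
    vol[walls] <- vol[walls] + config$reticular_amplitude_hu * wfield[walls]

    # honeycomb micro-cysts: Poisson-disk-style seeded sampling, weighted
    # toward the basal-peripheral zone
    n_cyst <- round(config$cyst_density * sum(mask) * prod(sp))
    if (n_cyst > 0 && config$cyst_radius_mm > 0) {
      set.seed(sub_seed(config$seed, 11L))
      idx <- which(mask & dist > config$cyst_radius_mm + 1)
      if (length(idx) > 0) {
        wts <- wfield[idx]^2
        centers <- matrix(numeric(0), 0, 3)
        tries <- 0L
        while (nrow(centers) < n_cyst && tries < 50L * n_cyst) {
          tries <- tries + 1L
          i <- sample(length(idx), 1, prob = wts)
          co <- arrayInd(idx[i], d)
          pos <- (co - 0.5) * sp
          if (nrow(centers) == 0 ||
              min(sqrt(rowSums(sweep(centers, 2, pos)^2))) > 2.5 * config$cyst_radius_mm) {
            centers <- rbind(centers, pos)
          }
        }
        r <- config$cyst_radius_mm
        for (k in seq_len(nrow(centers))) {
          lo <- pmax(1L, floor((centers[k, ] - r - 1.5) / sp));
          hi <- pmin(d, ceiling((centers[k, ] + r + 1.5) / sp))
          xi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; zi <- lo[3]:hi[3]
          dd <- sqrt(outer(outer((xs[xi] - centers[k, 1])^2,
                                 (ys[yi] - centers[k, 2])^2, "+"),
                           (zs[zi] - centers[k, 3])^2, "+"))
          sub <- vol[xi, yi, zi]; msub <- mask[xi, yi, zi]
          sub[msub & dd <= r] <- config$air_hu                    # air pocket
          shell <- msub & dd > r & dd <= r + 1.5
          sub[shell] <- sub[shell] + 100                          # +100 HU wall
          vol[xi, yi, zi] <- sub
        }
      }
    }
  } else {
    # ground glass: 3-6 large Gaussian blobs, geometry independent of amplitude
    set.seed(sub_seed(config$seed, 23L))
    nb <- sample(3:6, 1)
    blob <- array(0, d)
    idx <- which(mask)
    for (k in seq_len(nb)) {
      ctr <- (arrayInd(idx[sample(length(idx), 1)], d) - 0.5) * sp
      wt <- runif(1, 0.6, 1)
      s <- config$ggo_scale_mm
      gx <- exp(-((xs - ctr[1])^2) / (2 * s^2))
      gy <- exp(-((ys - ctr[2])^2) / (2 * s^2))
      gz <- exp(-((zs - ctr[3])^2) / (2 * s^2))
      blob <- blob + wt * outer(outer(gx, gy, "*"), gz, "*")
    }
    vol[mask] <- vol[mask] + config$ggo_amplitude_hu * blob[mask]
  }

  if (config$noise_sd_hu > 0) {
    set.seed(sub_seed(config$seed, 37L))
    vol <- vol + array(rnorm(length(vol), 0, config$noise_sd_hu), d)
  }

  list(volume = fg_volume(vol, sp),
       mask = fg_mask(mask, sp, lung = lung),
       class_label = config$class_label)
}

#' Generate a synthetic cohort on disk
#'
#' Samples per-patient class labels and 1-5 scans per patient, generates each
#' phantom with a per-scan seed derived deterministically from the master
#' seed, writes NIfTI volumes and masks under `out_dir`, and writes
#' `manifest.csv` with columns scan_id, patient_id, path, mask_path, label,
#' seed.
#'
#' @param n_patients number of synthetic patients (>= 2).
#' @param fibrotic_fraction expected fraction of fibrotic patients, in (0,1).
#' @param scans_per_patient_range integer range within `[1, 5]`.
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param grid_shape passed to [phantom_config()].
#' @param config_overrides named list of further [phantom_config()] arguments
#'   applied to every scan.
#' @return the cohort manifest as a data.frame (invisibly also on disk).
#' @export
generate_cohort <- function(n_patients, fibrotic_fraction = 0.5,
                            scans_per_patient_range = c(1, 5),
                            out_dir = tempfile("cohort"), seed = 1L,
                            grid_shape = c(96, 96, 96),
                            config_overrides = list()) {
  stopifnot(n_patients >= 2, fibrotic_fraction > 0, fibrotic_fraction < 1)
  rng <- as.integer(scans_per_patient_range)
  if (length(rng) != 2 || rng[1] < 1 || rng[2] > 5 || rng[1] > rng[2])
    stop("scans_per_patient_range must lie within [1, 5]")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  # class counts fixed at round(fraction * n), at least one per class;
  # assignment to patients randomised
  n_fib <- min(max(round(fibrotic_fraction * n_patients), 1L), n_patients - 1L)
  cls <- sample(c(rep(1L, n_fib), rep(0L, n_patients - n_fib)))
  nscan <- if (rng[1] == rng[2]) rep(rng[1], n_patients) else
    sample(rng[1]:rng[2], n_patients, replace = TRUE)

  rows <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    lab <- if (cls[i] == 1) "fibrotic" else "non_fibrotic"
    for (j in seq_len(nscan[i])) {
      sid <- sprintf("%s_S%d", pid, j)
      sseed <- as.integer((abs(seed) * 1000003 + i * 1009 + j * 101) %% 2147483647L)
      args <- c(list(grid_shape = grid_shape, class_label = lab, seed = sseed),
                config_overrides)
      cfg <- do.call(phantom_config, args)
      ph <- generate_phantom(cfg)
      vpath <- file.path(out_dir, paste0(sid, ".nii.gz"))
      mpath <- file.path(out_dir, paste0(sid, "_mask.nii.gz"))
      write_volume(ph$volume, vpath)
      write_volume(ph$mask, mpath)
      rows[[length(rows) + 1]] <- data.frame(
        scan_id = sid, patient_id = pid, path = vpath, mask_path = mpath,
        label = lab, seed = sseed, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
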