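# Synthetic FFA study generator.
#
# Ground-truthed synthetic angiography: a branching vessel tree over a
# textured background inside a dark circular field of view, fluorescein
# kinetics with a fast rise peaking near 30 s and a decaying tail over a
# session-dependent leakage plateau, per-frame motion, vignetting, sensor
# noise, and optional burned-in timestamps. Every frame carries its true
# transform and noiseless region means, so each pipeline stage has an
# independent oracle.

#' Fluorescein kinetic parameters
#'
#' The vascular (bolus) term is a gamma-variate normalised to peak amplitude
#' `K` at `t0 + alpha * beta`; the leakage term saturates monotonically to
#' plateau amplitude `L` with time constant `tau_L`. Vessels additionally
#' retain an intravascular plateau `V_p * (1 - exp(-s / tau_L))`
#' (recirculating dye) so late-phase frames keep their vasculature visible,
#' as real late-phase angiograms do.
#'
#' @param t0 Bolus arrival (s, >= 0).
#' @param alpha Rise shape (> 0).
#' @param beta Decay scale (s, > 0).
#' @param K Vascular peak amplitude.
#' @param L Leakage plateau amplitude.
#' @param tau_L Plateau rise time constant (s).
#' @param V_p Intravascular (vessel) plateau amplitude.
#' @export
kinetic_params <- function(t0 = 5, alpha = 2.5, beta = 10, K = 0.55,
                           L = 0.12, tau_L = 120, V_p = 0.12) {
  vals <- c(alpha = alpha, beta = beta, K = K, L = L, tau_L = tau_L,
            V_p = V_p)
  if (t0 < 0 || any(vals <= 0)) {
    abort("Kinetic parameters must be positive (t0 >= 0).",
          class = "ffa_parameter_error")
  }
  structure(list(t0 = t0, alpha = alpha, beta = beta, K = K, L = L,
                 tau_L = tau_L, V_p = V_p),
            class = "ffa_kinetics")
}

#' Evaluate the kinetic model
#'
#' @param t Seconds post-injection (vectorised).
#' @param p [kinetic_params()].
#' @return Tibble with `t`, `vascular`, `leakage`, `total`. The vascular
#'   term equals `K` exactly at `t = t0 + alpha * beta` and the total tends
#'   to `L` as `t` grows.
#' @export
kinetic_intensity <- function(t, p) {
  s <- pmax(t - p$t0, 0)
  tp <- p$alpha * p$beta
  vascular <- ifelse(s > 0, p$K * (s / tp)^p$alpha * exp(p$alpha - s / p$beta), 0)
  leakage <- ifelse(s > 0, p$L * (1 - exp(-s / p$tau_L)), 0)
  vp <- p$V_p %||% 0
  vessel_plateau <- ifelse(s > 0, vp * (1 - exp(-s / p$tau_L)), 0)
  tibble::tibble(t = t, vascular = vascular, leakage = leakage,
                 vessel_plateau = vessel_plateau,
                 total = vascular + leakage)
}

# ---- vessel tree -------------------------------------------------------------

#' Generate a branching vessel tree with ground truth
#'
#' Recursive bifurcation from the optic-disc margin: child widths follow
#' Murray's law (`w_child = w_parent * 2^(-1/3)`), branch angles are drawn
#' within a configured cone, and segments are rendered as anti-aliased
#' bright tubes with a smooth cross-profile. The returned ground truth holds
#' every centreline segment with its width.
#'
#' @param seed RNG seed (same seed, identical image).
#' @param size Canvas size `c(h, w)`.
#' @param depth Branching depth (>= 1).
#' @param trunk_width Root vessel full width in pixels.
#' @param n_roots Vessels leaving the disc margin.
#' @param disc Optic-disc centre `(x, y)`; default left-of-centre.
#' @param cone Half-angle (degrees) of the random branch cone.
#' @return List: `image` (matrix in `[0, 1]`), `segments` (tibble with
#'   endpoints, width and depth), `disc`.
#' @export
generate_vessel_tree <- function(seed = 1L, size = c(256, 256), depth = 5L,
                                 trunk_width = 8, n_roots = 6L,
                                 disc = NULL, cone = 35) {
  h <- size[1]; w <- size[2]
  if (depth < 1) { warn("depth clamped to 1"); depth <- 1L }
  if (is.null(disc)) disc <- c(0.32 * w, 0.5 * h)
  segs <- with_seed(child_seed(seed, "tree"), {
    out <- list()
    grow <- function(x, y, angle, width, level) {
      len <- runif(1, 0.16, 0.24) * min(h, w) * 0.9^(level - 1)
      x2 <- x + len * cos(angle); y2 <- y + len * sin(angle)
      out[[length(out) + 1]] <<- tibble::tibble(
        x0 = x, y0 = y, x1 = x2, y1 = y2, width = width, depth = level)
      if (level < depth) {
        spread <- cone * pi / 180
        for (da in runif(2, 0.25, 1) * spread * c(-1, 1)) {
          grow(x2, y2, angle + da, width * 2^(-1 / 3), level + 1)
        }
      }
    }
    base_angles <- seq(0, 2 * pi, length.out = n_roots + 1)[-(n_roots + 1)]
    for (a in base_angles + runif(n_roots, -0.25, 0.25)) {
      grow(disc[1], disc[2], a, trunk_width, 1L)
    }
    dplyr::bind_rows(out)
  })
  image <- render_tubes(segs, h, w)
  list(image = image, segments = segs, disc = disc)
}

# anti-aliased rendering: for each segment, intensity falls off smoothly
# from the centreline over the half-width
render_tubes <- function(segs, h, w) {
  g <- coord_grid(h, w)
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    hw <- s$width / 2
    pad <- ceiling(hw + 2)
    r0 <- max(1, floor(min(s$y0, s$y1)) - pad)
    r1 <- min(h, ceiling(max(s$y0, s$y1)) + pad)
    c0 <- max(1, floor(min(s$x0, s$x1)) - pad)
    c1 <- min(w, ceiling(max(s$x0, s$x1)) + pad)
    if (r0 > r1 || c0 > c1) next
    xs <- g$x[r0:r1, c0:c1]; ys <- g$y[r0:r1, c0:c1]
    vx <- s$x1 - s$x0; vy <- s$y1 - s$y0
    len2 <- vx^2 + vy^2
    tproj <- clamp(((xs - s$x0) * vx + (ys - s$y0) * vy) / len2, 0, 1)
    dx <- xs - (s$x0 + tproj * vx); dy <- ys - (s$y0 + tproj * vy)
    dist <- sqrt(dx^2 + dy^2)
    # smooth tube profile: flat core, cosine shoulder one pixel wide
    prof <- clamp((hw + 0.5 - dist), 0, 1)
    img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], prof)
  }
  img
}

# points along segment centrelines (for mask-selectivity oracles)
#' Sample centreline points of tree segments
#' @param segs Segment tibble from [generate_vessel_tree()].
#' @param spacing Sampling step along each segment (px).
#' @export
centerline_points <- function(segs, spacing = 1) {
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    len <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)
    tt <- seq(0, 1, length.out = max(2, ceiling(len / spacing)))
    tibble::tibble(x = s$x0 + tt * (s$x1 - s$x0),
                   y = s$y0 + tt * (s$y1 - s$y0),
                   width = s$width, depth = s$depth)
  })
  dplyr::bind_rows(rows)
}

# ---- frame rendering ---------------------------------------------------------

radial_vignette <- function(h, w, strength) {
  g <- coord_grid(h, w)
  r <- sqrt((g$x - (w + 1) / 2)^2 + (g$y - (h + 1) / 2)^2) / (min(h, w) / 2)
  1 - strength * clamp(r)^2
}

#' Render one synthetic FFA frame
#'
#' Scene = textured background + spatially uniform leakage signal inside the
#' FOV + vessel tree scaled by the vascular term, multiplied by a radial
#' vignette, warped by the per-frame motion, with additive and
#' signal-dependent Gaussian noise, a dark surround outside the FOV disk and
#' an optional burned-in `mm:ss` timestamp.
#'
#' @param t Seconds post-injection.
#' @param tree Output of [generate_vessel_tree()].
#' @param kinetics [kinetic_params()].
#' @param motion `ffa_transform` applied to the scene (identity = no
#'   motion).
#' @param vignette_strength 0 disables vignetting.
#' @param noise_sd Additive Gaussian noise SD.
#' @param noise_signal_sd Signal-proportional noise SD.
#' @param texture Background texture matrix (from [background_texture()]),
#'   or `NULL`.
#' @param fov_radius_frac FOV disk radius as a fraction of `min(h, w) / 2`.
#' @param timestamp Stamp the time as `mm:ss` (logical).
#' @param seed Noise seed.
#' @return List: `frame` (`ffa_frame`), `truth` (list with the applied
#'   transform, noiseless scene and FOV mask).
#' @export
render_frame <- function(t, tree, kinetics, motion = tf_identity(),
                         vignette_strength = 0.3, noise_sd = 0.005,
                         noise_signal_sd = 0.01, texture = NULL,
                         fov_radius_frac = 0.94, timestamp = FALSE,
                         seed = 1L) {
  h <- nrow(tree$image); w <- ncol(tree$image)
  kin <- kinetic_intensity(t, kinetics)
  base <- 0.06                       # pre-injection tissue autofluorescence
  scene <- base + kin$leakage +
    tree$image * (kin$vascular + kin$vessel_plateau)
  if (!is.null(texture)) scene <- scene + texture
  if (vignette_strength > 0) scene <- scene * radial_vignette(h, w, vignette_strength)
  g <- coord_grid(h, w)
  fov_r <- fov_radius_frac * min(h, w) / 2
  fov <- (g$x - (w + 1) / 2)^2 + (g$y - (h + 1) / 2)^2 <= fov_r^2
  scene[!fov] <- 0.005
  clean <- clamp(scene)
  px <- clean
  if (noise_sd > 0 || noise_signal_sd > 0) {
    px <- with_seed(child_seed(seed, "noise", round(t * 1000)), {
      px + rnorm(h * w, sd = noise_sd) + sqrt(pmax(px, 0)) * rnorm(h * w, sd = noise_signal_sd)
    })
  }
  px <- clamp(matrix(px, h, w))
  if (!identical(motion$kind, "translation") || motion$tx != 0 || motion$ty != 0) {
    warped <- warp_frame(px, motion)
    warped[is.na(warped)] <- 0.005   # camera surround, not missing data
    px <- warped
  }
  if (timestamp) {
    st <- render_timestamp(px, t)
    px <- st$pixels
  }
  list(frame = new_frame(px, t_acq = t, dialect = "synthetic"),
       truth = list(transform = motion, clean = clean, fov = fov))
}

#' Smooth background texture (fixed per subject anatomy)
#' @param seed RNG seed.
#' @param size `c(h, w)`.
#' @param amplitude Peak-to-peak scale of the texture.
#' @export
background_texture <- function(seed, size = c(256, 256), amplitude = 0.05) {
  h <- size[1]; w <- size[2]
  with_seed(child_seed(seed, "texture"), {
    n <- matrix(rnorm(h * w), h, w)
    sm <- gauss_smooth(n, sigma = 3)
    amplitude * (sm - mean(sm)) / max(abs(sm - mean(sm)))
  })
}

# ---- study generation --------------------------------------------------------

#' Synthetic study configuration
#'
#' Defaults reproduce the desk-scale study conditions: 15 subjects, one eye,
#' frames every 30 s from 30 s to 10 min, mouse-style full-FOV analysis,
#' 256 x 256 frames, circadian leakage `L_PM = (1 + delta) * L_AM`.
#'
#' @param n_subjects Number of subjects.
#' @param schedule Acquisition schedule (s post-injection).
#' @param species `"mouse"`, `"nhp"` or `"human"`.
#' @param size Frame size `c(h, w)`.
#' @param delta Circadian leakage contrast: `L_PM = (1 + delta) * L_AM`.
#' @param kinetics_am AM [kinetic_params()].
#' @param motion_px Maximum per-frame translation jitter (uniform, px).
#' @param motion_deg Maximum per-frame rotation jitter (deg; primates only).
#' @param noise_sd,noise_signal_sd Sensor noise levels.
#' @param vignette_strength Radial vignetting strength.
#' @param timestamp Burn mm:ss timestamps into frames.
#' @param eyes Eyes imaged per subject (`"OS"`, or both for nested designs).
#' @param seed Master seed; the whole study is a deterministic function of
#'   it.
#' @export
synthetic_study_config <- function(n_subjects = 15L,
                                   schedule = seq(30, 600, by = 30),
                                   species = "mouse", size = c(256, 256),
                                   delta = 0, kinetics_am = kinetic_params(),
                                   motion_px = 8, motion_deg = 0,
                                   noise_sd = 0.005, noise_signal_sd = 0.01,
                                   vignette_strength = 0.3,
                                   timestamp = FALSE, eyes = "OS",
                                   seed = 1L) {
  if (delta < -1) abort("`delta` must be >= -1.", class = "ffa_parameter_error")
  kin_pm <- kinetics_am
  kin_pm$L <- (1 + delta) * kinetics_am$L
  list(n_subjects = as.integer(n_subjects), schedule = schedule,
       species = species, size = size, delta = delta,
       kinetics = list(AM = kinetics_am, PM = kin_pm),
       motion_px = motion_px, motion_deg = motion_deg,
       noise_sd = noise_sd, noise_signal_sd = noise_signal_sd,
       vignette_strength = vignette_strength, timestamp = timestamp,
       eyes = eyes, seed = as.integer(seed))
}

subject_motion <- function(cfg, seed) {
  with_seed(seed, {
    tx <- runif(1, -cfg$motion_px, cfg$motion_px)
    ty <- runif(1, -cfg$motion_px, cfg$motion_px)
    rot <- if (cfg$motion_deg > 0) runif(1, -cfg$motion_deg, cfg$motion_deg) else 0
    if (rot != 0) {
      tf_about_center(rotation = rot, tx = tx, ty = ty,
                      center = c((cfg$size[2] + 1) / 2, (cfg$size[1] + 1) / 2))
    } else {
      transform2d(tx = tx, ty = ty)
    }
  })
}

#' Generate a synthetic FFA study on disk
#'
#' Writes a directory tree consumable by [ingest_study()]: per-subject
#' PNG frames named `<subject>_<eye>_<session>_t<sss>.png`, a
#' `timing.csv` sidecar, and a `ground_truth.json` holding per-subject
#' kinetics, per-frame transforms, the exact noiseless region means, and the
#' analytic late-phase percent change per region (the oracle for
#' parameter-recovery validation).
#'
#' @param config [synthetic_study_config()].
#' @param dir Target directory; must be empty unless `force`.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the ground-truth list.
#' @export
generate_study <- function(config = synthetic_study_config(), dir,
                           force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0) {
    if (!force) {
      abort(sprintf("Directory %s is not empty (use force = TRUE).", dir),
            class = "ffa_parameter_error")
    }
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- config$size[1]; w <- config$size[2]
  timing <- list()
  truth_subjects <- list()
  for (si in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", si)
    anatomy_seed <- child_seed(config$seed, "anatomy", si)
    tree <- generate_vessel_tree(seed = anatomy_seed, size = config$size)
    texture <- background_texture(anatomy_seed, size = config$size)
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    truth_series <- list()
    for (eye in config$eyes) {
      for (session in c("AM", "PM")) {
        kin <- config$kinetics[[session]]
        frames_truth <- list()
        for (t in config$schedule) {
          mseed <- child_seed(config$seed, "motion", si, eye, session, t)
          motion <- subject_motion(config, mseed)
          fr <- render_frame(
            t, tree, kin, motion = motion,
            vignette_strength = config$vignette_strength,
            noise_sd = config$noise_sd,
            noise_signal_sd = config$noise_signal_sd,
            texture = texture, timestamp = config$timestamp,
            seed = child_seed(config$seed, "frame", si, eye, session, t))
          fname <- sprintf("%s_%s_%s_t%04d.png", sid, eye, session, t)
          png::writePNG(fr$frame$pixels, file.path(sdir, fname))
          timing[[length(timing) + 1]] <- tibble::tibble(
            filename = fname, seconds = t)
          frames_truth[[as.character(t)]] <- list(
            t = t, tx = motion$tx, ty = motion$ty,
            rotation = motion$rotation, scale = motion$scale,
            fov_mean_clean = mean(fr$truth$clean[fr$truth$fov]))
        }
        truth_series[[paste(eye, session, sep = "_")]] <- frames_truth
      }
    }
    truth_subjects[[sid]] <- list(
      anatomy_seed = anatomy_seed,
      series = truth_series,
      kinetics = lapply(config$kinetics, unclass))
  }
  timing <- dplyr::bind_rows(timing)
  utils::write.csv(timing, file.path(dir, "timing.csv"), row.names = FALSE)

  analytic <- analytic_truth(config)
  truth <- list(config = list(n_subjects = config$n_subjects,
                              schedule = config$schedule,
                              species = config$species, size = config$size,
                              delta = config$delta, seed = config$seed),
                analytic = analytic, subjects = truth_subjects)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Analytic late-phase percent change implied by a study configuration
#'
#' The microvascular analysis region (FOV minus large trunks) sees region
#' mean `v_bar * V(t) + b_bar * (base + L(t))`-style signal; only the
#' leakage amplitude differs between sessions, so the late-phase percent
#' change is `100 * delta * (leakage share of the late AM signal)`. The
#' share is computed exactly from a noiseless rendering of a reference
#' anatomy.
#'
#' @param config [synthetic_study_config()].
#' @param windows [phase_windows()].
#' @return List with `late_pct_change`, `leakage_share`, `cumulative_pct_change`.
#' @export
analytic_truth <- function(config, windows = phase_windows()) {
  h <- config$size[1]; w <- config$size[2]
  g <- coord_grid(h, w)
  fov_r <- 0.94 * min(h, w) / 2
  fov <- (g$x - (w + 1) / 2)^2 + (g$y - (h + 1) / 2)^2 <= fov_r^2
  vign <- radial_vignette(h, w, config$vignette_strength)
  base <- 0.06
  late <- config$schedule[config$schedule > windows$late[1]]
  if (length(late) == 0) {
    warn("Schedule has no late-phase timepoints; late-phase truth is undefined.",
         class = "ffa_configuration_warning")
  }
  kinA <- kinetic_intensity(late, config$kinetics$AM)
  kinP <- kinetic_intensity(late, config$kinetics$PM)
  allA <- kinetic_intensity(config$schedule, config$kinetics$AM)
  allP <- kinetic_intensity(config$schedule, config$kinetics$PM)
  per_subject <- lapply(seq_len(config$n_subjects), function(si) {
    tree <- generate_vessel_tree(
      seed = child_seed(config$seed, "anatomy", si), size = config$size)
    # analysis region: FOV minus major trunks (the pipeline masks these)
    wide <- tree$segments[tree$segments$width >= 5, ]
    trunk <- render_tubes(wide, h, w) > 0.2
    region <- fov & !trunk
    v_bar <- mean((tree$image * vign)[region])
    b_bar <- mean(vign[region])
    region_mean <- function(kin) {
      v_bar * (kin$vascular + kin$vessel_plateau) + b_bar * (base + kin$leakage)
    }
    amv <- mean(region_mean(kinA)); pmv <- mean(region_mean(kinP))
    tibble::tibble(
      subject = sprintf("s%02d", si),
      late_pct_change = 100 * (pmv - amv) / amv,
      leakage_share = mean(b_bar * kinA$leakage) / amv,
      cumulative_pct_change =
        100 * (sum(region_mean(allP)) - sum(region_mean(allA))) /
          sum(region_mean(allA)))
  })
  per_subject <- dplyr::bind_rows(per_subject)
  list(late_pct_change = mean(per_subject$late_pct_change),
       leakage_share = mean(per_subject$leakage_share),
       cumulative_pct_change = mean(per_subject$cumulative_pct_change),
       per_subject = per_subject)
}
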