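# Shared fixtures: tiny synthetic scenes built in code at test time.

# a small vessel scene pair (reference + moved copy) for registration tests
make_scene_pair <- function(seed, motion = tf_identity(), t = 40,
                            size = c(192, 192), noiseless = FALSE) {
  tree <- generate_vessel_tree(seed = seed, size = size)
  tex <- background_texture(seed, size)
  kin <- kinetic_params()
  ns <- if (noiseless) 0 else 0.005
  nss <- if (noiseless) 0 else 0.01
  ref <- render_frame(t, tree, kin, texture = tex, noise_sd = ns,
                      noise_signal_sd = nss, seed = seed * 7 + 1)
  mov <- render_frame(t, tree, kin, motion = motion, texture = tex,
                      noise_sd = ns, noise_signal_sd = nss, seed = seed * 7 + 2)
  list(ref = ref$frame, mov = mov$frame, tree = tree)
}

# a small on-disk study; cached per test file via the tmpdir
make_tiny_study <- function(dir, n_subjects = 2, delta = 0.3, seed = 5,
                            schedule = seq(30, 600, by = 60), ...) {
  cfg <- synthetic_study_config(n_subjects = n_subjects, delta = delta,
                                seed = seed, schedule = schedule, ...)
  # short test schedules may have no late-phase timepoints; that warning is
  # expected here
  truth <- suppressWarnings(generate_study(cfg, dir, force = TRUE))
  list(config = cfg, truth = truth, dir = dir)
}

# intensity record tibble builder for temporal-metric oracles
toy_records <- function(subject, session, t, value, region = "fov",
                        eye = "OS", species = "mouse") {
  tibble::tibble(subject = subject, eye = eye, session = session,
                 species = species, region = region, t_sec = t,
                 mean_intensity = value, n_pixels = 100L)
}
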