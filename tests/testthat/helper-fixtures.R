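# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Default phantom at full working resolution (0.5 mm isotropic).
phantom_fine <- function() {
  fixture("phantom_fine", function() generate_phantom(phantom_spec()))
}

# Coarse phantom (1.6 mm, 64^3) for training-speed tests.
phantom_coarse <- function() {
  fixture("phantom_coarse", function() {
    generate_phantom(phantom_spec(shape = c(64, 64, 64),
                                  spacing = c(1.6, 1.6, 1.6)))
  })
}

# A small random binary blob mask.
random_mask <- function(d = c(10, 10, 10), p = 0.3, seed = 1) {
  withr::with_seed(seed, as_mask(array(rbinom(prod(d), 1, p), d)))
}

# Tiny fast 3D network config for mechanics tests.
tiny3d_config <- function(...) {
  vnet_config(dims = 3, n_channels = 2, n_levels = 1, convs_per_level = 1,
              bottom_convs = 1, kernel_size = 3, dropout_keep_prob = 1,
              learning_rate = 1e-3, ...)
}

# Landmark set built directly from coordinates (mm).
make_landmarks <- function(sup, inf, ant, post, center, medial, flat, f0,
                           fdir, acromion) {
  structure(list(glenoid_superior = sup, glenoid_inferior = inf,
                 glenoid_anterior = ant, glenoid_posterior = post,
                 glenoid_center = center, medial_scapula_edge = medial,
                 lateral_supraspinatus_fossa = flat, fossa_floor_point = f0,
                 fossa_floor_direction = fdir, lateral_acromion = acromion),
            class = "scap_landmarks")
}
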