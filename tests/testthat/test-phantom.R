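test_that("enhancement curves follow the uptake-washout closed form", {
  # zero amplitude gives a flat curve
  k0 <- kinetic_params(0, 1, 0.1)
  expect_equal(enhancement_curve(k0, 20, 0.5), rep(0, 20))

  # with no washout and fast uptake the curve saturates at the amplitude
  ksat <- kinetic_params(1.5, 50, 0)
  y <- enhancement_curve(ksat, 70, 46 / 70)
  expect_equal(y[60:70], rep(1.5, 11), tolerance = 1e-8)

  # independently coded evaluation of the same formula, frame by frame
  k <- kinetic_params(2, 1, 0.05, onset_index = 4L)
  fi <- 46 / 70
  got <- enhancement_curve(k, 70, fi)
  expected <- vapply(1:70, function(f) {
    dt <- (f - 4) * fi
    if (dt < 0) 0 else 2 * (1 - exp(-1 * dt)) * exp(-0.05 * dt)
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)

  # frames strictly before onset are exactly zero
  expect_identical(got[1:3], c(0, 0, 0))
  expect_error(kinetic_params(-1, 1, 0), "amplitude")
  expect_error(kinetic_params(1, 0, 0), "k_in")
})

test_that("noiseless phantom pixels equal the compartment construction", {
  spec <- phantom_spec(noise_sigma = 0, texture_amp = 0, anatomy_contrast = 0)
  ph <- generate_phantom(spec)
  inner_curve <- enhancement_curve(spec$kinetics_inner, spec$n_frames,
                                   spec$frame_interval)
  expected <- spec$baseline_signal * (1 + inner_curve)
  idx <- which(ph$truth$inner_mask)
  for (px in idx[c(1, length(idx) %/% 2, length(idx))]) {
    coord <- arrayInd(px, dim(ph$truth$inner_mask))
    expect_equal(ph$series$data[coord[1], coord[2], ], expected,
                 tolerance = 1e-12)
  }
})

test_that("phantom geometry partitions the node at the requested fraction", {
  spec <- phantom_spec(inner_fraction = 0.25)
  msk <- generate_phantom(spec)$truth
  n_node <- sum(msk$node_mask)
  n_inner <- sum(msk$inner_mask)
  # concentric-ellipse discretization: within a few pixels of the target
  expect_lt(abs(n_inner / n_node - 0.25), 0.05)
  expect_true(all(msk$node_mask == (msk$inner_mask | msk$outer_mask)))
  expect_false(any(msk$inner_mask & msk$outer_mask))
})

test_that("phantom output is deterministic in the seed", {
  s1 <- phantom_spec(seed = 11)
  a <- generate_phantom(s1)$series$data
  b <- generate_phantom(s1)$series$data
  expect_identical(a, b)
  s2 <- phantom_spec(seed = 12)
  c_ <- generate_phantom(s2)$series$data
  expect_false(identical(a, c_))
  # geometry does not depend on the seed
  expect_identical(generate_phantom(s1)$truth$node_mask,
                   generate_phantom(s2)$truth$node_mask)
})

test_that("motion schedule displaces frames and is recorded in the truth", {
  ms <- matrix(0, 70, 2); ms[20, ] <- c(3, -2)
  spec <- phantom_spec(noise_sigma = 0, motion_schedule = ms)
  ph <- generate_phantom(spec)
  expect_identical(ph$truth$applied_shifts[20, ], c(dy = 3, dx = -2))
  still <- generate_phantom(phantom_spec(noise_sigma = 0))$series$data
  expect_identical(ph$series$data[, , 19], still[, , 19])
  expect_false(identical(ph$series$data[, , 20], still[, , 20]))
  # an integer shift is an exact roll of the interior
  expect_equal(ph$series$data[10:40, 10:40, 20], still[7:37, 12:42, 20],
               tolerance = 1e-12)
})

test_that("rician noise keeps magnitude signals non-negative", {
  ph <- generate_phantom(phantom_spec(noise_model = "rician", noise_sigma = 20,
                                      seed = 2))
  expect_true(all(ph$series$data >= 0))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(inner_fraction = 1.2), "inner_fraction")
  expect_error(phantom_spec(muscle_region = c(20, 40, 20, 45)), "overlap")
  expect_error(phantom_spec(n_frames = 3, n_baseline = 3), "n_baseline")
  expect_error(phantom_spec(muscle_region = c(0, 10, 1, 5)), "rectangle")
})

test_that("wash-out of the noiseless inner cluster curve matches the true slope", {
  spec <- phantom_spec(noise_sigma = 0)
  ph <- generate_phantom(spec)
  cl <- kmeans_segment(nde_of(ph), seed = 0)
  got <- wash_out(cl$cluster_curves["inner", ], spec$frame_interval,
                  normalizer = 1)
  # independent least squares on the true inner compartment curve
  tail_idx <- 31:70
  t <- (tail_idx - 1) * spec$frame_interval
  y <- ph$truth$true_curves["inner", tail_idx]
  fit <- stats::lm(y ~ t)
  expect_equal(got, unname(stats::coef(fit)[2]), tolerance = 1e-9)
})
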