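test_that("AUC follows the trapezoid over the post-injection window", {
  expect_equal(auc(rep(0, 50), 0.5, 3), 0)
  # constant 1 over a 40-minute post-injection window
  expect_equal(auc(rep(1, 41), 1, 1), 40)
  # arbitrary curve vs midpoint quadrature of its linear interpolant at 10x
  set.seed(20)
  y <- cumsum(rnorm(70)); fi <- 46 / 70; nb <- 3L
  t <- (seq_along(y) - 1) * fi
  f <- approxfun(t, y)
  tt <- seq(t[nb], t[70], length.out = 10 * (70 - nb) + 1)
  midpts <- (tt[-1] + tt[-length(tt)]) / 2
  oracle <- sum(f(midpts) * diff(tt))
  expect_equal(auc(y, fi, nb), oracle, tolerance = 1e-9)
  # linearity
  expect_equal(auc(3.5 * y, fi, nb), 3.5 * auc(y, fi, nb), tolerance = 1e-12)
})

test_that("wash-in is the peak consecutive slope up to maximal enhancement", {
  crv <- c(0, 0, 0, 0.5, 1.2, 1.5)
  expect_equal(wash_in(crv, 3, 1, normalizer = 1.5), 0.7 / 1.5)
  # monotone linear rise of slope s normalizes to s / max
  lin <- c(0, 0, 0, seq(0.2, 2, by = 0.2))
  expect_equal(wash_in(lin, 3, 1, normalizer = 2), 0.1)
  # exhaustive scan oracle on a random unimodal curve
  set.seed(21)
  up <- sort(runif(30)); down <- sort(runif(39), decreasing = TRUE) * max(up)
  crv2 <- c(0, up, down)
  nb <- 1L; fi <- 46 / 70
  imax <- which.max(crv2)
  oracle <- max(vapply(nb:(imax - 1), function(i)
    (crv2[i + 1] - crv2[i]) / fi, numeric(1))) / max(crv2)
  expect_equal(wash_in(crv2, nb, fi), oracle, tolerance = 1e-12)
  # a curve that never rises yields zero with a warning
  expect_warning(w0 <- wash_in(c(1, 0.5, 0.2, 0.1), 1, 1, normalizer = 1),
                 "does not rise")
  expect_equal(w0, 0)
})

test_that("wash-out is the normalized OLS slope of the 40-frame tail", {
  # exactly linear tail: slope -0.02 per frame, node max 2.0
  fi <- 46 / 70
  crv <- c(rep(2, 30), 2 - 0.02 * (1:40))
  expect_equal(wash_out(crv, fi, normalizer = 2), (-0.02 * 70 / 46) / 2,
               tolerance = 1e-9)
  # flat tail
  expect_equal(wash_out(rep(1.3, 70), fi, normalizer = 1.3), 0)
  # noisy tail vs closed-form normal-equations oracle
  set.seed(22)
  crv2 <- c(rep(0, 30), 3 - 0.05 * (1:40) + rnorm(40, sd = 0.2))
  t <- (31:70 - 1) * fi
  y <- crv2[31:70]
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(wash_out(crv2, fi, normalizer = 3), beta[2] / 3,
               tolerance = 1e-10)
  # too few frames for the window
  expect_error(wash_out(rep(1, 30), fi), "40")
  expect_equal(wash_out(c(rep(1, 20), seq(1, 0.5, length.out = 10)), fi,
                        normalizer = 1, washout_frames = 10),
               wash_out(c(rep(9, 60), seq(1, 0.5, length.out = 10)), fi,
                        normalizer = 1, washout_frames = 10),
               tolerance = 1e-12)
})

test_that("noiseless phantom parameters match the true compartment curves", {
  spec <- phantom_spec(noise_sigma = 0)
  ph <- generate_phantom(spec)
  res <- kmeans_segment(nde_of(ph), seed = 0)
  tab <- extract_all(res)

  f_in <- sum(ph$truth$inner_mask) / sum(ph$truth$node_mask)
  node_mean <- f_in * ph$truth$true_curves["inner", ] +
    (1 - f_in) * ph$truth$true_curves["outer", ]
  normalizer <- max(node_mean)
  fi <- spec$frame_interval; nb <- spec$n_baseline
  for (cl in c("inner", "outer")) {
    crv <- ph$truth$true_curves[cl, ]
    row <- tab[tab$cluster == cl, ]
    expect_equal(row$auc, auc(crv, fi, nb), tolerance = 1e-6)
    expect_equal(row$wash_in, wash_in(crv, nb, fi, normalizer),
                 tolerance = 1e-6)
    expect_equal(row$wash_out, wash_out(crv, fi, normalizer),
                 tolerance = 1e-6)
  }
  expect_equal(tab$volume_pct[tab$cluster == "inner"], 100 * f_in)
  expect_equal(sum(tab$volume_pct), 100)
  # both clusters share the node-level normalizer
  expect_equal(attr(tab, "max_enhancement_node"), normalizer,
               tolerance = 1e-10)
})

test_that("parameter rows carry the reference table schema", {
  ph <- generate_phantom(phantom_spec(noise_sigma = 0))
  res <- kmeans_segment(nde_of(ph), seed = 0)
  tab <- extract_all(res, node_id = 3L, agent = "Gd-BOPTA")
  ref <- load_param_table()
  expect_true(all(c("node", "agent", "cluster", "auc", "wash_in", "wash_out",
                    "volume_pct") %in% names(tab)))
  expect_identical(setdiff(names(tab), names(ref)), character(0))
  expect_setequal(tab$cluster, c("inner", "outer"))
  expect_equal(unique(tab$agent), "Gd-BOPTA")
})
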