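test_that("uniform-disc controls stay on the disc and carry its density", {
  tr <- toy_track(T = 15, seed = 2)
  ss <- sample_controls(tr, N = 20, scheme = "uniform_disc", R = 2, seed = 5)
  d <- ss$data
  m <- step_metrics(tr)
  anchors <- m[match(d$step, m$step), c("x0", "y0")]
  r <- sqrt((d$x - anchors$x0)^2 + (d$y - anchors$y0)^2)
  expect_true(all(r[d$endpoint > 0] <= 2))
  expect_equal(unique(d$log_h[d$endpoint > 0]), -log(pi * 4))
  # interior point density and exterior zero
  expect_equal(importance_density("uniform_disc", c(0, 0), c(1, 1), R = 2),
               1 / (4 * pi))
  expect_equal(importance_density("uniform_disc", c(0, 0), c(2, 1), R = 2), 0)
})

test_that("a disc that does not cover the observed steps is an error", {
  tr <- toy_track(T = 15, seed = 2)
  maxL <- max(step_metrics(tr)$L)
  expect_error(sample_controls(tr, N = 5, scheme = "uniform_disc",
                               R = maxL / 2, seed = 1),
               "exceeds disc radius")
})

test_that("gamma-radial control distances match the pooled moments", {
  # large-sample check of the sampling law against the observed moments
  tr <- toy_track(T = 402, seed = 8, step_scale = 0.3)
  m <- step_metrics(tr)
  pooled_mean <- mean(m$L)
  ss <- sample_controls(tr, N = 250, scheme = "gamma_radial", seed = 31)
  ctrl <- ss$data[ss$data$endpoint > 0, ]
  expect_gt(nrow(ctrl), 99000)
  expect_lt(abs(mean(ctrl$L) - pooled_mean) / pooled_mean, 0.01)
})

test_that("gamma-radial importance density matches a histogram of its sampler", {
  # 2D histogram oracle: empirical cell frequencies vs h integrated over
  # cells (density at centre x area), on cells with enough expected mass
  tr <- toy_track(T = 200, seed = 12, step_scale = 0.5)
  ss <- sample_controls(tr, N = 600, scheme = "gamma_radial", seed = 77)
  d <- ss$data[ss$data$endpoint > 0, ]
  m <- step_metrics(tr)
  anchors <- m[match(d$step, m$step), ]
  dx <- d$x - anchors$x0; dy <- d$y - anchors$y0
  n <- length(dx)
  h_bin <- 0.2
  brk <- seq(-2, 2, by = h_bin)
  cx <- cut(dx, brk); cy <- cut(dy, brk)
  counts <- table(cx, cy)
  centres <- brk[-length(brk)] + h_bin / 2
  sh <- ss$params$shape; rt <- ss$params$rate
  exp_dens <- outer(centres, centres, function(x, y) {
    r <- sqrt(x^2 + y^2)
    dgamma(r, sh, rt) / (2 * pi * r)
  })
  exp_count <- exp_dens * h_bin^2 * n
  use <- exp_count > 500
  rel_err <- abs(counts[use] - exp_count[use]) / exp_count[use]
  expect_gt(sum(use), 20)
  expect_lt(stats::median(rel_err), 0.1)
  expect_lt(max(rel_err), 0.35)
})

test_that("control sampling is a pure function of the seed", {
  tr <- toy_track(T = 10, seed = 2)
  a <- sample_controls(tr, N = 7, seed = 99)
  b <- sample_controls(tr, N = 7, seed = 99)
  expect_identical(a$data, b$data)
  c <- sample_controls(tr, N = 7, seed = 100)
  expect_false(identical(a$data, c$data))
})

test_that("case rows reproduce the step metrics", {
  tr <- toy_track(T = 12, seed = 6)
  land <- flat_landscape()
  ss <- sample_controls(tr, N = 5, seed = 3)
  des <- build_design(ss, land, ssf_formula())
  m <- step_metrics(tr)
  cases <- des$data[des$data$endpoint == 0, ]
  expect_equal(cases$L, m$L[m$usable])
  expect_equal(des$X[des$data$endpoint == 0, "L"], m$L[m$usable],
               ignore_attr = TRUE)
  expect_equal(des$X[des$data$endpoint == 0, "cos_theta"],
               cos(m$theta[m$usable]), ignore_attr = TRUE)
  expect_equal(des$X[des$data$endpoint == 0, "logL"], log(m$L[m$usable]),
               ignore_attr = TRUE)
})

test_that("design columns expand habitat levels against the reference", {
  set.seed(10)
  land <- generate_landscape(3, c(-60, 60, -60, 60), 2,
    categorical = list(veg = list(
      levels = c("grassland", "bushed_grassland", "bushland", "woodland"),
      proportions = c(0.4, 0.3, 0.2, 0.1), patch_scale = 6,
      ref = "grassland")))
  tr <- toy_track(T = 15, seed = 2)
  ss <- sample_controls(tr, N = 6, seed = 4)
  des <- build_design(ss, land, ssf_formula(habitat = "veg"))
  expect_length(des$colnames, 6)   # 3 indicators + 3 movement terms
  expect_true(all(c("veg_bushed_grassland", "veg_bushland", "veg_woodland",
                    "L", "logL", "cos_theta") %in% des$colnames))
  # interactions multiply indicator and movement columns
  des2 <- build_design(ss, land,
                       ssf_formula(habitat = "veg",
                                   interactions = "veg:cos_theta"))
  expect_length(des2$colnames, 9)
  expect_equal(des2$X[, "veg_bushland:cos_theta"],
               des2$X[, "veg_bushland"] * des2$X[, "cos_theta"],
               ignore_attr = TRUE)
  expect_error(build_design(ss, land, ssf_formula(habitat = "cover")),
               "unknown layer")
})

test_that("endpoints off the landscape are flagged and excluded", {
  # small landscape: most gamma-radial controls from an edge anchor fall out
  land <- flat_landscape(extent = c(-2, 2, -2, 2), res = 0.5)
  tr <- toy_track(T = 10, seed = 2, step_scale = 0.4)
  ss <- sample_controls(tr, N = 30, seed = 5)
  d <- ss$data
  inside <- d$x >= -2 & d$x < 2 & d$y >= -2 & d$y < 2
  expect_lt(sum(inside), nrow(d))
  # steps whose observed endpoint leaves the landscape are dropped whole
  bad_steps <- d$step[d$endpoint == 0 & !inside]
  keep <- inside & !(d$step %in% bad_steps)
  expect_warning(des <- build_design(ss, land, ssf_formula()), "dropped")
  expect_equal(nrow(des$X), sum(keep))
  # per-step divisor follows the surviving endpoint count
  idx <- switchSSF:::design_index(des)
  expect_true(all(idx$sizes <= 31))
  expect_equal(sum(idx$sizes), sum(keep))
})

test_that("plain Monte Carlo and importance weighting agree under uniform discs", {
  # with h constant the two estimators differ exactly by the disc area
  land <- flat_landscape()
  tr <- toy_track(T = 12, seed = 13)
  R <- max(step_metrics(tr)$L) * 1.2
  ss <- sample_controls(tr, N = 40, scheme = "uniform_disc", R = R, seed = 8)
  des <- build_design(ss, land, ssf_formula())
  beta <- matrix(c(-3, -0.5, 0.8), 1)
  with_h <- state_densities(des, beta, importance = TRUE)$logdens
  plain <- state_densities(des, beta, importance = FALSE)$logdens
  expect_equal(with_h - plain, matrix(-log(pi * R^2), nrow(plain), 1),
               ignore_attr = TRUE)
})

test_that("Monte Carlo denominators tighten as N grows (about half the SD per 4x N)", {
  land <- flat_landscape()
  tr <- toy_track(T = 4, seed = 21)
  beta <- matrix(c(-1, 0, 0.3), 1)
  denom_at <- function(N, seed) {
    ss <- sample_controls(tr, N = N, scheme = "uniform_disc", R = 3,
                          seed = seed)
    des <- build_design(ss, land, ssf_formula())
    # log densities -> recover the per-step log denominator
    eta_case <- des$X[des$data$endpoint == 0, , drop = FALSE] %*% t(beta)
    eta_case[1] - state_densities(des, beta, importance = FALSE)$logdens[1, 1]
  }
  sd_small <- sd(vapply(1:60, function(s) denom_at(100, s), 0))
  sd_big <- sd(vapply(1:60, function(s) denom_at(400, s + 500), 0))
  expect_gt(sd_small / sd_big, 1.4)
  expect_lt(sd_small / sd_big, 3.0)
})

test_that("designs serialise to the long case-control table", {
  land <- flat_landscape()
  tr <- toy_track(T = 8, seed = 2)
  ss <- sample_controls(tr, N = 4, seed = 1)
  des <- build_design(ss, land, ssf_formula())
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(des, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab), nrow(des$X))
  expect_true(all(c("id", "step", "case", "L", "logL", "cos_theta", "h")
                  %in% names(tab)))
  expect_equal(sum(tab$case), sum(des$data$endpoint == 0))
  expect_true(all(tab$h > 0))
})
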