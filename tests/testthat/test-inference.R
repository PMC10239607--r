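test_that("zero coefficients give unit densities under plain Monte Carlo", {
  land <- flat_landscape()
  tr <- toy_track(T = 10, seed = 1)
  ss <- sample_controls(tr, N = 8, scheme = "uniform_disc", R = 3, seed = 2)
  des <- build_design(ss, land, ssf_formula())
  sdn <- state_densities(des, matrix(0, 1, 3), importance = FALSE)
  expect_equal(sdn$logdens, matrix(0, nrow(sdn$logdens), 1),
               ignore_attr = TRUE)
})

test_that("K = 1 collapses the forward recursion to a sum of log densities", {
  land <- flat_landscape()
  tr <- toy_track(T = 12, seed = 3)
  ss <- sample_controls(tr, N = 10, seed = 4)
  des <- build_design(ss, land, ssf_formula())
  beta <- matrix(c(-4, -0.3, 0.7), 1, 3,
                 dimnames = list(NULL, des$colnames))
  model <- hmmssf_model(beta, transition_model(1))
  sdn <- state_densities(des, beta)
  expect_equal(forward_nll(des, model), -sum(sdn$logdens))
})

test_that("forward likelihood matches exhaustive enumeration", {
  land <- patchy_landscape()
  for (seed in 1:25) {
    inst <- random_instance(seed, land)
    fi <- forward_inputs(inst)
    oracle <- brute_force_hmm(fi$ld, fi$G, fi$delta)
    got <- -forward_nll(inst$design, inst$model)
    expect_equal(got, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("missing locations contribute identity matrices", {
  land <- flat_landscape()
  tr <- toy_track(T = 10, seed = 5)
  tr$x[5] <- NA; tr$y[5] <- NA; tr$observed[5] <- FALSE
  ss <- sample_controls(tr, N = 6, seed = 6)
  des <- build_design(ss, land, ssf_formula())
  model <- toy_movement_model()
  # enumeration oracle on the full slot grid (zero rows at excluded steps)
  sdn <- state_densities(des, model$beta)
  M <- length(tr$times) - 1L
  ld <- matrix(0, M, 2)
  ld[sdn$steps$step, ] <- sdn$logdens
  expect_true(all(ld[c(1, 4, 5, 6), ] == 0))  # first step + 3 around the gap
  omega <- switchSSF:::transition_omega(tr$times[seq_len(M)],
                                        model$transitions$covariates)
  G <- transition_matrix(model$transitions, omega)
  delta <- stationary_distribution(G[, , 1])
  oracle <- brute_force_hmm(ld, G, delta)
  expect_equal(-forward_nll(des, model), oracle$loglik, tolerance = 1e-10)
})

test_that("globally rescaling h shifts the NLL by a known constant only", {
  # the per-step normalising constant is shared across states, so it moves
  # the NLL but cannot move estimates or decoding
  land <- flat_landscape()
  tr <- toy_track(T = 15, seed = 7)
  ss <- sample_controls(tr, N = 10, seed = 8)
  des <- build_design(ss, land, ssf_formula())
  model <- toy_movement_model()
  nll0 <- forward_nll(des, model)
  des2 <- des
  des2$data$log_h <- des$data$log_h + log(7)   # h -> 7 h
  # each denominator shrinks 7-fold, each density grows 7-fold
  n_steps <- sum(des$data$endpoint == 0)
  expect_equal(forward_nll(des2, model), nll0 - n_steps * log(7),
               tolerance = 1e-9)
  # per-state density ratios (what the forward vector sees) are unchanged
  s1 <- state_densities(des, model$beta)$logdens
  s2 <- state_densities(des2, model$beta)$logdens
  expect_equal(s1[, 1] - s1[, 2], s2[, 1] - s2[, 2], tolerance = 1e-12)
})

test_that("densities converge to the closed-form movement kernel", {
  # homogeneous landscape + movement-only coefficients: the selection
  # function is the gamma x von Mises step density, exactly recovered by
  # importance sampling as N grows (no free constant: h integrates to 1)
  # the movement coefficients are moment-matched to the track so the pooled
  # importance gamma covers the kernel's small-r tail (a mismatched, lower
  # shape there gives heavy-tailed importance weights; see the vignette)
  land <- flat_landscape()
  tr <- toy_track(T = 42, seed = 9, step_scale = 0.4)
  m <- step_metrics(tr)
  beta_m <- c(coeffs_from_gamma(0.4, 0.2)$beta_L,
              coeffs_from_gamma(0.4, 0.2)$beta_logL, 1.2)
  g <- gamma_from_coeffs(beta_m[1], beta_m[2])
  vm <- vonmises_from_coeff(beta_m[3])
  usable <- m[m$usable, ]
  truth <- log(dgamma(usable$L, g$shape, g$rate) *
               dvm(usable$theta, vm$mu, vm$kappa) / usable$L)
  ss <- sample_controls(tr, N = 3000, seed = 10)
  des <- build_design(ss, land, ssf_formula())
  approx <- state_densities(des, matrix(beta_m, 1))$logdens[, 1]
  expect_lt(max(abs(approx - truth)), 0.05)
  # and the error shrinks with N (mean absolute log error at N=100 vs 3000)
  ss2 <- sample_controls(tr, N = 100, seed = 10)
  des2 <- build_design(ss2, land, ssf_formula())
  approx2 <- state_densities(des2, matrix(beta_m, 1))$logdens[, 1]
  expect_lt(mean(abs(approx - truth)), mean(abs(approx2 - truth)))
})

test_that("independent control seeds agree at large N", {
  land <- flat_landscape()
  tr <- toy_track(T = 20, seed = 11)
  cf <- coeffs_from_gamma(0.5, 0.25)   # matched to the track's step scale
  beta <- matrix(c(cf$beta_L, cf$beta_logL, 0.6), 1)
  d1 <- build_design(sample_controls(tr, N = 10000, seed = 1), land,
                     ssf_formula())
  d2 <- build_design(sample_controls(tr, N = 10000, seed = 2), land,
                     ssf_formula())
  p1 <- state_densities(d1, beta)$logdens
  p2 <- state_densities(d2, beta)$logdens
  expect_lt(max(abs(p1 - p2)), 0.02)
})

test_that("fitting is deterministic and keeps the best of all starts", {
  land <- patchy_landscape()
  model <- toy_model()
  fm <- ssf_formula(habitat = "res1")
  sim <- simulate_track(model, land, fm, n_steps = 220, burn_in = 20,
                        n_proposals = 400, seed = 33)
  des <- build_design(sample_controls(sim$track, N = 10, seed = 34),
                      land, fm)
  f1 <- fit_hmmssf(des, K = 2, n_starts = 3, seed = 77, maxit = 200)
  f2 <- fit_hmmssf(des, K = 2, n_starts = 3, seed = 77, maxit = 200)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$nll, f2$nll)
  expect_equal(f1$nll, min(f1$starts$nll, na.rm = TRUE))
  expect_equal(nrow(f1$starts), 3)
  # reported states are ordered slow-first
  mp <- movement_params(f1$model)
  expect_true(!is.unsorted(mp$mu_L))
  # summary table carries one row per parameter with finite SEs
  s <- summary(f1)
  expect_equal(nrow(s), length(f1$par))
  expect_true(all(is.finite(s$se)))
})

test_that("delta-method transition bands behave and match a bootstrap oracle", {
  land <- patchy_landscape()
  model <- toy_model()
  fm <- ssf_formula(habitat = "res1")
  sim <- simulate_track(model, land, fm, n_steps = 420, burn_in = 20,
                        n_proposals = 400, seed = 43)
  des <- build_design(sample_controls(sim$track, N = 10, seed = 44),
                      land, fm)
  fit <- fit_hmmssf(des, K = 2,
                    transition_covariates = c("tod_cos", "tod_sin"),
                    n_starts = 1, seed = 45, maxit = 300)
  tau <- seq(0, 23, by = 1)
  omega <- cyclic_time_covariates(tau)
  bands <- transition_cis(fit, omega)
  expect_true(all(bands$lower >= 0 & bands$upper <= 1))
  expect_true(all(bands$lower <= bands$estimate + 1e-12 &
                  bands$estimate <= bands$upper + 1e-12))
  # parametric bootstrap oracle: draw alpha from its estimated Gaussian
  a_idx <- grep("^alpha\\[", names(fit$par))
  Sa <- fit$vcov[a_idx, a_idx]
  ev <- eigen(Sa, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  set.seed(46)
  tm <- fit$model$transitions
  draws <- replicate(500, {
    av <- fit$par[a_idx] + as.numeric(A %*% rnorm(length(a_idx)))
    tm2 <- tm; tm2$alpha <- matrix(av, nrow(tm$alpha), ncol(tm$alpha))
    transition_matrix(tm2, omega)[1, 2, ]
  })
  boot_w <- apply(draws, 1, quantile, 0.975) - apply(draws, 1, quantile, 0.025)
  delta_w <- with(subset(bands, from == 1 & to == 2), upper - lower)
  expect_lt(max(abs(delta_w - boot_w) / boot_w), 0.15)
  # zero covariance: bands collapse onto the estimate
  fit0 <- fit
  fit0$vcov[] <- 0
  b0 <- transition_cis(fit0, omega)
  expect_equal(b0$lower, b0$estimate, tolerance = 1e-12)
  expect_equal(b0$upper, b0$estimate, tolerance = 1e-12)
})
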