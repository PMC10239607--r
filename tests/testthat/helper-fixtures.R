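# Shared fixtures, built in code at test time.

# small homogeneous landscape (constant covariate): the SSF reduces to the
# movement kernel, enabling closed-form oracles
flat_landscape <- function(extent = c(-50, 50, -50, 50), res = 1) {
  nc <- round((extent[2] - extent[1]) / res)
  nr <- round((extent[4] - extent[3]) / res)
  landscape(covariate_layer(matrix(0, nr, nc), extent, "flat", "continuous"))
}

# smooth continuous landscape for recovery-style tests
patchy_landscape <- function(seed = 1, extent = c(0, 10, 0, 10), res = 0.1,
                             patch_scale = 0.5) {
  generate_landscape(seed, extent, res,
                     continuous = list(res1 = list(patch_scale = patch_scale,
                                                   variance = 1)))
}

# deterministic synthetic track: a noisy random walk with regular timestamps
toy_track <- function(T = 20, seed = 1, interval = 1800, id = "a",
                      step_scale = 0.5) {
  set.seed(seed)
  ang <- cumsum(stats::runif(T - 1, -1, 1))
  L <- stats::rgamma(T - 1, shape = 4, rate = 4 / step_scale)
  x <- cumsum(c(0, L * cos(ang)))
  y <- cumsum(c(0, L * sin(ang)))
  track(id, as.POSIXct("2020-01-01", tz = "UTC") + (0:(T - 1)) * interval,
        x, y)
}

# 2-state model used across inference/simulation tests: a slow tortuous
# state and a fast directed one, selection on one continuous covariate,
# diel cycle on the transitions
toy_model <- function(cols = c("res1", "L", "logL", "cos_theta")) {
  beta <- rbind(c(1.0, -10, -1, -0.2),
                c(-0.5, -4, 0, 1.5))
  colnames(beta) <- cols
  tm <- transition_model(2, c("tod_cos", "tod_sin"),
                         alpha = cbind(c(-1.83, -1.26),
                                       c(0.03, 0.15),
                                       c(0.81, 0.14)))
  hmmssf_model(beta, tm)
}

# movement-only variant of the 2-state model (no habitat column)
toy_movement_model <- function() {
  beta <- rbind(c(-10, -1, -0.2),
                c(-4, 0, 1.5))
  colnames(beta) <- c("L", "logL", "cos_theta")
  tm <- transition_model(2, alpha = cbind(c(-1.8, -1.2)))
  hmmssf_model(beta, tm)
}

# independent enumeration oracle: joint likelihood summed over all K^M state
# sequences. logdens rows of zeros represent missing/identity steps.
brute_force_hmm <- function(logdens, G, delta) {
  M <- nrow(logdens); K <- ncol(logdens)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  jl <- apply(seqs, 1, function(s) {
    lp <- log(delta[s[1]]) + logdens[1, s[1]]
    for (t in seq_len(M - 1))
      lp <- lp + log(G[s[t], s[t + 1], t + 1]) + logdens[t + 1, s[t + 1]]
    lp
  })
  m <- max(jl)
  lik <- m + log(sum(exp(jl - m)))
  # marginals Pr(S_t = k | data)
  marg <- matrix(0, M, K)
  w <- exp(jl - lik)
  for (t in seq_len(M))
    for (k in seq_len(K))
      marg[t, k] <- sum(w[seqs[, t] == k])
  best <- seqs[which.max(jl), ]
  list(loglik = lik, viterbi = as.integer(best), marginals = marg)
}

# von Mises density (closed form for the turning-angle oracle)
dvm <- function(theta, mu, kappa)
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))

# random tiny design + model for oracle tests: a short track on a smooth
# landscape with few controls, random coefficients
random_instance <- function(seed, land, Tmax = 9, Kmax = 3) {
  set.seed(seed)
  K <- sample(1:Kmax, 1)
  T_ <- sample(4:Tmax, 1)
  tr <- toy_track(T = T_, seed = seed + 1000, step_scale = 0.3)
  # shift into the landscape interior
  tr$x <- tr$x + 5; tr$y <- tr$y + 5
  ss <- sample_controls(tr, N = 4, seed = seed + 2000)
  fm <- ssf_formula(habitat = "res1")
  des <- build_design(ss, land, fm)
  beta <- matrix(stats::rnorm(K * 4, 0, 0.5), K, 4)
  beta[, 2] <- -abs(beta[, 2])          # keep step-length part sane
  colnames(beta) <- des$colnames
  P <- sample(0:1, 1)
  covs <- if (P) c("tod_cos") else character()
  alpha <- matrix(stats::rnorm(K * (K - 1) * (P + 1), 0, 0.8),
                  ncol = P + 1)
  tm <- transition_model(K, covs, alpha)
  list(design = des, model = hmmssf_model(beta, tm), track = tr)
}

# rebuild the forward inputs for an instance exactly as the package does,
# but through the public API only (state_densities + transition_matrix)
forward_inputs <- function(inst) {
  des <- inst$design; model <- inst$model
  sdn <- state_densities(des, model$beta)
  M <- des$track_lengths[1] - 1L
  K <- model$K
  ld <- matrix(0, M, K)
  ld[sdn$steps$step, ] <- sdn$logdens
  omega <- switchSSF:::transition_omega(des$track_times[[1]][seq_len(M)],
                                        model$transitions$covariates)
  G <- transition_matrix(model$transitions, omega)
  delta <- stationary_distribution(G[, , 1])
  list(ld = ld, G = G, delta = delta, slots = sdn$steps$step)
}
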