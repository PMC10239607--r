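## Likelihood approximation and maximum-likelihood fitting.
##
## The state-dependent density of each step is approximated by Monte Carlo /
## importance sampling over the control endpoints (design module); the model
## likelihood combines these densities with the covariate-dependent
## transition matrices through the scaled forward algorithm (C++ kernel).

# Row bookkeeping computed once per design: contiguous endpoint groups per
# step, case-row positions, and per-track slot maps for the forward pass.
design_index <- function(design) {
  d <- design$data
  key <- paste(d$id, formatC(d$step, width = 9, flag = "0"))
  grp <- match(key, unique(key))
  sizes <- tabulate(grp)
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  case_rows <- which(d$endpoint == 0)
  if (length(case_rows) != length(sizes) ||
      any(d$endpoint[starts + 1L] != 0))
    stop("design rows not grouped with the case endpoint first")
  first <- starts + 1L
  tracks <- list()
  g0 <- 0L
  for (ti in seq_along(design$track_ids)) {
    id <- design$track_ids[ti]
    M <- design$track_lengths[ti] - 1L
    in_track <- which(d$id[first] == id)
    tracks[[id]] <- list(M = M,
                         groups = in_track,
                         slots = d$step[first[in_track]],
                         times = design$track_times[[ti]])
    g0 <- g0 + length(in_track)
  }
  list(starts = starts, sizes = sizes, case_rows = first,
       n_steps = length(sizes), tracks = tracks)
}

#' Approximate state-dependent step densities
#'
#' For each usable step and state, computes the importance-sampling
#' approximation of the selection-function step density: the numerator is
#' `exp(c(y_t, z_0) . beta_k)` at the observed endpoint and the denominator
#' is the mean over all valid endpoints of `exp(c . beta_k) / h`, where `h`
#' is the control sampling density. Everything is computed on the log scale
#' with log-sum-exp. With `importance = FALSE` the weights `h` are treated
#' as constant (plain Monte Carlo), which is exact for uniform sampling up
#' to the constant disc area.
#'
#' @param design an `hmmssf_design`.
#' @param beta coefficient matrix, `K` rows by design columns.
#' @param importance divide by the stored importance density (default).
#' @return A list with `logdens` (steps x K matrix of log densities) and
#'   `steps` (data frame keying each row: `id`, `step`, `t0`, `n_valid`).
#' @export
state_densities <- function(design, beta, importance = TRUE) {
  idx <- design_index(design)
  beta <- rbind(beta)
  sd_core(design, idx, beta, importance)
}

sd_core <- function(design, idx, beta, importance = TRUE) {
  K <- nrow(beta)
  ld <- matrix(NA_real_, idx$n_steps, K)
  off <- if (importance) design$data$log_h else 0
  for (k in seq_len(K)) {
    eta <- as.numeric(design$X %*% beta[k, ])
    denom <- grp_logsumexp_cpp(eta - off, idx$starts, idx$sizes) -
      log(idx$sizes)
    ld[, k] <- eta[idx$case_rows] - denom
  }
  d <- design$data
  list(logdens = ld,
       steps = data.frame(id = d$id[idx$case_rows],
                          step = d$step[idx$case_rows],
                          t0 = d$t0[idx$case_rows],
                          n_valid = idx$sizes))
}

# transition covariate matrix for a vector of slot start times
transition_omega <- function(times, covariates) {
  if (!length(covariates)) return(matrix(0, length(times), 0))
  tod <- NULL
  out <- matrix(NA_real_, length(times), length(covariates),
                dimnames = list(NULL, covariates))
  for (cv in covariates) {
    if (cv %in% c("tod_cos", "tod_sin")) {
      if (is.null(tod)) tod <- cyclic_time_covariates(times)
      out[, cv] <- tod[, cv]
    } else {
      stop("unknown transition covariate '", cv,
           "'; built-ins are 'tod_cos', 'tod_sin'")
    }
  }
  out
}

#' Scaled forward-algorithm negative log-likelihood
#'
#' Evaluates the hidden-Markov likelihood: per track, the initial
#' distribution is the stationary distribution of the first transition
#' matrix, and the forward vector is propagated through alternating
#' transition matrices and diagonal step-density matrices, renormalising at
#' every step to prevent underflow. Steps excluded from the likelihood
#' (first step of a track, steps with missing locations or dropped
#' covariates) contribute an identity matrix. Tracks are combined by
#' summing their negative log-likelihoods (complete pooling: all individuals
#' share the same parameters).
#'
#' @param design an `hmmssf_design`.
#' @param model an `hmmssf_model`.
#' @param importance use importance weights (see [state_densities()]).
#' @return The negative log-likelihood (scalar).
#' @export
forward_nll <- function(design, model, importance = TRUE) {
  idx <- design_index(design)
  omegas <- track_omegas(idx, model$transitions$covariates)
  nll_core(design, idx, omegas, model$beta, model$transitions, importance)
}

# per-track transition covariate matrices, computed once per fit
track_omegas <- function(idx, covariates) {
  lapply(idx$tracks, function(trk)
    transition_omega(trk$times[seq_len(trk$M)], covariates))
}

nll_core <- function(design, idx, omegas, beta, tm, importance = TRUE) {
  sd <- sd_core(design, idx, beta, importance)
  total <- 0
  K <- nrow(rbind(beta))
  for (ti in seq_along(idx$tracks)) {
    trk <- idx$tracks[[ti]]
    if (!length(trk$groups)) next
    M <- trk$M
    ld <- matrix(0, M, K)
    ld[trk$slots, ] <- sd$logdens[trk$groups, , drop = FALSE]
    G <- transition_matrix(tm, omegas[[ti]])
    delta <- stationary_distribution(G[, , 1])
    total <- total + forward_nll_cpp(ld, as.numeric(G), delta)
  }
  total
}

#' Low-level forward negative log-likelihood for one sequence
#'
#' Exposed for testing and for models built outside the design pipeline:
#' takes precomputed per-step log densities and transition matrices.
#'
#' @param logdens `M x K` matrix of log state-dependent densities (rows of
#'   zeros encode missing steps, i.e. identity contribution).
#' @param Gammas `K x K x M` array; slice `s >= 2` moves the chain from step
#'   `s-1` to `s` (slice 1 unused).
#' @param delta initial state distribution.
#' @return Negative log-likelihood (scalar).
#' @export
hmm_forward_nll <- function(logdens, Gammas, delta) {
  logdens <- rbind(logdens)
  forward_nll_cpp(logdens, as.numeric(Gammas), delta)
}

## ---- parameter packing -----------------------------------------------------

par_pack <- function(beta, alpha) c(as.numeric(t(beta)), as.numeric(alpha))

par_unpack <- function(par, K, p, npair, P) {
  nb <- K * p
  beta <- matrix(par[seq_len(nb)], K, p, byrow = TRUE)
  alpha <- matrix(par[nb + seq_len(npair * (P + 1))], npair, P + 1)
  list(beta = beta, alpha = alpha)
}

par_names <- function(cols, K, pairs, covariates) {
  bn <- as.character(t(outer(seq_len(K), cols,
                             function(k, cl) paste0("beta[", k, "]:", cl))))
  if (!nrow(pairs)) return(bn)
  an <- outer(paste0(pairs[, 1], ">", pairs[, 2]),
              c("intercept", covariates),
              function(pr, cv) paste0("alpha[", pr, "]:", cv))
  c(bn, as.character(an))
}

## ---- starting values -------------------------------------------------------

# Movement-moment heuristic in the spirit of two-stage fitting: split the
# observed steps into K speed classes by step-length quantiles, moment-fit a
# gamma in each, and estimate the angular concentration from the mean cosine.
moment_starts <- function(design, K) {
  d <- design$data
  cases <- d[d$endpoint == 0, ]
  p <- length(design$colnames)
  beta <- matrix(0, K, p, dimnames = list(NULL, design$colnames))
  br <- stats::quantile(cases$L, probs = seq(0, 1, length.out = K + 1))
  grp <- cut(cases$L, breaks = unique(br), include.lowest = TRUE,
             labels = FALSE)
  if (length(unique(br)) < K + 1) grp <- rep(seq_len(K), length.out = nrow(cases))
  for (k in seq_len(K)) {
    Lk <- cases$L[grp == k]
    m <- mean(Lk); s <- stats::sd(Lk)
    if (!is.finite(s) || s <= 0) s <- m / 2
    cf <- coeffs_from_gamma(m, s)
    if ("L" %in% colnames(beta)) beta[k, "L"] <- cf$beta_L
    if ("logL" %in% colnames(beta)) beta[k, "logL"] <- cf$beta_logL
    if ("cos_theta" %in% colnames(beta)) {
      cbar <- mean(cos(cases$theta[grp == k]), na.rm = TRUE)
      cbar <- max(min(cbar, 0.95), -0.95)
      beta[k, "cos_theta"] <- cbar * (2 - cbar^2) / (1 - cbar^2)
    }
  }
  beta
}

#' Fit the state-switching step selection model by maximum likelihood
#'
#' Minimises the forward-algorithm negative log-likelihood over all
#' selection coefficients and transition parameters with an unconstrained
#' quasi-Newton optimiser (`optim(method = "BFGS")`, finite-difference
#' gradients). Multiple starting values are used: the first is a
#' movement-moment heuristic (step-length quantile classes), the rest are
#' random perturbations of it; the solution with the lowest negative
#' log-likelihood is kept. States are then relabelled by ascending implied
#' mean step length. Standard errors come from the inverse of a
#' finite-difference Hessian at the optimum; 95% confidence intervals are
#' Wald intervals on the working scale.
#'
#' @param design an `hmmssf_design` from [build_design()].
#' @param K number of states (fixed, not estimated).
#' @param transition_covariates character vector of transition covariate
#'   names (`"tod_cos"`, `"tod_sin"`), or empty for a homogeneous chain.
#' @param n_starts number of starting values (default 10).
#' @param seed RNG seed for start generation (fits are deterministic given
#'   the seed and design).
#' @param importance use importance weights (default `TRUE`).
#' @param maxit,reltol optimiser settings passed to `optim`.
#' @param hessian compute the Hessian / covariance (default `TRUE`).
#' @return An object of class `hmmssf_fit`.
#' @export
fit_hmmssf <- function(design, K = 2, transition_covariates = character(),
                       n_starts = 10, seed = 1, importance = TRUE,
                       maxit = 1000, reltol = 1e-8, hessian = TRUE) {
  stopifnot(inherits(design, "hmmssf_design"), K >= 1)
  idx <- design_index(design)
  p <- length(design$colnames)
  P <- length(transition_covariates)
  tm0 <- transition_model(K, transition_covariates)
  npair <- nrow(tm0$pairs)
  n_par <- K * p + npair * (P + 1)
  if (idx$n_steps < 10 * n_par)
    warning("only ", idx$n_steps, " usable steps for ", n_par,
            " parameters; estimates may be unstable")
  set.seed(as.integer(seed))

  omegas <- track_omegas(idx, transition_covariates)
  objective <- function(par) {
    up <- par_unpack(par, K, p, npair, P)
    tm <- tm0; tm$alpha <- up$alpha
    val <- tryCatch(nll_core(design, idx, omegas, up$beta, tm, importance),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }

  beta0 <- moment_starts(design, K)
  alpha0 <- matrix(0, npair, P + 1)
  if (npair) alpha0[, 1] <- -2
  base <- par_pack(beta0, alpha0)
  starts <- vector("list", n_starts)
  starts[[1]] <- base
  if (n_starts > 1) {
    scale <- pmax(abs(base) * 0.3, 0.3)
    for (s in 2:n_starts)
      starts[[s]] <- base + stats::rnorm(n_par, 0, scale)
  }

  ledger <- data.frame(start = seq_len(n_starts), nll = NA_real_,
                       convergence = NA_integer_)
  best <- NULL
  for (s in seq_len(n_starts)) {
    opt <- tryCatch(
      stats::optim(starts[[s]], objective, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    ledger$nll[s] <- opt$value
    ledger$convergence[s] <- opt$convergence
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all ", n_starts, " starts failed to converge")

  up <- par_unpack(best$par, K, p, npair, P)
  colnames(up$beta) <- design$colnames
  tm <- transition_model(K, transition_covariates, up$alpha)
  model <- hmmssf_model(up$beta, tm)

  # deterministic state labels: slow state first
  os <- order_states(model)
  model <- os$model
  perm <- par_permutation(os$order, K, p, tm0$pairs, P)
  par <- par_pack(model$beta, model$transitions$alpha)

  nm <- par_names(design$colnames, K, tm0$pairs, transition_covariates)
  vcov <- NULL; se <- rep(NA_real_, n_par); singular <- FALSE
  if (hessian) {
    H <- tryCatch(stats::optimHess(best$par, objective),
                  error = function(e) NULL)
    if (!is.null(H)) {
      H <- H[perm, perm, drop = FALSE]
      ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
      tol <- 1e-10 * max(abs(ev$values))
      if (any(ev$values <= tol)) {
        singular <- TRUE
        warning("Hessian is (near-)singular: smallest eigenvalue ",
                signif(min(ev$values), 3),
                "; covariance is a pseudo-inverse and some SEs are unavailable")
      }
      inv <- ifelse(ev$values > tol, 1 / ev$values, 0)
      vcov <- ev$vectors %*% (inv * t(ev$vectors))
      dimnames(vcov) <- list(nm, nm)
      se <- sqrt(pmax(diag(vcov), 0))
      if (singular) se[se == 0] <- NA_real_
    }
  }
  names(par) <- nm; names(se) <- nm
  ci <- cbind(lower = par - 1.96 * se, upper = par + 1.96 * se)

  structure(list(model = model, par = par, nll = best$value,
                 convergence = best$convergence,
                 vcov = vcov, se = se, ci = ci,
                 starts = ledger, seed = seed,
                 N = design$params$N, scheme = design$params$scheme,
                 importance = importance,
                 n_steps = idx$n_steps, design = design),
            class = "hmmssf_fit")
}

# permutation of the packed parameter vector induced by a state reordering
par_permutation <- function(ord, K, p, pairs, P) {
  bperm <- as.numeric(t(matrix(seq_len(K * p), K, p, byrow = TRUE)[ord, ,
                                                                   drop = FALSE]))
  if (!nrow(pairs)) return(bperm)
  inv <- match(seq_len(K), ord)
  rowperm <- integer(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    # row r describes old pair (i, j); it becomes new pair (inv[i], inv[j])
    dest <- which(pairs[, 1] == inv[pairs[r, 1]] &
                  pairs[, 2] == inv[pairs[r, 2]])
    rowperm[dest] <- r
  }
  am <- matrix(K * p + seq_len(nrow(pairs) * (P + 1)), nrow(pairs), P + 1)
  c(bperm, as.numeric(am[rowperm, , drop = FALSE]))
}

#' @export
print.hmmssf_fit <- function(x, ...) {
  cat(sprintf("<hmmssf_fit> K = %d, NLL = %.4f, %d usable steps, scheme %s (N = %d)\n",
              x$model$K, x$nll, x$n_steps, x$scheme, x$N))
  print(summary(x))
  invisible(x)
}

#' @export
summary.hmmssf_fit <- function(object, ...) {
  data.frame(parameter = names(object$par),
             estimate = as.numeric(object$par),
             se = as.numeric(object$se),
             lower = object$ci[, "lower"],
             upper = object$ci[, "upper"],
             row.names = NULL)
}

#' Write a fit summary, covariance matrix and run manifest
#'
#' @param fit an `hmmssf_fit`.
#' @param dir output directory (created if needed).
#' @param config_hash optional config checksum recorded in the manifest.
#' @return The directory, invisibly.
#' @export
write_fit <- function(fit, dir, config_hash = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary(fit), file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  if (!is.null(fit$vcov))
    utils::write.csv(as.data.frame(fit$vcov), file.path(dir, "vcov.csv"))
  manifest <- list(package = "switchSSF",
                   version = as.character(utils::packageVersion("switchSSF")),
                   seed = fit$seed, N = fit$N, scheme = fit$scheme,
                   importance = fit$importance,
                   K = fit$model$K, nll = fit$nll,
                   convergence = fit$convergence,
                   n_steps = fit$n_steps,
                   start_nll = fit$starts$nll,
                   config_hash = config_hash)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

## ---- delta-method confidence bands ----------------------------------------

#' Pointwise confidence bands for transition probabilities
#'
#' For each off-diagonal pair and each covariate grid row, builds a 95%
#' interval for the linear predictor `eta_ij` from the alpha-block of the
#' parameter covariance (delta method on the working scale), then maps the
#' bounds through the multinomial-logit link (holding the other linear
#' predictors at their estimates), so the bands stay within [0, 1].
#'
#' @param fit an `hmmssf_fit` with a valid covariance.
#' @param omega matrix of covariate values (columns matching the transition
#'   covariates), one row per grid point.
#' @return A data frame: grid row, `from`, `to`, `estimate`, `lower`,
#'   `upper`.
#' @export
transition_cis <- function(fit, omega = NULL) {
  if (is.null(fit$vcov)) stop("fit has no covariance; rerun with hessian = TRUE")
  tm <- fit$model$transitions
  K <- tm$K; P <- length(tm$covariates)
  if (is.null(omega)) omega <- matrix(0, 1, P)
  omega <- as.matrix(omega)
  n <- nrow(omega)
  a_idx <- grep("^alpha\\[", names(fit$par))
  Sa <- fit$vcov[a_idx, a_idx, drop = FALSE]
  npair <- nrow(tm$pairs)
  G <- transition_matrix(tm, omega)
  out <- vector("list", npair)
  for (r in seq_len(npair)) {
    i <- tm$pairs[r, 1]; j <- tm$pairs[r, 2]
    X <- cbind(1, omega)
    # packing order: alpha columns are contiguous over pairs
    cols <- r + npair * (0:P)
    eta <- as.numeric(X %*% tm$alpha[r, ])
    v <- rowSums((X %*% Sa[cols, cols, drop = FALSE]) * X)
    se <- sqrt(pmax(v, 0))
    lo <- eta - 1.96 * se; hi <- eta + 1.96 * se
    # map eta bounds through the softmax with other predictors fixed
    gmap <- function(e, row_idx) {
      others <- vapply(setdiff(seq_len(K), c(i, j)), function(k2) {
        rr <- which(tm$pairs[, 1] == i & tm$pairs[, 2] == k2)
        as.numeric(X[row_idx, , drop = FALSE] %*% tm$alpha[rr, ])
      }, numeric(length(row_idx)))
      denom <- 1 + exp(e) +
        (if (length(others)) rowSums(rbind(exp(others))) else 0)
      exp(e) / denom
    }
    out[[r]] <- data.frame(grid = seq_len(n), from = i, to = j,
                           estimate = G[i, j, ],
                           lower = gmap(lo, seq_len(n)),
                           upper = gmap(hi, seq_len(n)))
  }
  do.call(rbind, out)
}
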