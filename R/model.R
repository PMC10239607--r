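#' Movement parameters implied by selection-function coefficients
#'
#' Under the integrated (exponential-form) step selection function, a gamma
#' distribution of step lengths is encoded by coefficients on the step length
#' `L` and its log: shape `= beta_logL + 2`, rate `= -beta_L`. The implied
#' mean and standard deviation are
#' `mu_L = (beta_logL + 2) / (-beta_L)` and
#' `sigma_L = sqrt(beta_logL + 2) / (-beta_L)`.
#' Coefficients are estimated unconstrained, so they may not correspond to a
#' valid gamma distribution (`beta_logL + 2 <= 0` or `beta_L >= 0`); in that
#' case a validity flag is returned rather than an error.
#'
#' @param beta_L coefficient on step length.
#' @param beta_logL coefficient on log step length.
#' @return A list with `mu`, `sigma`, `shape`, `rate`, `valid`.
#' @seealso [coeffs_from_gamma()] for the inverse map.
#' @export
gamma_from_coeffs <- function(beta_L, beta_logL) {
  shape <- beta_logL + 2
  rate <- -beta_L
  valid <- shape > 0 & rate > 0
  mu <- ifelse(valid, shape / rate, NA_real_)
  sigma <- ifelse(valid, sqrt(shape) / rate, NA_real_)
  list(mu = mu, sigma = sigma,
       shape = ifelse(valid, shape, NA_real_),
       rate = ifelse(valid, rate, NA_real_),
       valid = valid)
}

#' Selection coefficients encoding a gamma step-length distribution
#'
#' Inverse of [gamma_from_coeffs()]: for mean `mu > 0` and standard
#' deviation `sigma > 0`, `beta_logL = mu^2/sigma^2 - 2` and
#' `beta_L = -mu/sigma^2`.
#'
#' @param mu,sigma gamma mean and standard deviation (map units).
#' @return A list with `beta_L`, `beta_logL`.
#' @export
coeffs_from_gamma <- function(mu, sigma) {
  stopifnot(all(mu > 0), all(sigma > 0))
  shape <- mu^2 / sigma^2
  rate <- mu / sigma^2
  list(beta_L = -rate, beta_logL = shape - 2)
}

#' Von Mises turning-angle parameters implied by the cosine coefficient
#'
#' The coefficient on `cos(theta)` encodes a von Mises distribution of
#' turning angles with concentration `kappa = |beta_theta|` and angular mean
#' 0 (directional persistence) when `beta_theta >= 0` or `pi` (reversals)
#' when `beta_theta < 0`.
#'
#' @param beta_theta coefficient on the cosine of the turning angle.
#' @return A list with `mu` (0 or `pi`) and `kappa`.
#' @export
vonmises_from_coeff <- function(beta_theta) {
  list(mu = ifelse(beta_theta >= 0, 0, pi), kappa = abs(beta_theta))
}

#' Relative selection strength
#'
#' For a selection coefficient `beta`, `exp(beta)` is the multiplicative
#' change in the selection function per unit increase of the covariate
#' (`rss()`), and `1/exp(beta)` is the relative selection strength of the
#' reference category compared to the category carrying `beta`
#' (`rss_reference()`): how much more likely a step into the reference
#' habitat is than into habitat `j`, all else equal.
#'
#' @param beta selection coefficient(s).
#' @return `exp(beta)` or `1/exp(beta)`.
#' @export
rss <- function(beta) exp(beta)

#' @rdname rss
#' @export
rss_reference <- function(beta) 1 / exp(beta)

## ---- transition model ------------------------------------------------------

#' Covariate-dependent transition model
#'
#' Off-diagonal transition probabilities are linked to covariates through a
#' multinomial logit: the linear predictor for the transition from state `i`
#' to `j != i` is `eta_ij = alpha0_ij + sum_p alpha_p_ij * omega_p`, with the
#' structural zero `eta_ii = 0`, and
#' `gamma_ij = exp(eta_ij) / sum_k exp(eta_ik)`.
#'
#' @param K number of states.
#' @param covariates character vector of transition covariate names (may be
#'   empty for a homogeneous chain); `"tod_cos"`/`"tod_sin"` are the cyclic
#'   time-of-day pair produced by [cyclic_time_covariates()].
#' @param alpha numeric matrix with `K*(K-1)` rows (ordered pairs `(i,j)`,
#'   `i != j`, row-major: (1,2), (1,3), ..., (2,1), ...) and `1 + P` columns
#'   (intercept then covariates). Defaults to zeros.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(K, covariates = character(), alpha = NULL) {
  stopifnot(K >= 1)
  P <- length(covariates)
  pairs <- pair_index(K)
  if (is.null(alpha)) alpha <- matrix(0, nrow(pairs), P + 1)
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != nrow(pairs) || ncol(alpha) != P + 1)
    stop("alpha must be ", nrow(pairs), " x ", P + 1)
  if (nrow(pairs)) {
    rownames(alpha) <- paste0(pairs[, 1], ">", pairs[, 2])
    colnames(alpha) <- c("intercept", covariates)
  }
  structure(list(K = K, covariates = covariates, alpha = alpha,
                 pairs = pairs),
            class = "transition_model")
}

# ordered off-diagonal pairs (i, j), i != j, row-major
pair_index <- function(K) {
  if (K == 1) return(matrix(integer(), 0, 2))
  g <- expand.grid(j = seq_len(K), i = seq_len(K))[, c("i", "j")]
  as.matrix(g[g$i != g$j, , drop = FALSE])
}

#' Transition probability matrices from covariates
#'
#' Evaluates the multinomial-logit transition matrix for each row of the
#' covariate matrix `omega`. Rows of every matrix sum to 1 and all entries
#' lie in (0, 1) for finite coefficients.
#'
#' @param tm a `transition_model`.
#' @param omega numeric matrix (rows = time points, columns matching
#'   `tm$covariates`), or `NULL` for an intercept-only model.
#' @return A `K x K x n` array of transition matrices.
#' @export
transition_matrix <- function(tm, omega = NULL) {
  stopifnot(inherits(tm, "transition_model"))
  K <- tm$K
  P <- length(tm$covariates)
  if (is.null(omega)) omega <- matrix(0, 1, P)
  omega <- as.matrix(omega)
  if (P > 0 && !is.null(colnames(omega)) &&
      all(tm$covariates %in% colnames(omega)))
    omega <- omega[, tm$covariates, drop = FALSE]
  if (ncol(omega) != P)
    stop("omega must have ", P, " column(s) matching the transition covariates")
  n <- nrow(omega)
  G <- array(0, c(K, K, n))
  if (K == 1) { G[1, 1, ] <- 1; return(G) }
  eta <- cbind(1, omega) %*% t(tm$alpha)    # n x K(K-1)
  for (i in seq_len(K)) {
    E <- matrix(0, n, K)                    # eta_ii = 0 structural zero
    for (j in setdiff(seq_len(K), i)) {
      col <- which(tm$pairs[, 1] == i & tm$pairs[, 2] == j)
      E[, j] <- eta[, col]
    }
    m <- E[, 1]
    for (j in seq_len(K)[-1]) m <- pmax(m, E[, j])
    M <- exp(E - m)
    G[i, , ] <- t(M / rowSums(M))
  }
  G
}

#' Stationary distribution of a transition matrix
#'
#' Solves `delta %*% Gamma = delta`, `sum(delta) = 1` as a linear system
#' (the standard augmented-system approach, not matrix powers).
#'
#' @param Gamma a `K x K` stochastic matrix with all entries positive (or at
#'   least irreducible).
#' @return The stationary probability vector `delta`.
#' @export
stationary_distribution <- function(Gamma) {
  if (!is.matrix(Gamma)) Gamma <- as.matrix(Gamma)
  K <- nrow(Gamma)
  if (K == 1) return(1)
  A <- t(diag(K) - Gamma)
  A <- rbind(A, rep(1, K))
  b <- c(rep(0, K), 1)
  delta <- tryCatch(as.numeric(qr.solve(A, b)),
                    error = function(e)
                      stop("degenerate transition matrix: ", conditionMessage(e)))
  if (any(!is.finite(delta)) || any(delta < -1e-8))
    stop("degenerate transition matrix: no valid stationary distribution")
  delta <- pmax(delta, 0)
  delta / sum(delta)
}

## ---- model container -------------------------------------------------------

#' Specify a state-switching step selection model
#'
#' Bundles per-state selection coefficients with a transition model. The
#' number of states `K` is fixed a priori, not estimated. For reporting and
#' label-switching resolution, states are conventionally ordered by
#' ascending implied mean step length (slow state first); see
#' [order_states()].
#'
#' @param beta numeric matrix, `K` rows (states) by `p` columns (design
#'   columns, named).
#' @param transitions a `transition_model` with matching `K`.
#' @return An object of class `hmmssf_model`.
#' @export
hmmssf_model <- function(beta, transitions) {
  beta <- rbind(beta)
  stopifnot(inherits(transitions, "transition_model"),
            nrow(beta) == transitions$K)
  structure(list(K = transitions$K, beta = beta, transitions = transitions),
            class = "hmmssf_model")
}

#' @export
print.hmmssf_model <- function(x, ...) {
  cat(sprintf("<hmmssf_model> K = %d states, %d selection coefficients/state\n",
              x$K, ncol(x$beta)))
  print(round(x$beta, 4))
  if (length(x$transitions$covariates))
    cat("transition covariates:",
        paste(x$transitions$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Reorder model states by ascending implied mean step length
#'
#' Hidden-state labels are arbitrary (label switching); for deterministic
#' reporting the slow state comes first. States without a valid implied gamma
#' mean sort last.
#'
#' @param model an `hmmssf_model`.
#' @return A list `list(model, order)` with relabelled coefficients and the
#'   permutation applied (`order[new] = old`).
#' @export
order_states <- function(model) {
  K <- model$K
  if (K == 1) return(list(model = model, order = 1L))
  bl <- model$beta[, "L"]
  bll <- model$beta[, "logL"]
  g <- gamma_from_coeffs(bl, bll)
  key <- ifelse(g$valid, g$mu, Inf)
  ord <- order(key)
  if (identical(ord, seq_len(K))) return(list(model = model, order = ord))
  beta <- model$beta[ord, , drop = FALSE]
  tm <- model$transitions
  inv <- match(seq_len(K), ord)
  new_alpha <- tm$alpha
  for (r in seq_len(nrow(tm$pairs))) {
    i_new <- inv[tm$pairs[r, 1]]; j_new <- inv[tm$pairs[r, 2]]
    dest <- which(tm$pairs[, 1] == i_new & tm$pairs[, 2] == j_new)
    new_alpha[dest, ] <- tm$alpha[r, ]
  }
  tm$alpha <- new_alpha
  list(model = hmmssf_model(beta, tm), order = ord)
}

#' Summarise implied movement parameters per state
#'
#' @param model an `hmmssf_model` whose design includes `L`, `logL` and
#'   optionally `cos_theta`.
#' @return A data frame with one row per state: gamma mean/sd, von Mises
#'   mean/concentration, and a validity flag for the gamma part.
#' @export
movement_params <- function(model) {
  g <- gamma_from_coeffs(model$beta[, "L"], model$beta[, "logL"])
  out <- data.frame(state = seq_len(model$K),
                    mu_L = g$mu, sigma_L = g$sigma, gamma_valid = g$valid)
  if ("cos_theta" %in% colnames(model$beta)) {
    vm <- vonmises_from_coeff(model$beta[, "cos_theta"])
    out$mu_theta <- vm$mu; out$kappa <- vm$kappa
  }
  out
}
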