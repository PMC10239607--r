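## Global (Viterbi) and local (forward-backward) state decoding.
##
## Decoding runs per track with that track's initial distribution (the
## stationary distribution of its first transition matrix). Steps excluded
## from the likelihood (the first step of each track, missing locations,
## dropped covariates) participate in the recursion through identity
## contributions but receive no decoded state: their outputs are NA.

# per-track decoding inputs shared by viterbi and forward-backward
decode_context <- function(design, model, importance = TRUE) {
  idx <- design_index(design)
  sd <- sd_core(design, idx, model$beta, importance)
  tracks <- list()
  for (id in names(idx$tracks)) {
    trk <- idx$tracks[[id]]
    if (!length(trk$groups)) next
    M <- trk$M
    K <- model$K
    ld <- matrix(0, M, K)
    ld[trk$slots, ] <- sd$logdens[trk$groups, , drop = FALSE]
    omega <- transition_omega(trk$times[seq_len(M)], model$transitions$covariates)
    G <- transition_matrix(model$transitions, omega)
    tracks[[id]] <- list(ld = ld, G = G,
                         delta = stationary_distribution(G[, , 1]),
                         slots = trk$slots, groups = trk$groups,
                         times = trk$times)
  }
  list(tracks = tracks, steps = sd$steps)
}

#' Most likely state sequence (global decoding)
#'
#' Runs the Viterbi algorithm in log space per track: the returned sequence
#' maximises the joint likelihood over all full state sequences. Ties are
#' broken toward the lower state index (deterministic). Steps excluded from
#' the likelihood are reported as `NA`.
#'
#' @param fit an `hmmssf_fit`, or an `hmmssf_design` (then `model` must be
#'   given).
#' @param model an `hmmssf_model` when `fit` is a design.
#' @param importance use importance weights.
#' @return A data frame: `id`, `step`, `t0`, `state`.
#' @export
viterbi_states <- function(fit, model = NULL, importance = TRUE) {
  ctx <- resolve_decode(fit, model, importance)
  out <- lapply(names(ctx$tracks), function(id) {
    trk <- ctx$tracks[[id]]
    M <- nrow(trk$ld); K <- ncol(trk$ld)
    lG <- log(trk$G)
    v <- log(trk$delta) + trk$ld[1, ]
    back <- matrix(NA_integer_, M, K)
    for (s in seq_len(M)[-1]) {
      vn <- numeric(K)
      for (j in seq_len(K)) {
        cand <- v + lG[, j, s]
        b <- which.max(cand)      # which.max takes the lowest index on ties
        back[s, j] <- b
        vn[j] <- cand[b] + trk$ld[s, j]
      }
      v <- vn
    }
    st <- integer(M)
    st[M] <- which.max(v)
    for (s in rev(seq_len(M - 1))) st[s] <- back[s + 1, st[s + 1]]
    st_out <- rep(NA_integer_, M)
    st_out[trk$slots] <- st[trk$slots]
    data.frame(id = id, step = seq_len(M),
               t0 = trk$times[seq_len(M)], state = st_out)
  })
  do.call(rbind, out)
}

#' Local state probabilities (forward-backward)
#'
#' Computes `Pr(S_t = k | all data)` for every step with the scaled
#' forward-backward algorithm, plus the sequence of locally most probable
#' states (usually similar to, but not identical with, the Viterbi
#' sequence). Rows sum to 1; excluded steps are `NA`.
#'
#' @inheritParams viterbi_states
#' @return A data frame: `id`, `step`, `t0`, `prob_1..prob_K`, `map_state`.
#' @export
local_probs <- function(fit, model = NULL, importance = TRUE) {
  ctx <- resolve_decode(fit, model, importance)
  out <- lapply(names(ctx$tracks), function(id) {
    trk <- ctx$tracks[[id]]
    M <- nrow(trk$ld); K <- ncol(trk$ld)
    # scaled forward
    la <- matrix(0, M, K)   # log alpha
    phi <- trk$delta * exp(trk$ld[1, ] - max(trk$ld[1, ]))
    c1 <- sum(phi); lscale <- max(trk$ld[1, ]) + log(c1)
    phi <- phi / c1
    la[1, ] <- log(phi) + lscale
    for (s in seq_len(M)[-1]) {
      m <- max(trk$ld[s, ])
      v <- as.numeric(phi %*% trk$G[, , s]) * exp(trk$ld[s, ] - m)
      cs <- sum(v)
      lscale <- lscale + m + log(cs)
      phi <- v / cs
      la[s, ] <- log(phi) + lscale
    }
    llk <- lscale
    # scaled backward
    lb <- matrix(0, M, K)
    bt <- rep(1, K); lsc <- 0
    lb[M, ] <- 0
    for (s in rev(seq_len(M - 1))) {
      m <- max(trk$ld[s + 1, ])
      v <- as.numeric(trk$G[, , s + 1] %*% (exp(trk$ld[s + 1, ] - m) * bt))
      cs <- sum(v)
      lsc <- lsc + m + log(cs)
      bt <- v / cs
      lb[s, ] <- log(bt) + lsc
    }
    lp <- la + lb - llk
    pr <- exp(lp - apply(lp, 1, max))
    pr <- pr / rowSums(pr)
    pr_out <- matrix(NA_real_, M, K)
    pr_out[trk$slots, ] <- pr[trk$slots, , drop = FALSE]
    map <- apply(pr_out, 1, function(r) if (anyNA(r)) NA_integer_
                 else which.max(r))
    df <- data.frame(id = id, step = seq_len(M), t0 = trk$times[seq_len(M)])
    colnames(pr_out) <- paste0("prob_", seq_len(K))
    cbind(df, as.data.frame(pr_out), map_state = map)
  })
  do.call(rbind, out)
}

resolve_decode <- function(fit, model, importance) {
  if (inherits(fit, "hmmssf_fit"))
    decode_context(fit$design, fit$model, importance)
  else if (inherits(fit, "hmmssf_design")) {
    if (is.null(model)) stop("supply a model with a design")
    decode_context(fit, model, importance)
  } else stop("fit must be an hmmssf_fit or hmmssf_design")
}

#' Stationary state probabilities over a covariate grid
#'
#' Evaluates the stationary distribution of the transition matrix at each
#' row of a covariate grid — e.g. the long-run probability of each state as
#' a function of time of day.
#'
#' @param tm a `transition_model` (or an `hmmssf_fit`).
#' @param omega covariate matrix, one row per grid point (columns matching
#'   `tm$covariates`), or `NULL` for intercept-only.
#' @return A matrix, grid points by states.
#' @export
stationary_probs <- function(tm, omega = NULL) {
  if (inherits(tm, "hmmssf_fit")) tm <- tm$model$transitions
  stopifnot(inherits(tm, "transition_model"))
  G <- transition_matrix(tm, omega)
  n <- dim(G)[3]
  out <- matrix(NA_real_, n, tm$K)
  for (i in seq_len(n)) out[i, ] <- stationary_distribution(G[, , i])
  colnames(out) <- paste0("state_", seq_len(tm$K))
  out
}

#' Delta-method bands for stationary state probabilities
#'
#' Pointwise 95% bands for each stationary probability over a covariate
#' grid, from a finite-difference gradient of the stationary distribution
#' with respect to the transition parameters and the alpha-block of the fit
#' covariance. Bands are clamped to [0, 1].
#'
#' @param fit an `hmmssf_fit` with a valid covariance.
#' @param omega covariate grid.
#' @return A data frame: grid row, state, estimate, lower, upper.
#' @export
stationary_cis <- function(fit, omega = NULL) {
  if (is.null(fit$vcov)) stop("fit has no covariance")
  tm <- fit$model$transitions
  P <- length(tm$covariates)
  if (is.null(omega)) omega <- matrix(0, 1, P)
  omega <- as.matrix(omega)
  a_idx <- grep("^alpha\\[", names(fit$par))
  Sa <- fit$vcov[a_idx, a_idx, drop = FALSE]
  a0 <- as.numeric(tm$alpha)
  eps <- 1e-5
  out <- list()
  for (g in seq_len(nrow(omega))) {
    om <- omega[g, , drop = FALSE]
    f <- function(av) {
      tm2 <- tm; tm2$alpha <- matrix(av, nrow(tm$alpha), ncol(tm$alpha))
      stationary_distribution(transition_matrix(tm2, om)[, , 1])
    }
    d0 <- f(a0)
    Jg <- vapply(seq_along(a0), function(q) {
      ap <- a0; ap[q] <- ap[q] + eps
      am <- a0; am[q] <- am[q] - eps
      (f(ap) - f(am)) / (2 * eps)
    }, numeric(tm$K))
    v <- diag(Jg %*% Sa %*% t(Jg))
    se <- sqrt(pmax(v, 0))
    out[[g]] <- data.frame(grid = g, state = seq_len(tm$K), estimate = d0,
                           lower = pmax(d0 - 1.96 * se, 0),
                           upper = pmin(d0 + 1.96 * se, 1))
  }
  do.call(rbind, out)
}

#' Write decoded states and probabilities to CSV
#'
#' Joins the Viterbi sequence and the local state probabilities on the step
#' table.
#'
#' @param fit an `hmmssf_fit`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_decoded <- function(fit, path) {
  vit <- viterbi_states(fit)
  lp <- local_probs(fit)
  out <- merge(vit, lp, by = c("id", "step", "t0"), sort = FALSE)
  out <- out[order(out$id, out$step), ]
  out$t0 <- format(out$t0, "%Y-%m-%dT%H:%M:%S")
  names(out)[names(out) == "state"] <- "viterbi"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
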