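#' Model formula for the state-dependent step selection function
#'
#' Declares which covariate columns enter the selection function. Habitat
#' terms name landscape layers (categorical layers expand to indicator
#' columns against their reference level). Movement terms are drawn from
#' `"L"` (step length), `"logL"` and `"cos_theta"`; together they encode a
#' gamma distribution of step lengths and a von Mises distribution of
#' turning angles. Interactions are written `"layer:movement"` and expand to
#' products of the corresponding columns.
#'
#' @param habitat character vector of layer names (may be empty).
#' @param movement character subset of `c("L", "logL", "cos_theta")`.
#' @param interactions character vector like `"veg:L"`, or `NULL`.
#' @return An object of class `ssf_formula`.
#' @export
ssf_formula <- function(habitat = character(),
                        movement = c("L", "logL", "cos_theta"),
                        interactions = NULL) {
  bad <- setdiff(movement, c("L", "logL", "cos_theta"))
  if (length(bad)) stop("unknown movement term(s): ", paste(bad, collapse = ", "))
  structure(list(habitat = habitat, movement = movement,
                 interactions = interactions),
            class = "ssf_formula")
}

## ---- importance densities --------------------------------------------------

#' Importance density of a control-location sampling scheme
#'
#' For `uniform_disc`, endpoints are uniform on the disc of radius `R` about
#' the step's start point, so the density is `1 / (pi R^2)` inside the disc
#' and 0 outside. For `gamma_radial`, the distance `r` from the start point
#' follows a gamma distribution and the direction is uniform; the planar
#' density is `f_gamma(r) / (2 pi r)`, the `1/(2 pi r)` factor being the
#' polar-coordinates Jacobian for a uniform angle.
#'
#' @param scheme `"uniform_disc"` or `"gamma_radial"`.
#' @param anchor numeric `c(x, y)`: the step's start point.
#' @param point numeric `c(x, y)` or a two-column matrix of endpoints.
#' @param R disc radius (`uniform_disc`).
#' @param shape,rate gamma parameters of the radial law (`gamma_radial`).
#' @param log return the log density.
#' @return Density value(s) at `point`.
#' @export
importance_density <- function(scheme = c("uniform_disc", "gamma_radial"),
                               anchor, point, R = NULL,
                               shape = NULL, rate = NULL, log = FALSE) {
  scheme <- match.arg(scheme)
  pm <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  r <- sqrt((pm[, 1] - anchor[1])^2 + (pm[, 2] - anchor[2])^2)
  ld <- log_importance_density(scheme, r, R = R, shape = shape, rate = rate)
  if (log) ld else exp(ld)
}

log_importance_density <- function(scheme, r, R = NULL,
                                   shape = NULL, rate = NULL) {
  if (scheme == "uniform_disc") {
    if (is.null(R) || R <= 0) stop("uniform_disc needs R > 0")
    ifelse(r <= R, -log(pi * R^2), -Inf)
  } else {
    if (is.null(shape) || is.null(rate)) stop("gamma_radial needs shape and rate")
    if (any(r <= 0)) stop("gamma_radial importance density undefined at r = 0")
    stats::dgamma(r, shape = shape, rate = rate, log = TRUE) - log(2 * pi * r)
  }
}

# moment-match a gamma distribution: mean m, sd s -> shape, rate
gamma_moment_match <- function(m, s) {
  if (!is.finite(m) || !is.finite(s) || m <= 0 || s <= 0)
    stop("degenerate observed step lengths: cannot moment-match a gamma ",
         "radial law (mean = ", m, ", sd = ", s, ")")
  list(shape = m^2 / s^2, rate = m / s^2)
}

## ---- control sampling ------------------------------------------------------

#' Sample control locations for every usable step
#'
#' For each usable step (start, end and previous location observed), draws
#' `N` control endpoints anchored at the step's start point, under one of two
#' schemes:
#' \describe{
#'   \item{`gamma_radial` (default)}{distances drawn from a gamma distribution
#'     moment-matched to the pooled observed step lengths (all individuals,
#'     all states), directions uniform. This importance-sampling scheme
#'     concentrates controls where the movement kernel puts mass and markedly
#'     reduces Monte Carlo variance compared to uniform sampling.}
#'   \item{`uniform_disc`}{uniform on the disc of radius `R` about the start
#'     point (plain Monte Carlo integration up to the constant disc area).}
#' }
#' The observed endpoint is kept as endpoint 0 of every step; its importance
#' weight uses the density evaluated at the observed step length (under
#' `uniform_disc` an observed step longer than `R` is an error: the disc
#' must cover the data).
#'
#' @param tracks a `track` or list of tracks.
#' @param N number of controls per step.
#' @param scheme `"gamma_radial"` or `"uniform_disc"`.
#' @param R disc radius for `uniform_disc` (defaults to 1.1 times the maximum
#'   observed step length).
#' @param seed RNG seed.
#' @return An object of class `step_set`: a long data frame (one row per
#'   endpoint) with columns `id`, `step`, `endpoint` (0 = case), `t0`, `x`,
#'   `y`, `L`, `theta`, `log_h`, plus scheme metadata in attributes.
#' @export
sample_controls <- function(tracks, N = 25,
                            scheme = c("gamma_radial", "uniform_disc"),
                            R = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(tracks, "track")) tracks <- list(tracks)
  stopifnot(N >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  metrics <- lapply(tracks, step_metrics)
  # pooled observed step lengths across individuals (no state stratification)
  pooled <- unlist(lapply(seq_along(tracks), function(i) {
    m <- metrics[[i]]
    ok <- tracks[[i]]$observed[m$step] & tracks[[i]]$observed[m$step + 1]
    m$L[ok]
  }))
  params <- list(scheme = scheme, N = as.integer(N))
  if (scheme == "gamma_radial") {
    mm <- gamma_moment_match(mean(pooled), stats::sd(pooled))
    params$shape <- mm$shape; params$rate <- mm$rate
    params$pooled_mean <- mean(pooled); params$pooled_sd <- stats::sd(pooled)
  } else {
    if (is.null(R)) R <- max(pooled) * 1.1
    if (R <= 0) stop("uniform_disc needs R > 0")
    if (max(pooled) > R)
      stop("observed step length ", signif(max(pooled), 4),
           " exceeds disc radius R = ", signif(R, 4),
           ": increase R so the disc covers the data")
    params$R <- R
  }
  rows <- vector("list", length(tracks))
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    m <- metrics[[ti]]
    use <- which(m$usable)
    if (!length(use)) { rows[[ti]] <- NULL; next }
    nstep <- length(use)
    # previous bearing = bearing into the step's start point
    prev_b <- m$bearing[use - 1L]
    anchor_x <- m$x0[use]; anchor_y <- m$y0[use]
    n_tot <- nstep * N
    if (scheme == "gamma_radial") {
      r <- stats::rgamma(n_tot, shape = params$shape, rate = params$rate)
      ang <- rep(prev_b, each = N) + stats::runif(n_tot, -pi, pi)
    } else {
      r <- params$R * sqrt(stats::runif(n_tot))
      ang <- stats::runif(n_tot, -pi, pi)
    }
    cx <- rep(anchor_x, each = N) + r * cos(ang)
    cy <- rep(anchor_y, each = N) + r * sin(ang)
    theta_c <- wrap_angle(ang - rep(prev_b, each = N))
    ctrl <- data.frame(
      id = tr$id, step = rep(use, each = N),
      endpoint = rep(seq_len(N), times = nstep),
      t0 = rep(m$t0[use], each = N),
      x = cx, y = cy, L = r, theta = theta_c,
      log_h = log_importance_density(scheme, r, R = params$R,
                                     shape = params$shape,
                                     rate = params$rate))
    case <- data.frame(
      id = tr$id, step = use, endpoint = 0L, t0 = m$t0[use],
      x = m$x1[use], y = m$y1[use], L = m$L[use], theta = m$theta[use],
      log_h = log_importance_density(scheme, m$L[use], R = params$R,
                                     shape = params$shape,
                                     rate = params$rate))
    if (any(!is.finite(case$log_h)))
      stop("importance density is zero at ", sum(!is.finite(case$log_h)),
           " observed endpoint(s): disc radius too small")
    out <- rbind(case, ctrl)
    rows[[ti]] <- out[order(out$step, out$endpoint), ]
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  structure(list(data = data, params = params,
                 track_lengths = vapply(tracks, function(t)
                   length(t$times), 0L),
                 track_ids = vapply(tracks, `[[`, "", "id"),
                 track_times = lapply(tracks, `[[`, "times")),
            class = "step_set")
}

#' @export
print.step_set <- function(x, ...) {
  ns <- nrow(unique(x$data[x$data$endpoint == 0, c("id", "step")]))
  cat(sprintf("<step_set> %d usable steps x (1 case + %d controls), scheme %s\n",
              ns, x$params$N, x$params$scheme))
  invisible(x)
}

## ---- design assembly -------------------------------------------------------

# expand one landscape + formula into covariate column names
design_colnames <- function(land, formula) {
  cols <- character()
  for (nm in formula$habitat) {
    layer <- land$layers[[nm]]
    if (is.null(layer)) stop("formula names unknown layer: ", nm)
    if (layer$kind == "categorical")
      cols <- c(cols, paste0(nm, "_", setdiff(layer$levels, layer$ref)))
    else cols <- c(cols, nm)
  }
  cols <- c(cols, formula$movement)
  for (ia in formula$interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("interaction must be 'layer:movement': ", ia)
    layer <- land$layers[[parts[1]]]
    if (is.null(layer)) stop("interaction names unknown layer: ", parts[1])
    hab_cols <- if (layer$kind == "categorical")
      paste0(parts[1], "_", setdiff(layer$levels, layer$ref)) else parts[1]
    cols <- c(cols, paste0(hab_cols, ":", parts[2]))
  }
  cols
}

# Shared covariate-matrix assembly: habitat extraction, movement terms and
# interactions, aligned to design_colnames(). drop_theta zeroes the
# cos_theta column (and its interactions) for steps with no previous
# bearing. Returns list(X, valid).
covariate_matrix <- function(land, formula, x, y, L, theta,
                             drop_theta = FALSE) {
  hab <- extract_covariates(land, x, y)
  valid <- hab$valid
  hab$valid <- NULL
  ct <- if (drop_theta) rep(0, length(L)) else cos(theta)
  mov <- data.frame(L = L, logL = log(L), cos_theta = ct)
  base <- cbind(hab, mov[, formula$movement, drop = FALSE])
  for (ia in formula$interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    layer <- land$layers[[parts[1]]]
    hcols <- if (layer$kind == "categorical")
      paste0(parts[1], "_", setdiff(layer$levels, layer$ref)) else parts[1]
    mv <- if (drop_theta && parts[2] == "cos_theta") ct else mov[[parts[2]]]
    for (hc in hcols) base[[paste0(hc, ":", parts[2])]] <- base[[hc]] * mv
  }
  cols <- design_colnames(land, formula)
  list(X = as.matrix(base[, cols, drop = FALSE]), valid = valid)
}

#' Assemble the case-control design for the selection function
#'
#' Extracts habitat covariates at every endpoint of a `step_set`, attaches
#' the movement covariates (step length, its log, cosine of the turning
#' angle measured against the bearing into the step's start point — the same
#' reference for case and controls), and expands interactions. Endpoints
#' whose covariates cannot be extracted (outside the extent or on missing
#' cells) are flagged invalid and excluded from the Monte Carlo denominator;
#' a step whose observed endpoint is invalid is dropped entirely (with a
#' warning) since its numerator is undefined.
#'
#' @param step_set a `step_set` from [sample_controls()].
#' @param land a `landscape`.
#' @param formula an [ssf_formula()].
#' @return An object of class `hmmssf_design` holding the covariate matrix
#'   (one row per valid endpoint), step bookkeeping and transition-covariate
#'   hooks for downstream fitting.
#' @export
build_design <- function(step_set, land, formula) {
  stopifnot(inherits(step_set, "step_set"), inherits(land, "landscape"),
            inherits(formula, "ssf_formula"))
  d <- step_set$data
  cm <- covariate_matrix(land, formula, d$x, d$y, d$L, d$theta)
  X <- cm$X
  valid <- cm$valid
  cols <- design_colnames(land, formula)
  # a usable step needs a valid case row and >= 1 valid endpoint besides it
  key <- paste(d$id, d$step)
  case_bad <- unique(key[d$endpoint == 0 & !valid])
  if (length(case_bad)) {
    warning(length(case_bad),
            " step(s) dropped: observed endpoint has missing covariates")
    keep <- !(key %in% case_bad)
    d <- d[keep, ]; X <- X[keep, , drop = FALSE]; valid <- valid[keep]
    key <- key[keep]
  }
  keep <- valid
  d <- d[keep, ]; X <- X[keep, , drop = FALSE]
  structure(list(data = d, X = X, colnames = cols,
                 params = step_set$params,
                 track_ids = step_set$track_ids,
                 track_lengths = step_set$track_lengths,
                 track_times = step_set$track_times,
                 formula = formula),
            class = "hmmssf_design")
}

#' @export
print.hmmssf_design <- function(x, ...) {
  ns <- sum(x$data$endpoint == 0)
  cat(sprintf("<hmmssf_design> %d steps, %d endpoint rows, %d covariates\n",
              ns, nrow(x$X), ncol(x$X)))
  cat("  columns:", paste(x$colnames, collapse = ", "), "\n")
  invisible(x)
}

#' Export a design as a flat case-control table
#'
#' Writes the long case-control format standard in step-selection analyses:
#' one row per endpoint with step identifiers, case flag, covariates and the
#' importance density.
#'
#' @param design an `hmmssf_design`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  d <- design$data
  out <- data.frame(id = d$id, step = d$step, endpoint = d$endpoint,
                    case = as.integer(d$endpoint == 0),
                    t0 = format(d$t0, "%Y-%m-%dT%H:%M:%S"),
                    x = d$x, y = d$y,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(design$X, check.names = FALSE))
  out$h <- exp(d$log_h)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
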