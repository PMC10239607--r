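#' Covariate raster layers and synthetic landscapes
#'
#' A `covariate_layer` stores one spatial covariate on a regular lattice in
#' projected planar map units. Layers are either continuous (e.g. resource
#' density) or categorical (e.g. vegetation type); categorical layers carry an
#' ordered set of levels and a declared reference level against which indicator
#' columns are expanded during design-matrix construction.
#'
#' @param values numeric matrix of cell values, rows indexed south-to-north
#'   (row 1 is the southernmost row), columns west-to-east. Categorical layers
#'   hold integer codes `1..length(levels)`.
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` in map units.
#' @param name layer name used in model formulas.
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels character vector of category labels (categorical only).
#' @param ref reference level, one of `levels` (categorical only).
#'
#' @return An object of class `covariate_layer`.
#' @export
covariate_layer <- function(values, extent, name,
                            kind = c("continuous", "categorical"),
                            levels = NULL, ref = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), length(extent) == 4)
  extent <- as.numeric(extent)
  res_x <- (extent[2] - extent[1]) / ncol(values)
  res_y <- (extent[4] - extent[3]) / nrow(values)
  if (abs(res_x - res_y) > 1e-8 * max(res_x, res_y))
    stop("non-square cells: extent and grid dimensions imply resolution ",
         signif(res_x, 6), " x ", signif(res_y, 6))
  if (kind == "categorical") {
    if (is.null(levels)) stop("categorical layer needs 'levels'")
    if (is.null(ref)) ref <- levels[1]
    if (!ref %in% levels) stop("reference level '", ref, "' not in levels")
    codes <- values[!is.na(values)]
    if (length(codes) && (any(codes != round(codes)) ||
                          any(codes < 1 | codes > length(levels))))
      stop("categorical layer contains values outside coded levels")
  }
  structure(list(name = name, kind = kind, values = values,
                 extent = extent, resolution = res_x,
                 levels = levels, ref = ref),
            class = "covariate_layer")
}

#' @export
print.covariate_layer <- function(x, ...) {
  cat(sprintf("<covariate_layer '%s'> %s, %d x %d cells, res %g\n",
              x$name, x$kind, nrow(x$values), ncol(x$values), x$resolution))
  cat(sprintf("  extent: [%g, %g] x [%g, %g]\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  if (x$kind == "categorical")
    cat("  levels:", paste(x$levels, collapse = ", "),
        sprintf("(reference: %s)\n", x$ref))
  invisible(x)
}

#' Bundle aligned covariate layers into a landscape
#'
#' All layers must share extent and resolution. The landscape `boundary` (a
#' rectangle, by default the shared extent) defines the study area: control
#' and proposal endpoints outside it are treated as unavailable.
#'
#' @param ... `covariate_layer` objects, or a single list of them.
#' @param boundary numeric `c(xmin, xmax, ymin, ymax)`; defaults to the shared
#'   extent. Must be contained in the extent.
#' @return An object of class `landscape`.
#' @export
landscape <- function(..., boundary = NULL) {
  layers <- list(...)
  if (length(layers) == 1 && !inherits(layers[[1]], "covariate_layer"))
    layers <- layers[[1]]
  if (!length(layers)) stop("landscape needs at least one layer")
  for (l in layers)
    if (!inherits(l, "covariate_layer")) stop("all layers must be covariate_layer")
  ext <- layers[[1]]$extent
  for (l in layers[-1])
    if (max(abs(l$extent - ext)) > 1e-8 ||
        abs(l$resolution - layers[[1]]$resolution) > 1e-10)
      stop("layers not aligned on one lattice")
  names(layers) <- vapply(layers, `[[`, "", "name")
  if (is.null(boundary)) boundary <- ext
  if (boundary[1] < ext[1] - 1e-9 || boundary[2] > ext[2] + 1e-9 ||
      boundary[3] < ext[3] - 1e-9 || boundary[4] > ext[4] + 1e-9)
    stop("boundary must be contained in the layer extent")
  structure(list(layers = layers, extent = ext,
                 resolution = layers[[1]]$resolution,
                 boundary = as.numeric(boundary)),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d layer(s), res %g, extent [%g, %g] x [%g, %g]\n",
              length(x$layers), x$resolution,
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  for (l in x$layers) cat("  -", l$name, sprintf("(%s)\n", l$kind))
  invisible(x)
}

## ---- raster I/O (ESRI ASCII grid) -----------------------------------------

#' Read a covariate raster
#'
#' Supports the ESRI ASCII grid format (plain text, `.asc`). Cells equal to
#' the declared `NODATA_value` are returned as `NA`. GeoTIFF input is not
#' supported in this build; convert to ASCII grid first.
#'
#' @param path path to an `.asc` file.
#' @param name layer name; defaults to the file name without extension.
#' @inheritParams covariate_layer
#' @return A `covariate_layer`.
#' @export
read_raster <- function(path, kind = c("continuous", "categorical"),
                        name = NULL, levels = NULL, ref = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read raster: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unsupported format: GeoTIFF. Provide an ESRI ASCII grid (.asc).")
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("unknown raster format: missing ASCII grid header in ", path)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  res <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner; yll <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - res / 2; yll <- hdr$yllcenter - res / 2
  } else stop("ASCII grid header lacks corner/center coordinates")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         ncols * nrows)
  # file rows run north-to-south; internal storage is south-to-north
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[nrows:1, , drop = FALSE]
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  covariate_layer(m, c(xll, xll + ncols * res, yll, yll + nrows * res),
                  name = name, kind = kind, levels = levels, ref = ref)
}

#' Write a covariate layer as an ESRI ASCII grid
#'
#' @param layer a `covariate_layer`.
#' @param path output path.
#' @param nodata numeric sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "covariate_layer"))
  m <- layer$values
  m[is.na(m)] <- nodata
  m <- m[nrow(m):1, , drop = FALSE]  # write north-to-south
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", layer$extent[1]),
    sprintf("yllcorner %.10g", layer$extent[3]),
    sprintf("cellsize %.10g", layer$resolution),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- extraction ------------------------------------------------------------

# map coordinates -> cell index with half-open cells [x0, x0 + res)
cell_index <- function(layer, x, y) {
  col <- floor((x - layer$extent[1]) / layer$resolution) + 1
  row <- floor((y - layer$extent[3]) / layer$resolution) + 1
  inside <- x >= layer$extent[1] & x < layer$extent[2] &
            y >= layer$extent[3] & y < layer$extent[4]
  list(row = row, col = col, inside = inside)
}

extract_layer <- function(layer, x, y, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (layer$kind == "categorical") method <- "nearest"
  out <- rep(NA_real_, length(x))
  if (method == "nearest") {
    ci <- cell_index(layer, x, y)
    ok <- ci$inside
    out[ok] <- layer$values[cbind(ci$row[ok], ci$col[ok])]
  } else {
    # bilinear between the four surrounding cell centres; clamp at edges
    res <- layer$resolution
    gx <- (x - layer$extent[1]) / res - 0.5
    gy <- (y - layer$extent[3]) / res - 0.5
    nr <- nrow(layer$values); nc <- ncol(layer$values)
    inside <- x >= layer$extent[1] & x < layer$extent[2] &
              y >= layer$extent[3] & y < layer$extent[4]
    c0 <- pmin(pmax(floor(gx), 0), nc - 1); c1 <- pmin(c0 + 1, nc - 1)
    r0 <- pmin(pmax(floor(gy), 0), nr - 1); r1 <- pmin(r0 + 1, nr - 1)
    fx <- pmin(pmax(gx - c0, 0), 1); fy <- pmin(pmax(gy - r0, 0), 1)
    v00 <- layer$values[cbind(r0 + 1, c0 + 1)]
    v01 <- layer$values[cbind(r0 + 1, c1 + 1)]
    v10 <- layer$values[cbind(r1 + 1, c0 + 1)]
    v11 <- layer$values[cbind(r1 + 1, c1 + 1)]
    v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11)
    out[inside] <- v[inside]
  }
  out
}

#' Extract covariate values at points
#'
#' Categorical layers always use nearest-cell lookup (interpolating category
#' codes is meaningless) and expand to indicator columns named
#' `<layer>_<level>` for every non-reference level. Continuous layers use
#' nearest-cell lookup by default, with bilinear interpolation as an option.
#' Points outside the extent or on missing cells are flagged invalid rather
#' than raising an error.
#'
#' @param land a `landscape`.
#' @param x,y point coordinates in map units.
#' @param method `"nearest"` (default) or `"bilinear"` for continuous layers.
#' @param expand_categorical expand categorical layers to 0/1 indicator
#'   columns against the reference level (default `TRUE`); otherwise return
#'   the integer codes.
#' @return A `data.frame` with one column per covariate term and a logical
#'   `valid` column.
#' @export
extract_covariates <- function(land, x, y, method = c("nearest", "bilinear"),
                               expand_categorical = TRUE) {
  stopifnot(inherits(land, "landscape"), length(x) == length(y))
  method <- match.arg(method)
  out <- list()
  valid <- rep(TRUE, length(x))
  for (layer in land$layers) {
    v <- extract_layer(layer, x, y, method)
    valid <- valid & !is.na(v)
    if (layer$kind == "categorical" && expand_categorical) {
      non_ref <- setdiff(layer$levels, layer$ref)
      for (lev in non_ref) {
        code <- match(lev, layer$levels)
        out[[paste0(layer$name, "_", lev)]] <- as.numeric(v == code)
      }
    } else {
      out[[layer$name]] <- v
    }
  }
  df <- as.data.frame(out, optional = TRUE)
  df$valid <- valid
  df
}

## ---- synthetic landscape generator ----------------------------------------

# Gaussian-smoothed white noise on the lattice (separable kernel, reflection
# padding); patch_scale is the kernel sd in map units and controls the spatial
# autocorrelation range.
smooth_field <- function(nrow, ncol, res, patch_scale) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  sigma <- max(patch_scale / res, 1e-8)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[n - seq_len(half) + 1L]))
    as.numeric(stats::filter(vp, k, sides = 2))[half + seq_len(n)]
  }
  z <- apply(z, 2, pad_conv)
  z <- t(apply(z, 1, pad_conv))
  z
}

#' Generate a synthetic landscape
#'
#' Continuous layers are Gaussian white noise smoothed with a Gaussian kernel
#' of standard deviation `patch_scale` (map units), then standardised to the
#' requested variance. Categorical layers are obtained by thresholding an
#' independent smoothed field at the quantiles that hit the target level
#' proportions, which yields contiguous habitat patches. The generator is a
#' pure function of `(seed, spec)`.
#'
#' @param seed integer RNG seed.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`.
#' @param resolution cell size in map units.
#' @param continuous named list of specs `list(name = list(patch_scale=,
#'   variance=))`; may be `NULL`.
#' @param categorical named list of specs `list(name = list(levels=,
#'   proportions=, patch_scale=, ref=))`; proportions must sum to 1.
#' @param boundary optional study-area rectangle (defaults to extent).
#' @return A `landscape`.
#' @export
generate_landscape <- function(seed, extent, resolution,
                               continuous = NULL, categorical = NULL,
                               boundary = NULL) {
  stopifnot(resolution > 0)
  set.seed(as.integer(seed))
  nc <- round((extent[2] - extent[1]) / resolution)
  nr <- round((extent[4] - extent[3]) / resolution)
  layers <- list()
  for (nm in names(continuous)) {
    sp <- continuous[[nm]]
    v <- if (is.null(sp$variance)) 1 else sp$variance
    z <- smooth_field(nr, nc, resolution, sp$patch_scale)
    z <- (z - mean(z)) / stats::sd(z) * sqrt(v)
    layers[[nm]] <- covariate_layer(z, extent, nm, "continuous")
  }
  for (nm in names(categorical)) {
    sp <- categorical[[nm]]
    p <- sp$proportions
    if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
    if (length(p) != length(sp$levels))
      stop("proportions and levels lengths differ")
    z <- smooth_field(nr, nc, resolution, sp$patch_scale)
    br <- stats::quantile(z, cumsum(p)[-length(p)])
    codes <- matrix(findInterval(z, c(-Inf, br)), nr, nc)
    ref <- if (is.null(sp$ref)) sp$levels[1] else sp$ref
    layers[[nm]] <- covariate_layer(codes, extent, nm, "categorical",
                                    levels = sp$levels, ref = ref)
  }
  if (!length(layers)) stop("no layers requested")
  landscape(layers, boundary = boundary)
}
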