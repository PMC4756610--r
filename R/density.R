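# Real-space electron-density maps: container, CCP4/MRC I/O, normalized
# sampling and the density-fit score.

#' Construct a density map object
#'
#' Values are stored on a 3-D grid over the unit cell (`mx`,`my`,`mz`
#' sampling intervals per cell edge); the stored block starts at grid
#' index `origin` and is periodic when it spans the full cell. The map
#' mean and r.m.s.d. over the stored grid are the normalization constants
#' for all density queries (values are reported in r.m.s.d. units about
#' the mean, the usual map-contouring convention).
#'
#' @param grid 3-D numeric array
#' @param cell a `unit_cell`
#' @param full_size integer(3): sampling intervals per full cell edge
#'   (defaults to `dim(grid)`, i.e. a full-cell periodic map)
#' @param origin integer(3) start offset of the stored block, grid units
#' @return object of class `density_map`
#' @export
density_map <- function(grid, cell, full_size = dim(grid), origin = c(0L, 0L, 0L)) {
  stopifnot(length(dim(grid)) == 3)
  structure(list(grid = grid, cell = cell,
                 full_size = as.integer(full_size), origin = as.integer(origin),
                 periodic = all(dim(grid) == full_size),
                 mean = mean(grid), rmsd = stats::sd(as.numeric(grid))),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density map %dx%dx%d (%s), mean %.4g, rmsd %.4g\n",
              dim(x$grid)[1], dim(x$grid)[2], dim(x$grid)[3],
              if (x$periodic) "periodic" else "bounded", x$mean, x$rmsd))
  invisible(x)
}

# Trilinear interpolation of raw (unnormalized) map values at orthogonal
# positions (n x 3 matrix). Periodic maps wrap; bounded maps error when a
# point falls outside the stored block.
interp_map <- function(map, pos) {
  if (!is.matrix(pos)) pos <- matrix(pos, 1, 3)
  fr <- frac_coords(map$cell, pos)
  g <- sweep(fr %*% diag(map$full_size), 2, map$origin)  # grid coords, 0-based
  d <- dim(map$grid)
  i0 <- floor(g)
  w <- g - i0
  val <- numeric(nrow(pos))
  idx <- function(iax, ax) {
    if (map$periodic) iax %% d[ax] + 1L
    else {
      if (any(iax < 0 | iax > d[ax] - 1L))
        stop("position outside a non-periodic map (axis ", ax, ")")
      iax + 1L
    }
  }
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx) w[, 1] else 1 - w[, 1]) *
          (if (cy) w[, 2] else 1 - w[, 2]) *
          (if (cz) w[, 3] else 1 - w[, 3])
    val <- val + wt * map$grid[cbind(idx(i0[, 1] + cx, 1),
                                     idx(i0[, 2] + cy, 2),
                                     idx(i0[, 3] + cz, 3))]
  }
  val
}

#' Normalized density at atom positions
#'
#' For each position, the map is interpolated at the point itself and at
#' six surrounding points displaced by `r` Angstrom along each Cartesian
#' axis; the seven values are averaged and expressed in map-r.m.s.d.
#' units about the map mean. With `r = 0` this reduces to the plain
#' interpolated normalized value.
#'
#' @param map a `density_map`
#' @param pos 3-vector or n x 3 matrix of orthogonal coordinates, Angstrom
#' @param r averaging radius, Angstrom
#' @return numeric vector of dimensionless density values
#' @export
sample_rho_prime <- function(map, pos, r = 0) {
  if (map$rmsd <= 0) stop("degenerate map: r.m.s.d. of map values is zero")
  if (!is.matrix(pos)) pos <- matrix(pos, 1, 3)
  n <- nrow(pos)
  if (r == 0) {
    v <- interp_map(map, pos)
  } else {
    offs <- rbind(c(0, 0, 0),
                  c(r, 0, 0), c(-r, 0, 0),
                  c(0, r, 0), c(0, -r, 0),
                  c(0, 0, r), c(0, 0, -r))
    big <- pos[rep(seq_len(n), each = 7), , drop = FALSE] +
      offs[rep(1:7, n), , drop = FALSE]
    v <- colMeans(matrix(interp_map(map, big), 7, n))
  }
  (v - map$mean) / map$rmsd
}

#' Density-fit parameters
#' @param r averaging radius, Angstrom
#' @param k_t penalty threshold, map-r.m.s.d. units
#' @param k_f penalty factor (1 = neutral; larger penalizes weak density)
#' @return object of class `density_params`
#' @export
density_params <- function(r = 0, k_t = 0, k_f = 1) {
  stopifnot(r >= 0, k_f >= 0)
  structure(list(r = r, k_t = k_t, k_f = k_f), class = "density_params")
}

#' Density-fit score of a conformation
#'
#' Sums the normalized density over the side-chain atoms. Atoms whose
#' density falls below the penalty threshold `k_t` contribute
#' `k_t - k_f * (k_t - rho')` instead of `rho'`, so `k_f = 1` is neutral
#' and `k_f > 1` preferentially scores conformations lying in continuous
#' density above the threshold. Monotonically non-decreasing in each
#' atom's density.
#'
#' @param map a `density_map`
#' @param coords side-chain atom coordinate matrix (global frame), or a
#'   `conformation` already placed via [place_conformation()]
#' @param params a `density_params`
#' @return the score D(c); 0 for an empty side chain
#' @export
density_score <- function(map, coords, params = density_params()) {
  if (inherits(coords, "conformation")) coords <- coords$coords
  if (is.null(coords) || nrow(coords) == 0) return(0)
  rho <- sample_rho_prime(map, coords, params$r)
  below <- rho < params$k_t
  rho[below] <- params$k_t - params$k_f * (params$k_t - rho[below])
  sum(rho)
}

.electrons <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

model_all_atoms <- function(model) {
  at <- do.call(rbind, lapply(model$residues, function(r) r$atoms))
  rbind(at, model$heteroatoms)
}

#' Synthesize a density map from a model
#'
#' Builds a Gaussian-sum density (one isotropic Gaussian of width `sigma`
#' per atom, scaled by element electron count and occupancy, unit
#' integral times electron count) on a full-cell periodic grid, then
#' optionally adds i.i.d. Gaussian noise with standard deviation
#' `noise_sd` relative to the r.m.s.d. of the noise-free map. Stands in
#' for a 2mFo-DFc-style map in tests and synthetic benchmarks; an
#' effective resolution d is emulated by `sigma` of roughly `0.425 * d`.
#'
#' @param model a `protein_model` with an orthogonal unit cell
#' @param sigma Gaussian width, Angstrom
#' @param spacing target grid spacing, Angstrom
#' @param noise_sd noise level in map-r.m.s.d. units
#' @param seed RNG seed (map is deterministic given the seed)
#' @return a `density_map`
#' @export
synthesize_map <- function(model, sigma = 0.8, spacing = 0.3, noise_sd = 0, seed = 1) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (!length(model$residues) && !nrow(model$heteroatoms)) stop("empty model")
  cell <- model$cell
  if (is.null(cell)) stop("synthesize_map requires a model with a unit cell")
  if (any(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) > 1e-6))
    stop("synthetic maps support orthogonal cells only")
  n <- pmax(4L, as.integer(ceiling(c(cell$a, cell$b, cell$c) / spacing)))
  step <- c(cell$a, cell$b, cell$c) / n
  grid <- array(0, dim = n)
  at <- model_all_atoms(model)
  pref <- 1 / ((2 * pi)^1.5 * sigma^3)
  halfw <- ceiling(4 * sigma / step)
  for (i in seq_len(nrow(at))) {
    z <- .electrons[[at$element[i]]]
    if (is.null(z)) z <- 6
    p <- c(at$x[i], at$y[i], at$z[i])
    amp <- pref * z * at$occupancy[i]
    ctr <- p / step  # grid coords (0-based)
    ax <- lapply(1:3, function(k) {
      ii <- floor(ctr[k] - halfw[k]):ceiling(ctr[k] + halfw[k])
      dx <- (ii - ctr[k]) * step[k]
      list(idx = ii %% n[k] + 1L, g = exp(-dx^2 / (2 * sigma^2)))
    })
    blk <- amp * (ax[[1]]$g %o% ax[[2]]$g %o% ax[[3]]$g)
    grid[ax[[1]]$idx, ax[[2]]$idx, ax[[3]]$idx] <-
      grid[ax[[1]]$idx, ax[[2]]$idx, ax[[3]]$idx] + blk
  }
  if (noise_sd > 0) {
    base_sd <- stats::sd(as.numeric(grid))
    set.seed(seed)
    grid <- grid + stats::rnorm(length(grid), 0, noise_sd * base_sd)
  }
  density_map(grid, cell)
}

# --- CCP4/MRC I/O ----------------------------------------------------------

#' Write a density map in CCP4/MRC format (mode 2)
#' @param map a `density_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(map$grid)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NX NY NZ
  wi(2L)                     # MODE 2 = float32
  wi(map$origin)             # NXSTART..
  wi(map$full_size)          # MX MY MZ
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1L, 2L, 3L))          # MAPC MAPR MAPS
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))
  wi(1L)                     # ISPG
  wi(0L)                     # NSYMBT
  wi(rep(0L, 25))            # EXTRA
  wf(c(0, 0, 0))             # ORIGIN (MRC2014)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(map$grid)))
  wi(0L)                     # NLABL
  writeBin(raw(800), con)    # labels
  writeBin(as.numeric(aperm(map$grid, c(1, 2, 3))), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC density map
#'
#' Supports modes 2 (float32) and 0 (int8); any axis order is permuted to
#' the canonical x,y,z layout. The normalization constants (mean and
#' r.m.s.d.) are recomputed over the stored grid.
#'
#' @param path map file path
#' @return a `density_map`
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  nstart <- ri(3)
  mxyz <- ri(3)
  cella <- rf(6)
  mapcrs <- ri(3)
  invisible(rf(3)); invisible(ri(2)); invisible(ri(25)); invisible(rf(3))
  magic <- rawToChar(readBin(con, "raw", 4))
  invisible(readBin(con, "raw", 4))
  invisible(rf(1)); invisible(ri(1)); invisible(readBin(con, "raw", 800))
  if (!(mode %in% c(0L, 2L))) stop("unsupported MRC mode: ", mode)
  if (!all(sort(mapcrs) == 1:3)) stop("unsupported axis-order codes: ",
                                      paste(mapcrs, collapse = ","))
  nvox <- prod(nxyz)
  vals <- if (mode == 2L) readBin(con, "numeric", nvox, size = 4, endian = "little")
          else as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE))
  if (length(vals) < nvox) stop("truncated map file: ", path)
  arr <- array(vals, dim = nxyz)
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  nstart <- nstart[perm]
  mxyz_xyz <- mxyz  # MX MY MZ are already per crystal axis
  cell <- unit_cell(cella[1], cella[2], cella[3], cella[4], cella[5], cella[6])
  density_map(arr, cell, full_size = mxyz_xyz, origin = nstart)
}
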