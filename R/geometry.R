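#' Build the structured tissue grid
#'
#' Discretises the reference tissue geometry: a cuboid muscle of size
#' `L x W x H` cm with fibres along the first axis, optionally covered by a
#' subcutaneous fat slab of thickness `d_fat` on the face with the largest
#' surface-normal coordinate. Axis semantics everywhere in the package:
#' axis 1 = `x_l` (fibre direction, "l parallel"), axis 2 = `x_t` (tangential,
#' across the fibres), axis 3 = `x_n` (surface normal).
#'
#' The grid is vertex-centred and regular. Only muscle and body (fat) nodes
#' are stored explicitly; the surrounding air enters the magnetic stage as a
#' padded box (see [magnetic_grid()]) whose width is `air_padding` cm on every
#' side, approximating the decay of the vector potential at infinity.
#'
#' @param L,W,H muscle edge lengths in cm (fibre, cross-fibre, normal axes).
#' @param d_fat fat-layer thickness in cm (0 for an isolated muscle).
#' @param spacing grid spacing in cm; must divide `L`, `W`, `H` and `d_fat`.
#' @param air_padding width of the air box around the tissue for the
#'   magnetic problem, cm. The default of 4 cm (about one body diagonal of
#'   the reference muscle) keeps the truncation error of the far-field
#'   boundary condition at surface sensors in the low percent range.
#' @return An object of class `sim_grid`.
#' @export
#' @examples
#' g <- build_grid(spacing = 0.1)
#' dim(g$region)      # 41 x 16 x 21
build_grid <- function(L = 4, W = 1.5, H = 2, d_fat = 0, spacing = 0.1,
                       air_padding = 4) {
  if (!is.numeric(spacing) || length(spacing) != 1 || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number (cm)")
  if (any(c(L, W, H) <= 0)) stop("muscle dimensions must be positive")
  if (d_fat < 0) stop("`d_fat` must be non-negative")
  if (air_padding <= 0) stop("`air_padding` must be positive")
  h <- spacing
  ncell <- function(len, what) {
    n <- round(len / h)
    if (abs(n - len / h) > 1e-6)
      stop(sprintf("spacing %g cm does not divide the %s extent %g cm",
                   h, what, len))
    n
  }
  nx <- ncell(L, "fibre-axis") + 1L
  ny <- ncell(W, "cross-fibre") + 1L
  nz_mus <- ncell(H, "normal-axis") + 1L
  nfat <- if (d_fat > 0) ncell(d_fat, "fat-layer") else 0L
  nz <- nz_mus + nfat
  region <- array(1L, dim = c(nx, ny, nz))         # 1 = MUSCLE
  if (nfat > 0) region[, , (nz_mus + 1L):nz] <- 2L  # 2 = BODY (fat)
  g <- structure(list(
    L = L, W = W, H = H, d_fat = d_fat, spacing = h,
    air_padding = air_padding,
    nx = nx, ny = ny, nz = nz, nz_mus = nz_mus,
    x = (seq_len(nx) - 1) * h,
    y = (seq_len(ny) - 1) * h,
    z = (seq_len(nz) - 1) * h,
    region = region,
    muscle_nodes = which(region == 1L),
    body_nodes = which(region == 2L),
    surface_iz = nz), class = "sim_grid")
  g
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> muscle %g x %g x %g cm, fat %g cm, h = %g cm\n",
              x$L, x$W, x$H, x$d_fat, x$spacing))
  cat(sprintf("  tissue nodes: %d x %d x %d (%d muscle, %d body)\n",
              x$nx, x$ny, x$nz, length(x$muscle_nodes),
              length(x$body_nodes)))
  invisible(x)
}

# linear index into the tissue array
grid_index <- function(grid, ix, iy, iz) {
  ix + grid$nx * ((iy - 1L) + grid$ny * (iz - 1L))
}

# snap a physical coordinate to the nearest grid line (1-based index),
# ties rounded up
snap_index <- function(coord, h, n) {
  i <- as.integer(floor(coord / h + 0.5)) + 1L
  min(max(i, 1L), n)
}

#' Region labels of the (optionally padded) grid
#'
#' @param grid a `sim_grid`.
#' @param include_air if `TRUE`, return labels over the padded magnetic box
#'   with `"AIR"` outside the tissue.
#' @return A character array (`"MUSCLE"`, `"BODY"`, `"AIR"`).
#' @export
grid_regions <- function(grid, include_air = FALSE) {
  lab <- c("MUSCLE", "BODY")[grid$region]
  dim(lab) <- dim(grid$region)
  if (!include_air) return(lab)
  mg <- magnetic_grid(grid)
  full <- array("AIR", dim = mg$dims)
  full[mg$offset[1] + seq_len(grid$nx),
       mg$offset[2] + seq_len(grid$ny),
       mg$offset[3] + seq_len(grid$nz)] <- lab
  full
}

#' Build the motor-unit territories and stimulation sites
#'
#' The reference experiments use two motor units. The recruited unit (MU1)
#' is the single fibre-parallel line of nodes at cross-sectional position
#' `x_t = 0.75` cm, `x_n = H - depth` cm; the passive unit (MU2) owns every
#' other muscle node. Both carry a motor-unit density factor `f_r = 1` on
#' their territory. MU1's neuromuscular junction (stimulus site) is the node
#' of that line at `x_l = 1` cm. Coordinates snap to the nearest grid line,
#' so on coarse grids the realised cross-section can be off by up to half a
#' spacing.
#'
#' @param grid a `sim_grid`.
#' @param depth activation depth `d` in cm, measured from the muscle surface
#'   (`x_n = H`); must satisfy `0 < depth < H`.
#' @param t_line cross-fibre coordinate of the active fibre line, cm.
#' @param nmj_x fibre-axis coordinate of the neuromuscular junction, cm.
#' @return An object of class `motor_unit_map` with territories (linear node
#'   indices into the tissue array), per-unit density factors and stimulus
#'   nodes.
#' @export
build_motor_unit_map <- function(grid, depth, t_line = 0.75, nmj_x = 1.0) {
  stopifnot(inherits(grid, "sim_grid"))
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0 ||
      depth >= grid$H)
    stop("`depth` must lie strictly inside the muscle: 0 < depth < H")
  h <- grid$spacing
  iy <- snap_index(t_line, h, grid$ny)
  iz <- snap_index(grid$H - depth, h, grid$nz_mus)
  ix_nmj <- snap_index(nmj_x, h, grid$nx)
  terr1 <- grid_index(grid, seq_len(grid$nx), iy, iz)
  terr2 <- setdiff(grid$muscle_nodes, terr1)
  structure(list(
    N = 2L,
    territories = list(terr1, terr2),
    f_r = list(rep(1, length(terr1)), rep(1, length(terr2))),
    nmj_nodes = list(grid_index(grid, ix_nmj, iy, iz), integer(0)),
    recruited = 1L,
    depth = depth,
    line_y = grid$y[iy], line_z = grid$z[iz],
    line_iy = iy, line_iz = iz), class = "motor_unit_map")
}

#' @export
print.motor_unit_map <- function(x, ...) {
  cat(sprintf(paste0("<motor_unit_map> %d units; active line at x_t = %g, ",
                     "x_n = %g cm (depth %g cm)\n"),
              x$N, x$line_y, x$line_z, x$depth))
  invisible(x)
}

#' Uniform fibre direction field
#'
#' @param grid a `sim_grid`.
#' @param direction a 3-vector, normalised internally.
#' @return A matrix with one unit row vector per muscle node.
#' @export
fibre_field <- function(grid, direction = c(1, 0, 0)) {
  stopifnot(inherits(grid, "sim_grid"), length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("fibre direction must be non-zero")
  matrix(direction / nrm, nrow = length(grid$muscle_nodes), ncol = 3,
         byrow = TRUE)
}

#' Build the per-node conductivity tensors
#'
#' Intracellular domains conduct only along the fibre direction `f`:
#' `sigma_i = sigma_i_l f (x) f` (rank one). The extracellular tensor is
#' transversally isotropic: `sigma_e = sigma_e_l f (x) f + sigma_e_t (I - f
#' (x) f)`. Body (fat) nodes are isotropic with `sigma_b`.
#'
#' @param grid a `sim_grid`.
#' @param fibres per-muscle-node fibre directions, as from [fibre_field()].
#' @param params a [tissue_parameters()] list.
#' @return An object of class `conductivity_model` with per-node symmetric
#'   tensors stored as n x 6 matrices (columns xx, yy, zz, xy, xz, yz).
#' @export
build_conductivities <- function(grid, fibres = fibre_field(grid),
                                 params = tissue_parameters()) {
  stopifnot(inherits(grid, "sim_grid"), inherits(params, "tissue_parameters"))
  nmus <- length(grid$muscle_nodes)
  if (!is.matrix(fibres) || nrow(fibres) != nmus || ncol(fibres) != 3)
    stop("`fibres` must be an n_muscle x 3 matrix")
  nrm <- sqrt(rowSums(fibres^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("fibre vectors must be unit length")
  ff <- cbind(fibres[, 1]^2, fibres[, 2]^2, fibres[, 3]^2,
              fibres[, 1] * fibres[, 2], fibres[, 1] * fibres[, 3],
              fibres[, 2] * fibres[, 3])
  eye <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = nmus), nmus, 6)
  sigma_i <- params$sigma_i_l * ff + params$sigma_i_t * (eye - ff)
  sigma_e <- params$sigma_e_l * ff + params$sigma_e_t * (eye - ff)
  structure(list(sigma_e = sigma_e, sigma_i = sigma_i,
                 sigma_b = params$sigma_b, fibres = fibres, params = params),
            class = "conductivity_model")
}
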