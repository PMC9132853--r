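#' Padded grid for the magnetostatic problem
#'
#' The vector-potential Poisson problem is posed on the tissue box extended
#' by `air_padding` cm of air on every side, with a zero-Dirichlet condition
#' on the (ghost) outer boundary approximating the decay of the field at
#' infinity. Magnetic permeability is uniform, so the interface conditions
#' (continuity of A and of its normal gradient) are satisfied by
#' construction on the single padded grid.
#'
#' @param grid a `sim_grid`.
#' @return A list with padded `dims`, per-axis `offset` of the tissue block,
#'   the spacing `h` (cm) and `h_m` (m), and `tissue_idx`, the linear
#'   indices of the tissue nodes inside the padded array.
#' @export
magnetic_grid <- function(grid) {
  h <- grid$spacing
  pad <- as.integer(round(grid$air_padding / h))
  if (pad < 1) stop("air padding must cover at least one grid cell")
  dims <- c(grid$nx, grid$ny, grid$nz) + 2L * pad
  n_t <- grid$nx * grid$ny * grid$nz
  ai <- arrayInd(seq_len(n_t), c(grid$nx, grid$ny, grid$nz))
  tissue_idx <- (ai[, 1] + pad) +
    dims[1] * ((ai[, 2] + pad - 1L) + dims[2] * (ai[, 3] + pad - 1L))
  list(dims = dims, offset = rep(pad, 3), h = h, h_m = h / 100,
       tissue_idx = tissue_idx)
}

#' Assemble the scalar Poisson operator of the vector-potential problem
#'
#' The negative 7-point Laplacian over the padded box with zero-Dirichlet
#' values on the ghost layer outside the box, applied componentwise to the
#' vector potential. Mainly used on small grids and in tests; large solves
#' go through the spectrally equivalent fast sine-transform path
#' ([poisson_solve()]), which solves the identical discrete system.
#'
#' @param grid a `sim_grid`, or an integer vector of box dimensions.
#' @param spacing grid spacing (same length unit as the right-hand side);
#'   ignored when `grid` is a `sim_grid`.
#' @return A sparse symmetric positive-definite matrix.
#' @export
assemble_poisson_operator <- function(grid, spacing = NULL) {
  if (inherits(grid, "sim_grid")) {
    mg <- magnetic_grid(grid)
    dims <- mg$dims
    spacing <- mg$h_m
  } else {
    dims <- as.integer(grid)
    if (is.null(spacing)) stop("`spacing` required for raw dimensions")
  }
  n <- prod(dims)
  strides <- cumprod(c(1L, dims[-length(dims)]))
  ii <- integer(0); jj <- integer(0)
  pos <- arrayInd(seq_len(n), dims)
  for (ax in seq_along(dims)) {
    if (dims[ax] < 2) next
    a <- which(pos[, ax] < dims[ax])
    b <- a + strides[ax]
    ii <- c(ii, a, b); jj <- c(jj, b, a)
  }
  K <- Matrix::Diagonal(n, 2 * sum(dims > 1) / spacing^2)
  if (length(ii))
    K <- K + Matrix::sparseMatrix(i = ii, j = jj, x = -1 / spacing^2,
                                  dims = c(n, n))
  K
}

# ---- fast sine-transform Poisson solver -----------------------------------

# unnormalised DST-I of the columns of a matrix via odd-extension FFT
dst_cols <- function(x) {
  n <- nrow(x)
  ext <- matrix(0, 2 * (n + 1), ncol(x))
  ext[2:(n + 1), ] <- x
  ext[(n + 3):(2 * n + 2), ] <- -x[n:1, , drop = FALSE]
  -Im(stats::mvfft(ext)[2:(n + 1), , drop = FALSE]) / 2
}

dst3 <- function(a) {
  d <- dim(a)
  a <- array(dst_cols(matrix(a, d[1], d[2] * d[3])), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(dst_cols(matrix(a, d[2], d[1] * d[3])), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))
  a <- array(dst_cols(matrix(a, d[3], d[2] * d[1])), c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}

#' Solve the Dirichlet Poisson problem on a box
#'
#' Solves `-Laplacian(u) = f` (7-point stencil, zero Dirichlet just outside
#' the box) by diagonalising the operator with the type-I discrete sine
#' transform. Exactly equivalent to solving with
#' [assemble_poisson_operator()]; cost `O(n log n)`.
#'
#' @param f right-hand side, a 3-d array.
#' @param spacing grid spacing (length unit of choice).
#' @return The solution array `u`.
#' @export
poisson_solve <- function(f, spacing) {
  d <- dim(f)
  lam <- function(n) (2 - 2 * cos(pi * seq_len(n) / (n + 1))) / spacing^2
  L <- outer(outer(lam(d[1]), lam(d[2]), `+`), lam(d[3]), `+`)
  dst3(dst3(f) / L) * prod(2 / (d + 1))
}

# ---- sources ---------------------------------------------------------------

DOMAIN_SOURCES <- c("extracellular", "intracellular_active",
                    "intracellular_passive", "body")

# tissue-node current density (n_tissue x 3, uA/cm^2) for a subset of
# domain sources; `J` as returned by current_densities()
tissue_currents <- function(grid, mus, J, sources = DOMAIN_SOURCES) {
  bad <- setdiff(sources, DOMAIN_SOURCES)
  if (length(bad)) stop("unknown source domain(s): ",
                        paste(bad, collapse = ", "))
  n <- grid$nx * grid$ny * grid$nz
  jt <- matrix(0, n, 3)
  if ("extracellular" %in% sources)
    jt[grid$muscle_nodes, ] <- jt[grid$muscle_nodes, ] + J$j_e
  active <- mus$recruited
  for (k in seq_len(mus$N)) {
    want <- if (k == active) "intracellular_active" else "intracellular_passive"
    if (want %in% sources) {
      terr <- mus$territories[[k]]
      jt[terr, ] <- jt[terr, ] + J$j_i[[k]]
    }
  }
  if ("body" %in% sources && !is.null(J$j_b))
    jt[grid$body_nodes, ] <- jt[grid$body_nodes, ] + J$j_b
  jt
}

#' Solve for the magnetic vector potential of selected current sources
#'
#' Three independent Poisson solves (one per component) over the padded air
#' box: `-Laplacian(A_c) = mu_0 j_c`, with the domain-wise current densities
#' placed at the tissue nodes (air is source free). The currents of the
#' individual domains add linearly, so any subset of sources can be solved
#' to obtain its contribution to the field.
#'
#' @param grid a `sim_grid`.
#' @param mus a `motor_unit_map`.
#' @param J current densities from [current_densities()] (uA/cm^2).
#' @param sources character subset of `"extracellular"`,
#'   `"intracellular_active"`, `"intracellular_passive"`, `"body"`.
#' @param mu_0 vacuum permeability, T m/A.
#' @return A list with the padded-grid arrays `A` (list of 3 components,
#'   T m), the `magnetic_grid` metadata, and `h_m`.
#' @export
solve_vector_potential <- function(grid, mus, J, sources = DOMAIN_SOURCES,
                                   mu_0 = 4e-7 * pi) {
  mg <- magnetic_grid(grid)
  jt <- tissue_currents(grid, mus, J, sources) * 1e-2  # uA/cm^2 -> A/m^2
  A <- vector("list", 3)
  for (c in 1:3) {
    rhs <- array(0, mg$dims)
    rhs[mg$tissue_idx] <- mu_0 * jt[, c]
    A[[c]] <- poisson_solve(rhs, mg$h_m)
  }
  list(A = A, mgrid = mg, h_m = mg$h_m)
}

#' Discrete curl of a vector field
#'
#' Centred differences in the interior, one-sided at the box boundary.
#' Component order follows the grid axes: fibre-aligned, tangential
#' cross-fibre, surface normal.
#'
#' @param A list of three 3-d arrays (the field components).
#' @param spacing grid spacing (consistent length unit).
#' @return A list of three 3-d arrays, `curl(A)`.
#' @export
curl_field <- function(A, spacing) {
  list(grad_axis(A[[3]], 2, spacing) - grad_axis(A[[2]], 3, spacing),
       grad_axis(A[[1]], 3, spacing) - grad_axis(A[[3]], 1, spacing),
       grad_axis(A[[2]], 1, spacing) - grad_axis(A[[1]], 2, spacing))
}

#' Discrete divergence of a vector field
#'
#' Same stencils as [curl_field()]; useful for gauge and solenoidality
#' checks.
#'
#' @inheritParams curl_field
#' @return A 3-d array, `div(A)`.
#' @export
div_field <- function(A, spacing) {
  grad_axis(A[[1]], 1, spacing) + grad_axis(A[[2]], 2, spacing) +
    grad_axis(A[[3]], 3, spacing)
}

#' Per-domain contributions to the magnetic field
#'
#' Solves the vector-potential problem separately for each source domain
#' and returns the resulting B fields together with the total. By linearity
#' the contributions sum to the total field (to rounding).
#'
#' @param grid a `sim_grid`.
#' @param mus a `motor_unit_map`.
#' @param J current densities from [current_densities()].
#' @param sources domains to separate.
#' @param mu_0 vacuum permeability.
#' @return A named list of B fields (each a list of 3 padded arrays, tesla),
#'   with an additional element `total`.
#' @export
domain_contributions <- function(grid, mus, J, sources = DOMAIN_SOURCES,
                                 mu_0 = 4e-7 * pi) {
  out <- vector("list", length(sources) + 1)
  names(out) <- c(sources, "total")
  for (s in sources) {
    sol <- solve_vector_potential(grid, mus, J, s, mu_0)
    out[[s]] <- curl_field(sol$A, sol$h_m)
  }
  sol <- solve_vector_potential(grid, mus, J, sources, mu_0)
  out$total <- curl_field(sol$A, sol$h_m)
  out
}

# ---- sensor adjoints -------------------------------------------------------

# centred-difference picking vector for d/d(axis) at padded node p, solved
# through the Laplacian: w = L^{-1} d. Returned restricted to tissue nodes.
sensor_adjoint <- function(mg, p_idx3, axis) {
  d <- array(0, mg$dims)
  up <- p_idx3; dn <- p_idx3
  up[axis] <- up[axis] + 1L
  dn[axis] <- dn[axis] - 1L
  if (dn[axis] < 1L || up[axis] > mg$dims[axis])
    stop("sensor too close to the air-box boundary")
  d[up[1], up[2], up[3]] <- 1 / (2 * mg$h_m)
  d[dn[1], dn[2], dn[3]] <- -1 / (2 * mg$h_m)
  w <- poisson_solve(d, mg$h_m)
  w[mg$tissue_idx]
}

#' Reciprocity weights for virtual magnetic sensors
#'
#' For each sensor and each needed component of A, solves one Poisson
#' problem `L w = d` where `d` is the centred-difference row of the curl at
#' the sensor node. The magnetic field at the sensor is then the dot
#' product of `w` with the (SI) tissue current densities, which makes the
#' per-time-step and per-domain evaluation of sensor MMG series cheap and
#' the domain decomposition exactly additive. Algebraically identical to
#' the full-field solve followed by [curl_field()].
#'
#' @param grid a `sim_grid`.
#' @param positions matrix (n x 2) of sensor coordinates `(x_l, x_t)` in cm
#'   on the recording surface, or n x 3 including the normal coordinate.
#' @param components which B components each sensor records: subset of
#'   `"B_l"`, `"B_t"`, `"B_n"` (fibre-aligned, tangential cross-fibre,
#'   surface normal).
#' @param cache optional environment reusing adjoint solves across calls
#'   (keyed by geometry, sensor node and axis).
#' @return An object of class `magnetic_sensors`.
#' @export
magnetic_sensor_weights <- function(grid, positions,
                                    components = c("B_l", "B_t", "B_n"),
                                    cache = NULL) {
  stopifnot(all(components %in% c("B_l", "B_t", "B_n")))
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  mg <- magnetic_grid(grid)
  # component -> axes of A entering its curl row
  need_axes <- list(B_l = c(2L, 3L), B_t = c(3L, 1L), B_n = c(1L, 2L))
  axes <- sort(unique(unlist(need_axes[components])))
  sensors <- vector("list", nrow(positions))
  for (s in seq_len(nrow(positions))) {
    ix <- snap_index(positions[s, 1], mg$h, grid$nx) + mg$offset[1]
    iy <- snap_index(positions[s, 2], mg$h, grid$ny) + mg$offset[2]
    iz <- if (ncol(positions) >= 3)
      snap_index(positions[s, 3], mg$h, grid$nz) + mg$offset[3]
    else grid$surface_iz + mg$offset[3]
    p3 <- c(ix, iy, iz)
    W <- vector("list", 3)
    for (ax in axes) {
      key <- sprintf("w_%s_%d_%d_%d_%d",
                     paste(mg$dims, collapse = "x"), ix, iy, iz, ax)
      w <- if (!is.null(cache)) cache[[key]] else NULL
      if (is.null(w)) {
        w <- sensor_adjoint(mg, p3, ax)
        if (!is.null(cache)) cache[[key]] <- w
      }
      W[[ax]] <- w
    }
    sensors[[s]] <- list(node = p3, W = W)
  }
  structure(list(grid_dims = mg$dims, h_m = mg$h_m, sensors = sensors,
                 components = components), class = "magnetic_sensors")
}

# evaluate B (pT) at all sensors for tissue currents jt (n_tissue x 3,
# uA/cm^2); returns matrix n_sensors x length(components)
sensor_B <- function(weights, jt, mu_0 = 4e-7 * pi) {
  comps <- weights$components
  jt <- jt * 1e-2  # -> A/m^2
  out <- matrix(0, length(weights$sensors), length(comps),
                dimnames = list(NULL, comps))
  for (s in seq_along(weights$sensors)) {
    W <- weights$sensors[[s]]$W
    for (ci in seq_along(comps)) {
      v <- switch(comps[ci],
        B_l = sum(W[[2]] * jt[, 3]) - sum(W[[3]] * jt[, 2]),
        B_t = sum(W[[3]] * jt[, 1]) - sum(W[[1]] * jt[, 3]),
        B_n = sum(W[[1]] * jt[, 2]) - sum(W[[2]] * jt[, 1]))
      out[s, ci] <- mu_0 * v * 1e12  # T -> pT
    }
  }
  out
}
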