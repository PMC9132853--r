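#' Assemble the coupled extracellular / body potential operator
#'
#' Builds the symmetric finite-difference operator of the elliptic problem
#' for the combined potential (extracellular potential inside the muscle,
#' body potential in the fat layer, one shared unknown on the interface):
#' `-div[(sigma_e + sum_k f_r^k sigma_i^k) grad phi] = sum_k f_r^k
#' div[sigma_i^k grad V_m^k]` with zero-Neumann outer boundaries. Face
#' conductivities are harmonic means of the node values, which yields a
#' conservative scheme and handles the muscle-fat interface. The pure
#' Neumann operator has a constant nullspace; a grounding node (an outer
#' corner, by default the one farthest from the neuromuscular junction) is
#' pinned to 0 mV.
#'
#' Fibre directions must be aligned with a grid axis (the assembly uses the
#' diagonal of the conductivity tensors).
#'
#' @param grid a `sim_grid`.
#' @param cond a `conductivity_model`.
#' @param mus a `motor_unit_map`.
#' @param ground optional linear node index to pin instead of the default.
#' @return An object of class `electric_operator` containing the pinned
#'   operator `K` and its Cholesky factorisation, the raw (un-pinned)
#'   operator `K_raw`, the per-unit along-fibre stiffness matrices and
#'   index metadata.
#' @export
assemble_elliptic_operator <- function(grid, cond, mus, ground = NULL) {
  stopifnot(inherits(grid, "sim_grid"), inherits(cond, "conductivity_model"),
            inherits(mus, "motor_unit_map"))
  if (max(abs(cond$sigma_e[, 4:6])) > 1e-10 ||
      max(abs(cond$sigma_i[, 4:6])) > 1e-10)
    stop("fibre directions must be aligned with a grid axis")
  n <- grid$nx * grid$ny * grid$nz
  h <- grid$spacing
  # per-node, per-axis effective conductivity of the phi operator
  eff <- matrix(cond$sigma_b, n, 3)
  eff[grid$muscle_nodes, ] <- cond$sigma_e[, 1:3]
  for (k in seq_len(mus$N)) {
    terr <- mus$territories[[k]]
    eff[terr, ] <- eff[terr, ] + mus$f_r[[k]] * cond$sigma_i[terr, 1:3]
  }
  K_raw <- fd_divgrad_operator(c(grid$nx, grid$ny, grid$nz), h, eff)
  if (min(Matrix::diag(K_raw)) <= 0)
    stop("conductive region is disconnected: node without conductive face")
  if (is.null(ground)) ground <- default_ground_node(grid, mus)
  K <- pin_node(K_raw, ground)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE, perm = TRUE)

  # per-unit along-fibre (1-D) stiffness on the territory, Neumann ends
  S_list <- vector("list", mus$N)
  lines_list <- vector("list", mus$N)
  stim_local <- vector("list", mus$N)
  for (k in seq_len(mus$N)) {
    terr <- mus$territories[[k]]
    li <- fibre_lines(grid, terr)
    S_list[[k]] <- line_stiffness(length(terr), li,
                                  cond$sigma_i[terr, 1], h)
    lines_list[[k]] <- li
    stim_local[[k]] <- match(mus$nmj_nodes[[k]], terr)
  }
  structure(list(
    grid = grid, cond = cond, mus = mus,
    n = n, K_raw = K_raw, K = K, ground = ground, chol = ch,
    S_list = S_list, lines = lines_list, stim_local = stim_local,
    diff_cache = new.env(parent = emptyenv())),
    class = "electric_operator")
}

# symmetric -div(c grad) operator on a box, zero-Neumann, harmonic face means
fd_divgrad_operator <- function(dims, h, eff) {
  n <- prod(dims)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  idx <- array(seq_len(n), dims)
  for (ax in 1:3) {
    if (dims[ax] < 2) next
    a <- as.vector(switch(ax,
                          idx[-dims[1], , , drop = FALSE],
                          idx[, -dims[2], , drop = FALSE],
                          idx[, , -dims[3], drop = FALSE]))
    b <- a + strides[ax]
    c1 <- eff[a, ax]; c2 <- eff[b, ax]
    w <- ifelse(c1 + c2 > 0, 2 * c1 * c2 / (c1 + c2), 0) / h^2
    keep <- w > 0
    a <- a[keep]; b <- b[keep]; w <- w[keep]
    ii <- c(ii, a, b, a, b)
    jj <- c(jj, a, b, b, a)
    xx <- c(xx, w, w, -w, -w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

default_ground_node <- function(grid, mus) {
  corners <- expand.grid(ix = c(1L, grid$nx), iy = c(1L, grid$ny),
                         iz = c(1L, grid$nz))
  nmj <- mus$nmj_nodes[[mus$recruited]]
  ai <- arrayInd(nmj, dim(grid$region))
  p0 <- c(grid$x[ai[1]], grid$y[ai[2]], grid$z[ai[3]])
  d2 <- (grid$x[corners$ix] - p0[1])^2 + (grid$y[corners$iy] - p0[2])^2 +
    (grid$z[corners$iz] - p0[3])^2
  i <- which.max(d2)
  grid_index(grid, corners$ix[i], corners$iy[i], corners$iz[i])
}

# pin one unknown to zero, keeping symmetry
pin_node <- function(K, g) {
  K[g, ] <- 0
  K[, g] <- 0
  K[g, g] <- 1
  Matrix::drop0(K)
}

# split a sorted territory index set into runs of fibre-parallel neighbours;
# returns run starts/lengths (territory-local indexing)
fibre_lines <- function(grid, terr) {
  ai <- arrayInd(terr, dim(grid$region))
  new_line <- c(TRUE, diff(terr) != 1L | diff(ai[, 2]) != 0L |
                  diff(ai[, 3]) != 0L)
  starts <- which(new_line)
  lengths <- diff(c(starts, length(terr) + 1L))
  list(starts = starts, lengths = lengths)
}

# 1-D stiffness -d/dx sigma d/dx along each fibre line, Neumann ends
line_stiffness <- function(n, li, sig_xx, h) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_along(li$starts)) {
    s <- li$starts[r]; len <- li$lengths[r]
    if (len < 2) next
    a <- s:(s + len - 2L); b <- a + 1L
    c1 <- sig_xx[a]; c2 <- sig_xx[b]
    w <- ifelse(c1 + c2 > 0, 2 * c1 * c2 / (c1 + c2), 0) / h^2
    ii <- c(ii, a, b, a, b); jj <- c(jj, a, b, b, a)
    xx <- c(xx, w, w, -w, -w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Solve the elliptic step for the extracellular / body potential
#'
#' Given the current transmembrane potentials, solves the pinned system
#' `K phi = -sum_k f_r^k S_k V_m^k` (scattered to the tissue grid) by the
#' cached sparse Cholesky factorisation.
#'
#' @param op an `electric_operator`.
#' @param V_list per-unit transmembrane potential vectors on the unit
#'   territories, mV.
#' @return The combined potential vector (mV) over all tissue nodes
#'   (extracellular in muscle, body potential in fat).
#' @export
solve_extracellular <- function(op, V_list) {
  rhs <- numeric(op$n)
  for (k in seq_along(V_list)) {
    sk <- op$mus$f_r[[k]] * as.numeric(op$S_list[[k]] %*% V_list[[k]])
    rhs[op$mus$territories[[k]]] <- rhs[op$mus$territories[[k]]] - sk
  }
  rhs[op$ground] <- 0
  phi <- as.numeric(Matrix::solve(op$chol, rhs))
  if (any(!is.finite(phi))) stop("extracellular solve produced non-finite values")
  phi
}

#' Implicit along-fibre diffusion of the transmembrane potentials
#'
#' Backward-Euler update of `dV_m/dt = 1/(C_m A_m) div[sigma_i grad(V_m +
#' phi_e)]` on each unit territory. Because the intracellular conductivity
#' is rank-one along the fibre direction this is a 1-D diffusion along each
#' fibre line, with zero-Neumann line ends (no intracellular current leaves
#' a fibre). The factorisation of `I + dt/(C_m A_m) S_k` is cached per time
#' step size.
#'
#' @param op an `electric_operator`.
#' @param V_list per-unit transmembrane potentials, mV.
#' @param phi combined potential from [solve_extracellular()], mV.
#' @param dt time step, ms.
#' @return Updated `V_list`.
#' @export
diffuse_vm <- function(op, V_list, phi, dt) {
  p <- op$cond$params
  a <- dt / (p$C_m * p$A_m)
  key <- sprintf("a_%.12g", a)
  fac <- op$diff_cache[[key]]
  if (is.null(fac)) {
    fac <- lapply(op$S_list, function(S)
      Matrix::Cholesky(Matrix::forceSymmetric(
        Matrix::Diagonal(nrow(S)) + a * S), LDL = FALSE, perm = TRUE))
    op$diff_cache[[key]] <- fac
  }
  out <- vector("list", length(V_list))
  for (k in seq_along(V_list)) {
    rhs <- V_list[[k]] -
      a * as.numeric(op$S_list[[k]] %*% phi[op$mus$territories[[k]]])
    out[[k]] <- as.numeric(Matrix::solve(fac[[k]], rhs))
  }
  out
}

#' Initial (resting) simulation state
#'
#' @param op an `electric_operator`.
#' @param membrane an [hh_parameters()] list.
#' @return A list with time `t`, per-unit `V` and gate fields, and the
#'   potential `phi` (all at the resting equilibrium).
#' @export
em_initial_state <- function(op, membrane = hh_parameters()) {
  rest <- hh_rest_state(membrane)
  V <- lapply(op$mus$territories, function(t) rep(rest$V, length(t)))
  gates <- lapply(op$mus$territories, function(t)
    list(m = rep(rest$m, length(t)), h = rep(rest$h, length(t)),
         n = rep(rest$n, length(t))))
  list(t = 0, V = V, gates = gates, phi = numeric(op$n))
}

#' Advance the coupled system by one PDE time step
#'
#' Godunov splitting: (i) `n_sub` membrane reaction substeps (Rush-Larsen /
#' forward Euler), (ii) elliptic solve for the extracellular and body
#' potential, (iii) implicit along-fibre diffusion of the transmembrane
#' potentials. Deterministic: identical states and arguments give identical
#' results.
#'
#' @param op an `electric_operator`.
#' @param state a state list as from [em_initial_state()].
#' @param dt PDE time step, ms (default 0.1 ms, matching the 10 kHz output
#'   sampling).
#' @param dt_ode membrane substep, ms.
#' @param stim a [stimulus_protocol()] or `NULL`; applied at the
#'   neuromuscular-junction nodes of the recruited unit.
#' @param membrane an [hh_parameters()] list.
#' @return The state at `t + dt`.
#' @export
em_step <- function(op, state, dt = 0.1, dt_ode = 0.01, stim = NULL,
                    membrane = hh_parameters()) {
  n_sub <- as.integer(round(dt / dt_ode))
  stopifnot(abs(n_sub * dt_ode - dt) < 1e-9, n_sub >= 1)
  for (k in seq_len(op$mus$N)) {
    sn <- op$stim_local[[k]]
    amps <- if (length(sn))
      stimulus_amplitudes(stim, state$t, dt, n_sub) else 0
    r <- integrate_reaction(state$V[[k]], state$gates[[k]], amps,
                            dt_ode, n_sub, stim_nodes = sn,
                            params = membrane)
    state$V[[k]] <- r$V
    state$gates[[k]] <- r$gates
  }
  state$phi <- solve_extracellular(op, state$V)
  state$V <- diffuse_vm(op, state$V, state$phi, dt)
  state$t <- state$t + dt
  state
}

#' Domain-wise current densities
#'
#' Ohm's law applied to the solved potentials with centred-difference
#' gradients (one-sided at region boundaries): extracellular
#' `j_e = -sigma_e grad phi_e` on muscle nodes, intracellular
#' `j_i^k = -sigma_i^k grad(V_m^k + phi_e)` on each unit territory (purely
#' along-fibre; the transverse intracellular conductivity is zero), and body
#' `j_b = -sigma_b grad phi_b` on fat nodes.
#'
#' @param op an `electric_operator`.
#' @param phi combined potential vector, mV.
#' @param V_list per-unit transmembrane potentials, mV.
#' @return A list with `j_e` (n_muscle x 3), `j_i` (per unit, n_territory x
#'   3, already weighted by `f_r`), and `j_b` (n_body x 3), in uA/cm^2.
#' @export
current_densities <- function(op, phi, V_list) {
  g <- op$grid
  h <- g$spacing
  dm <- c(g$nx, g$ny, g$nz_mus)
  phi_m <- array(phi[seq_len(prod(dm))], dm)
  j_e <- -cond_times_grad(phi_m, op$cond$sigma_e[, 1:3], h)
  j_b <- NULL
  if (g$nz > g$nz_mus) {
    # slab including the interface layer so the first fat layer gets a
    # centred difference; only body-labelled nodes are reported
    db <- c(g$nx, g$ny, g$nz - g$nz_mus + 1L)
    phi_b <- array(phi[(prod(dm) - g$nx * g$ny + 1L):(g$nx * g$ny * g$nz)],
                   db)
    jb_full <- -op$cond$sigma_b * grad3(phi_b, h)
    keep <- as.vector(slice.index(array(0, db), 3) > 1)
    j_b <- jb_full[keep, , drop = FALSE]
  }
  j_i <- vector("list", length(V_list))
  for (k in seq_along(V_list)) {
    terr <- op$mus$territories[[k]]
    u <- V_list[[k]] + phi[terr]
    du <- line_gradient(u, op$lines[[k]], h)
    ji <- matrix(0, length(terr), 3)
    ji[, 1] <- -op$mus$f_r[[k]] * op$cond$sigma_i[terr, 1] * du
    j_i[[k]] <- ji
  }
  list(j_e = j_e, j_i = j_i, j_b = j_b)
}

# gradient of a 3-d array: centred interior, one-sided boundary; returns
# n x 3 matrix
grad3 <- function(a, h) {
  cbind(as.vector(grad_axis(a, 1, h)), as.vector(grad_axis(a, 2, h)),
        as.vector(grad_axis(a, 3, h)))
}

grad_axis <- function(a, ax, h) {
  d <- dim(a)
  n <- d[ax]
  g <- array(0, d)
  if (n < 2) return(g)
  # shift helpers along axis `ax`
  take <- function(i) {
    switch(ax, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  assign_slice <- function(g, i, val) {
    switch(ax, g[i, , ] <- val, g[, i, ] <- val, g[, , i] <- val)
    g
  }
  if (n > 2) {
    mid <- (take(3:n) - take(1:(n - 2))) / (2 * h)
    g <- assign_slice(g, 2:(n - 1), mid)
  }
  g <- assign_slice(g, 1, (take(2) - take(1)) / h)
  g <- assign_slice(g, n, (take(n) - take(n - 1)) / h)
  g
}

cond_times_grad <- function(phi_arr, sig_diag, h) {
  gr <- grad3(phi_arr, h)
  gr * sig_diag
}

# along-line first derivative of a territory-ordered vector
line_gradient <- function(u, li, h) {
  du <- numeric(length(u))
  for (r in seq_along(li$starts)) {
    s <- li$starts[r]; len <- li$lengths[r]
    if (len < 2) next
    seg <- u[s:(s + len - 1L)]
    d <- numeric(len)
    if (len > 2) d[2:(len - 1)] <- (seg[3:len] - seg[1:(len - 2)]) / (2 * h)
    d[1] <- (seg[2] - seg[1]) / h
    d[len] <- (seg[len] - seg[len - 1]) / h
    du[s:(s + len - 1L)] <- d
  }
  du
}
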