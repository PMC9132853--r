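test_that("elliptic operator is symmetric with zero row sums before pinning", {
  m <- tiny_model(d_fat = 0.2)
  K <- m$op$K_raw
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(K))), 1e-9)
  # pinned operator is SPD (Cholesky existed) and fixes the ground node
  expect_equal(m$op$K[m$op$ground, m$op$ground], 1)
})

test_that("1-D reduction reproduces the hand-assembled cable operators", {
  h <- 0.1
  p <- tissue_parameters()
  s_eff <- p$sigma_e_l + p$sigma_i_l
  K <- myomag:::fd_divgrad_operator(c(5L, 1L, 1L), h,
                                    matrix(s_eff, 5, 3))
  tri <- matrix(0, 5, 5)
  diag(tri) <- c(1, 2, 2, 2, 1)
  tri[cbind(1:4, 2:5)] <- -1
  tri[cbind(2:5, 1:4)] <- -1
  expect_equal(as.matrix(K), s_eff * tri / h^2, ignore_attr = TRUE)

  # intracellular along-fibre stiffness on a 5-node line, Neumann ends
  li <- list(starts = 1L, lengths = 5L)
  S <- myomag:::line_stiffness(5L, li, rep(p$sigma_i_l, 5), h)
  expect_equal(as.matrix(S), p$sigma_i_l * tri / h^2, ignore_attr = TRUE)
})

test_that("uniform transmembrane potential produces zero potential", {
  m <- tiny_model()
  V <- lapply(m$mus$territories, function(t) rep(-7.5, length(t)))
  phi <- solve_extracellular(m$op, V)
  expect_lt(max(abs(phi)), 1e-9)
})

test_that("opposite step sources give an antisymmetric potential", {
  m <- tiny_model()
  x <- m$grid$x[arrayInd(m$mus$territories[[1]], dim(m$grid$region))[, 1]]
  L <- m$grid$L
  # V(x) = g(x) - g(L - x): antisymmetric source about the midplane
  g <- function(x) 40 * (1 + tanh((x - 0.45) / 0.1)) / 2
  V1 <- g(x) - g(L - x)
  V <- list(V1, rep(0, length(m$mus$territories[[2]])))
  phi <- solve_extracellular(m$op, V)
  arr <- array(phi, dim(m$grid$region))
  mirr <- arr[m$grid$nx:1, , ]
  s <- arr + mirr  # constant if phi is antisymmetric up to gauge
  expect_lt(max(s) - min(s), 1e-8 * max(abs(arr)))
})

test_that("a compact source reproduces the anisotropic dipole far field", {
  grid <- build_grid(L = 6, W = 3, H = 3, spacing = 0.1, air_padding = 1)
  mus <- build_motor_unit_map(grid, depth = 1.5, t_line = 1.5, nmj_x = 3)
  cond <- build_conductivities(grid)
  op <- assemble_elliptic_operator(grid, cond, mus)
  h <- grid$spacing
  dV <- 100
  Vm1 <- dV * (1 + tanh((grid$x - 3) / 0.25)) / 2
  V <- list(Vm1, rep(0, length(mus$territories[[2]])))
  phi <- solve_extracellular(op, V)
  p <- tissue_parameters()
  sig <- c(p$sigma_e_l + p$sigma_i_l, p$sigma_e_t, p$sigma_e_t)
  pmom <- -p$sigma_i_l * dV * h^2   # current dipole of the V_m step
  arr <- array(phi, dim(grid$region))
  c0 <- c(3, 1.5, 1.5)
  offs <- list(c(0.6, 0.3, 0), c(0.6, 0, 0.3), c(0.8, 0.4, 0),
               c(0.5, 0.4, 0.4), c(-0.6, 0.3, 0), c(0.4, 0.5, 0))
  for (off in offs) {
    ii <- round((c0 + off) / h) + 1
    num <- arr[ii[1], ii[2], ii[3]] - mean(arr)
    Rt <- sqrt(sum(off^2 / sig))
    ana <- pmom * (off[1] / sig[1]) / (4 * pi * sqrt(prod(sig)) * Rt^3)
    expect_equal(num, ana, tolerance = 0.05,
                 label = sprintf("phi at offset (%g,%g,%g)",
                                 off[1], off[2], off[3]))
  }
})

test_that("along-fibre diffusion matches the 1-D heat kernel", {
  g <- build_grid(L = 4, W = 0.1, H = 0.1, spacing = 0.05, air_padding = 1)
  mus <- build_motor_unit_map(g, depth = 0.05, t_line = 0.05)
  cond <- build_conductivities(g)
  op <- assemble_elliptic_operator(g, cond, mus)
  p <- tissue_parameters()
  D <- p$sigma_i_l / (p$C_m * p$A_m)
  s0 <- 0.25
  V0 <- 30 * exp(-(g$x - 2)^2 / (2 * s0^2))
  V <- list(V0, rep(0, length(mus$territories[[2]])))
  phi0 <- numeric(op$n)
  dt <- 0.005
  for (s in seq_len(round(1 / dt))) V <- diffuse_vm(op, V, phi0, dt)
  s1sq <- s0^2 + 2 * D * 1
  Vref <- 30 * (s0 / sqrt(s1sq)) * exp(-(g$x - 2)^2 / (2 * s1sq))
  expect_lt(max(abs(V[[1]] - Vref)) / max(Vref), 0.01)
  # Neumann line ends conserve the integral of V_m exactly
  expect_lt(abs(sum(V[[1]]) - sum(V0)) / sum(V0), 1e-12)
  # uniform fields are invariant under the diffusion step
  Vu <- lapply(mus$territories, function(t) rep(5, length(t)))
  Vu2 <- diffuse_vm(op, Vu, phi0, 0.1)
  expect_lt(max(abs(Vu2[[1]] - 5)), 1e-10)
})

test_that("current densities follow Ohm's law with the fibre constraint", {
  m <- tiny_model(d_fat = 0.2)
  g <- m$grid
  # phi linear in x: j_e = -sigma_e_l * slope along x only
  slope <- 3
  xs <- g$x[arrayInd(seq_len(m$op$n), dim(g$region))[, 1]]
  phi <- slope * xs
  V0 <- lapply(m$mus$territories, function(t) rep(0, length(t)))
  J <- current_densities(m$op, phi, V0)
  expect_equal(max(abs(J$j_e[, 1] + 6.7 * slope)), 0, tolerance = 1e-9)
  expect_lt(max(abs(J$j_e[, 2:3])), 1e-9)
  expect_equal(max(abs(J$j_b[, 1] + 0.4 * slope)), 0, tolerance = 1e-9)
  # intracellular currents are strictly fibre-parallel
  st <- em_initial_state(m$op)
  for (s in 1:8) st <- em_step(m$op, st, 0.1, 0.01,
                               stimulus_protocol(onset = 0.2))
  J2 <- current_densities(m$op, st$phi, st$V)
  for (k in 1:2) expect_equal(max(abs(J2$j_i[[k]][, 2:3])), 0)
})

test_that("total current is solenoidal with residual shrinking under refinement", {
  res_for <- function(h) {
    g <- build_grid(L = 2, W = 1, H = 1, spacing = h, air_padding = 1)
    mus <- build_motor_unit_map(g, depth = 0.5, t_line = 0.5, nmj_x = 1)
    cond <- build_conductivities(g)
    op <- assemble_elliptic_operator(g, cond, mus)
    # smooth prescribed transmembrane wave on the active line
    V1 <- 50 * exp(-(g$x - 1)^2 / (2 * 0.3^2))
    V <- list(V1, rep(0, length(mus$territories[[2]])))
    phi <- solve_extracellular(op, V)
    J <- current_densities(op, phi, V)
    jt <- myomag:::tissue_currents(g, mus, J)
    dims <- dim(g$region)
    F <- lapply(1:3, function(c) array(jt[, c], dims))
    dv <- div_field(F, h)
    # evaluate away from the boundary and outside a fixed physical
    # neighbourhood of the singular line source
    pos <- arrayInd(seq_len(prod(dims)), dims)
    yy <- g$y[pos[, 2]]; zz <- g$z[pos[, 3]]
    far <- array(sqrt((yy - mus$line_y)^2 + (zz - mus$line_z)^2) > 0.25,
                 dims)
    inner <- array(FALSE, dims)
    inner[3:(dims[1] - 2), 3:(dims[2] - 2), 3:(dims[3] - 2)] <- TRUE
    sel <- far & inner
    max(abs(dv[sel])) * h / max(abs(jt[sel, ]))
  }
  r_coarse <- res_for(0.1)
  r_fine <- res_for(0.05)
  expect_lt(r_fine, 0.5 * r_coarse)
  expect_lt(r_fine, 0.05)
})

test_that("discrete conservation: sources always sum to zero", {
  m <- tiny_model()
  st <- em_initial_state(m$op)
  stim <- stimulus_protocol(onset = 0.2)
  for (s in 1:6) {
    st <- em_step(m$op, st, 0.1, 0.01, stim)
    rhs <- numeric(m$op$n)
    for (k in 1:2) {
      sk <- m$mus$f_r[[k]] *
        as.numeric(m$op$S_list[[k]] %*% st$V[[k]])
      rhs[m$mus$territories[[k]]] <- rhs[m$mus$territories[[k]]] - sk
    }
    expect_lt(abs(sum(rhs)), 1e-8 * max(abs(rhs)))
  }
})

test_that("moving the grounding node shifts phi by a constant only", {
  m <- tiny_model()
  x <- m$grid$x[arrayInd(m$mus$territories[[1]], dim(m$grid$region))[, 1]]
  V1 <- 40 * exp(-(x - 0.6)^2 / (2 * 0.15^2))
  V <- list(V1, rep(0, length(m$mus$territories[[2]])))
  phi1 <- solve_extracellular(m$op, V)
  op2 <- assemble_elliptic_operator(m$grid, m$cond, m$mus, ground = 1L)
  phi2 <- solve_extracellular(op2, V)
  d <- phi1 - phi2
  expect_lt(max(d) - min(d), 1e-8 * max(abs(phi1)))
  # sensor fields are gauge invariant: identical current densities
  J1 <- current_densities(m$op, phi1, V)
  J2 <- current_densities(op2, phi2, V)
  expect_equal(J1$j_e, J2$j_e, tolerance = 1e-8)
})

test_that("a checkpointed simulation restarts bit-identically", {
  m <- tiny_model()
  stim <- stimulus_protocol(onset = 0.2)
  st <- em_initial_state(m$op)
  for (s in 1:4) st <- em_step(m$op, st, 0.1, 0.01, stim)
  saved <- st                      # checkpoint (plain R list)
  for (s in 1:4) st <- em_step(m$op, st, 0.1, 0.01, stim)
  st2 <- saved
  for (s in 1:4) st2 <- em_step(m$op, st2, 0.1, 0.01, stim)
  expect_identical(st$phi, st2$phi)
  expect_identical(st$V, st2$V)
  expect_identical(st$gates, st2$gates)
})

test_that("without stimulus the coupled system stays at rest", {
  m <- tiny_model(d_fat = 0.2)
  st <- em_initial_state(m$op)
  rest_V <- st$V
  for (s in 1:10) st <- em_step(m$op, st, 0.1, 0.01, stim = NULL)
  expect_lt(max(abs(st$phi)), 1e-9)
  for (k in 1:2) expect_lt(max(abs(st$V[[k]] - rest_V[[k]])), 1e-7)
})

test_that("halving the default time steps changes the surface RMS by <2%", {
  rms_of <- function(dt, dt_ode) {
    cfg <- experiment_config(depth = 0.3, d_fat = 0, spacing = 0.1,
                             duration = 25, L = 4, W = 0.7, H = 0.8,
                             air_padding = 2, channel = c(2.5, 0.2),
                             line_x = 2.5, dt = dt, dt_ode = dt_ode)
    run <- run_experiment(cfg, record_contributions = FALSE)
    rms(run$channels[[1]]$series[, "phi"])
  }
  r1 <- rms_of(0.1, 0.01)
  r2 <- rms_of(0.05, 0.005)
  expect_lt(abs(r2 - r1) / r1, 0.02)
})

test_that("surface potential of a propagating action potential is triphasic", {
  cfg <- experiment_config(depth = 0.3, d_fat = 0, spacing = 0.1,
                           duration = 25, L = 4, W = 0.7, H = 0.8,
                           air_padding = 2, channel = c(2.5, 0.2),
                           line_x = 2.5)
  run <- run_experiment(cfg, record_contributions = FALSE)
  ch <- run$channels[[1]]
  x <- ch$series[, "phi"]
  x2 <- x[ch$time > 2]
  lobes <- rle(sign(x2[abs(x2) > 0.07 * max(abs(x2))]))$values
  expect_gte(length(lobes), 3)
  expect_lte(length(lobes), 4)
})
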