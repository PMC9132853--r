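# Shared builders for small test models. All fixtures are generated in code.

# a small but fully featured model: ~550 tissue nodes, cheap to assemble
tiny_config <- function(depth = 0.2, d_fat = 0, ...) {
  experiment_config(depth = depth, d_fat = d_fat, spacing = 0.1,
                    duration = 6, L = 1.2, W = 0.5, H = 0.6,
                    air_padding = 1, channel = c(0.8, 0.2), line_x = 0.8,
                    ...)
}

tiny_model <- function(d_fat = 0, depth = 0.2, spacing = 0.1) {
  grid <- build_grid(L = 1.2, W = 0.5, H = 0.6, d_fat = d_fat,
                     spacing = spacing, air_padding = 1)
  mus <- build_motor_unit_map(grid, depth)
  cond <- build_conductivities(grid)
  list(grid = grid, mus = mus, cond = cond,
       op = assemble_elliptic_operator(grid, cond, mus))
}

# literal transcription of the original 1952 rate equations (original sign
# convention, v = V_rest - V), used as an independent oracle
hh_rates_1952 <- function(V, V_rest = -75) {
  v <- V_rest - V
  list(alpha_m = 0.1 * (v + 25) / (exp((v + 25) / 10) - 1),
       beta_m = 4 * exp(v / 18),
       alpha_h = 0.07 * exp(v / 20),
       beta_h = 1 / (exp((v + 30) / 10) + 1),
       alpha_n = 0.01 * (v + 10) / (exp((v + 10) / 10) - 1),
       beta_n = 0.125 * exp(v / 80))
}

# right-hand side of the space-clamped membrane ODE for deSolve
hh_ode_rhs <- function(t, y, parms) {
  V <- y[1]
  r <- hh_rates(V)
  istim <- if (t >= parms$onset && t < parms$onset + parms$dur)
    parms$amp else 0
  gates <- list(m = y[2], h = y[3], n = y[4])
  dV <- -hh_ionic_current(V, gates, istim, parms$hh) / parms$hh$C_m
  list(c(dV,
         r$alpha_m * (1 - y[2]) - r$beta_m * y[2],
         r$alpha_h * (1 - y[3]) - r$beta_h * y[3],
         r$alpha_n * (1 - y[4]) - r$beta_n * y[4]))
}
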