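#' Kinetic parameters of the diffusion-reaction model
#'
#' Diffusivities, buffering rate constants, total buffer, resting and
#' extracellular calcium. Derived quantities: the dissociation constant
#' `K_D = k_off / k_on` and the resting free-buffer concentration
#' `B_V0 = B_total * K_D / (Ca_V0 + K_D)`, i.e. the chemical equilibrium
#' of the buffer at resting calcium. With `k_on = 0` the buffer is inert
#' and `B_V0 = B_total`.
#'
#' @param D_Ca,D_B diffusivities of calcium and buffer (um^2/s).
#' @param k_on,k_off buffering on-rate (1/(s uM)) and off-rate (1/s).
#' @param B_total total buffer concentration (uM).
#' @param Ca_V0 resting intracellular calcium (uM; 0.05 uM = 50 nM).
#' @param Ca_e extracellular calcium (uM; 1500 uM = 1.5 mM).
#' @return list of class `az_kinetics` including `K_D` and `B_V0`.
#' @export
kinetic_params <- function(D_Ca = 200, D_B = 30,
                           k_on = 44, k_off = 36,
                           B_total = 40, Ca_V0 = 0.05, Ca_e = 1500) {
  stopifnot(D_Ca > 0, D_B > 0, k_on >= 0, k_off >= 0,
            B_total >= 0, Ca_V0 >= 0, Ca_e >= 0)
  K_D <- if (k_on > 0) k_off / k_on else NA_real_
  B_V0 <- if (k_on > 0) B_total * K_D / (Ca_V0 + K_D) else B_total
  structure(list(D_Ca = D_Ca, D_B = D_B, k_on = k_on, k_off = k_off,
                 B_total = B_total, Ca_V0 = Ca_V0, Ca_e = Ca_e,
                 K_D = K_D, B_V0 = B_V0), class = "az_kinetics")
}

#' Solver configuration
#'
#' Time-step policy and numerical options of the operator-split solver.
#' Each step is: gating update, membrane-flux evaluation on the channel
#' faces (using the adjacent cell's calcium), implicit diffusion of both
#' species, then the exact local reaction update. Diffusion is implicit
#' backward Euler; the default backend solves it by dimension-split
#' tridiagonal sweeps with alternating sweep order, the `"direct"` backend
#' by an unsplit sparse Cholesky solve (slower; used as a reference).
#'
#' @param dt_spike time step inside the spike window (s).
#' @param dt_rest time step outside spike windows (s).
#' @param spike_window window after each spike onset stepped at
#'   `dt_spike` (s).
#' @param method `"adi"` (dimension-split backward Euler with the Douglas
#'   stabilizing correction, the default), `"lie"` (plain sequential
#'   sweeps with alternating order; strictly positivity-preserving), or
#'   `"direct"` (unsplit sparse-Cholesky solve; slow reference).
#' @param wall_bc `"dirichlet"` (resting values held at side/top walls) or
#'   `"reflect"` (sealed box, zero flux everywhere; for conservation
#'   checks).
#' @param reaction_mode `"exact"` closed-form local update, or
#'   `"substepped"` explicit sub-stepping (reference).
#' @param lin_tol tolerance used in conservation diagnostics.
#' @param max_halvings retries by step halving if a step produces a
#'   negative concentration.
#' @param record_every record probe values every this many steps.
#' @return list of class `az_solver`.
#' @export
solver_config <- function(dt_spike = 2e-6, dt_rest = 2e-5,
                          spike_window = 6e-3,
                          method = c("adi", "lie", "direct"),
                          wall_bc = c("dirichlet", "reflect"),
                          reaction_mode = c("exact", "substepped"),
                          lin_tol = 1e-10, max_halvings = 20L,
                          record_every = 1L) {
  stopifnot(dt_spike > 0, dt_rest >= dt_spike, lin_tol > 0)
  structure(list(dt_spike = dt_spike, dt_rest = dt_rest,
                 spike_window = spike_window,
                 method = match.arg(method),
                 wall_bc = match.arg(wall_bc),
                 reaction_mode = match.arg(reaction_mode),
                 lin_tol = lin_tol,
                 max_halvings = as.integer(max_halvings),
                 record_every = as.integer(record_every)),
            class = "az_solver")
}

#' Initialize the concentration fields
#'
#' Spatially constant fields at the resting calcium `Ca_V0` and the
#' equilibrium free buffer `B_V0`; obstacle cells hold `NA`.
#'
#' @param grid an `az_grid`.
#' @param kin an `az_kinetics`.
#' @return list of class `az_fields` with arrays `Ca`, `B` (uM) and
#'   simulation time `t` (s).
#' @export
init_fields <- function(grid, kin) {
  Ca <- array(kin$Ca_V0, dim = grid$shape)
  B <- array(kin$B_V0, dim = grid$shape)
  Ca[!grid$fluid] <- NA_real_
  B[!grid$fluid] <- NA_real_
  structure(list(Ca = Ca, B = B, t = 0), class = "az_fields")
}

#' Local buffering reaction update
#'
#' Advances the mass-action pair `dCa/dt = dB/dt = -R`,
#' `R = k_on * B * Ca - k_off * (B_total - B)`, exactly over `dt` at every
#' point: since `Ca - B` is conserved during pure reaction, `B` satisfies
#' a scalar Riccati equation solved in closed form. Preserves
#' non-negativity and `B <= B_total` and is exact at chemical equilibrium.
#'
#' @param Ca,B concentrations (uM), vectors or arrays of equal shape.
#' @param kin `az_kinetics`.
#' @param dt time step (s).
#' @param mode `"exact"` or `"substepped"` (explicit Euler sub-steps, a
#'   slow reference path).
#' @return list with updated `Ca` and `B`.
#' @export
reaction_step <- function(Ca, B, kin, dt, mode = "exact") {
  stopifnot(dt >= 0)
  dm <- dim(Ca)
  fl <- as.integer(!is.na(Ca))
  if (mode == "exact") {
    out <- reaction_exact(as.numeric(Ca), as.numeric(B), fl,
                          kin$k_on, kin$k_off, kin$B_total, dt)
  } else {
    ca <- as.numeric(Ca); b <- as.numeric(B)
    nsub <- max(1L, ceiling(dt * (kin$k_on * kin$B_total + kin$k_off) * 200))
    dts <- dt / nsub
    for (s in seq_len(nsub)) {
      R <- kin$k_on * b * ca - kin$k_off * (kin$B_total - b)
      ca <- ca - dts * R
      b <- b - dts * R
    }
    out <- list(Ca = ca, B = b)
  }
  if (!is.null(dm)) { dim(out$Ca) <- dm; dim(out$B) <- dm }
  out
}

## ---- simulation context ----------------------------------------------

## Precomputes everything the stepper needs: channel-face linear indices,
## fluid mask in C++ layout, probe interpolation operator, and a cache for
## direct-backend factorizations.
make_sim_context <- function(grid, faces, kin, channel, pumps, train,
                             cfg, consts = physical_constants(),
                             rho_vgcc = faces$rho_vgcc) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  cface_lin <- faces$C$i + nx * (faces$C$j - 1L)  # bottom layer, k = 1
  ctx <- new.env(parent = emptyenv())
  ctx$grid <- grid
  ctx$faces <- faces
  ctx$kin <- kin
  ctx$channel <- channel
  ctx$pumps <- pumps
  ctx$train <- train
  ctx$cfg <- cfg
  ctx$consts <- consts
  ctx$rho_vgcc <- rho_vgcc
  ctx$cface_lin <- cface_lin
  ctx$fluid_int <- as.integer(grid$fluid)
  ctx$fluid_idx <- which(grid$fluid)
  ctx$cache <- new.env(parent = emptyenv())
  ctx$step_count <- 0L
  ctx
}

## Unsplit backward-Euler solve for one species on the fluid cells,
## cached sparse Cholesky per (D, dt).
direct_solve <- function(vec, ctx, D, dt, c0) {
  key <- sprintf("op_%g_%g", D, dt)
  op <- ctx$cache[[key]]
  if (is.null(op)) {
    grid <- ctx$grid
    nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
    lam <- D * dt / grid$h^2
    full2f <- integer(prod(grid$shape))
    full2f[ctx$fluid_idx] <- seq_along(ctx$fluid_idx)
    idx <- array(seq_len(prod(grid$shape)), dim = grid$shape)
    pair_fluid <- function(a, b) {
      keep <- grid$fluid[a] & grid$fluid[b]
      cbind(full2f[a[keep]], full2f[b[keep]])
    }
    px <- pair_fluid(as.vector(idx[-nx, , ]), as.vector(idx[-1, , ]))
    py <- pair_fluid(as.vector(idx[, -ny, ]), as.vector(idx[, -1, ]))
    pz <- pair_fluid(as.vector(idx[, , -nz]), as.vector(idx[, , -1]))
    pr <- rbind(px, py, pz)
    nf <- length(ctx$fluid_idx)
    deg <- tabulate(c(pr[, 1], pr[, 2]), nbins = nf)
    ## Dirichlet wall-face count per fluid cell (sides + top; not floor)
    nwall <- numeric(nf)
    if (ctx$cfg$wall_bc == "dirichlet") {
      arr <- array(0, dim = grid$shape)
      arr[1, , ] <- arr[1, , ] + 1; arr[nx, , ] <- arr[nx, , ] + 1
      arr[, 1, ] <- arr[, 1, ] + 1; arr[, ny, ] <- arr[, ny, ] + 1
      arr[, , nz] <- arr[, , nz] + 1
      nwall <- arr[ctx$fluid_idx]
    }
    A <- Matrix::sparseMatrix(
      i = c(seq_len(nf), pr[, 1], pr[, 2]),
      j = c(seq_len(nf), pr[, 2], pr[, 1]),
      x = c(1 + lam * deg + 2 * lam * nwall,
            rep(-lam, 2 * nrow(pr))),
      dims = c(nf, nf), symmetric = FALSE)
    op <- list(ch = Matrix::Cholesky(Matrix::forceSymmetric(A),
                                     LDL = FALSE, super = TRUE),
               rhs_dir = 2 * lam * nwall)
    ctx$cache[[key]] <- op
  }
  x <- Matrix::solve(op$ch, vec[ctx$fluid_idx] + op$rhs_dir * c0,
                     system = "A")
  vec[ctx$fluid_idx] <- as.numeric(x)
  vec
}

diffuse_species <- function(vec, ctx, D, dt, c0, reverse) {
  sh <- ctx$grid$shape
  switch(ctx$cfg$method,
    adi = douglas_diffuse(vec, ctx$fluid_int, sh[1], sh[2], sh[3],
                          D * dt / ctx$grid$h^2, c0,
                          ctx$cfg$wall_bc == "dirichlet"),
    lie = adi_diffuse(vec, ctx$fluid_int, sh[1], sh[2], sh[3],
                      D * dt / ctx$grid$h^2, c0,
                      ctx$cfg$wall_bc == "dirichlet", reverse),
    direct = direct_solve(vec, ctx, D, dt, c0))
}

#' One implicit diffusion step with membrane influx
#'
#' Applies the Neumann channel-zone source (flux density times face area
#' over cell volume) and advances both species by implicit backward-Euler
#' diffusion with zero flux across the floor and the obstacle interface
#' and resting-value Dirichlet conditions on the side and top walls.
#'
#' @param state `az_fields`.
#' @param grid,faces geometry objects.
#' @param flux_bc inward molar flux density on each channel face
#'   (uM*um/s), recycled over faces.
#' @param kin `az_kinetics`.
#' @param dt step (s).
#' @param cfg `az_solver`.
#' @return updated `az_fields` (time not advanced; the scenario runner
#'   owns the clock).
#' @export
diffusion_step <- function(state, grid, faces, flux_bc, kin, dt,
                           cfg = solver_config()) {
  ctx <- make_sim_context(grid, faces, kin, channel_params(),
                          pump_params(), NULL, cfg)
  diffusion_step_ctx(state, ctx, flux_bc, dt, reverse = FALSE)
}

diffusion_step_ctx <- function(state, ctx, flux_bc, dt, reverse) {
  kin <- ctx$kin
  ca <- state$Ca
  if (length(ctx$cface_lin) && any(flux_bc != 0)) {
    ca[ctx$cface_lin] <- ca[ctx$cface_lin] +
      dt * rep_len(flux_bc, length(ctx$cface_lin)) / ctx$grid$h
  }
  ca <- diffuse_species(ca, ctx, kin$D_Ca, dt, kin$Ca_V0, reverse)
  b <- diffuse_species(state$B, ctx, kin$D_B, dt, kin$B_V0, reverse)
  dim(ca) <- dim(b) <- ctx$grid$shape
  state$Ca <- ca
  state$B <- b
  state
}

#' Advance the coupled system by one split step
#'
#' One operator-split step at frozen voltage `V(t)`: exact gating update,
#' membrane-flux evaluation on the channel faces using each face's
#' adjacent-cell calcium, implicit diffusion with that flux, exact local
#' reaction. If a step produces a negative concentration it is retried
#' as two half steps (bounded recursion); clipping is never used so mass
#' balance is preserved.
#'
#' @param state `az_fields` carrying also the gating state in
#'   `state$gating`.
#' @param ctx simulation context from the scenario runner.
#' @param dt step (s).
#' @return updated state with `t` advanced by `dt`.
#' @keywords internal
advance_ctx <- function(state, ctx, dt, depth = 0L) {
  V <- ap_voltage(state$t, ctx$train)
  gating <- step_gating(state$gating, V, dt, ctx$channel, ctx$consts)
  ## effective flux density over the step: exponential (linearized) update
  ## of the face-cell source; the pump feedback is stiff relative to
  ## dt_rest, so a plain explicit source would be unstable
  flux <- membrane_flux_effective(ctx, V, gating,
                                  state$Ca[ctx$cface_lin], dt)
  if (ctx$cfg$method == "adi") {
    ## fast path: one in-place C++ call (source + Douglas diffusion of
    ## both species + exact reaction), persistent scratch, internal
    ## backup for the negativity retry
    sh <- ctx$grid$shape
    kin <- ctx$kin
    h2 <- ctx$grid$h^2
    status <- az_step_inplace(state$Ca, state$B, ctx$fluid_int,
                              sh[1], sh[2], sh[3],
                              kin$D_Ca * dt / h2, kin$D_B * dt / h2,
                              kin$Ca_V0, kin$B_V0,
                              ctx$cfg$wall_bc == "dirichlet",
                              kin$k_on, kin$k_off, kin$B_total, dt,
                              ctx$cface_lin, flux * dt / ctx$grid$h)
    if (status != 0L) {
      if (depth >= ctx$cfg$max_halvings)
        stop("negative concentration persisted after maximal step halving")
      half <- advance_ctx(state, ctx, dt / 2, depth + 1L)
      return(advance_ctx(half, ctx, dt / 2, depth + 1L))
    }
    state$gating <- gating
    state$t <- state$t + dt
    ctx$step_count <- ctx$step_count + 1L
    return(state)
  }
  reverse <- (ctx$step_count %% 2L) == 1L
  new <- diffusion_step_ctx(state, ctx, flux, dt, reverse)
  if (ctx$cfg$reaction_mode == "exact") {
    r <- reaction_exact(new$Ca, new$B, ctx$fluid_int,
                        ctx$kin$k_on, ctx$kin$k_off, ctx$kin$B_total, dt)
    dim(r$Ca) <- dim(r$B) <- ctx$grid$shape
  } else {
    r <- reaction_step(new$Ca, new$B, ctx$kin, dt,
                       mode = ctx$cfg$reaction_mode)
  }
  new$Ca <- r$Ca
  new$B <- r$B
  bad <- min(new$Ca, na.rm = TRUE) < 0 || min(new$B, na.rm = TRUE) < 0
  if (bad) {
    if (depth >= ctx$cfg$max_halvings)
      stop("negative concentration persisted after maximal step halving")
    half <- advance_ctx(state, ctx, dt / 2, depth + 1L)
    return(advance_ctx(half, ctx, dt / 2, depth + 1L))
  }
  new$gating <- gating
  new$t <- state$t + dt
  ctx$step_count <- ctx$step_count + 1L
  new
}

## Average membrane flux density over one step from the linearized local
## source ODE dCa/dt = F(Ca)/h at each channel face: with slope
## Fp = dF/dCa (numerically differenced), the exact solution of the
## linearization gives the increment (F0/Fp)(exp(Fp*dt/h) - 1), returned
## as an equivalent constant flux density increment/(dt/h). Reduces to
## the plain explicit source as Fp -> 0 and is unconditionally stable
## for the damping (Fp < 0) pump feedback.
membrane_flux_effective <- function(ctx, V, gating, ca, dt) {
  tmf <- function(x) total_membrane_flux(V, gating, x, ctx$kin,
                                         ctx$channel, ctx$pumps,
                                         ctx$rho_vgcc, ctx$consts)
  F0 <- tmf(ca)
  eps <- pmin(pmax(1e-6, 1e-4 * ca), ca / 2)
  Fp <- (tmf(ca + eps) - tmf(ca - eps)) / (2 * eps)
  a <- Fp * dt / ctx$grid$h
  small <- abs(a) < 1e-8
  dca <- numeric(length(F0))
  dca[small] <- F0[small] * dt / ctx$grid$h
  if (any(!small))
    dca[!small] <- (F0[!small] / Fp[!small]) * (exp(a[!small]) - 1)
  dca * ctx$grid$h / dt
}

## time to next schedule event (spike onset or window end) for the dt
## policy; returns the nominal dt truncated to event boundaries.
next_dt <- function(t, t_end, train, cfg) {
  if (is.null(train)) return(min(cfg$dt_rest, t_end - t))
  per <- 1 / train$frequency
  phase <- t - floor(t / per + 1e-9) * per
  if (phase < cfg$spike_window - 1e-12 && t < train$duration) {
    dt <- min(cfg$dt_spike, cfg$spike_window - phase)
  } else {
    nxt <- (floor(t / per + 1e-9) + 1) * per
    dt <- min(cfg$dt_rest, nxt - t)
  }
  min(dt, t_end - t)
}

#' Run one scenario simulation
#'
#' Advances the full model from rest to `t_end`, recording circle-probe
#' averages, the under-roof subdomain average, and a mass-balance log at
#' every recorded step, and detecting per-period concentration peaks.
#' The leak is calibrated before the run so that the unstimulated system
#' is exactly at steady state.
#'
#' @param config an `az_config` from [scenario_config()] or
#'   [make_preset()].
#' @return An object of class `az_result`: `times`, `probes` (matrix of
#'   circle averages, uM), `probe_meta` (R, H per probe), `U_avg`,
#'   `peaks`, `mass` log, `config` echo, field `snapshots` at the
#'   requested times, the `grid`, and the final `state`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "az_config"))
  grid <- build_geometry(config$geometry, config$h)
  faces <- classify_faces(grid)
  U <- subdomain_U(grid)
  kin <- config$kinetics
  consts <- config$constants
  rho_vgcc <- if (!is.null(config$rho_vgcc_override))
    config$rho_vgcc_override else faces$rho_vgcc
  pumps <- calibrate_leak(kin, config$channel, config$pumps, rho_vgcc,
                          V_rest = config$V_rest, consts = consts)
  ctx <- make_sim_context(grid, faces, kin, config$channel, pumps,
                          config$train, config$solver, consts, rho_vgcc)
  state <- init_fields(grid, kin)
  state$gating <- gating_state(config$channel, config$V_rest, consts)

  probes <- build_probe_set(grid, config$probes)
  t_end <- config$t_end
  cfg <- config$solver
  ## upper bound on number of records
  nmax <- ceiling(t_end / cfg$dt_spike) + 2L
  nmax <- min(nmax, ceiling(t_end / min(cfg$dt_spike, cfg$dt_rest)) + 2L)
  times <- numeric(0)
  pvals <- list()
  uvals <- numeric(0)
  mass <- list()
  h3 <- grid$h^3
  nfluid <- length(ctx$fluid_idx)
  U_lin <- U$cells[, 1] + grid$shape[1] * (U$cells[, 2] - 1L) +
    prod(grid$shape[1:2]) * (U$cells[, 3] - 1L)
  record <- function(state) {
    times[[length(times) + 1L]] <<- state$t
    pvals[[length(pvals) + 1L]] <<- probe_values(probes, state$Ca)
    uvals[[length(uvals) + 1L]] <<- mean(state$Ca[U_lin])
    mass[[length(mass) + 1L]] <<- c(
      free = sum(state$Ca, na.rm = TRUE) * h3,
      bound = (kin$B_total * nfluid - sum(state$B, na.rm = TRUE)) * h3)
  }
  record(state)
  snaps <- list()
  snap_times <- sort(config$snapshot_times)
  k <- 0L
  while (state$t < t_end - 1e-12) {
    dt <- next_dt(state$t, t_end, config$train, cfg)
    t_prev <- state$t
    state <- advance_ctx(state, ctx, dt)
    k <- k + 1L
    if (k %% cfg$record_every == 0L || state$t >= t_end - 1e-12)
      record(state)
    while (length(snap_times) &&
             snap_times[1] > t_prev && snap_times[1] <= state$t + 1e-15) {
      ## deep-copy: the state arrays are mutated in place by the stepper
      snaps[[length(snaps) + 1L]] <-
        list(t = state$t, Ca = state$Ca * 1, B = state$B * 1)
      snap_times <- snap_times[-1]
    }
  }
  pm <- do.call(rbind, pvals)
  colnames(pm) <- probes$labels
  massm <- do.call(rbind, mass)
  res <- structure(list(
    times = unlist(times),
    probes = pm,
    probe_meta = probes$meta,
    U_avg = unlist(uvals),
    mass = massm,
    config = config,
    rho_vgcc = rho_vgcc,
    leak_flux = pumps$leak_flux,
    snapshots = snaps,
    grid = grid,
    state = state
  ), class = "az_result")
  res$peaks <- if (!is.null(config$train))
    result_peaks(res, config$train) else NULL
  res
}

#' @export
print.az_result <- function(x, ...) {
  cat(sprintf("Scenario result: %s, %d steps recorded, t = [0, %g] s\n",
              x$config$label, length(x$times), max(x$times)))
  cat(sprintf("  %d probes; peak Ca at first probe: %.3g uM\n",
              ncol(x$probes), max(x$probes[, 1])))
  invisible(x)
}

#' @export
summary.az_result <- function(object, ...) {
  cat(sprintf("Scenario: %s\n", object$config$label))
  cat(sprintf("  channel density: %.1f um^-2, leak flux: %.4g uM*um/s\n",
              object$rho_vgcc, object$leak_flux))
  if (!is.null(object$peaks)) {
    cat("  first-period peaks (uM):\n")
    p1 <- subset(object$peaks, object$peaks$period == 1)
    print(p1[, c("probe", "time", "value")], row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.az_result <- function(x, probe = 1, ...) {
  matplot(x$times * 1e3, x$probes[, probe, drop = FALSE], type = "l",
          xlab = "time (ms)", ylab = "[Ca2+] (uM)",
          main = x$config$label, ...)
  invisible(x)
}
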