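test_that("initial fields implement the buffer equilibrium", {
  kin <- kinetic_params(k_on = 44, k_off = 36)
  expect_equal(kin$K_D, 36 / 44)
  expect_equal(kin$B_V0, 40 * (36 / 44) / (0.05 + 36 / 44))
  expect_equal(kin$B_V0, 37.70, tolerance = 1e-3)
  ## limits of the equilibrium expression
  expect_equal(kinetic_params(k_on = 44, k_off = 0)$B_V0, 0)
  expect_equal(kinetic_params(k_on = 0, k_off = 0)$B_V0, 40)
  g <- build_geometry(mini_geometry(), 0.01)
  st <- init_fields(g, kin)
  expect_equal(st$t, 0)
  expect_true(all(st$Ca[g$fluid] == kin$Ca_V0))
  expect_true(all(st$B[g$fluid] == kin$B_V0))
  expect_true(all(is.na(st$Ca[!g$fluid])))
})

test_that("the exact reaction step fixes chemical equilibrium and zero rates", {
  kin <- kinetic_params()
  ## equilibrium: k_on*B*Ca = k_off*(B_total - B)
  ca <- 1
  b <- kin$k_off * kin$B_total / (kin$k_on * ca + kin$k_off)
  out <- reaction_step(ca, b, kin, dt = 5e-3)
  expect_equal(out$Ca, ca, tolerance = 1e-12)
  expect_equal(out$B, b, tolerance = 1e-12)
  out0 <- reaction_step(3, 20, kinetic_params(k_on = 0, k_off = 0), 1)
  expect_identical(out0$Ca, 3)
  expect_identical(out0$B, 20)
})

test_that("the exact reaction step matches an adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  kin <- kinetic_params()
  ca0 <- 10; b0 <- 37.70; dt <- 1e-4
  out <- reaction_step(ca0, b0, kin, dt)
  sol <- deSolve::lsoda(
    c(ca = ca0, b = b0), c(0, dt),
    function(t, y, p) {
      R <- kin$k_on * y[2] * y[1] - kin$k_off * (kin$B_total - y[2])
      list(c(-R, -R))
    }, rtol = 1e-12, atol = 1e-14)
  expect_equal(out$Ca, unname(sol[2, "ca"]), tolerance = 1e-8)
  expect_equal(out$B, unname(sol[2, "b"]), tolerance = 1e-8)
  ## the explicit substepped reference agrees to its own accuracy
  sub <- reaction_step(ca0, b0, kin, dt, mode = "substepped")
  expect_equal(sub$Ca, out$Ca, tolerance = 2e-3)
})

test_that("reaction preserves positivity, the bound state and Ca - B", {
  kin <- kinetic_params()
  set.seed(7)
  for (i in 1:200) {
    ca0 <- runif(1, 0, 100)
    b0 <- runif(1, 0, kin$B_total)
    dt <- 10^runif(1, -7, -1)
    out <- reaction_step(ca0, b0, kin, dt)
    expect_gte(out$Ca, 0)
    expect_gte(out$B, 0)
    expect_lte(out$B, kin$B_total + 1e-12)
    expect_equal(out$Ca - out$B, ca0 - b0, tolerance = 1e-10)
  }
})

test_that("both diffusion backends leave a uniform resting field unchanged", {
  g <- build_geometry(mini_geometry(), 0.01)
  f <- classify_faces(g)
  kin <- kinetic_params()
  for (method in c("adi", "direct")) {
    st <- init_fields(g, kin)
    cfg <- solver_config(method = method)
    out <- diffusion_step(st, g, f, flux_bc = 0, kin, dt = 1e-5, cfg)
    expect_equal(out$Ca[g$fluid], st$Ca[g$fluid], tolerance = 1e-12)
    expect_equal(out$B[g$fluid], st$B[g$fluid], tolerance = 1e-12)
  }
})

test_that("a sealed box conserves total calcium over many steps", {
  geo <- geometry_spec(box_dims = c(0.12, 0.12, 0.06))
  g <- build_geometry(geo, 0.01)
  f <- classify_faces(g)
  kin <- kinetic_params()
  cfg <- solver_config(wall_bc = "reflect")
  st <- init_fields(g, kin)
  ## deterministic non-uniform initial condition
  cc <- expand.grid(x = seq_len(g$shape[1]), y = seq_len(g$shape[2]),
                    z = seq_len(g$shape[3]))
  bump <- array(2 * exp(-((cc$x - 4)^2 + (cc$y - 7)^2 + (cc$z - 2)^2) / 8),
                dim = g$shape)
  st$Ca[g$fluid] <- st$Ca[g$fluid] + bump[g$fluid]
  total <- function(s) sum(s$Ca[g$fluid]) + sum(kin$B_total - s$B[g$fluid])
  t0 <- total(st)
  for (k in 1:1000)
    st <- diffusion_step(st, g, f, flux_bc = 0, kin, dt = 2e-6, cfg)
  r <- reaction_step(st$Ca, st$B, kin, 1e-3)
  st$Ca <- r$Ca; st$B <- r$B
  expect_equal(total(st), t0, tolerance = 1e-10)
  ## and the obstacle never acquires values
  expect_true(all(is.na(st$Ca[!g$fluid])))
})

test_that("split and unsplit implicit diffusion agree", {
  g <- build_geometry(mini_geometry(), 0.01)
  f <- classify_faces(g)
  kin <- kinetic_params()
  ## smooth initial bump around the T-bar, no source: the stabilizing-
  ## correction scheme should track the unsplit solve closely
  bump <- function() {
    st <- init_fields(g, kin)
    cc <- azsim:::grid_centers(g)
    r2 <- outer(outer(cc$cx^2, cc$cy^2, `+`), cc$cz^2, `+`)
    st$Ca <- st$Ca + 10 * exp(-r2 / 0.002)
    st$Ca[!g$fluid] <- NA
    st
  }
  run <- function(method, dt, nstep, with_flux = FALSE, init = bump) {
    st <- init()
    cfg <- solver_config(method = method)
    for (k in 1:nstep)
      st <- diffusion_step(st, g, f, flux_bc = if (with_flux) 5e4 else 0,
                           kin, dt, cfg)
    st
  }
  a <- run("adi", 1e-6, 40)
  d <- run("direct", 1e-6, 40)
  ## within 0.1% of the bump amplitude everywhere
  expect_lt(max(abs(a$Ca[g$fluid] - d$Ca[g$fluid])), 0.01)
  ## plain sequential (Lie) sweeps with a sharp membrane source:
  ## first-order splitting error that shrinks as dt is halved
  flat <- function() init_fields(g, kin)
  l1 <- run("lie", 1e-6, 40, with_flux = TRUE, init = flat)
  d1 <- run("direct", 1e-6, 40, with_flux = TRUE, init = flat)
  l2 <- run("lie", 5e-7, 80, with_flux = TRUE, init = flat)
  d2 <- run("direct", 5e-7, 80, with_flux = TRUE, init = flat)
  err1 <- max(abs(l1$Ca[g$fluid] - d1$Ca[g$fluid]))
  err2 <- max(abs(l2$Ca[g$fluid] - d2$Ca[g$fluid]))
  expect_lt(err2, err1)
})

test_that("steady point influx reproduces the hemispherical Green's function", {
  ## large box, single-face source at the floor center; one backward-Euler
  ## solve with a huge time step approximates the steady Poisson problem
  geo <- geometry_spec(box_dims = c(0.6, 0.6, 0.3), has_tbar = FALSE)
  g <- build_geometry(geo, 0.01)
  kin <- kinetic_params()
  phi <- 1e4                        # uM*um/s influx density on one face
  Q <- phi * g$h^2                  # total source, uM*um^3/s
  ctx <- azsim:::make_sim_context(g, classify_faces(g), kin,
                                  channel_params(), pump_params(), NULL,
                                  solver_config(method = "direct"))
  ca <- array(0, dim = g$shape)
  ic <- g$shape[1] %/% 2            # face center next to the axis
  ca[ic, ic, 1] <- phi * 1e6 / g$h  # source * dt / h with dt = 1e6 s
  ca <- azsim:::direct_solve(as.numeric(ca), ctx, kin$D_Ca, 1e6, 0)
  dim(ca) <- g$shape
  ## cells on the source column have centers at r = (k - 0.5) * h
  ## compare radial differences to Q/(2 pi D r) in the source's far field
  for (pair in list(c(4L, 8L), c(5L, 10L))) {
    r1 <- (pair[1] - 0.5) * g$h
    r2 <- (pair[2] - 0.5) * g$h
    got <- ca[ic, ic, pair[1]] - ca[ic, ic, pair[2]]
    want <- Q / (2 * pi * kin$D_Ca) * (1 / r1 - 1 / r2)
    expect_equal(got, want, tolerance = 0.05)
  }
})

test_that("a calibrated unstimulated system holds 50 nM indefinitely", {
  cfg <- mini_config("tbar_clustered")
  cfg$train <- NULL
  cfg$t_end <- 0.05
  res <- run_scenario(cfg)
  ca <- res$probes
  expect_lt(max(abs(ca - 0.05)) / 0.05, 1e-3)
  expect_lt(max(abs(res$U_avg - 0.05)) / 0.05, 1e-3)
})

test_that("identical configurations give bit-identical trajectories", {
  r1 <- run_scenario(mini_config("no_tbar_clustered", t_end = 0.002))
  r2 <- run_scenario(mini_config("no_tbar_clustered", t_end = 0.002))
  expect_identical(r1$probes, r2$probes)
  expect_identical(r1$state$Ca, r2$state$Ca)
})

test_that("a single action potential produces a transient microdomain that decays", {
  res <- mini_run("tbar_clustered")
  tr <- res$probes[, "R0.030_H0.010"]
  peak <- max(tr)
  ca0 <- res$config$kinetics$Ca_V0
  expect_gt(peak, 20 * ca0)  # strong transient above the 50 nM baseline
  ## rises near the voltage peak, decays back afterwards
  t_peak <- res$times[which.max(tr)]
  expect_gt(t_peak, 1e-3)
  expect_lt(t_peak, 6e-3)
  expect_lt(tr[length(tr)], 0.6 * peak)
  ## buffer is consumed where calcium rises
  expect_lt(min(res$state$B, na.rm = TRUE),
            res$config$kinetics$B_V0)
})

test_that("mass balance logs free and bound calcium", {
  res <- mini_run("tbar_clustered")
  expect_equal(nrow(res$mass), length(res$times))
  ## total calcium grows during influx
  tot <- res$mass[, "free"] + res$mass[, "bound"]
  expect_gt(max(tot), tot[1])
})
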