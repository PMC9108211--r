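## Unit conventions used throughout the package:
##   length um, time s, concentration uM, voltage mV (converted to V
##   internally), amount uM*um^3 (1 mol = 1e21 uM*um^3), current A.
## Membrane flux densities are inward-positive molar surface densities in
## uM*um/s; surface pump/channel densities in um^-2.
MOL_TO_UMUM3 <- 1e21

#' Physical constants
#'
#' Faraday constant, gas constant, temperature and calcium valence used in
#' the Goldman-Hodgkin-Katz flux and the Nernst potential.
#'
#' @param T_kelvin absolute temperature (K), default 300 K (27 C).
#' @return list with `F_faraday` (C/mol), `R_gas` (V C / (K mol)),
#'   `T_kelvin` (K), `z` (valence of Ca2+).
#' @export
physical_constants <- function(T_kelvin = 300) {
  stopifnot(T_kelvin > 0)
  list(F_faraday = 9.648e4, R_gas = 8.314, T_kelvin = T_kelvin, z = 2L)
}

## zFV/RT for V in mV (dimensionless)
zFV_RT <- function(V_mV, consts) {
  consts$z * consts$F_faraday * (V_mV * 1e-3) /
    (consts$R_gas * consts$T_kelvin)
}

#' Nernst (reversal) potential for calcium
#'
#' @param Ca_i,Ca_e intra-/extracellular concentrations (uM).
#' @param consts see [physical_constants()].
#' @return potential in mV.
#' @export
nernst_potential <- function(Ca_i, Ca_e, consts = physical_constants()) {
  1e3 * consts$R_gas * consts$T_kelvin /
    (consts$z * consts$F_faraday) * log(Ca_e / Ca_i)
}

#' Borg-Graham style gating-variable parameterization
#'
#' One Hodgkin-Huxley-like gating variable with voltage-dependent forward
#' and backward rates exponential in voltage,
#' `alpha = alpha0 * exp(gamma * w)`, `beta = alpha0 * exp(-(1-gamma) * w)`
#' with `w = z_g * F * (V - V_half) / (R T)`, so that
#' `x_inf = 1 / (1 + exp(-w))` and `tau = max(tau0, 1/(alpha+beta))`.
#'
#' @param V_half half-activation voltage (mV); `x_inf(V_half) = 0.5`.
#' @param z_g effective gating charge (sign selects activation/inactivation).
#' @param gamma partition of the gating charge between forward and
#'   backward rates, in `[0, 1]`.
#' @param alpha0 rate at `V_half` (1/s).
#' @param tau0 minimum time constant (s).
#' @return list of class `az_gate`.
#' @export
gate_params <- function(V_half, z_g, gamma, alpha0, tau0) {
  stopifnot(alpha0 > 0, tau0 >= 0, gamma >= 0, gamma <= 1)
  structure(list(V_half = V_half, z_g = z_g, gamma = gamma,
                 alpha0 = alpha0, tau0 = tau0), class = "az_gate")
}

#' N-type channel parameters
#'
#' Per-channel permeability plus the gating structure `G = m^a * h^b` of
#' the Borg-Graham voltage-gated channel model. The default gate constants
#' are the package's N-type preset: a fast activation pair (`a = 2`) and a
#' slow inactivation gate (`b = 1`) with literature-typical half-voltages,
#' gating charges and time-constant floors. The permeability default puts
#' peak microdomain concentrations in the tens of micromolar; scenario
#' ratios are insensitive to its value because the influx scale cancels
#' between geometries.
#'
#' @param p_x single-channel permeability (um^3/s).
#' @param a,b integer powers of the activation/inactivation gates.
#' @param m,h [gate_params()] for the two gates.
#' @return list of class `az_channel`.
#' @export
channel_params <- function(p_x = 0.1,
                           a = 2L, b = 1L,
                           m = gate_params(V_half = -21, z_g = 3.4,
                                           gamma = 0.8, alpha0 = 800,
                                           tau0 = 2e-3),
                           h = gate_params(V_half = -40, z_g = -2,
                                           gamma = 0.5, alpha0 = 40,
                                           tau0 = 75e-3)) {
  stopifnot(p_x > 0, a >= 0, b >= 0)
  structure(list(p_x = p_x, a = as.integer(a), b = as.integer(b),
                 gates = list(m = m, h = h)), class = "az_channel")
}

#' Pump, exchanger and leak parameters
#'
#' Hill-type extrusion by plasma-membrane Ca-ATPase (PMCA) and Na/Ca
#' exchange (NCX), plus a constant leak flux density fixed by
#' [calibrate_leak()]. Defaults are the literature single-pump turnovers
#' and half-saturations; densities default to the maximal reported surface
#' densities (set them to 0 for the pump-free comparison case).
#'
#' The NCX denominator exponent is kept as a separate field `n_x_den`
#' (default equal to `n_x`) so both exponent conventions are expressible.
#'
#' @param I_p,H_p,n_p PMCA turnover (mol/s), half-saturation (uM), Hill
#'   coefficient.
#' @param I_x,H_x,n_x NCX turnover (mol/s), half-saturation (uM), Hill
#'   coefficient; `n_x_den` the denominator exponent.
#' @param rho_pmca,rho_ncx surface densities (um^-2).
#' @param leak_flux constant inward leak flux density (uM*um/s); set by
#'   calibration, not by hand.
#' @return list of class `az_pumps`.
#' @export
pump_params <- function(I_p = 8e-24, H_p = 0.06, n_p = 2,
                        I_x = 2.5e-21, H_x = 1.8, n_x = 1,
                        n_x_den = n_x,
                        rho_pmca = 75000, rho_ncx = 2500,
                        leak_flux = 0) {
  stopifnot(I_p >= 0, I_x >= 0, H_p > 0, H_x > 0, n_p >= 1, n_x >= 1,
            rho_pmca >= 0, rho_pmca <= 75000,
            rho_ncx >= 0, rho_ncx <= 2500)
  structure(list(I_p = I_p, H_p = H_p, n_p = n_p,
                 I_x = I_x, H_x = H_x, n_x = n_x, n_x_den = n_x_den,
                 rho_pmca = rho_pmca, rho_ncx = rho_ncx,
                 leak_flux = leak_flux), class = "az_pumps")
}

#' Goldman-Hodgkin-Katz single-channel current
#'
#' The open-channel calcium current through one channel. Follows the
#' electrophysiological sign convention: inward (calcium-entering) current
#' is negative. A first-order series branch is used near `V = 0` where the
#' GHK expression is 0/0. The current is zero exactly at the Nernst
#' potential and strictly monotone in voltage on either side.
#'
#' @param V membrane potential (mV), may be a vector.
#' @param Ca_i,Ca_e intra-/extracellular calcium (uM).
#' @param channel [channel_params()].
#' @param consts [physical_constants()].
#' @return current in A (single open channel).
#' @export
ghk_flux <- function(V, Ca_i, Ca_e, channel = channel_params(),
                     consts = physical_constants()) {
  stopifnot(all(Ca_i >= 0), all(Ca_e >= 0))
  J <- ghk_molar_efflux(V, Ca_i, Ca_e, channel, consts)
  consts$z * consts$F_faraday * J / MOL_TO_UMUM3
}

## Outward-positive molar flux through one open channel, in uM*um^3/s.
## J = p * u * (Ca_i - Ca_e*exp(-u)) / (1 - exp(-u)), u = zFV/RT.
ghk_molar_efflux <- function(V, Ca_i, Ca_e, channel, consts) {
  u <- zFV_RT(V, consts)
  n <- max(length(u), length(Ca_i))
  u <- rep_len(u, n)
  Ca_i <- rep_len(Ca_i, n)
  small <- abs(u) < 1e-5
  J <- numeric(n)
  if (any(!small)) {
    us <- u[!small]
    J[!small] <- us * (Ca_i[!small] - Ca_e * exp(-us)) / (1 - exp(-us))
  }
  if (any(small)) {
    J[small] <- (Ca_i[small] - Ca_e) + u[small] * (Ca_i[small] + Ca_e) / 2
  }
  channel$p_x * J
}

#' Steady-state activation and time constant of a gate
#'
#' @param V membrane potential (mV), vectorized.
#' @param gate a [gate_params()].
#' @param consts [physical_constants()].
#' @return list with `x_inf` in (0,1) and `tau` (s, `>= tau0`).
#' @export
gating_curves <- function(V, gate, consts = physical_constants()) {
  w <- gate$z_g * consts$F_faraday * ((V - gate$V_half) * 1e-3) /
    (consts$R_gas * consts$T_kelvin)
  alpha <- gate$alpha0 * exp(gate$gamma * w)
  beta <- gate$alpha0 * exp(-(1 - gate$gamma) * w)
  list(x_inf = 1 / (1 + exp(-w)), tau = pmax(gate$tau0, 1 / (alpha + beta)))
}

#' Create / advance the gating state
#'
#' `gating_state()` initializes all gates at their steady state for the
#' given voltage. `step_gating()` advances the state over `dt` under
#' frozen voltage using the exact exponential relaxation
#' `x <- x_inf + (x - x_inf) exp(-dt / tau)`.
#'
#' @param channel [channel_params()].
#' @param V membrane potential (mV).
#' @param consts [physical_constants()].
#' @return named numeric vector of gate values in `[0, 1]`.
#' @export
gating_state <- function(channel, V, consts = physical_constants()) {
  vapply(channel$gates, function(g) gating_curves(V, g, consts)$x_inf,
         numeric(1))
}

#' @rdname gating_state
#' @param state named gate vector as returned by `gating_state()`.
#' @param dt time step (s).
#' @export
step_gating <- function(state, V, dt, channel = channel_params(),
                        consts = physical_constants()) {
  stopifnot(dt >= 0)
  out <- state
  for (nm in names(channel$gates)) {
    gc <- gating_curves(V, channel$gates[[nm]], consts)
    out[nm] <- gc$x_inf + (state[nm] - gc$x_inf) * exp(-dt / gc$tau)
  }
  pmin(pmax(out, 0), 1)
}

## Composite gating function G = m^a * h^b
gating_G <- function(state, channel) {
  unname(state["m"]^channel$a * state["h"]^channel$b)
}

#' Gated single-channel current
#'
#' Product of the composite gating function `G = m^a h^b` and the GHK
#' open-channel current.
#'
#' @inheritParams ghk_flux
#' @param state gating state from [gating_state()].
#' @return current in A.
#' @export
vgcc_current <- function(V, state, Ca_i, Ca_e,
                         channel = channel_params(),
                         consts = physical_constants()) {
  gating_G(state, channel) * ghk_flux(V, Ca_i, Ca_e, channel, consts)
}

#' Hill-type pump fluxes
#'
#' Per-transporter calcium extrusion of the PMCA pump and the NCX
#' exchanger. Both are monotone non-decreasing in intracellular calcium
#' and saturate at the turnover rates `I_p`, `I_x`.
#'
#' @param Ca_i intracellular calcium (uM), vectorized.
#' @param pumps [pump_params()].
#' @return efflux in mol/s per transporter.
#' @export
pmca_flux <- function(Ca_i, pumps = pump_params()) {
  stopifnot(all(Ca_i >= 0))
  pumps$I_p * Ca_i^pumps$n_p / (pumps$H_p^pumps$n_p + Ca_i^pumps$n_p)
}

#' @rdname pmca_flux
#' @export
ncx_flux <- function(Ca_i, pumps = pump_params()) {
  stopifnot(all(Ca_i >= 0))
  pumps$I_x * Ca_i^pumps$n_x / (pumps$H_x^pumps$n_x_den + Ca_i^pumps$n_x_den)
}

#' Total membrane calcium flux density on the channel zone
#'
#' The composite inward-positive molar flux density (uM*um/s) on channel
#' faces: gated VGCC influx (current converted by `1/(zF)` and
#' `1 mol = 1e21 uM*um^3`), minus PMCA and NCX extrusion, plus the
#' constant leak. All terms act only on the channel zone C.
#'
#' @param V membrane potential (mV).
#' @param state gating state.
#' @param Ca_i intracellular calcium at the membrane (uM), vectorized
#'   (one value per channel face).
#' @param kin kinetic parameters ([kinetic_params()]) supplying `Ca_e`.
#' @param channel,pumps,consts model parameters.
#' @param rho_vgcc channel surface density (um^-2).
#' @return inward-positive flux density (uM*um/s), same length as `Ca_i`.
#' @export
total_membrane_flux <- function(V, state, Ca_i, kin,
                                channel, pumps, rho_vgcc,
                                consts = physical_constants()) {
  influx <- -gating_G(state, channel) *
    ghk_molar_efflux(V, Ca_i, kin$Ca_e, channel, consts)
  rho_vgcc * influx -
    pumps$rho_pmca * pmca_flux(Ca_i, pumps) * MOL_TO_UMUM3 -
    pumps$rho_ncx * ncx_flux(Ca_i, pumps) * MOL_TO_UMUM3 +
    pumps$leak_flux
}

#' Calibrate the membrane leak
#'
#' Returns pump parameters whose constant leak flux density exactly
#' balances the resting VGCC current and the pump extrusion at the resting
#' potential and resting calcium, so that the net membrane flux at rest is
#' zero and the resting state is a steady state of the full model.
#'
#' @param kin [kinetic_params()] (supplies `Ca_V0`, `Ca_e`).
#' @param channel,pumps,consts model parameters.
#' @param rho_vgcc channel density (um^-2).
#' @param V_rest resting potential (mV).
#' @return `pumps` with `leak_flux` set.
#' @export
calibrate_leak <- function(kin, channel, pumps, rho_vgcc, V_rest,
                           consts = physical_constants()) {
  state <- gating_state(channel, V_rest, consts)
  p0 <- pumps
  p0$leak_flux <- 0
  net <- total_membrane_flux(V_rest, state, kin$Ca_V0, kin,
                             channel, p0, rho_vgcc, consts)
  pumps$leak_flux <- -net
  pumps
}

#' Action-potential train specification
#'
#' A periodic spike train: a difference-of-exponentials depolarization
#' riding on the resting potential, one spike per period, resting voltage
#' between spikes. The template is shifted so it reaches `V_rest`
#' continuously at the end of its support and normalized so it peaks at
#' `V_peak`. The default time constants give a spike a few milliseconds
#' wide, typical of the larval neuromuscular junction, and place the peak
#' calcium influx about 4 ms after spike onset.
#'
#' @param frequency spike rate (Hz).
#' @param duration total stimulation time (s); voltage is `V_rest` for
#'   `t` beyond the last requested spike as well.
#' @param V_rest,V_peak resting and peak potential (mV).
#' @param tau_rise,tau_decay waveform time constants (s).
#' @param support spike support (s); the waveform returns to `V_rest` at
#'   this time within each period. Must be shorter than the period.
#' @param waveform optional measured spike template overriding the
#'   analytic one: a data.frame with columns `time` (s, from spike
#'   onset) and `voltage` (mV), or the path of a CSV file with those
#'   columns. Values are interpolated linearly within the template
#'   support; outside it the voltage is `V_rest`.
#' @return list of class `az_train`.
#' @export
ap_train <- function(frequency = 40, duration = 0.005,
                     V_rest = -70, V_peak = 20,
                     tau_rise = 1e-3, tau_decay = 2.5e-3,
                     support = 8e-3, waveform = NULL) {
  if (!is.null(waveform)) {
    if (is.character(waveform))
      waveform <- utils::read.csv(waveform)
    stopifnot(all(c("time", "voltage") %in% names(waveform)),
              !is.unsorted(waveform$time))
    support <- max(waveform$time)
    V_rest <- waveform$voltage[1]
  }
  stopifnot(frequency > 0, duration > 0, tau_decay > tau_rise,
            support < 1 / frequency)
  ## difference of exponentials with a linear taper so the waveform is
  ## exactly V_rest at spike onset and at the end of the support
  w <- function(s) exp(-s / tau_decay) - exp(-s / tau_rise)
  w_end <- w(support)
  sfine <- seq(0, support, length.out = 4001)
  norm <- max(w(sfine) - (sfine / support) * w_end)
  structure(list(frequency = frequency, duration = duration,
                 V_rest = V_rest, V_peak = V_peak,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 support = support, norm = norm, w_end = w_end,
                 waveform = waveform),
            class = "az_train")
}

#' Membrane voltage of an action-potential train
#'
#' @param t time (s), vectorized; spike onsets at `k / frequency`,
#'   `k = 0, 1, 2, ...`.
#' @param train an [ap_train()]; if `NULL`, returns `V_rest`.
#' @return voltage (mV).
#' @export
ap_voltage <- function(t, train) {
  stopifnot(all(t >= -1e-15))
  if (is.null(train)) return(rep(-70, length(t)))
  s <- t - floor(t * train$frequency + 1e-12) / train$frequency
  v <- rep(train$V_rest, length(t))
  on <- s < train$support & t < train$duration
  if (any(on)) {
    if (!is.null(train$waveform)) {
      v[on] <- stats::approx(train$waveform$time, train$waveform$voltage,
                             xout = s[on], rule = 2)$y
    } else {
      amp <- (train$V_peak - train$V_rest) / train$norm
      v[on] <- train$V_rest +
        amp * (exp(-s[on] / train$tau_decay) -
                 exp(-s[on] / train$tau_rise) -
                 (s[on] / train$support) * train$w_end)
    }
  }
  v
}
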