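#' Evaluation circle around the T-bar socket
#'
#' A ring of sample points at radius `R = n_r * delta_r` and height
#' `H = n_h * delta_h` centered on the vertical axis through the T-bar
#' base point (virtual in scenarios without a T-bar). The circle's
#' average concentration is the standard microdomain read-out.
#'
#' @param base_point floor center (um), typically `grid$base_point`.
#' @param n_r,n_h positive integers selecting radius and height rungs.
#' @param delta_r,delta_h raster spacings (um).
#' @param n_phi_max number of evenly spaced points on the circle (>= 4;
#'   64 by default so the circles are finely resolved).
#' @return object of class `az_probe` with derived `R` and `H`.
#' @export
circle_probe <- function(base_point, n_r, n_h,
                         delta_r = 0.01, delta_h = 0.01,
                         n_phi_max = 64L) {
  stopifnot(n_r >= 1, n_h >= 1, delta_r > 0, delta_h > 0, n_phi_max >= 4)
  structure(list(base_point = base_point, n_r = n_r, n_h = n_h,
                 delta_r = delta_r, delta_h = delta_h,
                 n_phi_max = as.integer(n_phi_max),
                 R = n_r * delta_r, H = n_h * delta_h),
            class = "az_probe")
}

#' Sample points of an evaluation circle
#'
#' @param probe an `az_probe`.
#' @param grid optional `az_grid`; if given, every point is validated to
#'   lie inside the box and outside the obstacle (and outside the leg
#'   socket radius when a leg exists), otherwise the probe is rejected.
#' @return `n_phi_max` x 3 matrix of coordinates (um).
#' @export
circle_points <- function(probe, grid = NULL) {
  phi <- 2 * pi * (seq_len(probe$n_phi_max) - 1) / probe$n_phi_max
  pts <- cbind(probe$base_point[1] + probe$R * cos(phi),
               probe$base_point[2] + probe$R * sin(phi),
               probe$base_point[3] + probe$H)
  if (!is.null(grid)) {
    spec <- grid$spec
    if (spec$has_tbar && probe$R <= spec$leg_diameter / 2)
      stop(sprintf("evaluation radius %g um lies inside the T-bar socket",
                   probe$R))
    if (any(pts[, 1] <= 0 | pts[, 1] >= grid$box[1] |
              pts[, 2] <= 0 | pts[, 2] >= grid$box[2] |
              pts[, 3] <= 0 | pts[, 3] >= grid$box[3]))
      stop("circle points fall outside the computational box")
    rel <- cbind(pts[, 1] - grid$base_point[1],
                 pts[, 2] - grid$base_point[2], pts[, 3])
    if (any(tbar_inside(spec, rel[, 1], rel[, 2], rel[, 3], open = TRUE)))
      stop("circle points fall inside the obstacle")
  }
  pts
}

## Trilinear interpolation weights from cell-centered values for a set of
## points. Stencil corners that are obstacle cells or outside the grid are
## dropped and the remaining weights renormalized (nearest-fluid
## fallback); each such point is flagged.
interp_weights <- function(grid, pts) {
  h <- grid$h
  sh <- grid$shape
  n <- nrow(pts)
  ii <- jj <- ww <- vector("list", n)
  flagged <- logical(n)
  for (p in seq_len(n)) {
    g <- pts[p, ] / h - 0.5   # fractional cell-center coordinates (0-based)
    i0 <- floor(g)
    fr <- g - i0
    cw <- numeric(8)
    cells <- integer(8)
    ok <- logical(8)
    m <- 0L
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      m <- m + 1L
      ci <- i0 + c(dx, dy, dz)  # 0-based cell index
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      cw[m] <- w
      inb <- all(ci >= 0) && all(ci < sh)
      if (inb) {
        lin <- 1L + ci[1] + sh[1] * (ci[2] + sh[2] * ci[3])
        cells[m] <- lin
        ok[m] <- grid$fluid[lin]
      }
    }
    if (!any(ok & cw > 0))
      stop("interpolation stencil entirely inside obstacle/outside box")
    keep <- ok & cw > 0
    flagged[p] <- any(!ok & cw > 1e-14)
    wsum <- sum(cw[keep])
    ii[[p]] <- rep.int(p, sum(keep))
    jj[[p]] <- cells[keep]
    ww[[p]] <- cw[keep] / wsum
  }
  list(W = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                x = unlist(ww),
                                dims = c(n, prod(sh))),
       flagged = flagged)
}

#' Circle-averaged concentration
#'
#' Arithmetic mean of trilinearly interpolated cell-centered field values
#' over the circle's sample points. Interpolation stencils touching
#' obstacle cells fall back to the fluid part of the stencil
#' (renormalized weights); the result carries a `flagged` attribute when
#' that happened.
#'
#' @param field an `az_fields` or a numeric array on the grid (uM).
#' @param probe an `az_probe`.
#' @param grid the `az_grid` the field lives on.
#' @return scalar average (uM).
#' @export
circle_average <- function(field, probe, grid) {
  arr <- if (inherits(field, "az_fields")) field$Ca else field
  pts <- circle_points(probe, grid)
  iw <- interp_weights(grid, pts)
  val <- mean(as.numeric(iw$W %*% as.numeric(arr)))
  attr(val, "flagged") <- any(iw$flagged)
  val
}

## Assemble the probe set of a scenario config into one sparse operator:
## row r of P gives the circle average of probe r as P %*% field.
build_probe_set <- function(grid, probes_spec) {
  Rv <- probes_spec$R
  Hv <- probes_spec$H
  combos <- expand.grid(R = Rv, H = Hv)
  n_phi <- probes_spec$n_phi_max %||% 64L
  rows <- vector("list", nrow(combos))
  flags <- logical(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    pr <- circle_probe(grid$base_point,
                       n_r = 1, n_h = 1,
                       delta_r = combos$R[r], delta_h = combos$H[r],
                       n_phi_max = n_phi)
    pts <- circle_points(pr, grid)
    iw <- interp_weights(grid, pts)
    rows[[r]] <- Matrix::colSums(iw$W) / nrow(pts)
    flags[r] <- any(iw$flagged)
  }
  P <- do.call(rbind, lapply(rows, function(x)
    Matrix::sparseMatrix(i = rep(1L, sum(x != 0)), j = which(x != 0),
                         x = x[x != 0], dims = c(1L, prod(grid$shape)))))
  labels <- sprintf("R%.3f_H%.3f", combos$R, combos$H)
  ## flat triplet form for the cheap per-step evaluation
  jj <- lapply(rows, function(x) which(x != 0))
  list(P = P, labels = labels, flagged = flags,
       idx = unlist(jj),
       w = unlist(lapply(rows, function(x) x[x != 0])),
       grp = rep(seq_along(rows), lengths(jj)),
       n_probe = length(rows),
       meta = data.frame(probe = labels, R = combos$R, H = combos$H,
                         flagged = flags))
}

probe_values <- function(probes, arr) {
  if (!is.null(probes$idx)) {
    v <- arr[probes$idx] * probes$w
    as.numeric(rowsum(v, probes$grp, reorder = TRUE))
  } else {
    as.numeric(probes$P %*% as.numeric(arr))
  }
}

#' Per-period concentration peaks of a time series
#'
#' Splits the trace into action-potential period windows aligned to spike
#' onsets and reports the maximum within each window. A flat window
#' yields its first sample with zero prominence and is flagged.
#'
#' @param times sample times (s), strictly increasing.
#' @param values concentrations (uM).
#' @param train the [ap_train()] defining the period windows.
#' @param allow_partial accept a trace that ends inside a period window
#'   (used for runs truncated just after a peak of interest).
#' @return data.frame with `period`, `time`, `value`, `prominence`,
#'   `flat`.
#' @export
detect_peaks <- function(times, values, train, allow_partial = FALSE) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  per <- 1 / train$frequency
  if (!allow_partial && max(times) < per - 1e-9)
    stop("time series shorter than one action-potential period")
  win <- floor(times / per + 1e-9)
  out <- lapply(sort(unique(win)), function(w) {
    sel <- which(win == w)
    k <- sel[which.max(values[sel])]
    prom <- max(values[sel]) - min(values[sel])
    data.frame(period = w + 1L, time = times[k], value = values[k],
               prominence = prom, flat = prom <= 0)
  })
  do.call(rbind, out)
}

## Peak table over all probes of a result (plus the subdomain-U average).
result_peaks <- function(res, train) {
  tabs <- lapply(seq_len(ncol(res$probes)), function(j) {
    pk <- detect_peaks(res$times, res$probes[, j], train,
                       allow_partial = TRUE)
    pk$probe <- colnames(res$probes)[j]
    pk$R <- res$probe_meta$R[j]
    pk$H <- res$probe_meta$H[j]
    pk
  })
  pkU <- detect_peaks(res$times, res$U_avg, train, allow_partial = TRUE)
  pkU$probe <- "U"
  pkU$R <- NA_real_
  pkU$H <- NA_real_
  do.call(rbind, c(tabs, list(pkU)))
}

## Concentration at the recorded time nearest to `t`.
value_at_time <- function(res, t) {
  k <- which.min(abs(res$times - t))
  res$probes[k, ]
}

#' Compare the three anatomical scenarios at matched peaks
#'
#' Computes, at one (R, H) probe and one action-potential period, the
#' percent excess of the T-bar scenario over the no-T-bar clustered
#' scenario, and the fold ratios of the T-bar scenario over both
#' alternatives. Peaks are matched per scenario (each scenario's own peak
#' time within the period window); baseline-subtracted variants
#' (peak minus resting calcium) are reported alongside.
#'
#' @param tbar,clustered,dispersed `az_result` objects for the three
#'   presets (`dispersed` may be `NULL`).
#' @param R,H probe radius and height (um).
#' @param peak_index action-potential period number (1 = first spike).
#' @return one-row data.frame of class `az_comparison`.
#' @export
scenario_ratios <- function(tbar, clustered, dispersed = NULL,
                            R = 0.03, H = 0.01, peak_index = 1L) {
  check_comparable(tbar, clustered)
  if (!is.null(dispersed)) check_comparable(tbar, dispersed)
  pk <- function(res) {
    sel <- res$peaks$R == R & res$peaks$H == H &
      res$peaks$period == peak_index
    if (!any(sel, na.rm = TRUE))
      stop(sprintf("no peak recorded at R = %g, H = %g, period %d",
                   R, H, peak_index))
    res$peaks[which(sel), ]
  }
  ca0 <- tbar$config$kinetics$Ca_V0
  pT <- pk(tbar); pC <- pk(clustered)
  out <- data.frame(
    R = R, H = H, peak_index = peak_index,
    tbar = pT$value, no_tbar_clustered = pC$value,
    excess_pct = 100 * (pT$value - pC$value) / pC$value,
    fold_clustered = pT$value / pC$value,
    excess_pct_baseline_sub =
      100 * ((pT$value - ca0) - (pC$value - ca0)) / (pC$value - ca0),
    t_peak_tbar = pT$time, t_peak_clustered = pC$time)
  if (!is.null(dispersed)) {
    pD <- pk(dispersed)
    out$no_tbar_dispersed <- pD$value
    out$fold_dispersed <- pT$value / pD$value
    out$fold_dispersed_baseline_sub <- (pT$value - ca0) / (pD$value - ca0)
    out$t_peak_dispersed <- pD$time
  }
  class(out) <- c("az_comparison", "data.frame")
  out
}

## Scenario results are only comparable when probes, stimulation and
## kinetics agree.
check_comparable <- function(a, b) {
  if (!identical(a$probe_meta[c("R", "H")], b$probe_meta[c("R", "H")]))
    stop("scenario results have different probe sets")
  if (!identical(a$config$kinetics, b$config$kinetics))
    stop("scenario results have different kinetic parameters")
  tra <- a$config$train; trb <- b$config$train
  if (!identical(tra[names(tra) != "duration"],
                 trb[names(trb) != "duration"]) ||
      !identical(tra$duration, trb$duration))
    stop("scenario results have different stimulation trains")
  invisible(TRUE)
}

#' Radial concentration profile at fixed height and time
#'
#' @param res an `az_result`.
#' @param H probe height (um).
#' @param t evaluation time (s); the nearest recorded sample is used.
#' @return data.frame with `R` and `value` (uM), ordered by radius.
#' @export
radial_profile <- function(res, H, t) {
  sel <- which(res$probe_meta$H == H)
  if (!length(sel)) stop(sprintf("no probes at H = %g um", H))
  v <- value_at_time(res, t)[sel]
  out <- data.frame(R = res$probe_meta$R[sel], value = as.numeric(v))
  out[order(out$R), ]
}

#' Average concentration in the under-roof subdomain
#'
#' Volume-weighted mean of the calcium field over the subdomain below the
#' (virtual) T-bar roof.
#'
#' @param field an `az_fields` or numeric array (uM).
#' @param U an `az_subU` from [subdomain_U()].
#' @return scalar (uM).
#' @export
subdomain_U_average <- function(field, U) {
  if (nrow(U$cells) == 0) stop("subdomain U is empty")
  arr <- if (inherits(field, "az_fields")) field$Ca else field
  mean(arr[U$cells])
}

#' Relative differences of probe values across grid-refinement levels
#'
#' For nested refinement levels (spacing halved between consecutive
#' levels, identical physical configuration) computes the successive
#' relative differences `|v_l - v_{l+1}| / |v_{l+1}|` per probe.
#'
#' @param values list of per-level numeric vectors (same probes, same
#'   order), coarsest first.
#' @param h_levels grid spacings (um), one per level.
#' @return list with `rel_diff` (matrix levels-1 x probes) and
#'   `max_rel_diff` per level pair.
#' @export
grid_convergence <- function(values, h_levels) {
  stopifnot(length(values) >= 2, length(values) == length(h_levels))
  r <- h_levels[-length(h_levels)] / h_levels[-1]
  if (any(abs(r - 2) > 1e-9))
    stop("refinement levels are not nested with ratio 2")
  nlev <- length(values)
  rd <- t(vapply(seq_len(nlev - 1), function(l) {
    abs(values[[l]] - values[[l + 1]]) / abs(values[[l + 1]])
  }, numeric(length(values[[1]]))))
  if (length(values[[1]]) == 1L) rd <- matrix(rd, ncol = 1L)
  list(rel_diff = rd, max_rel_diff = apply(rd, 1, max))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
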