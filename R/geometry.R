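#' Parametric active-zone geometry specification
#'
#' Describes one presynaptic active-zone anatomy: a rectangular cuboid of
#' cytosol whose floor is the presynaptic membrane, optionally bearing a
#' T-bar obstacle (a cylindrical leg topped by a thin circular roof), and a
#' channel zone on the floor where voltage-gated calcium channels sit.
#' All lengths are in micrometres.
#'
#' The default dimensions are the typical T-bar measures from EM images:
#' roof ("table desk") diameter 140 nm, roof thickness 10 nm, leg height
#' 40 nm, leg diameter 30 nm. The clustered channel zone is an annulus
#' around the (possibly virtual) leg socket with outer diameter 70 nm; the
#' dispersed zone is a full disk of diameter 140 nm.
#'
#' @param box_dims numeric length-3, cuboid dimensions (um).
#' @param has_tbar logical, is the T-bar obstacle present?
#' @param roof_diameter,roof_thickness,leg_height,leg_diameter T-bar
#'   measures (um).
#' @param channels_clustered logical; clustered channels occupy an annulus
#'   around the (virtual) socket, dispersed channels a full disk.
#' @param channel_zone_outer_diameter outer diameter of the channel zone
#'   (um). Defaults to 0.07 for clustered and 0.14 for dispersed channels.
#' @param n_channels number of voltage-gated calcium channels spread
#'   uniformly over the zone.
#' @return An object of class `az_geometry`.
#' @export
geometry_spec <- function(box_dims = c(1.2, 1.2, 0.6),
                          has_tbar = TRUE,
                          roof_diameter = 0.14,
                          roof_thickness = 0.01,
                          leg_height = 0.04,
                          leg_diameter = 0.03,
                          channels_clustered = TRUE,
                          channel_zone_outer_diameter = if (channels_clustered) 0.07 else 0.14,
                          n_channels = 6L) {
  stopifnot(length(box_dims) == 3L, all(box_dims > 0),
            roof_diameter > leg_diameter, leg_diameter > 0,
            leg_height > 0, roof_thickness > 0,
            channel_zone_outer_diameter > 0, n_channels >= 1)
  if (channel_zone_outer_diameter > min(box_dims[1:2]))
    stop("channel zone does not fit inside the box footprint")
  if (has_tbar && leg_height + roof_thickness > box_dims[3])
    stop("T-bar taller than the box")
  structure(list(
    box_dims = as.numeric(box_dims),
    has_tbar = isTRUE(has_tbar),
    roof_diameter = roof_diameter,
    roof_thickness = roof_thickness,
    leg_height = leg_height,
    leg_diameter = leg_diameter,
    channels_clustered = isTRUE(channels_clustered),
    channel_zone_outer_diameter = channel_zone_outer_diameter,
    n_channels = as.integer(n_channels)
  ), class = "az_geometry")
}

#' @export
print.az_geometry <- function(x, ...) {
  cat("Active-zone geometry\n")
  cat(sprintf("  box: %.3g x %.3g x %.3g um, T-bar: %s\n",
              x$box_dims[1], x$box_dims[2], x$box_dims[3],
              if (x$has_tbar) "present" else "absent"))
  cat(sprintf("  channel zone: %s, outer diameter %g nm, %d channels\n",
              if (x$channels_clustered) "clustered (annulus)" else "dispersed (disk)",
              1000 * x$channel_zone_outer_diameter, x$n_channels))
  invisible(x)
}

## Point-in-solid test for the analytic T-bar (leg cylinder + roof disk).
## Coordinates relative to the T-bar base point on the floor.
tbar_inside <- function(spec, dx, dy, z, open = FALSE) {
  if (!spec$has_tbar) return(rep(FALSE, length(dx)))
  r2 <- dx^2 + dy^2
  if (open) {
    ## strict interior: points on the solid's surface count as fluid
    leg <- r2 < (spec$leg_diameter / 2)^2 & z > 0 & z < spec$leg_height
    roof <- r2 < (spec$roof_diameter / 2)^2 &
      z > spec$leg_height & z < spec$leg_height + spec$roof_thickness
  } else {
    leg <- r2 < (spec$leg_diameter / 2)^2 & z >= 0 & z < spec$leg_height
    roof <- r2 < (spec$roof_diameter / 2)^2 &
      z >= spec$leg_height & z < spec$leg_height + spec$roof_thickness
  }
  leg | roof
}

#' Voxelize an active-zone geometry
#'
#' Realizes an [geometry_spec()] as a uniform cell-centered Cartesian voxel
#' grid. A cell is an obstacle cell exactly when its center lies inside the
#' analytic T-bar solid (staircase approximation); all other cells are
#' fluid. The T-bar base point (center of the floor) anchors the evaluation
#' circles and the subdomain below the roof.
#'
#' @param spec an `az_geometry`.
#' @param h uniform grid spacing (um). Must tile all box dimensions and
#'   must not exceed the roof thickness, so the roof spans at least one
#'   cell layer.
#' @return An object of class `az_grid` with fields `h`, `shape`, `box`,
#'   `origin`, `fluid` (logical array), `base_point`, and `spec`.
#' @export
build_geometry <- function(spec, h) {
  stopifnot(inherits(spec, "az_geometry"), h > 0)
  n <- spec$box_dims / h
  if (any(abs(n - round(n)) > 1e-9 * pmax(1, n)))
    stop(sprintf("spacing h = %g um does not tile the box %s um",
                 h, paste(spec$box_dims, collapse = " x ")))
  if (spec$has_tbar && h > spec$roof_thickness + 1e-12)
    stop(sprintf("h = %g um does not resolve the roof thickness %g um",
                 h, spec$roof_thickness))
  shape <- as.integer(round(n))
  base_point <- c(spec$box_dims[1] / 2, spec$box_dims[2] / 2, 0)
  cx <- (seq_len(shape[1]) - 0.5) * h - base_point[1]
  cy <- (seq_len(shape[2]) - 0.5) * h - base_point[2]
  cz <- (seq_len(shape[3]) - 0.5) * h
  fluid <- array(TRUE, dim = shape)
  if (spec$has_tbar) {
    ## only columns near the axis can hold obstacle cells
    rmax <- spec$roof_diameter / 2
    ix <- which(abs(cx) < rmax)
    iy <- which(abs(cy) < rmax)
    iz <- which(cz < spec$leg_height + spec$roof_thickness)
    g <- expand.grid(i = ix, j = iy, k = iz)
    inside <- tbar_inside(spec, cx[g$i], cy[g$j], cz[g$k])
    if (any(inside)) {
      sel <- g[inside, ]
      fluid[cbind(sel$i, sel$j, sel$k)] <- FALSE
    }
  }
  structure(list(
    h = h, shape = shape, box = spec$box_dims, origin = c(0, 0, 0),
    fluid = fluid, base_point = base_point, spec = spec
  ), class = "az_grid")
}

#' @export
print.az_grid <- function(x, ...) {
  cat(sprintf("Voxel grid %d x %d x %d (h = %g nm), %d obstacle cells\n",
              x$shape[1], x$shape[2], x$shape[3], 1000 * x$h,
              sum(!x$fluid)))
  invisible(x)
}

## Cell-center coordinates relative to the T-bar axis / floor.
grid_centers <- function(grid) {
  h <- grid$h
  list(cx = (seq_len(grid$shape[1]) - 0.5) * h - grid$base_point[1],
       cy = (seq_len(grid$shape[2]) - 0.5) * h - grid$base_point[2],
       cz = (seq_len(grid$shape[3]) - 0.5) * h)
}

#' Classify boundary faces of a voxel grid
#'
#' Partitions the domain boundary into the face sets used by the membrane
#' flux conditions: `C`, the floor faces carrying channel flux; `B`, the
#' remaining floor; `W`, the Dirichlet side and top walls; and `T`, the
#' fluid-obstacle interface, which like `B` is a zero-flux surface.
#'
#' Channel faces are the floor faces whose centers lie inside the channel
#' zone: an annulus between the (virtual) leg socket radius and the zone
#' outer radius for clustered channels, a full disk for dispersed channels.
#' The clustered no-T-bar case keeps the same annular footprint as the
#' T-bar case so that the two scenarios differ only in the obstacle.
#'
#' @param grid an `az_grid`.
#' @param spec the `az_geometry` (defaults to the one embedded in `grid`).
#' @return An object of class `az_faces`: `C` is a data.frame with cell
#'   indices (`i`,`j`), radii and face area; `area_C`, `area_B` are the
#'   discretized areas; `area_C_analytic` the analytic zone area; `n_T` the
#'   number of fluid-obstacle interface faces; `rho_vgcc` the channel
#'   density derived as `n_channels / area_C`.
#' @export
classify_faces <- function(grid, spec = grid$spec) {
  stopifnot(inherits(grid, "az_grid"))
  h <- grid$h
  cc <- grid_centers(grid)
  r <- sqrt(outer(cc$cx^2, cc$cy^2, `+`))
  r_out <- spec$channel_zone_outer_diameter / 2
  r_in <- if (spec$channels_clustered) spec$leg_diameter / 2 else 0
  in_zone <- r >= r_in & r < r_out & grid$fluid[, , 1]
  if (!any(in_zone))
    stop("channel zone smaller than one floor face; refine the grid")
  idx <- which(in_zone, arr.ind = TRUE)
  Cfaces <- data.frame(i = idx[, 1], j = idx[, 2],
                       r = r[idx], area = h^2)
  n_floor <- prod(grid$shape[1:2])
  area_C <- nrow(Cfaces) * h^2
  area_analytic <- pi * (r_out^2 - r_in^2)
  ## fluid-obstacle interface faces (T): count faces between fluid and
  ## obstacle cells plus obstacle floor faces (the leg stands on the floor)
  f <- grid$fluid
  n_T <- 0L
  if (any(!f)) {
    nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
    n_T <- sum(f[-nx, , ] != f[-1, , ]) + sum(f[, -ny, ] != f[, -1, ]) +
      sum(f[, , -nz] != f[, , -1]) + sum(!f[, , 1])
  }
  structure(list(
    C = Cfaces,
    area_C = area_C,
    area_B = n_floor * h^2 - area_C,
    area_C_analytic = area_analytic,
    r_in = r_in, r_out = r_out,
    n_T = n_T,
    rho_vgcc = spec$n_channels / area_C
  ), class = "az_faces")
}

#' @export
print.az_faces <- function(x, ...) {
  cat(sprintf("Boundary faces: %d channel faces, area(C) = %.4g um^2 (analytic %.4g)\n",
              nrow(x$C), x$area_C, x$area_C_analytic))
  cat(sprintf("  derived channel density: %.1f um^-2\n", x$rho_vgcc))
  invisible(x)
}

#' Subdomain below the (virtual) T-bar roof
#'
#' The fluid cells whose centers lie inside the cylinder of the roof
#' footprint and below the roof height. With a T-bar present the leg cells
#' are excluded automatically (they are not fluid); without a T-bar the
#' same virtual cylinder is used, leg included.
#'
#' @param grid an `az_grid`.
#' @param spec the geometry (defaults to the grid's).
#' @return Object of class `az_subU`: `cells` (matrix of array indices),
#'   `volume` (um^3).
#' @export
subdomain_U <- function(grid, spec = grid$spec) {
  cc <- grid_centers(grid)
  r2 <- outer(cc$cx^2, cc$cy^2, `+`)
  member <- array(FALSE, dim = grid$shape)
  kz <- which(cc$cz < spec$leg_height)
  for (k in kz) member[, , k] <- r2 < (spec$roof_diameter / 2)^2
  member <- member & grid$fluid
  idx <- which(member, arr.ind = TRUE)
  structure(list(cells = idx, volume = nrow(idx) * grid$h^3),
            class = "az_subU")
}

## Obstacle volume of the grid (um^3), staircase measure.
obstacle_volume <- function(grid) sum(!grid$fluid) * grid$h^3

## Analytic T-bar solid volume (um^3).
tbar_volume_analytic <- function(spec) {
  if (!spec$has_tbar) return(0)
  pi * ((spec$leg_diameter / 2)^2 * spec$leg_height +
          (spec$roof_diameter / 2)^2 * spec$roof_thickness)
}
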