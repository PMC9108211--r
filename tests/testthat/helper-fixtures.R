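## Small deterministic fixtures shared across test files. Everything is
## generated in code; the expensive shared simulation runs are memoized in
## `.run_cache` so several test files can reuse them within one session.

.run_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

## a small box that still contains the full T-bar and the default probes
mini_geometry <- function(has_tbar = TRUE, clustered = TRUE) {
  geometry_spec(box_dims = c(0.24, 0.24, 0.12), has_tbar = has_tbar,
                channels_clustered = clustered)
}

mini_probes <- list(R = c(0.02, 0.03, 0.04), H = c(0.01, 0.04),
                    n_phi_max = 32L)

## fast scenario config on the small box (7 ms reaches past the first
## 40 Hz calcium peak at ~4.2 ms)
mini_config <- function(name = "tbar_clustered", frequency = 40,
                        t_end = 0.007, h = 0.01, ...) {
  geo <- switch(name,
    tbar_clustered = mini_geometry(TRUE, TRUE),
    no_tbar_clustered = mini_geometry(FALSE, TRUE),
    no_tbar_dispersed = mini_geometry(FALSE, FALSE))
  scenario_config(geometry = geo, h = h,
                  train = ap_train(frequency = frequency,
                                   duration = t_end),
                  t_end = t_end, probes = mini_probes,
                  label = name, ...)
}

mini_run <- function(name, frequency = 40, t_end = 0.007, ...) {
  extra <- paste(deparse(substitute(list(...))), collapse = "")
  key <- sprintf("mini_%s_%g_%g_%s", name, frequency, t_end, extra)
  memo(key, run_scenario(mini_config(name, frequency, t_end, ...)))
}

## the three desk-scale runs (reduced box, h = 10 nm) used by the
## quantitative scenario comparisons
desk_run <- function(name, frequency = 40, t_end = 0.006) {
  key <- sprintf("desk_%s_%g_%g", name, frequency, t_end)
  memo(key, run_scenario(make_preset(
    name, box_mode = "reduced", h = 0.01, frequency = frequency,
    t_end = t_end,
    probes = list(R = c(0.03, 0.04), H = c(0.01, 0.02, 0.03, 0.04),
                  n_phi_max = 64L))))
}

## independent point-in-solid predicate for the geometry oracle tests,
## deliberately written differently from the package internals
oracle_in_tbar <- function(x, y, z, cx, cy) {
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  in_leg <- (r < 0.015) && (z >= 0) && (z < 0.04)
  in_roof <- (r < 0.07) && (z >= 0.04) && (z < 0.05)
  in_leg || in_roof
}
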