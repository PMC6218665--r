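# End-to-end drivers for the three verification experiments. Each driver
# builds its protocol, runs it and reduces the output to the quantities of
# interest; they are what the acceptance script and the command-line
# front end call.

#' Rod conduction-velocity measurement
#'
#' Runs the [protocol_rod()] plane-wave experiment and measures CV from
#' the activation-time difference between the probes nearest x = 18 and
#' x = 22 mm (using the actual node coordinates). The run stops as soon as
#' both probes have activated.
#'
#' @param h element size (mm).
#' @param family element family.
#' @param scheme `"SI"` or `"FI"`.
#' @param dt time-step size (ms).
#' @param d_iso isotropic conductivity (mm^2/ms).
#' @param t_max run horizon (ms); an error is raised if the wave has not
#'   reached both probes by then.
#' @return list with `cv` (cm/s), probe activation times and coordinates,
#'   and the run metadata.
#' @export
rod_cv <- function(h, family = "Q1", scheme = "SI", dt = 0.001,
                   d_iso = 0.0952, t_max = 250) {
  cfg <- protocol_rod(h, family, dt, d_iso, t_max)
  cfg$scheme$type <- scheme
  built <- build_from_config(cfg)
  pidx <- resolve_probes(built$mesh, cfg$probes)
  res <- run_simulation(built$system, t_max, probes = pidx,
                        scheme = scheme, stop_nodes = pidx)
  tacts <- res$activation[pidx]
  x <- built$mesh$nodes[pidx, 1]
  cv <- conduction_velocity(tacts[1], tacts[2], x[1], x[2])
  list(cv = cv, h = h, family = element_family(family)$name,
       scheme = scheme, dt = dt,
       t1 = tacts[1], t2 = tacts[2], x1 = x[1], x2 = x[2],
       steps = res$steps, run = res, mesh = built$mesh)
}

#' Rod CV mesh-refinement sweep
#'
#' Repeats the rod experiment for a list of element sizes and reports the
#' CV per `h` together with the wall time (informational only).
#'
#' @param h_values element sizes (mm).
#' @inheritParams rod_cv
#' @param csv optional path; when given the table is also written as CSV.
#' @return data.frame with `h`, `cv` (cm/s) and `seconds`.
#' @export
cv_sweep <- function(h_values, family = "Q1", scheme = "SI", dt = 0.001,
                     d_iso = 0.0952, t_max = 250, csv = NULL) {
  rows <- lapply(h_values, function(h) {
    el <- system.time(r <- rod_cv(h, family, scheme, dt, d_iso, t_max))
    data.frame(h = h, cv = r$cv, seconds = unname(el["elapsed"]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE, quote = FALSE)
  out
}

#' Cuboid benchmark run
#'
#' Runs [protocol_cuboid()] and extracts the activation-time profile along
#' the corner-to-corner diagonal. The run stops once every node near the
#' diagonal has activated.
#'
#' @inheritParams rod_cv
#' @return list with the `mesh`, per-node `activation` times, and the
#'   diagonal `profile` data.frame.
#' @export
cuboid_experiment <- function(h, family = "Q1", dt = 0.02, t_max = 150) {
  cfg <- protocol_cuboid(h, family, dt, t_max)
  built <- build_from_config(cfg)
  mesh <- built$mesh
  dvec <- mesh$dimensions / sqrt(sum(mesh$dimensions^2))
  rel <- mesh$nodes
  s <- as.vector(rel %*% dvec)
  perp2 <- rowSums(rel^2) - s^2
  diag_nodes <- which(perp2 <= (max(mesh$elem_size) / 2)^2 + 1e-12)
  res <- run_simulation(built$system, t_max, scheme = "SI",
                        stop_nodes = diag_nodes)
  if (anyNA(res$activation[diag_nodes]))
    stop("cuboid wave did not reach the full diagonal within ", t_max, " ms")
  prof <- diagonal_profile(res$activation, mesh)
  list(mesh = mesh, activation = res$activation, profile = prof,
       h = h, family = element_family(family)$name, dt = dt,
       steps = res$steps)
}

# Interpolate a reference diagonal profile onto query arc lengths.
profile_interp <- function(profile, s) {
  stats::approx(profile$distance, profile$activation, xout = s,
                rule = 2)$y
}

#' S1-S2 spiral-wave run
#'
#' Runs [protocol_spiral()] to `t_end` and summarises the electrical state
#' at the end: the maximum normalized potential over the sheet and whether
#' any node is depolarized above threshold (sustained re-entrant
#' activity). Also records the maximum potential at S2 onset for
#' diagnostics.
#'
#' @inheritParams rod_cv
#' @param t_end final time (ms).
#' @return list with `max_phi_end`, `active_end` (any node above 0.5),
#'   `family`, and run metadata.
#' @export
spiral_experiment <- function(family = "Q1NC", h = 1, dt = 0.005,
                              t_end = 600) {
  cfg <- protocol_spiral(h, family, dt, t_end)
  built <- build_from_config(cfg)
  # once the whole sheet is sub-threshold after the last stimulus, the
  # state can only relax to rest, so the run may stop early
  last_stim <- max(vapply(cfg$stimuli, function(s) s$start + s$duration, 1))
  res <- run_simulation(built$system, t_end, scheme = "SI",
                        quiet_after = last_stim + 5)
  u <- res$state$u
  list(max_phi_end = max(u), active_end = any(u > 0.5),
       family = element_family(family)$name, h = h, dt = dt,
       t_end = t_end, t_stop = res$state$t, steps = res$steps,
       state = res$state, mesh = built$mesh)
}
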