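# Stimulus definitions, the ready-made experiment protocols, and the YAML
# run-configuration round trip.

#' Define a stimulus event
#'
#' Volume stimuli add a normalized current (1/ms) to the reaction at every
#' quadrature point inside the region; surface stimuli apply a Neumann
#' influx (mm/ms) on boundary faces selected by a plane region. Events are
#' active on `[start, start + duration)`.
#'
#' @param kind `"volume"` or `"surface"`.
#' @param region a [region_box()] (volume) or [region_plane()] (surface).
#' @param amplitude normalized amplitude (1/ms for volume, mm/ms for
#'   surface). Physical mV-scaled amplitudes can be converted with
#'   [normalize_stimulus()].
#' @param start onset time (ms).
#' @param duration duration (ms), `> 0`.
#' @export
stimulus <- function(kind = c("volume", "surface"), region, amplitude,
                     start = 0, duration) {
  kind <- match.arg(kind)
  if (!(duration > 0)) stop("stimulus duration must be positive")
  if (!is.finite(amplitude)) stop("stimulus amplitude must be finite")
  structure(list(kind = kind, region = as_region(region),
                 amplitude = amplitude, start = start, duration = duration),
            class = "monofem_stimulus")
}

#' Normalize a physical stimulus amplitude
#'
#' Divides mV-scaled amplitudes by the voltage span `V_p - V_r` (100 mV by
#' default) so they act on the normalized potential: `20 mV/ms` becomes
#' `0.2/ms` (volume), `12 mV/(ms mm^2)` becomes `0.12 mm/ms` (surface
#' flux).
#'
#' @param amplitude physical amplitude.
#' @param units one of `"mV/ms"`, `"mV/(ms*mm^2)"`, `"mV/(ms*mm^3)"`.
#' @param params ionic parameters providing `V_r`, `V_p`.
#' @return normalized amplitude.
#' @export
normalize_stimulus <- function(amplitude, units,
                               params = aliev_panfilov_params()) {
  canon <- gsub("[ .]", "", tolower(units))
  ok <- c("mv/ms", "mv/(ms*mm^2)", "mv/(msmm^2)", "mv/(ms*mm2)",
          "mv/(msmm2)", "mv/(ms*mm^3)", "mv/(msmm^3)", "mv/(ms*mm3)",
          "mv/(msmm3)")
  if (!(canon %in% ok))
    stop("unknown stimulus units: ", units)
  amplitude / (params$V_p - params$V_r)
}

# Quadrature-point coordinates of every element along one axis: nel x nq.
qp_coords_axis <- function(system, d) {
  rp <- gauss_rule(system$family$quad_points_per_axis)$points[, d]
  system$mesh$elem_origin[, d] +
    outer(system$mesh$elem_size[, d], (rp + 1) / 2)
}

# Nodal load vector of a unit Neumann influx on a set of boundary faces:
# integral of each basis function over the faces.
face_load_vector <- function(mesh, faces) {
  fam <- element_family(mesh$family)
  k <- fam$quad_points_per_axis
  g1 <- if (k == 2) list(x = c(-1, 1) / sqrt(3), w = c(1, 1)) else
    list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)
  fg <- expand.grid(a = g1$x, b = g1$x)
  fw <- expand.grid(wa = g1$w, wb = g1$w)
  out <- numeric(nrow(mesh$nodes))
  basis <- if (fam$name == "Q2") eval_q2_basis else eval_q1_basis
  for (i in seq_len(nrow(faces))) {
    e <- faces$elem[i]; fid <- faces$face[i]
    ax <- (fid + 1L) %/% 2L
    sgn <- if (fid %% 2L == 1L) -1 else 1
    free <- setdiff(1:3, ax)
    coords <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (q in seq_len(nrow(fg))) {
      xi <- numeric(3)
      xi[ax] <- sgn
      xi[free] <- c(fg$a[q], fg$b[q])
      b <- basis(xi)
      t1 <- as.vector(crossprod(coords, b$ref_gradients[, free[1]]))
      t2 <- as.vector(crossprod(coords, b$ref_gradients[, free[2]]))
      dS <- sqrt(sum(t1 * t1) * sum(t2 * t2) - sum(t1 * t2)^2)
      out[mesh$elems[e, ]] <- out[mesh$elems[e, ]] +
        fw$wa[q] * fw$wb[q] * dS * b$values
    }
  }
  out
}

#' Attach stimuli to an assembled system
#'
#' Precompiles each event: volume events become an (elements x quadrature
#' points) current matrix over the points inside the region; surface
#' events become a nodal boundary-load vector over the matching outer
#' faces. Stepping then only toggles precomputed contributions.
#'
#' @param system a [assemble_system()] object.
#' @param stimuli list of [stimulus()] events.
#' @return the system with compiled stimuli attached.
#' @export
compile_stimuli <- function(system, stimuli) {
  vol <- list(); surf <- list()
  nq <- ncol(system$Nval)
  tolc <- 1e-9
  for (s in stimuli) {
    if (s$kind == "volume") {
      reg <- s$region
      if (reg$type != "box") stop("volume stimuli use box regions")
      inside <- matrix(TRUE, system$nel, nq)
      for (d in 1:3) {
        xd <- qp_coords_axis(system, d)
        inside <- inside & xd >= reg$min[d] - tolc & xd <= reg$max[d] + tolc
      }
      if (!any(inside)) stop("volume stimulus region contains no ",
                             "quadrature points")
      vol[[length(vol) + 1L]] <- list(start = s$start,
                                      duration = s$duration,
                                      mat = s$amplitude * inside)
    } else {
      faces <- select_faces(system$mesh, s$region)
      surf[[length(surf) + 1L]] <- list(start = s$start,
                                        duration = s$duration,
                                        vec = s$amplitude *
                                          face_load_vector(system$mesh, faces))
    }
  }
  system$stim_vol <- vol
  system$stim_surf <- surf
  system$cache <- new.env(parent = emptyenv())
  system
}

#' Plane-wave rod protocol
#'
#' A 25 mm rod (one element of size `h` per transverse axis) with isotropic
#' conductivity, stimulated at the left end with a normalized volume
#' current of 0.2/ms for 2 ms; probes track the potential at x = 18 and
#' x = 22 mm for conduction-velocity measurement, all other boundaries
#' zero-flux. The stimulated slab spans the first element layer but at
#' least 0.5 mm, so fine meshes receive the same depolarizing charge as
#' coarse ones.
#'
#' @param h element size (mm).
#' @param family element family.
#' @param dt time-step size (ms).
#' @param d_iso isotropic normalized conductivity (mm^2/ms).
#' @param t_end simulation horizon (ms).
#' @return a run-configuration list (see [run_from_config()]).
#' @export
protocol_rod <- function(h, family = "Q1", dt = 0.001, d_iso = 0.0952,
                         t_end = 250) {
  depth <- max(h, 0.5)
  list(geometry = list(dimensions = c(25, h, h), h = h),
       family = element_family(family)$name,
       scheme = list(type = "SI", dt = dt, t_end = t_end),
       conductivity = list(d_l = d_iso, d_t = d_iso, fiber = c(1, 0, 0)),
       stimuli = list(list(kind = "volume",
                           region = list(type = "box", min = c(0, 0, 0),
                                         max = c(depth, h, h)),
                           amplitude = 0.2, start = 0, duration = 2)),
       probes = list(c(18, 0, 0), c(22, 0, 0)))
}

#' Anisotropic cuboid benchmark protocol
#'
#' A 20 x 7 x 3 mm block with fibers along the long axis (normalized
#' conductivities 0.0952 / 0.0126 mm^2/ms), stimulated for 2 ms in a
#' 1.5 mm corner cube with a normalized current of 0.357/ms (50000
#' microA/cm^3 on the rod protocol's 28000 microA/cm^3 = 0.2/ms scale).
#' Activation is analysed along the corner-to-corner diagonal.
#'
#' @inheritParams protocol_rod
#' @export
protocol_cuboid <- function(h, family = "Q1", dt = 0.02, t_end = 150) {
  amp <- 0.2 * 50000 / 28000
  list(geometry = list(dimensions = c(20, 7, 3), h = h),
       family = element_family(family)$name,
       scheme = list(type = "SI", dt = dt, t_end = t_end),
       conductivity = list(d_l = 0.0952, d_t = 0.0126, fiber = c(1, 0, 0)),
       stimuli = list(list(kind = "volume",
                           region = list(type = "box", min = c(0, 0, 0),
                                         max = c(1.5, 1.5, 1.5)),
                           amplitude = amp, start = 0, duration = 2)),
       probes = list(c(0, 0, 0), c(20, 7, 3)))
}

#' S1-S2 spiral-wave protocol
#'
#' A 50 x 50 mm sheet (one element thick, zero-flux top/bottom, so the 2-D
#' dynamics are exact): S1 is a surface influx of 0.12 mm/ms on the x = 0
#' border for 2 ms creating a plane wave; S2 is a volume current of
#' 0.15/ms in the quadrant x < 25, y < 25 mm applied at 280 ms for 5 ms,
#' timed into the repolarization tail so that the premature wave breaks
#' and curls into a spiral. Conductivity is isotropic 0.0952 mm^2/ms.
#'
#' @inheritParams protocol_rod
#' @export
protocol_spiral <- function(h = 1, family = "Q1NC", dt = 0.005,
                            t_end = 600) {
  list(geometry = list(dimensions = c(50, 50, h), h = h),
       family = element_family(family)$name,
       scheme = list(type = "SI", dt = dt, t_end = t_end),
       conductivity = list(d_l = 0.0952, d_t = 0.0952, fiber = c(1, 0, 0)),
       stimuli = list(list(kind = "surface",
                           region = list(type = "plane", axis = 1, value = 0),
                           amplitude = 0.12, start = 0, duration = 2),
                      list(kind = "volume",
                           region = list(type = "box", min = c(0, 0, 0),
                                         max = c(25, 25, h)),
                           amplitude = 0.15, start = 280, duration = 5)),
       probes = list(c(25, 25, 0)))
}

.config_keys <- list(
  top = c("geometry", "family", "scheme", "conductivity", "ionic",
          "stimuli", "probes", "output"),
  geometry = c("dimensions", "h"),
  scheme = c("type", "dt", "t_end", "newton_tol", "newton_max_iter",
             "snapshot_every"),
  conductivity = c("d_l", "d_t", "fiber"),
  stimulus = c("kind", "region", "amplitude", "units", "start", "duration"),
  region = c("type", "min", "max", "axis", "value", "tol"),
  output = c("directory", "snapshot_every"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Validate a run configuration
#'
#' Checks structure, units and positivity of every physical quantity
#' before any computation; unknown keys are errors so typos in physical
#' parameters cannot pass silently.
#'
#' @param config a configuration list (see [protocol_rod()] for shape).
#' @return the validated (normalized) configuration, invisibly.
#' @export
validate_run_config <- function(config) {
  check_keys(config, .config_keys$top, "config")
  for (k in c("geometry", "family", "scheme", "conductivity", "stimuli"))
    if (is.null(config[[k]])) stop("config is missing '", k, "'")
  check_keys(config$geometry, .config_keys$geometry, "geometry")
  if (length(config$geometry$dimensions) != 3 ||
      any(config$geometry$dimensions <= 0))
    stop("geometry$dimensions must be three positive lengths")
  if (!(config$geometry$h > 0)) stop("geometry$h must be positive")
  element_family(config$family)
  check_keys(config$scheme, .config_keys$scheme, "scheme")
  if (!config$scheme$type %in% c("SI", "FI"))
    stop("scheme$type must be SI or FI")
  if (!(config$scheme$dt > 0)) stop("scheme$dt must be positive")
  if (!(config$scheme$t_end > 0)) stop("scheme$t_end must be positive")
  check_keys(config$conductivity, .config_keys$conductivity, "conductivity")
  conductivity(config$conductivity$d_l,
               if (is.null(config$conductivity$d_t)) config$conductivity$d_l
               else config$conductivity$d_t,
               if (is.null(config$conductivity$fiber)) c(1, 0, 0)
               else config$conductivity$fiber)
  if (!is.null(config$ionic)) as_ionic_params(config$ionic)
  for (i in seq_along(config$stimuli)) {
    s <- config$stimuli[[i]]
    check_keys(s, .config_keys$stimulus, paste0("stimuli[[", i, "]]"))
    check_keys(s$region, .config_keys$region,
               paste0("stimuli[[", i, "]]$region"))
    if (!s$kind %in% c("volume", "surface"))
      stop("stimulus kind must be volume or surface")
    if (!(s$duration > 0)) stop("stimulus duration must be positive")
  }
  if (!is.null(config$output))
    check_keys(config$output, .config_keys$output, "output")
  invisible(config)
}

#' Write / read a run configuration as YAML
#'
#' The round trip is exact for every protocol shipped with the package.
#' @param config a configuration list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_run_config(config)
  config
}

# Build mesh + system + stimuli from a validated configuration.
build_from_config <- function(config) {
  validate_run_config(config)
  mesh <- build_box_mesh(config$geometry$dimensions, config$geometry$h,
                         config$family)
  cond <- conductivity(config$conductivity$d_l,
                       if (is.null(config$conductivity$d_t))
                         config$conductivity$d_l
                       else config$conductivity$d_t,
                       if (is.null(config$conductivity$fiber)) c(1, 0, 0)
                       else config$conductivity$fiber)
  params <- if (is.null(config$ionic)) aliev_panfilov_params() else
    as_ionic_params(config$ionic)
  stims <- lapply(config$stimuli, function(s) {
    amp <- if (is.null(s$units)) s$amplitude else
      normalize_stimulus(s$amplitude, s$units, params)
    stimulus(s$kind, s$region, amp,
             if (is.null(s$start)) 0 else s$start, s$duration)
  })
  system <- assemble_system(mesh, cond, config$scheme$dt, params)
  system <- compile_stimuli(system, stims)
  list(mesh = mesh, system = system, config = config)
}
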