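# Activation maps, conduction velocity and the cuboid diagonal profile.

#' First-crossing activation map from sampled traces
#'
#' Activation time at a point is the first sample time at which the
#' normalized potential strictly exceeds the threshold; later re-crossings
#' (re-entry) are ignored. Points that never cross get `NA`. No sub-step
#' interpolation is performed (the literal first-sample rule); with the
#' millisecond-scale time steps used here the quantization error is
#' negligible.
#'
#' @param times sample times (ms), increasing.
#' @param values samples: a matrix with one row per time and one column per
#'   point, or a vector for a single point.
#' @param threshold activation threshold on the normalized potential.
#' @return An `activation_map` list with per-point `times` (ms, `NA` if
#'   never activated) and the `threshold` used.
#' @export
activation_map <- function(times, values, threshold = 0.5) {
  if (length(times) == 0) stop("empty trace")
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (nrow(values) != length(times))
    stop("values must have one row per sample time")
  act <- apply(values > threshold, 2, function(cr) {
    i <- which(cr)
    if (length(i)) times[i[1]] else NA_real_
  })
  structure(list(times = act, threshold = threshold),
            class = "activation_map")
}

#' Conduction velocity between two probes
#'
#' \eqn{CV = (x_2 - x_1)/(t_2 - t_1)} in mm/ms, reported in cm/s
#' (1 mm/ms = 100 cm/s). Both probes must have activated with
#' \eqn{t_2 > t_1}.
#'
#' @param t1,t2 activation times (ms) at the two probes.
#' @param x1,x2 probe coordinates along the propagation axis (mm).
#' @return conduction velocity (cm/s).
#' @export
conduction_velocity <- function(t1, t2, x1, x2) {
  if (is.na(t1) || is.na(t2))
    stop("conduction velocity undefined: a probe never activated")
  if (!(t2 > t1))
    stop("conduction velocity undefined: t2 must exceed t1 (got ",
         t1, ", ", t2, ")")
  (x2 - x1) / (t2 - t1) * 100
}

#' Activation profile along a mesh diagonal
#'
#' Collects the nodes within `max_dist` of the straight line between two
#' corners (default: the full box diagonal), orders them by arc length and
#' returns their activation times. Duplicate arc-length positions (several
#' nodes equidistant from the line) are averaged.
#'
#' @param act an [activation_map()] result or a numeric vector of per-node
#'   activation times.
#' @param mesh the mesh the activation lives on.
#' @param from,to diagonal end points (mm); default opposite box corners.
#' @param max_dist node-to-line distance cutoff (mm); default half the
#'   largest element edge.
#' @return data.frame with `distance` (mm along the diagonal) and
#'   `activation` (ms).
#' @export
diagonal_profile <- function(act, mesh, from = c(0, 0, 0),
                             to = mesh$dimensions, max_dist = NULL) {
  tv <- if (inherits(act, "activation_map")) act$times else act
  if (length(tv) != nrow(mesh$nodes))
    stop("activation must have one value per mesh node")
  if (is.null(max_dist)) max_dist <- max(mesh$elem_size) / 2
  dvec <- to - from
  len <- sqrt(sum(dvec^2))
  e <- dvec / len
  rel <- sweep(mesh$nodes, 2, from)
  s <- as.vector(rel %*% e)
  perp2 <- rowSums(rel^2) - s^2
  keep <- which(perp2 <= max_dist^2 + 1e-12 & s >= -1e-9 & s <= len + 1e-9)
  if (!length(keep)) stop("no nodes within ", max_dist, " mm of the diagonal")
  df <- data.frame(distance = s[keep], activation = tv[keep])
  df <- stats::aggregate(activation ~ distance, df, mean, na.action = NULL)
  df[order(df$distance), , drop = FALSE]
}
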