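# Reference-domain element machinery: Lagrange bases on [-1,1]^3,
# incompatible modes, Gauss quadrature and the isoparametric mapping.

# Corner ordering of the trilinear brick: sign pattern of (xi1, xi2, xi3)
# per node. This order is also used for mesh connectivity and VTK export.
.q1_signs <- matrix(c(-1, -1, -1,
                      +1, -1, -1,
                      +1, +1, -1,
                      -1, +1, -1,
                      -1, -1, +1,
                      +1, -1, +1,
                      +1, +1, +1,
                      -1, +1, +1), ncol = 3, byrow = TRUE)

.check_xi <- function(xi) {
  if (!is.numeric(xi) || length(xi) != 3L || anyNA(xi))
    stop("xi must be a numeric reference coordinate of length 3")
  if (any(abs(xi) > 1 + 1e-12))
    stop("reference coordinate outside [-1,1]^3: (",
         paste(signif(xi, 6), collapse = ", "), ")")
  invisible(xi)
}

#' Tensor-product Gauss-Legendre quadrature on the reference cube
#'
#' @param points_per_axis 2 or 3 points per axis, giving the 8-point rule
#'   used by Q1/Q1NC elements or the 27-point rule used by Q2.
#' @return An object of class `quadrature_rule` with `points` (n x 3 matrix
#'   of reference coordinates, first axis fastest) and positive `weights`
#'   summing to 8.
#' @examples
#' r <- gauss_rule(2)
#' sum(r$weights)  # volume of [-1,1]^3
#' @export
gauss_rule <- function(points_per_axis) {
  if (!is.numeric(points_per_axis) || length(points_per_axis) != 1L ||
      !(points_per_axis %in% c(2, 3)))
    stop("points_per_axis must be 2 or 3")
  if (points_per_axis == 2) {
    x1 <- c(-1, 1) / sqrt(3)
    w1 <- c(1, 1)
  } else {
    x1 <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
    w1 <- c(5, 8, 5) / 9
  }
  g <- as.matrix(expand.grid(xi1 = x1, xi2 = x1, xi3 = x1,
                             KEEP.OUT.ATTRS = FALSE))
  w <- as.matrix(expand.grid(w1, w1, w1, KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  structure(list(points = g, weights = w[, 1] * w[, 2] * w[, 3],
                 points_per_axis = as.integer(points_per_axis)),
            class = "quadrature_rule")
}

#' Hexahedral element families
#'
#' `Q1` is the 8-node trilinear brick, `Q2` the 27-node triquadratic brick,
#' and `Q1NC` the trilinear brick enhanced with three internal incompatible
#' modes (quadratic bubbles) that are condensed out at the element level.
#' Q1 and Q1NC integrate with the 8-point Gauss rule, Q2 with the 27-point
#' rule.
#'
#' @param name one of `"Q1"`, `"Q2"`, `"Q1NC"`, or an `element_family`
#'   object (returned unchanged).
#' @return An `element_family` list with `name`, `nodes_per_element`,
#'   `nc_modes` and `quad_points_per_axis`.
#' @export
element_family <- function(name) {
  if (inherits(name, "element_family")) return(name)
  name <- match.arg(name, c("Q1", "Q2", "Q1NC"))
  fam <- switch(name,
    Q1   = list(name = "Q1",   nodes_per_element = 8L,  nc_modes = 0L,
                quad_points_per_axis = 2L),
    Q2   = list(name = "Q2",   nodes_per_element = 27L, nc_modes = 0L,
                quad_points_per_axis = 3L),
    Q1NC = list(name = "Q1NC", nodes_per_element = 8L,  nc_modes = 3L,
                quad_points_per_axis = 2L))
  structure(fam, class = "element_family")
}

#' Trilinear (Q1) basis at a reference point
#'
#' Returns the 8 trilinear shape functions
#' \eqn{\hat N_a = (1 + s_{a1}\xi_1)(1 + s_{a2}\xi_2)(1 + s_{a3}\xi_3)/8}
#' in the canonical corner order, together with their exact gradients with
#' respect to the reference coordinates.
#'
#' @param xi numeric length-3 reference coordinate in `[-1,1]^3`.
#' @return list with `values` (length 8) and `ref_gradients` (8 x 3).
#' @export
eval_q1_basis <- function(xi) {
  .check_xi(xi)
  s <- .q1_signs
  t1 <- 1 + s[, 1] * xi[1]
  t2 <- 1 + s[, 2] * xi[2]
  t3 <- 1 + s[, 3] * xi[3]
  vals <- t1 * t2 * t3 / 8
  grads <- cbind(s[, 1] * t2 * t3, t1 * s[, 2] * t3, t1 * t2 * s[, 3]) / 8
  list(values = vals, ref_gradients = grads)
}

# 1-D quadratic Lagrange polynomials on nodes {-1, 0, 1} and derivatives.
.lag2 <- function(x) cbind(x * (x - 1) / 2, 1 - x * x, x * (x + 1) / 2)
.dlag2 <- function(x) cbind(x - 0.5, -2 * x, x + 0.5)

#' Triquadratic (Q2) basis at a reference point
#'
#' Triple tensor product of 1-D quadratic Lagrange polynomials on nodes
#' `{-1, 0, 1}`. Node ordering is lexicographic over the 3 x 3 x 3 lattice
#' with the first reference axis fastest, so node `l` (1-based) sits at
#' `(-1,0,1)[i1+1], ...` with `l - 1 = i1 + 3 i2 + 9 i3`.
#'
#' @inheritParams eval_q1_basis
#' @return list with `values` (length 27) and `ref_gradients` (27 x 3).
#' @export
eval_q2_basis <- function(xi) {
  .check_xi(xi)
  idx <- as.matrix(expand.grid(0:2, 0:2, 0:2, KEEP.OUT.ATTRS = FALSE))
  l1 <- .lag2(xi[1]); l2 <- .lag2(xi[2]); l3 <- .lag2(xi[3])
  d1 <- .dlag2(xi[1]); d2 <- .dlag2(xi[2]); d3 <- .dlag2(xi[3])
  a <- idx[, 1] + 1L; b <- idx[, 2] + 1L; cc <- idx[, 3] + 1L
  vals <- l1[a] * l2[b] * l3[cc]
  grads <- cbind(d1[a] * l2[b] * l3[cc],
                 l1[a] * d2[b] * l3[cc],
                 l1[a] * l2[b] * d3[cc])
  list(values = vals, ref_gradients = grads)
}

#' Incompatible-mode (bubble) functions at a reference point
#'
#' The three internal modes \eqn{1-\xi_1^2,\ 1-\xi_2^2,\ 1-\xi_3^2} that
#' enrich the Q1 element to form Q1NC. They vanish identically on all six
#' faces of the reference cube, so inter-element continuity is violated
#' only in element interiors.
#'
#' @inheritParams eval_q1_basis
#' @return list with `values` (length 3) and `ref_gradients` (3 x 3).
#' @export
eval_nc_modes <- function(xi) {
  .check_xi(xi)
  list(values = 1 - xi^2,
       ref_gradients = diag(-2 * xi, 3, 3))
}

# Reference nodal coordinates of a family (rows in connectivity order).
family_ref_nodes <- function(family) {
  family <- element_family(family)
  if (family$name == "Q2") {
    idx <- as.matrix(expand.grid(0:2, 0:2, 0:2, KEEP.OUT.ATTRS = FALSE))
    m <- matrix(c(-1, 0, 1)[idx + 1L], ncol = 3)
    dimnames(m) <- NULL
    m
  } else {
    .q1_signs
  }
}

# Family basis values/gradients at many points: values (nn x nq),
# grads (nn x 3 x nq).
family_basis_at <- function(family, pts) {
  family <- element_family(family)
  nq <- nrow(pts)
  f <- if (family$name == "Q2") eval_q2_basis else eval_q1_basis
  nn <- family$nodes_per_element
  vals <- matrix(0, nn, nq)
  grads <- array(0, c(nn, 3, nq))
  for (q in seq_len(nq)) {
    b <- f(pts[q, ])
    vals[, q] <- b$values
    grads[, , q] <- b$ref_gradients
  }
  list(values = vals, grads = grads)
}

nc_basis_at <- function(pts) {
  nq <- nrow(pts)
  vals <- matrix(0, 3, nq)
  grads <- array(0, c(3, 3, nq))
  for (q in seq_len(nq)) {
    b <- eval_nc_modes(pts[q, ])
    vals[, q] <- b$values
    grads[, , q] <- b$ref_gradients
  }
  list(values = vals, grads = grads)
}

#' Isoparametric mapping of one hexahedral element
#'
#' Maps the reference cube onto a physical element and evaluates, at every
#' quadrature point, the physical coordinates, Jacobian, its determinant
#' and inverse, and physical gradients of the family basis (and of the
#' incompatible modes for Q1NC, using the same per-point Jacobian, i.e.
#' plain Wilson modes).
#'
#' @param node_coords matrix (nodes x 3) of element node coordinates in mm,
#'   ordered by the family's connectivity convention.
#' @param rule a [gauss_rule()] object.
#' @param family element family (name or object), default `"Q1"`.
#' @return A `mapped_element` list; `wdet` holds the physical integration
#'   measure (quadrature weight times Jacobian determinant) per point.
#' @export
map_element <- function(node_coords, rule, family = "Q1") {
  family <- element_family(family)
  node_coords <- as.matrix(node_coords)
  if (nrow(node_coords) != family$nodes_per_element || ncol(node_coords) != 3)
    stop("node_coords must be ", family$nodes_per_element, " x 3 for ",
         family$name)
  pts <- rule$points
  nq <- nrow(pts)
  bas <- family_basis_at(family, pts)
  nn <- family$nodes_per_element
  xq <- matrix(0, nq, 3)
  detJ <- numeric(nq)
  Jac <- array(0, c(3, 3, nq))
  invJ <- array(0, c(3, 3, nq))
  gradN <- array(0, c(nn, 3, nq))
  for (q in seq_len(nq)) {
    G <- bas$grads[, , q]
    J <- crossprod(node_coords, G)      # J[i,j] = sum_a x_a[i] dN_a/dxi_j
    dJ <- det(J)
    if (!is.finite(dJ) || dJ <= 0)
      stop("non-positive Jacobian determinant (", signif(dJ, 6),
           ") at quadrature point ", q)
    Ji <- solve(J)
    xq[q, ] <- colSums(node_coords * bas$values[, q])
    detJ[q] <- dJ
    Jac[, , q] <- J
    invJ[, , q] <- Ji
    gradN[, , q] <- G %*% Ji            # rows are J^-T ref-gradients
  }
  out <- list(node_coords = node_coords, rule = rule, family = family,
              xq = xq, detJ = detJ, wdet = rule$weights * detJ,
              J = Jac, invJ = invJ,
              val_N = bas$values, grad_N = gradN)
  if (family$nc_modes > 0) {
    ncb <- nc_basis_at(pts)
    gradW <- array(0, c(3, 3, nq))
    for (q in seq_len(nq)) gradW[, , q] <- ncb$grads[, , q] %*% invJ[, , q]
    out$val_W <- ncb$values
    out$grad_W <- gradW
  }
  structure(out, class = "mapped_element")
}
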