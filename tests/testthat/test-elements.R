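# Reference-domain bases, quadrature and the isoparametric map.

test_that("Gauss rules have the printed points, positive weights summing to 8", {
  r2 <- gauss_rule(2)
  expect_equal(nrow(r2$points), 8L)
  expect_true(all(abs(abs(r2$points) - 1 / sqrt(3)) < 1e-15))
  expect_equal(r2$weights, rep(1, 8))
  r3 <- gauss_rule(3)
  expect_equal(nrow(r3$points), 27L)
  expect_true(all(r3$weights > 0))
  expect_equal(sum(r3$weights), 8)
  expect_error(gauss_rule(4), "2 or 3")
})

test_that("quadrature is exact for the advertised monomial degrees", {
  r2 <- gauss_rule(2); r3 <- gauss_rule(3)
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
    got <- quad_apply(r2, function(x) x[1]^a * x[2]^b * x[3]^cc)
    expect_equal(got, monomial_integral(a, b, cc), tolerance = 1e-13)
  }
  for (deg in list(c(5, 0, 0), c(4, 5, 2), c(5, 5, 5), c(3, 4, 5))) {
    got <- quad_apply(r3, function(x)
      x[1]^deg[1] * x[2]^deg[2] * x[3]^deg[3])
    expect_equal(got, monomial_integral(deg[1], deg[2], deg[3]),
                 tolerance = 1e-13)
  }
  # the 8-point rule integrates the bubble exactly: int (1 - xi1^2) = 16/3
  expect_equal(quad_apply(r2, function(x) 1 - x[1]^2), 16 / 3)
})

test_that("trilinear basis: nodal values, centroid symmetry, exact gradients", {
  b1 <- eval_q1_basis(c(-1, -1, -1))
  expect_equal(b1$values, c(1, rep(0, 7)))
  expect_equal(eval_q1_basis(c(0, 0, 0))$values, rep(1 / 8, 8))
  set.seed(11)
  for (i in 1:25) {
    xi <- runif(3, -0.99, 0.99)
    b <- eval_q1_basis(xi)
    expect_equal(sum(b$values), 1, tolerance = 1e-14)
    expect_equal(b$ref_gradients, fd_gradient(eval_q1_basis, xi),
                 tolerance = 1e-8)
  }
  expect_error(eval_q1_basis(c(1.5, 0, 0)), "outside")
})

test_that("triquadratic basis: Kronecker property, partition of unity, gradients", {
  nodes <- family_ref_nodes("Q2")
  for (l in seq_len(27)) {
    v <- eval_q2_basis(nodes[l, ])$values
    expect_equal(v, replace(numeric(27), l, 1), tolerance = 1e-14)
  }
  ctr <- eval_q2_basis(c(0, 0, 0))$values
  expect_equal(which(ctr == 1), 14L)    # centre of the lattice
  expect_equal(ctr[-14], rep(0, 26))
  set.seed(12)
  for (i in 1:25) {
    xi <- runif(3, -0.99, 0.99)
    b <- eval_q2_basis(xi)
    expect_equal(sum(b$values), 1, tolerance = 1e-13)
    expect_equal(b$ref_gradients, fd_gradient(eval_q2_basis, xi),
                 tolerance = 1e-7)
  }
})

test_that("partition of unity holds at 1000 random points to machine precision", {
  set.seed(1)
  pts <- matrix(runif(3000, -1, 1), ncol = 3)
  s1 <- apply(pts, 1, function(x) sum(eval_q1_basis(x)$values))
  s2 <- apply(pts, 1, function(x) sum(eval_q2_basis(x)$values))
  expect_true(max(abs(s1 - 1)) < 1e-13)
  expect_true(max(abs(s2 - 1)) < 1e-12)
})

test_that("incompatible modes: printed values, gradients, vanishing on faces", {
  expect_equal(eval_nc_modes(c(0, 0, 0))$values, c(1, 1, 1))
  b <- eval_nc_modes(c(0.5, 0, 0))
  expect_equal(b$values, c(0.75, 1, 1))
  expect_equal(b$ref_gradients[1, ], c(-1, 0, 0))
  # all three modes vanish identically on the six faces of the cube
  grid <- seq(-1, 1, length.out = 7)
  for (d in 1:3) for (s in c(-1, 1)) {
    for (a in grid) for (b2 in grid) {
      xi <- numeric(3)
      xi[d] <- s
      xi[setdiff(1:3, d)] <- c(a, b2)
      expect_equal(eval_nc_modes(xi)$values[d], 0)
    }
  }
  set.seed(13)
  for (i in 1:10) {
    xi <- runif(3, -0.99, 0.99)
    expect_equal(eval_nc_modes(xi)$ref_gradients,
                 fd_gradient(eval_nc_modes, xi), tolerance = 1e-8)
  }
})

test_that("element families match the published DOF/quadrature table", {
  q1 <- element_family("Q1"); q2 <- element_family("Q2")
  nc <- element_family("Q1NC")
  expect_equal(c(q1$nodes_per_element, q1$nc_modes, q1$quad_points_per_axis^3),
               c(8, 0, 8))
  expect_equal(c(q2$nodes_per_element, q2$nc_modes, q2$quad_points_per_axis^3),
               c(27, 0, 27))
  expect_equal(c(nc$nodes_per_element, nc$nc_modes, nc$quad_points_per_axis^3),
               c(8, 3, 8))
})

test_that("isoparametric map: affine scalings and linear-field reproduction", {
  rule <- gauss_rule(2)
  h <- 0.7
  cube <- box_coords <- monofem:::box_elem_coords(element_family("Q1"),
                                                  c(h, h, h))
  m <- map_element(cube, rule)
  expect_equal(m$detJ, rep((h / 2)^3, 8))
  unit <- monofem:::box_elem_coords(element_family("Q1"), c(1, 1, 1))
  mu <- map_element(unit, rule)
  for (q in 1:8) expect_equal(mu$J[, , q], diag(3) / 2)

  # distorted hexahedron still reproduces the gradient of a linear field
  set.seed(3)
  coords <- unit
  coords[7, ] <- coords[7, ] + c(0.15, -0.1, 0.12)
  md <- map_element(coords, rule)
  grad_true <- c(0.3, -1.2, 0.7)
  u_e <- 0.5 + coords %*% grad_true
  for (q in 1:8) {
    g <- as.vector(crossprod(md$grad_N[, , q], u_e))
    expect_equal(g, grad_true, tolerance = 1e-12)
    # cross-check against finite differences in reference coordinates:
    # d(u o xhat)/dxi = J^T grad_x u
    fd <- sapply(1:3, function(d) {
      e <- numeric(3); e[d] <- 1e-6
      xi <- gauss_rule(2)$points[q, ]
      (sum(eval_q1_basis(xi + e)$values * u_e) -
         sum(eval_q1_basis(xi - e)$values * u_e)) / 2e-6
    })
    expect_equal(fd, as.vector(t(md$J[, , q]) %*% grad_true),
                 tolerance = 1e-6)
  }

  flipped <- unit[c(2, 1, 4, 3, 6, 5, 8, 7), ]
  expect_error(map_element(flipped, rule), "Jacobian")
})
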