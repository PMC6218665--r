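# Element blocks, static condensation and global assembly.

test_that("conductivity tensor has the prescribed eigenstructure", {
  cd <- conductivity(0.0952, 0.0126, fiber = c(1, 0, 0))
  ev <- sort(eigen(cd$D, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(ev, c(0.0952, 0.0126, 0.0126))
  expect_equal(cd$d_l / cd$d_t, 0.0952 / 0.0126)
  # rotated fiber keeps eigenvalues, stays SPD
  cd2 <- conductivity(0.1, 0.02, fiber = c(1, 1, 1))
  expect_equal(sort(eigen(cd2$D)$values), c(0.02, 0.02, 0.1))
  expect_error(conductivity(0.01, 0.02), "d_l >= d_t")
})

test_that("Q1 blocks: consistent mass matches the tensor-product oracle,
           stiffness annihilates constants", {
  fam <- element_family("Q1")
  rule <- gauss_rule(2)
  for (size in list(c(1, 1, 1), c(0.8, 0.5, 0.3))) {
    mapped <- map_element(monofem:::box_elem_coords(fam, size), rule, fam)
    mass <- element_blocks(mapped, matrix(0, 3, 3), dt = 1)$K_u
    expect_equal(mass, q1_mass_oracle(size[1], size[2], size[3]),
                 tolerance = 1e-13)
    stiff <- element_blocks(mapped, conductivity(0.0952), dt = Inf)$K_u
    expect_equal(rowSums(stiff), rep(0, 8), tolerance = 1e-13)
    expect_equal(stiff, t(stiff), tolerance = 1e-13)
  }
  b <- element_blocks(map_element(monofem:::box_elem_coords(fam, c(1, 1, 1)),
                                  rule, fam), diag(3), dt = 0.1)
  expect_equal(dim(b$L), c(0L, 8L))       # no incompatible modes for Q1
  expect_equal(dim(b$K_alpha), c(0L, 0L))
})

test_that("Q1NC mode block matches closed-form integrals on the reference cube", {
  fam <- element_family("Q1NC")
  rule <- gauss_rule(2)
  # element coincides with the reference cube: corners at +-1
  mapped <- map_element(family_ref_nodes("Q1"), rule, fam)
  bl <- element_blocks(mapped, diag(3), dt = 1)
  # bubble mass under the prescribed 2-point rule (hand Gauss sum):
  # (1-x^2)^2 at +-1/sqrt(3) is (2/3)^2, so per-axis value 8/9 (the exact
  # 16/15 is quartic, beyond the rule) -> diagonal mass 8/9 * 2 * 2 = 32/9;
  # gradient term int 4 xi^2 * 2 * 2 = 32/3 is quadratic, hence exact
  expect_equal(diag(bl$K_alpha), rep(32 / 9 + 32 / 3, 3), tolerance = 1e-13)
  # off-diagonal: mass int (1-xi1^2)(1-xi2^2) dV = (4/3)(4/3)(2) = 32/9,
  # gradients orthogonal under isotropic D
  expect_equal(bl$K_alpha[1, 2], 32 / 9, tolerance = 1e-13)
  expect_equal(bl$K_alpha, t(bl$K_alpha), tolerance = 1e-12)
  ev <- eigen(bl$K_alpha, symmetric = TRUE)$values
  expect_true(all(ev > 0))
  expect_true(all(2 * abs(diag(bl$K_alpha)) > rowSums(abs(bl$K_alpha))))
})

test_that("static condensation: toy Schur complement and quadratic-form bound", {
  toy <- list(K_u = matrix(c(2, 0, 0, 2), 2), L = matrix(c(1, 0), 1),
              K_alpha = matrix(2, 1, 1))
  cond <- condense(toy)
  expect_equal(cond$Ae, matrix(c(1.5, 0, 0, 2), 2))
  expect_equal(recover_alpha(c(1, 0), cond, 0), -0.5)

  fam <- element_family("Q1NC")
  mapped <- map_element(monofem:::box_elem_coords(fam, c(0.9, 0.7, 0.4)),
                        gauss_rule(2), fam)
  bl <- element_blocks(mapped, conductivity(0.0952, 0.0126), dt = 0.01)
  cond <- condense(bl)
  expect_equal(cond$Ae, t(cond$Ae), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(8)
    expect_lte(as.numeric(t(x) %*% cond$Ae %*% x),
               as.numeric(t(x) %*% bl$K_u %*% x) + 1e-12)
  }
  # zero coupling leaves K_u untouched
  bl0 <- bl; bl0$L <- matrix(0, 3, 8)
  expect_equal(condense(bl0)$Ae, bl$K_u)
})

test_that("element loads: rest is zero, constants give mass action,
           stimulus integrates the basis", {
  fam <- element_family("Q1")
  mapped <- map_element(monofem:::box_elem_coords(fam, c(0.5, 0.5, 0.5)),
                        gauss_rule(2), fam)
  p <- aliev_panfilov_params()
  rest <- element_rhs(mapped, rep(0, 8), numeric(0), rep(0, 8), 0.01, p)
  expect_equal(rest$p_u, rep(0, 8))

  vol <- prod(c(0.5, 0.5, 0.5))
  unif <- element_rhs(mapped, rep(0.3, 8), numeric(0), rep(0, 8), 0.01, p,
                      freeze_reaction = TRUE)
  expect_equal(unif$p_u, rep(0.3 / 0.01 * vol / 8, 8), tolerance = 1e-13)

  stim <- element_rhs(mapped, rep(0, 8), numeric(0), rep(0, 8), 0.01, p,
                      stim_q = 0.2)
  expect_equal(stim$p_u, rep(0.2 * vol / 8, 8), tolerance = 1e-13)
})

test_that("global assembly: single element equals its block, overlap only on
           shared nodes, constants in the stiffness null space", {
  m1 <- build_box_mesh(c(1, 1, 1), h = 1)
  sys1 <- assemble_system(m1, conductivity(0.1), dt = 0.01)
  cn <- m1$elems[1, ]          # node ids in element corner order
  expect_equal(as.matrix(sys1$A)[cn, cn], sys1$groups[[1]]$cond$Ae,
               ignore_attr = TRUE, tolerance = 1e-14)

  m2 <- build_box_mesh(c(2, 1, 1), h = 1)
  sys2 <- assemble_system(m2, conductivity(0.1), dt = 0.01)
  A <- as.matrix(sys2$A)
  shared <- intersect(m2$elems[1, ], m2$elems[2, ])
  expect_length(shared, 4L)
  only1 <- setdiff(m2$elems[1, ], shared)
  only2 <- setdiff(m2$elems[2, ], shared)
  expect_true(all(A[only1, only2] == 0))

  syss <- assemble_system(m2, conductivity(0.1), dt = Inf)
  expect_equal(max(abs(syss$A %*% rep(1, sys2$ndof))), 0, tolerance = 1e-12)
})

test_that("R reference load assembly matches the compiled kernel", {
  m <- build_box_mesh(c(3, 1, 1), h = 0.8, family = "Q1NC")
  sys <- assemble_system(m, conductivity(0.0952), dt = 0.01)
  set.seed(8)
  st <- new_state(sys)
  st$u <- runif(sys$ndof, 0, 0.8)
  st$alpha <- matrix(rnorm(sys$nel * 3, sd = 0.05), sys$nel, 3)
  st$r <- matrix(runif(sys$nel * 8, 0, 0.4), sys$nel, 8)
  b_ref <- assemble_rhs(st, sys)
  ks <- monofem:::si_rhs_gating_cpp(st$u, st$alpha, st$r, sys$conn0,
                                    sys$egroup0, sys$Nval, sys$Wval,
                                    sys$wdetg, sys$Ce, matrix(0, 0, 0),
                                    sys$dt, sys$params$tau,
                                    monofem:::ionic_vec(sys$params),
                                    sys$ndof)
  expect_equal(b_ref, -ks$rhs, tolerance = 1e-12)
})

test_that("patch reproduction: linear fields are exact for Q1, Q2 and Q1NC,
           also on remainder meshes and with anisotropy", {
  lin <- function(x) 0.3 + 0.7 * x[, 1] - 0.2 * x[, 2] + 0.05 * x[, 3]
  for (fam in c("Q1", "Q2", "Q1NC")) {
    for (case in list(list(c(2, 1, 1), 0.5, conductivity(0.0952)),
                      list(c(2, 1.3, 1), 0.6,
                           conductivity(0.0952, 0.0126, c(1, 0, 0))))) {
      mesh <- build_box_mesh(case[[1]], case[[2]], fam)
      bnd <- unique(unlist(mesh$node_sets))
      exact <- lin(mesh$nodes)
      sol <- solve_steady_diffusion(mesh, case[[3]], bnd, exact[bnd])
      expect_equal(sol$u, exact, tolerance = 1e-9)
      if (fam == "Q1NC")
        expect_lt(max(abs(sol$alpha)), 1e-9)
    }
  }
})
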