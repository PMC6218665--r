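# Semi-implicit stepping, mode recovery, the fully-implicit comparator and
# the run driver.

test_that("rest is a fixed point; recovery decays toward zero", {
  m <- build_box_mesh(c(2, 1, 1), h = 1, family = "Q1NC")
  sys <- assemble_system(m, conductivity(0.0952), dt = 0.01)
  st <- new_state(sys)
  r_prev <- st$r[1, 1]
  for (i in 1:5) {
    st <- si_step(st, sys)
    expect_equal(st$u, rep(0, sys$ndof))
    expect_equal(st$alpha, matrix(0, sys$nel, 3))
    expect_lt(st$r[1, 1], r_prev)
    r_prev <- st$r[1, 1]
  }
})

test_that("with decoupled nodes and uniform state the SI step reduces to
           forward Euler on the kinetics", {
  m <- build_box_mesh(c(1, 1, 1), h = 1)
  sys <- assemble_system(m, matrix(0, 3, 3), dt = 0.004)
  p <- sys$params
  st <- new_state(sys)
  st$u <- rep(0.3, 8)
  st1 <- si_step(st, sys)
  expect_equal(st1$u,
               rep(0.3 + 0.004 * ionic_current(0.3, p$r0, p) / p$tau, 8),
               tolerance = 1e-12)
  expect_equal(st1$r[1, ],
               rep(p$r0 + 0.004 / p$tau * gating_rate(0.3, p$r0, p), 8),
               tolerance = 1e-14)
})

test_that("condensed step equals the monolithic-elimination oracle", {
  for (case in list(c(2, 1, 1), c(3, 3, 3))) {
    m <- build_box_mesh(case, h = 1, family = "Q1NC")
    sys <- assemble_system(m, conductivity(0.0952, 0.03), dt = 0.005)
    set.seed(9)
    st <- bump_state(sys, height = 0.4)
    st$alpha <- matrix(rnorm(sys$nel * 3, sd = 0.02), sys$nel, 3)
    st$r <- matrix(runif(sys$nel * 8, 0.05, 0.3), sys$nel, 8)
    oracle <- monolithic_si_step(st, sys)
    st1 <- si_step(st, sys)
    scale <- max(abs(oracle$u))
    expect_lt(max(abs(st1$u - oracle$u)) / scale, 1e-10)
    expect_lt(max(abs(st1$alpha - oracle$alpha)) / scale, 1e-10)
  }
})

test_that("recovered modes satisfy the element-level residual", {
  m <- build_box_mesh(c(2, 2, 1), h = 1, family = "Q1NC")
  sys <- assemble_system(m, conductivity(0.0952), dt = 0.005)
  set.seed(10)
  st <- bump_state(sys, height = 0.5)
  st$r <- matrix(runif(sys$nel * 8, 0, 0.3), sys$nel, 8)
  ks <- monofem:::si_rhs_gating_cpp(st$u, st$alpha, st$r, sys$conn0,
                                    sys$egroup0, sys$Nval, sys$Wval,
                                    sys$wdetg, sys$Ce, matrix(0, 0, 0),
                                    sys$dt, sys$params$tau,
                                    monofem:::ionic_vec(sys$params),
                                    sys$ndof)
  st1 <- si_step(st, sys)
  for (e in seq_len(sys$nel)) {
    bl <- sys$groups[[sys$gid[e]]]$blocks
    resid <- bl$L %*% st1$u[m$elems[e, ]] +
      bl$K_alpha %*% st1$alpha[e, ] - ks$p_alpha[e, ]
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("Q1NC with modes constrained to zero reproduces Q1 bit for bit", {
  mq1 <- build_box_mesh(c(5, 1, 1), h = 1, family = "Q1")
  mnc <- build_box_mesh(c(5, 1, 1), h = 1, family = "Q1NC")
  s1 <- assemble_system(mq1, conductivity(0.0952), dt = 0.01)
  s2 <- assemble_system(mnc, conductivity(0.0952), dt = 0.01,
                        nc_disabled = TRUE)
  stim <- list(stimulus("volume", region_box(c(0, 0, 0), c(1, 1, 1)),
                        amplitude = 0.2, duration = 2))
  s1 <- compile_stimuli(s1, stim)
  s2 <- compile_stimuli(s2, stim)
  st1 <- new_state(s1); st2 <- new_state(s2)
  for (i in 1:30) {
    st1 <- si_step(st1, s1)
    st2 <- si_step(st2, s2)
  }
  expect_identical(st1$u, st2$u)
  expect_identical(st1$r, st2$r)
  expect_identical(st2$alpha, matrix(0, s2$nel, 3))
})

test_that("pure diffusion conserves the consistent-mass integral of phi", {
  p0 <- aliev_panfilov_params(c1 = 0, c2 = 0)    # f identically zero
  for (fam in c("Q1", "Q1NC")) {
    m <- build_box_mesh(c(4, 1, 1), h = 0.5, family = fam)
    sys <- assemble_system(m, conductivity(0.0952), dt = 0.05, params = p0)
    st <- bump_state(sys, height = 0.8)
    m0 <- monofem:::field_integral(sys, st)
    for (i in 1:100) st <- si_step(st, sys)
    m1 <- monofem:::field_integral(sys, st)
    expect_equal(m1, m0, tolerance = 1e-10)
  }
})

test_that("semi-implicit diffusion is unconditionally stable in the max norm", {
  p0 <- aliev_panfilov_params(c1 = 0, c2 = 0)
  m <- build_box_mesh(c(4, 1, 1), h = 1)
  for (dt in c(1e-3, 1e-2, 0.1, 1)) {
    sys <- assemble_system(m, conductivity(0.0952), dt = dt, params = p0)
    st <- bump_state(sys, height = 1)
    prev <- max(abs(st$u))
    for (i in 1:250) {
      st <- si_step(st, sys)
      cur <- max(abs(st$u))
      expect_lte(cur, prev + 1e-13)
      prev <- cur
    }
  }
})

test_that("one-step defect against a tiny-dt reference halves with dt
           (first order in time)", {
  m <- build_box_mesh(c(1, 1, 1), h = 1)
  run_to <- function(dt, t_final = 0.08) {
    sys <- assemble_system(m, conductivity(0.0952), dt = dt)
    st <- new_state(sys)
    st$u <- rep(0.4, 8)       # uniform supra-threshold start
    for (i in seq_len(round(t_final / dt))) st <- si_step(st, sys)
    st$u[1]
  }
  ref <- run_to(0.0004)
  e1 <- abs(run_to(0.02) - ref)
  e2 <- abs(run_to(0.01) - ref)
  expect_gt(e1 / e2, 1.7)
  expect_lt(e1 / e2, 2.4)
})

test_that("fully-implicit scheme: rest stays rest; linear reaction makes
           FI and SI coincide; one-step gap shrinks as dt^2", {
  m <- build_box_mesh(c(3, 1, 1), h = 1, family = "Q1NC")
  p0 <- aliev_panfilov_params(c1 = 0, c2 = 0)
  sys0 <- assemble_system(m, conductivity(0.0952), dt = 0.01, params = p0)
  str <- new_state(sys0)
  expect_equal(fi_step(str, sys0)$u, rep(0, sys0$ndof))

  st <- bump_state(sys0, height = 0.5)
  expect_equal(fi_step(st, sys0)$u, si_step(st, sys0)$u, tolerance = 1e-9)

  gaps <- sapply(c(4e-3, 2e-3, 1e-3), function(dt) {
    sys <- assemble_system(m, conductivity(0.0952), dt = dt)
    st <- bump_state(sys, height = 0.5)
    max(abs(fi_step(st, sys)$u - si_step(st, sys)$u))
  })
  slopes <- diff(log2(gaps))
  expect_true(all(slopes < -1.7 & slopes > -2.3))
})

test_that("run driver: no stimulus keeps zero snapshots; reruns are
           byte-identical; wavefront respects causality", {
  m <- build_box_mesh(c(4, 1, 1), h = 1)
  sys <- assemble_system(m, conductivity(0.0952), dt = 0.01)
  res <- run_simulation(sys, 0.1, snapshot_every = 0.01)
  expect_equal(res$steps, 10L)
  expect_true(all(vapply(res$snapshots, function(u) all(u == 0), TRUE)))

  cfg <- protocol_rod(1, "Q1", dt = 0.01, t_end = 60)
  built <- monofem:::build_from_config(cfg)
  pidx <- monofem:::resolve_probes(built$mesh, cfg$probes)
  r1 <- run_simulation(built$system, 60, probes = pidx, stop_nodes = pidx)
  built2 <- monofem:::build_from_config(cfg)
  r2 <- run_simulation(built2$system, 60, probes = pidx, stop_nodes = pidx)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$activation, r2$activation)
  t18 <- r1$activation[pidx[1]]; t22 <- r1$activation[pidx[2]]
  expect_false(anyNA(c(t18, t22)))
  expect_lt(t18, t22)                      # x = 18 activates before x = 22
})
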