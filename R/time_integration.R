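# Time integration: the semi-implicit (IMEX) stepper built on the
# factorised condensed operator, and a fully-implicit backward-Euler
# comparator that keeps the incompatible-mode coefficients as explicit
# unknowns in a monolithic Newton system.

#' Initial simulation state
#'
#' Resting tissue: `u = 0` everywhere, incompatible-mode coefficients zero,
#' recovery variable at its initial value `params$r0` at every quadrature
#' point.
#'
#' @param system a [assemble_system()] object.
#' @return A `monofem_state` with fields `u`, `alpha`, `r`, `t`.
#' @export
new_state <- function(system) {
  nq <- ncol(system$Nval)
  structure(list(u = numeric(system$ndof),
                 alpha = if (system$nc_modes > 0)
                   matrix(0, system$nel, 3) else NULL,
                 r = matrix(system$params$r0, system$nel, nq),
                 t = 0),
            class = "monofem_state")
}

ionic_vec <- function(p) c(p$c1, p$c2, p$alpha, p$b, p$gamma, p$mu1, p$mu2)

# Active stimulus contributions at time t (reaction time level). Cached by
# the pattern of active events; the amplitude is constant within a window.
stim_at <- function(system, t) {
  va <- vapply(system$stim_vol, function(s)
    t >= s$start - 1e-12 && t < s$start + s$duration - 1e-12, TRUE)
  sa <- vapply(system$stim_surf, function(s)
    t >= s$start - 1e-12 && t < s$start + s$duration - 1e-12, TRUE)
  key <- paste(c("v", which(va), "s", which(sa)), collapse = ".")
  cached <- system$cache[[key]]
  if (!is.null(cached)) return(cached)
  mat <- NULL
  if (any(va)) {
    mat <- system$stim_vol[[which(va)[1]]]$mat
    for (i in which(va)[-1]) mat <- mat + system$stim_vol[[i]]$mat
  }
  vec <- NULL
  if (any(sa)) {
    vec <- system$stim_surf[[which(sa)[1]]]$vec
    for (i in which(sa)[-1]) vec <- vec + system$stim_surf[[i]]$vec
  }
  out <- list(mat = mat, vec = vec)
  system$cache[[key]] <- out
  out
}

.empty_stim <- matrix(0, 0, 0)

#' One semi-implicit step
#'
#' Advances the state from `t` to `t + dt`: (i) the right-hand side is
#' evaluated from \eqn{(u_n, \alpha_n, r_n)} and stimuli at \eqn{t_n}
#' (reaction explicit); (ii) \eqn{u_{n+1}} solves the condensed linear
#' system through the stored factorization (diffusion implicit); (iii) the
#' incompatible-mode coefficients are recovered element-wise; (iv) the
#' recovery variable is updated by forward Euler at each quadrature point.
#'
#' @param state a `monofem_state`.
#' @param system a [assemble_system()] object (same `dt`).
#' @param t time at the start of the step; defaults to `state$t`.
#' @return the state at `t + dt`.
#' @export
si_step <- function(state, system, t = state$t) {
  st <- stim_at(system, t)
  ks <- si_rhs_gating_cpp(state$u,
                          if (is.null(state$alpha)) .empty_stim else state$alpha,
                          state$r, system$conn0, system$egroup0,
                          system$Nval, system$Wval, system$wdetg,
                          system$Ce, if (is.null(st$mat)) .empty_stim else st$mat,
                          system$dt, system$params$tau,
                          ionic_vec(system$params), system$ndof)
  rhs <- ks$rhs
  if (!is.null(st$vec)) rhs <- rhs + st$vec
  unew <- as.numeric(Matrix::solve(system$chol, matrix(rhs, ncol = 1),
                                   system = "A"))
  if (!all(is.finite(unew)))
    stop("semi-implicit step produced non-finite potentials at t = ", t)
  alpha <- state$alpha
  if (system$nc_modes > 0)
    alpha <- nc_alpha_update_cpp(unew, ks$p_alpha, system$conn0,
                                 system$egroup0, system$Kai, system$KaiL)
  structure(list(u = unew, alpha = alpha, r = ks$r_new, t = t + system$dt),
            class = "monofem_state")
}

#' Recover incompatible-mode coefficients from a nodal update
#'
#' Element-level back-substitution
#' \eqn{\alpha_{n+1} = K_\alpha^{-1} p_\alpha - K_\alpha^{-1} L u_{n+1}},
#' using only quantities cached by [condense()].
#'
#' @param u_e element nodal potentials at the new time level.
#' @param cond a [condense()] result.
#' @param p_alpha element mode load vector.
#' @return length-3 coefficient vector.
#' @export
recover_alpha <- function(u_e, cond, p_alpha) {
  as.vector(cond$Kai %*% p_alpha - cond$KaiL %*% u_e)
}

#' One fully-implicit (backward-Euler) step
#'
#' All terms, including the reaction, are evaluated at \eqn{t_{n+1}}; the
#' nonlinear system in the monolithic unknowns \eqn{(u, \alpha)} is solved
#' by Newton iteration with the analytic reaction Jacobian. The gating
#' variable is advanced per quadrature point by an inner backward-Euler
#' solve refreshed before each Newton iteration (staggered coupling).
#'
#' @inheritParams si_step
#' @param newton_tol convergence tolerance on the max-norm Newton update.
#' @param newton_max_iter iteration cap; exceeding it is an error.
#' @export
fi_step <- function(state, system, t = state$t, newton_tol = 1e-9,
                    newton_max_iter = 20) {
  full <- system$cache$full
  if (is.null(full)) {
    full <- build_full_system(system)
    system$cache$full <- full
  }
  p <- system$params
  dt <- system$dt
  nel <- system$nel
  st <- stim_at(system, t + dt)     # all terms at t_{n+1}
  stim_mat <- st$mat
  stim_vec <- numeric(full$ndof_full)
  if (!is.null(st$vec)) stim_vec[seq_len(system$ndof)] <- st$vec

  z_n <- c(state$u, if (full$nc > 0) as.vector(t(state$alpha)) else NULL)
  Mzn <- as.numeric(full$M %*% z_n) / dt
  z <- z_n
  r_new <- state$r
  converged <- FALSE
  for (it in seq_len(newton_max_iter)) {
    phi_q <- full_phi_q(full, z, system)
    r_new <- solve_gating_be(phi_q, state$r, dt / p$tau, p)
    f <- ionic_current(phi_q, r_new, p) / p$tau
    fw <- (f + if (is.null(stim_mat)) 0 else stim_mat) * full$wdet_e
    pe <- fw %*% t(full$Phi)                       # nel x nloc
    Fvec <- as.numeric(full$Sfull %*% as.vector(pe))
    Res <- as.numeric(full$A0 %*% z) - Mzn - Fvec - stim_vec
    fp <- (p$c1 * ((phi_q - p$alpha) * (1 - phi_q) +
                     phi_q * (1 - phi_q) - phi_q * (phi_q - p$alpha)) -
             p$c2 * r_new) / p$tau
    Rvals <- (fp * full$wdet_e) %*% t(full$O)      # nel x nloc^2
    delta <- as.numeric(full$Agg %*% as.vector(Rvals)[full$upper])
    J <- full$A0
    J@x <- J@x - delta
    dz <- if (!is.null(full$chol0)) {
      ch <- Matrix::update(full$chol0, J)
      as.numeric(Matrix::solve(ch, matrix(Res, ncol = 1), system = "A"))
    } else {
      as.numeric(Matrix::solve(J, Res))
    }
    z <- z - dz
    if (max(abs(dz)) < newton_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("fully-implicit Newton did not converge within ", newton_max_iter,
         " iterations at t = ", t, " (last update ", signif(max(abs(dz)), 3),
         ")")
  phi_q <- full_phi_q(full, z, system)
  r_new <- solve_gating_be(phi_q, state$r, dt / p$tau, p)
  u <- z[seq_len(system$ndof)]
  alpha <- if (full$nc > 0)
    matrix(z[-seq_len(system$ndof)], nel, 3, byrow = TRUE) else state$alpha
  structure(list(u = u, alpha = alpha, r = r_new, t = t + dt),
            class = "monofem_state")
}

resolve_probes <- function(mesh, probes) {
  if (is.null(probes)) return(integer(0))
  if (is.numeric(probes) && is.null(dim(probes)) &&
      all(probes == round(probes)) && all(probes >= 1))
    return(as.integer(probes))
  probes <- if (is.list(probes)) do.call(rbind, probes) else
    matrix(probes, ncol = 3)
  vapply(seq_len(nrow(probes)), function(i)
    nearest_node(mesh, probes[i, ]), 1L)
}

#' Run a fixed-step simulation
#'
#' Drives [si_step()] (or [fi_step()]) over `[0, t_end]`, recording probe
#' traces every step, first-crossing activation times
#' (\eqn{\phi > } `activation_threshold` at a node) and optional field
#' snapshots. Entirely deterministic: identical inputs give identical
#' outputs.
#'
#' @param system a [assemble_system()] object, typically with stimuli
#'   attached via [compile_stimuli()].
#' @param t_end final time (ms).
#' @param probes node indices or a matrix/list of probe coordinates
#'   (nearest node is used).
#' @param scheme `"SI"` (semi-implicit) or `"FI"` (fully implicit).
#' @param snapshot_every snapshot cadence in ms (`Inf` = none).
#' @param stop_nodes optional node indices: the run stops early once all of
#'   them have activated.
#' @param activation_threshold normalized-potential threshold, default 0.5.
#' @param newton_tol,newton_max_iter Newton controls for `scheme = "FI"`.
#' @param initial_state optional starting `monofem_state`.
#' @param quiet_after optional time (ms): past it, the run stops once the
#'   maximum potential falls below `quiet_tol` and no stimulus lies ahead
#'   (with sub-threshold potentials, no stimuli and decaying recovery the
#'   tissue can only relax further, so the remaining evolution is
#'   monotone decay to rest).
#' @param quiet_tol quiescence threshold on `max(u)`, default `1e-4`.
#' @return list with `times`, `traces`, `probe_nodes`, `activation` (NA for
#'   never-activated nodes), `snapshots`, `snapshot_times`, final `state`
#'   and the number of `steps` taken.
#' @export
run_simulation <- function(system, t_end, probes = NULL,
                           scheme = c("SI", "FI"), snapshot_every = Inf,
                           stop_nodes = NULL, activation_threshold = 0.5,
                           newton_tol = 1e-9, newton_max_iter = 20,
                           initial_state = NULL, quiet_after = NULL,
                           quiet_tol = 1e-4) {
  scheme <- match.arg(scheme)
  dt <- system$dt
  if (!is.finite(dt)) stop("system was assembled for the steady problem")
  nsteps <- as.integer(round(t_end / dt))
  state <- if (is.null(initial_state)) new_state(system) else initial_state
  if (scheme == "FI" && is.null(system$cache$full))
    system$cache$full <- build_full_system(system)

  pidx <- resolve_probes(system$mesh, probes)
  traces <- if (length(pidx))
    matrix(NA_real_, nsteps + 1L, length(pidx)) else NULL
  if (length(pidx)) traces[1L, ] <- state$u[pidx]
  act <- rep(NA_real_, system$ndof)
  remaining <- seq_len(system$ndof)
  snap_stride <- if (is.finite(snapshot_every))
    max(1L, as.integer(round(snapshot_every / dt))) else NA_integer_
  snapshots <- list()
  snap_times <- numeric(0)
  n_done <- 0L
  for (n in seq_len(nsteps)) {
    tn <- (n - 1L) * dt
    state <- if (scheme == "SI") si_step(state, system, tn) else
      fi_step(state, system, tn, newton_tol, newton_max_iter)
    n_done <- n
    if (length(remaining)) {
      hit <- state$u[remaining] > activation_threshold
      if (any(hit)) {
        act[remaining[hit]] <- n * dt
        remaining <- remaining[!hit]
      }
    }
    if (length(pidx)) traces[n + 1L, ] <- state$u[pidx]
    if (!is.na(snap_stride) && n %% snap_stride == 0L) {
      snapshots[[length(snapshots) + 1L]] <- state$u
      snap_times <- c(snap_times, n * dt)
    }
    if (!is.null(stop_nodes) && !anyNA(act[stop_nodes])) break
    if (!is.null(quiet_after) && n %% 100L == 0L && n * dt > quiet_after &&
        max(state$u) < quiet_tol)
      break
  }
  if (length(pidx)) traces <- traces[seq_len(n_done + 1L), , drop = FALSE]
  list(times = (0:n_done) * dt, traces = traces, probe_nodes = pidx,
       activation = act, snapshots = snapshots, snapshot_times = snap_times,
       state = state, steps = n_done)
}
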