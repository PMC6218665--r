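# Element operator blocks, static condensation and global sparse assembly
# for the semi-implicit scheme. The global matrix A combines consistent
# mass over dt with anisotropic stiffness; for Q1NC the incompatible-mode
# block is eliminated per element (Schur complement) before scattering, so
# A keeps Q1 size. A is constant in time and factorised once (sparse
# Cholesky through Matrix/CHOLMOD), never densely inverted.

#' Anisotropic conductivity tensor
#'
#' \eqn{D = d_t I + (d_l - d_t) f \otimes f} with longitudinal/transverse
#' normalized diffusivities (mm^2/ms) and fiber unit vector `f`.
#'
#' @param d_l longitudinal diffusivity (mm^2/ms).
#' @param d_t transverse diffusivity, `d_l >= d_t > 0`; defaults to `d_l`
#'   (isotropic).
#' @param fiber fiber direction (normalized internally).
#' @return A `monofem_conductivity` with the 3 x 3 SPD tensor in `$D`.
#' @export
conductivity <- function(d_l, d_t = d_l, fiber = c(1, 0, 0)) {
  if (!(d_l >= d_t && d_t > 0))
    stop("require d_l >= d_t > 0")
  f <- fiber / sqrt(sum(fiber^2))
  D <- d_t * diag(3) + (d_l - d_t) * tcrossprod(f)
  structure(list(D = D, d_l = d_l, d_t = d_t, fiber = f),
            class = "monofem_conductivity")
}

as_cond_matrix <- function(D) {
  if (inherits(D, "monofem_conductivity")) return(D$D)
  D <- as.matrix(D)
  if (!all(dim(D) == c(3, 3))) stop("D must be 3 x 3")
  D
}

#' Element operator blocks for the semi-implicit system
#'
#' Computes, with the family's quadrature rule,
#' \eqn{K_u[a,b] = \int (N_a N_b/\Delta t + \nabla N_a \cdot D \nabla N_b)},
#' the mode/node coupling \eqn{L[c,b]} and the mode block
#' \eqn{K_\alpha[c,d]} (empty for Q1/Q2). `dt = Inf` drops the mass part
#' and yields the pure stiffness blocks of the steady problem.
#'
#' @param mapped a [map_element()] result.
#' @param D conductivity tensor (3 x 3 matrix or [conductivity()]).
#' @param dt time-step size (ms), `> 0` (may be `Inf`).
#' @return list with `K_u`, `L`, `K_alpha`.
#' @export
element_blocks <- function(mapped, D, dt) {
  D <- as_cond_matrix(D)
  if (!(dt > 0)) stop("dt must be positive")
  idt <- if (is.finite(dt)) 1 / dt else 0
  fam <- mapped$family
  nn <- fam$nodes_per_element
  nc <- fam$nc_modes
  nq <- length(mapped$wdet)
  K_u <- matrix(0, nn, nn)
  L <- matrix(0, nc, nn)
  K_a <- matrix(0, nc, nc)
  for (q in seq_len(nq)) {
    w <- mapped$wdet[q]
    Nq <- mapped$val_N[, q]
    Gq <- mapped$grad_N[, , q]
    K_u <- K_u + w * (idt * tcrossprod(Nq) + Gq %*% D %*% t(Gq))
    if (nc > 0) {
      Wq <- mapped$val_W[, q]
      Hq <- mapped$grad_W[, , q]
      L <- L + w * (idt * tcrossprod(Wq, Nq) + Hq %*% D %*% t(Gq))
      K_a <- K_a + w * (idt * tcrossprod(Wq) + Hq %*% D %*% t(Hq))
    }
  }
  list(K_u = K_u, L = L, K_alpha = K_a, family = fam)
}

#' Static condensation of the incompatible-mode block
#'
#' Schur complement \eqn{A^e = K_u - L^T K_\alpha^{-1} L}; the factors
#' needed later for mode recovery (`Kai = K_alpha^-1`,
#' `KaiL = K_alpha^-1 L`, `Ce = L^T K_alpha^-1`) are cached. With no modes
#' (`L` empty) `A^e = K_u`.
#'
#' @param blocks an [element_blocks()] result.
#' @return list with `Ae`, `Kai`, `KaiL`, `Ce`.
#' @export
condense <- function(blocks) {
  nc <- nrow(blocks$L)
  if (is.null(nc) || nc == 0)
    return(list(Ae = blocks$K_u,
                Kai = matrix(0, 0, 0),
                KaiL = matrix(0, 0, ncol(blocks$K_u)),
                Ce = matrix(0, ncol(blocks$K_u), 0)))
  Kai <- tryCatch(solve(blocks$K_alpha),
                  error = function(e) stop("singular K_alpha block: ",
                                           conditionMessage(e)))
  KaiL <- Kai %*% blocks$L
  Ae <- blocks$K_u - crossprod(blocks$L, KaiL)
  Ae <- (Ae + t(Ae)) / 2
  list(Ae = Ae, Kai = Kai, KaiL = KaiL, Ce = t(KaiL))
}

# Representative element node coordinates for a given box size.
box_elem_coords <- function(family, size) {
  ref <- family_ref_nodes(family)
  sweep((ref + 1) / 2, 2, size, `*`)
}

# Group elements of a structured mesh by identical size; returns group ids
# and per-group representative geometry.
element_groups <- function(mesh) {
  key <- apply(round(mesh$elem_size, 10), 1, paste, collapse = ",")
  uk <- unique(key)
  gid <- match(key, uk)
  sizes <- mesh$elem_size[match(uk, key), , drop = FALSE]
  list(gid = gid, sizes = sizes, n = length(uk))
}

#' Assemble the condensed global system operators
#'
#' Builds the global sparse symmetric matrix `A` from the element Schur
#' complements and factorises it once (sparse Cholesky); the factorization
#' is reused at every time step. Per-group condensed blocks, basis tables
#' and quadrature measures needed for right-hand-side evaluation and mode
#' recovery are stored alongside.
#'
#' @param mesh a [build_box_mesh()] mesh.
#' @param D conductivity (matrix or [conductivity()]).
#' @param dt time-step size (ms); `Inf` assembles the steady (pure
#'   stiffness) operator, which is singular under zero-flux conditions and
#'   is not factorised.
#' @param params ionic parameter set attached for later stepping.
#' @param nc_disabled internal switch that zeroes the incompatible-mode
#'   coupling of a Q1NC mesh, reducing it exactly to Q1 (used to verify the
#'   non-conforming construction).
#' @return A `monofem_system` list.
#' @export
assemble_system <- function(mesh, D, dt, params = aliev_panfilov_params(),
                            nc_disabled = FALSE) {
  fam <- element_family(mesh$family)
  params <- as_ionic_params(params)
  Dm <- as_cond_matrix(D)
  rule <- gauss_rule(fam$quad_points_per_axis)
  nn <- fam$nodes_per_element
  nc <- fam$nc_modes
  nq <- length(rule$weights)
  N <- nrow(mesh$nodes)
  nel <- nrow(mesh$elems)

  grp <- element_groups(mesh)
  G <- grp$n
  wdetg <- matrix(0, G, nq)
  Aes <- vector("list", G)
  groups <- vector("list", G)
  Ce <- array(0, c(nn, 3, G))
  Kai <- array(0, c(3, 3, G))
  KaiL <- array(0, c(3, nn, G))
  Nval <- NULL; Wval <- matrix(0, 0, nq)
  for (g in seq_len(G)) {
    mapped <- map_element(box_elem_coords(fam, grp$sizes[g, ]), rule, fam)
    blocks <- element_blocks(mapped, Dm, dt)
    cond <- condense(blocks)
    if (nc > 0 && nc_disabled) {
      cond$Ae <- (blocks$K_u + t(blocks$K_u)) / 2
      cond$Ce[] <- 0
      cond$KaiL[] <- 0
    }
    wdetg[g, ] <- mapped$wdet
    Aes[[g]] <- cond$Ae
    groups[[g]] <- list(size = grp$sizes[g, ], mapped = mapped,
                        blocks = blocks, cond = cond)
    if (nc > 0) {
      Ce[, , g] <- cond$Ce
      Kai[, , g] <- cond$Kai
      KaiL[, , g] <- cond$KaiL
    }
  }
  if (nc > 0) {
    Wval <- groups[[1]]$mapped$val_W
    if (nc_disabled) Wval <- matrix(0, 3, nq)
  }
  Nval <- groups[[1]]$mapped$val_N   # reference values are group-independent

  # scatter-add element Schur complements
  ii <- jj <- xx <- vector("list", G)
  for (g in seq_len(G)) {
    els <- which(grp$gid == g)
    cn <- mesh$elems[els, , drop = FALSE]
    ii[[g]] <- as.vector(cn[, rep(seq_len(nn), times = nn)])
    jj[[g]] <- as.vector(cn[, rep(seq_len(nn), each = nn)])
    xx[[g]] <- rep(as.vector(Aes[[g]]), each = length(els))
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, N))
  A <- Matrix::forceSymmetric(A, uplo = "U")
  chol_fac <- if (is.finite(dt))
    Matrix::Cholesky(A, LDL = FALSE, super = TRUE) else NULL

  structure(list(mesh = mesh, family = fam, D = Dm, dt = dt,
                 params = params, ndof = N, nel = nel,
                 conn0 = mesh$elems - 1L, egroup0 = as.integer(grp$gid - 1L),
                 gid = grp$gid, groups = groups,
                 Nval = Nval, Wval = Wval, wdetg = wdetg,
                 Ce = Ce, Kai = Kai, KaiL = KaiL,
                 A = A, chol = chol_fac,
                 nc = nc > 0L && !nc_disabled, nc_modes = nc,
                 nc_disabled = nc_disabled,
                 stim_vol = list(), stim_surf = list(),
                 cache = new.env(parent = emptyenv())),
            class = "monofem_system")
}

#' @export
print.monofem_system <- function(x, ...) {
  cat(sprintf(paste0("monofem system: %s, %d dofs, %d elements, ",
                     "dt = %g ms, nnz(A) = %d\n"),
              x$family$name, x$ndof, x$nel, x$dt,
              length(x$A@x)))
  invisible(x)
}

#' Element right-hand-side vectors
#'
#' Reference implementation of the per-element load at time level n:
#' \eqn{p_u[a] = \int N_a\,[(u^h_n+\alpha^h_n)/\Delta t +
#' f(u^h_n+\alpha^h_n, r_n)/\tau + I_{app}]} and the analogous
#' \eqn{p_\alpha[c]} with the incompatible modes as weights. Used by the
#' test oracles; production stepping evaluates the same integrals in
#' compiled code.
#'
#' @param mapped a [map_element()] result.
#' @param u_e element nodal potentials.
#' @param alpha_e incompatible-mode coefficients (length 3, Q1NC only).
#' @param r_e recovery values at the element's quadrature points.
#' @param dt time-step size (ms).
#' @param params ionic parameters.
#' @param stim_q applied current at quadrature points (1/ms), scalar or
#'   per-point.
#' @param freeze_reaction set `TRUE` to drop the reaction term (pure
#'   diffusion).
#' @return list with `p_u` and `p_alpha`.
#' @export
element_rhs <- function(mapped, u_e, alpha_e, r_e, dt,
                        params = aliev_panfilov_params(), stim_q = 0,
                        freeze_reaction = FALSE) {
  fam <- mapped$family
  nq <- length(mapped$wdet)
  stim_q <- rep_len(stim_q, nq)
  phi <- as.vector(crossprod(mapped$val_N, u_e))
  if (fam$nc_modes > 0 && length(alpha_e))
    phi <- phi + as.vector(crossprod(mapped$val_W, alpha_e))
  f <- if (freeze_reaction) 0 else
    ionic_current(phi, r_e, params) / params$tau
  s <- (phi / dt + f + stim_q) * mapped$wdet
  p_u <- as.vector(mapped$val_N %*% s)
  p_alpha <- if (fam$nc_modes > 0) as.vector(mapped$val_W %*% s) else numeric(0)
  list(p_u = p_u, p_alpha = p_alpha)
}

#' Assemble the global semi-implicit right-hand side
#'
#' Pure-R reference of the condensed load
#' \eqn{b_n = L^T K_\alpha^{-1} p_\alpha - p_u} (global scatter), in the
#' sign convention of the update \eqn{A u_{n+1} = -b_n}. The compiled
#' stepping kernel computes `-b_n` directly; this function exists as the
#' slow, transparent counterpart for verification.
#'
#' @param state a simulation state (see [new_state()]).
#' @param system a [assemble_system()] object.
#' @param stim_q optional applied current at quadrature points
#'   (elements x points matrix, 1/ms).
#' @return numeric vector `b_n` of length `ndof`.
#' @export
assemble_rhs <- function(state, system, stim_q = NULL) {
  b <- numeric(system$ndof)
  for (e in seq_len(system$nel)) {
    g <- system$gid[e]
    grpdat <- system$groups[[g]]
    conn <- system$mesh$elems[e, ]
    sq <- if (is.null(stim_q)) 0 else stim_q[e, ]
    alpha_e <- if (system$nc) state$alpha[e, ] else numeric(0)
    # honour the nc_disabled reduction (zeroed mode values)
    mapped <- grpdat$mapped
    if (system$nc_modes > 0 && !system$nc) {
      mapped$val_W <- matrix(0, 3, ncol(mapped$val_N))
      alpha_e <- if (is.null(state$alpha)) numeric(0) else state$alpha[e, ]
    }
    pr <- element_rhs(mapped, state$u[conn], alpha_e, state$r[e, ],
                      system$dt, system$params, stim_q = sq)
    be <- if (system$nc_modes > 0) {
      Ce <- if (system$nc) grpdat$cond$Ce else matrix(0, length(conn), 3)
      as.vector(Ce %*% pr$p_alpha) - pr$p_u
    } else {
      -pr$p_u
    }
    b[conn] <- b[conn] + be
  }
  b
}

# ---- monolithic (uncondensed) operators -----------------------------------
# Keeps the incompatible-mode coefficients as explicit unknowns
# z = [u, alpha_1^1..3, alpha_2^1..3, ...]. Used by the fully-implicit
# scheme and as the independent oracle for the condensation path.

build_full_system <- function(system) {
  fam <- system$family
  nn <- fam$nodes_per_element
  nc <- if (system$nc) 3L else 0L
  nel <- system$nel
  N <- system$ndof
  ndof_full <- N + nc * nel
  nq <- ncol(system$Nval)

  conn_full <- system$mesh$elems
  if (nc > 0)
    conn_full <- cbind(conn_full,
                       N + 3L * (seq_len(nel) - 1L) + matrix(rep(1:3, each = nel),
                                                             nel, 3))
  storage.mode(conn_full) <- "integer"
  nloc <- nn + nc

  # per-group dynamic and mass blocks in full (u, alpha) ordering
  Fes <- Mes <- vector("list", length(system$groups))
  for (g in seq_along(system$groups)) {
    bl <- system$groups[[g]]$blocks
    mapped <- system$groups[[g]]$mapped
    mbl <- element_blocks(mapped, matrix(0, 3, 3), 1)   # pure mass blocks
    if (nc > 0) {
      Fe <- rbind(cbind(bl$K_u, t(bl$L)), cbind(bl$L, bl$K_alpha))
      Me <- rbind(cbind(mbl$K_u, t(mbl$L)), cbind(mbl$L, mbl$K_alpha))
    } else {
      Fe <- bl$K_u
      Me <- mbl$K_u
    }
    Fes[[g]] <- (Fe + t(Fe)) / 2
    Mes[[g]] <- (Me + t(Me)) / 2
  }
  scatter <- function(mats) {
    ii <- jj <- xx <- vector("list", length(mats))
    for (g in seq_along(mats)) {
      els <- which(system$gid == g)
      cn <- conn_full[els, , drop = FALSE]
      ii[[g]] <- as.vector(cn[, rep(seq_len(nloc), times = nloc)])
      jj[[g]] <- as.vector(cn[, rep(seq_len(nloc), each = nloc)])
      xx[[g]] <- rep(as.vector(mats[[g]]), each = length(els))
    }
    Matrix::forceSymmetric(
      Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                           dims = c(ndof_full, ndof_full)), uplo = "U")
  }
  A0 <- scatter(Fes)
  M <- scatter(Mes)

  Phi <- rbind(system$Nval,
               if (nc > 0) system$Wval else NULL)       # nloc x nq
  O <- matrix(0, nloc * nloc, nq)                       # outer products
  for (q in seq_len(nq)) O[, q] <- as.vector(tcrossprod(Phi[, q]))
  iiM <- conn_full[, rep(seq_len(nloc), times = nloc)]
  jjM <- conn_full[, rep(seq_len(nloc), each = nloc)]
  Sfull <- Matrix::sparseMatrix(
    i = as.vector(conn_full), j = seq_len(nel * nloc),
    x = 1, dims = c(ndof_full, nel * nloc))
  wdet_e <- system$wdetg[system$gid, , drop = FALSE]

  # The reaction Jacobian shares A0's sparsity (dofs couple only within an
  # element), so Newton updates the values of a pattern template in place
  # and reuses CHOLMOD's symbolic factorization.
  iv <- as.vector(iiM); jv <- as.vector(jjM)
  upper <- which(iv <= jv)
  colidx <- rep.int(seq_len(ndof_full), diff(A0@p))
  keyA0 <- (A0@i + 1) + (colidx - 1) * ndof_full
  pos <- match(iv[upper] + (jv[upper] - 1) * ndof_full, keyA0)
  Agg <- Matrix::sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                              dims = c(length(A0@x), length(pos)))
  chol0 <- tryCatch(Matrix::Cholesky(A0), error = function(e) NULL)

  list(ndof_full = ndof_full, conn_full = conn_full, nloc = nloc,
       A0 = A0, M = M, Phi = Phi, O = O, iiM = iiM, jjM = jjM,
       Sfull = Sfull, wdet_e = wdet_e, nc = nc,
       upper = upper, Agg = Agg, chol0 = chol0)
}

# phi at quadrature points from a full state vector z: (nel x nq)
full_phi_q <- function(full, z, system) {
  Ue <- matrix(z[full$conn_full], system$nel, full$nloc)
  Ue %*% full$Phi
}

# consistent integral of phi over the domain (u + alpha parts)
field_integral <- function(system, state) {
  nq <- ncol(system$Nval)
  Ue <- matrix(state$u[system$mesh$elems], system$nel,
               system$family$nodes_per_element)
  phi <- Ue %*% system$Nval
  if (system$nc) phi <- phi + state$alpha %*% system$Wval
  sum(system$wdetg[system$gid, , drop = FALSE] * phi)
}

#' Steady anisotropic diffusion solve with Dirichlet data
#'
#' Assembles the condensed stiffness operator (no mass) and solves
#' \eqn{K u = 0} subject to prescribed nodal values, by row/column
#' elimination with a lift of the boundary data. For Q1NC the
#' incompatible-mode coefficients are recovered element-wise afterwards.
#' On a regular mesh a linear exact solution is reproduced to machine
#' precision by Q1, Q2 and Q1NC (patch reproduction).
#'
#' @param mesh a box mesh.
#' @param D conductivity.
#' @param dirichlet_nodes node indices with prescribed values.
#' @param dirichlet_values values at those nodes.
#' @return list with nodal solution `u` and mode coefficients `alpha`.
#' @export
solve_steady_diffusion <- function(mesh, D, dirichlet_nodes,
                                   dirichlet_values) {
  system <- assemble_system(mesh, D, dt = Inf)
  N <- system$ndof
  u <- numeric(N)
  u[dirichlet_nodes] <- dirichlet_values
  free <- setdiff(seq_len(N), dirichlet_nodes)
  A <- system$A
  rhs <- -as.numeric(A[free, dirichlet_nodes, drop = FALSE] %*%
                       u[dirichlet_nodes])
  u[free] <- as.numeric(Matrix::solve(A[free, free], rhs))
  alpha <- NULL
  if (system$nc) {
    alpha <- matrix(0, system$nel, 3)
    for (e in seq_len(system$nel)) {
      g <- system$gid[e]
      alpha[e, ] <- -as.vector(system$groups[[g]]$cond$KaiL %*%
                                 u[mesh$elems[e, ]])
    }
  }
  list(u = u, alpha = alpha)
}
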