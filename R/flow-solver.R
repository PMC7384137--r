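# Incompressible finite-volume solver: Euler-implicit momentum with
# first-order upwind convection and central diffusion, SIMPLE-style
# pressure correction on the staggered grid, immersed-boundary conditions
# supplied by the cell classification. At the capillary scale
# (Re ~ 6e-4) the equations are diffusion dominated and each implicit
# step is close to a steady Stokes solve.

# Inlet/wall/outlet conditions on the staggered arrays: Dirichlet plug
# inlet, no-penetration walls, zero-gradient outlet with a global
# mass-flux correction so the outflow matches the inflow exactly.
apply_domain_bc <- function(state) {
  g <- state$grid
  state$u[1L, ] <- state$bc$u_in
  state$v[, 1L] <- 0
  state$v[, g$ny + 1L] <- 0
  out <- state$u[g$nx, ]
  q_in <- sum(state$u[1L, ])
  q_out <- sum(out)
  state$u[g$nx + 1L, ] <- if (abs(q_out) > 1e-300) out * (q_in / q_out)
                          else rep(q_in / g$ny, g$ny)
  state
}

# Assemble the u- or v-momentum system for one time step. Convective mass
# fluxes are lagged from the step-start fields so the matrix is fixed for
# the whole pressure-correction loop and its factorisation is reused.
assemble_momentum <- function(comp, grid, props, bc, un, vn, fm, dt, relax) {
  g <- grid
  rho <- props$density; mu <- props$viscosity
  De <- mu * g$dy / g$dx
  Dn <- mu * g$dx / g$dy
  vol <- g$dx * g$dy
  ap0_t <- rho * vol / dt

  if (comp == "u") {
    nr <- g$nx + 1L; nc <- g$ny
    solid <- fm$u_solid
    unknown <- matrix(FALSE, nr, nc)
    unknown[2:g$nx, ] <- TRUE
    unknown <- unknown & !solid
  } else {
    nr <- g$nx; nc <- g$ny + 1L
    solid <- fm$v_solid
    unknown <- matrix(FALSE, nr, nc)
    unknown[, 2:g$ny] <- TRUE
    unknown <- unknown & !solid
  }
  idx <- matrix(0L, nr, nc)
  ids <- which(unknown)
  idx[ids] <- seq_along(ids)
  n <- length(ids)
  if (n == 0L) stop("assemble_momentum: no fluid faces", call. = FALSE)

  cap <- 4L * n
  ti <- integer(cap); tj <- integer(cap); tx <- numeric(cap); nt <- 0L
  fi <- integer(cap); fj <- integer(cap); fx <- numeric(cap); nf <- 0L
  aP <- numeric(n)
  pW <- integer(n); pE <- integer(n)  # linear indices into p
  b0 <- numeric(n)

  lin <- function(i, j) i + (j - 1L) * nr
  plin <- function(i, j) i + (j - 1L) * g$nx

  arr <- which(unknown, arr.ind = TRUE)
  for (r in seq_len(n)) {
    i <- arr[r, 1L]; j <- arr[r, 2L]
    if (comp == "u") {
      Fe <- rho * g$dy * 0.5 * (un[i, j] + un[i + 1L, j])
      Fw <- rho * g$dy * 0.5 * (un[i - 1L, j] + un[i, j])
      Fn <- rho * g$dx * 0.5 * (vn[i - 1L, j + 1L] + vn[i, j + 1L])
      Fs <- rho * g$dx * 0.5 * (vn[i - 1L, j] + vn[i, j])
      old <- un[i, j]
    } else {
      Fe <- rho * g$dy * 0.5 * (un[i + 1L, j - 1L] + un[i + 1L, j])
      Fw <- rho * g$dy * 0.5 * (un[i, j - 1L] + un[i, j])
      Fn <- rho * g$dx * 0.5 * (vn[i, j] + vn[i, j + 1L])
      Fs <- rho * g$dx * 0.5 * (vn[i, j - 1L] + vn[i, j])
      old <- vn[i, j]
    }
    aE <- De + max(-Fe, 0); aW <- De + max(Fw, 0)
    aN <- Dn + max(-Fn, 0); aS <- Dn + max(Fs, 0)
    ap <- aE + aW + aN + aS + (Fe - Fw + Fn - Fs) + ap0_t

    add_nb <- function(ii, jj, a) {
      if (idx[ii, jj] > 0L) {
        nt <<- nt + 1L
        ti[nt] <<- r; tj[nt] <<- idx[ii, jj]; tx[nt] <<- -a
      } else {
        nf <<- nf + 1L
        fi[nf] <<- r; fj[nf] <<- lin(ii, jj); fx[nf] <<- a
      }
    }

    if (comp == "u") {
      add_nb(i + 1L, j, aE)          # i+1 = nx+1 -> fixed outlet value
      add_nb(i - 1L, j, aW)          # i-1 = 1 -> fixed inlet value
      if (j + 1L > g$ny) ap <- ap + aN else add_nb(i, j + 1L, aN)  # wall mirror
      if (j - 1L < 1L) ap <- ap + aS else add_nb(i, j - 1L, aS)
      pW[r] <- plin(i - 1L, j); pE[r] <- plin(i, j)
    } else {
      if (i + 1L > g$nx) ap <- ap - aE else add_nb(i + 1L, j, aE)  # outlet dv/dx = 0
      if (i - 1L < 1L) ap <- ap + aW else add_nb(i - 1L, j, aW)    # inlet mirror v = 0
      if (j + 1L > g$ny + 1L) NULL else add_nb(i, j + 1L, aN)  # wall rows are fixed zeros
      add_nb(i, j - 1L, aS)
      pW[r] <- plin(i, j - 1L); pE[r] <- plin(i, j)
    }
    aP[r] <- ap
    b0[r] <- ap0_t * old
  }
  ti <- ti[seq_len(nt)]; tj <- tj[seq_len(nt)]; tx <- tx[seq_len(nt)]
  fi <- fi[seq_len(nf)]; fj <- fj[seq_len(nf)]; fx <- fx[seq_len(nf)]

  A <- Matrix::sparseMatrix(i = c(seq_len(n), ti), j = c(seq_len(n), tj),
                            x = c(aP / relax, tx), dims = c(n, n))
  Ffix <- Matrix::sparseMatrix(i = fi, j = fj, x = fx, dims = c(n, nr * nc))
  list(comp = comp, idx = idx, mask = unknown, ids = ids, n = n,
       lu = Matrix::lu(A), Ffix = Ffix, aP = aP, b0 = b0,
       pW = pW, pE = pE, relax = relax,
       pcoef = if (comp == "u") g$dy else g$dx)
}

solve_momentum <- function(sys, st) {
  full <- if (sys$comp == "u") st$u else st$v
  cur <- full[sys$ids]
  rhs <- sys$b0 +
    (1 - sys$relax) / sys$relax * sys$aP * cur +
    as.numeric(sys$Ffix %*% as.vector(full)) -
    (as.vector(st$p)[sys$pE] - as.vector(st$p)[sys$pW]) * sys$pcoef
  sol <- as.numeric(Matrix::solve(sys$lu, rhs))
  full[sys$ids] <- sol
  full
}

# Pressure-correction (continuity) system over fluid cells with the face
# d-coefficients from the momentum diagonals; outlet treated as a p' = 0
# reference so the system is non-singular and the pressure datum sits at
# the outlet.
assemble_pressure <- function(grid, fm, mu_sys, mv_sys, fluid) {
  g <- grid
  du <- matrix(0, g$nx + 1L, g$ny)
  du[mu_sys$ids] <- g$dy / mu_sys$aP
  # outlet faces inherit the adjacent interior coefficient
  du[g$nx + 1L, ] <- ifelse(mu_sys$idx[g$nx, ] > 0L,
                            g$dy / mu_sys$aP[pmax(mu_sys$idx[g$nx, ], 1L)], 0)
  dv <- matrix(0, g$nx, g$ny + 1L)
  dv[mv_sys$ids] <- g$dx / mv_sys$aP

  pidx <- matrix(0L, g$nx, g$ny)
  ids <- which(fluid)
  pidx[ids] <- seq_along(ids)
  n <- length(ids)
  cap <- 4L * n
  ti <- integer(cap); tj <- integer(cap); tx <- numeric(cap); nt <- 0L
  aP <- numeric(n)
  arr <- which(fluid, arr.ind = TRUE)
  for (r in seq_len(n)) {
    i <- arr[r, 1L]; j <- arr[r, 2L]
    aE <- du[i + 1L, j] * g$dy
    aW <- du[i, j] * g$dy
    aN <- dv[i, j + 1L] * g$dx
    aS <- dv[i, j] * g$dx
    ap <- aE + aW + aN + aS
    # neighbours: fluid -> coupled; outside/solid -> p' = 0 (coefficient
    # stays on the diagonal; at the outlet this pins the datum)
    if (i + 1L <= g$nx && pidx[i + 1L, j] > 0L) {
      nt <- nt + 1L; ti[nt] <- r; tj[nt] <- pidx[i + 1L, j]; tx[nt] <- -aE
    }
    if (i - 1L >= 1L && pidx[i - 1L, j] > 0L) {
      nt <- nt + 1L; ti[nt] <- r; tj[nt] <- pidx[i - 1L, j]; tx[nt] <- -aW
    }
    if (j + 1L <= g$ny && pidx[i, j + 1L] > 0L) {
      nt <- nt + 1L; ti[nt] <- r; tj[nt] <- pidx[i, j + 1L]; tx[nt] <- -aN
    }
    if (j - 1L >= 1L && pidx[i, j - 1L] > 0L) {
      nt <- nt + 1L; ti[nt] <- r; tj[nt] <- pidx[i, j - 1L]; tx[nt] <- -aS
    }
    if (ap <= 0) ap <- 1  # isolated cell: decouple with p' = 0
    aP[r] <- ap
  }
  ti <- ti[seq_len(nt)]; tj <- tj[seq_len(nt)]; tx <- tx[seq_len(nt)]
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ti), j = c(seq_len(n), tj),
                            x = c(aP, tx), dims = c(n, n))
  list(lu = Matrix::lu(A), pidx = pidx, ids = ids, n = n,
       du = du, dv = dv, arr = arr)
}

mass_imbalance <- function(st, ps) {
  g <- st$grid
  div <- (st$u[-1L, , drop = FALSE] - st$u[-(g$nx + 1L), , drop = FALSE]) * g$dy +
    (st$v[, -1L, drop = FALSE] - st$v[, -(g$ny + 1L), drop = FALSE]) * g$dx
  div[ps$ids]
}

#' Advance the flow by one implicit time step
#'
#' Euler-implicit momentum with lagged first-order upwind convection and
#' central diffusion, iterated with a SIMPLE pressure-correction loop until
#' the normalised iterate change drops to `tol` (reference 0.5e-6).
#' Immersed-boundary and domain boundary conditions are re-imposed every
#' iteration; the mass-flux divergence of fluid cells vanishes to linear
#' solver precision after the final correction.
#'
#' @param state a `flow_state`.
#' @param cls optional [classify_cells()] result carrying the particle
#'   configuration (`NULL` for particle-free flow).
#' @param dt time step in seconds (reference 1e-5).
#' @param tol convergence tolerance on the normalised residual.
#' @param max_iter pressure-correction iteration cap; exceeding it is an
#'   error.
#' @param relax_u,relax_p velocity and pressure under-relaxation factors.
#' @return The advanced `flow_state`; attributes `iterations` and
#'   `residuals` carry the convergence history.
#' @export
advance_flow <- function(state, cls = NULL, dt, tol = 0.5e-6, max_iter = 5000L,
                         relax_u = 0.7, relax_p = 0.3) {
  stopifnot(inherits(state, "flow_state"))
  if (!is.finite(dt) || dt <= 0) stop_config("advance_flow: dt must be > 0")
  if (!is.finite(tol) || tol <= 0) stop_config("advance_flow: tol must be > 0")
  g <- state$grid
  particles <- if (!is.null(cls)) cls$particles else NULL
  have_p <- !is.null(particles) && nrow(particles) > 0L &&
    any(particles$in_domain)
  fm <- if (!is.null(cls)) attr(cls, "face_masks") else face_masks(g, NULL)
  fluid <- if (!is.null(cls)) cls$label == "fluid" else
    matrix(TRUE, g$nx, g$ny)

  un <- state$u; vn <- state$v
  st <- state
  mu_sys <- assemble_momentum("u", g, st$props, st$bc, un, vn, fm, dt, relax_u)
  mv_sys <- assemble_momentum("v", g, st$props, st$bc, un, vn, fm, dt, relax_u)
  ps <- assemble_pressure(g, fm, mu_sys, mv_sys, fluid)

  uscale <- max(abs(st$bc$u_in), max(abs(un)), max(abs(vn)), 1e-300)
  res_hist <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u_prev <- st$u; v_prev <- st$v
    st <- apply_domain_bc(st)
    if (have_p) st <- apply_boundary_conditions(st, cls, particles)
    st$u <- solve_momentum(mu_sys, st)
    st$v <- solve_momentum(mv_sys, st)
    st <- apply_domain_bc(st)
    b <- mass_imbalance(st, ps)
    pp <- as.numeric(Matrix::solve(ps$lu, -b))
    P <- matrix(0, g$nx, g$ny)
    P[ps$ids] <- pp
    st$p[ps$ids] <- st$p[ps$ids] + relax_p * pp
    # velocity corrections (neighbouring solid or boundary cells carry p' = 0)
    Ppad_w <- rbind(rep(0, g$ny), P)        # p' west of face i = p'[i-1,]
    Ppad_e <- rbind(P, rep(0, g$ny))        # p' east of face i = p'[i,]
    st$u <- st$u + ps$du * (Ppad_w - Ppad_e)
    Ppad_s <- cbind(rep(0, g$nx), P)
    Ppad_n <- cbind(P, rep(0, g$nx))
    st$v <- st$v + ps$dv * (Ppad_s - Ppad_n)
    res <- max(max(abs(st$u - u_prev)), max(abs(st$v - v_prev))) / uscale
    res_hist <- c(res_hist, res)
    if (res <= tol) { converged <- TRUE; break }
    if (it >= 100L && res > 1e3 * max(tol, min(res_hist))) {
      win <- utils::tail(res_hist, 30L)
      if (all(diff(win) > 0))
        stop(sprintf(paste0("advance_flow: pressure-correction iteration ",
                            "diverging at t = %.4g s (iteration %d, residual ",
                            "%.3g; last residuals %s)"),
                     state$t, it, res,
                     paste(signif(utils::tail(win, 5L), 3), collapse = ", ")),
             call. = FALSE)
    }
  }
  if (!converged)
    stop(sprintf(paste0("advance_flow: iteration cap %d reached at ",
                        "t = %.4g s (residual %.3g > tol %.3g)"),
                 max_iter, state$t, utils::tail(res_hist, 1L), tol),
         call. = FALSE)
  st$t <- state$t + dt
  attr(st, "iterations") <- it
  attr(st, "residuals") <- res_hist
  st
}

#' Steady channel-flow benchmark
#'
#' Drives the particle-free capillary flow to steady state and compares the
#' streamwise profile at mid-domain with the analytic plane-Poiseuille
#' solution. Used as the flow-solver validation case.
#'
#' @param nx,ny grid resolution (benchmark reference 150 x 40).
#' @param Lx_um,Ly_um domain size in micrometres.
#' @param u_in inlet velocity (m/s).
#' @param props fluid properties.
#' @param dt pseudo-time step (s); with implicit diffusion a large step
#'   reaches steady state in very few steps.
#' @param tol pressure-correction tolerance.
#' @param max_steps cap on pseudo-time steps.
#' @param steady_tol inter-step normalised change at which the flow is
#'   declared steady.
#' @return A list with the final `state`, the mid-domain profile
#'   (`y_um`, `u`, `u_exact`), the relative L2 profile error `l2_error`,
#'   the centreline-to-mean ratio `centre_ratio`, the inlet/outlet flux
#'   mismatch `mass_error`, the maximum fluid-cell divergence `max_div`,
#'   and the residual history of the last step.
#' @export
solve_channel_flow <- function(nx = 150, ny = 40, Lx_um = 30, Ly_um = 8,
                               u_in = 3e-4, props = fluid_properties(),
                               dt = 0.01, tol = 0.5e-6, max_steps = 8L,
                               steady_tol = 1e-8) {
  grid <- flow_grid(nx, ny, Lx_um, Ly_um)
  st <- init_flow(grid, boundary_spec(u_in), props)
  res_hist <- numeric(0)
  for (k in seq_len(max_steps)) {
    nxt <- advance_flow(st, NULL, dt = dt, tol = tol)
    change <- flow_residual(st, nxt)
    res_hist <- attr(nxt, "residuals")
    st <- nxt
    if (change <= steady_tol) break
  }
  i_mid <- as.integer(round(nx / 2)) + 1L
  uprof <- st$u[i_mid, ]
  y_um <- grid$yc * 1e6
  u_mean <- sum(uprof) / ny
  u_exact <- analytic_channel_profile(y_um, u_mean, Ly_um)
  l2 <- sqrt(sum((uprof - u_exact)^2) / sum(u_exact^2))
  u_centre <- bilinear_mat(st$u, grid$xu, grid$yc, grid$Lx / 2, grid$Ly / 2)
  q_in <- sum(st$u[1L, ]) * grid$dy
  q_out <- sum(st$u[nx + 1L, ]) * grid$dy
  div <- divergence_field(st)
  list(state = st,
       profile = data.frame(y_um = y_um, u = uprof, u_exact = u_exact),
       u_mean = u_mean,
       l2_error = l2,
       centre_ratio = u_centre / u_mean,
       mass_error = abs(q_out - q_in) / q_in,
       max_div = max(abs(div)),
       residuals = res_hist)
}
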