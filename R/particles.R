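#' Create a set of circular AIC aggregate particles
#'
#' Particles are circular aggregates of alpha-immuno-conjugates carried by
#' the capillary flow. Positions and radii are in micrometres (the natural
#' scale of the domain); velocities are in m/s. The particle mass is taken
#' from the 3D sphere of the same radius at the fluid density (neutrally
#' buoyant aggregate; only the flow is two-dimensional).
#'
#' @param positions two-column matrix or data.frame of centre coordinates
#'   (micrometres).
#' @param radius_um aggregate radius in micrometres (reference 0.2).
#' @param density mass density used for the particle mass, kg/m^3.
#' @param velocity initial velocity, a length-2 vector (m/s) recycled to all
#'   particles (sources are released at rest).
#' @param domain optional [flow_grid()] used to set the `in_domain` flag.
#' @return A data.frame of class `aic_particles` with columns `id`, `x_um`,
#'   `y_um`, `u`, `v`, `radius_um`, `mass_kg`, `in_domain`.
#' @export
make_particles <- function(positions, radius_um = 0.2, density = 1025,
                           velocity = c(0, 0), domain = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop_config("make_particles: positions must have two columns (x_um, y_um)")
  n <- nrow(positions)
  if (any(radius_um <= 0)) stop_config("make_particles: radius_um must be > 0")
  a_m <- um(rep_len(radius_um, n))
  mass <- 4 / 3 * pi * a_m^3 * density
  p <- data.frame(
    id = seq_len(n),
    x_um = positions[, 1], y_um = positions[, 2],
    u = rep_len(velocity[1], n), v = rep_len(velocity[2], n),
    radius_um = rep_len(radius_um, n),
    mass_kg = mass,
    in_domain = TRUE
  )
  if (!is.null(domain)) {
    p$in_domain <- p$x_um >= 0 & p$x_um <= domain$Lx_um &
      p$y_um >= 0 & p$y_um <= domain$Ly_um
  }
  class(p) <- c("aic_particles", "data.frame")
  p
}

#' Seeded random placement of irradiation sources
#'
#' Places `n` source centres: the first at a fixed predetermined position,
#' the remainder uniformly at random inside the stated rectangle, rejecting
#' candidates whose surface gap to any accepted source is below `min_gap`.
#' The reference scenario places 158 sources of radius 0.2 um with the
#' first at (7.25, 4.0) um, the rest in [3, 25] x [1, 7] um with a minimal
#' surface gap of 0.1 um.
#'
#' @param n number of sources (>= 1).
#' @param x_range,y_range placement rectangle for the random sources
#'   (micrometres).
#' @param min_gap minimal surface-to-surface gap between sources
#'   (micrometres).
#' @param first fixed position of the first source (micrometres).
#' @param seed integer seed fixing the placement stream.
#' @param radius_um source radius used for the surface gap.
#' @param max_tries rejection-sampling budget per source.
#' @return An `n` x 2 matrix of centre positions (micrometres).
#' @export
generate_source_positions <- function(n, x_range = c(3, 25), y_range = c(1, 7),
                                      min_gap = 0.1, first = c(7.25, 4.0),
                                      seed = 1L, radius_um = 0.2,
                                      max_tries = 5000L) {
  if (n < 1) stop_config("generate_source_positions: n must be >= 1")
  if (min_gap < 0) stop_config("generate_source_positions: min_gap must be >= 0")
  dmin <- 2 * radius_um + min_gap
  with_seed(seed, {
    pos <- matrix(NA_real_, n, 2L)
    pos[1L, ] <- first
    k <- 1L
    while (k < n) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- c(runif(1, x_range[1], x_range[2]),
                  runif(1, y_range[1], y_range[2]))
        d2 <- (pos[seq_len(k), 1] - cand[1])^2 + (pos[seq_len(k), 2] - cand[2])^2
        if (all(d2 >= dmin^2)) {
          k <- k + 1L
          pos[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_config(paste0("generate_source_positions: could not place source ",
                           "%d of %d within the retry budget (placed %d)"),
                    k + 1L, n, k)
    }
    colnames(pos) <- c("x_um", "y_um")
    pos
  })
}

# Bilinear interpolation of the staggered u (resp. v) component at arbitrary
# points (metres). Coordinates are clamped to the array span.
interp_u <- function(state, x, y) {
  g <- state$grid
  bilinear_mat(state$u, g$xu, g$yc, x, y)
}

interp_v <- function(state, x, y) {
  g <- state$grid
  bilinear_mat(state$v, g$xc, g$yv, x, y)
}

# Bilinear interpolation that ignores masked (solid) stencil nodes and
# renormalises the weights; returns NA where every node is masked.
bilinear_masked <- function(M, solidM, xs, ys, x, y) {
  nx <- length(xs); ny <- length(ys)
  x <- pmin(pmax(x, xs[1]), xs[nx])
  y <- pmin(pmax(y, ys[1]), ys[ny])
  i <- pmin(pmax(findInterval(x, xs), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(y, ys), 1L), ny - 1L)
  tx <- (x - xs[i]) / (xs[i + 1L] - xs[i])
  ty <- (y - ys[j]) / (ys[j + 1L] - ys[j])
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  o00 <- !solidM[cbind(i, j)];      o10 <- !solidM[cbind(i + 1L, j)]
  o01 <- !solidM[cbind(i, j + 1L)]; o11 <- !solidM[cbind(i + 1L, j + 1L)]
  wsum <- w00 * o00 + w10 * o10 + w01 * o01 + w11 * o11
  val <- M[cbind(i, j)] * w00 * o00 + M[cbind(i + 1L, j)] * w10 * o10 +
    M[cbind(i, j + 1L)] * w01 * o01 + M[cbind(i + 1L, j + 1L)] * w11 * o11
  ifelse(wsum > 1e-12, val / wsum, NA_real_)
}

bilinear_mat <- function(M, xs, ys, x, y) {
  nx <- length(xs); ny <- length(ys)
  x <- pmin(pmax(x, xs[1]), xs[nx])
  y <- pmin(pmax(y, ys[1]), ys[ny])
  i <- pmin(pmax(findInterval(x, xs), 1L), nx - 1L)
  j <- pmin(pmax(findInterval(y, ys), 1L), ny - 1L)
  tx <- (x - xs[i]) / (xs[i + 1L] - xs[i])
  ty <- (y - ys[j]) / (ys[j + 1L] - ys[j])
  M[cbind(i, j)] * (1 - tx) * (1 - ty) +
    M[cbind(i + 1L, j)] * tx * (1 - ty) +
    M[cbind(i, j + 1L)] * (1 - tx) * ty +
    M[cbind(i + 1L, j + 1L)] * tx * ty
}

# Fluid velocity seen by each particle. With a classification available the
# particle's own immersed boundary writes its velocity into the surrounding
# faces, so a plain interpolation at the centre would return the particle's
# own velocity; instead average the non-solid face velocities in a thin
# shell around the particle surface. Falls back to bilinear interpolation.
fluid_velocity_at_particles <- function(particles, state, cls = NULL) {
  g <- state$grid
  xp <- um(particles$x_um); yp <- um(particles$y_um)
  up <- interp_u(state, xp, yp)
  vp <- interp_v(state, xp, yp)
  if (!is.null(cls)) {
    fm <- attr(cls, "face_masks")
    if (is.null(fm)) fm <- face_masks(g, particles)
    shell <- 2 * max(g$dx, g$dy)
    for (k in seq_len(nrow(particles))) {
      if (!particles$in_domain[k]) next
      a <- um(particles$radius_um[k])
      ru2 <- outer(g$xu - xp[k], g$yc - yp[k], function(dx, dy) dx^2 + dy^2)
      su <- ru2 >= a^2 & ru2 <= (a + shell)^2 & !fm$u_solid
      rv2 <- outer(g$xc - xp[k], g$yv - yp[k], function(dx, dy) dx^2 + dy^2)
      sv <- rv2 >= a^2 & rv2 <= (a + shell)^2 & !fm$v_solid
      if (any(su)) up[k] <- mean(state$u[su])
      if (any(sv)) vp[k] <- mean(state$v[sv])
    }
  }
  cbind(u = up, v = vp)
}

#' Advance particles through the flow
#'
#' In-domain particles relax toward the locally interpolated fluid velocity
#' with a Stokes-drag relaxation time `tau = m_p / (6 pi mu a)` (exact
#' exponential update, so the scheme is stable for any `dt/tau`), then move
#' ballistically over the step. Particles whose centre leaves the domain
#' are flagged and keep their exit velocity thereafter (they continue to
#' contribute dose from outside). Wall contacts reflect the normal velocity
#' with the restitution coefficient. Collisions are detected and resolved
#' after the move, followed by a positional de-overlap projection.
#'
#' @param particles an `aic_particles` data.frame.
#' @param flow a `flow_state`.
#' @param dt time step (s).
#' @param domain a [flow_grid()] (defaults to the flow's grid).
#' @param tau drag relaxation time (s); `NULL` computes the Stokes value
#'   from particle mass and fluid viscosity, `0` is perfect-tracer mode.
#' @param restitution restitution coefficient for particle and wall
#'   collisions.
#' @param cls optional cell classification from [classify_cells()]; when
#'   given, the fluid velocity is sampled in a shell outside each
#'   particle's own immersed boundary.
#' @return The updated `aic_particles` data.frame.
#' @export
advance_particles <- function(particles, flow, dt, domain = flow$grid,
                              tau = NULL, restitution = 1, cls = NULL) {
  stopifnot(dt > 0)
  n <- nrow(particles)
  if (n == 0L) return(particles)
  uf <- fluid_velocity_at_particles(particles, flow, cls)
  if (is.null(tau)) {
    a_m <- um(particles$radius_um)
    tau_k <- particles$mass_kg / (6 * pi * flow$props$viscosity * a_m)
  } else {
    tau_k <- rep_len(tau, n)
  }
  decay <- ifelse(tau_k > 0, exp(-dt / tau_k), 0)
  ins <- particles$in_domain
  particles$u[ins] <- uf[ins, "u"] + (particles$u[ins] - uf[ins, "u"]) * decay[ins]
  particles$v[ins] <- uf[ins, "v"] + (particles$v[ins] - uf[ins, "v"]) * decay[ins]
  if (any(!is.finite(particles$u)) || any(!is.finite(particles$v)))
    stop("advance_particles: non-finite particle velocity", call. = FALSE)

  # ballistic move (positions in um, velocities in m/s)
  particles$x_um <- particles$x_um + particles$u * dt * 1e6
  particles$y_um <- particles$y_um + particles$v * dt * 1e6

  # wall reflection (in-domain particles only; specular with restitution)
  if (!is.null(domain)) {
    a <- particles$radius_um
    lo <- ins & particles$y_um - a < 0
    hi <- ins & particles$y_um + a > domain$Ly_um
    particles$y_um[lo] <- 2 * a[lo] - particles$y_um[lo]
    particles$v[lo] <- -restitution * particles$v[lo]
    particles$y_um[hi] <- 2 * (domain$Ly_um - a[hi]) - particles$y_um[hi]
    particles$v[hi] <- -restitution * particles$v[hi]
    particles$in_domain <- particles$in_domain &
      particles$x_um >= 0 & particles$x_um <= domain$Lx_um
  }

  resolve_all_collisions(particles, restitution = restitution)
}

#' Detect approaching particle contacts
#'
#' Returns particle pairs whose centre distance is at or below the sum of
#' radii plus a contact tolerance and which are approaching (negative
#' normal relative velocity), sorted by ids for deterministic processing.
#'
#' @param particles an `aic_particles` data.frame.
#' @param tol_um contact tolerance in micrometres.
#' @return A two-column matrix of particle ids (possibly zero rows).
#' @export
detect_collisions <- function(particles, tol_um = 1e-3) {
  n <- nrow(particles)
  out <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("id1", "id2")))
  if (n < 2L) return(out)
  idx <- which(particles$in_domain)
  if (length(idx) < 2L) return(out)
  cmb <- utils::combn(sort(idx), 2L)
  i1 <- cmb[1L, ]; i2 <- cmb[2L, ]
  dx <- particles$x_um[i1] - particles$x_um[i2]
  dy <- particles$y_um[i1] - particles$y_um[i2]
  d <- sqrt(dx^2 + dy^2)
  touch <- d <= particles$radius_um[i1] + particles$radius_um[i2] + tol_um
  # approach condition: relative velocity projected on the contact normal
  ex <- ifelse(d > 0, dx / d, 1); ey <- ifelse(d > 0, dy / d, 0)
  un <- (particles$u[i1] - particles$u[i2]) * ex +
    (particles$v[i1] - particles$v[i2]) * ey
  keep <- touch & un < 0
  cbind(id1 = particles$id[i1[keep]], id2 = particles$id[i2[keep]])
}

#' Resolve a binary hard-sphere collision
#'
#' Applies the restitution-based normal impulse: particle 1 receives
#' `-(m_eff/m_1)(1 + eps)(u_12 . e) e` and particle 2 the equal-and-opposite
#' impulse, so total momentum is conserved exactly; kinetic energy is
#' conserved iff `eps = 1` and the normal relative velocity vanishes after
#' impact for `eps = 0`.
#'
#' @param p1,p2 single-row `aic_particles` entries (or any list with
#'   `x_um`, `y_um`, `u`, `v`, `mass_kg`).
#' @param restitution restitution coefficient in `[0, 1]`.
#' @return A list with post-collision velocities `v1` and `v2` (each c(u, v))
#'   and the collision bookkeeping (`e`, `u12`, `m_eff`).
#' @export
resolve_collision <- function(p1, p2, restitution = 1) {
  if (!is.finite(restitution) || restitution < 0 || restitution > 1)
    stop_config("resolve_collision: restitution must be in [0, 1]")
  r12 <- c(p1$x_um - p2$x_um, p1$y_um - p2$y_um)
  nr <- sqrt(sum(r12^2))
  e <- if (nr > 0) r12 / nr else c(1, 0)
  u12 <- c(p1$u - p2$u, p1$v - p2$v)
  meff <- p1$mass_kg * p2$mass_kg / (p1$mass_kg + p2$mass_kg)
  un <- sum(u12 * e)
  imp <- (1 + restitution) * un
  list(
    v1 = c(p1$u, p1$v) - (meff / p1$mass_kg) * imp * e,
    v2 = c(p2$u, p2$v) + (meff / p2$mass_kg) * imp * e,
    e = e, u12 = u12, m_eff = meff
  )
}

# Sequentially resolve all approaching contacts in sorted pair order,
# re-checking the approach condition after each impulse, then project
# overlapping pairs apart (velocity-free positional correction).
resolve_all_collisions <- function(particles, restitution = 1, tol_um = 1e-3) {
  repeat {
    pairs <- detect_collisions(particles, tol_um = tol_um)
    if (nrow(pairs) == 0L) break
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs[r, 1L], particles$id)
      j <- match(pairs[r, 2L], particles$id)
      # the pair may be separating by now due to an earlier impulse
      chk <- detect_collisions(particles[c(i, j), , drop = FALSE], tol_um = tol_um)
      if (nrow(chk) == 0L) next
      res <- resolve_collision(particles[i, ], particles[j, ], restitution)
      particles$u[i] <- res$v1[1]; particles$v[i] <- res$v1[2]
      particles$u[j] <- res$v2[1]; particles$v[j] <- res$v2[2]
    }
    break
  }
  # positional de-overlap: symmetric push along the contact normal
  for (pass in 1:8) {
    moved <- FALSE
    idx <- which(particles$in_domain)
    if (length(idx) < 2L) break
    cmb <- utils::combn(sort(idx), 2L)
    for (r in seq_len(ncol(cmb))) {
      i <- cmb[1L, r]; j <- cmb[2L, r]
      dx <- particles$x_um[i] - particles$x_um[j]
      dy <- particles$y_um[i] - particles$y_um[j]
      d <- sqrt(dx^2 + dy^2)
      dmin <- particles$radius_um[i] + particles$radius_um[j]
      if (d < dmin - tol_um) {
        e <- if (d > 0) c(dx, dy) / d else c(1, 0)
        push <- (dmin - d) / 2
        particles$x_um[i] <- particles$x_um[i] + push * e[1]
        particles$y_um[i] <- particles$y_um[i] + push * e[2]
        particles$x_um[j] <- particles$x_um[j] - push * e[1]
        particles$y_um[j] <- particles$y_um[j] - push * e[2]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  particles
}
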