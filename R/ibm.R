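# Ghost-cell immersed boundary machinery.
#
# The circular particles are embedded in the Cartesian grid by marking grid
# points inside any particle as solid. A solid point adjacent to fluid is a
# ghost point: its value is set from an image point mirrored across the
# nearest particle surface so that, relative to the particle, the
# tangential velocity gradient vanishes (slip condition) and the normal
# velocity vanishes at the boundary (impermeability condition).

# Signed depth of points below the nearest particle surface, and the owner.
# Returns list(inside = logical, owner = integer (0 = none)).
point_particle_owner <- function(x_um, y_um, particles) {
  n <- length(x_um)
  depth <- rep(-Inf, n)
  owner <- integer(n)
  for (k in seq_len(nrow(particles))) {
    dk <- particles$radius_um[k] -
      sqrt((x_um - particles$x_um[k])^2 + (y_um - particles$y_um[k])^2)
    upd <- dk > depth
    depth[upd] <- dk[upd]
    owner[upd & dk > 0] <- k
    owner[upd & dk <= 0] <- 0L
  }
  list(inside = depth > 0, owner = owner, depth = depth)
}

# Particles that are represented in the flow: fully inside the domain and
# at least one cell away from the inlet and outlet, where an immersed
# mask would conflict with the Dirichlet/zero-gradient conditions.
maskable <- function(grid, particles) {
  dx_um <- grid$dx * 1e6
  particles$in_domain &
    particles$x_um - particles$radius_um >= dx_um &
    particles$x_um + particles$radius_um <= grid$Lx_um - dx_um
}

# Solid/ghost masks for the staggered velocity faces.
face_masks <- function(grid, particles) {
  g <- grid
  if (is.null(particles) || nrow(particles) == 0L) {
    return(list(
      u_solid = matrix(FALSE, g$nx + 1L, g$ny),
      v_solid = matrix(FALSE, g$nx, g$ny + 1L),
      u_owner = matrix(0L, g$nx + 1L, g$ny),
      v_owner = matrix(0L, g$nx, g$ny + 1L),
      u_ghost = matrix(FALSE, g$nx + 1L, g$ny),
      v_ghost = matrix(FALSE, g$nx, g$ny + 1L)
    ))
  }
  keep <- maskable(grid, particles)
  pin <- particles[keep, , drop = FALSE]
  if (nrow(pin) == 0L) return(face_masks(grid, NULL))
  xu_um <- g$xu * 1e6; yc_um <- g$yc * 1e6
  xc_um <- g$xc * 1e6; yv_um <- g$yv * 1e6
  gu <- expand.grid(x = xu_um, y = yc_um)
  gv <- expand.grid(x = xc_um, y = yv_um)
  ou <- point_particle_owner(gu$x, gu$y, pin)
  ov <- point_particle_owner(gv$x, gv$y, pin)
  u_solid <- matrix(ou$inside, g$nx + 1L, g$ny)
  v_solid <- matrix(ov$inside, g$nx, g$ny + 1L)
  # map owner back to the row index in the full particle table
  map <- which(keep)
  u_owner <- matrix(ifelse(ou$owner > 0L, map[pmax(ou$owner, 1L)], 0L),
                    g$nx + 1L, g$ny)
  v_owner <- matrix(ifelse(ov$owner > 0L, map[pmax(ov$owner, 1L)], 0L),
                    g$nx, g$ny + 1L)
  list(
    u_solid = u_solid, v_solid = v_solid,
    u_owner = u_owner, v_owner = v_owner,
    u_ghost = u_solid & has_open_neighbour(u_solid),
    v_ghost = v_solid & has_open_neighbour(v_solid)
  )
}

# TRUE where at least one 4-neighbour inside the array is not solid.
has_open_neighbour <- function(solid) {
  nr <- nrow(solid); nc <- ncol(solid)
  open <- !solid
  nb <- matrix(FALSE, nr, nc)
  nb[-nr, ] <- nb[-nr, ] | open[-1L, ]
  nb[-1L, ] <- nb[-1L, ] | open[-nr, ]
  nb[, -nc] <- nb[, -nc] | open[, -1L]
  nb[, -1L] <- nb[, -1L] | open[, -nc]
  nb
}

#' Classify grid cells against the immersed particles
#'
#' Cells whose centre lies inside any particle are solid; solid cells with
#' at least one fluid 4-neighbour form the one-cell-deep ghost layer. Each
#' ghost cell carries an image point mirrored across the nearest particle
#' surface and the owning particle id.
#'
#' @param grid a [flow_grid()].
#' @param particles an `aic_particles` data.frame (may be empty or `NULL`).
#' @return An object of class `cell_classification`: a list with the label
#'   matrix (`"fluid"`, `"solid"`, `"ghost"`), a data.frame `ghosts`
#'   (`i`, `j`, `x_img_um`, `y_img_um`, `owner`), and the particle table.
#' @export
classify_cells <- function(grid, particles = NULL) {
  g <- grid
  label <- matrix("fluid", g$nx, g$ny)
  ghosts <- data.frame(i = integer(), j = integer(),
                       x_img_um = numeric(), y_img_um = numeric(),
                       owner = integer())
  if (!is.null(particles) && nrow(particles) > 0L) {
    keep <- maskable(grid, particles)
    pin <- particles[keep, , drop = FALSE]
    if (nrow(pin) > 0L) {
      if (any(pin$radius_um < 2 * max(g$dx, g$dy) * 1e6))
        warning("classify_cells: particle radius below 2 grid cells; ",
                "immersed boundary is under-resolved", call. = FALSE)
      xc_um <- g$xc * 1e6; yc_um <- g$yc * 1e6
      gc <- expand.grid(x = xc_um, y = yc_um)
      oc <- point_particle_owner(gc$x, gc$y, pin)
      solid <- matrix(oc$inside, g$nx, g$ny)
      owner_local <- matrix(oc$owner, g$nx, g$ny)
      ghost <- solid & has_open_neighbour(solid)
      label[solid] <- "solid"
      label[ghost] <- "ghost"
      gi <- which(ghost, arr.ind = TRUE)
      if (nrow(gi) > 0L) {
        map <- which(keep)
        own_l <- owner_local[gi]
        cx <- pin$x_um[own_l]; cy <- pin$y_um[own_l]; a <- pin$radius_um[own_l]
        px <- xc_um[gi[, 1L]]; py <- yc_um[gi[, 2L]]
        r <- sqrt((px - cx)^2 + (py - cy)^2)
        nx_ <- ifelse(r > 0, (px - cx) / r, 1)
        ny_ <- ifelse(r > 0, (py - cy) / r, 0)
        ghosts <- data.frame(
          i = gi[, 1L], j = gi[, 2L],
          x_img_um = cx + (2 * a - r) * nx_,
          y_img_um = cy + (2 * a - r) * ny_,
          owner = map[own_l]
        )
      }
    }
  }
  out <- structure(list(label = label, ghosts = ghosts,
                        particles = particles, grid = grid),
                   class = "cell_classification")
  attr(out, "face_masks") <- face_masks(grid, particles)
  out
}

#' Impose immersed-boundary conditions on the velocity field
#'
#' Writes the particle boundary conditions into the staggered velocity
#' arrays: faces deep inside a particle take the particle velocity; ghost
#' faces take the mirrored value `V_G = V_p + w_t - w_n`, where `w = V_I -
#' V_p` is the image-point velocity relative to the owning particle split
#' into components tangential and normal to the particle surface (slip and
#' impermeability conditions in the co-moving frame). Image-point values
#' are interpolated from open (non-solid) faces only, with renormalised
#' weights: a ghost never feeds back on itself, which keeps the
#' interleaved pressure-correction loop stable even for marginally
#' resolved particles. A ghost whose whole image stencil is solid falls
#' back to the particle velocity, with a warning.
#'
#' @param state a `flow_state`.
#' @param cls a [classify_cells()] result for the current particle
#'   configuration.
#' @param particles particle table (defaults to the one recorded in `cls`).
#' @param relax optional under-relaxation of the ghost update in `(0, 1]`
#'   (the fixed point is unchanged).
#' @param min_resolved_cells particles whose radius is below this many
#'   grid cells are treated by direct forcing (all their solid faces take
#'   the particle velocity): below ~2 cells the mirror geometry cannot be
#'   represented and its feedback can destabilise the solver loop.
#' @return The updated `flow_state`.
#' @export
apply_boundary_conditions <- function(state, cls, particles = cls$particles,
                                      relax = 1, min_resolved_cells = 2) {
  if (is.null(particles) || nrow(particles) == 0L) return(state)
  g <- state$grid
  fm <- attr(cls, "face_masks")
  if (is.null(fm)) fm <- face_masks(g, particles)
  warned <- FALSE
  resolved <- particles$radius_um >= min_resolved_cells * max(g$dx, g$dy) * 1e6

  set_component <- function(M, solid, ghost, owner, xs, ys, comp) {
    deep <- solid & !ghost
    if (any(deep)) {
      own <- owner[deep]
      M[deep] <- if (comp == 1L) particles$u[own] else particles$v[own]
    }
    # direct forcing for under-resolved owners
    direct <- ghost & matrix(!resolved[pmax(owner, 1L)] & owner > 0L,
                             nrow(owner), ncol(owner))
    if (any(direct)) {
      own <- owner[direct]
      M[direct] <- if (comp == 1L) particles$u[own] else particles$v[own]
    }
    ghost <- ghost & !direct
    gidx <- which(ghost, arr.ind = TRUE)
    if (nrow(gidx) > 0L) {
      own <- owner[ghost]
      cx <- um(particles$x_um[own]); cy <- um(particles$y_um[own])
      a <- um(particles$radius_um[own])
      px <- xs[gidx[, 1L]]; py <- ys[gidx[, 2L]]
      r <- sqrt((px - cx)^2 + (py - cy)^2)
      nhx <- ifelse(r > 0, (px - cx) / r, 1)
      nhy <- ifelse(r > 0, (py - cy) / r, 0)
      xi <- cx + (2 * a - r) * nhx
      yi <- cy + (2 * a - r) * nhy
      uI <- bilinear_masked(state$u, fm$u_solid, g$xu, g$yc, xi, yi)
      vI <- bilinear_masked(state$v, fm$v_solid, g$xc, g$yv, xi, yi)
      wpu <- particles$u[own]; wpv <- particles$v[own]
      bad <- is.na(uI) | is.na(vI)
      if (any(bad)) {
        if (!warned) {
          warning("apply_boundary_conditions: image stencil fully solid; ",
                  "falling back to the particle velocity", call. = FALSE)
          warned <<- TRUE
        }
        uI[bad] <- wpu[bad]
        vI[bad] <- wpv[bad]
      }
      wu <- uI - wpu; wv <- vI - wpv
      wn <- wu * nhx + wv * nhy
      gu <- wpu + (wu - 2 * wn * nhx)
      gv <- wpv + (wv - 2 * wn * nhy)
      val <- if (comp == 1L) gu else gv
      M[ghost] <- (1 - relax) * M[ghost] + relax * val
    }
    M
  }

  state$u <- set_component(state$u, fm$u_solid, fm$u_ghost, fm$u_owner,
                           g$xu, g$yc, 1L)
  state$v <- set_component(state$v, fm$v_solid, fm$v_ghost, fm$v_owner,
                           g$xc, g$yv, 2L)
  state
}
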