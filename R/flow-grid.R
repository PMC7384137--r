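#' Define the capillary flow grid
#'
#' Cartesian cell-centred grid for the 2D capillary lumen. The origin is at
#' the bottom-left corner; cell centres lie strictly inside the domain.
#' Velocities are stored on a staggered (MAC) arrangement: `u` on vertical
#' cell faces, `v` on horizontal cell faces, pressure at cell centres.
#'
#' @param nx,ny number of cells in x and y (both >= 4).
#' @param Lx_um,Ly_um domain length and height in micrometres
#'   (reference capillary segment: 30 x 8).
#' @return An object of class `flow_grid` with cell sizes and coordinate
#'   vectors in metres (`dx`, `dy`, cell centres `xc`, `yc`, u-face
#'   abscissae `xu`, v-face ordinates `yv`) plus the originals in
#'   micrometres.
#' @examples
#' g <- flow_grid(150, 40)
#' g$dx  # 0.2 um in metres
#' @export
flow_grid <- function(nx, ny, Lx_um = 30, Ly_um = 8) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 4L || ny < 4L)
    stop_config("flow_grid: nx and ny must be integers >= 4 (got %s, %s)", nx, ny)
  if (!is.finite(Lx_um) || !is.finite(Ly_um) || Lx_um <= 0 || Ly_um <= 0)
    stop_config("flow_grid: Lx_um and Ly_um must be positive")
  Lx <- um(Lx_um); Ly <- um(Ly_um)
  dx <- Lx / nx; dy <- Ly / ny
  structure(list(
    nx = nx, ny = ny,
    Lx = Lx, Ly = Ly, Lx_um = Lx_um, Ly_um = Ly_um,
    dx = dx, dy = dy,
    xc = (seq_len(nx) - 0.5) * dx,
    yc = (seq_len(ny) - 0.5) * dy,
    xu = (seq_len(nx + 1L) - 1) * dx,
    yv = (seq_len(ny + 1L) - 1) * dy
  ), class = "flow_grid")
}

#' Fluid properties of the capillary blood
#'
#' @param density mass density in kg/m^3 (reference whole blood: 1025).
#' @param viscosity dynamic viscosity in Pa.s (reference: 4.0e-3).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1025, viscosity = 4.0e-3) {
  if (!is.finite(density) || density <= 0)
    stop_config("fluid_properties: density must be > 0")
  if (!is.finite(viscosity) || viscosity <= 0)
    stop_config("fluid_properties: viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Boundary conditions for the capillary segment
#'
#' Dirichlet plug inflow on the left edge, zero-gradient (Neumann) outflow
#' with a global mass-flux correction on the right edge, and no-slip
#' impermeable walls on top and bottom.
#'
#' @param u_in inlet velocity in m/s (reference 0.03 cm/s = 3e-4 m/s).
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(u_in = 3e-4) {
  if (!is.finite(u_in) || u_in < 0)
    stop_config("boundary_spec: u_in must be >= 0 (m/s)")
  structure(list(u_in = u_in), class = "boundary_spec")
}

#' Initialise the flow state
#'
#' Plug initialisation: interior streamwise velocity set to the inlet value,
#' transverse velocity and pressure zero, walls consistent with no-slip.
#'
#' @param grid a [flow_grid()].
#' @param bc a [boundary_spec()].
#' @param props a [fluid_properties()].
#' @return An object of class `flow_state` holding the staggered fields
#'   `u` ((nx+1) x ny), `v` (nx x (ny+1)), `p` (nx x ny) and the time `t`
#'   in seconds.
#' @export
init_flow <- function(grid, bc, props) {
  stopifnot(inherits(grid, "flow_grid"), inherits(bc, "boundary_spec"),
            inherits(props, "fluid_properties"))
  structure(list(
    grid = grid, bc = bc, props = props,
    u = matrix(bc$u_in, grid$nx + 1L, grid$ny),
    v = matrix(0, grid$nx, grid$ny + 1L),
    p = matrix(0, grid$nx, grid$ny),
    t = 0
  ), class = "flow_state")
}

#' @rdname init_flow
#' @param x a `flow_state`.
#' @param ... unused.
#' @method print flow_state
#' @export
print.flow_state <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<flow_state> %d x %d cells (%.3g x %.3g um), t = %.4g s\n",
              g$nx, g$ny, g$Lx_um, g$Ly_um, x$t))
  cat(sprintf("  max |u| = %.4g m/s, max |v| = %.4g m/s, max |div| = %.3g 1/s\n",
              max(abs(x$u)), max(abs(x$v)), max(abs(divergence_field(x)))))
  invisible(x)
}

#' Discrete divergence of the velocity field
#'
#' Face-flux divergence of the staggered field per cell,
#' `(u_e - u_w)/dx + (v_n - v_s)/dy`, the quantity the pressure-correction
#' step drives to zero in fluid cells.
#'
#' @param state a `flow_state`.
#' @return An `nx` x `ny` matrix (1/s).
#' @export
divergence_field <- function(state) {
  stopifnot(inherits(state, "flow_state"))
  g <- state$grid
  (state$u[-1L, , drop = FALSE] - state$u[-(g$nx + 1L), , drop = FALSE]) / g$dx +
    (state$v[, -1L, drop = FALSE] - state$v[, -(g$ny + 1L), drop = FALSE]) / g$dy
}

#' Normalised change between two flow states
#'
#' Maximum-norm difference of the velocity fields normalised by the inlet
#' velocity scale; this is the residual monitored by the pressure-correction
#' loop (reference convergence criterion 0.5e-6).
#'
#' @param prev,next_ two `flow_state`s on the same grid.
#' @return A non-negative scalar; zero iff the fields are identical.
#' @export
flow_residual <- function(prev, next_) {
  stopifnot(inherits(prev, "flow_state"), inherits(next_, "flow_state"))
  if (!identical(dim(prev$u), dim(next_$u)) ||
      !identical(dim(prev$v), dim(next_$v)))
    stop_config("flow_residual: states are on different grids")
  scale <- abs(prev$bc$u_in)
  if (scale <= 0) scale <- 1
  max(max(abs(next_$u - prev$u)), max(abs(next_$v - prev$v))) / scale
}

#' Analytic plane-Poiseuille channel profile
#'
#' Fully developed laminar profile `6 u_mean (y/H)(1 - y/H)` used as the
#' validation oracle for the channel-flow benchmark.
#'
#' @param y wall-normal coordinate (same length unit as `H`).
#' @param u_mean mean (bulk) velocity.
#' @param H channel height.
#' @return Streamwise velocity at `y` (units of `u_mean`).
#' @export
analytic_channel_profile <- function(y, u_mean, H) {
  if (any(y < 0 | y > H))
    stop_config("analytic_channel_profile: y must lie in [0, H]")
  6 * u_mean * (y / H) * (1 - y / H)
}
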