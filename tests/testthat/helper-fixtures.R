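# Shared fixtures: small grids and hand-built flow states.

small_grid <- function(nx = 20, ny = 10, Lx_um = 10, Ly_um = 5) {
  flow_grid(nx, ny, Lx_um, Ly_um)
}

# A flow_state with prescribed staggered fields (defaults to uniform u).
manual_state <- function(grid, u = 3e-4, v = 0,
                         props = fluid_properties(),
                         bc = boundary_spec(if (is.matrix(u)) max(u) else u)) {
  st <- init_flow(grid, bc, props)
  st$u <- if (is.matrix(u)) u else matrix(u, grid$nx + 1L, grid$ny)
  st$v <- if (is.matrix(v)) v else matrix(v, grid$nx, grid$ny + 1L)
  st
}

# Independent second implementation of the staggered divergence stencil,
# written loop-wise as the oracle for divergence_field().
divergence_loops <- function(state) {
  g <- state$grid
  out <- matrix(NA_real_, g$nx, g$ny)
  for (i in seq_len(g$nx)) {
    for (j in seq_len(g$ny)) {
      out[i, j] <- (state$u[i + 1L, j] - state$u[i, j]) / g$dx +
        (state$v[i, j + 1L] - state$v[i, j]) / g$dy
    }
  }
  out
}

# Reference channel benchmark shared between tests (computed once).
channel_bench_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- solve_channel_flow(nx = 60, ny = 16)
    cache
  }
})
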