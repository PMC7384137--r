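# File outputs: CSV time series, a JSON run header, and legacy-VTK
# structured-grid snapshots of the flow fields.

fmt_df <- function(df) {
  for (k in seq_along(df)) {
    if (is.numeric(df[[k]]) && !is.integer(df[[k]]))
      df[[k]] <- sprintf("%.17g", df[[k]])  # exact read-back round trip
  }
  df
}

write_csv_exact <- function(df, path) {
  utils::write.csv(fmt_df(df), path, row.names = FALSE, quote = FALSE)
}

# Legacy ASCII VTK snapshot of one flow state: cell-centred velocity,
# pressure and cell classification on a STRUCTURED_POINTS lattice.
write_vtk_state <- function(state, cls, path, title = "aicdosim flow field") {
  g <- state$grid
  uc <- 0.5 * (state$u[-1L, , drop = FALSE] + state$u[-(g$nx + 1L), , drop = FALSE])
  vc <- 0.5 * (state$v[, -1L, drop = FALSE] + state$v[, -(g$ny + 1L), drop = FALSE])
  lab <- if (!is.null(cls)) cls$label else matrix("fluid", g$nx, g$ny)
  code <- matrix(match(lab, c("fluid", "solid", "ghost")) - 1L, g$nx, g$ny)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$nx + 1L, g$ny + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9e %.9e 1", g$dx, g$dy),
               sprintf("CELL_DATA %d", g$nx * g$ny)), con)
  wr_scalar <- function(name, M, type = "double") {
    writeLines(sprintf("SCALARS %s %s 1", name, type), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(paste(sprintf("%.9e", as.vector(M)), collapse = " "), con)
  }
  wr_scalar("u_mps", uc)
  wr_scalar("v_mps", vc)
  wr_scalar("p_Pa", state$p)
  writeLines("SCALARS cell_class int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(paste(as.vector(code), collapse = " "), con)
  invisible(path)
}

#' Write simulation outputs to disk
#'
#' Writes the dose, trajectory, activity, residual and source CSV files, a
#' JSON run header carrying the configuration, seeds and derived scenario
#' quantities, and (if snapshots were recorded) legacy-VTK flow-field
#' files named by step index.
#'
#' @param result an `aic_simulation`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "aic_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    if (is.null(df) || nrow(df) == 0L) return()
    p <- file.path(dir, name)
    write_csv_exact(df, p)
    files <<- c(files, p)
  }
  emit(result$dose, "dose.csv")
  emit(result$summary, "summary.csv")
  emit(result$trajectories, "trajectories.csv")
  emit(result$activity, "activity.csv")
  emit(result$residuals, "residuals.csv")
  emit(data.frame(id = seq_len(nrow(result$sources)),
                  x_um = result$sources[, 1], y_um = result$sources[, 2]),
       "sources.csv")
  header <- list(
    mode = result$mode,
    steps = result$steps, dt_s = result$dt_s, t_end_s = result$t_end_s,
    seeds = list(sources = result$config$sources$seed,
                 mc = result$config$mc$seed),
    scenario = result$scenario,
    config = unclass(result$config)
  )
  hp <- file.path(dir, "run_header.json")
  jsonlite::write_json(header, hp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, hp)
  for (sn in result$snapshots) {
    p <- file.path(dir, sprintf("flow_%05d.vtk", sn$step))
    write_vtk_state(sn$state, sn$cls, p)
    files <- c(files, p)
  }
  invisible(files)
}
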