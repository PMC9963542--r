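#' Write a trajectory to CSV
#'
#' Delimited text with \code{#}-prefixed header lines echoing the run
#' configuration and unit ledger, then the data columns
#' \code{time_s, x_um, y_um, uy_um_per_s, acoustic_force_N}.  Output is
#' byte-deterministic for a deterministic run (the simulator contains no
#' random number generation).
#'
#' @param traj a \code{trajectory}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  if (nrow(traj) == 0) .stop_invalid("traj", "trajectory is empty")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) .stop_config(
                    sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  hdr <- c(.echo_lines("config", attr(traj, "config")),
           .echo_lines("units", attr(traj, "units")),
           sprintf("# settled: %s", isTRUE(attr(traj, "settled"))),
           sprintf("# steady_y_m: %s",
                   formatC(attr(traj, "steady_y_m"), format = "g",
                           digits = 12)))
  writeLines(hdr, con)
  cols <- c("time_s", "x_um", "y_um", "uy_um_per_s", "acoustic_force_N")
  writeLines(paste(cols, collapse = ","), con)
  rows <- do.call(paste, c(lapply(cols, function(cc)
    formatC(traj[[cc]], format = "g", digits = 12)), sep = ","))
  writeLines(rows, con)
  invisible(path)
}

.echo_lines <- function(prefix, x) {
  if (is.null(x)) return(character())
  vapply(names(x), function(nm) {
    v <- x[[nm]]
    sprintf("# %s.%s: %s", prefix, nm,
            if (is.numeric(v)) formatC(v, format = "g", digits = 12)
            else as.character(v))
  }, "")
}

#' Write a field snapshot in legacy VTK format
#'
#' Density and velocity on the structured grid as an ASCII legacy VTK
#' STRUCTURED_POINTS file (loadable by standard visualization tools); an
#' optional membrane is written next to it as a POLYDATA point set at
#' \code{<path>_membrane.vtk}.
#'
#' @param state either a \code{\link{latticeState}} or a list with matrices
#'   \code{rho}, \code{ux}, \code{uy}.
#' @param path output file path.
#' @param membrane optional \code{membrane}.
#' @return the path, invisibly.
#' @export
writeSnapshot <- function(state, path, membrane = NULL) {
  if (inherits(state, "lattice_state")) {
    m <- latticeMoments(state$f)
    rho <- m$rho; ux <- m$u[, , 1]; uy <- m$u[, , 2]
  } else {
    rho <- state$rho; ux <- state$ux; uy <- state$uy
  }
  nx <- nrow(rho); ny <- ncol(rho)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) .stop_config(
                    sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 9)
  writeLines(c("# vtk DataFile Version 3.0",
               "acoustoLBM field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               "ORIGIN 0 0 0", "SPACING 1 1 1",
               sprintf("POINT_DATA %d", nx * ny),
               "SCALARS density double 1",
               "LOOKUP_TABLE default"), con)
  # VTK expects x fastest
  writeLines(num(as.vector(rho)), con)
  writeLines("VECTORS velocity double", con)
  writeLines(paste(num(as.vector(ux)), num(as.vector(uy)), "0"), con)
  if (!is.null(membrane)) {
    mp <- sub("(\\.vtk)?$", "_membrane.vtk", path)
    con2 <- file(mp, open = "wb"); on.exit(close(con2), add = TRUE)
    writeLines(c("# vtk DataFile Version 3.0",
                 "acoustoLBM membrane nodes", "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", membrane$n)), con2)
    writeLines(paste(num(membrane$nodes[, 1]), num(membrane$nodes[, 2]), "0"),
               con2)
  }
  invisible(path)
}

#' Read back a snapshot written by \code{\link{writeSnapshot}}
#'
#' @param path a legacy VTK STRUCTURED_POINTS file produced by this package.
#' @return list with matrices \code{rho}, \code{ux}, \code{uy}.
#' @export
readSnapshot <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
                                         grep("^DIMENSIONS", lines,
                                              value = TRUE))), "\\s+")[[1]])
  nx <- dims[1]; ny <- dims[2]
  i_sc <- grep("^LOOKUP_TABLE", lines)[1]
  rho <- as.numeric(lines[(i_sc + 1):(i_sc + nx * ny)])
  i_vec <- grep("^VECTORS velocity", lines)[1]
  vec <- do.call(rbind, strsplit(trimws(lines[(i_vec + 1):(i_vec + nx * ny)]),
                                 "\\s+"))
  list(rho = matrix(rho, nx, ny),
       ux = matrix(as.numeric(vec[, 1]), nx, ny),
       uy = matrix(as.numeric(vec[, 2]), nx, ny))
}

#' Write a JSON run summary
#'
#' @param summary a named list (settle time, steady position, error norms,
#'   config echo, ...).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRunSummary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
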