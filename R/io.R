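# Output writers: tidy CSV tables and legacy-ASCII VTK rectilinear-grid
# snapshots. All writers are bit-stable given identical inputs.

#' Write probe series to CSV
#'
#' Columns: `time_s`, `probe`, `field`, `value_umol_per_L`.
#'
#' @param result A [simulate()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_probes_csv <- function(result, path) {
  stopifnot(inherits(result, "bu_result"))
  utils::write.csv(result$probes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the mass-audit ledger to CSV
#'
#' @param result A [simulate()] result run with `audit = TRUE`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_audit_csv <- function(result, path) {
  audit <- mass_audit(result)
  utils::write.csv(as.data.frame(audit), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a field snapshot as a legacy-ASCII VTK rectilinear grid
#'
#' Cell data on the tensor-product mesh: the requested concentration fields
#' plus an integer `domain` mask (0 = ECF, 1 = plasma). Values outside a
#' field's domain are written as 0.
#'
#' @param result A [simulate()] result.
#' @param time One of `result$times`.
#' @param path Output file path (conventionally `.vtk`).
#' @param fields Fields to include.
#' @return The path, invisibly.
#' @export
write_snapshot_vtk <- function(result, time, path,
                               fields = c("Cpl", "Cecf", "B1", "B2")) {
  stopifnot(inherits(result, "bu_result"))
  mesh <- result$mesh
  con <- file(path, "w")
  on.exit(close(con))
  brk <- mesh$breaks
  npts <- length(brk)
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("brain unit snapshot t = %.10g s", time),
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", npts, npts, npts)), con)
  for (ax in c("X", "Y", "Z")) {
    writeLines(sprintf("%s_COORDINATES %d double", ax, npts), con)
    writeLines(paste(format(brk, digits = 12, scientific = TRUE), collapse = " "), con)
  }
  writeLines(sprintf("CELL_DATA %d", mesh$ncell), con)
  writeLines(c("SCALARS domain int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(mesh$plasma), collapse = " "), con)
  for (fld in fields) {
    arr <- get_field(result, fld, time)
    arr[is.na(arr)] <- 0
    writeLines(c(sprintf("SCALARS %s double 1", fld), "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.numeric(arr), digits = 12, scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Plot probe concentration-time profiles
#'
#' Log-log concentration-time curves of the plasma probe and the free,
#' specifically bound and non-specifically bound concentrations at the ECF
#' middle probe.
#'
#' @param x A [simulate()] result.
#' @param probe ECF probe to plot (default `"ecf_middle"`).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.bu_result <- function(x, probe = "ecf_middle", ...) {
  cpl <- probe_series(x, "plasma_x1_mid", "Cpl")
  ce <- probe_series(x, probe, "Cecf")
  b1 <- probe_series(x, probe, "B1")
  b2 <- probe_series(x, probe, "B2")
  t <- cpl$time_s
  m <- cbind(Cpl = cpl$value_umol_per_L, Cecf = ce$value_umol_per_L,
             B1 = b1$value_umol_per_L, B2 = b2$value_umol_per_L)
  keep <- t > 0
  floor_v <- 1e-12
  graphics::matplot(t[keep], pmax(m[keep, ], floor_v), type = "l", log = "xy",
                    lty = 1, col = c("red", "blue", "darkgreen", "orange"),
                    xlab = "time (s)", ylab = "concentration (umol/L)", ...)
  graphics::legend("bottomright", legend = colnames(m), lty = 1,
                   col = c("red", "blue", "darkgreen", "orange"), bty = "n")
  invisible(m)
}
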