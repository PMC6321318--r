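# Plain-text trajectory / energy I/O.

#' Write a configuration in GRO format
#'
#' Writes the real and virtual sites (O, H1, H2, M) of every molecule with
#' positions in nm and the cubic box on the last line.
#'
#' @param state a `cos_state`.
#' @param top a [build_topology()].
#' @param path output file.
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_gro <- function(state, top, path, title = "coswater configuration") {
  n <- top$nmol
  names4 <- c("OW", "HW1", "HW2", "MW")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, format(4L * n)), con)
  at <- 0L
  for (m in seq_len(n)) {
    for (s in 1:4) {
      at <- at + 1L
      p <- state$pos[(m - 1L) * 5L + s, ]
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         m, "SOL", names4[s], at, p[1], p[2], p[3]), con)
    }
  }
  L <- max(state$L, 0)
  writeLines(sprintf("%10.5f%10.5f%10.5f", L, L, L), con)
  invisible(path)
}

#' Write oxygen coordinates in XYZ format
#'
#' @param sim result of [run_simulation()] with `store_xyz = TRUE`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(sim, path) {
  if (is.null(sim$xyz)) stop("write_xyz: simulation has no stored coordinates")
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(sim$xyz)[1]; n <- dim(sim$xyz)[2]
  for (f in seq_len(nf)) {
    writeLines(c(format(n), sprintf("frame %d", f)), con)
    writeLines(sprintf("O %10.5f %10.5f %10.5f",
                       sim$xyz[f, , 1], sim$xyz[f, , 2], sim$xyz[f, , 3]), con)
  }
  invisible(path)
}

#' Write / read the per-frame energy report as CSV
#'
#' @param report the `report` data.frame of [run_simulation()].
#' @param path CSV file.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_energies <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_energies
#' @export
read_energies <- function(path) utils::read.csv(path)
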