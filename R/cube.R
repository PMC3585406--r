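# Gaussian CUBE volumetric format: header in bohr, values z-fastest.

#' Write a potential grid to a Gaussian CUBE file
#'
#' Header lengths are converted to bohr; values are written z-fastest, six
#' per line.  Atom records are optional (a CUBE natoms of 0 is accepted by
#' this package's reader).
#'
#' @param grid A `potential_grid`.
#' @param path Output path.
#' @param atoms Optional `mol_structure` whose atoms populate the header.
#' @param comment Two header comment lines.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path, atoms = NULL,
                       comment = c("electrostatic potential (kT/e)",
                                   "generated by mutsmith")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment[1:2], con)
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  b <- ANGSTROM_TO_BOHR
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", natoms,
                     grid$origin[1] * b, grid$origin[2] * b, grid$origin[3] * b), con)
  hx <- grid$spacing * b
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$dims[1], hx, 0, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$dims[2], 0, hx, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$dims[3], 0, 0, hx), con)
  if (natoms) {
    zmap <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
    z <- zmap[atoms$element]; z[is.na(z)] <- 6
    q <- if ("charge" %in% names(atoms)) atoms$charge else rep(0, natoms)
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", z, q,
                       atoms$x * b, atoms$y * b, atoms$z * b), con)
  }
  # z-fastest: for each (x, y) row, all z values
  v <- grid$values
  for (i in seq_len(grid$dims[1])) {
    for (j in seq_len(grid$dims[2])) {
      line_vals <- v[i, j, ]
      chunks <- split(line_vals, ceiling(seq_along(line_vals) / 6))
      for (ch in chunks) writeLines(paste(sprintf("%13.5E", ch), collapse = ""), con)
    }
  }
  invisible(path)
}

#' Read a Gaussian CUBE file
#'
#' Only orthogonal axis-aligned grids are supported; non-orthogonal axis
#' vectors are rejected.
#'
#' @param path Path to a CUBE file.
#' @return A `potential_grid` (values in the file's units).
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) abort(paste0("no such CUBE file: ", path))
  lines <- readLines(path)
  if (length(lines) < 6) abort("malformed CUBE header: fewer than 6 lines")
  parse_nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- parse_nums(lines[3])
  if (length(hdr) < 4 || is.na(hdr[1])) abort("malformed CUBE header line 3")
  natoms <- abs(as.integer(hdr[1]))
  b <- ANGSTROM_TO_BOHR
  origin <- hdr[2:4] / b
  axes <- lapply(4:6, function(i) parse_nums(lines[i]))
  dims <- vapply(axes, function(a) as.integer(a[1]), integer(1))
  vecs <- do.call(rbind, lapply(axes, function(a) a[2:4]))
  if (any(abs(vecs[upper.tri(vecs) | lower.tri(vecs)]) > 1e-8)) {
    abort("non-orthogonal CUBE axes are not supported")
  }
  spac <- diag(vecs) / b
  if (max(abs(spac - spac[1])) > 1e-8) abort("anisotropic CUBE spacing not supported")
  first_data <- 7 + natoms
  vals <- as.numeric(unlist(strsplit(trimws(lines[first_data:length(lines)]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims)) {
    abort(sprintf("CUBE value count %d does not match dims %d x %d x %d",
                  length(vals), dims[1], dims[2], dims[3]))
  }
  v <- array(0, dims)
  idx <- 1
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    v[i, j, ] <- vals[idx:(idx + dims[3] - 1)]
    idx <- idx + dims[3]
  }
  new_potential_grid(origin, spac[1], v)
}
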