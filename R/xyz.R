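#' Read an XYZ file
#'
#' Standard XYZ: first line the atom count, second a comment, then one
#' `El x y z` line per atom (Angstrom). A fifth numeric column, when
#' present, is read as a per-atom partial charge (extended XYZ
#' convention used by this toolkit).
#'
#' @param path file path.
#' @return a `cspkit_molecule`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path))
    stop("cannot open XYZ file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty XYZ file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("line 1: invalid atom count in ", path, call. = FALSE)
  if (length(lines) < n + 2)
    stop("file declares ", n, " atoms but has only ",
         max(0, length(lines) - 2), " atom lines: ", path, call. = FALSE)
  symbols <- character(n)
  coords <- matrix(0, n, 3)
  charges <- numeric(n)
  has_q <- FALSE
  for (i in seq_len(n)) {
    ln <- i + 2
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 4)
      stop("line ", ln, ": expected 'El x y z', got '", lines[ln], "'",
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz))
      stop("line ", ln, ": non-numeric coordinates", call. = FALSE)
    symbols[i] <- toks[1]
    coords[i, ] <- xyz
    if (length(toks) >= 5) {
      q <- suppressWarnings(as.numeric(toks[5]))
      if (!is.na(q)) { charges[i] <- q; has_q <- TRUE }
    }
  }
  molecule(symbols, coords, charges = if (has_q) charges else NULL)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a `cspkit_molecule`.
#' @param path output path.
#' @param comment comment line (default the atom count summary).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = NULL) {
  stopifnot(inherits(mol, "cspkit_molecule"))
  if (is.null(comment))
    comment <- sprintf("%d atoms, mass %.4f amu", nrow(mol$coords), mol$mass)
  has_q <- any(mol$charges != 0)
  lines <- c(
    as.character(nrow(mol$coords)),
    comment,
    vapply(seq_len(nrow(mol$coords)), function(i) {
      if (has_q)
        sprintf("%-2s %18.10f %18.10f %18.10f %12.6f", mol$symbols[i],
                mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3],
                mol$charges[i])
      else
        sprintf("%-2s %18.10f %18.10f %18.10f", mol$symbols[i],
                mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
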