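#' @title Minimal CIF input/output
#' @description A deliberately small CIF dialect for trusted sources: cell
#'   tags, space-group name/number, `_symmetry_equiv_pos_as_xyz` strings and
#'   fractional atom sites. Anything else is ignored with a warning.
#'   Coordinates are fractional in CIF; all internal geometry is Cartesian
#'   Angstrom.
#' @name cif
NULL

.cif_cell_tags <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                    "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")

#' Write a crystal structure to CIF
#'
#' In `"P1"` mode all Z molecule copies are written with `P1` symmetry (one
#' `x,y,z` operator); in `"symmetric"` mode only the asymmetric-unit
#' (canonical) molecule is written together with the group's operators as
#' canonical `_symmetry_equiv_pos_as_xyz` strings (bit-exact round-trip
#' with [read_cif()]).
#'
#' @param struct a `cspkit_crystal`.
#' @param path output path.
#' @param mode `"P1"` or `"symmetric"`.
#' @return `path`, invisibly.
#' @export
write_cif <- function(struct, path, mode = c("P1", "symmetric")) {
  mode <- match.arg(mode)
  stopifnot(inherits(struct, "cspkit_crystal"))
  cl <- struct$cell
  sg <- struct$sg
  lines <- c(
    sprintf("data_%s", gsub("[^A-Za-z0-9]", "", paste0("cspkit_", sg$symbol))),
    sprintf("_cell_length_a    %.8f", cl$lengths[1]),
    sprintf("_cell_length_b    %.8f", cl$lengths[2]),
    sprintf("_cell_length_c    %.8f", cl$lengths[3]),
    sprintf("_cell_angle_alpha %.8f", cl$angles[1]),
    sprintf("_cell_angle_beta  %.8f", cl$angles[2]),
    sprintf("_cell_angle_gamma %.8f", cl$angles[3])
  )
  if (mode == "P1") {
    lines <- c(lines,
               "_symmetry_space_group_name_H-M 'P1'",
               "_symmetry_Int_Tables_number 1",
               "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'")
    atoms <- do.call(rbind, struct$frac_copies)
    symbols <- rep(struct$mol$symbols, length(struct$copies))
  } else {
    lines <- c(lines,
               sprintf("_symmetry_space_group_name_H-M '%s'", sg$symbol),
               sprintf("_symmetry_Int_Tables_number %d", sg$number),
               "loop_", "_symmetry_equiv_pos_as_xyz",
               sprintf("'%s'", sg$op_strings))
    atoms <- struct$frac_copies[[struct$canonical_index]]
    symbols <- struct$mol$symbols
  }
  lines <- c(lines,
             "loop_",
             "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             vapply(seq_len(nrow(atoms)), function(i)
               sprintf("%s%d %s %.8f %.8f %.8f", symbols[i], i, symbols[i],
                       atoms[i, 1], atoms[i, 2], atoms[i, 3]),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

# tokenize one CIF line respecting single quotes
.cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(line, list(m))[[1]]
  gsub("^'|'$", "", toks)
}

#' Read a crystal structure from a (trusted) CIF file
#'
#' Requires the six cell tags, at least one `_symmetry_equiv_pos_as_xyz`
#' operator and fractional atom sites. The operator set must match one of
#' the supported space groups (standard settings only; non-standard
#' settings are rejected, not converted). Atom sites are grouped into Z
#' contiguous molecule blocks; the generating crystal parameters are
#' recovered with [extract_parameters()] using the first block as the
#' reference molecule.
#'
#' @param path CIF file path.
#' @param verbose warn about ignored tags.
#' @return a `cspkit_crystal`.
#' @export
read_cif <- function(path, verbose = FALSE) {
  if (!file.exists(path))
    stop("cannot open CIF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tags <- list()
  symops <- character(0)
  atom_rows <- list()
  atom_cols <- character(0)
  i <- 1
  ignored <- character(0)
  while (i <= length(lines)) {
    ln <- lines[i]
    if (identical(ln, "loop_")) {
      hdr <- character(0)
      i <- i + 1
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        hdr <- c(hdr, .cif_tokens(lines[i])[1])
        i <- i + 1
      }
      body <- list()
      while (i <= length(lines) && !startsWith(lines[i], "_") &&
             !identical(lines[i], "loop_") && !startsWith(lines[i], "data_")) {
        body[[length(body) + 1]] <- .cif_tokens(lines[i])
        i <- i + 1
      }
      if ("_symmetry_equiv_pos_as_xyz" %in% hdr) {
        col <- match("_symmetry_equiv_pos_as_xyz", hdr)
        symops <- vapply(body, function(row) row[col], character(1))
      } else if (any(startsWith(hdr, "_atom_site_"))) {
        atom_cols <- hdr
        atom_rows <- body
      } else {
        ignored <- c(ignored, hdr)
      }
      next
    }
    if (startsWith(ln, "_")) {
      toks <- .cif_tokens(ln)
      if (length(toks) >= 2) tags[[toks[1]]] <- toks[2] else
        ignored <- c(ignored, toks[1])
    } else if (!startsWith(ln, "data_")) {
      ignored <- c(ignored, ln)
    }
    i <- i + 1
  }
  if (verbose && length(ignored))
    warning("ignored CIF content: ", paste(unique(ignored), collapse = ", "),
            call. = FALSE)
  missing <- setdiff(.cif_cell_tags, names(tags))
  if (length(missing))
    stop("CIF missing mandatory tag(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cellv <- as.numeric(unlist(tags[.cif_cell_tags]))
  if (anyNA(cellv)) stop("non-numeric cell tags in ", path, call. = FALSE)
  if (length(symops) == 0)
    stop("CIF missing _symmetry_equiv_pos_as_xyz operators", call. = FALSE)
  sg <- .match_spacegroup(symops)
  fx <- match("_atom_site_fract_x", atom_cols)
  fy <- match("_atom_site_fract_y", atom_cols)
  fz <- match("_atom_site_fract_z", atom_cols)
  ty <- match("_atom_site_type_symbol", atom_cols)
  if (is.na(ty)) ty <- match("_atom_site_label", atom_cols)
  if (anyNA(c(fx, fy, fz, ty)) || length(atom_rows) == 0)
    stop("CIF missing fractional atom sites", call. = FALSE)
  frac <- t(vapply(atom_rows, function(row)
    as.numeric(row[c(fx, fy, fz)]), numeric(3)))
  symbols <- gsub("[0-9]+$", "", vapply(atom_rows, function(row) row[ty],
                                        character(1)))
  cl <- make_cell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  cellpar <- c(cl$lengths, cl$angles)
  if (sg$Z == 1) {
    # P1 export: all atoms form one (possibly multi-copy) block; the
    # caller regroups with extract_parameters() and the true group
    mol <- molecule(symbols, frac %*% cl$T)
    mol <- standardize(mol)$molecule
    params <- extract_parameters(list(cell = cl, copies = list(frac %*% cl$T)),
                                 mol, sg)
    return(build_unit_cell(mol, params))
  }
  # symmetric export: the atom block is the asymmetric-unit conformer
  mol <- molecule(symbols, frac %*% cl$T)
  mol <- standardize(mol)$molecule
  cf <- colMeans(frac)
  cen_frac <- cf - floor(cf + 1e-9)
  if (!.in_asym(sg, cen_frac))
    stop("asymmetric-unit molecule centroid (",
         paste(signif(cen_frac, 6), collapse = ", "),
         ") lies outside the asymmetric unit of ", sg$symbol, call. = FALSE)
  X <- frac %*% cl$T
  fit <- .kabsch(mol$std_coords, sweep(X, 2, colMeans(X)))
  params <- crystal_parameters(cellpar, cen_frac,
                               rotvec_from_rotation(fit$R), sg, check = FALSE)
  build_unit_cell(mol, params)
}

# identify a supported space group from its operator strings
.match_spacegroup <- function(symops) {
  ops <- lapply(symops, parse_symop)
  canon <- sort(vapply(ops, symop_to_string, character(1)))
  for (g in .sg_registry) {
    if (length(g$ops) == length(ops) &&
        identical(sort(g$op_strings), canon)) return(g)
  }
  supp <- supported_spacegroups()
  stop("unsupported space group (operators match no supported standard ",
       "setting); supported: ",
       paste(sprintf("%d (%s)", supp$number, supp$symbol), collapse = ", "),
       call. = FALSE)
}
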