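#' @title Space-group symmetry tables
#' @description Hard-coded standard settings for the space groups that
#'   dominate organic molecular crystals. Each group stores its
#'   general-position operators (as affine maps on fractional coordinates),
#'   the multiplicity Z (including centering), the crystal system (which
#'   fixes cell-angle constraints), and the fractional bounds of a
#'   parallelepiped asymmetric unit that is a fundamental domain for the
#'   action of the group on molecule centroids.
#' @name symmetry
NULL

# general positions in standard settings (International Tables, standard
# cell choices; monoclinic unique axis b). Asymmetric-unit boxes are chosen
# so that for a generic point exactly one orbit image (mod 1) lies inside.
.sg_defs <- list(
  list(number = 1L, symbol = "P1", system = "triclinic",
       ops = c("x,y,z"),
       asym = c(1, 1, 1)),
  list(number = 2L, symbol = "P-1", system = "triclinic",
       ops = c("x,y,z", "-x,-y,-z"),
       asym = c(1, 1, 1 / 2)),
  list(number = 4L, symbol = "P21", system = "monoclinic",
       ops = c("x,y,z", "-x,y+1/2,-z"),
       asym = c(1, 1 / 2, 1)),
  list(number = 7L, symbol = "Pc", system = "monoclinic",
       ops = c("x,y,z", "x,-y,z+1/2"),
       asym = c(1, 1 / 2, 1)),
  list(number = 9L, symbol = "Cc", system = "monoclinic",
       ops = c("x,y,z", "x,-y,z+1/2", "x+1/2,y+1/2,z", "x+1/2,-y+1/2,z+1/2"),
       asym = c(1 / 2, 1 / 2, 1)),
  list(number = 14L, symbol = "P21/c", system = "monoclinic",
       ops = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
       asym = c(1, 1 / 4, 1)),
  list(number = 15L, symbol = "C2/c", system = "monoclinic",
       ops = c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
               "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2",
               "-x+1/2,-y+1/2,-z", "x+1/2,-y+1/2,z+1/2"),
       asym = c(1 / 2, 1 / 2, 1 / 2)),
  list(number = 18L, symbol = "P21212", system = "orthorhombic",
       ops = c("x,y,z", "-x,-y,z", "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
       asym = c(1 / 4, 1, 1)),
  list(number = 19L, symbol = "P212121", system = "orthorhombic",
       ops = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
       asym = c(1, 1 / 4, 1)),
  list(number = 29L, symbol = "Pca21", system = "orthorhombic",
       ops = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y,z", "-x+1/2,y,z+1/2"),
       asym = c(1 / 4, 1, 1)),
  list(number = 33L, symbol = "Pna21", system = "orthorhombic",
       ops = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y+1/2,z", "-x+1/2,y+1/2,z+1/2"),
       asym = c(1 / 4, 1, 1)),
  list(number = 61L, symbol = "Pbca", system = "orthorhombic",
       ops = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z",
               "-x,-y,-z", "x+1/2,y,-z+1/2", "x,-y+1/2,z+1/2", "-x+1/2,y+1/2,z"),
       asym = c(1 / 2, 1 / 2, 1 / 2))
)

#' Parse a CIF-style symmetry-operator string
#'
#' Converts a `_symmetry_equiv_pos_as_xyz` string such as
#' `"-x,y+1/2,-z+1/2"` into a 3 x 3 rotation matrix and a translation
#' 3-vector acting on fractional coordinate columns: `p' = M p + t`.
#'
#' @param s operator string (three comma-separated terms).
#' @return list with `M` (3 x 3) and `t` (length-3, reduced mod 1 to [0,1)).
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[ ']", "", s), ",")[[1]]
  if (length(parts) != 3)
    stop("malformed symmetry operator string: ", s, call. = FALSE)
  M <- matrix(0, 3, 3)
  tv <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        M[i, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        tv[i] <- tv[i] + sgn * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tv[i] <- tv[i] + sgn * as.numeric(body)
      } else {
        stop("cannot parse symmetry operator term '", tok, "' in: ", s,
             call. = FALSE)
      }
    }
  }
  list(M = M, t = tv %% 1)
}

#' Format a symmetry operator as a CIF string
#'
#' Inverse of [parse_symop()]: produces the canonical string form
#' (`x`,`y`,`z` terms in order, translation as a reduced fraction appended),
#' so that `symop_to_string(parse_symop(s))` reproduces canonical strings
#' bit-exactly.
#'
#' @param op list with `M` and `t` as returned by [parse_symop()].
#' @return character string.
#' @export
symop_to_string <- function(op) {
  frac_str <- function(v) {
    v <- v %% 1
    if (abs(v) < 1e-9 || abs(v - 1) < 1e-9) return("")
    for (den in c(2, 3, 4, 6)) {
      num <- v * den
      if (abs(num - round(num)) < 1e-9) return(sprintf("%d/%d", as.integer(round(num)), den))
    }
    sprintf("%.6f", v)
  }
  out <- character(3)
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    term <- ""
    for (j in 1:3) {
      cij <- op$M[i, j]
      if (abs(cij) < 1e-9) next
      sgn <- if (cij < 0) "-" else if (nzchar(term)) "+" else ""
      term <- paste0(term, sgn, ax[j])
    }
    fs <- frac_str(op$t[i])
    if (nzchar(fs)) term <- paste0(term, "+", fs)
    out[i] <- term
  }
  paste(out, collapse = ",")
}

.build_spacegroup <- function(def) {
  ops <- lapply(def$ops, parse_symop)
  sg <- structure(list(
    number = def$number,
    symbol = def$symbol,
    system = def$system,
    ops = ops,
    op_strings = vapply(ops, symop_to_string, character(1)),
    Z = length(ops),
    asym_min = c(0, 0, 0),
    asym_max = def$asym
  ), class = "cspkit_spacegroup")
  sg
}

.sg_registry <- lapply(.sg_defs, .build_spacegroup)
names(.sg_registry) <- vapply(.sg_defs, function(d) as.character(d$number), character(1))

#' Supported space groups
#' @return data.frame of supported group numbers, Hermann-Mauguin symbols,
#'   multiplicities and crystal systems.
#' @export
supported_spacegroups <- function() {
  data.frame(
    number = vapply(.sg_registry, function(g) g$number, integer(1)),
    symbol = vapply(.sg_registry, function(g) g$symbol, character(1)),
    Z = vapply(.sg_registry, function(g) g$Z, integer(1)),
    system = vapply(.sg_registry, function(g) g$system, character(1)),
    row.names = NULL
  )
}

#' Look up a space group
#'
#' @param key integer space-group number or Hermann-Mauguin symbol (e.g.
#'   `33` or `"Pna21"`). Only the standard setting is provided; non-standard
#'   settings are not converted.
#' @return a `cspkit_spacegroup` with fields `number`, `symbol`, `system`,
#'   `ops` (list of `list(M, t)`), `op_strings`, `Z`, `asym_min`, `asym_max`.
#' @export
get_spacegroup <- function(key) {
  if (inherits(key, "cspkit_spacegroup")) return(key)
  if (is.numeric(key)) {
    g <- .sg_registry[[as.character(as.integer(key))]]
  } else {
    sym <- gsub(" ", "", toupper(as.character(key)))
    syms <- toupper(vapply(.sg_registry, function(g) g$symbol, character(1)))
    g <- if (sym %in% syms) .sg_registry[[which(syms == sym)[1]]] else NULL
  }
  if (is.null(g)) {
    supp <- supported_spacegroups()
    stop("unsupported space group '", key, "'; supported: ",
         paste(sprintf("%d (%s)", supp$number, supp$symbol), collapse = ", "),
         call. = FALSE)
  }
  g
}

#' Apply all symmetry operators to fractional points
#'
#' Applies each general-position operator of the group to every point.
#' Results are NOT wrapped into the unit cell; wrapping is done molecule-wise
#' by the crystal assembler.
#'
#' @param sg a space group (or key accepted by [get_spacegroup()]).
#' @param frac_points M x 3 matrix of fractional coordinates.
#' @return array of dimension Z x M x 3.
#' @export
apply_ops <- function(sg, frac_points) {
  sg <- get_spacegroup(sg)
  fp <- matrix(as.numeric(frac_points), ncol = 3)
  out <- array(0, dim = c(sg$Z, nrow(fp), 3))
  for (k in seq_len(sg$Z)) {
    op <- sg$ops[[k]]
    out[k, , ] <- fp %*% t(op$M) + matrix(op$t, nrow(fp), 3, byrow = TRUE)
  }
  out
}

# angle constraints implied by the crystal system (unique axis b for
# monoclinic): returns the angles with fixed ones set to 90 degrees.
.constrain_angles <- function(sg, angles) {
  switch(sg$system,
         triclinic = angles,
         monoclinic = c(90, angles[2], 90),
         orthorhombic = c(90, 90, 90),
         stop("unknown crystal system"))
}

# logical mask of free cell parameters (a,b,c always free)
.free_angle_mask <- function(sg) {
  switch(sg$system,
         triclinic = c(TRUE, TRUE, TRUE),
         monoclinic = c(FALSE, TRUE, FALSE),
         orthorhombic = c(FALSE, FALSE, FALSE))
}

#' @export
print.cspkit_spacegroup <- function(x, ...) {
  cat(sprintf("<space group %d (%s), %s, Z = %d>\n",
              x$number, x$symbol, x$system, x$Z))
  invisible(x)
}
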