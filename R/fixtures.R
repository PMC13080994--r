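#' @title Synthetic rigid test molecules
#' @description Deterministic toy molecules (elements from H, C, N, O, F,
#'   at most 24 atoms) standing in for database entries: a planar
#'   six-membered ring with substituents, a two-atom dumbbell, and a seeded
#'   random rigid blob. All are returned standardized. The ring carries two
#'   fluorine substituents so its principal moments are non-degenerate and
#'   the canonical orientation is unique.
#' @name fixtures
NULL

.fixture_builders <- list(
  # planar aromatic-like ring: C6 hexagon (1.40 A bonds), two adjacent F
  # (1.35 A) and four H (1.08 A) substituents
  ring6 = function(rng) {
    th <- (0:5) * pi / 3
    ring <- cbind(1.40 * cos(th), 1.40 * sin(th), 0)
    rsub <- c(1.40 + 1.35, 1.40 + 1.35, rep(1.40 + 1.08, 4))
    subs <- cbind(rsub * cos(th), rsub * sin(th), 0)
    molecule(c(rep("C", 6), "F", "F", rep("H", 4)), rbind(ring, subs))
  },
  # rigid dumbbell: two carbons at a 1.54 A single-bond distance
  dumbbell = function(rng) {
    molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)))
  },
  # 10-atom random rigid blob: heavy atoms grown with 1.3-1.6 A spacing,
  # minimum separation 1.2 A, elements drawn from C/N/O/F with H padding
  blob = function(rng) {
    n <- 10
    pool <- c("C", "C", "C", "N", "O", "F", "H")
    symbols <- pool[1 + floor(rng(n) * length(pool))]
    coords <- matrix(0, n, 3)
    for (i in 2:n) {
      repeat {
        j <- 1 + floor(rng(1) * (i - 1))
        dir <- stats::qnorm(pmin(pmax(rng(3), 1e-6), 1 - 1e-6))
        dir <- dir / sqrt(sum(dir^2))
        cand <- coords[j, ] + (1.3 + 0.3 * rng(1)) * dir
        d <- sqrt(rowSums((coords[seq_len(i - 1), , drop = FALSE] -
                             matrix(cand, i - 1, 3, byrow = TRUE))^2))
        if (all(d > 1.2)) { coords[i, ] <- cand; break }
      }
    }
    molecule(symbols, coords)
  }
)

#' Names of the built-in fixture molecules
#' @return character vector.
#' @export
fixture_names <- function() names(.fixture_builders)

#' Generate a synthetic rigid molecule
#'
#' Deterministic given `(name, seed)`; the result is standardized.
#'
#' @param name one of [fixture_names()].
#' @param seed integer seed for the stochastic fixtures (ignored by the
#'   deterministic ones).
#' @return a standardized `cspkit_molecule`.
#' @export
generate_fixture <- function(name, seed = 1) {
  if (!name %in% names(.fixture_builders))
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "), call. = FALSE)
  # private RNG stream: does not disturb the global .Random.seed
  state <- as.integer(seed)
  rng <- function(k) {
    out <- numeric(k)
    for (i in seq_len(k)) {
      state <<- (69069 * state + 12345) %% 2147483648
      out[i] <- state / 2147483648
    }
    out
  }
  mol <- .fixture_builders[[name]](rng)
  standardize(mol)$molecule
}
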