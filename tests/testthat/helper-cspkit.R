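# shared helpers: independent numerical oracles and small constructors

# central-difference gradient (independent of the package's analytic path);
# Richardson-extrapolated (4th order) because jammed random crystals have
# steep repulsive contacts where the plain h^2 truncation term dominates
num_grad <- function(f, p, h = 1e-4) {
  cd <- function(hh) vapply(seq_along(p), function(i) {
    pp <- p; pm <- p
    pp[i] <- pp[i] + hh
    pm[i] <- pm[i] - hh
    (f(pp) - f(pm)) / (2 * hh)
  }, numeric(1))
  (4 * cd(h / 2) - cd(h)) / 3
}

# uniform random rotation matrix
rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force scalar-loop LJ cluster energy (independent oracle)
brute_lj <- function(cluster, pp) {
  total <- 0
  for (nb in cluster$neighbors) {
    for (i in seq_len(nrow(cluster$central))) {
      for (j in seq_len(nrow(nb$coords))) {
        r <- sqrt(sum((cluster$central[i, ] - nb$coords[j, ])^2))
        if (r >= pp$cutoff) next
        s <- (pp$sigma[cluster$symbols[i]] + pp$sigma[cluster$symbols[j]]) / 2
        e <- sqrt(pp$epsilon[cluster$symbols[i]] * pp$epsilon[cluster$symbols[j]])
        S <- if (pp$taper <= 0 || r <= pp$cutoff - pp$taper) 1 else
          0.5 * (1 + cos(pi * (r - (pp$cutoff - pp$taper)) / pp$taper))
        total <- total + 4 * e * ((s / r)^12 - (s / r)^6) * S
      }
    }
  }
  as.numeric(total)
}

# brute-force RDF histogram counts by unordered element pair
brute_rdf <- function(cluster, r_max, n_bins) {
  keys <- character(0)
  counts <- list()
  for (nb in cluster$neighbors) {
    for (i in seq_len(nrow(cluster$central))) {
      for (j in seq_len(nrow(nb$coords))) {
        r <- sqrt(sum((cluster$central[i, ] - nb$coords[j, ])^2))
        if (r >= r_max) next
        key <- paste(sort(c(cluster$symbols[i], cluster$symbols[j])),
                     collapse = "-")
        if (!key %in% keys) {
          keys <- c(keys, key)
          counts[[key]] <- numeric(n_bins)
        }
        b <- min(floor(r / (r_max / n_bins)) + 1, n_bins)
        counts[[key]][b] <- counts[[key]][b] + 1
      }
    }
  }
  counts
}

# hand-built two-atom cluster: one single-atom central molecule and one
# single-atom neighbor at distance r along x
pair_cluster <- function(r, sym = "C") {
  mol <- molecule(sym, matrix(0, 1, 3))
  structure(list(symbols = mol$symbols, central = matrix(0, 1, 3),
                 neighbors = list(list(op = 1L, shift = c(0, 0, 0),
                                       coords = matrix(c(r, 0, 0), 1, 3))),
                 cell = make_cell(50, 50, 50), sg = get_spacegroup(1),
                 mol = mol, cutoff = r + 1, params = NULL),
            class = "cspkit_cluster")
}

# a synthetic RDF profile with given per-pair counts over shared binning
toy_rdf <- function(counts, r_max = 10, n_bins = 100) {
  counts <- as.matrix(counts)
  structure(list(edges = seq(0, r_max, length.out = n_bins + 1),
                 counts = counts, normalization = "counts"),
            class = "cspkit_rdf")
}
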