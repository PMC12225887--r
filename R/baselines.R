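# Baseline ensembles: freely jointed chains, orientation-random space-filling
# curves, and tunable-heterogeneity synthetic ensembles.

# ---- orientation-random space-filling (Hilbert-type) curves ---------------
#
# The canonical order-1 template visits the 8 corners of the unit cube along
# a Hamiltonian path (a 3D Hilbert curve of order 1). Higher orders are built
# recursively: the 8 octants are traversed along a (possibly reoriented)
# copy of the template, and each octant holds an order-(p-1) curve whose
# entry and exit corners are re-anchored so that consecutive cells are
# always lattice neighbors. Randomness enters through a fresh random cube
# symmetry (signed axis permutation) at the top level and through random
# choices among the valid continuity tables at every internal node; the
# resulting replicas are distinct bijective space-filling orderings that all
# retain unit steps and Hilbert-like locality (scaling exponent near 1/3).

hilbert_template <- function() {
  # corner sequence: Hamiltonian path 000 -> 001 on the unit cube
  matrix(c(0, 0, 0,
           0, 1, 0,
           1, 1, 0,
           1, 0, 0,
           1, 0, 1,
           1, 1, 1,
           0, 1, 1,
           0, 0, 1), ncol = 3L, byrow = TRUE)
}

# all 48 signed axis permutations as functions on 0/1 corner matrices
signed_perms <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (s1 in 0:1) for (s2 in 0:1) for (s3 in 0:1)
    out[[length(out) + 1L]] <- list(perm = p, flip = c(s1, s2, s3))
  out
}

apply_sym <- function(sym, corners) {
  m <- corners[, sym$perm, drop = FALSE]
  for (a in 1:3) if (sym$flip[a] == 1) m[, a] <- 1 - m[, a]
  m
}

# orderings of the 8 octants from corner a to corner b (unit-axis pair),
# as images of the template under the cube symmetry group
octant_orderings <- function(a, b, syms) {
  tpl <- hilbert_template()
  out <- list()
  for (sym in syms) {
    m <- apply_sym(sym, tpl)
    if (all(m[1L, ] == a) && all(m[8L, ] == b))
      out[[length(out) + 1L]] <- m
  }
  out
}

# child entry/exit corner tables for a given octant ordering: backtracking
# over exit corners so that every octant-to-octant transition is a unit step
# and every child's (entry, exit) pair is a unit-axis corner pair.
corner_tables <- function(orders, a, b) {
  solutions <- list()
  recurse <- function(k, a_k, acc) {
    if (k == 8L) {
      if (sum(abs(b - a_k)) == 1L)
        solutions[[length(solutions) + 1L]] <<-
          rbind(acc, c(a_k, b))
      return(invisible())
    }
    u <- orders[k + 1L, ] - orders[k, ]
    ax <- which(u != 0)
    side <- if (u[ax] > 0) 1L else 0L
    # exit corner: unit neighbor of a_k lying on the face toward octant k+1
    for (flip_ax in 1:3) {
      b_k <- a_k
      b_k[flip_ax] <- 1L - b_k[flip_ax]
      if (b_k[ax] != side) next
      a_next <- b_k
      a_next[ax] <- 1L - a_next[ax]
      recurse(k + 1L, a_next, rbind(acc, c(a_k, b_k)))
    }
  }
  recurse(1L, a, NULL)
  solutions
}

build_curve <- function(q, a, b, syms, randomize) {
  if (q == 0L) return(matrix(0L, 1L, 3L))
  orders <- octant_orderings(a, b, syms)
  pick <- function(lst) if (randomize && length(lst) > 1L)
    lst[[sample.int(length(lst), 1L)]] else lst[[1L]]
  ord <- pick(orders)
  tables <- corner_tables(ord, a, b)
  if (!length(tables)) {                       # fall back to the other coset
    for (o in orders) {
      tables <- corner_tables(o, a, b)
      if (length(tables)) { ord <- o; break }
    }
  }
  tab <- pick(tables)
  m <- 2L^(q - 1L)
  blocks <- vector("list", 8L)
  for (k in 1:8) {
    child <- build_curve(q - 1L, tab[k, 1:3], tab[k, 4:6], syms, randomize)
    blocks[[k]] <- sweep(child, 2L, ord[k, ] * m, "+")
  }
  do.call(rbind, blocks)
}

#' Generate orientation-random space-filling curve replicas
#'
#' Builds `n_replicas` distinct approximate-Hilbert space-filling curves of
#' `8^p` points on the `2^p` cube: each replica visits every lattice cell
#' exactly once with unit steps, but the traversal pattern differs from
#' replica to replica through random reorientation, mimicking cell-to-cell
#' variability of territorial, fractal-like chromatin packing. With
#' `randomize = FALSE` every replica is the canonical curve (at `p = 1`,
#' the canonical 8-point order-1 template).
#'
#' @param p recursion order; each replica has `8^p` points.
#' @param n_replicas number of curves.
#' @param seed integer seed.
#' @param unit_genomic_kb genomic size assigned to one lattice cell, in kb.
#' @param randomize draw a fresh random orientation per replica.
#' @return A `chrom_ensemble` (length unit `"arbitrary"`).
#' @export
gen_hilbert_ensemble <- function(p = 4L, n_replicas = 18L, seed = NULL,
                                 unit_genomic_kb = 10, randomize = TRUE) {
  stopifnot(p >= 1L)
  if (!is.null(seed)) set.seed(seed)
  syms <- signed_perms()
  tpl <- hilbert_template()
  confs <- lapply(seq_len(n_replicas), function(r) {
    if (randomize) {
      top <- apply_sym(syms[[sample.int(48L, 1L)]], tpl)
    } else {
      top <- tpl
    }
    curve <- build_curve(p, top[1L, ], top[8L, ], syms, randomize)
    conformation(curve, cell_id = paste0("hilbert_", r),
                 genomic_kb = unit_genomic_kb)
  })
  conformation_ensemble(confs, length_unit = "arbitrary",
                        resolution_kb = unit_genomic_kb)
}

# ---- freely jointed chains -------------------------------------------------

#' Generate freely jointed chain replicas
#'
#' Each replica is a random walk of `n_segments` segments of exact length
#' `segment_length` with isotropic directions (normalized 3D Gaussian
#' draws), the simplest generic polymer baseline. For long chains the
#' end-to-end distance approaches mean `l * sqrt(s)` with spread
#' `l * sqrt(s/3)`, so the Relative C.H. approaches `1/sqrt(3)` (see
#' [fjc_relative_ch_limit()]).
#'
#' @param n_segments segments per chain (beads = `n_segments + 1`).
#' @param segment_length exact segment length `l`.
#' @param n_replicas number of chains.
#' @param seed integer seed.
#' @param unit_genomic_kb genomic size per segment, in kb.
#' @return A `chrom_ensemble` (length unit `"arbitrary"`).
#' @export
gen_fjc_ensemble <- function(n_segments = 2047L, segment_length = 1,
                             n_replicas = 18L, seed = NULL,
                             unit_genomic_kb = 10) {
  if (!is.null(seed)) set.seed(seed)
  confs <- lapply(seq_len(n_replicas), function(r) {
    g <- matrix(rnorm(3L * n_segments), ncol = 3L)
    steps <- g / sqrt(rowSums(g^2)) * segment_length
    coords <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    conformation(coords, cell_id = paste0("fjc_", r),
                 genomic_kb = unit_genomic_kb)
  })
  conformation_ensemble(confs, length_unit = "arbitrary",
                        resolution_kb = unit_genomic_kb)
}

#' Large-separation Relative C.H. limit of the freely jointed chain
#'
#' Under the normal approximation for the FJC end-to-end distance (mean
#' `l * sqrt(s)`, standard deviation `l * sqrt(s/3)`), the ratio of spread
#' to mean is independent of s, giving the s -> infinity Relative C.H.
#' limit `1/sqrt(3) ~= 0.5774` (conventionally printed as 0.57). Finite
#' chains stay below this bound. Note the exact end-to-end distance of an
#' ideal chain is Maxwell-distributed, for which the ratio would be
#' `sqrt(3 * pi / 8 - 1) ~= 0.42`; the normal-approximation value is the
#' one used as the reference bound here.
#'
#' @return `1/sqrt(3)`, with attribute `printed` carrying the conventional
#'   two-decimal rounding 0.57.
#' @export
fjc_relative_ch_limit <- function() {
  structure(1 / sqrt(3), printed = 0.57)
}

# ---- coarse-graining and synthetic heterogeneity ---------------------------

#' Coarse-grain a bead chain by an integer factor
#'
#' Keeps every `factor`-th bead starting at bead 0 and assigns each retained
#' segment the genomic size `unit_genomic_kb` (e.g. a 4096-point curve
#' coarse-grained by 2 gives a 2048-bead chain spanning about 20 Mb at
#' 10 kb per segment).
#'
#' @param x a [conformation()].
#' @param factor integer decimation factor (1 = identity).
#' @param unit_genomic_kb genomic size per retained bead, in kb.
#' @return A [conformation()].
#' @export
coarse_grain_chain <- function(x, factor = 2L, unit_genomic_kb = 10) {
  stopifnot(inherits(x, "conformation"))
  if (factor < 1L) stop("factor must be >= 1")
  keep <- seq.int(1L, nrow(x$coords), by = factor)
  conformation(x$coords[keep, , drop = FALSE], cell_id = x$cell_id,
               genomic_kb = unit_genomic_kb,
               radius = x$radius[keep])
}

#' Synthetic ensemble with tunable cell-to-cell heterogeneity
#'
#' Builds `n_cells` conformations as global rescalings of one base
#' conformation: cell k has coordinates `base * (1 + eps_k)` with
#' `eps_k ~ Normal(0, tau^2)` truncated at `eps > -0.9`. Because each cell's
#' curve is a constant multiple of the base curve, the Relative C.H. of the
#' ensemble equals the population spread of the normalized scale factors
#' (approximately `tau`) at every s, making `tau` a recoverable ground
#' truth for parameter-recovery checks.
#'
#' @param base a [conformation()] used as the common shape.
#' @param tau standard deviation of the per-cell scale factor.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param length_unit,resolution_kb passed to [conformation_ensemble()].
#' @return A `chrom_ensemble`.
#' @export
gen_synthetic_heterogeneous_ensemble <- function(base, tau, n_cells = 50L,
                                                 seed = NULL,
                                                 length_unit = "arbitrary",
                                                 resolution_kb = NULL) {
  stopifnot(inherits(base, "conformation"))
  if (tau < 0) stop("tau must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  eps <- numeric(n_cells)
  for (k in seq_len(n_cells)) {
    repeat {
      e <- rnorm(1L, 0, tau)
      if (e > -0.9) break
    }
    eps[k] <- e
  }
  confs <- lapply(seq_len(n_cells), function(k)
    conformation(base$coords * (1 + eps[k]),
                 cell_id = paste0("synth_", k),
                 genomic_kb = base$genomic_kb, radius = base$radius))
  out <- conformation_ensemble(confs, length_unit = length_unit,
                               resolution_kb = if (is.null(resolution_kb))
                                 mean(base$genomic_kb) else resolution_kb)
  attr(out, "eps") <- eps
  out
}
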