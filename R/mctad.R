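# MC-TAD: permissible lattice paths through N x N x N-bin cubes (TADs),
# the dimensionless intra-TAD spread sigma and its physical conversion.

#' Permissibility rules for MC-TAD paths
#'
#' A TAD is modelled as a cube of N x N x N bins; a chromatin conformation is
#' a path over bin centers that traverses N^3 - 1 full segments per cube.
#' The default rule set is the calibrated configuration that reproduces the
#' reference unique-path counts at N = 2 (384 in one cube, 98,304 in two):
#' axis-aligned unit steps, no lattice edge traversed twice, no segment
#' crossing except at a bin center, at most one bin visited twice, and the
#' permitted self-crossing restricted to the path's entry bin. For two-cube
#' paths the face constraint requires the starting-face axes of the two
#' cubes' sub-paths to differ.
#'
#' @param N bins per cube edge (resolution: one bin is roughly
#'   `118/N^3` kb at fruit-fly TAD size).
#' @param max_revisited_bins bins that may be visited twice (0 or 1).
#' @param revisit_at `"entry"` (revisit only the entry bin; calibrated
#'   default) or `"anywhere"`.
#' @param forbid_edge_reuse disallow traversing a lattice edge twice.
#' @param forbid_segment_crossing disallow geometric crossing of two path
#'   segments anywhere except at bin centers.
#' @param face_constraint apply the two-cube starting-face rule.
#' @return An object of class `mctad_rules`.
#' @export
mctad_rules <- function(N = 2L, max_revisited_bins = 1L,
                        revisit_at = c("entry", "anywhere"),
                        forbid_edge_reuse = TRUE,
                        forbid_segment_crossing = TRUE,
                        face_constraint = TRUE) {
  revisit_at <- match.arg(revisit_at)
  stopifnot(N >= 1L, max_revisited_bins >= 0L)
  structure(list(N = as.integer(N),
                 max_revisited_bins = as.integer(max_revisited_bins),
                 revisit_at = revisit_at,
                 forbid_edge_reuse = forbid_edge_reuse,
                 forbid_segment_crossing = forbid_segment_crossing,
                 face_constraint = face_constraint),
            class = "mctad_rules")
}

#' @export
print.mctad_rules <- function(x, ...) {
  cat("<mctad_rules> N =", x$N, "| revisit:", x$max_revisited_bins,
      "bin(s) at", x$revisit_at,
      "| edge reuse:", if (x$forbid_edge_reuse) "forbidden" else "allowed",
      "| face constraint:", x$face_constraint, "\n")
  invisible(x)
}

# segment intersection helper: closest approach of segments (p1,q1), (p2,q2);
# returns TRUE if they intersect at a point that is not a lattice vertex.
segments_cross <- function(p1, q1, p2, q2, tol = 1e-9) {
  d1 <- q1 - p1; d2 <- q2 - p2; w <- p2 - p1
  a <- sum(d1 * d1); b <- sum(d1 * d2); c <- sum(d2 * d2)
  e <- sum(w * d1); f <- sum(w * d2)
  den <- a * c - b * b
  if (den < tol) {            # parallel: overlap beyond a shared point?
    cr <- c(w[2] * d1[3] - w[3] * d1[2], w[3] * d1[1] - w[1] * d1[3],
            w[1] * d1[2] - w[2] * d1[1])
    if (sum(cr^2) > tol) return(FALSE)    # parallel, not collinear
    t0 <- e / a; t1 <- t0 + b / a
    lo <- max(min(t0, t1), 0); hi <- min(max(t0, t1), 1)
    if (hi - lo > tol) return(TRUE)       # collinear overlap
    if (hi - lo < -tol) return(FALSE)
    pt <- p1 + lo * d1
    return(any(abs(pt - round(pt)) > tol))
  }
  t <- (e * c - b * f) / den; u <- (e * b - a * f) / den
  if (t < -tol || t > 1 + tol || u < -tol || u > 1 + tol) return(FALSE)
  pt1 <- p1 + t * d1; pt2 <- p2 + u * d2
  if (sum((pt1 - pt2)^2) > tol) return(FALSE)
  any(abs(pt1 - round(pt1)) > tol)        # crossing away from a bin center
}

check_subpath <- function(pts, rules, entry = NULL) {
  n <- nrow(pts)
  N <- rules$N
  if (n != N^3) return(FALSE)            # must traverse N^3 - 1 segments
  if (any(pts < 0 | pts >= N)) return(FALSE)
  steps <- diff(pts)
  if (any(rowSums(abs(steps)) != 1L)) return(FALSE)  # axis unit moves only
  key <- apply(pts, 1L, paste, collapse = ",")
  edges <- paste(pmin(key[-n], key[-1L]), pmax(key[-n], key[-1L]))
  if (rules$forbid_edge_reuse && anyDuplicated(edges)) return(FALSE)
  counts <- table(key)
  if (any(counts > 2L)) return(FALSE)
  multi <- names(counts)[counts > 1L]
  if (length(multi) > rules$max_revisited_bins) return(FALSE)
  if (rules$revisit_at == "entry" && length(multi) &&
      !all(multi == key[1L])) return(FALSE)
  if (rules$forbid_segment_crossing && n > 3L) {
    for (i in seq_len(n - 3L)) {
      for (j in seq.int(i + 2L, n - 1L)) {
        if (segments_cross(pts[i, ], pts[i + 1L, ],
                           pts[j, ], pts[j + 1L, ])) return(FALSE)
      }
    }
  }
  TRUE
}

first_step_axis <- function(pts) which(pts[2L, ] != pts[1L, ])[1L]

#' Test whether a lattice path is permissible
#'
#' Pure predicate implementing the MC-TAD permissibility rules. For one-cube
#' paths the path must consist of N^3 bin centers inside the cube; for
#' two-cube paths the first N^3 vertices must lie in the first cube and the
#' remaining N^3 in the neighboring cube (translated by N along x), each
#' sub-path permissible on its own, with the starting-face axes of the two
#' sub-paths differing when the face constraint is active. The inter-TAD
#' connecting segment is the chromatin linker and is exempt from the lattice
#' step rules.
#'
#' @param path integer matrix of lattice points (rows are bin centers in
#'   lattice units), or one row of a `lattice_paths` matrix.
#' @param rules an [mctad_rules()] object.
#' @param n_cubes 1 or 2.
#' @return `TRUE` or `FALSE`.
#' @export
path_is_permissible <- function(path, rules = mctad_rules(), n_cubes = 1L) {
  pts <- as.matrix(path)
  if (ncol(pts) != 3L) stop("path must be an L x 3 matrix of lattice points")
  N <- rules$N
  if (n_cubes == 1L) {
    if (N == 1L) return(nrow(pts) == 1L && all(pts == 0L))
    return(check_subpath(pts, rules))
  }
  if (nrow(pts) != 2L * N^3) return(FALSE)
  a <- pts[seq_len(N^3), , drop = FALSE]
  b <- pts[N^3 + seq_len(N^3), , drop = FALSE]
  if (any(b[, 1L] < N)) return(FALSE)      # second cube: x in N..2N-1
  b[, 1L] <- b[, 1L] - N
  if (!check_subpath(a, rules) || !check_subpath(b, rules)) return(FALSE)
  if (rules$face_constraint && N^3 > 1L &&
      first_step_axis(a) == first_step_axis(b)) return(FALSE)
  TRUE
}

#' Generate the ensemble of permissible MC-TAD paths
#'
#' Within one cube, paths are generated either by exhaustive depth-first
#' enumeration (feasible for N <= 2) or by stochastic growth with restarts,
#' de-duplication, and convergence by stagnation (generation stops once
#' `stagnation_limit` consecutive attempts yield no new unique path). The
#' two modes agree exactly at N <= 2.
#'
#' Two-cube ensembles pair every permissible first-cube path with every
#' permissible second-cube path whose starting-face axis differs (the face
#' constraint); the second cube is the neighboring block translated by N
#' along x and the linker joins the first path's end to the second path's
#' start. For N <= 2 the pairing is exhaustive; for larger N a random sample
#' of `n_pairs` unique pairs is drawn from the stochastically generated
#' per-cube path sets.
#'
#' @param rules an [mctad_rules()] object.
#' @param n_cubes 1 or 2.
#' @param seed integer seed for the stochastic mode.
#' @param mode `"auto"` (exhaustive for N <= 2), `"exhaustive"`, or
#'   `"stochastic"`.
#' @param stagnation_limit consecutive no-new-path attempts that declare
#'   convergence; default `max(1e4, 50 * current unique count)`.
#' @param max_attempts hard cap on growth attempts per cube.
#' @param max_unique cap on unique paths retained per cube in stochastic
#'   mode.
#' @param n_pairs two-cube pairs to sample when the pairing is not
#'   exhaustive.
#' @return An object of class `lattice_paths`: list with the path matrix
#'   (`paths`; one row per path, vertices as consecutive x,y,z triples in
#'   lattice units), `N`, `n_cubes`, `unique_count`, `exhaustive`,
#'   `converged`, `attempts` and `stagnation_record`.
#' @export
generate_paths <- function(rules = mctad_rules(), n_cubes = 1L, seed = NULL,
                           mode = c("auto", "exhaustive", "stochastic"),
                           stagnation_limit = NULL, max_attempts = 2e6,
                           max_unique = 1e5, n_pairs = 3e4) {
  mode <- match.arg(mode)
  N <- rules$N
  if (!is.null(seed)) set.seed(seed)
  if (mode == "auto") mode <- if (N <= 2L) "exhaustive" else "stochastic"
  entry_only <- rules$revisit_at == "entry"
  gen_cube <- function() {
    if (mode == "exhaustive") {
      list(paths = cpp_enum_paths(N, rules$max_revisited_bins, entry_only,
                                  5e6),
           attempts = NA_real_, since_new = NA_real_, converged = TRUE)
    } else {
      res <- cpp_sample_paths(N,
                              if (is.null(stagnation_limit)) 1e4 else
                                stagnation_limit,
                              max_attempts, max_unique,
                              adaptive_stagnation = is.null(stagnation_limit),
                              rules$max_revisited_bins, entry_only)
      limit <- if (is.null(stagnation_limit))
        max(1e4, 50 * nrow(res$paths)) else stagnation_limit
      res$converged <- res$since_new >= limit
      res
    }
  }
  c1 <- gen_cube()
  if (nrow(c1$paths) == 0L) {
    warning("rule set admits no permissible paths")
    return(new_lattice_paths(c1$paths, rules, n_cubes, mode, c1))
  }
  if (n_cubes == 1L) return(new_lattice_paths(c1$paths, rules, n_cubes,
                                              mode, c1))
  c2 <- gen_cube()
  exhaustive_pairs <- mode == "exhaustive"
  paired <- cpp_pair_paths(c1$paths, c2$paths, N, rules$face_constraint,
                           exhaustive_pairs, n_pairs)
  info <- list(attempts = c1$attempts + if (is.na(c1$attempts)) 0 else
                 c2$attempts,
               since_new = c1$since_new,
               converged = isTRUE(c1$converged) && isTRUE(c2$converged))
  out <- new_lattice_paths(paired, rules, n_cubes, mode, info)
  out$exhaustive <- exhaustive_pairs
  out$cube_unique_counts <- c(nrow(c1$paths), nrow(c2$paths))
  out
}

new_lattice_paths <- function(paths, rules, n_cubes, mode, info) {
  structure(list(paths = paths, N = rules$N, n_cubes = n_cubes,
                 rules = rules, mode = mode,
                 exhaustive = mode == "exhaustive",
                 unique_count = nrow(paths),
                 converged = isTRUE(info$converged),
                 attempts = info$attempts,
                 stagnation_record = info$since_new),
            class = "lattice_paths")
}

#' @export
print.lattice_paths <- function(x, ...) {
  cat("<lattice_paths> N =", x$N, "|", x$n_cubes, "cube(s) |",
      format(x$unique_count, big.mark = ","), "unique paths |",
      if (x$exhaustive) "exhaustive" else
        paste0("stochastic (converged: ", x$converged, ")"), "\n")
  invisible(x)
}

#' Intra-TAD subchain spread sigma
#'
#' Over every two-cube path and every window of `contour_segments`
#' consecutive segments (default N^3 segments, the genomic content of one
#' TAD at bin resolution), computes the Euclidean distance between the
#' window endpoints in cube-edge units (cube size 1 a.u., bin spacing 1/N).
#' sigma is the population standard deviation of these subchain end-to-end
#' distances across conformations: the across-path variance is taken at
#' each window position and averaged over positions before the square root,
#' so that an ensemble of identical paths gives sigma = 0. (On the full
#' symmetric path ensemble every window position has the same marginal
#' distribution, so this coincides with the pooled standard deviation.)
#' A block-wise Monte-Carlo standard error is attached when the ensemble is
#' a sample rather than an exhaustive enumeration.
#'
#' @param paths a `lattice_paths` object with `n_cubes = 2`.
#' @param contour_segments window length in segments (default `N^3`).
#' @param n_blocks blocks for the Monte-Carlo standard error.
#' @return An object of class `path_stats`: list with `sigma`, `mean`,
#'   `n_paths`, `n_distances`, `mc_se` and `contour_segments`.
#' @export
sigma_subchain <- function(paths, contour_segments = NULL, n_blocks = 10L) {
  stopifnot(inherits(paths, "lattice_paths"))
  if (paths$n_cubes != 2L)
    stop("sigma is defined on two-cube (neighboring-TAD) path ensembles")
  if (is.null(contour_segments)) contour_segments <- paths$N^3
  L <- ncol(paths$paths) / 3L
  if (contour_segments > L - 1L)
    stop("contour of ", contour_segments,
         " segments exceeds path length of ", L - 1L)
  d <- cpp_window_distances(paths$paths, paths$N,
                            as.integer(contour_segments))
  per_path <- L - contour_segments
  dm <- matrix(d, nrow = per_path)   # window position x path
  between_sigma <- function(m)
    sqrt(mean((m - rowMeans(m))^2))
  sig <- between_sigma(dm)
  mc_se <- NA_real_
  if (!isTRUE(paths$exhaustive) && paths$unique_count >= n_blocks) {
    blk <- rep(seq_len(n_blocks), length.out = paths$unique_count)
    sigs <- vapply(seq_len(n_blocks), function(b)
      between_sigma(dm[, blk == b, drop = FALSE]), numeric(1))
    mc_se <- sd(sigs) / sqrt(n_blocks)
  }
  structure(list(sigma = sig, mean = mean(d),
                 n_paths = paths$unique_count, n_distances = length(d),
                 mc_se = mc_se, contour_segments = contour_segments),
            class = "path_stats")
}

#' @export
print.path_stats <- function(x, ...) {
  cat("<path_stats> sigma =", format(x$sigma, digits = 4), "a.u.",
      if (!is.na(x$mc_se)) paste("(MC se", format(x$mc_se, digits = 2),
                                 ")") else "(exhaustive)",
      "|", format(x$n_distances, big.mark = ","), "subchain distances from",
      format(x$n_paths, big.mark = ","), "paths\n")
  invisible(x)
}

#' Convert dimensionless sigma to physical spread Sigma
#'
#' Multiplies the cube-edge-unit spread sigma by the conversion factor
#' `c_conv` (microns per cube edge), giving the physical spread Sigma used
#' by the resolution up-conversion. The default `c_conv = 0.147` um is
#' back-solved from the reference pair Sigma(2 kb) = 0.05 um with
#' sigma(4x4x4) = 0.34.
#'
#' @param sigma dimensionless spread (cube edge = 1 a.u.), or a
#'   `path_stats` object.
#' @param c_conv microns per cube edge; must be positive.
#' @return Sigma in microns.
#' @export
sigma_to_physical <- function(sigma, c_conv = 0.147) {
  if (inherits(sigma, "path_stats")) sigma <- sigma$sigma
  if (!is.finite(c_conv) || c_conv <= 0)
    stop("c_conv must be a positive length (um per cube edge)")
  if (sigma < 0) stop("sigma must be non-negative")
  sigma * c_conv
}
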