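# Per-cell <Rs>(s) curves, the Conformational Heterogeneity metric and its
# dimensionless Relative form, replicate error bars, scaling-exponent fits.

#' Per-cell average inter-locus distance curve
#'
#' For one conformation, computes the average Euclidean distance between bead
#' centers separated by s beads, for every genomic separation s on the
#' equal-genomic-size bead grid:
#' \deqn{\langle R_s \rangle = \frac{1}{n-s}\sum_{i} |r_{i+s} - r_i|}
#' At the maximum separation s = n-1 the average runs over a single bead
#' pair, which is why heterogeneity profiles rise sharply at the chain end.
#'
#' @param x a [conformation()].
#' @param s_max largest separation to compute (default: all, `n - 1`).
#' @param resolution_kb kb per bead used to express s in kb; defaults to the
#'   mean per-bead genomic size of the conformation.
#' @return An object of class `rs_curve`: list with `cell_id`, `s_beads`,
#'   `s_kb` and `values`.
#' @export
rs_curve <- function(x, s_max = NULL, resolution_kb = NULL) {
  stopifnot(inherits(x, "conformation"))
  n <- nrow(x$coords)
  if (is.null(s_max)) s_max <- n - 1L
  s_max <- min(s_max, n - 1L)
  if (is.null(resolution_kb)) resolution_kb <- mean(x$genomic_kb)
  vals <- cpp_rs_curve(x$coords, as.integer(s_max))
  new_rs_curve(x$cell_id, seq_len(s_max), seq_len(s_max) * resolution_kb,
               vals)
}

new_rs_curve <- function(cell_id, s_beads, s_kb, values, is_guide = NULL) {
  structure(list(cell_id = cell_id, s_beads = as.numeric(s_beads),
                 s_kb = as.numeric(s_kb), values = as.numeric(values),
                 is_guide = if (is.null(is_guide))
                   rep(FALSE, length(values)) else is_guide),
            class = "rs_curve")
}

#' @export
print.rs_curve <- function(x, ...) {
  cat("<rs_curve> cell", x$cell_id, "-", sum(!x$is_guide),
      "separations; range",
      format(min(x$values), digits = 3), "-",
      format(max(x$values), digits = 3), "\n")
  invisible(x)
}

#' Per-cell curves for a whole ensemble
#'
#' @param ensemble a `chrom_ensemble`.
#' @inheritParams rs_curve
#' @return List of [rs_curve()] objects, one per cell.
#' @export
rs_curves <- function(ensemble, s_max = NULL) {
  stopifnot(inherits(ensemble, "chrom_ensemble"))
  lapply(ensemble$conformations, rs_curve, s_max = s_max,
         resolution_kb = ensemble$resolution_kb)
}

# Stack curve values into cells x s matrix on the common analytic grid,
# dropping eye-guide points. Returns list(values, s_beads, s_kb).
curve_matrix <- function(curves) {
  if (length(curves) < 2L)
    stop("need at least 2 cells to compute heterogeneity")
  keep <- !curves[[1L]]$is_guide
  grid <- curves[[1L]]$s_beads[keep]
  for (cu in curves) {
    k2 <- !cu$is_guide
    if (!isTRUE(all.equal(cu$s_beads[k2], grid)))
      stop("cell ", cu$cell_id, " is on a different s grid")
  }
  vals <- t(vapply(curves, function(cu) cu$values[!cu$is_guide],
                   numeric(length(grid))))
  list(values = vals, s_beads = grid,
       s_kb = curves[[1L]]$s_kb[keep])
}

pop_sd <- function(m) {
  # population (divide-by-n) standard deviation by column
  mu <- colMeans(m)
  sqrt(colMeans(sweep(m, 2L, mu)^2))
}

#' Conformational Heterogeneity profile
#'
#' The Conformational Heterogeneity C.H.(s) of an ensemble of n single-cell
#' conformations is the population standard deviation, across cells, of the
#' per-cell average distances at genomic separation s:
#' \deqn{C.H.(s) = \sqrt{\tfrac{1}{n}\sum_k (\langle R_s^{(k)}\rangle -
#'   \overline{\langle R_s\rangle})^2}}
#' The Relative C.H. column applies the same formula to the per-cell curves
#' normalized by the ensemble mean at each s (a dimensionless quantity that
#' is comparable across models and unit systems).
#'
#' @param x a `chrom_ensemble` or a list of [rs_curve()] objects on a common
#'   grid (eye-guide points, if present, are excluded).
#' @param s_max passed to [rs_curves()] when `x` is an ensemble.
#' @return An object of class `het_profile`: a data.frame with columns
#'   `s_beads`, `s_kb`, `mean_Rs`, `CH`, `relative_CH` and attribute
#'   `n_cells`.
#' @export
ch_profile <- function(x, s_max = NULL) {
  curves <- if (inherits(x, "chrom_ensemble")) rs_curves(x, s_max) else x
  cm <- curve_matrix(curves)
  mean_rs <- colMeans(cm$values)
  ch <- pop_sd(cm$values)
  rel <- relative_values(cm$values)
  out <- data.frame(s_beads = cm$s_beads, s_kb = cm$s_kb,
                    mean_Rs = mean_rs, CH = ch,
                    relative_CH = pop_sd(rel))
  attr(out, "n_cells") <- nrow(cm$values)
  class(out) <- c("het_profile", "data.frame")
  out
}

relative_values <- function(vals) {
  mu <- colMeans(vals)
  if (any(mu <= 0))
    stop("ensemble mean <Rs> is zero at s = ",
         which(mu <= 0)[1L], "; relative curves undefined")
  sweep(vals, 2L, mu, "/")
}

#' @export
print.het_profile <- function(x, ...) {
  cat("<het_profile>", attr(x, "n_cells"), "cells,", nrow(x),
      "separations\n")
  print(head(as.data.frame(x), 4L), row.names = FALSE)
  if (nrow(x) > 4L) cat("  ... (", nrow(x) - 4L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
plot.het_profile <- function(x, which = c("relative_CH", "CH"), log = "x",
                             ...) {
  which <- match.arg(which)
  graphics::plot(x$s_kb, x[[which]], type = "l", log = log,
                 xlab = "genomic separation s (kb)", ylab = which, ...)
  invisible(x)
}

#' Normalize per-cell curves by the ensemble mean
#'
#' Divides each cell's curve by the ensemble-mean curve at every s, giving
#' dimensionless Relative curves whose per-s ensemble mean is exactly 1.
#'
#' @param curves list of [rs_curve()] objects on a common grid.
#' @return List of dimensionless `rs_curve` objects.
#' @export
relative_curves <- function(curves) {
  cm <- curve_matrix(curves)
  rel <- relative_values(cm$values)
  lapply(seq_along(curves), function(k)
    new_rs_curve(curves[[k]]$cell_id, cm$s_beads, cm$s_kb, rel[k, ]))
}

#' Relative Conformational Heterogeneity profile
#'
#' Computes the heterogeneity profile of the mean-normalized (Relative)
#' curves; its `CH` column is the Relative C.H. itself. Algebraically
#' Relative C.H.(s) equals C.H.(s) divided by the ensemble mean curve, since
#' the normalization divides by a per-s constant.
#'
#' @inheritParams ch_profile
#' @return A `het_profile` computed on the normalized curves.
#' @export
relative_ch_profile <- function(x, s_max = NULL) {
  curves <- if (inherits(x, "chrom_ensemble")) rs_curves(x, s_max) else x
  ch_profile(relative_curves(curves))
}

#' Replicate-subsampling error bars for heterogeneity metrics
#'
#' Computes the chosen metric independently on each replicate ensemble and
#' returns the per-s mean and sample (divide-by-n-1) standard deviation
#' across replicates. Replicates are draws of k cells from a larger pool, so
#' the sample standard deviation is the appropriate spread estimate.
#'
#' @param replicates list of `chrom_ensemble` objects (or lists of curves)
#'   on a common grid, e.g. from [subsample_replicates()].
#' @param metric `"relative_ch"` or `"ch"`.
#' @param s_max passed to [rs_curves()].
#' @return data.frame with columns `s_beads`, `s_kb`, `mean`, `sd`, `n_rep`.
#' @export
replicate_errorbars <- function(replicates, metric = c("relative_ch", "ch"),
                                s_max = NULL) {
  metric <- match.arg(metric)
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  profs <- lapply(replicates, function(e)
    if (metric == "ch") ch_profile(e, s_max) else
      relative_ch_profile(e, s_max))
  grid <- profs[[1L]]$s_beads
  for (p in profs)
    if (!isTRUE(all.equal(p$s_beads, grid)))
      stop("replicates are on different s grids")
  m <- t(vapply(profs, function(p) p$CH, numeric(length(grid))))
  data.frame(s_beads = grid, s_kb = profs[[1L]]$s_kb,
             mean = colMeans(m), sd = apply(m, 2L, sd),
             n_rep = length(replicates))
}

#' Power-law scaling exponent of an <Rs> curve
#'
#' Fits `log(Rs)` against `log(s)` by unweighted ordinary least squares over
#' integer separations in `[s_lo, s_hi]`, the standard estimate of the
#' polymer scaling exponent alpha in R(s) proportional to s^alpha (1/2 for an
#' ideal random walk, 1/3 for a compact space-filling curve).
#'
#' @param x an [rs_curve()], a list of them, or a `chrom_ensemble` (the two
#'   latter give per-replica fits aggregated as mean and sd).
#' @param s_lo,s_hi fit window in bead units.
#' @return For a single curve, an object of class `scaling_fit` with elements
#'   `alpha`, `intercept`, `s_lo`, `s_hi`; for ensembles/lists, additionally
#'   `alpha_std` and `per_replica`.
#' @export
fit_scaling_exponent <- function(x, s_lo = 2L, s_hi = 400L) {
  if (inherits(x, "chrom_ensemble")) x <- rs_curves(x, s_max = s_hi)
  if (inherits(x, "rs_curve")) {
    keep <- !x$is_guide & x$s_beads >= s_lo & x$s_beads <= s_hi
    if (max(x$s_beads[!x$is_guide]) < s_hi)
      stop("curve grid ends at s = ", max(x$s_beads[!x$is_guide]),
           " < s_hi = ", s_hi)
    v <- x$values[keep]
    if (any(v <= 0)) stop("non-positive <Rs> values in the fit window")
    co <- coef(lm(log(v) ~ log(x$s_beads[keep])))
    return(structure(list(alpha = unname(co[2L]),
                          intercept = unname(co[1L]),
                          s_lo = s_lo, s_hi = s_hi),
                     class = "scaling_fit"))
  }
  fits <- lapply(x, fit_scaling_exponent, s_lo = s_lo, s_hi = s_hi)
  alphas <- vapply(fits, `[[`, numeric(1), "alpha")
  structure(list(alpha = mean(alphas), alpha_std = sd(alphas),
                 per_replica = alphas, s_lo = s_lo, s_hi = s_hi),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> alpha =", format(x$alpha, digits = 4))
  if (!is.null(x$alpha_std))
    cat(" +/-", format(x$alpha_std, digits = 3),
        paste0("(", length(x$per_replica), " replicas)"))
  cat("  [fit window s in", x$s_lo, "..", x$s_hi, "]\n")
  invisible(x)
}

#' Write a heterogeneity profile as tab-separated text
#'
#' Columns: `s_beads`, `s_kb`, `mean_Rs`, `CH`, `relative_CH`, `err_CH`,
#' `err_relative_CH`, `n_cells`. Error columns are `NA` unless replicate
#' error bars are supplied.
#'
#' @param profile a `het_profile`.
#' @param path output file.
#' @param errorbars optional result of [replicate_errorbars()] with
#'   `metric = "relative_ch"` (matched on `s_beads`).
#' @param errorbars_ch optional absolute-C.H. error bars.
#' @param header optional character vector written as `#`-prefixed header
#'   lines (run parameters, seed, version).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, errorbars = NULL,
                          errorbars_ch = NULL, header = NULL) {
  out <- data.frame(s_beads = profile$s_beads, s_kb = profile$s_kb,
                    mean_Rs = profile$mean_Rs, CH = profile$CH,
                    relative_CH = profile$relative_CH,
                    err_CH = NA_real_, err_relative_CH = NA_real_,
                    n_cells = attr(profile, "n_cells"))
  if (!is.null(errorbars_ch))
    out$err_CH <- errorbars_ch$sd[match(out$s_beads, errorbars_ch$s_beads)]
  if (!is.null(errorbars))
    out$err_relative_CH <-
      errorbars$sd[match(out$s_beads, errorbars$s_beads)]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(format(out, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
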