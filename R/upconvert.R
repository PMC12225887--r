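# Resolution up-conversion: inject MC-TAD-derived spread into TAD-resolution
# <Rs> curve ensembles and prepend the non-analytic eye-guide interpolation.

#' Up-conversion specification
#'
#' Parameters of the statistical resolution up-conversion: a TAD-resolution
#' model (one bead per TAD, `source_resolution_kb`) is emulated at a finer
#' `target_resolution_kb` by drawing one offset per cell from
#' `Normal(0, Sigma)` — `Sigma` being the physical intra-TAD subchain
#' spread from the MC-TAD algorithm — and shifting each cell's entire
#' analytic curve by its offset. A linear eye-guide segment connects the
#' target resolution to the first analytic point; its values are flagged
#' and excluded from any further analysis.
#'
#' @param source_resolution_kb resolution of the input model (kb per bead),
#'   e.g. 118 for TAD-resolution fruit-fly models.
#' @param target_resolution_kb emulated finer resolution (kb), e.g. 14 or 2.
#' @param sigma_physical Sigma in the ensemble's length unit (um for micron
#'   ensembles); must be non-negative.
#' @param anchor_value curve value pinned at the target resolution for the
#'   eye-guide segment (plotting only).
#' @param seed integer seed for the offset draws.
#' @param shift `"whole"` (default: the per-cell offset shifts the entire
#'   analytic curve) or `"at_source"` (only the value at the source
#'   resolution separation is shifted).
#' @param distances optional numeric vector of MC-TAD subchain distances;
#'   when supplied, offsets are resampled from these (centered, scaled to
#'   sd `sigma_physical`) instead of the normal approximation.
#' @return An object of class `upconversion_spec`.
#' @export
upconversion_spec <- function(source_resolution_kb = 118,
                              target_resolution_kb = 14,
                              sigma_physical, anchor_value = 0.1,
                              seed = NULL,
                              shift = c("whole", "at_source"),
                              distances = NULL) {
  shift <- match.arg(shift)
  if (target_resolution_kb >= source_resolution_kb)
    stop("target resolution must be finer than the source resolution")
  if (sigma_physical < 0) stop("sigma_physical must be non-negative")
  structure(list(source_resolution_kb = source_resolution_kb,
                 target_resolution_kb = target_resolution_kb,
                 sigma_physical = sigma_physical,
                 anchor_value = anchor_value, seed = seed, shift = shift,
                 distances = distances),
            class = "upconversion_spec")
}

draw_offsets <- function(spec, n) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(spec$distances)) return(rnorm(n, 0, spec$sigma_physical))
  d <- spec$distances
  pool <- (d - mean(d)) / if (sd(d) > 0) sd(d) else 1
  pool[sample.int(length(pool), n, replace = TRUE)] * spec$sigma_physical
}

#' Up-convert an ensemble of <Rs> curves to a finer resolution
#'
#' Draws one offset per cell (normal with sd `Sigma`, or resampled from
#' supplied MC-TAD subchain distances) and shifts the cell's analytic curve,
#' clamping shifted values at zero (distances are non-negative; occurrences
#' are reported via a message). A non-analytic eye-guide point at the target
#' resolution is prepended with `is_guide = TRUE`; guide points are ignored
#' by [ch_profile()] and [fit_scaling_exponent()].
#'
#' @param curves list of [rs_curve()] objects on a common grid.
#' @param spec an [upconversion_spec()].
#' @return List of `rs_curve` objects with the guide point prepended and
#'   attribute `offsets` carrying the applied per-cell offsets.
#' @export
upconvert_curves <- function(curves, spec) {
  stopifnot(inherits(spec, "upconversion_spec"))
  offsets <- draw_offsets(spec, length(curves))
  n_clamped <- 0L
  out <- lapply(seq_along(curves), function(k) {
    cu <- curves[[k]]
    keep <- !cu$is_guide
    v <- cu$values[keep]
    if (spec$shift == "whole") {
      v <- v + offsets[k]
    } else {
      at <- which.min(abs(cu$s_kb[keep] - spec$source_resolution_kb))
      v[at] <- v[at] + offsets[k]
    }
    n_clamped <<- n_clamped + sum(v < 0)
    v[v < 0] <- 0
    new_rs_curve(cu$cell_id,
                 c(spec$target_resolution_kb /
                     (cu$s_kb[keep][1L] / cu$s_beads[keep][1L]),
                   cu$s_beads[keep]),
                 c(spec$target_resolution_kb, cu$s_kb[keep]),
                 c(spec$anchor_value, v),
                 is_guide = c(TRUE, rep(FALSE, length(v))))
  })
  if (n_clamped > 0L)
    message(n_clamped, " shifted value(s) clamped at 0")
  attr(out, "offsets") <- offsets
  out
}

#' Eye-guide anchoring for Relative curves
#'
#' For dimensionless Relative curves the eye-guide interpolation runs to
#' 1.00 at the resolution limit: prepends a guide point with value 1 at
#' `target_resolution_kb` to every curve.
#'
#' @param curves list of dimensionless [rs_curve()] objects (e.g. from
#'   [relative_curves()]).
#' @param target_resolution_kb resolution limit, in kb.
#' @return List of `rs_curve` objects with the guide point prepended.
#' @export
relative_anchor <- function(curves, target_resolution_kb) {
  lapply(curves, function(cu) {
    keep <- !cu$is_guide
    new_rs_curve(cu$cell_id,
                 c(target_resolution_kb /
                     (cu$s_kb[keep][1L] / cu$s_beads[keep][1L]),
                   cu$s_beads[keep]),
                 c(target_resolution_kb, cu$s_kb[keep]),
                 c(1, cu$values[keep]),
                 is_guide = c(TRUE, rep(FALSE, sum(keep))))
  })
}
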