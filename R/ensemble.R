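# Conformation ensembles: containers, validation, file formats, resampling.

#' Single-cell chromatin conformation
#'
#' A conformation is an ordered chain of bead centers representing one
#' single-cell (single-nucleus) chromatin structure. Beads carry a genomic
#' size in kb; coordinates are in the length unit declared by the enclosing
#' ensemble.
#'
#' @param coords numeric matrix with one row per bead and columns x, y, z.
#' @param cell_id character label identifying the cell.
#' @param genomic_kb per-bead genomic size in kb; a single value is recycled.
#' @param radius optional per-bead radius (same length unit as the coords).
#'
#' @return An object of class `conformation`: a list with elements
#'   `cell_id`, `coords`, `genomic_kb` and (optionally) `radius`.
#' @export
#' @examples
#' conformation(cbind(0:2, 0, 0), cell_id = "cell1", genomic_kb = 118)
conformation <- function(coords, cell_id = "cell", genomic_kb = 1,
                         radius = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have three columns (x, y, z)")
  if (nrow(coords) < 2L)
    stop("a conformation needs at least 2 beads (cell ", cell_id, ")")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in cell ", cell_id, " (bead ",
         which(!apply(is.finite(coords), 1L, all))[1L], ")")
  genomic_kb <- rep_len(as.numeric(genomic_kb), nrow(coords))
  if (any(!is.finite(genomic_kb)) || any(genomic_kb <= 0))
    stop("genomic_kb must be positive for every bead (cell ", cell_id, ")")
  if (!is.null(radius)) {
    radius <- rep_len(as.numeric(radius), nrow(coords))
    if (any(!is.finite(radius)) || any(radius < 0))
      stop("bead radii must be finite and non-negative (cell ", cell_id, ")")
  }
  structure(list(cell_id = as.character(cell_id), coords = coords,
                 genomic_kb = genomic_kb, radius = radius),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> cell", x$cell_id, "-", nrow(x$coords), "beads,",
      format(sum(x$genomic_kb), big.mark = ","), "kb\n")
  invisible(x)
}

#' Ensemble of single-cell conformations
#'
#' An ensemble collects one conformation per cell, all with identical bead
#' count and identical per-bead genomic sizes, so that genomic separation can
#' be measured on a common equal-genomic-size bead grid.
#'
#' @param conformations list of [conformation()] objects (or a single one).
#' @param length_unit `"micron"` or `"arbitrary"`; the coordinate unit.
#' @param resolution_kb genomic size represented by one bead, in kb
#'   (e.g. 118 for TAD-resolution fruit-fly X-chromosome models, 10 for
#'   single-cell Hi-C based models).
#'
#' @return An object of class `chrom_ensemble`.
#' @export
conformation_ensemble <- function(conformations,
                                  length_unit = c("micron", "arbitrary"),
                                  resolution_kb = NULL) {
  if (inherits(conformations, "conformation"))
    conformations <- list(conformations)
  length_unit <- match.arg(length_unit)
  if (length(conformations) < 1L) stop("empty ensemble")
  nb <- vapply(conformations, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(nb)) != 1L)
    stop("inconsistent bead counts across cells: ",
         paste(unique(nb), collapse = ", "))
  kb0 <- conformations[[1L]]$genomic_kb
  for (cf in conformations)
    if (!isTRUE(all.equal(cf$genomic_kb, kb0)))
      stop("cell ", cf$cell_id, " has a different genomic_kb vector")
  if (is.null(resolution_kb)) resolution_kb <- mean(kb0)
  structure(list(conformations = conformations,
                 length_unit = length_unit,
                 resolution_kb = as.numeric(resolution_kb)),
            class = "chrom_ensemble")
}

#' @export
print.chrom_ensemble <- function(x, ...) {
  cat("<chrom_ensemble>", length(x$conformations), "cells x",
      n_beads(x), "beads; unit:", x$length_unit,
      "; resolution:", x$resolution_kb, "kb/bead\n")
  invisible(x)
}

#' @export
length.chrom_ensemble <- function(x) length(x$conformations)

#' Number of beads per conformation in an ensemble
#' @param ensemble a `chrom_ensemble`.
#' @return integer bead count.
#' @export
n_beads <- function(ensemble) nrow(ensemble$conformations[[1L]]$coords)

#' Trajectory of one cell
#'
#' A time-ordered list of conformation snapshots for one simulated nucleus,
#' used for interval-based single-cell sampling.
#'
#' @param frames list of [conformation()] snapshots in time order.
#' @param cell_id cell label.
#' @return An object of class `chrom_trajectory`.
#' @export
trajectory <- function(frames, cell_id = "cell") {
  nb <- vapply(frames, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(nb)) != 1L)
    stop("trajectory frames of cell ", cell_id, " differ in bead count")
  structure(list(cell_id = as.character(cell_id), frames = frames),
            class = "chrom_trajectory")
}

# ---- file formats ----------------------------------------------------------

#' Read a conformation ensemble from disk
#'
#' Two plain-text formats are supported. `"table"` is tab-separated with
#' header columns `cell_id`, `bead_index`, `x`, `y`, `z` and optional
#' `genomic_kb` and `radius`. `"xyz_multiframe"` is standard multi-frame XYZ:
#' a bead-count line, a comment line carrying `cell_id=<id>`, then one
#' `TAD x y z` line per bead; one frame per cell.
#'
#' @param path file to read.
#' @param format `"table"` or `"xyz_multiframe"`.
#' @param length_unit coordinate unit of the file (`"micron"`/`"arbitrary"`).
#' @param resolution_kb genomic size per bead in kb (used when the file has
#'   no `genomic_kb` column).
#' @param quiet suppress the record-count message.
#' @return A [conformation_ensemble()].
#' @export
read_ensemble <- function(path, format = c("table", "xyz_multiframe"),
                          length_unit = c("micron", "arbitrary"),
                          resolution_kb = 1, quiet = FALSE) {
  format <- match.arg(format)
  length_unit <- match.arg(length_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  confs <- if (format == "table") {
    read_ensemble_table(path, resolution_kb)
  } else {
    read_ensemble_xyz(path, resolution_kb)
  }
  if (!quiet)
    message("read ", length(confs), " conformations (",
            nrow(confs[[1L]]$coords), " beads each) from ", path)
  conformation_ensemble(confs, length_unit = length_unit,
                        resolution_kb = resolution_kb)
}

read_ensemble_table <- function(path, resolution_kb) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("cell_id", "bead_index", "x", "y", "z")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (cc in c("x", "y", "z"))
    if (!all(is.finite(tab[[cc]])))
      stop("non-finite ", cc, " coordinate at row ",
           which(!is.finite(tab[[cc]]))[1L])
  split_rows <- split(seq_len(nrow(tab)), tab$cell_id)
  lapply(names(split_rows), function(id) {
    rows <- split_rows[[id]]
    sub <- tab[rows, , drop = FALSE]
    sub <- sub[order(sub$bead_index), , drop = FALSE]
    if (!identical(as.integer(sub$bead_index),
                   seq.int(0L, nrow(sub) - 1L)))
      stop("bead_index of cell ", id,
           " is not a gap-free 0-based sequence")
    conformation(as.matrix(sub[, c("x", "y", "z")]), cell_id = id,
                 genomic_kb = if ("genomic_kb" %in% names(sub))
                   sub$genomic_kb else resolution_kb,
                 radius = if ("radius" %in% names(sub)) sub$radius else NULL)
  })
}

read_ensemble_xyz <- function(path, resolution_kb) {
  lines <- readLines(path)
  confs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nb <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nb)) stop("expected a bead count at line ", i)
    comment <- lines[i + 1L]
    id <- sub(".*cell_id=([^ \t]+).*", "\\1", comment)
    if (identical(id, comment)) id <- as.character(length(confs) + 1L)
    block <- lines[(i + 2L):(i + 1L + nb)]
    fields <- strsplit(trimws(block), "[ \t]+")
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (!all(is.finite(xyz)))
      stop("non-finite coordinate in frame ", id, " (bead ",
           which(!apply(is.finite(xyz), 1L, all))[1L], ")")
    confs[[length(confs) + 1L]] <-
      conformation(xyz, cell_id = id, genomic_kb = resolution_kb)
    i <- i + 2L + nb
  }
  confs
}

#' Write a conformation ensemble to disk
#'
#' Inverse of [read_ensemble()]; the written file round-trips through
#' `read_ensemble()` with coordinates preserved to the printed precision
#' (17 significant digits, i.e. losslessly for doubles).
#'
#' @param ensemble a `chrom_ensemble`.
#' @param path output file.
#' @param format `"table"` or `"xyz_multiframe"`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path,
                           format = c("table", "xyz_multiframe")) {
  format <- match.arg(format)
  stopifnot(inherits(ensemble, "chrom_ensemble"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (format == "table") {
    rows <- lapply(ensemble$conformations, function(cf) {
      d <- data.frame(cell_id = cf$cell_id,
                      bead_index = seq.int(0L, nrow(cf$coords) - 1L),
                      x = fmt(cf$coords[, 1]), y = fmt(cf$coords[, 2]),
                      z = fmt(cf$coords[, 3]),
                      genomic_kb = fmt(cf$genomic_kb),
                      stringsAsFactors = FALSE)
      if (!is.null(cf$radius)) d$radius <- fmt(cf$radius)
      d
    })
    tab <- do.call(rbind, rows)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (cf in ensemble$conformations) {
      writeLines(as.character(nrow(cf$coords)), con)
      writeLines(paste0("cell_id=", cf$cell_id,
                        " unit=", ensemble$length_unit), con)
      writeLines(paste("TAD", fmt(cf$coords[, 1]), fmt(cf$coords[, 2]),
                       fmt(cf$coords[, 3])), con)
    }
  }
  invisible(path)
}

# ---- homolog merging -------------------------------------------------------

#' Merge paired homolog chains into single chains
#'
#' Diploid models that represent the two homologous copies of a chromosome as
#' two separate bead chains are reduced to a single-chain representation:
#' bead i of the merged chain is placed at the midpoint (center of mass of
#' two equal beads) of bead i of the two homolog chains. The bead radius is
#' kept equal to the radius of the original beads.
#'
#' @param ensemble a `chrom_ensemble` whose cells appear as homolog pairs:
#'   either consecutive conformations `2k-1, 2k` belong to the same cell, or
#'   pairing is declared with `pair_ids`.
#' @param pair_ids optional factor/vector, one entry per conformation, whose
#'   levels define the pairs.
#' @return A `chrom_ensemble` with one merged chain per pair.
#' @export
merge_homolog_chains <- function(ensemble, pair_ids = NULL) {
  confs <- ensemble$conformations
  if (is.null(pair_ids)) {
    if (length(confs) %% 2L != 0L)
      stop("odd number of chains; homologs must come in pairs")
    pair_ids <- rep(seq_len(length(confs) / 2L), each = 2L)
  }
  groups <- split(seq_along(confs), pair_ids)
  merged <- lapply(names(groups), function(g) {
    ix <- groups[[g]]
    if (length(ix) != 2L)
      stop("pair ", g, " has ", length(ix), " chains; expected 2")
    a <- confs[[ix[1L]]]; b <- confs[[ix[2L]]]
    if (nrow(a$coords) != nrow(b$coords))
      stop("homolog chains of pair ", g, " differ in length (",
           nrow(a$coords), " vs ", nrow(b$coords), ")")
    conformation((a$coords + b$coords) / 2, cell_id = g,
                 genomic_kb = a$genomic_kb, radius = a$radius)
  })
  conformation_ensemble(merged, length_unit = ensemble$length_unit,
                        resolution_kb = ensemble$resolution_kb)
}

# ---- resampling ------------------------------------------------------------

#' Sample one single-cell conformation per trajectory
#'
#' Each trajectory is divided into `n_intervals` equal time intervals; the
#' candidate frames are the `n_intervals` interval-boundary snapshots (evenly
#' spaced, including the first and last frame). One candidate is drawn
#' uniformly at random per trajectory, yielding one single-cell conformation
#' per simulated nucleus.
#'
#' @param trajectories list of [trajectory()] objects.
#' @param n_intervals number of candidate snapshots per trajectory.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param length_unit,resolution_kb passed to [conformation_ensemble()].
#' @return A `chrom_ensemble` with one conformation per trajectory.
#' @export
sample_trajectory_cells <- function(trajectories, n_intervals = 50L, seed,
                                    length_unit = c("micron", "arbitrary"),
                                    resolution_kb = 1) {
  length_unit <- match.arg(length_unit)
  if (!missing(seed)) set.seed(seed)
  confs <- lapply(trajectories, function(tr) {
    Tn <- length(tr$frames)
    if (Tn < n_intervals)
      stop("trajectory of cell ", tr$cell_id, " has ", Tn,
           " frames; need at least ", n_intervals)
    boundaries <- if (n_intervals == 1L) 1L else
      round(seq.int(0L, Tn - 1L, length.out = n_intervals)) + 1L
    pick <- boundaries[sample.int(n_intervals, 1L)]
    cf <- tr$frames[[pick]]
    cf$cell_id <- tr$cell_id
    cf
  })
  conformation_ensemble(confs, length_unit = length_unit,
                        resolution_kb = resolution_kb)
}

#' Replicate subsampling of an ensemble
#'
#' Draws `n_rep` replicate ensembles of `k` distinct conformations each
#' (sampling without replacement within a replicate), the resampling scheme
#' used to put error bars on heterogeneity profiles.
#'
#' @param ensemble a `chrom_ensemble`.
#' @param k cells per replicate.
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return List of `n_rep` `chrom_ensemble` objects.
#' @export
subsample_replicates <- function(ensemble, k, n_rep = 10L, seed) {
  n <- length(ensemble$conformations)
  if (k > n) stop("k = ", k, " exceeds ensemble size n = ", n)
  if (!missing(seed)) set.seed(seed)
  lapply(seq_len(n_rep), function(r) {
    ix <- sample.int(n, k)
    conformation_ensemble(ensemble$conformations[ix],
                          length_unit = ensemble$length_unit,
                          resolution_kb = ensemble$resolution_kb)
  })
}
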