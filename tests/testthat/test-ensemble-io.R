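test_that("a tabular file reads back as the conformations it describes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_id\tbead_index\tx\ty\tz",
               "c1\t0\t0\t0\t0",
               "c1\t1\t1\t0\t0",
               "c1\t2\t2\t0\t0"), path)
  ens <- read_ensemble(path, format = "table", length_unit = "micron",
                       resolution_kb = 118, quiet = TRUE)
  expect_length(ens, 1L)
  expect_equal(n_beads(ens), 3L)
  expect_equal(ens$conformations[[1]]$coords,
               cbind(x = c(0, 1, 2), y = 0, z = 0), ignore_attr = TRUE)
})

test_that("write/read round-trips preserve coordinates in both formats", {
  ens <- random_walk_ensemble(5, 50, seed = 100, resolution_kb = 10)
  for (fmt in c("table", "xyz_multiframe")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_ensemble(ens, path, format = fmt)
    back <- read_ensemble(path, format = fmt, length_unit = "arbitrary",
                          resolution_kb = 10, quiet = TRUE)
    for (k in seq_along(ens$conformations)) {
      expect_equal(back$conformations[[k]]$coords,
                   ens$conformations[[k]]$coords, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("per-bead radii survive a table round-trip", {
  cf <- conformation(cbind(0:3, 0, 0), genomic_kb = 118,
                     radius = c(0.07, 0.08, 0.09, 0.1))
  ens <- conformation_ensemble(list(cf), length_unit = "micron",
                               resolution_kb = 118)
  path <- withr::local_tempfile()
  write_ensemble(ens, path, format = "table")
  back <- read_ensemble(path, format = "table", length_unit = "micron",
                        resolution_kb = 118, quiet = TRUE)
  expect_equal(back$conformations[[1]]$radius, cf$radius,
               tolerance = 1e-12)
})

test_that("a 184-bead TAD-chain fixture keeps its bead count per cell", {
  # mimics the X-chromosome chain-of-TADs models (184 beads per cell)
  ens <- random_walk_ensemble(3, 184, seed = 5, resolution_kb = 118)
  path <- withr::local_tempfile()
  write_ensemble(ens, path, format = "xyz_multiframe")
  back <- read_ensemble(path, format = "xyz_multiframe",
                        length_unit = "arbitrary", resolution_kb = 118,
                        quiet = TRUE)
  expect_equal(n_beads(back), 184L)
  expect_length(back, 3L)
})

test_that("malformed inputs are rejected with informative errors", {
  path <- withr::local_tempfile()
  writeLines(c("cell_id\tbead_index\tx\ty", "c1\t0\t0\t0"), path)
  expect_error(read_ensemble(path, "table", quiet = TRUE),
               "missing required columns.*z")
  writeLines(c("cell_id\tbead_index\tx\ty\tz",
               "c1\t0\t0\t0\t0", "c1\t2\t1\t0\t0"), path)
  expect_error(read_ensemble(path, "table", quiet = TRUE), "gap-free")
  expect_error(conformation(cbind(c(0, NA), 0, 0)), "non-finite")
  expect_error(conformation_ensemble(list(straight_chain(3),
                                          straight_chain(4))),
               "inconsistent bead counts")
})

test_that("homolog merging is the per-bead midpoint and commutes with translation", {
  a <- conformation(cbind(c(0, 0), c(0, 1), c(0, 0)), cell_id = "h1",
                    genomic_kb = 118, radius = 0.07)
  b <- conformation(cbind(c(2, 2), c(0, 1), c(0, 0)), cell_id = "h2",
                    genomic_kb = 118, radius = 0.07)
  ens <- conformation_ensemble(list(a, b), length_unit = "micron",
                               resolution_kb = 118)
  merged <- merge_homolog_chains(ens)
  expect_equal(merged$conformations[[1]]$coords[1, ], c(1, 0, 0),
               ignore_attr = TRUE)
  expect_equal(merged$conformations[[1]]$radius, c(0.07, 0.07))

  # degenerate pair: identical homologs merge to themselves
  ens2 <- conformation_ensemble(list(a, a), length_unit = "micron",
                                resolution_kb = 118)
  expect_equal(merge_homolog_chains(ens2)$conformations[[1]]$coords,
               a$coords, ignore_attr = TRUE)

  # random 184-bead pair vs element-wise mean oracle
  h1 <- random_walk_conformation(184, seed = 11)
  h2 <- random_walk_conformation(184, seed = 12)
  h1$radius <- rep(0.07, 184); h2$radius <- rep(0.07, 184)
  ens3 <- conformation_ensemble(list(h1, h2), length_unit = "micron",
                                resolution_kb = 118)
  m3 <- merge_homolog_chains(ens3)
  expect_equal(m3$conformations[[1]]$coords, (h1$coords + h2$coords) / 2,
               ignore_attr = TRUE)

  # rigid translation commutes with merging
  shift <- c(1.5, -2, 0.25)
  tr <- function(cf) { cf$coords <- sweep(cf$coords, 2, shift, "+"); cf }
  ens4 <- conformation_ensemble(list(tr(h1), tr(h2)),
                                length_unit = "micron", resolution_kb = 118)
  m4 <- merge_homolog_chains(ens4)
  expect_equal(m4$conformations[[1]]$coords,
               sweep(m3$conformations[[1]]$coords, 2, shift, "+"),
               tolerance = 1e-12, ignore_attr = TRUE)

  # unequal homolog lengths are an error
  uneven <- structure(
    list(conformations = list(h1, conformation(h2$coords[1:10, ])),
         length_unit = "micron", resolution_kb = 118),
    class = "chrom_ensemble")
  expect_error(merge_homolog_chains(uneven), "differ in length")
})

test_that("trajectory sampling draws one boundary snapshot per cell", {
  make_traj <- function(id, n_frames) {
    frames <- lapply(seq_len(n_frames), function(t)
      conformation(cbind(seq_len(4) - 1 + t, 0, 0)))
    trajectory(frames, cell_id = id)
  }
  trajs <- lapply(1:18, function(i) make_traj(paste0("nuc", i), 120))
  ens <- sample_trajectory_cells(trajs, n_intervals = 50, seed = 3)
  expect_length(ens, 18L)

  # n_intervals = 1: always the first frame, whatever the seed
  e1 <- sample_trajectory_cells(trajs, n_intervals = 1, seed = 1)
  e2 <- sample_trajectory_cells(trajs, n_intervals = 1, seed = 99)
  expect_equal(e1$conformations[[1]]$coords, e2$conformations[[1]]$coords)
  expect_equal(e1$conformations[[1]]$coords[1, 1], 1)  # frame 1

  # deterministic under a fixed seed; different seeds almost surely differ
  s1 <- sample_trajectory_cells(trajs, seed = 7)
  s2 <- sample_trajectory_cells(trajs, seed = 7)
  s3 <- sample_trajectory_cells(trajs, seed = 8)
  expect_identical(lapply(s1$conformations, `[[`, "coords"),
                   lapply(s2$conformations, `[[`, "coords"))
  expect_false(identical(lapply(s1$conformations, `[[`, "coords"),
                         lapply(s3$conformations, `[[`, "coords")))

  short <- lapply(1:2, function(i) make_traj(paste0("s", i), 10))
  expect_error(sample_trajectory_cells(short, n_intervals = 50, seed = 1),
               "s1")
})

test_that("replicate subsampling draws distinct cells without replacement", {
  ens <- random_walk_ensemble(30, 10, seed = 20)
  reps <- subsample_replicates(ens, k = 20, n_rep = 10, seed = 4)
  expect_length(reps, 10L)
  for (r in reps) {
    ids <- vapply(r$conformations, `[[`, "", "cell_id")
    expect_length(ids, 20L)
    expect_false(anyDuplicated(ids) > 0)
  }
  # k = n reproduces the full ensemble up to ordering
  full <- subsample_replicates(ens, k = 30, n_rep = 2, seed = 5)
  ids <- sort(vapply(full[[1]]$conformations, `[[`, "", "cell_id"))
  expect_equal(ids, sort(vapply(ens$conformations, `[[`, "", "cell_id")))
  expect_error(subsample_replicates(ens, k = 31, seed = 1), "exceeds")

  # selection frequencies are approximately uniform (k/n) over many draws
  many <- subsample_replicates(ens, k = 10, n_rep = 400, seed = 6)
  counts <- table(unlist(lapply(many, function(r)
    vapply(r$conformations, `[[`, "", "cell_id"))))
  freq <- as.numeric(counts) / 400
  expect_true(all(abs(freq - 1 / 3) < 0.1))
})
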