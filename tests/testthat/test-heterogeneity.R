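test_that("<Rs> curves match geometry and the brute-force oracle", {
  # collinear unit-spaced chain: <Rs> = s exactly
  line <- straight_chain(12)
  cu <- rs_curve(line)
  expect_equal(cu$values, as.numeric(1:11), tolerance = 1e-12)

  # two beads: a single value equal to the inter-bead distance
  two <- conformation(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(rs_curve(two)$values, 5)

  # random 30-bead chain equals the O(n^2) double-loop oracle
  rw <- random_walk_conformation(30, seed = 42)
  expect_equal(rs_curve(rw)$values, brute_force_rs(rw$coords),
               tolerance = 1e-12)

  # s_kb grid follows the declared resolution
  expect_equal(rs_curve(line, resolution_kb = 118)$s_kb,
               118 * (1:11))
})

test_that("C.H. is the population spread across cells and vanishes for identical nuclei", {
  base <- random_walk_conformation(20, seed = 1)
  same <- conformation_ensemble(
    lapply(1:6, function(k) conformation(base$coords,
                                         cell_id = paste0("c", k))),
    length_unit = "arbitrary", resolution_kb = 1)
  prof <- ch_profile(same)
  expect_true(all(prof$CH == 0))
  expect_true(all(prof$relative_CH == 0))

  # two cells: C.H. = |a - b| / 2 at every s (two-point population sd)
  e2 <- random_walk_ensemble(2, 15, seed = 30)
  curves <- rs_curves(e2)
  prof2 <- ch_profile(curves)
  expect_equal(prof2$CH,
               abs(curves[[1]]$values - curves[[2]]$values) / 2,
               tolerance = 1e-12)

  # 18-cell ensemble matches the direct-formula oracle
  e18 <- random_walk_ensemble(18, 25, seed = 77)
  curves18 <- rs_curves(e18)
  prof18 <- ch_profile(curves18)
  vals <- sapply(curves18, `[[`, "values")  # s x cells
  direct <- apply(vals, 1, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(prof18$CH, direct, tolerance = 1e-12)
  expect_equal(attr(prof18, "n_cells"), 18L)
})

test_that("Relative curves are mean-normalized, dimensionless, scale-invariant", {
  e <- random_walk_ensemble(10, 20, seed = 9)
  curves <- rs_curves(e)
  rel <- relative_curves(curves)
  vals <- sapply(rel, `[[`, "values")
  expect_equal(rowMeans(vals), rep(1, nrow(vals)), tolerance = 1e-12)

  # identical curves normalize to exactly 1
  base <- random_walk_conformation(20, seed = 2)
  same <- lapply(1:4, function(k) rs_curve(base))
  expect_true(all(abs(sapply(relative_curves(same), `[[`, "values") - 1)
                  < 1e-12))

  # rescaling all coordinates by c > 0 leaves relative curves unchanged
  scaled <- conformation_ensemble(
    lapply(e$conformations, function(cf)
      conformation(cf$coords * 3.7, cell_id = cf$cell_id)),
    length_unit = "arbitrary", resolution_kb = 1)
  rel2 <- relative_curves(rs_curves(scaled))
  expect_equal(sapply(rel2, `[[`, "values"), vals, tolerance = 1e-12)

  # zero ensemble mean at any s is an error
  degenerate <- lapply(1:3, function(k)
    rs_curve(conformation(matrix(0, 4, 3) + 0)))
  expect_error(relative_curves(degenerate), "zero")
})

test_that("Relative C.H. equals C.H. / mean curve and recovers known spreads", {
  e <- random_walk_ensemble(18, 30, seed = 55)
  prof <- ch_profile(e)
  rel_prof <- relative_ch_profile(e)
  # dual route: explicit normalization vs the algebraic identity
  expect_equal(rel_prof$CH, prof$CH / prof$mean_Rs, tolerance = 1e-12)
  expect_equal(prof$relative_CH, prof$CH / prof$mean_Rs,
               tolerance = 1e-12)

  # fixed per-cell factors {0.9, 1, 1.1}: Relative C.H. is the population
  # sd of the normalized factors = sqrt(0.02/3) ~= 0.0816 at every s
  base <- rs_curve(random_walk_conformation(25, seed = 3))
  fac <- c(0.9, 1, 1.1)
  curves <- lapply(seq_along(fac), function(k)
    new_curve <- structure(list(cell_id = paste0("c", k),
                                s_beads = base$s_beads, s_kb = base$s_kb,
                                values = base$values * fac[k],
                                is_guide = rep(FALSE, length(base$values))),
                           class = "rs_curve"))
  rp <- relative_ch_profile(curves)
  expect_equal(rp$CH, rep(sqrt(mean((fac - 1)^2)), nrow(rp)),
               tolerance = 1e-10)
  expect_equal(sqrt(mean((fac - 1)^2)), 0.08165, tolerance = 1e-3)
})

test_that("the last separation averages a single pair, inflating the spread", {
  e <- random_walk_ensemble(12, 10, seed = 8)
  curves <- rs_curves(e)
  n <- n_beads(e)
  for (k in seq_along(curves)) {
    endpoint <- sqrt(sum((e$conformations[[k]]$coords[n, ] -
                          e$conformations[[k]]$coords[1, ])^2))
    expect_equal(curves[[k]]$values[n - 1], endpoint, tolerance = 1e-12)
  }
})

test_that("replicate error bars behave like a sample spread", {
  ens <- random_walk_ensemble(40, 12, seed = 61)
  reps <- subsample_replicates(ens, k = 15, n_rep = 6, seed = 2)
  eb <- replicate_errorbars(reps, metric = "relative_ch")
  expect_true(all(eb$sd >= 0))

  # identical replicates: zero sd everywhere
  same <- list(reps[[1]], reps[[1]], reps[[1]])
  eb0 <- replicate_errorbars(same, metric = "ch")
  expect_true(all(eb0$sd == 0))

  # two replicates: mean (m1+m2)/2 and sd |m1-m2|/sqrt(2)
  two <- reps[1:2]
  m1 <- ch_profile(two[[1]])$CH
  m2 <- ch_profile(two[[2]])$CH
  eb2 <- replicate_errorbars(two, metric = "ch")
  expect_equal(eb2$mean, (m1 + m2) / 2, tolerance = 1e-12)
  expect_equal(eb2$sd, abs(m1 - m2) / sqrt(2), tolerance = 1e-12)
})

test_that("scaling-exponent fits recover exact power laws and reject bad windows", {
  s <- 1:400
  exact <- structure(list(cell_id = "exact", s_beads = s, s_kb = s,
                          values = sqrt(s),
                          is_guide = rep(FALSE, 400)),
                     class = "rs_curve")
  fit <- fit_scaling_exponent(exact, s_lo = 2, s_hi = 400)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-12)

  short <- rs_curve(straight_chain(50))
  expect_error(fit_scaling_exponent(short, s_hi = 400), "grid ends")
})

test_that("profile files carry the declared columns", {
  ens <- random_walk_ensemble(8, 10, seed = 13)
  prof <- ch_profile(ens)
  reps <- subsample_replicates(ens, k = 6, n_rep = 4, seed = 3)
  eb <- replicate_errorbars(reps, metric = "relative_ch")
  path <- withr::local_tempfile()
  write_profile(prof, path, errorbars = eb,
                header = c("seed=13", "metric=relative_ch"))
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "# seed=13"))
  tab <- read.delim(path, comment.char = "#")
  expect_named(tab, c("s_beads", "s_kb", "mean_Rs", "CH", "relative_CH",
                      "err_CH", "err_relative_CH", "n_cells"))
  expect_equal(nrow(tab), nrow(prof))
})
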