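test_that("default affinity grid matches the antennal population spec", {
  g <- affinity_grid_default()
  expect_length(g, 50)
  expect_equal(g[1], 2e-4)
  expect_equal(g[50], 1e-2)
  expect_equal(unique(round(diff(g), 12)), 2e-4)
  sp <- population_spec()
  expect_equal(sp$dissociation, 1e2)
  expect_equal(length(sp$affinities) * sp$n_per_group, 1250)
})

test_that("population simulation emits one histogram per group", {
  sp <- population_spec(affinities = c(0, 2e-3, 1e-2), n_per_group = 3,
                        seed = 5)
  w <- wave_staircase(data.frame(amplitude = c(0, 60, 100),
                                 duration = c(0.5, 1, 1)), dt = 2e-4)
  pp <- population_simulate(sp, w)
  expect_equal(attr(pp, "n_osn"), 9)
  expect_equal(dplyr::n_distinct(pp$group), 3)
  agg <- dplyr::summarise(dplyr::group_by(pp, affinity),
                          late = mean(rate[t > 1.6]))
  # zero-affinity group stays at spontaneous level; others respond
  expect_lt(agg$late[agg$affinity == 0], 10)
  expect_gt(agg$late[agg$affinity == 1e-2], 50)
})

test_that("rate movie frames keep the matrix shape and determinism", {
  am <- matrix(c(1e-3, 1e-3, 5e-3, 2e-3, 4e-3, 8e-3), 2, 3,
               dimnames = list(c("r1", "r2"), c("o1", "o2", "o3")))
  w <- wave_staircase(data.frame(amplitude = c(0, 80), duration = c(0.5, 1)),
                      dt = 2e-4)
  mv <- rate_matrix_movie(am, dissociation = 132, w = w, n_neurons = 2,
                          seed = 3)
  fr <- movie_frame(mv, 1.2)
  expect_equal(dim(fr), c(2, 3))
  expect_equal(rownames(fr), c("r1", "r2"))
  # identical affinities (r1/o1 and r2/o1) produce identical responses
  expect_equal(fr["r1", "o1"], fr["r2", "o1"])
})

test_that("staircase jumps drive overshoot-then-settle responses", {
  am <- matrix(c(2e-3, 5e-3, 8e-3), 1, 3,
               dimnames = list("r", c("o1", "o2", "o3")))
  w <- wave_staircase(data.frame(amplitude = c(0, 100), duration = c(0.5, 2.5)),
                      dt = 2e-4)
  mv <- rate_matrix_movie(am, dissociation = 10, w = w, n_neurons = 10,
                          seed = 4)
  by_entry <- dplyr::summarise(
    dplyr::group_by(mv, odorant),
    transient = max(rate[t > 0.5 & t < 1.2]),
    settled = mean(rate[t > 2.2]))
  expect_true(all(by_entry$transient > by_entry$settled))
})
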