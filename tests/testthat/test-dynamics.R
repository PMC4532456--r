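# The Circle_4 nor systems (closed 1-neighborhoods) are the canonical
# worked examples: their images, cycles, transients and basins are known
# exactly.

test_that("apply_block updates only the block, simultaneously", {
  sys <- circle4_nor(scheme_sequential(1:4))
  expect_equal(apply_block(sys, c(0, 0, 0, 0), 1), c(1, 0, 0, 0))
  # a full-vertex block is one synchronous step
  expect_equal(apply_block(sys, c(0, 0, 0, 0), 1:4), c(1, 1, 1, 1))
  # within-block evaluation reads the pre-block state: updating {1,2}
  # together must not let the new x1 feed x2
  expect_equal(apply_block(sys, c(0, 0, 0, 0), c(1, 2)), c(1, 1, 0, 0))
  expect_error(apply_block(sys, c(0, 0, 0, 0), integer(0)), "non-empty")
  expect_error(apply_block(sys, c(0, 0, 0, 0), 5), "unknown vertex")
})

test_that("the three update schemes give the printed images of the zero state", {
  expect_equal(gds_map(circle4_nor(scheme_synchronous(4)), c(0, 0, 0, 0)),
               c(1, 1, 1, 1))
  expect_equal(gds_map(circle4_nor(scheme_sequential(1:4)), c(0, 0, 0, 0)),
               c(1, 0, 1, 0))
  expect_equal(gds_map(circle4_nor(scheme_block(list(c(1, 2), 3, 4))),
                       c(0, 0, 0, 0)),
               c(1, 1, 0, 0))
})

test_that("forward trajectories split into prefix and cycle", {
  sys <- circle4_nor(scheme_sequential(1:4))
  tr <- forward_trajectory(sys, c(0, 0, 1, 1))
  expect_equal(nrow(tr$prefix), 1)          # transient of length 1
  expect_equal(tr$period, 7)                # the unique 7-cycle
  # starting on the cycle: empty prefix
  on_cycle <- tr$cycle[1, ]
  tr2 <- forward_trajectory(sys, on_cycle)
  expect_equal(nrow(tr2$prefix), 0)
  expect_equal(tr2$period, 7)
  expect_error(forward_trajectory(sys, c(0, 0, 0, 0), max_steps = 0),
               "max_steps")
  expect_error(forward_trajectory(sys, c(0, 0, 0, 0), max_steps = 2),
               "recurrence")
})

test_that("phase-space enumeration yields a functional digraph", {
  ps <- enumerate_phase_space(circle4_nor(scheme_synchronous(4)))
  expect_length(ps$successor, 16)
  expect_true(all(ps$successor >= 0 & ps$successor < 16))
  expect_equal(sum(basins(ps)$sizes$size), 16)
  big <- gds(make_template("circle", n = 30, self_loops = TRUE),
             vf_multithreshold(c(2, 3, 6, 6, 4, 5), r = 3),
             scheme_sequential(1:30), r = 3)
  expect_error(enumerate_phase_space(big), "cap")
})

test_that("cycle structure of the three nor systems matches the known counts", {
  seq_ps <- enumerate_phase_space(circle4_nor(scheme_sequential(1:4)))
  expect_equal(summarize_phase_space(seq_ps)$cycle_lengths, 7L)
  expect_equal(max_transient(seq_ps), 1)

  sync_ps <- enumerate_phase_space(circle4_nor(scheme_synchronous(4)))
  expect_equal(summarize_phase_space(sync_ps)$cycle_lengths, c(2L, 2L, 2L))
  expect_equal(nrow(find_attractors(sync_ps)), 3)
  # the 2-cycle {(0,1,0,0),(0,0,0,1)} is its own basin
  att <- find_attractors(sync_ps)
  i <- which(vapply(att$states, function(s) {
    setequal(s, c(encode_state(c(0, 1, 0, 0), 2), encode_state(c(0, 0, 0, 1), 2)))
  }, logical(1)))
  expect_equal(att$basin_size[i], 2)

  blk_ps <- enumerate_phase_space(circle4_nor(scheme_block(list(c(1, 2), 3, 4))))
  expect_equal(summarize_phase_space(blk_ps)$cycle_lengths, 2L)
  expect_equal(max_transient(blk_ps), 3)
  expect_equal(sum(transient_lengths(blk_ps) == 3), 10)
  # (0,0,1,1) realizes the maximum
  expect_equal(blk_ps$transient[encode_state(c(0, 0, 1, 1), 2) + 1], 3)
})

test_that("attractor cycles are canonical: start at min code, follow successors", {
  ps <- enumerate_phase_space(circle4_nor(scheme_sequential(1:4)))
  att <- find_attractors(ps)
  cyc <- att$states[[1]]
  expect_equal(cyc[1], min(cyc))
  for (i in seq_along(cyc)) {
    expect_equal(ps$successor[cyc[i] + 1], cyc[if (i == length(cyc)) 1 else i + 1])
  }
  expect_false(is.unsorted(att$period[order(vapply(att$states, min, numeric(1)))]))
})

test_that("scheme reductions hold pointwise on random instances", {
  for (seed in 1:5) {
    sys <- random_gds_instance(5, family = "bithreshold", seed = seed,
                               scheme_kind = "sequential")
    perm <- unlist(sys$scheme$blocks)
    as_blocks <- gds(sys$graph, sys$functions,
                     scheme_block(as.list(perm)))
    expect_true(functional_equivalence(sys, as_blocks))
    sync <- gds(sys$graph, sys$functions, scheme_synchronous(5))
    one_block <- gds(sys$graph, sys$functions, scheme_block(list(1:5)))
    expect_true(functional_equivalence(sync, one_block))
  }
})

test_that("the vectorized engine agrees with the scalar-path oracle", {
  systems <- c(
    lapply(1:3, function(s) random_gds_instance(5, family = "bithreshold",
                                                seed = s)),
    lapply(4:5, function(s) random_gds_instance(4, r = 3,
                                                family = "multithreshold",
                                                seed = s)),
    list(random_gds_instance(5, family = "linear_threshold", seed = 6),
         random_gds_instance(5, family = "nor", seed = 7),
         gds_example("circle4_nor_block")))
  for (sys in systems) {
    M <- t(vapply(0:(sys$r^sys$n - 1), decode_state, numeric(sys$n),
                  n = sys$n, r = sys$r))
    fast <- t(apply(M, 1, function(x) gds_map(sys, x)))
    slow <- t(apply(M, 1, function(x) slow_map(sys, x)))
    expect_equal(fast, slow)
  }
})

test_that("enumeration agrees with the brute-force orbit oracle", {
  for (seed in 1:3) {
    sys <- random_gds_instance(4, family = "bithreshold", seed = seed)
    ps <- enumerate_phase_space(sys)
    for (code in seq(0, 15, by = 3)) {
      orb <- slow_orbit(sys, decode_state(code, sys$n, sys$r))
      expect_equal(ps$transient[code + 1], orb$transient)
      aid <- ps$attractor_id[code + 1]
      expect_equal(ps$attractors[[aid]]$period, orb$period)
      expect_equal(min(ps$attractors[[aid]]$states), orb$cycle_min)
    }
  }
})

test_that("forward trajectories agree with enumeration for every state", {
  sys <- random_gds_instance(4, family = "threshold", seed = 11)
  ps <- enumerate_phase_space(sys)
  for (code in 0:15) {
    tr <- forward_trajectory(sys, decode_state(code, 4, 2))
    expect_equal(nrow(tr$prefix), ps$transient[code + 1])
    aid <- ps$attractor_id[code + 1]
    expect_equal(tr$period, ps$attractors[[aid]]$period)
  }
})

test_that("fixed points are invariant across fair schemes", {
  fixed_codes <- function(sys) {
    ps <- enumerate_phase_space(sys)
    which(ps$successor == seq_along(ps$successor) - 1L) - 1L
  }
  for (seed in 1:4) {
    base <- random_gds_instance(5, family = "threshold", seed = seed,
                                scheme_kind = "synchronous")
    ref <- fixed_codes(base)
    for (perm_seed in 1:3) {
      perm <- withr::with_seed(perm_seed, sample(5))
      seq_sys <- gds(base$graph, base$functions, scheme_sequential(perm))
      expect_equal(fixed_codes(seq_sys), ref)
    }
  }
})

test_that("synchronous bithreshold systems only have cycles of length <= 2", {
  for (seed in 1:6) {
    sys <- random_gds_instance(5, family = "bithreshold", seed = seed,
                               scheme_kind = "synchronous")
    ps <- enumerate_phase_space(sys)
    expect_lte(summarize_phase_space(ps)$max_cycle, 2)
  }
})

test_that("sequential bithreshold with delta <= 1 has only fixed points", {
  for (seed in 1:6) {
    sys <- random_gds_instance(5, family = "bithreshold", seed = seed,
                               scheme_kind = "sequential", delta_max = 1)
    ps <- enumerate_phase_space(sys)
    expect_equal(summarize_phase_space(ps)$max_cycle, 1)
  }
})

test_that("closed-neighborhood nor systems have no fixed points", {
  for (seed in 1:5) {
    sys <- random_gds_instance(5, family = "nor", seed = seed,
                               self_loops = TRUE)
    ps <- enumerate_phase_space(sys)
    expect_equal(summarize_phase_space(ps)$fixed_points, 0)
  }
})

test_that("unfair words compose as one composite map per time step", {
  g <- make_template("circle", n = 3, self_loops = TRUE)
  sys <- gds(g, vf_nor(), scheme_word(c(1, 2, 1)))
  # vertex 3 never fires: its coordinate is constant along any trajectory
  x <- c(0, 0, 1)
  for (i in 1:5) {
    x <- gds_map(sys, x)
    expect_equal(x[3], 1)
  }
  ps <- enumerate_phase_space(sys)
  expect_length(ps$successor, 8)
})
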