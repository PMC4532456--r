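test_that("functional and cycle equivalence behave on the nor trio", {
  sync <- circle4_nor(scheme_synchronous(4))
  sq <- circle4_nor(scheme_sequential(1:4))
  blk <- circle4_nor(scheme_block(list(c(1, 2), 3, 4)))
  expect_true(functional_equivalence(sync, sync))
  pairs <- list(list(sync, sq), list(sync, blk), list(sq, blk))
  for (p in pairs) {
    expect_false(functional_equivalence(p[[1]], p[[2]]))
    expect_false(cycle_equivalence(p[[1]], p[[2]]))
  }
  v <- compare_gds(sync, blk)
  expect_false(v$functional)
  expect_equal(v$cycles_a[[1]], c(2L, 2L, 2L))
  expect_equal(v$cycles_b[[1]], 2L)
  small <- gds(make_template("circle", n = 3, self_loops = TRUE), vf_nor(),
               scheme_synchronous(3))
  expect_error(functional_equivalence(sync, small), "share n and r")
})

test_that("functional equivalence implies cycle equivalence on random pairs", {
  for (seed in 1:6) {
    a <- random_gds_instance(4, family = "bithreshold", seed = seed)
    b <- random_gds_instance(4, family = "bithreshold", seed = seed + 100)
    if (functional_equivalence(a, b)) expect_true(cycle_equivalence(a, b))
    # a system is always equivalent to itself both ways
    expect_true(functional_equivalence(a, a))
    expect_true(cycle_equivalence(a, a))
  }
})

test_that("tree graphs give one cycle-equivalence class over sequential orders", {
  g <- make_template("balanced_tree", branching = 2, depth = 2,
                     self_loops = TRUE)   # 7 vertices
  perms <- lapply(1:4, function(s) withr::with_seed(s, sample(7)))
  systems <- lapply(perms, function(p) {
    gds(g, vf_bithreshold(1, 3), scheme_sequential(p))
  })
  for (i in 2:length(systems)) {
    expect_true(cycle_equivalence(systems[[1]], systems[[i]]))
  }
})

test_that("the bithreshold circle's attractor graph is one closed ergodic set", {
  sys <- gds_example("circle4_bithreshold")
  ps <- enumerate_phase_space(sys)
  expect_equal(length(ps$attractors), 4)          # four basins
  ag <- build_attractor_graph(ps)
  expect_equal(ag$n_attractors, 4)
  has_edge <- function(i, j) any(ag$edges$from == i & ag$edges$to == j)
  # flipping x4 of (0,0,0,0) lands in the basin of the attractor holding
  # (0,0,0,1); flipping x4 of (1,0,1,1) lands in the basin holding (1,0,1,0)
  a_of <- function(state) ps$attractor_id[encode_state(state, 2) + 1]
  expect_true(has_edge(a_of(c(0, 0, 0, 0)), a_of(c(0, 0, 0, 1))))
  expect_true(has_edge(a_of(c(1, 0, 1, 1)), a_of(c(1, 0, 1, 0))))
  es <- ergodic_sets(ag)
  expect_equal(nrow(es), 1)
  expect_equal(es$size, 4)
  expect_true(es$closed)
})

test_that("ergodic sets partition the attractors of any system", {
  for (seed in 1:4) {
    sys <- random_gds_instance(4, family = "threshold", seed = seed)
    ps <- enumerate_phase_space(sys)
    ag <- build_attractor_graph(ps)
    es <- ergodic_sets(ag)
    members <- sort(unlist(es$attractors))
    expect_equal(members, seq_len(ag$n_attractors))
    expect_equal(sum(es$size), ag$n_attractors)
  }
  # a single attractor gives one closed SCC of size 1
  one <- enumerate_phase_space(circle4_nor(scheme_sequential(1:4)))
  es1 <- ergodic_sets(build_attractor_graph(one))
  expect_equal(es1$size, 1)
  expect_true(es1$closed)
})

test_that("the four fixed-point inequalities evaluate as printed", {
  ok <- check_fixed_point_conditions(c(2, 3, 6, 6, 4, 5), C1 = -2, C2 = -6)
  expect_true(ok$all_hold)
  expect_equal(ok$delta01, 1)
  # dropping k01 to 1 violates condition (i) minimally: delta01 = 2 > 1
  bad <- check_fixed_point_conditions(c(1, 3, 6, 6, 4, 5), C1 = -2, C2 = -6)
  expect_false(bad$cond1)
  expect_true(bad$cond2 && bad$cond3 && bad$cond4)
  expect_equal(bad$delta01, 2)
  # C1 = -2 turns condition (i) into delta01 <= 1
  edge <- check_fixed_point_conditions(c(2, 3, 6, 6, 4, 5), C1 = -2, C2 = -6)
  expect_true(edge$cond1)
  expect_false(check_fixed_point_conditions(c(1.5, 3, 6, 6, 4, 5),
                                            C1 = -2, C2 = -6)$cond1)
  expect_error(check_fixed_point_conditions(c(k01 = 2, k10 = 3)), "missing")
})

test_that("when the conditions hold, enumeration finds only fixed points", {
  # computational echo of the fixed-point theorem on small circles
  for (n in 4:6) {
    sys <- gds_example("multistate_circle", n = n)
    ps <- enumerate_phase_space(sys)
    expect_equal(summarize_phase_space(ps)$max_cycle, 1)
  }
})

test_that("a closed K6 clique with thresholds (5,5) has exactly the two uniform fixed points", {
  sys <- gds(make_template("clique", q = 6, self_loops = TRUE),
             vf_bithreshold(5, 5), scheme_sequential(1:6))
  ps <- enumerate_phase_space(sys)
  s <- summarize_phase_space(ps)
  expect_equal(s$fixed_points, 2)
  fixed <- which(ps$successor == seq(0, 63)) - 1L
  expect_setequal(fixed, c(0, 63))
})

test_that("factorized fixed-point counts equal brute force on disjoint systems", {
  two <- gds(make_template("disjoint_cliques", sizes = c(4, 4),
                           self_loops = TRUE),
             vf_bithreshold(3, 3), scheme_sequential(1:8))
  direct <- summarize_phase_space(enumerate_phase_space(two))$fixed_points
  expect_equal(count_fixed_points_factorized(two), direct)
  # 9 independent closed K6 cliques: 2^9 fixed points by factorization
  expect_equal(count_fixed_points_factorized(gds_example("clique_chain")), 512)
  # random disconnected instances
  for (seed in 1:3) {
    g <- make_template("disjoint_cliques", sizes = c(3, 2, 3),
                       self_loops = TRUE)
    perm <- withr::with_seed(seed, sample(8))
    k01 <- withr::with_seed(seed + 50, sample(0:3, 1))
    sys <- gds(g, vf_bithreshold(k01, k01 + 1), scheme_sequential(perm))
    direct <- summarize_phase_space(enumerate_phase_space(sys))$fixed_points
    expect_equal(count_fixed_points_factorized(sys), direct)
  }
  unfair <- gds(make_template("circle", n = 3, self_loops = TRUE), vf_nor(),
                scheme_word(c(1, 2, 1)))
  expect_error(count_fixed_points_factorized(unfair), "fair")
})

test_that("the max-cycle sweep exposes the bifurcation at k01 = 1", {
  flat <- sweep_max_cycle("circle", vf_multithreshold(c(2, 3, 6, 6, 4, 5), r = 3),
                          4:6, r = 3)
  expect_equal(flat$max_cycle, rep(1L, 3))
  grow <- sweep_max_cycle("circle", vf_multithreshold(c(1, 3, 6, 6, 4, 5), r = 3),
                          4:6, r = 3)
  expect_equal(grow$max_cycle, grow$n - 1L)
  expect_equal(nrow(sweep_max_cycle("circle", vf_nor(), integer(0))), 0)
})
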