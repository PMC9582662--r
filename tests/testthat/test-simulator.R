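test_that("minimum-image displacement folds into [-L/2, L/2)", {
  expect_equal(periodic_displacement(c(0, 0), c(1, 0), 50), c(1, 0))
  expect_equal(periodic_displacement(c(49, 0), c(1, 0), 50), c(2, 0))
  expect_equal(periodic_displacement(c(3, 4), c(3, 4), 50), c(0, 0))
  set.seed(3)
  a <- matrix(runif(100, 0, 50), 50, 2)
  b <- matrix(runif(100, 0, 50), 50, 2)
  d <- periodic_displacement(a, b, 50)
  expect_true(all(d >= -25 & d < 25))
  # folding is consistent with the unfolded difference modulo L
  expect_true(all(abs((b - a - d) %% 50) < 1e-9))
})

test_that("initial population fills the central disk without overlaps", {
  p <- model_params()
  set.seed(5)
  st <- init_population(p)
  expect_equal(nrow(st$positions), 35)
  r_from_centre <- sqrt(rowSums(sweep(st$positions, 2, c(25, 25))^2))
  expect_true(all(r_from_centre <= p$init_radius + 1e-12))
  dm <- as.matrix(dist(st$positions))
  expect_true(all(dm[upper.tri(dm)] >= 2 * p$R))
  expect_true(all(st$headings >= 0 & st$headings < 2 * pi))
  # single cell
  set.seed(6)
  st1 <- init_population(update_params(p, N = 1))
  expect_equal(nrow(st1$positions), 1)
  # determinism: same seed identical, different seed different
  set.seed(9); a <- init_population(p)
  set.seed(9); b <- init_population(p)
  set.seed(10); c3 <- init_population(p)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, c3$positions))
})

test_that("an overcrowded initial disk warns and relaxes non-overlap", {
  p <- update_params(model_params(), N = 20, init_radius = 3)
  set.seed(1)
  expect_warning(st <- init_population(p), "init_radius too small")
  expect_equal(nrow(st$positions), 20)
})

test_that("neighbour search matches the brute-force oracle", {
  set.seed(42)
  for (rep in seq_len(100)) {
    N <- sample(2:50, 1)
    L <- runif(1, 10, 60)
    pos <- matrix(runif(2 * N, 0, L), N, 2)
    st <- make_state(pos, rep(0, N), L = L)
    radius <- runif(1, 0, L / 2)
    i <- sample(N, 1)
    inc <- rep %% 2 == 0
    expect_identical(sort(neighbors_within(st, i, radius, include_self = inc)),
                     sort(brute_force_neighbors(pos, i, radius, L, inc)))
  }
})

test_that("range conditions are strict inequalities", {
  st <- make_state(rbind(c(10, 10), c(12, 10)), c(0, 0))
  expect_length(neighbors_within(st, 1, 2), 0)        # exactly 2.0 apart
  expect_identical(neighbors_within(st, 1, 2.001), 2L)
  expect_length(neighbors_within(st, 1, 0, include_self = TRUE), 0)
})

test_that("pairwise repulsion is proportional to overlap and pushes apart", {
  p <- model_params()
  # no overlap and exact contact give zero force
  st <- make_state(rbind(c(10, 10), c(12.5, 10)), c(0, 0))
  expect_equal(pair_repulsion(1, 2, st, p), c(0, 0))
  st <- make_state(rbind(c(10, 10), c(12, 10)), c(0, 0))
  expect_equal(pair_repulsion(1, 2, st, p), c(0, 0))
  # overlap of 0.5 with j east of i: force 0.15 pointing west
  st <- make_state(rbind(c(10, 10), c(11.5, 10)), c(0, 0))
  expect_equal(pair_repulsion(1, 2, st, p), c(-0.15, 0), tolerance = 1e-12)
  expect_equal(pair_repulsion(2, 1, st, p), c(0.15, 0), tolerance = 1e-12)
})

test_that("pairwise repulsion is antisymmetric on random overlapping pairs", {
  p <- model_params()
  set.seed(13)
  for (rep in seq_len(50)) {
    centre <- runif(2, 5, 45)
    offset <- runif(1, 0.05, 1.95) * {
      a <- runif(1, 0, 2 * pi); c(cos(a), sin(a))
    }
    st <- make_state(rbind(centre, centre + offset), c(0, 0))
    expect_equal(pair_repulsion(1, 2, st, p),
                 -pair_repulsion(2, 1, st, p), tolerance = 1e-12)
  }
  # coincident centres: deterministic unit-scaled push, still antisymmetric
  st <- make_state(rbind(c(10, 10), c(10, 10)), c(0, 0))
  f12 <- pair_repulsion(1, 2, st, p)
  expect_equal(sqrt(sum(f12^2)), p$k * 2 * p$R, tolerance = 1e-12)
  expect_equal(f12, -pair_repulsion(2, 1, st, p))
  expect_identical(f12, pair_repulsion(1, 2, st, p))
})

test_that("total repulsion sums pair forces and cancels by symmetry", {
  p <- model_params()
  st <- make_state(matrix(c(25, 25), 1), 0)
  expect_equal(total_repulsion(1, st, p), c(0, 0))
  # neighbours placed symmetrically east and west cancel exactly
  st <- make_state(rbind(c(25, 25), c(26.5, 25), c(23.5, 25)), rep(0, 3))
  expect_equal(total_repulsion(1, st, p), c(0, 0), tolerance = 1e-12)
  # three-cell line, spacing 1.5: middle cancels, ends pushed outwards
  expect_equal(total_repulsion(2, st, p), c(0.15, 0), tolerance = 1e-12)
  expect_equal(total_repulsion(3, st, p), c(-0.15, 0), tolerance = 1e-12)
})

test_that("alignment averages neighbour headings and applies scaled noise", {
  p <- update_params(model_params(), eta = 0)
  # isolated cell keeps its heading
  st <- make_state(matrix(c(25, 25), 1), 1.2)
  expect_equal(alignment_heading(1, st, p), 1.2)
  # two in-range cells with headings 0 and pi/2 agree on pi/4
  st <- make_state(rbind(c(25, 25), c(26, 25)), c(0, pi / 2))
  expect_equal(alignment_heading(1, st, p), pi / 4, tolerance = 1e-12)
  expect_equal(alignment_heading(2, st, p), pi / 4, tolerance = 1e-12)
  # noise term enters as eta * xi
  pn <- update_params(model_params(), eta = 0.05)
  st <- make_state(matrix(c(25, 25), 1), 0)
  expect_equal(alignment_heading(1, st, pn, xi = pi / 2), 0.025 * pi,
               tolerance = 1e-12)
  # r_a = 0 leaves even the self out: current heading is kept
  p0 <- update_params(model_params(), r_a = 0, eta = 0)
  st <- make_state(rbind(c(25, 25), c(25.5, 25)), c(0.7, 2))
  expect_equal(alignment_heading(1, st, p0), 0.7)
})

test_that("a mutually aligned cluster is a fixed point of the alignment rule", {
  p <- update_params(model_params(), eta = 0, E0 = 0)
  pos <- rbind(c(25, 25), c(26.5, 25), c(25.7, 26.2))  # all within r_a = 2
  st <- make_state(pos, rep(0.9, 3))
  for (i in 1:3) expect_equal(alignment_heading(i, st, p), 0.9,
                              tolerance = 1e-12)
})

test_that("one step applies the overdamped update from the time-t state", {
  g0 <- uniform_field(50, E0 = 0)
  # free ballistic motion: displacement exactly v0 along the heading
  p <- update_params(model_params(), N = 1, eta = 0, E0 = 0)
  st <- make_state(matrix(c(25, 25), 1), 0.6, v0 = p$v0)
  st2 <- step_swarm(st, g0, p)
  expect_equal(attr(st2, "displacement"),
               0.1 * cbind(cos(0.6), sin(0.6)), tolerance = 1e-15)
  expect_identical(st2$time_index, 1L)
  # heading +y with an anodal +x field: x shrinks by mu |D|, y grows by v0
  p <- update_params(model_params(), N = 1, eta = 0)
  g <- uniform_field(50, E0 = 0.014)
  st <- make_state(matrix(c(25, 25), 1), pi / 2, v0 = p$v0)
  st2 <- step_swarm(st, g, p)
  expect_equal(attr(st2, "displacement")[1, ],
               c(-p$mu * 9 * 0.014, p$v0), tolerance = 1e-12)
})

test_that("dynamics are invariant under periodic wrapping of coordinates", {
  p <- update_params(model_params(), eta = 0)
  g <- uniform_field(50, E0 = 0.014)
  # an overlapping pair translated by a lattice vector across the boundary
  # behaves exactly as the original (translation by a multiple of the grid
  # spacing, here 24, so the sensed field is identical)
  inner <- make_state(rbind(c(25, 25), c(26.5, 25)), c(0.3, 1.1))
  outer <- make_state((rbind(c(25, 25), c(26.5, 25)) +
                         matrix(c(24, 0), 2, 2, byrow = TRUE)) %% 50,
                      c(0.3, 1.1))
  si <- step_swarm(inner, g, p)
  so <- step_swarm(outer, g, p)
  expect_equal(attr(si, "displacement"), attr(so, "displacement"),
               tolerance = 1e-12)
  expect_equal(si$headings, so$headings, tolerance = 1e-12)
})

test_that("volume exclusion separates overlapping cells monotonically", {
  p <- update_params(model_params(), v0 = 0, eta = 0, E0 = 0, N = 2)
  g0 <- uniform_field(50, E0 = 0)
  st <- make_state(rbind(c(25, 25), c(25.8, 25)), c(0, pi), v0 = 0)
  sep <- 0.8
  for (t in seq_len(200)) {
    st <- step_swarm(st, g0, p)
    d <- periodic_displacement(st$positions[1, ], st$positions[2, ], 50)
    new_sep <- sqrt(sum(d^2))
    if (sep < 2 * p$R) expect_gt(new_sep, sep)
    sep <- new_sep
  }
  # overlap relaxes towards contact (approach is asymptotic from below)
  expect_gt(sep, 1.99)
  expect_lte(sep, 2 * p$R)
})

test_that("full runs are deterministic, unwrapped-consistent and ballistic in the free limit", {
  # trajectory bookkeeping
  p <- model_params(N = 8, T = 25, seed = 21)
  tr <- run_simulation(p)
  expect_equal(dim(tr$wrapped), c(26, 8, 2))
  expect_true(all(abs(tr$wrapped - (tr$unwrapped %% 50)) < 1e-9))
  tr2 <- run_simulation(p)
  expect_identical(tr$unwrapped, tr2$unwrapped)
  expect_false(identical(tr$unwrapped, run_simulation(p, seed = 22)$unwrapped))
  # T = 0 keeps only the initial state
  expect_equal(dim(run_simulation(update_params(p, T = 0))$wrapped)[1], 1)
  # free single cell: endpoint displacement exactly T * v0
  pf <- model_params(N = 1, T = 140, eta = 0, E0 = 0, seed = 3)
  trf <- run_simulation(pf)
  d <- trf$unwrapped[141, 1, ] - trf$unwrapped[1, 1, ]
  expect_equal(sqrt(sum(d^2)), 14, tolerance = 1e-12)
  th0 <- trf$headings[1, 1]
  expect_equal(d, 14 * c(cos(th0), sin(th0)), tolerance = 1e-9)
})

test_that("trajectory tables carry one row per cell and step", {
  tr <- run_simulation(model_params(N = 4, T = 10, seed = 2))
  df <- trajectory_df(tr, run_id = 7)
  expect_equal(nrow(df), 4 * 11)
  expect_equal(unique(df$run_id), 7)
  expect_equal(df$x_wrapped, df$x_unwrapped %% 50, tolerance = 1e-9)
  last <- df[df$cell_id == 3 & df$t == 10, ]
  expect_equal(c(last$x_unwrapped, last$y_unwrapped), tr$unwrapped[11, 3, ])
})
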