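r_grid <- c(0.25, 0.5, 1, 2, 10, 100)

test_that("switching probabilities normalise and match the tabulated cases", {
  expect_equal(switch_probability(5, 1, 0:5), rep(0.2, 6))
  # r p_0 = 1/n for every r; n = 2 gives r p_1 = r/(1+r)
  for (r in r_grid) {
    expect_equal(r * switch_probability(5, r, 0), 1 / 5)
    expect_equal(r * switch_probability(2, r, 1), r / (1 + r))
  }
  expect_error(switch_probability(5, 1, 6), "\\[0, n\\]")
})

test_that("stationary distribution reproduces the small-n tables and sums to 1", {
  expect_equal(stationary_distribution(2, 1), c(0.25, 0.5, 0.25))
  expect_equal(stationary_distribution(5, 1), c(1, 5, 10, 10, 5, 1) / 32)
  for (r in r_grid) {
    # full n = 5 table as explicit functions of r
    expect_equal(stationary_distribution(5, r) * 2 * (1 + r)^4,
                 c(1, 1 + 4 * r, 2 * r * (3 * r + 2), 2 * r^2 * (2 * r + 3),
                   r^3 * (r + 4), r^4))
    for (n in c(1:8, 12)) {
      pi_k <- stationary_distribution(n, r)
      expect_equal(sum(pi_k), 1)
      # birth-death stationarity across every edge of the chain
      k <- 0:(n - 1)
      up <- pi_k[k + 1] * (n - k) * r * switch_probability(n, r, k)
      down <- pi_k[k + 2] * (k + 1) * switch_probability(n, r, k + 1)
      expect_equal(up, down)
    }
  }
})

test_that("mean jump matches the n = 1 collapse and the n = 2 enumeration", {
  Eeta <- outreach_mean_vector(default_nu)
  for (r in r_grid) {
    expect_equal(mean_jump(1, r, default_nu), Eeta / 2)
    expect_equal(mean_jump(2, r, default_nu), mean_jump_n2_oracle(r, Eeta))
  }
  expect_equal(mean_jump(2, 1, default_nu), (3 / 8) * c(15 / pi, 0))
  expect_equal(mean_jump(7, 3, isotropic_nu), c(0, 0))
  expect_error(mean_jump(3, 1, default_nu, weights = c(1, 2, 1)),
               "equal spring weights")
})

test_that("attach displacement and its expectation scale as 1/k", {
  expect_equal(attach_displacement(1, c(2, 3)), c(2, 3))
  expect_equal(attach_displacement(2, c(1, 0)), c(0.5, 0))
  expect_equal(attach_displacement(5, c(5, 0)), c(1, 0))
  expect_equal(attach_expectation(1, default_nu), 100 / 3)
  expect_equal(attach_expectation(2, default_nu), 25 / 3)
  k <- 1:50
  expect_true(all(diff(attach_expectation(k, default_nu)) < 0))
})

test_that("sequential states are built by the centroid update recursion", {
  st1 <- build_sequential_state(sequential_config())
  expect_equal(st1$centroid, c(0, 0))
  st2 <- build_sequential_state(rbind(c(1, 0)))
  expect_equal(st2$centroid, c(0.5, 0))
  st3 <- build_sequential_state(rbind(c(1, 0), c(0, 1)))
  expect_equal(st3$centroid, c(0.5, 1 / 3))
  expect_equal(st3$v, rbind(c(0, 0), c(1, 0), c(0.5, 1)))
})

test_that("detach possibilities match the tabulated entries and the geometric oracle", {
  expect_equal(detach_possibilities(rbind(c(1, 0))),
               rbind(c(0.5, 0), c(-0.5, 0)))
  expect_equal(detach_possibilities(rbind(c(1, 0), c(0, 1))),
               rbind(c(0.25, 1 / 6), c(-0.25, 1 / 6), c(0, -1 / 3)))
  # symbolic entries for k = 3, 4, 5 with arbitrary outreaches eta_2..eta_5
  set.seed(11)
  eta <- matrix(stats::rnorm(8), 4, 2)   # rows eta_2..eta_5
  e <- function(m) eta[m - 1, ]
  expect_equal(detach_possibilities(eta[1:2, ]), rbind(
    (e(2) / 2 + e(3) / 3) / 2, (-e(2) / 2 + e(3) / 3) / 2, -e(3) / 3))
  expect_equal(detach_possibilities(eta[1:3, ]), rbind(
    (e(2) / 2 + e(3) / 3 + e(4) / 4) / 3,
    (-e(2) / 2 + e(3) / 3 + e(4) / 4) / 3,
    (-2 * e(3) / 3 + e(4) / 4) / 3,
    -e(4) / 4))
  expect_equal(detach_possibilities(eta), rbind(
    (e(2) / 2 + e(3) / 3 + e(4) / 4 + e(5) / 5) / 4,
    (-e(2) / 2 + e(3) / 3 + e(4) / 4 + e(5) / 5) / 4,
    (-2 * e(3) / 3 + e(4) / 4 + e(5) / 5) / 4,
    (-3 * e(4) / 4 + e(5) / 5) / 4,
    -e(5) / 5))
  # brute-force geometric rebuild for random configurations
  set.seed(23)
  for (i in 1:100) {
    k <- sample(2:10, 1)
    etas <- sample_outreach(default_nu, k - 1)
    expect_equal(detach_possibilities(etas), geometric_detach_oracle(etas),
                 tolerance = 1e-12)
  }
  expect_error(detach_possibilities(sequential_config()), "k >= 2")
})

test_that("detach sum expectation reduces correctly and matches simulation", {
  expect_equal(detach_sum_expectation(2, default_nu), 50 / 3)
  expect_equal(detach_sum_expectation(3, isotropic_nu), (7 / 24) * (100 / 3))
  # Monte-Carlo oracle with an isotropic law (cross terms vanish exactly):
  # sum the squared geometric displacements over the k possibilities
  set.seed(5)
  for (k in c(3, 5)) {
    tot <- replicate(4000, {
      etas <- sample_outreach(isotropic_nu, k - 1)
      sum(geometric_detach_oracle(etas)^2)
    })
    expect_lt(abs(mean(tot) - detach_sum_expectation(k, isotropic_nu)),
              4 * stats::sd(tot) / sqrt(length(tot)))
  }
})

test_that("AMSD matches its constructive assembly and the exact small-n MSD", {
  expect_equal(amsd(2, 1, default_nu), 12.5)
  expect_equal(exact_msd_small_n(1, 1, default_nu), 50 / 3)
  expect_equal(exact_msd_small_n(2, 1, default_nu), 12.5)
  for (r in r_grid) {
    expect_equal(amsd(1, r, default_nu), 50 / 3)
    expect_equal(amsd(2, r, default_nu), exact_msd_small_n(2, r, default_nu))
    expect_equal(exact_msd_small_n(2, r, default_nu),
                 msd_n2_oracle(r, 100 / 3))
    for (n in c(3, 5, 8, 12)) {
      # independent route: assemble from pi_k, p_k and the two expectations
      pi_k <- stationary_distribution(n, r)
      p <- switch_probability(n, r, 0:n)
      att <- sum(pi_k[1:n] * r * p[1:n] * (n - 0:(n - 1)) *
                   attach_expectation(1:n, default_nu))
      det <- sum(pi_k[3:(n + 1)] * p[3:(n + 1)] *
                   detach_sum_expectation(2:n, default_nu))
      expect_equal(amsd(n, r, default_nu), att + det)
    }
  }
  # n = 2, r -> 0 collapses to the single-FA value
  expect_equal(exact_msd_small_n(2, 1e-12, default_nu), 50 / 3,
               tolerance = 1e-9)
})

test_that("sequential path probability has its exact values and r-limits", {
  expect_equal(sequential_path_probability(5, 1, 1), 1 / 160)
  expect_equal(sequential_path_probability(2, 1, 2), 1 / 8)
  # sequential histories are a subset of being in state k and detaching
  for (r in r_grid) for (n in c(2, 5, 9)) {
    k <- 1:n
    full <- k * stationary_distribution(n, r)[k + 1] * switch_probability(n, r, k)
    expect_true(all(sequential_path_probability(n, r, k) <= full + 1e-15))
  }
  expect_equal(sequential_path_probability(7, 1e-9, 1), 0.5, tolerance = 1e-6)
  expect_lt(max(sequential_path_probability(7, 1e-9, 2:7)), 1e-6)
  expect_lt(max(sequential_path_probability(7, 1e9, 1:7)), 1e-6)
})

test_that("lower bound reduces to the attach part and never exceeds the AMSD", {
  expect_equal(lower_bound_msd(2, 1, default_nu), 275 / 24)
  for (r in r_grid) expect_equal(lower_bound_msd(1, r, default_nu), 50 / 3)
  for (r in r_grid) for (n in 2:12)
    expect_lte(lower_bound_msd(n, r, default_nu), amsd(n, r, default_nu))
})

test_that("the quadratic lag law reduces to AMSD at tau = 1", {
  for (n in c(1, 2, 5)) for (r in c(0.5, 1, 10))
    expect_equal(msd_of_tau(n, r, default_nu, 1), amsd(n, r, default_nu))
  m2 <- sum((45 / (8 * pi))^2)
  expect_equal(msd_of_tau(2, 1, default_nu, 2), 2 * 12.5 + 2 * m2)
  # isotropic outreach: zero drift, linear in tau
  expect_equal(msd_of_tau(5, 1, isotropic_nu, 7),
               7 * amsd(5, 1, isotropic_nu))
})
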