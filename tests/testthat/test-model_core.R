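test_that("leading_lineage applies the margin rule and tie-breaks", {
  expect_identical(leading_lineage(c(10, 3, 2, 4, 1), alpha = 5), 1L)
  expect_identical(leading_lineage(c(5, 5, 5, 5, 5), alpha = 1), NA_integer_)
  expect_identical(leading_lineage(c(8, 6, 2, 2, 2), alpha = 3), NA_integer_)
  # alpha = 0 with an exact tie resolves to the lowest index
  expect_identical(leading_lineage(c(7, 7, 1), alpha = 0), 1L)
  expect_error(leading_lineage(5, alpha = 1), "two lineages")
  expect_error(leading_lineage(c(-1, 2), alpha = 1), "non-negative")
})

test_that("division_multipliers match the two inhibition variants", {
  p <- model_params("threshold", K_hill = 4, m_hill = 2, alpha = 3)
  # no lead: identity
  expect_equal(division_multipliers(rep(5, 5), p), rep(1, 5))
  # lead at half-saturation: non-lead factors exactly 0.5
  h <- division_multipliers(c(4, 1, 1, 1, 1), p)
  expect_equal(h, c(1, 0.5, 0.5, 0.5, 0.5))
  pm <- model_params("mutual", K_hill = 20, m_hill = 2)
  expect_equal(division_multipliers(rep(5, 5), pm), rep(0.5, 5))
  expect_error(division_multipliers(c(-1, 1), p), "non-negative")
  # bounds property across random states and both variants
  set.seed(1)
  for (k in 1:25) {
    O <- runif(5, 0, 50)
    for (pp in list(p, pm)) {
      h <- division_multipliers(O, pp)
      expect_true(all(h > 0 & h <= 1))
    }
  }
})

test_that("drift encodes equal anticlinal/periclinal split and gamma", {
  p <- model_params("threshold", r = 0.08, gamma = 0.5)
  st <- lineage_state(outer = 10, inner = 4)
  d <- drift_rates(st, multipliers = 1, p)
  expect_equal(d$dO, 0.4)
  expect_equal(d$dI, 0.56)
  # absorbing empty state
  d0 <- drift_rates(lineage_state(0, 0), 1, p)
  expect_equal(c(d0$dO, d0$dI), c(0, 0))
  dh <- drift_rates(lineage_state(2, 2), 0.5, p)
  expect_equal(c(dh$dO, dh$dI), c(0.04, 0.08))
})

test_that("em_step: noise-free limit, clamping, determinism", {
  p <- model_params("threshold", sigma = 0, n_lineages = 2, dt = 0.1)
  st <- lineage_state(c(3, 1), c(1, 0))
  s1 <- em_step(st, p, noise_draws = rep(0, 4))
  h <- division_multipliers(st$outer, p)
  d <- drift_rates(st, h, p)
  expect_equal(s1$outer, st$outer + 0.1 * d$dO)
  expect_equal(s1$inner, st$inner + 0.1 * d$dI)
  expect_equal(s1$t, 0.1)
  # clamp at zero under a large negative draw (additive coupling so the
  # noise term does not vanish with the small state)
  pa <- model_params("threshold", sigma = 1, n_lineages = 2, dt = 0.1,
                     noise_coupling = "additive")
  s2 <- em_step(lineage_state(c(0.01, 5), c(0.01, 5)), pa,
                noise_draws = c(-8, 0, -8, 0))
  expect_identical(s2$outer[1], 0)
  expect_identical(s2$inner[1], 0)
  # same inputs, same outputs
  z <- rnorm(4)
  expect_identical(em_step(st, pa, z), em_step(st, pa, z))
  expect_error(em_step(st, p, rep(0, 3)), "one value per state component")
})

test_that("compiled trajectory equals an R-level em_step loop exactly", {
  p <- model_params("threshold", sigma = 0.3, t_end = 2, dt = 0.05)
  tr <- simulate_trajectory(p, seed = 11)
  set.seed(11)
  st <- lineage_state(rep(1, p$n_lineages), rep(0, p$n_lineages))
  for (k in seq_len(round(p$t_end / p$dt))) {
    z <- c(rnorm(p$n_lineages), rnorm(p$n_lineages))
    st <- em_step(st, p, z)
    expect_equal(unname(tr$outer[k + 1, ]), st$outer, tolerance = 1e-12)
    expect_equal(unname(tr$inner[k + 1, ]), st$inner, tolerance = 1e-12)
  }
})

test_that("noise-free closed form is reproduced and converges in dt", {
  closed <- uninhibited_closed_form(model_params("threshold", r = 0.05))
  err_at <- function(dt) {
    p <- model_params("threshold", sigma = 0, K_hill = 1e12, alpha = 1e12,
                      r = 0.05, dt = dt)
    tr <- simulate_trajectory(p, seed = 1, record_every = 1000L)
    k <- nrow(tr$outer)
    c(o = abs(tr$outer[k, 1] - closed$outer) / closed$outer,
      i = abs(tr$inner[k, 1] - closed$inner) / closed$inner)
  }
  e_def <- err_at(0.05)
  e_half <- err_at(0.025)
  e_tenth <- err_at(0.005)
  # first-order scheme: error halves with dt and is ~10x smaller at dt/10
  expect_lt(e_half["o"], 0.6 * e_def["o"])
  expect_lt(e_tenth["o"], 0.15 * e_def["o"])
  expect_lt(e_tenth["i"], 0.15 * e_def["i"])
  # at dt = 0.005 both components are within 0.1% of the closed form
  expect_lt(max(e_tenth), 1e-3)
  # documented magnitude of the default-step Euler error (~n h^2 / 2)
  expect_equal(unname(e_def["o"]), 0.00187, tolerance = 0.05)
})

test_that("step-size robustness and symmetry of noise-free trajectories", {
  p1 <- model_params("threshold", sigma = 0, dt = 0.02)
  p2 <- model_params("threshold", sigma = 0, dt = 0.01)
  f1 <- final_totals(simulate_trajectory(p1, 1, record_every = 6000L))
  f2 <- final_totals(simulate_trajectory(p2, 1, record_every = 12000L))
  expect_lt(max(abs(f1 - f2) / f1), 1e-3)
  # all five lineages identical at all times when sigma = 0
  tr <- simulate_trajectory(model_params("mutual", sigma = 0), 3,
                            record_every = 20L)
  expect_true(all(abs(tr$outer - tr$outer[, 1]) < 1e-12))
  expect_true(all(abs(tr$inner - tr$inner[, 1]) < 1e-12))
})

test_that("trajectories are non-negative, seeded and well-formed", {
  p <- model_params("threshold")
  tr <- simulate_trajectory(p, seed = 5, record_every = 20L)
  expect_true(all(tr$outer >= 0) && all(tr$inner >= 0))
  expect_true(all(diff(tr$times) > 0))
  tr2 <- simulate_trajectory(p, seed = 5, record_every = 20L)
  expect_identical(tr$outer, tr2$outer)
  df <- as.data.frame(tr)
  expect_identical(names(df), c("time_h", "lineage", "outer", "inner"))
  expect_identical(nrow(df), length(tr$times) * p$n_lineages)
})

test_that("model_params validates inputs and loads variant defaults", {
  expect_error(model_params("threshold", r = -1), "r must be")
  expect_error(model_params("threshold", gamma = 0), "gamma")
  expect_error(model_params("threshold", dt = 0.05, t_end = 0.01), "t_end")
  expect_error(model_params("nope"), "arg")
  pt <- model_params("threshold")
  pm <- model_params("mutual")
  expect_false(pt$K_hill == pm$K_hill)
  expect_identical(pt$gamma, 0.5)
  expect_equal(pt$t_end, 120)
})
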