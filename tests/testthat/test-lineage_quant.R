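test_that("cells_per_lineage counts forced cases and rejects unknown ids", {
  expect_equal(unname(cells_per_lineage(tiny_static_table())[1, ]),
               c(1L, 1L, 1L))
  expect_equal(unname(cells_per_lineage(tiny_division_table())[1, ]),
               c(1L, 2L, 3L))
  expect_error(cells_per_lineage(tiny_static_table(), "L9"),
               "unknown lineage")
})

test_that("division_events classifies orientations from daughter layers", {
  ev <- division_events(tiny_division_table())
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$orientation[ev$parent_id == "a"], "anticlinal")
  expect_identical(ev$orientation[ev$parent_id == "b"], "periclinal")
  expect_equal(ev$t_end - ev$t_start, rep(6, 2))
  expect_identical(nrow(division_events(tiny_static_table())), 0L)
})

test_that("divisions_per_window labels parents and enforces alignment", {
  tab <- tiny_division_table()
  lab <- divisions_per_window(tab, window_h = 6)
  w1 <- lab[lab$window_start == 0, ]
  expect_true(w1$divided[w1$nucleus_id == "a"])
  expect_false(any(w1$divided[w1$nucleus_id != "a"]))
  w2 <- lab[lab$window_start == 6, ]
  expect_true(w2$divided[w2$nucleus_id == "b"])
  expect_false(any(w2$divided[w2$nucleus_id != "b"]))
  # no divisions: everything undivided
  expect_false(any(divisions_per_window(tiny_static_table(), 6)$divided))
  expect_error(divisions_per_window(tab, 7), "multiple")
})

test_that("progeny_division_totals counts subtree events", {
  expect_equal(unname(progeny_division_totals(tiny_static_table(), 0, 12)),
               0L)
  # root a divides once, daughter b once: 2 events in a's subtree
  tot <- progeny_division_totals(tiny_division_table(), 0, 12)
  expect_equal(unname(tot["a"]), 2L)
  # from t = 6, roots b and c: only b's division counts
  tot6 <- progeny_division_totals(tiny_division_table(), 6, 6)
  expect_equal(unname(tot6[c("b", "c")]), c(1L, 0L))
  expect_error(progeny_division_totals(tiny_division_table(), 0,
                                       roots = "zz"), "not present")
})

test_that("quantification equals the generator ground truth exactly", {
  gen <- generate_lineage_table(synth_config(seed = 12))
  tab <- gen$table
  truth <- gen$truth
  expect_identical(unname(cells_per_lineage(tab)[rownames(truth$counts), ]),
                   unname(truth$counts))
  # monotone lineage growth
  expect_true(all(apply(cells_per_lineage(tab), 1,
                        function(v) all(diff(v) >= 0))))
  # event ledger matches, window by window
  ev <- division_events(tab)
  expect_identical(nrow(ev), nrow(truth$events))
  expect_identical(c(table(ev$t_end)), c(table(truth$events$t_end)))
  expect_identical(sort(ev$parent_id), sort(truth$events$parent_id))
  expect_identical(c(table(ev$orientation)),
                   c(table(truth$events$orientation)))
  # per-root progeny totals over the generator's Phase II window
  pr <- truth$progeny
  tot <- progeny_division_totals(tab, pr$start_t, pr$duration)
  expect_identical(unname(tot[names(pr$totals)]), unname(pr$totals))
  # window additivity: 6 h divided counts sum to the 12 h counts
  d6 <- divisions_per_window(tab, 6)
  d12 <- divisions_per_window(tab, 12)
  s6 <- tapply(d6$divided, floor(d6$window_start / 12), sum)
  s12 <- tapply(d12$divided, d12$window_start / 12, sum)
  expect_equal(unname(s6), unname(s12))
})

test_that("welch_t_test matches its closed forms and stats::t.test", {
  w <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4)
  expect_equal(w$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(round(w$p_value, 4), 0.0213)
  # zero-variance second group: t = 3, Welch df = 1
  w2 <- welch_t_test(c(2, 3), c(1, 1))
  expect_equal(w2$t, 3)
  expect_equal(w2$df, 1)
  expect_equal(w2$p_value, 0.2048, tolerance = 1e-3)
  # identical groups
  w3 <- welch_t_test(c(2, 4), c(4, 2))
  expect_equal(w3$t, 0)
  expect_equal(w3$p_value, 1)
  # independent oracle on random data
  set.seed(8)
  for (k in 1:5) {
    a <- rnorm(7, 1)
    b <- rnorm(11)
    w <- welch_t_test(a, b)
    ref <- t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "degenerate")
  expect_error(welch_t_test(1, c(2, 3)), "at least two")
})

test_that("compare_layer_divisions reports the Welch comparison", {
  cmp <- compare_layer_divisions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$mean_outer, 2)
  expect_equal(cmp$mean_inner, 5)
  expect_equal(cmp$t, -3.674, tolerance = 1e-3)
})

test_that("orientation_summary tests marginal events against 0.5", {
  mk_tab <- function(n_anti, n_peri) {
    founders <- data.frame(
      nucleus_id = sprintf("f%02d", seq_len(n_anti + n_peri)), time_h = 0,
      x_px = seq_len(n_anti + n_peri) * 10, y_px = 5, lineage_id = "L1",
      layer = "outer", is_antheridium = FALSE, parent_id = NA_character_)
    dl <- c(rep("outer", 2 * n_anti),
            rep(c("outer", "inner"), n_peri))
    daughters <- data.frame(
      nucleus_id = sprintf("d%02d", seq_len(2 * (n_anti + n_peri))),
      time_h = 6, x_px = seq_len(2 * (n_anti + n_peri)) * 5, y_px = 5,
      lineage_id = "L1", layer = dl, is_antheridium = FALSE,
      parent_id = rep(founders$nucleus_id, each = 2))
    lineage_table(rbind(founders, daughters), interval = 6)
  }
  o <- orientation_summary(mk_tab(3, 3))
  expect_identical(c(o$n_anticlinal, o$n_periclinal), c(3L, 3L))
  expect_equal(o$p_binomial, 1)
  o2 <- orientation_summary(mk_tab(5, 0))
  expect_equal(o2$p_binomial, 2 * 0.5^5)
  expect_error(orientation_summary(tiny_static_table()), "degenerate")
})

test_that("antheridium records are excluded from every statistic", {
  rec <- rbind(
    data.frame(nucleus_id = c("a", "ant"), time_h = 0, x_px = c(5, 20),
               y_px = 5, lineage_id = c("L1", "A1"), layer = "outer",
               is_antheridium = c(FALSE, TRUE), parent_id = NA_character_),
    data.frame(nucleus_id = c("a", "ant"), time_h = 6, x_px = c(5, 20),
               y_px = 5, lineage_id = c("L1", "A1"), layer = "outer",
               is_antheridium = c(FALSE, TRUE), parent_id = NA_character_))
  tab <- lineage_table(rec, interval = 6)
  expect_identical(rownames(cells_per_lineage(tab)), "L1")
  expect_false("ant" %in% divisions_per_window(tab, 6)$nucleus_id)
  expect_false("ant" %in% names(progeny_division_totals(tab, 0, 6)))
})
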