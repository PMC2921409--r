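# KMC loop: waiting times, rule selection, reactant selection,
# observables, determinism, degenerate cases

test_that("waiting times follow the closed form", {
  expect_equal(sample_tau(2, exp(-2)), 1)
  expect_lt(sample_tau(5, 1 - 1e-12), 1e-11)   # u -> 1-  gives tau -> 0+
  expect_error(sample_tau(0, 0.5), "positive")
  expect_error(sample_tau(-1, 0.5), "positive")
})

test_that("rule selection is the smallest index reaching the cumulative target", {
  expect_equal(select_rule(c(1, 3), 0.5), 2L)    # cumulative 0.25 < 0.5
  expect_equal(select_rule(c(1, 3), 0.2), 1L)
  for (u in c(0.01, 0.5, 0.99))
    expect_equal(select_rule(c(0, 7, 0), u), 2L) # zero-rate rules never chosen
  expect_error(select_rule(c(0, 0), 0.5), "zero")
})

test_that("observable match numbers follow Molecules/Species semantics", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(a)", "end molecule types",
    "begin species", "A(a) 3", "A(a!1).A(a!1) 1", "end species",
    "begin reaction rules", "dim: A(a) + A(a) -> A(a!1).A(a!1) 1",
    "end reaction rules",
    "begin observables",
    "Molecules Atot A()", "Species Asp A()", "Species Dim A(a!1).A(a!1)",
    "end observables"))
  st <- init_state(mdl)
  expect_equal(eval_observable(st, 1L), 5)   # 3 monomers + 2 in the dimer
  expect_equal(eval_observable(st, 2L), 4)   # 4 species instances
  expect_equal(eval_observable(st, 3L), 1)
})

test_that("trajectories are reproducible bit for bit under a fixed seed", {
  mdl <- make_tlbr(N_L = 12L, N_R = 8L, k_plus1 = 0.01, k_plus2 = 0.001,
                   k_off = 1)
  a <- simulate_nf(mdl, t_end = 3, n_report = 6, seed = 17L)
  b <- simulate_nf(mdl, t_end = 3, n_report = 6, seed = 17L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "event_count"), attr(b, "event_count"))
  c2 <- simulate_nf(mdl, t_end = 3, n_report = 6, seed = 18L)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("an absorbing initial state yields a flat trajectory at t_end", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "X(y~0~1)", "end molecule types",
    "begin species", "X(y~1) 5", "end species",
    "begin reaction rules", "decay: X(y~0) -> X(y~1) 1",
    "end reaction rules",
    "begin observables", "Molecules X1 X(y~1)", "end observables"))
  tr <- simulate_nf(mdl, t_end = 4, n_report = 4, seed = 1)
  expect_equal(tr$X1, rep(5, 5))
  expect_identical(attr(tr, "event_count"), 0L)
})

test_that("max_events truncates with a warning and freezes remaining reports", {
  mdl <- decay_model(k = 1, n0 = 40L)
  expect_warning(
    tr <- simulate_nf(mdl, t_end = 50, n_report = 10, seed = 2,
                      max_events = 5L),
    "max_events")
  expect_true(attr(tr, "truncated"))
  expect_identical(attr(tr, "event_count"), 5L)
  expect_equal(tr$X0[11L], 35)
})

test_that("reactant instances are drawn proportionally to center counts", {
  # two species: one with 1 eligible center, one with 2
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "X2(y~0~1,y~0~1)", "end molecule types",
    "begin species", "X2(y~0,y~1) 1", "X2(y~0,y~0) 1", "end species",
    "begin reaction rules", "r: X2(y~0) -> X2(y~1) 1",
    "end reaction rules",
    "begin observables", "Molecules X0 X2(y~0)", "end observables"))
  sim <- nf_init(mdl)
  set.seed(99)
  n <- 4000L
  picks <- vapply(seq_len(n), function(q)
    rulekmc:::select_reactants(sim$st, sim$act, 1L)$uid, 0L)
  p1 <- mean(picks == 1L)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(p1 - 1 / 3), 3 * se)
})

test_that("single eligible center means deterministic selection", {
  mdl <- decay_model(k = 1, n0 = 1L)
  sim <- nf_init(mdl)
  set.seed(1)
  sel <- rulekmc:::select_reactants(sim$st, sim$act, 1L)
  expect_identical(sel$uid, 1L)
  expect_identical(unname(sel$center), c(1L, 1L))
})

test_that("event counts equal steps (rejection-free) on a short run", {
  mdl <- make_stiff(phi = 50, n0 = 200L, k = 1)
  sim <- nf_init(mdl)
  for (q in 1:100) expect_false(is.na(nf_step(sim)))
  expect_identical(sim$st$events, 100L)
})
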