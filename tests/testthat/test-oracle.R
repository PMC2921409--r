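# Generate-first oracle: network closure, direct SSA, ODE integration

test_that("network closure reproduces hand-derived small networks", {
  # irreversible decay: 2 species, 1 reaction
  net <- generate_network(decay_model(n0 = 5L), max_species = 10L)
  expect_length(net$species, 2L)
  expect_length(net$reactions, 1L)
  # 2-site phosphorylation: 4 phosphoforms, 8 unidirectional reactions
  net2 <- generate_network(make_multisite_phos(n_sites = 2L,
                                               n_substrate = 3L),
                           max_species = 10L)
  expect_length(net2$species, 4L)
  expect_length(net2$reactions, 8L)
  expect_equal(sum(net2$init), 3)
  # dimerization: c embeds the 1/2 symmetry factor
  net3 <- generate_network(make_dimerization(k_plus = 1, k_minus = 2,
                                             n0 = 4L), max_species = 5L)
  cdim <- vapply(net3$reactions, `[[`, 0, "c")
  expect_setequal(cdim, c(1, 2))
})

test_that("TLBR closure exceeds any small species guard", {
  tl <- make_tlbr(N_L = 50L, N_R = 30L, k_plus1 = 0.005, k_plus2 = 5e-5,
                  k_off = 1)
  expect_error(generate_network(tl, max_species = 40L),
               "network too large")
})

test_that("network closure is order-independent", {
  rules <- c("dim: A(a) + A(a) -> A(a!1).A(a!1) 1",
             "undim: A(a!1).A(a!1) -> A(a) + A(a) 2",
             "flip: X(y~0) -> X(y~1) 3")
  mk <- function(rr) parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(a)", "X(y~0~1)", "end molecule types",
    "begin species", "A(a) 3", "X(y~0) 2", "end species",
    "begin reaction rules", rr, "end reaction rules",
    "begin observables", "end observables"))
  n1 <- generate_network(mk(rules), max_species = 20L)
  n2 <- generate_network(mk(rev(rules)), max_species = 20L)
  expect_setequal(n1$species, n2$species)
  expect_setequal(network_to_text(n1), network_to_text(n2))
})

test_that("direct SSA reproduces the analytic decay law", {
  k <- 0.7; n0 <- 40L
  net <- generate_network(decay_model(k = k, n0 = n0), max_species = 5L)
  nrun <- 300L
  set.seed(314)
  tt <- c(0, 0.5, 1, 2)
  runs <- vapply(seq_len(nrun), function(q)
    simulate_ssa_network(net, t_end = 2, report_times = tt)$X0,
    numeric(4L))
  mn <- rowMeans(runs)
  sem <- sqrt(apply(runs, 1L, var) / nrun)
  expected <- n0 * exp(-k * tt)
  expect_true(all(abs(mn - expected) <= 3 * pmax(sem, 1e-9)))
  # zero propensity everywhere -> flat
  flat <- simulate_ssa_network(net, t_end = 2, report_times = tt,
                               init = c(0, n0))
  expect_equal(flat$X0, rep(0, 4L))
  expect_equal(flat$X1, rep(n0, 4L))
})

test_that("ODE integration matches closed forms and conserves totals", {
  k <- 0.7; n0 <- 40L
  net <- generate_network(decay_model(k = k, n0 = n0), max_species = 5L)
  tt <- seq(0, 3, length.out = 7L)
  ode <- integrate_ode_network(net, t_end = 3, report_times = tt)
  expect_equal(ode$X0, n0 * exp(-k * tt), tolerance = 1e-6)
  expect_equal(ode$X0 + ode$X1, rep(n0, 7L), tolerance = 1e-8)
  # reversible dimerization steady state satisfies detailed balance:
  # k_plus * x_A^2 / 2 == k_minus * x_D
  dm <- make_dimerization(k_plus = 0.05, k_minus = 1, n0 = 50L)
  netd <- generate_network(dm, max_species = 5L)
  oded <- integrate_ode_network(netd, t_end = 200,
                                report_times = c(0, 200))
  # recover species populations from the observables (Amono counts free
  # monomer species, Dimer counts dimer species)
  xA <- oded$Amono[2L]; xD <- oded$Dimer[2L]
  expect_equal(0.05 * xA^2 / 2, 1 * xD, tolerance = 1e-5)
  expect_equal(xA + 2 * xD, 50, tolerance = 1e-8)
})

test_that("SSA equilibrium means agree with the ODE fixed point (linear system)", {
  pm <- make_multisite_phos(n_sites = 1L, n_substrate = 30L, k_p = 2,
                            k_d = 1)
  net <- generate_network(pm, max_species = 4L)
  tt <- c(0, 5, 10)
  nrun <- 200L
  set.seed(2718)
  runs <- vapply(seq_len(nrun), function(q)
    simulate_ssa_network(net, t_end = 10, report_times = tt)$P_s1,
    numeric(3L))
  mn <- rowMeans(runs)
  sem <- sqrt(apply(runs, 1L, var) / nrun)
  ode <- integrate_ode_network(net, t_end = 10, report_times = tt)
  expect_true(all(abs(mn - ode$P_s1) <= 3 * pmax(sem, 1e-9)))
})

test_that("brute-force rate enumeration handles trivial cases", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(b)", "B(a)", "end molecule types",
    "begin species", "A(b) 2", "B(a) 3", "end species",
    "begin reaction rules",
    "bind: A(b) + B(a) -> A(b!1).B(a!1) 0.1",
    "other: B(a) + B(a) -> B(a!1).B(a!1) 1",
    "end reaction rules", "begin observables", "end observables"))
  st <- init_state(mdl)
  expect_equal(brute_force_rule_rate(mdl$rules[[1L]], st), 0.6)
  # no matches -> 0: bond both A monomers to each other so no free A(b)
  st$bmol[1L, 1L] <- 2L; st$bcomp[1L, 1L] <- 1L
  st$bmol[2L, 1L] <- 1L; st$bcomp[2L, 1L] <- 1L
  for (u in state_uids(st)) st$sp_mols[u] <- list(NULL)
  split_into_species(st, seq_len(st$n_mol))
  expect_equal(brute_force_rule_rate(mdl$rules[[1L]], st), 0)
})
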