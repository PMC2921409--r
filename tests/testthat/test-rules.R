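# Rule classification, the five class-specific rate formulas (pinned by
# hand enumeration and the brute-force oracle), graph rewriting and
# incremental activity maintenance

test_that("rules are classified into the five supported classes", {
  mdl <- parse_model(c(
    "begin parameters", "k 1", "end parameters",
    "begin molecule types", "X(y~0~1)", "A(b)", "B(a)", "P(sh3,pro)",
    "D(a,b)", "end molecule types",
    "begin species", "X(y~0) 1", "A(b) 1", "B(a) 1", "P(sh3,pro) 1",
    "D(a,b) 1", "end species",
    "begin reaction rules",
    "X(y~0) -> X(y~1) k",
    "A(b!1).B(a!1) -> A(b) + B(a) k",
    "A(b!1).B(a!1) -> A(b).B(a) k",
    "A(b) + B(a) -> A(b!1).B(a!1) k",
    "P(sh3,pro) -> P(sh3!1,pro!1) k",
    "D(a).D(b) -> D(a!1).D(b!1) k",
    "end reaction rules",
    "begin observables", "end observables"))
  expect_equal(vapply(mdl$rules, rule_class, ""),
               c("STATE_CHANGE", "DISSOCIATION", "DISSOCIATION",
                 "ASSOCIATION", "RING_MONO", "RING_NONMONO"))
  expect_equal(c(mdl$rules[[2L]]$nprod, mdl$rules[[3L]]$nprod), c(2L, 1L))
  # a rule doing two things at once is unsupported
  expect_error(parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "X(y~0~1,z~0~1)", "end molecule types",
    "begin species", "X(y~0,z~0) 1", "end species",
    "begin reaction rules", "X(y~0,z~0) -> X(y~1,z~1) 1",
    "end reaction rules", "begin observables", "end observables")),
    "unsupported rule")
})

test_that("state-change rates count distinct centers", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "X(y~0~1)", "X2(y~0~1,y~0~1)",
    "end molecule types",
    "begin species", "X(y~0) 3", "X2(y~0,y~0) 1", "end species",
    "begin reaction rules",
    "r1: X(y~0) -> X(y~1) 2",
    "r2: X2(y~0) -> X2(y~1) 1",
    "end reaction rules", "begin observables", "end observables"))
  st <- init_state(mdl)
  expect_equal(rate_state_change(mdl$rules[[1L]], st), 6)   # 3 centers * k=2
  expect_equal(rate_state_change(mdl$rules[[2L]], st), 2)   # 2 centers in one species
  # no instance matched -> 0
  st$cstate[seq_len(3L), 1L] <- 2L   # flip all X to y~1
  expect_equal(rate_state_change(mdl$rules[[1L]], st), 0)
})

test_that("dissociation rates respect the product-count application condition", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(b)", "B(a)", "Q(a,b)", "end molecule types",
    "begin species", "A(b!1).B(a!1) 5",
    "Q(a!1,b!3).Q(a!3,b!2).Q(a!2,b!1) 1", "end species",
    "begin reaction rules",
    "cutAB: A(b!1).B(a!1) -> A(b) + B(a) 1",
    "cutQ2: Q(a!1).Q(b!1) -> Q(a) + Q(b) 1",
    "openQ: Q(a!1).Q(b!1) -> Q(a).Q(b) 1",
    "end reaction rules", "begin observables", "end observables"))
  st <- init_state(mdl)
  expect_equal(rate_dissociation(mdl$rules[[1L]], st), 5)
  # every bond of the cyclic trimer leaves one connected product
  expect_equal(rate_dissociation(mdl$rules[[2L]], st), 0)
  expect_equal(rate_dissociation(mdl$rules[[3L]], st), 3)
})

test_that("association rates enforce molecularity 2 with the over-counting correction", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(b)", "B(a)", "end molecule types",
    "begin species", "A(b) 2", "B(a) 3", "end species",
    "begin reaction rules",
    "bind: A(b) + B(a) -> A(b!1).B(a!1) 0.1",
    "end reaction rules", "begin observables", "end observables"))
  st <- init_state(mdl)
  expect_equal(rate_association(mdl$rules[[1L]], st), 0.6)  # 6 pairs * 0.1
  # single chain matched by both patterns, no other instance -> 0
  mdl2 <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(b)", "B(a,x)", "end molecule types",
    "begin species", "B(a,x!1).B(a!1,x) 1", "end species",
    "begin reaction rules",
    "bind: B(a) + B(x) -> B(a!1).B(x!1) 1",
    "end reaction rules", "begin observables", "end observables"))
  st2 <- init_state(mdl2)
  expect_equal(rate_association(mdl2$rules[[1L]], st2), 0)
  # symmetric A+A on 4 monomers: k * n(n-1)/2 = 6
  mdl3 <- make_dimerization(k_plus = 1, k_minus = 1, n0 = 4L)
  expect_equal(rate_association(mdl3$rules[[1L]], init_state(mdl3)), 6)
  expect_equal(mdl3$rules[[1L]]$f, 0.5)
})

test_that("ring-closure rates distinguish monogamous and non-monogamous cases", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "P(sh3,pro)", "P2(sh3,pro,x)", "D(a,b)",
    "end molecule types",
    "begin species", "P(sh3,pro) 4", "P2(sh3,pro,x!1).P2(sh3,pro,x!1) 1",
    "D(a,b!1).D(a!1,b) 2", "D(a,b) 1",
    "end species",
    "begin reaction rules",
    "rm: P(sh3,pro) -> P(sh3!1,pro!1) 1",
    "rm2: P2(sh3,pro) -> P2(sh3!1,pro!1) 1",
    "rn: D(a).D(b) -> D(a!1).D(b!1) 2",
    "end reaction rules", "begin observables", "end observables"))
  st <- init_state(mdl)
  expect_equal(rate_ring_mono(mdl$rules[[1L]], st), 4)   # one pair per monomer
  expect_equal(rate_ring_mono(mdl$rules[[2L]], st), 2)   # both linked molecules eligible
  # two open dimers, one closing pair each, k=2 -> 4; the free D(a,b)
  # monomer contributes 0 (centers must sit in different molecules)
  expect_equal(rate_ring_nonmono(mdl$rules[[3L]], st), 4)
  # molecule with sh3 already bound contributes 0
  st2 <- init_state(mdl)
  st2$bmol[1L, 1L] <- 1L; st2$bcomp[1L, 1L] <- 2L  # close a ring on monomer 1
  st2$bmol[1L, 2L] <- 1L; st2$bcomp[1L, 2L] <- 1L
  expect_equal(rate_ring_mono(mdl$rules[[1L]], st2), 3)
})

test_that("engine rates match the brute-force oracle on randomized states", {
  set.seed(20240917)
  for (cls in names(CLASS_RULES)) {
    for (rep in 1:20) {
      st <- random_state(CLASS_RULES[[cls]])
      for (rule in st$model$rules) {
        expect_equal(rule_rate(rule, st), brute_force_rule_rate(rule, st),
                     tolerance = 0,
                     info = paste(cls, rule$name, "rep", rep))
      }
    }
  }
})

test_that("graph rewrites conserve molecules and keep bookkeeping consistent", {
  set.seed(11)
  mdl <- ring_model(n_extra_chains = 6L)
  sim <- nf_init(mdl)
  st <- sim$st
  n0 <- type_counts(st)
  for (ev in 1:150) {
    expect_false(is.na(nf_step(sim)))
    # incremental r_i equals de-novo recomputation at every event
    r_inc <- rulekmc:::rule_rates(sim$act)
    r_dn <- vapply(mdl$rules, rule_rate, 0, st = st)
    expect_equal(r_inc, r_dn, tolerance = 1e-12)
  }
  expect_identical(type_counts(st), n0)
  # bonds remain mutual
  for (m in seq_len(st$n_mol)) {
    for (j in which(st$bmol[m, ] > 0L)) {
      w <- st$bmol[m, j]; p <- st$bcomp[m, j]
      expect_identical(st$bmol[w, p], m)
      expect_identical(st$bcomp[w, p], j)
    }
  }
})

test_that("association events join two distinct instances into one", {
  mdl <- make_dimerization(k_plus = 1, k_minus = 0, n0 = 2L)
  set.seed(5)
  sim <- nf_init(mdl)
  nf_step(sim)
  st <- sim$st
  uids <- state_uids(st)
  expect_length(uids, 1L)
  expect_setequal(st$sp_mols[[uids]], 1:2)   # original molecule uids kept
  expect_equal(species_to_string(st, uids), "A(a!1).A(a!1)")
  # absorbing now that k_minus = 0
  expect_true(is.na(nf_step(sim)))
})

test_that("two-product dissociation of a chain partitions its molecules", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "Q(a,b)", "end molecule types",
    "begin species", "Q(a,b!1).Q(a!1,b!2).Q(a!2,b) 1", "end species",
    "begin reaction rules", "cut: Q(a!1).Q(b!1) -> Q(a) + Q(b) 1",
    "end reaction rules", "begin observables", "end observables"))
  set.seed(3)
  sim <- nf_init(mdl)
  nf_step(sim)
  st <- sim$st
  uids <- state_uids(st)
  expect_length(uids, 2L)
  expect_setequal(unlist(st$sp_mols[uids]), 1:3)
})
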