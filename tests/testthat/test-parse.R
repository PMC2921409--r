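# BNGL-subset parsing, reversible expansion, validation errors, rendering

test_that("an association rule is parsed with its resolved rate constant", {
  mdl <- parse_model(c(
    "begin parameters", "kon 0.1", "end parameters",
    "begin molecule types", "A(b)", "B(a)", "end molecule types",
    "begin species", "A(b) 2", "B(a) 3", "end species",
    "begin reaction rules", "A(b) + B(a) -> A(b!1).B(a!1) kon",
    "end reaction rules",
    "begin observables", "Molecules Afree A(b)", "end observables"))
  expect_length(mdl$rules, 1L)
  r <- mdl$rules[[1L]]
  expect_equal(rule_class(r), "ASSOCIATION")
  expect_equal(r$k, 0.1)
  expect_equal(r$f, 1)
})

test_that("reversible rules expand to forward and reverse unidirectional rules", {
  mdl <- parse_model(c(
    "begin parameters", "kp 2", "km 0.5", "end parameters",
    "begin molecule types", "R(y~0~1)", "end molecule types",
    "begin species", "R(y~0) 5", "end species",
    "begin reaction rules", "flip: R(y~0) <-> R(y~1) kp, km",
    "end reaction rules",
    "begin observables", "Molecules on R(y~1)", "end observables"))
  expect_length(mdl$rules, 2L)
  expect_equal(vapply(mdl$rules, `[[`, 0, "k"), c(2, 0.5))
  expect_equal(vapply(mdl$rules, rule_class, ""),
               rep("STATE_CHANGE", 2L))
  # forward rule phosphorylates, reverse rule reverts
  expect_equal(mdl$rules[[1L]]$new_state, "1")
  expect_equal(mdl$rules[[2L]]$new_state, "0")
  # pass-through and identity behaviour of the expander itself
  expect_identical(expand_reversible(list()), list())
  one <- list(list(reversible = FALSE, k = 1, lhs = 1, rhs = 2))
  expect_identical(expand_reversible(one), one)
})

test_that("validation rejects malformed or undeclared constructs by name", {
  base <- function(rules = "X(y~0) -> X(y~1) 1", species = "X(y~0) 1",
                   types = "X(y~0~1)", blocks = NULL) {
    c("begin parameters", "end parameters",
      "begin molecule types", types, "end molecule types",
      "begin species", species, "end species",
      "begin reaction rules", rules, "end reaction rules",
      "begin observables", "end observables", blocks)
  }
  expect_error(parse_model(base(species = "X(y~2) 1")), "~2")
  expect_error(parse_model(base(rules = "Z(y~0) -> Z(y~1) 1")), "'Z'")
  expect_error(parse_model(base(rules = "X(q~0) -> X(q~1) 1")), "'q'")
  expect_error(parse_model(base(species = "X(y~0!1) 1")), "dangling bond")
  expect_error(parse_model(c("begin foobar", "end foobar")), "'foobar'")
  expect_error(parse_model(base(species = "X(y~0) -3")), "nonnegative")
  expect_error(parse_model(base(species = "X(y~0) 1.5")), "nonnegative")
  # reversible form with one rate / irreversible with two
  expect_error(parse_model(base(rules = "X(y~0) <-> X(y~1) 1")),
               "two rates")
  expect_error(parse_model(base(rules = "X(y~0) -> X(y~1) 1, 2")),
               "one rate")
  # RHS inconsistent with LHS
  expect_error(parse_model(base(rules = "X(y~0) -> X(y~1).X(y~1) 1")),
               "molecule counts")
})

test_that("parameter arithmetic supports + - * / and parentheses only", {
  mdl <- parse_model(c(
    "begin parameters", "a 2", "b (a+1)*3/2 - 1", "end parameters",
    "begin molecule types", "X(y~0~1)", "end molecule types",
    "begin species", "X(y~0) 4", "end species",
    "begin reaction rules", "X(y~0) -> X(y~1) b", "end reaction rules",
    "begin observables", "end observables"))
  expect_equal(mdl$rules[[1L]]$k, 3.5)
  expect_error(parse_model(c("begin parameters", "a exp(1)",
                             "end parameters")), "not allowed")
  expect_error(parse_model(c("begin parameters", "a nope+1",
                             "end parameters")), "unknown parameter")
})

test_that("rendered models re-parse to the same model (round trip)", {
  for (mdl in list(make_dimerization(n0 = 7L),
                   make_multisite_phos(n_sites = 3L, n_substrate = 4L),
                   make_tlbr(N_L = 5L, N_R = 3L, beta = 0.5),
                   make_stiff(phi = 100, n0 = 9L))) {
    txt1 <- model_to_bngl(mdl)
    mdl2 <- parse_model(txt1)
    expect_identical(model_to_bngl(mdl2), txt1)
    # parsing is deterministic
    expect_identical(model_to_bngl(parse_model(txt1)), txt1)
  }
})

test_that("simulate actions are read and unknown actions only warn", {
  txt <- c("begin parameters", "end parameters",
           "begin molecule types", "X(y~0~1)", "end molecule types",
           "begin species", "X(y~0) 1", "end species",
           "begin reaction rules", "X(y~0) -> X(y~1) 1",
           "end reaction rules",
           "begin observables", "end observables",
           "generate_network({overwrite=>1})",
           "simulate_rm({t_end=>12.5,n_steps=>25,seed=>99})")
  expect_warning(mdl <- parse_model(txt), "generate_network")
  expect_equal(mdl$actions$t_end, 12.5)
  expect_equal(mdl$actions$n_report, 25L)
  expect_equal(mdl$actions$seed, 99L)
})
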