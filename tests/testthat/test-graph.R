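# Site-graph matching, reaction-center counting, connectivity, species
# identity

dimer_model <- parse_model(c(
  "begin parameters", "end parameters",
  "begin molecule types", "A(a)", "L(s,s,s)", "R(s,s)",
  "end molecule types",
  "begin species", "A(a) 1", "A(a!1).A(a!1) 1", "R(s,s) 1",
  "L(s!1,s!2,s).R(s!1,s).R(s!2,s) 1",
  "end species",
  "begin reaction rules", "A(a) + A(a) -> A(a!1).A(a!1) 1",
  "end reaction rules",
  "begin observables", "Molecules Atot A()", "end observables"))

test_that("find_matches returns every injection", {
  st <- init_state(dimer_model)
  # uid 1: free monomer; uid 2: dimer; uid 3: free receptor;
  # uid 4: L bridging two receptors
  expect_length(find_matches(st, "A(a)", 1L), 1L)
  expect_length(find_matches(st, "A()", 2L), 2L)
  expect_length(find_matches(st, "R(s)", 3L), 2L)  # two free s slots
  expect_length(find_matches(st, "R(s)", 4L), 2L)  # one per receptor
  expect_length(find_matches(st, "A(a)", 2L), 0L)
  # symmetric permutations count as distinct injections
  expect_length(find_matches(st, "R(s,s)", 3L), 2L)
  expect_length(find_matches(st, "L(s,s,s)", 4L), 0L)
})

test_that("distinct reaction centers are fewer than matches under ambiguous context", {
  st <- init_state(dimer_model)
  # L(s,s!+) on the doubly-bound ligand: the free-s center is unique but
  # the bonded-s context can be satisfied two ways
  expect_length(find_matches(st, "L(s,s!+)", 4L), 2L)
  expect_equal(count_reaction_centers(st, "L(s,s!+)", list(c(1L, 1L)), 4L), 1L)
  # center == whole pattern: counts agree
  expect_equal(count_reaction_centers(st, "R(s)", list(c(1L, 1L)), 3L), 2L)
  expect_equal(count_reaction_centers(st, "A(a)", list(c(1L, 1L)), 2L), 0L)
})

test_that("splitting after bond deletion restores connectivity", {
  st <- init_state(ring_model(n_extra_chains = 1L))
  # uid 2 is the open chain dimer: cut its only bond -> 2 singletons
  members <- st$sp_mols[[2L]]
  m1 <- members[1L]
  j <- which(st$bmol[m1, ] > 0L)[1L]
  m2 <- st$bmol[m1, j]; p2 <- st$bcomp[m1, j]
  st$bmol[m1, j] <- 0L; st$bcomp[m1, j] <- 0L
  st$bmol[m2, p2] <- 0L; st$bcomp[m2, p2] <- 0L
  st$sp_mols[2L] <- list(NULL)
  uids <- split_into_species(st, members)
  expect_length(uids, 2L)
  # cut one bond of the triangle (uid 1): stays one connected chain
  tri <- st$sp_mols[[1L]]
  t1 <- tri[1L]
  j <- which(st$bmol[t1, ] > 0L)[1L]
  t2 <- st$bmol[t1, j]; q2 <- st$bcomp[t1, j]
  st$bmol[t1, j] <- 0L; st$bcomp[t1, j] <- 0L
  st$bmol[t2, q2] <- 0L; st$bcomp[t2, q2] <- 0L
  st$sp_mols[1L] <- list(NULL)
  uids <- split_into_species(st, tri)
  expect_length(uids, 1L)
  expect_setequal(st$sp_mols[[uids]], tri)
})

test_that("species identity ignores molecule order and slot labelling", {
  mdl <- parse_model(c(
    "begin parameters", "end parameters",
    "begin molecule types", "A(b)", "B(a)", "R(s,s)", "Q(a,b)",
    "end molecule types",
    "begin species", "A(b!1).B(a!1) 1", "B(a!1).A(b!1) 1",
    "Q(a!1,b!3).Q(a!3,b!2).Q(a!2,b!1) 1",
    "Q(a,b!1).Q(a!1,b!2).Q(a!2,b) 1",
    "end species",
    "begin reaction rules", "A(b) + B(a) -> A(b!1).B(a!1) 1",
    "end reaction rules",
    "begin observables", "end observables"))
  st <- init_state(mdl)
  expect_true(species_isomorphic(1L, 1L, st = st))
  expect_true(species_isomorphic(1L, 2L, st = st))       # label order
  expect_false(species_isomorphic(3L, 4L, st = st))      # triangle vs chain
  expect_equal(canonical_label(st, uid = 1L), canonical_label(st, uid = 2L))
  expect_false(canonical_label(st, uid = 3L) == canonical_label(st, uid = 4L))
  # bound via slot 1 vs slot 2 of R(s,s) is the same chemical species
  a <- graph_to_species(parse_graph_expr("R(s!1,s).A(b!1)"), mdl)
  b <- graph_to_species(parse_graph_expr("R(s,s!1).A(b!1)"), mdl)
  expect_true(species_isomorphic(a, b, model = mdl))
  expect_equal(canonical_label(a, mdl), canonical_label(b, mdl))
})

test_that("canonical labels agree with isomorphism on random small graphs", {
  set.seed(42)
  mdl <- mixed_model("sc1: M(y~0) -> M(y~1) k", nM = 4L, nN = 2L)
  pool <- list()
  for (rep in 1:25) {
    st <- random_rewire(init_state(mdl), sample.int(6L, 1L) - 1L)
    for (u in state_uids(st))
      pool[[length(pool) + 1L]] <- extract_species(st, st$sp_mols[[u]])
  }
  pool <- pool[vapply(pool, function(s) length(s$type), 0L) <= 6L]
  labs <- vapply(pool, canonical_label, "", model = mdl)
  # storage-order invariance: a random permutation keeps the label
  for (q in seq_along(pool)) {
    k <- length(pool[[q]]$type)
    perm <- sample.int(k)
    expect_identical(canonical_label(permute_species(pool[[q]], perm), mdl),
                     labs[q])
  }
  # pairwise: equal label <=> isomorphic (checked on a subsample)
  idx <- sample(seq_along(pool), min(15L, length(pool)))
  for (i in idx) for (j in idx) {
    iso <- species_isomorphic(pool[[i]], pool[[j]], model = mdl)
    expect_identical(iso, labs[i] == labs[j])
  }
})

test_that("matching is stable under permuted molecule storage", {
  set.seed(7)
  rules <- CLASS_RULES$ASSOCIATION
  st <- random_state(rules, nM = 8L, nN = 5L, nbonds = 5L)
  mdl <- st$model
  r1 <- vapply(mdl$rules, rule_rate, 0, st = st)
  # rebuild the same chemical state with molecules in reverse order
  st2 <- init_state(mdl)
  n <- st$n_mol
  rev_map <- rev(seq_len(n))
  st2$mol_type <- st$mol_type[rev_map]
  st2$cstate <- st$cstate[rev_map, , drop = FALSE]
  bm <- st$bmol[rev_map, , drop = FALSE]
  bm[bm > 0L] <- (n + 1L) - bm[bm > 0L]
  st2$bmol <- bm
  st2$bcomp <- st$bcomp[rev_map, , drop = FALSE]
  for (u in state_uids(st2)) st2$sp_mols[u] <- list(NULL)
  split_into_species(st2, seq_len(n))
  r2 <- vapply(mdl$rules, rule_rate, 0, st = st2)
  expect_equal(r1, r2)
})
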