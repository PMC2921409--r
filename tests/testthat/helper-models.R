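# Shared fixture builders for the test suite.  All fixtures are generated
# in code; no data files.

# irreversible one-site decay X(y~0) -> X(y~1)
decay_model <- function(k = 0.5, n0 = 50L, t_end = 10, n_report = 10L) {
  parse_model(c(
    "begin parameters", sprintf("k %.17g", k), sprintf("n0 %d", n0),
    "end parameters",
    "begin molecule types", "X(y~0~1)", "end molecule types",
    "begin species", "X(y~0) n0", "end species",
    "begin reaction rules", "decay: X(y~0) -> X(y~1) k",
    "end reaction rules",
    "begin observables", "Molecules X0 X(y~0)", "Molecules X1 X(y~1)",
    "end observables",
    sprintf("simulate_rm({t_end=>%.17g,n_steps=>%d})", t_end, n_report)))
}

# model harness for randomized engine-vs-oracle states: two molecule
# types with bindable components and a two-state residue
mixed_model <- function(rules, nM = 6L, nN = 4L) {
  parse_model(c(
    "begin parameters", "k 1", "end parameters",
    "begin molecule types", "M(a,b,y~0~1)", "N(c,d)", "end molecule types",
    "begin species",
    sprintf("M(a,b,y~0) %d", nM), sprintf("N(c,d) %d", nN),
    "end species",
    "begin reaction rules", rules, "end reaction rules",
    "begin observables", "Molecules Mtot M()", "end observables"))
}

# randomize internal states and wire `nbonds` random bonds between free
# component slots (any pair, including intra-molecular), then rebuild the
# species partition
random_rewire <- function(st, nbonds) {
  tinfo <- st$tinfo
  for (m in seq_len(st$n_mol)) {
    info <- tinfo[[st$mol_type[m]]]
    for (j in seq_len(info$ncomp))
      if (length(info$states[[j]]) > 0L)
        st$cstate[m, j] <- sample.int(length(info$states[[j]]), 1L)
  }
  valid <- matrix(FALSE, st$n_mol, st$maxc)
  for (m in seq_len(st$n_mol))
    valid[m, seq_len(tinfo[[st$mol_type[m]]]$ncomp)] <- TRUE
  for (b in seq_len(nbonds)) {
    free <- which(valid & st$bmol == 0L, arr.ind = TRUE)
    if (nrow(free) < 2L) break
    pick <- sample.int(nrow(free), 2L)
    m1 <- free[pick[1L], 1L]; p1 <- free[pick[1L], 2L]
    m2 <- free[pick[2L], 1L]; p2 <- free[pick[2L], 2L]
    st$bmol[m1, p1] <- m2; st$bcomp[m1, p1] <- p2
    st$bmol[m2, p2] <- m1; st$bcomp[m2, p2] <- p1
  }
  for (u in state_uids(st)) st$sp_mols[u] <- list(NULL)
  split_into_species(st, seq_len(st$n_mol))
  st
}

# a random small state for a given rule harness
random_state <- function(rules, nM = 6L, nN = 4L, nbonds = NULL) {
  if (is.null(nbonds)) nbonds <- sample.int(8L, 1L) - 1L
  mdl <- mixed_model(rules, nM = nM, nN = nN)
  random_rewire(init_state(mdl), nbonds)
}

# the five rule harnesses used by oracle-equivalence tests
CLASS_RULES <- list(
  STATE_CHANGE = c("sc1: M(y~0) -> M(y~1) k",
                   "sc2: M(y~0,a!+) -> M(y~1,a!+) k"),
  DISSOCIATION = c("d2: M(a!1).M(b!1) -> M(a) + M(b) k",
                   "d1: M(a!1).N(c!1) -> M(a).N(c) k"),
  ASSOCIATION  = c("asym: M(a) + N(c) -> M(a!1).N(c!1) k",
                   "sym: M(a) + M(a) -> M(a!1).M(a!1) k"),
  RING_MONO    = c("rm: M(a,b) -> M(a!1,b!1) k"),
  RING_NONMONO = c("rn: M(a).M(b) -> M(a!1).M(b!1) k",
                   "rn2: M(a).N(c) -> M(a!1).N(c!1) k"))

# triangle ring of three bivalent molecules plus ring rules
ring_model <- function(n_extra_chains = 0L) {
  seeds <- c("Q(a!1,b!3).Q(a!3,b!2).Q(a!2,b!1) 1")
  if (n_extra_chains > 0L)
    seeds <- c(seeds, sprintf("Q(a,b!1).Q(a!1,b) %d", n_extra_chains))
  parse_model(c(
    "begin parameters", "k 1", "end parameters",
    "begin molecule types", "Q(a,b)", "end molecule types",
    "begin species", seeds, "end species",
    "begin reaction rules",
    "chain: Q(a) + Q(b) -> Q(a!1).Q(b!1) k",
    "close: Q(a).Q(b) -> Q(a!1).Q(b!1) k",
    "open: Q(a!1).Q(b!1) -> Q(a).Q(b) k",
    "cut: Q(a!1).Q(b!1) -> Q(a) + Q(b) k",
    "end reaction rules",
    "begin observables", "Molecules Qtot Q()", "end observables"))
}

# permute molecule storage order of an rk_species (for invariance tests)
permute_species <- function(sp, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  bm <- sp$bm[perm, , drop = FALSE]
  bm[bm > 0L] <- inv[bm[bm > 0L]]
  structure(list(type = sp$type[perm], st = sp$st[perm, , drop = FALSE],
                 bm = bm, bc = sp$bc[perm, , drop = FALSE]),
            class = "rk_species")
}

# counts of molecules per type, for conservation checks
type_counts <- function(st) tabulate(st$mol_type, length(st$model$types))
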