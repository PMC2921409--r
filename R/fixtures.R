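# Programmatic builders for the benchmark models, emitted as BNGL-subset
# text and parsed back, so every generated model is round-tripped through
# the parser by construction.

#' Trivalent-ligand bivalent-receptor (TLBR) aggregation model
#'
#' Trivalent ligand `L(s,s,s)` and bivalent cell-surface receptor `R(s,s)`.
#' Rules: capture of a fully free ligand (association), receptor
#' crosslinking by an already-bound ligand (association between distinct
#' species instances only), and bond dissociation demanding two products.
#' There is no ring-closure rule, and the 2-product dissociation condition
#' never fires on an in-ring bond, so aggregates remain acyclic trees.
#' The dimensionless crosslinking parameter `beta = N_R * k_plus2 / k_off`
#' controls the equilibrium extent of receptor aggregation: far below the
#' percolation transition aggregates stay small, far above it a giant
#' aggregate holds most receptors.
#'
#' @param N_L,N_R Ligand and receptor copy numbers.
#' @param k_plus1 Free-ligand capture rate constant (per site pair, 1/s).
#' @param k_plus2 Crosslinking rate constant (per site pair, 1/s); either
#'   give this or `beta`.
#' @param k_off Dissociation rate constant (1/s).
#' @param beta Dimensionless crosslinking parameter; when given,
#'   `k_plus2 = beta * k_off / N_R`.
#' @param t_end,n_report Simulation action defaults written to the model.
#' @return An `rk_model`; `attr(, "params")` carries the numeric
#'   parameters including the derived `beta`.
#' @export
make_tlbr <- function(N_L = 300L, N_R = 300L, k_plus1 = 1e-3,
                      k_plus2 = NULL, k_off = 0.01, beta = NULL,
                      t_end = 100, n_report = 20L) {
  if (is.null(k_plus2)) {
    if (is.null(beta))
      stop("give either k_plus2 or beta", call. = FALSE)
    k_plus2 <- beta * k_off / N_R
  }
  beta <- N_R * k_plus2 / k_off
  txt <- c(
    "begin parameters",
    sprintf("NL %d", as.integer(N_L)),
    sprintf("NR %d", as.integer(N_R)),
    sprintf("kp1 %.17g", k_plus1),
    sprintf("kp2 %.17g", k_plus2),
    sprintf("koff %.17g", k_off),
    "end parameters",
    "begin molecule types", "L(s,s,s)", "R(s,s)", "end molecule types",
    "begin species", "L(s,s,s) NL", "R(s,s) NR", "end species",
    "begin reaction rules",
    "capture: L(s,s,s) + R(s) -> L(s!1,s,s).R(s!1) kp1",
    "crosslink: L(s,s!+) + R(s) -> L(s!1,s!+).R(s!1) kp2",
    "unbind: L(s!1).R(s!1) -> L(s) + R(s) koff",
    "end reaction rules",
    "begin observables",
    "Species FreeL L(s,s,s)",
    "Species FreeR R(s,s)",
    "Molecules Bonds R(s!+)",
    "end observables",
    sprintf("simulate_rm({t_end=>%.17g,n_steps=>%d})", t_end,
            as.integer(n_report)))
  mdl <- parse_model(txt)
  attr(mdl, "params") <- list(N_L = N_L, N_R = N_R, k_plus1 = k_plus1,
                              k_plus2 = k_plus2, k_off = k_off, beta = beta)
  mdl
}

#' Multisite phosphorylation model
#'
#' One substrate molecule type with `n_sites` independent two-state
#' residues (`~0` unphosphorylated, `~P` phosphorylated) and per-site
#' phosphorylation / dephosphorylation state-change rules.  The implied
#' reaction network has `2^n_sites` species, so for moderate `n_sites`
#' exhaustive network generation fails while network-free simulation is
#' unaffected.
#'
#' @param n_sites Number of modifiable sites (>= 1).
#' @param n_substrate Substrate copy number.
#' @param k_p,k_d Phosphorylation / dephosphorylation rate constants (1/s).
#' @param t_end,n_report Simulation action defaults.
#' @return An `rk_model`.
#' @export
make_multisite_phos <- function(n_sites = 2L, n_substrate = 50L,
                                k_p = 1, k_d = 1, t_end = 2, n_report = 10L) {
  stopifnot(n_sites >= 1L)
  sites <- paste0("s", seq_len(n_sites))
  decl <- paste0("S(", paste0(sites, "~0~P", collapse = ","), ")")
  seed <- paste0("S(", paste0(sites, "~0", collapse = ","), ")")
  rules <- unlist(lapply(sites, function(s) c(
    sprintf("phos_%s: S(%s~0) -> S(%s~P) kp", s, s, s),
    sprintf("deph_%s: S(%s~P) -> S(%s~0) kd", s, s, s))))
  obs <- c(vapply(sites, function(s)
    sprintf("Molecules P_%s S(%s~P)", s, s), ""),
    paste0("Species FullyP S(",
           paste0(sites, "~P", collapse = ","), ")"))
  txt <- c("begin parameters",
           sprintf("kp %.17g", k_p), sprintf("kd %.17g", k_d),
           sprintf("n0 %d", as.integer(n_substrate)),
           "end parameters",
           "begin molecule types", decl, "end molecule types",
           "begin species", paste(seed, "n0"), "end species",
           "begin reaction rules", rules, "end reaction rules",
           "begin observables", obs, "end observables",
           sprintf("simulate_rm({t_end=>%.17g,n_steps=>%d})", t_end,
                   as.integer(n_report)))
  parse_model(txt)
}

#' Stiff two-timescale model
#'
#' Two molecule types, each with one two-state component, and two
#' first-order state-change rules whose rate constants differ by the
#' stiffness ratio `phi`.  Used to demonstrate that the rejection-free
#' procedure's per-event cost is independent of `phi`.
#'
#' @param phi Ratio of the fast to the slow rate constant (> 0).
#' @param n0 Copy number per molecule type.
#' @param k Slow rate constant (1/s).
#' @param t_end,n_report Simulation action defaults.
#' @return An `rk_model`.
#' @export
make_stiff <- function(phi = 1e3, n0 = 1000L, k = 1, t_end = 1,
                       n_report = 10L) {
  stopifnot(phi > 0)
  txt <- c("begin parameters",
           sprintf("k %.17g", k), sprintf("kfast %.17g", k * phi),
           sprintf("n0 %d", as.integer(n0)),
           "end parameters",
           "begin molecule types", "A(x~0~1)", "B(x~0~1)",
           "end molecule types",
           "begin species", "A(x~0) n0", "B(x~0) n0", "end species",
           "begin reaction rules",
           "slow: A(x~0) -> A(x~1) k",
           "fast: B(x~0) -> B(x~1) kfast",
           "end reaction rules",
           "begin observables",
           "Molecules A0 A(x~0)", "Molecules B0 B(x~0)",
           "end observables",
           sprintf("simulate_rm({t_end=>%.17g,n_steps=>%d})", t_end,
                   as.integer(n_report)))
  parse_model(txt)
}

#' Symmetric dimerization model
#'
#' Monovalent molecule `A(a)` with the symmetric association rule
#' `A(a) + A(a) -> A(a!1).A(a!1)` (symmetry factor 1/2, so the initial
#' association rate is `k_plus * n0 * (n0 - 1) / 2`) and the 2-product
#' dissociation back-rule.
#'
#' @param k_plus Association rate constant (per pair, 1/s).
#' @param k_minus Dissociation rate constant (1/s).
#' @param n0 Monomer copy number (>= 2).
#' @param t_end,n_report Simulation action defaults.
#' @return An `rk_model`.
#' @export
make_dimerization <- function(k_plus = 0.01, k_minus = 1, n0 = 60L,
                              t_end = 5, n_report = 10L) {
  stopifnot(n0 >= 2L)
  txt <- c("begin parameters",
           sprintf("kp %.17g", k_plus), sprintf("km %.17g", k_minus),
           sprintf("n0 %d", as.integer(n0)),
           "end parameters",
           "begin molecule types", "A(a)", "end molecule types",
           "begin species", "A(a) n0", "end species",
           "begin reaction rules",
           "dim: A(a) + A(a) -> A(a!1).A(a!1) kp",
           "undim: A(a!1).A(a!1) -> A(a) + A(a) km",
           "end reaction rules",
           "begin observables",
           "Species Amono A(a)", "Species Dimer A(a!1).A(a!1)",
           "end observables",
           sprintf("simulate_rm({t_end=>%.17g,n_steps=>%d})", t_end,
                   as.integer(n_report)))
  parse_model(txt)
}

#' Fraction of molecules of a type held by the largest aggregate
#'
#' @param st An `rk_state`.
#' @param molecule_name Declared molecule type name.
#' @return Real in `[0, 1]`: count of the named molecules in the largest
#'   species instance (largest by that count) divided by the total count.
#' @export
largest_aggregate_fraction <- function(st, molecule_name) {
  ti <- st$model$type_index[molecule_name]
  if (is.na(ti))
    stop("molecule type '", molecule_name, "' not declared", call. = FALSE)
  total <- sum(st$mol_type == ti)
  if (total == 0L)
    stop("no molecules of type '", molecule_name, "' in the state",
         call. = FALSE)
  best <- 0L
  for (uid in state_uids(st)) {
    cnt <- sum(st$mol_type[st$sp_mols[[uid]]] == ti)
    if (cnt > best) best <- cnt
  }
  best / total
}
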