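# Generate-first validation oracle: exhaustive derivation of the reaction
# network implied by a rule set (for small models), direct Gillespie SSA
# and mass-action ODE integration on that network, plus a brute-force
# per-rule rate enumerator.
#
# The combinatorics here are deliberately implemented from scratch on the
# nested rk_species representation and share no code with the rule
# engine's rate paths: an oracle sharing code with the system under test
# proves nothing.

# --- independent pattern matcher on rk_species -----------------------------

# all injections of raw pattern graph g into species sp; returns list of
# list(mols, slots) exactly like the engine matcher (same output contract,
# separate implementation)
oracle_matches <- function(sp, g, model, tinfo = type_info(model)) {
  np <- length(g$mols)
  k <- length(sp$type)
  res <- list()
  mols_pick <- integer(np)
  slots_pick <- vector("list", np)
  edge_ok <- function(upto) {
    for (e in g$edges) {
      if (e[1L] > upto || e[3L] > upto) next
      i1 <- mols_pick[e[1L]]; s1 <- slots_pick[[e[1L]]][e[2L]]
      i2 <- mols_pick[e[3L]]; s2 <- slots_pick[[e[3L]]][e[4L]]
      if (sp$bm[i1, s1] != i2 || sp$bc[i1, s1] != s2) return(FALSE)
    }
    TRUE
  }
  try_mol <- function(pi) {
    if (pi > np) { res[[length(res) + 1L]] <- list(mols = mols_pick,
                                                   slots = slots_pick)
                   res <<- res; return() }
    pmol <- g$mols[[pi]]
    ti <- model$type_index[[pmol$name]]
    for (mi in seq_len(k)) {
      if (sp$type[mi] != ti) next
      if (mi %in% mols_pick[seq_len(pi - 1L)]) next
      # enumerate injective slot choices for this molecule's requirements
      nq <- length(pmol$comps)
      choose_slot <- function(qi, chosen) {
        if (qi > nq) {
          mols_pick[pi] <<- mi
          slots_pick[[pi]] <<- chosen
          if (edge_ok(pi)) try_mol(pi + 1L)
          mols_pick[pi] <<- 0L
          return()
        }
        cc <- pmol$comps[[qi]]
        for (p in tinfo[[ti]]$name_pos[[cc$name]]) {
          if (p %in% chosen) next
          if (!is.na(cc$state)) {
            want <- match(cc$state, tinfo[[ti]]$states[[p]])
            if (sp$st[mi, p] != want) next
          }
          if (cc$bond == BOND_FREE && sp$bm[mi, p] != 0L) next
          if ((cc$bond == BOND_ANY || cc$bond > 0L) && sp$bm[mi, p] == 0L) next
          choose_slot(qi + 1L, c(chosen, p))
        }
      }
      choose_slot(1L, integer())
    }
  }
  try_mol(1L)
  res
}

# distinct images of one or two center components under all injections
oracle_centers <- function(sp, g, centers, model, tinfo = type_info(model)) {
  ms <- oracle_matches(sp, g, model, tinfo)
  if (length(ms) == 0L) return(matrix(0L, 0L, 2L * length(centers)))
  rows <- lapply(ms, function(mt) {
    pts <- lapply(centers, function(ct)
      c(mt$mols[ct[1L]], mt$slots[[ct[1L]]][ct[2L]]))
    if (length(pts) == 2L) {
      a <- pts[[1L]]; b <- pts[[2L]]
      if (a[1L] > b[1L] || (a[1L] == b[1L] && a[2L] > b[2L]))
        pts <- list(b, a)
    }
    unlist(pts)
  })
  unique(do.call(rbind, rows))
}

# --- species surgery on the nested representation --------------------------

oracle_split <- function(sp) {
  k <- length(sp$type)
  comp <- integer(k); nc <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s; comp[s] <- nc
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      for (w in sp$bm[v, ]) if (w > 0L && comp[w] == 0L) {
        comp[w] <- nc; queue <- c(queue, w)
      }
    }
  }
  lapply(seq_len(nc), function(ci) {
    keep <- which(comp == ci)
    remap <- integer(k); remap[keep] <- seq_along(keep)
    bm <- sp$bm[keep, , drop = FALSE]
    bc <- sp$bc[keep, , drop = FALSE]
    bm[bm > 0L] <- remap[bm[bm > 0L]]
    structure(list(type = sp$type[keep],
                   st = sp$st[keep, , drop = FALSE], bm = bm, bc = bc),
              class = "rk_species")
  })
}

oracle_merge <- function(a, b) {
  ka <- length(a$type)
  bm <- b$bm; bm[bm > 0L] <- bm[bm > 0L] + ka
  structure(list(type = c(a$type, b$type), st = rbind(a$st, b$st),
                 bm = rbind(a$bm, bm), bc = rbind(a$bc, b$bc)),
            class = "rk_species")
}

oracle_set_bond <- function(sp, m1, p1, m2, p2) {
  sp$bm[m1, p1] <- m2; sp$bc[m1, p1] <- p2
  sp$bm[m2, p2] <- m1; sp$bc[m2, p2] <- p1
  sp
}

oracle_cut_bond <- function(sp, m1, p1) {
  m2 <- sp$bm[m1, p1]; p2 <- sp$bc[m1, p1]
  sp$bm[m1, p1] <- 0L; sp$bc[m1, p1] <- 0L
  sp$bm[m2, p2] <- 0L; sp$bc[m2, p2] <- 0L
  sp
}

# --- per-rule reaction-instance enumeration --------------------------------

# all concrete reaction instances of a unimolecular rule applied to one
# species; each instance: list(products = list of rk_species)
oracle_uni_instances <- function(rule, sp, model, tinfo = type_info(model)) {
  out <- list()
  if (rule$class == "STATE_CHANGE") {
    ctr <- oracle_centers(sp, rule$lhs[[1L]], list(rule$center), model, tinfo)
    if (nrow(ctr) == 0L) return(out)
    pmol <- rule$lhs[[1L]]$mols[[rule$center[1L]]]
    for (r in seq_len(nrow(ctr))) {
      m <- ctr[r, 1L]; p <- ctr[r, 2L]
      new_idx <- match(rule$new_state, tinfo[[sp$type[m]]]$states[[p]])
      s2 <- sp; s2$st[m, p] <- new_idx
      out[[length(out) + 1L]] <- list(products = list(s2))
    }
  } else if (rule$class == "DISSOCIATION") {
    ctr <- oracle_centers(sp, rule$lhs[[1L]],
                          list(rule$center[1L, ], rule$center[2L, ]),
                          model, tinfo)
    for (r in seq_len(nrow(ctr))) {
      s2 <- oracle_cut_bond(sp, ctr[r, 1L], ctr[r, 2L])
      prods <- oracle_split(s2)
      if (length(prods) == rule$nprod)
        out[[length(out) + 1L]] <- list(products = prods)
    }
  } else if (rule$class %in% c("RING_MONO", "RING_NONMONO")) {
    ctr <- oracle_centers(sp, rule$lhs[[1L]],
                          list(rule$center1, rule$center2), model, tinfo)
    for (r in seq_len(nrow(ctr))) {
      if (ctr[r, 1L] == ctr[r, 3L] && ctr[r, 2L] == ctr[r, 4L]) next
      s2 <- oracle_set_bond(sp, ctr[r, 1L], ctr[r, 2L], ctr[r, 3L], ctr[r, 4L])
      out[[length(out) + 1L]] <- list(products = list(s2))
    }
  } else stop("not a unimolecular rule")
  out
}

# all ordered reaction instances of an association rule between two
# DISTINCT species copies (role 1 in a, role 2 in b)
oracle_assoc_instances <- function(rule, a, b, model,
                                   tinfo = type_info(model)) {
  c1 <- oracle_centers(a, rule$lhs[[1L]], list(rule$center1), model, tinfo)
  c2 <- oracle_centers(b, rule$lhs[[2L]], list(rule$center2), model, tinfo)
  out <- list()
  if (nrow(c1) == 0L || nrow(c2) == 0L) return(out)
  ka <- length(a$type)
  for (r1 in seq_len(nrow(c1)))
    for (r2 in seq_len(nrow(c2))) {
      merged <- oracle_merge(a, b)
      merged <- oracle_set_bond(merged, c1[r1, 1L], c1[r1, 2L],
                                c2[r2, 1L] + ka, c2[r2, 2L])
      out[[length(out) + 1L]] <- list(products = list(merged))
    }
  out
}

#' Brute-force cumulative rule rate
#'
#' Enumerates every concrete reaction instance of a rule in the current
#' state by direct combinatorial search (all distinct center images, all
#' distinct-instance pairs for association, product-count filtering for
#' dissociation) and returns `k * f * count`.  Shares no code with the
#' rule engine's incremental rate paths; intended as an independent oracle
#' on small states.
#'
#' @param rule An `rk_rule`.
#' @param st An `rk_state` (small; cost grows combinatorially).
#' @return Nonnegative real rate.
#' @export
brute_force_rule_rate <- function(rule, st) {
  model <- st$model; tinfo <- st$tinfo
  uids <- state_uids(st)
  spp <- lapply(uids, function(u) extract_species(st, st$sp_mols[[u]]))
  if (rule$class == "ASSOCIATION") {
    total <- 0L
    for (i in seq_along(spp)) for (j in seq_along(spp)) {
      if (i == j) next
      c1 <- oracle_centers(spp[[i]], rule$lhs[[1L]], list(rule$center1),
                           model, tinfo)
      c2 <- oracle_centers(spp[[j]], rule$lhs[[2L]], list(rule$center2),
                           model, tinfo)
      total <- total + nrow(c1) * nrow(c2)
    }
    rule$f * rule$k * total
  } else {
    total <- 0L
    for (s in spp)
      total <- total + length(oracle_uni_instances(rule, s, model, tinfo))
    rule$k * total
  }
}

# --- exhaustive network generation -----------------------------------------

#' Exhaustively derive the reaction network implied by a rule set
#'
#' Fixed-point closure: every rule is applied to every species (and
#' species pair) discovered so far; products are canonicalized and added
#' until closure.  Per-reaction rate constants include the statistical
#' factor (reaction-path count between fixed copies), so SSA propensities
#' and ODE mass-action terms match the rule-level rates by construction.
#'
#' @param model An `rk_model`.
#' @param max_species Guard: exceeding it raises an error containing
#'   "network too large" (the motivating failure mode of network-free
#'   simulation).
#' @param max_molecules Optional truncation: reactions producing species
#'   with more than this many molecules are dropped.  Only meaningful for
#'   oracle use in parameter regimes where such species are unpopulated.
#' @return An object of class `rk_network`: `species` (canonical labels),
#'   `strings` (BNGL renderings), `spp` (nested species), `reactions`
#'   (each with reactant indices `r`, logical `same`, product indices
#'   `prod`, rate constant `c`, generating rule `rule`), and `init`
#'   (seed copy numbers per species).
#' @export
generate_network <- function(model, max_species = 500L,
                             max_molecules = Inf) {
  tinfo <- type_info(model)
  spp <- list(); labels <- character(); init <- numeric()
  add_species <- function(sp) {
    lab <- canonical_label(sp, model)
    hit <- match(lab, labels)
    if (!is.na(hit)) return(hit)
    if (length(labels) + 1L > max_species)
      stop("network too large: more than ", max_species,
           " species implied by the rules", call. = FALSE)
    spp[[length(spp) + 1L]] <<- sp
    labels <<- c(labels, lab)
    init <<- c(init, 0)
    length(labels)
  }
  for (s in model$seed_species) {
    idx <- add_species(graph_to_species(s$graph, model, tinfo))
    init[idx] <- init[idx] + s$count
  }
  reactions <- new.env(parent = emptyenv())
  note_reaction <- function(rule_i, r, same, prods, npaths) {
    key <- paste(rule_i, paste(sort(r), collapse = ","),
                 paste(sort(prods), collapse = ","), sep = "|")
    cur <- reactions[[key]]
    if (is.null(cur))
      reactions[[key]] <- list(rule = rule_i, r = r, same = same,
                               prod = prods, npaths = npaths)
    else {
      cur$npaths <- cur$npaths + npaths
      reactions[[key]] <- cur
    }
  }
  rules <- model$rules
  uni <- which(vapply(rules, function(r) r$class != "ASSOCIATION", TRUE))
  bi <- which(vapply(rules, function(r) r$class == "ASSOCIATION", TRUE))
  i <- 1L
  while (i <= length(spp)) {
    sp_i <- spp[[i]]
    for (ri in uni) {
      insts <- oracle_uni_instances(rules[[ri]], sp_i, model, tinfo)
      for (inst in insts) {
        prods <- vapply(inst$products, add_species, 0L)
        note_reaction(ri, i, FALSE, prods, 1)
      }
    }
    for (ri in bi) {
      rule <- rules[[ri]]
      for (j in seq_len(i)) {
        sp_j <- spp[[j]]
        if (length(sp_i$type) + length(sp_j$type) > max_molecules) next
        insts <- oracle_assoc_instances(rule, sp_i, sp_j, model, tinfo)
        if (i != j)
          insts <- c(insts,
                     oracle_assoc_instances(rule, sp_j, sp_i, model, tinfo))
        for (inst in insts) {
          prods <- vapply(inst$products, add_species, 0L)
          # same-species pairs: both role orders give isomorphic products,
          # so each enumerated combo stands for 2 ordered assignments
          note_reaction(ri, c(i, j), i == j, prods,
                        if (i == j) 2 else 1)
        }
      }
    }
    i <- i + 1L
  }
  rxns <- lapply(ls(reactions), function(k) {
    rx <- reactions[[k]]
    rule <- rules[[rx$rule]]
    rx$c <- rule$f * rule$k * rx$npaths
    rx$rule <- rule$name
    rx
  })
  structure(list(species = labels,
                 strings = vapply(spp, render_species, "", model = model),
                 spp = spp, reactions = rxns, init = init, model = model),
            class = "rk_network")
}

#' @export
print.rk_network <- function(x, ...) {
  cat("reaction network:", length(x$species), "species,",
      length(x$reactions), "unidirectional reactions\n")
  for (rx in x$reactions)
    cat(" ", paste(x$strings[rx$r], collapse = " + "), "->",
        paste(x$strings[rx$prod], collapse = " + "),
        sprintf(" c=%g (%s)\n", rx$c, rx$rule))
  invisible(x)
}

#' Text dump of a generated reaction network
#'
#' @param net An `rk_network`.
#' @return Character vector, one "reactants -> products rate" line per
#'   reaction, with canonical species renderings.
#' @export
network_to_text <- function(net) {
  vapply(net$reactions, function(rx)
    paste0(paste(net$strings[rx$r], collapse = " + "), " -> ",
           paste(net$strings[rx$prod], collapse = " + "),
           " ", format(rx$c, digits = 12)), "")
}

# per-species observable weights on a network (oracle matcher)
network_obs_weights <- function(net) {
  model <- net$model
  tinfo <- type_info(model)
  obs <- model$observables
  W <- matrix(0, length(obs), length(net$spp))
  for (o in seq_along(obs)) {
    for (s in seq_along(net$spp)) {
      nm <- vapply(obs[[o]]$patterns, function(g)
        length(oracle_matches(net$spp[[s]], g, model, tinfo)), 0L)
      W[o, s] <- if (obs[[o]]$type == "Molecules") sum(nm)
                 else as.numeric(any(nm > 0L))
    }
  }
  rownames(W) <- vapply(obs, `[[`, "", "name")
  W
}

# flat reaction arrays for fast propensity evaluation
network_arrays <- function(net) {
  m <- length(net$reactions)
  r1 <- integer(m); r2 <- integer(m); same <- logical(m); cc <- numeric(m)
  for (q in seq_len(m)) {
    rx <- net$reactions[[q]]
    r1[q] <- rx$r[1L]
    r2[q] <- if (length(rx$r) == 2L) rx$r[2L] else 0L
    same[q] <- isTRUE(rx$same)
    cc[q] <- rx$c
  }
  list(r1 = r1, r2 = r2, same = same, c = cc,
       bi = which(r2 > 0L & !same), bs = which(same))
}

# propensities for current copy-number vector n (vectorized)
network_propensities <- function(arr, n) {
  a <- arr$c * n[arr$r1]
  if (length(arr$bi)) a[arr$bi] <- a[arr$bi] * n[arr$r2[arr$bi]]
  if (length(arr$bs)) a[arr$bs] <- a[arr$bs] * (n[arr$r1[arr$bs]] - 1) / 2
  a
}

#' Direct stochastic simulation on an explicit reaction network
#'
#' Gillespie's direct method with mass-action propensities
#' (`c*n` unimolecular, `c*nA*nB` for distinct reactants,
#' `c*n*(n-1)/2` for identical reactants).  Observables are evaluated
#' through per-species match weights, so trajectories are directly
#' comparable with [simulate_nf()] output.
#'
#' @param net An `rk_network` from [generate_network()].
#' @param t_end End time.
#' @param report_times Report times (default `seq(0, t_end, length.out =
#'   n_report + 1)`).
#' @param n_report Number of report intervals when `report_times` is NULL.
#' @param seed Optional RNG seed.
#' @param init Initial copy numbers per network species (default: the
#'   model's seed counts).
#' @return A `data.frame` with `time` and one column per observable;
#'   attribute `event_count`.
#' @export
simulate_ssa_network <- function(net, t_end, report_times = NULL,
                                 n_report = 20L, seed = NULL, init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(report_times))
    report_times <- seq(0, t_end, length.out = n_report + 1L)
  if (is.null(init)) init <- net$init
  n <- init
  W <- network_obs_weights(net)
  nrep <- length(report_times)
  vals <- matrix(NA_real_, nrep, nrow(W))
  t <- 0; next_rep <- 1L; events <- 0L
  # precompute reaction arrays
  m <- length(net$reactions)
  arr <- network_arrays(net)
  delta <- vector("list", m)
  for (q in seq_len(m)) {
    rx <- net$reactions[[q]]
    d <- numeric(length(n))
    for (s in rx$r) d[s] <- d[s] - 1
    for (s in rx$prod) d[s] <- d[s] + 1
    delta[[q]] <- d
  }
  record_through <- function(tt) {
    while (next_rep <= nrep && report_times[next_rep] < tt) {
      vals[next_rep, ] <<- as.numeric(W %*% n)
      next_rep <<- next_rep + 1L
    }
  }
  repeat {
    a <- network_propensities(arr, n)
    atot <- sum(a)
    if (atot <= 0) { record_through(Inf); break }
    u <- stats::runif(1L)
    while (u <= 0) u <- stats::runif(1L)
    tau <- log(1 / u) / atot
    if (t + tau > t_end) { record_through(Inf); break }
    record_through(t + tau)
    q <- which(cumsum(a) >= stats::runif(1L) * atot)[1L]
    n <- n + delta[[q]]
    t <- t + tau
    events <- events + 1L
  }
  out <- data.frame(time = report_times)
  for (o in seq_len(nrow(W))) out[[rownames(W)[o]]] <- vals[, o]
  attr(out, "event_count") <- events
  out
}

#' Deterministic mass-action ODE integration on an explicit network
#'
#' Integrates the population-level rate equations whose terms mirror the
#' SSA propensities in the large-copy-number limit (`c*x`, `c*xA*xB`,
#' `c*x^2/2`), with relative tolerance 1e-8.
#'
#' @inheritParams simulate_ssa_network
#' @return A `data.frame` with `time` and one column per observable.
#' @export
integrate_ode_network <- function(net, t_end, report_times = NULL,
                                  n_report = 20L, init = NULL) {
  if (is.null(report_times))
    report_times <- seq(0, t_end, length.out = n_report + 1L)
  if (is.null(init)) init <- net$init
  W <- network_obs_weights(net)
  m <- length(net$reactions)
  ns <- length(init)
  S <- matrix(0, ns, m)
  for (q in seq_len(m)) {
    rx <- net$reactions[[q]]
    for (s in rx$r) S[s, q] <- S[s, q] - 1
    for (s in rx$prod) S[s, q] <- S[s, q] + 1
  }
  arr <- network_arrays(net)
  derivs <- function(t, x, parms) {
    rates <- arr$c * x[arr$r1]
    if (length(arr$bi)) rates[arr$bi] <- rates[arr$bi] * x[arr$r2[arr$bi]]
    if (length(arr$bs)) rates[arr$bs] <- rates[arr$bs] * x[arr$r1[arr$bs]] / 2
    list(as.numeric(S %*% rates))
  }
  sol <- deSolve::lsoda(y = init, times = report_times, func = derivs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed: ", paste(attr(sol, "istate"),
                                           collapse = " "), call. = FALSE)
  x <- t(sol[, -1L, drop = FALSE])
  out <- data.frame(time = report_times)
  obsvals <- W %*% x
  for (o in seq_len(nrow(W))) out[[rownames(W)[o]]] <- as.numeric(obsvals[o, ])
  out
}
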