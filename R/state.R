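# Particle-based system state: every molecule, component internal state and
# bond is tracked individually in flat integer arrays.  Species instances
# are connected site graphs; membership is kept per species uid.
#
# Matching cost is kept per-event-bounded by caching per-molecule pattern
# assignments under a local signature (type + states + bond-status vector):
# molecules with equal signatures match any purely local pattern molecule
# identically, and in aggregation models signatures repeat massively.

# per-type lookup tables used by the matcher
type_info <- function(model) {
  lapply(model$types, function(ty) {
    np <- split(seq_along(ty$comps), ty$comps)
    list(ncomp = length(ty$comps), names = ty$comps, states = ty$states,
         name_pos = np)
  })
}

# ---------------------------------------------------------------------------
# Nested, self-contained species representation (rk_species): local arrays
# type (k), st (k x maxc internal-state indices, 0 = none), bm/bc (k x maxc
# bond partner molecule / partner slot, 0 = unbound).  Used for seeds,
# canonical labels, the oracle and debugging output.

# build an rk_species from a concrete rk_graph
graph_to_species <- function(g, model, tinfo = type_info(model)) {
  k <- length(g$mols)
  maxc <- max(1L, vapply(tinfo, `[[`, 0L, "ncomp"))
  type <- integer(k)
  stm <- matrix(0L, k, maxc); bm <- matrix(0L, k, maxc); bc <- matrix(0L, k, maxc)
  slots <- vector("list", k)
  for (i in seq_len(k)) {
    mol <- g$mols[[i]]
    ti <- model$type_index[[mol$name]]
    type[i] <- ti
    used <- logical(tinfo[[ti]]$ncomp)
    sl <- integer(length(mol$comps))
    for (q in seq_along(mol$comps)) {
      cc <- mol$comps[[q]]
      pos <- tinfo[[ti]]$name_pos[[cc$name]]
      p <- pos[!used[pos]][1L]
      if (is.na(p)) stop("component multiplicity exceeded in species graph")
      used[p] <- TRUE
      sl[q] <- p
      if (!is.na(cc$state))
        stm[i, p] <- match(cc$state, tinfo[[ti]]$states[[p]])
    }
    slots[[i]] <- sl
  }
  for (e in g$edges) {
    i1 <- e[1L]; p1 <- slots[[e[1L]]][e[2L]]
    i2 <- e[3L]; p2 <- slots[[e[3L]]][e[4L]]
    bm[i1, p1] <- i2; bc[i1, p1] <- p2
    bm[i2, p2] <- i1; bc[i2, p2] <- p1
  }
  structure(list(type = type, st = stm, bm = bm, bc = bc),
            class = "rk_species")
}

#' Instantiate the particle state of a model
#'
#' Creates every seed-species copy as an individual species instance and
#' returns the mutable system state (an environment).  Molecule counts are
#' fixed for the lifetime of the state: only association, dissociation and
#' state-change transformations are supported, under which molecule and
#' component counts are conserved.
#'
#' @param model An `rk_model`.
#' @return An environment of class `rk_state` with fields `t` (time),
#'   `events` (events executed) and internal particle arrays.
#' @export
init_state <- function(model) {
  tinfo <- type_info(model)
  maxc <- max(1L, vapply(tinfo, `[[`, 0L, "ncomp"))
  templates <- lapply(model$seed_species, function(s)
    graph_to_species(s$graph, model, tinfo))
  sizes <- vapply(templates, function(sp) length(sp$type), 0L)
  counts <- vapply(model$seed_species, `[[`, 0L, "count")
  n_mol <- sum(sizes * counts)
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$tinfo <- tinfo
  st$maxc <- maxc
  st$n_mol <- n_mol
  st$mol_type <- integer(n_mol)
  st$cstate <- matrix(0L, max(n_mol, 1L), maxc)
  st$bmol <- matrix(0L, max(n_mol, 1L), maxc)
  st$bcomp <- matrix(0L, max(n_mol, 1L), maxc)
  st$sp_of <- integer(n_mol)
  st$sp_mols <- vector("list", max(16L, sum(counts)))
  st$n_uid <- 0L
  st$t <- 0
  st$events <- 0L
  nxt <- 1L
  for (i in seq_along(templates)) {
    sp <- templates[[i]]
    k <- sizes[i]
    for (copy in seq_len(counts[i])) {
      ids <- nxt:(nxt + k - 1L)
      st$mol_type[ids] <- sp$type
      st$cstate[ids, ] <- sp$st
      bm <- sp$bm
      bm[bm > 0L] <- ids[bm[bm > 0L]]
      st$bmol[ids, ] <- bm
      st$bcomp[ids, ] <- sp$bc
      uid <- new_uid(st)
      st$sp_mols[[uid]] <- ids
      st$sp_of[ids] <- uid
      nxt <- nxt + k
    }
  }
  class(st) <- c("rk_state", "environment")
  st
}

new_uid <- function(st) {
  st$n_uid <- st$n_uid + 1L
  if (st$n_uid > length(st$sp_mols))
    length(st$sp_mols) <- 2L * length(st$sp_mols)
  st$n_uid
}

#' Species instances currently alive
#'
#' @param st An `rk_state`.
#' @return Integer vector of live species uids.
#' @export
state_uids <- function(st) {
  which(!vapply(st$sp_mols[seq_len(st$n_uid)], is.null, TRUE))
}

# vectorized local signature of molecules (type, internal states, bond
# status per slot); equal signatures imply identical local match behaviour
sig_of <- function(st, mols) {
  cs <- st$cstate[mols, , drop = FALSE]
  bb <- st$bmol[mols, , drop = FALSE] > 0L
  do.call(paste, c(list(st$mol_type[mols]),
                   lapply(seq_len(ncol(cs)), function(j) cs[, j]),
                   lapply(seq_len(ncol(bb)), function(j) as.integer(bb[, j])),
                   sep = ","))
}

# ---------------------------------------------------------------------------
# Pattern compilation

compile_pattern <- function(g, model, tinfo = type_info(model)) {
  nm <- length(g$mols)
  pm <- vector("list", nm)
  any_label <- FALSE
  for (i in seq_len(nm)) {
    mol <- g$mols[[i]]
    ti <- model$type_index[[mol$name]]
    reqs <- lapply(mol$comps, function(cc) {
      pos <- tinfo[[ti]]$name_pos[[cc$name]]
      sidx <- NA_integer_
      if (!is.na(cc$state))
        sidx <- match(cc$state, tinfo[[ti]]$states[[pos[1L]]])
      list(name = cc$name, state = sidx, bond = cc$bond, pos = pos)
    })
    if (any(vapply(reqs, function(r) r$bond > 0L, TRUE))) any_label <- TRUE
    pm[[i]] <- list(ti = ti, reqs = reqs, nreq = length(reqs))
  }
  plan <- "generic"
  if (nm == 1L && !any_label) plan <- "local1"
  else if (nm == 2L && length(g$edges) == 1L) {
    e <- g$edges[[1L]]
    n_explicit <- vapply(pm, function(p)
      sum(vapply(p$reqs, function(r) r$bond > 0L, TRUE)), 0L)
    if (e[1L] != e[3L] && all(n_explicit == 1L)) plan <- "bond2"
  }
  structure(list(g = g, nm = nm, pm = pm, edges = g$edges, plan = plan,
                 cache = new.env(parent = emptyenv())),
            class = "rk_cpattern")
}

# Enumerate injective slot assignments of one pattern molecule's
# requirements onto one concrete molecule.  Returns a matrix with one row
# per assignment and one column per requirement (slot indices).
# `forced` optionally pins requirement `forced[1]` to slot `forced[2]`.
mol_assignments <- function(st, pmol, m, forced = NULL) {
  nreq <- pmol$nreq
  if (st$mol_type[m] != pmol$ti) return(matrix(0L, 0L, nreq))
  if (nreq == 0L) return(matrix(0L, 1L, 0L))
  cands <- vector("list", nreq)
  for (r in seq_len(nreq)) {
    rq <- pmol$reqs[[r]]
    p <- rq$pos
    if (!is.na(rq$state)) p <- p[st$cstate[m, p] == rq$state]
    b <- rq$bond
    if (b == BOND_FREE) p <- p[st$bmol[m, p] == 0L]
    else if (b == BOND_ANY || b > 0L) p <- p[st$bmol[m, p] > 0L]
    if (!is.null(forced) && forced[1L] == r) p <- p[p == forced[2L]]
    if (length(p) == 0L) return(matrix(0L, 0L, nreq))
    cands[[r]] <- p
  }
  rows <- list()
  slots <- integer(nreq)
  rec <- function(r, used) {
    if (r > nreq) { rows[[length(rows) + 1L]] <<- slots; return() }
    for (p in cands[[r]]) {
      if (p %in% used) next
      slots[r] <<- p
      rec(r + 1L, c(used, p))
    }
  }
  rec(1L, integer())
  if (length(rows) == 0L) return(matrix(0L, 0L, nreq))
  do.call(rbind, rows)
}

assign_summary <- function(mat) {
  list(mat = mat, n = nrow(mat),
       uc = lapply(seq_len(ncol(mat)), function(j) unique(mat[, j])))
}

# Cached per-molecule assignment summary for local pattern molecules.
local_assign <- function(st, cpat, mi, m, sig = NULL) {
  if (is.null(sig)) sig <- sig_of(st, m)
  key <- paste0(mi, "#", sig)
  hit <- cpat$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- assign_summary(mol_assignments(st, cpat$pm[[mi]], m))
  assign(key, val, envir = cpat$cache)
  val
}

# forced-slot variant (bond2 plan); cached on (mi, sig, req, slot)
local_assign_forced <- function(st, cpat, mi, m, req, slot, sig = NULL) {
  if (is.null(sig)) sig <- sig_of(st, m)
  key <- paste0(mi, "#", sig, "#", req, "@", slot)
  hit <- cpat$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- assign_summary(mol_assignments(st, cpat$pm[[mi]], m,
                                        forced = c(req, slot)))
  assign(key, val, envir = cpat$cache)
  val
}

# ---------------------------------------------------------------------------
# Generic backtracking matcher (all injections of a pattern into a species)

generic_matches <- function(st, cpat, members, first_only = FALSE) {
  nm <- cpat$nm
  out <- list()
  mol_assigned <- integer(nm)
  slot_assigned <- vector("list", nm)
  edges <- cpat$edges
  check_edges_upto <- function(i) {
    for (e in edges) {
      if (e[1L] > i || e[3L] > i) next
      m1 <- mol_assigned[e[1L]]; s1 <- slot_assigned[[e[1L]]][e[2L]]
      m2 <- mol_assigned[e[3L]]; s2 <- slot_assigned[[e[3L]]][e[4L]]
      if (e[1L] == i || e[3L] == i) {
        if (st$bmol[m1, s1] != m2 || st$bcomp[m1, s1] != s2) return(FALSE)
      }
    }
    TRUE
  }
  done <- FALSE
  rec <- function(i) {
    if (done) return()
    if (i > nm) {
      out[[length(out) + 1L]] <<- list(mols = mol_assigned,
                                       slots = slot_assigned)
      if (first_only) done <<- TRUE
      return()
    }
    for (m in members) {
      if (m %in% mol_assigned[seq_len(i - 1L)]) next
      mat <- mol_assignments(st, cpat$pm[[i]], m)
      if (nrow(mat) == 0L) next
      mol_assigned[i] <<- m
      for (rw in seq_len(nrow(mat))) {
        slot_assigned[[i]] <<- mat[rw, ]
        if (check_edges_upto(i)) rec(i + 1L)
        if (done) break
      }
      mol_assigned[i] <<- 0L
      if (done) break
    }
  }
  rec(1L)
  out
}

#' Find all embeddings of a pattern in a species instance
#'
#' Returns every injection (embedding) of the pattern graph into the
#' species instance, including embeddings that differ only by symmetric
#' component permutations.
#'
#' @param st An `rk_state`.
#' @param pattern Pattern as BNGL text or an `rk_graph`.
#' @param uid Species instance uid.
#' @return A list of matches; each match has `mols` (concrete molecule ids
#'   per pattern molecule) and `slots` (component slot indices per pattern
#'   molecule, one per listed pattern component).
#' @export
find_matches <- function(st, pattern, uid) {
  g <- if (inherits(pattern, "rk_graph")) pattern else parse_graph_expr(pattern)
  validate_graph(g, st$model, where = "pattern")
  cpat <- compile_pattern(g, st$model, st$tinfo)
  members <- st$sp_mols[[uid]]
  if (is.null(members)) stop("no species instance with uid ", uid)
  generic_matches(st, cpat, members)
}

#' Count distinct reaction centers of a pattern in a species instance
#'
#' Counts distinct images of the designated center component(s) under all
#' embeddings -- not the number of matches: when a contextual constraint
#' can be satisfied in several ways around one center, the center counts
#' once.
#'
#' @param st An `rk_state`.
#' @param pattern Pattern as BNGL text or `rk_graph`.
#' @param centers A list of one or two `c(mol, comp)` pairs indexing the
#'   pattern molecule and its listed component that the owning rule
#'   modifies.
#' @param uid Species instance uid.
#' @return Nonnegative integer count of distinct center images.
#' @export
count_reaction_centers <- function(st, pattern, centers, uid) {
  g <- if (inherits(pattern, "rk_graph")) pattern else parse_graph_expr(pattern)
  validate_graph(g, st$model, where = "pattern")
  cpat <- compile_pattern(g, st$model, st$tinfo)
  members <- st$sp_mols[[uid]]
  ms <- generic_matches(st, cpat, members)
  if (length(ms) == 0L) return(0L)
  imgs <- vapply(ms, function(mt) {
    key <- vapply(centers, function(ct)
      paste0(mt$mols[ct[1L]], ".", mt$slots[[ct[1L]]][ct[2L]]), "")
    paste(sort(key), collapse = "|")
  }, "")
  length(unique(imgs))
}

# ---------------------------------------------------------------------------
# Connectivity maintenance

# Partition a molecule set into connected components via bonds.
species_components <- function(st, members) {
  k <- length(members)
  if (k == 1L) return(list(members))
  idx <- integer(max(members))
  idx[members] <- seq_len(k)
  comp <- integer(k)
  ncomp <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      partners <- st$bmol[members[v], ]
      partners <- partners[partners > 0L]
      for (pm in partners) {
        w <- idx[pm]
        if (comp[w] == 0L) { comp[w] <- ncomp; queue <- c(queue, w) }
      }
    }
  }
  lapply(seq_len(ncomp), function(cc) members[comp == cc])
}

#' Split a molecule set into connected species instances
#'
#' Partitions the given molecules into connected components via their
#' bonds, registering each component as a live species instance.  Used
#' after bond deletion to restore the connectivity invariant.
#'
#' @param st An `rk_state`.
#' @param members Integer vector of molecule ids.
#' @return Integer vector of the new species uids (one per component).
#' @export
split_into_species <- function(st, members) {
  comps <- species_components(st, members)
  vapply(comps, function(cc) {
    uid <- new_uid(st)
    st$sp_mols[[uid]] <- cc
    st$sp_of[cc] <- uid
    uid
  }, 0L)
}

# number of products if the bond (m1,p1)-(m2,p2) were deleted: 1 if the
# endpoints remain connected through another path, else 2
bond_cut_products <- function(st, members, m1, p1, m2, p2) {
  # tree shortcut: a connected graph with |E| == |V|-1 has only bridges
  nb <- sum(st$bmol[members, , drop = FALSE] > 0L) / 2L
  if (nb == length(members) - 1L) return(2L)
  seen <- integer(max(members))
  seen[m1] <- 1L; queue <- m1
  while (length(queue)) {
    v <- queue[length(queue)]; queue <- queue[-length(queue)]
    for (j in seq_len(st$maxc)) {
      w <- st$bmol[v, j]
      if (w == 0L) next
      if (v == m1 && j == p1 && w == m2 && st$bcomp[v, j] == p2) next
      if (v == m2 && j == p2 && w == m1 && st$bcomp[v, j] == p1) next
      if (seen[w] == 0L) {
        if (w == m2) return(1L)
        seen[w] <- 1L; queue <- c(queue, w)
      }
    }
  }
  2L
}

# extract species `members` from the flat state into an rk_species
extract_species <- function(st, members) {
  k <- length(members)
  idx <- integer(max(members)); idx[members] <- seq_len(k)
  bm <- st$bmol[members, , drop = FALSE]
  bc <- st$bcomp[members, , drop = FALSE]
  bm[bm > 0L] <- idx[bm[bm > 0L]]
  structure(list(type = st$mol_type[members],
                 st = st$cstate[members, , drop = FALSE],
                 bm = bm, bc = bc),
            class = "rk_species")
}

# render an rk_species in BNGL species syntax
render_species <- function(sp, model, order = seq_along(sp$type)) {
  tinfo <- type_info(model)
  lab <- matrix(0L, length(sp$type), ncol(sp$bm))
  nxt <- 1L
  for (i in order) {
    for (j in seq_len(tinfo[[sp$type[i]]]$ncomp)) {
      w <- sp$bm[i, j]
      if (w == 0L || lab[i, j] != 0L) next
      lab[i, j] <- nxt
      lab[w, sp$bc[i, j]] <- nxt
      nxt <- nxt + 1L
    }
  }
  txt <- vapply(order, function(i) {
    ti <- sp$type[i]
    info <- tinfo[[ti]]
    comps <- vapply(seq_len(info$ncomp), function(j) {
      s <- info$names[j]
      if (sp$st[i, j] > 0L)
        s <- paste0(s, "~", info$states[[j]][sp$st[i, j]])
      if (lab[i, j] > 0L) s <- paste0(s, "!", lab[i, j])
      s
    }, "")
    paste0(model$types[[ti]]$name, "(", paste(comps, collapse = ","), ")")
  }, "")
  paste(txt, collapse = ".")
}

#' Debug rendering of a species instance in BNGL species syntax
#'
#' @param st An `rk_state`.
#' @param uid Species instance uid.
#' @return A character scalar such as `"A(b!1).B(a!1)"`.
#' @export
species_to_string <- function(st, uid) {
  render_species(extract_species(st, st$sp_mols[[uid]]), st$model)
}

# ---------------------------------------------------------------------------
# Isomorphism and canonical labelling.
#
# Two species are the same chemical species up to (a) relabelling of
# molecule instances and (b) permutation of identically named component
# slots within a molecule.  Both symmetries are respected below.

# admissible slot permutations of a molecule: bijections of declared slots
# mapping each same-name group onto itself
slot_perms <- function(tinfo_ty) {
  groups <- tinfo_ty$name_pos
  perm_list <- lapply(groups, function(g) {
    if (length(g) == 1L) return(list(g))
    # all permutations of the group's positions
    permute <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in permute(v[-i]))
          out[[length(out) + 1L]] <- c(v[i], rest)
      out
    }
    permute(g)
  })
  combos <- list(integer(tinfo_ty$ncomp))
  for (gi in seq_along(perm_list)) {
    positions <- groups[[gi]]
    newcombos <- list()
    for (base in combos)
      for (pp in perm_list[[gi]]) {
        nb <- base
        nb[positions] <- pp
        newcombos[[length(newcombos) + 1L]] <- nb
      }
    combos <- newcombos
  }
  combos
}

# slot-permutation-invariant neighborhood refinement colors
canon_refine <- function(sp, tinfo) {
  k <- length(sp$type)
  slot_names <- lapply(seq_len(k), function(i) tinfo[[sp$type[i]]]$names)
  col <- vapply(seq_len(k), function(i) {
    nc <- length(slot_names[[i]])
    paste0(sp$type[i], "|",
           paste(sort(paste0(slot_names[[i]], "~", sp$st[i, seq_len(nc)], "!",
                             as.integer(sp$bm[i, seq_len(nc)] > 0L))),
                 collapse = ";"))
  }, "")
  ranks <- match(col, sort(unique(col)))
  repeat {
    newcol <- vapply(seq_len(k), function(i) {
      nc <- length(slot_names[[i]])
      nb <- character()
      for (j in seq_len(nc)) {
        w <- sp$bm[i, j]
        if (w > 0L)
          nb <- c(nb, paste0(slot_names[[i]][j], ">",
                             slot_names[[w]][sp$bc[i, j]], ":", ranks[w]))
      }
      paste0(ranks[i], "|", paste(sort(nb), collapse = ";"))
    }, "")
    newranks <- match(newcol, sort(unique(newcol)))
    if (length(unique(newranks)) == length(unique(ranks))) return(newranks)
    ranks <- newranks
  }
}

#' Canonical label of a species instance
#'
#' A text label such that two species instances receive the same label if
#' and only if they represent the same chemical species.  Computed by
#' iterative neighborhood refinement followed by a lexicographically
#' minimal ordered traversal, branching over refinement ties and over
#' admissible permutations of identically named component slots.  Adequate
#' for oracle-scale species (up to dozens of molecules).
#'
#' @param x An `rk_species` or an `rk_state` (with `uid`).
#' @param model The owning `rk_model`; required when `x` is an
#'   `rk_species`.
#' @param uid Species uid when `x` is an `rk_state`.
#' @return A character scalar, stable across runs and storage orderings.
#' @export
canonical_label <- function(x, model = NULL, uid = NULL) {
  if (inherits(x, "rk_state")) {
    model <- x$model
    sp <- extract_species(x, x$sp_mols[[uid]])
  } else sp <- x
  tinfo <- type_info(model)
  k <- length(sp$type)
  ranks <- if (k > 1L) canon_refine(sp, tinfo) else rep(1L, k)
  perms <- lapply(seq_len(k), function(i) slot_perms(tinfo[[sp$type[i]]]))
  best <- NULL
  order_pos <- integer(k)       # molecule -> depth placed (0 = unplaced)
  perm_inv <- vector("list", k) # actual slot -> canonical slot, per molecule
  chunks <- character(k)
  n_explored <- 0L

  chunk_of <- function(i, perm) {
    # perm: canonical slot c -> actual slot perm[c]
    nc <- tinfo[[sp$type[i]]]$ncomp
    inv <- integer(nc); inv[perm] <- seq_len(nc)
    parts <- character(nc)
    for (cpos in seq_len(nc)) {
      p <- perm[cpos]
      w <- sp$bm[i, p]
      tok <- if (w == 0L) "-"
      else if (w == i) paste0("s", inv[sp$bc[i, p]])
      else if (order_pos[w] > 0L)
        paste0(order_pos[w], ".", perm_inv[[w]][sp$bc[i, p]])
      else "x"
      parts[cpos] <- paste0(sp$st[i, p], ":", tok)
    }
    list(txt = paste0("T", sp$type[i], "[", paste(parts, collapse = ","), "]"),
         inv = inv)
  }

  rec <- function(depth) {
    if (depth > k) {
      s <- paste(chunks, collapse = "&")
      if (is.null(best) || s < best) best <<- s
      return()
    }
    n_explored <<- n_explored + 1L
    if (n_explored > 500000L)
      stop("canonical label search exceeded budget (species too large/symmetric)")
    unused <- which(order_pos == 0L)
    cand <- list()
    for (i in unused)
      for (perm in perms[[i]]) {
        ch <- chunk_of(i, perm)
        cand[[length(cand) + 1L]] <-
          list(i = i, inv = ch$inv,
               txt = sprintf("%04d~%s", ranks[i], ch$txt))
      }
    txts <- vapply(cand, `[[`, "", "txt")
    mn <- min(txts)
    if (!is.null(best)) {
      prefix <- paste(c(chunks[seq_len(depth - 1L)], mn), collapse = "&")
      if (prefix > substr(best, 1L, nchar(prefix))) return()
    }
    seen_inv <- character()
    for (q in which(txts == mn)) {
      i <- cand[[q]]$i
      ikey <- paste0(i, "/", paste(cand[[q]]$inv, collapse = ","))
      if (ikey %in% seen_inv) next
      seen_inv <- c(seen_inv, ikey)
      order_pos[i] <<- depth
      perm_inv[[i]] <<- cand[[q]]$inv
      chunks[depth] <<- mn
      rec(depth + 1L)
      order_pos[i] <<- 0L
      perm_inv[i] <<- list(NULL)
    }
  }
  rec(1L)
  best
}

#' Test whether two species instances are the same chemical species
#'
#' True iff the two site graphs are isomorphic: same multiset of molecules
#' and internal states with the same bond topology, up to relabelling of
#' molecules and permutation of identically named component slots.
#' Implemented as a backtracking isomorphism search independent of
#' [canonical_label()].
#'
#' @param a,b `rk_species` objects, or species uids when `st` is given.
#' @param model The owning `rk_model` (when passing `rk_species`).
#' @param st Optional `rk_state` owning uids `a` and `b`.
#' @return Logical scalar.
#' @export
species_isomorphic <- function(a, b, model = NULL, st = NULL) {
  if (!is.null(st)) {
    model <- st$model
    a <- extract_species(st, st$sp_mols[[a]])
    b <- extract_species(st, st$sp_mols[[b]])
  }
  tinfo <- type_info(model)
  k <- length(a$type)
  if (k != length(b$type)) return(FALSE)
  invkey <- function(sp) {
    sort(vapply(seq_along(sp$type), function(i) {
      nc <- tinfo[[sp$type[i]]]$ncomp
      paste0(sp$type[i], "|",
             paste(sort(paste0(tinfo[[sp$type[i]]]$names, "~",
                               sp$st[i, seq_len(nc)], "!",
                               as.integer(sp$bm[i, seq_len(nc)] > 0L))),
                   collapse = ";"))
    }, ""))
  }
  if (!identical(invkey(a), invkey(b))) return(FALSE)
  mol_map <- integer(k)          # a molecule -> b molecule
  slot_map <- vector("list", k)  # per a molecule: a slot -> b slot
  used <- logical(k)

  # all slot bijections i(a) -> j(b) preserving name group, state and
  # bond status
  slot_bijections <- function(i, j) {
    nc <- tinfo[[a$type[i]]]$ncomp
    groups <- tinfo[[a$type[i]]]$name_pos
    out <- list(integer(nc))
    for (g in groups) {
      newout <- list()
      cands_per_slot <- lapply(g, function(p)
        g[a$st[i, p] == b$st[j, g] &
            (a$bm[i, p] > 0L) == (b$bm[j, g] > 0L)])
      assign_rec <- function(qi, cur, usedb) {
        if (qi > length(g)) { newout[[length(newout) + 1L]] <<- cur; return() }
        for (q in cands_per_slot[[qi]]) {
          if (q %in% usedb) next
          cur[g[qi]] <- q
          assign_rec(qi + 1L, cur, c(usedb, q))
        }
      }
      for (base in out) assign_rec(1L, base, integer())
      out <- newout
      if (length(out) == 0L) return(out)
    }
    out
  }

  bonds_ok <- function(i, j, sm) {
    nc <- tinfo[[a$type[i]]]$ncomp
    for (p in seq_len(nc)) {
      wa <- a$bm[i, p]
      if (wa == 0L) next
      if (mol_map[wa] == 0L && wa != i) next  # partner not yet mapped
      tgt_m <- if (wa == i) j else mol_map[wa]
      tgt_s <- if (wa == i) sm[a$bc[i, p]] else slot_map[[wa]][a$bc[i, p]]
      if (b$bm[j, sm[p]] != tgt_m || b$bc[j, sm[p]] != tgt_s) return(FALSE)
    }
    # and reverse direction: bonds of j into already-mapped region must be
    # mirrored (guaranteed by mutuality once all molecules checked)
    TRUE
  }

  rec <- function(i) {
    if (i > k) return(TRUE)
    for (j in seq_len(k)) {
      if (used[j] || a$type[i] != b$type[j]) next
      for (sm in slot_bijections(i, j)) {
        if (!bonds_ok(i, j, sm)) next
        mol_map[i] <<- j; used[j] <<- TRUE; slot_map[[i]] <<- sm
        if (rec(i + 1L)) return(TRUE)
        mol_map[i] <<- 0L; used[j] <<- FALSE; slot_map[i] <<- list(NULL)
      }
    }
    FALSE
  }
  rec(1L)
}
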