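# Rule engine: class-specific cumulative rates with over-counting
# corrections, reactant selection proportional to reaction-center counts,
# graph rewriting, and on-the-fly incremental rate maintenance.
#
# All per-species quantities are integer center counts, so incremental
# updates of the cumulative rates are exact (no floating-point drift): the
# rates are k * f * (sums and products of integers).

# compile one rule against a state's type tables
compile_rule <- function(rule, model, tinfo) {
  cr <- list(rule = rule, name = rule$name, class = rule$class, k = rule$k,
             f = rule$f)
  if (rule$class == "ASSOCIATION") {
    cr$cpat1 <- compile_pattern(rule$lhs[[1L]], model, tinfo)
    cr$cpat2 <- compile_pattern(rule$lhs[[2L]], model, tinfo)
    cr$c1 <- rule$center1
    cr$c2 <- rule$center2
  } else {
    cr$cpat <- compile_pattern(rule$lhs[[1L]], model, tinfo)
    if (rule$class == "STATE_CHANGE") {
      cr$center <- rule$center
      pmol <- cr$cpat$pm[[rule$center[1L]]]
      rq <- pmol$reqs[[rule$center[2L]]]
      allowed <- tinfo[[pmol$ti]]$states[[rq$pos[1L]]]
      cr$new_state <- match(rule$new_state, allowed)
      if (is.na(cr$new_state))
        stop("rule ", rule$name, ": product state '~", rule$new_state,
             "' not declared", call. = FALSE)
    } else if (rule$class == "DISSOCIATION") {
      cr$center <- rule$center       # 2 x (mol, comp-req)
      cr$nprod <- rule$nprod
      # fast bond2 path only when the pattern's single edge IS the center
      if (cr$cpat$plan == "bond2") {
        e <- cr$cpat$edges[[1L]]
        ctr <- rule$center
        is_center <- (all(e[1:2] == ctr[1L, ]) && all(e[3:4] == ctr[2L, ])) ||
          (all(e[3:4] == ctr[1L, ]) && all(e[1:2] == ctr[2L, ]))
        if (!is_center) cr$cpat$plan <- "generic"
      }
    } else {                          # RING_MONO / RING_NONMONO
      cr$c1 <- rule$center1
      cr$c2 <- rule$center2
      cr$mono <- rule$class == "RING_MONO"
    }
  }
  cr
}

# ---------------------------------------------------------------------------
# Center counting / enumeration per species instance.
# Each function returns list(n = count, centers = matrix or NULL).
# Center matrices: single centers (mol, slot); pair centers
# (mol1, slot1, mol2, slot2) with unordered identity already deduplicated.

# distinct images of one center component of a (possibly multi-molecule)
# pattern
centers_single <- function(st, cpat, ctr, members, enumerate = FALSE) {
  if (cpat$plan == "local1") {
    creq <- ctr[2L]
    sigs <- sig_of(st, members)
    n <- 0L
    rows <- if (enumerate) vector("list", length(members))
    for (q in seq_along(members)) {
      m <- members[q]
      val <- local_assign(st, cpat, 1L, m, sig = sigs[q])
      if (val$n == 0L) next
      uc <- val$uc[[creq]]
      n <- n + length(uc)
      if (enumerate) rows[[q]] <- cbind(m, uc)
    }
    return(list(n = n,
                centers = if (enumerate) do.call(rbind, rows)))
  }
  ms <- generic_matches(st, cpat, members)
  if (length(ms) == 0L) return(list(n = 0L, centers = NULL))
  img <- unique(t(vapply(ms, function(mt)
    c(mt$mols[ctr[1L]], mt$slots[[ctr[1L]]][ctr[2L]]), c(0L, 0L))))
  list(n = nrow(img), centers = if (enumerate) img)
}

# distinct bonded center pairs of a dissociation rule, filtered by the
# number of products the cut would yield
centers_dissoc <- function(st, cpat, ctr, nprod, members, enumerate = FALSE) {
  cand <- NULL
  if (cpat$plan == "bond2") {
    e <- cpat$edges[[1L]]
    # orient so that e matches ctr rows (compile_rule guarantees equality)
    if (!(all(e[1:2] == ctr[1L, ]))) e <- e[c(3L, 4L, 1L, 2L)]
    sigs <- sig_of(st, members)
    sig_by_mol <- stats::setNames(sigs, members)
    rows <- list()
    for (m in members) {
      nc <- st$tinfo[[st$mol_type[m]]]$ncomp
      for (j in seq_len(nc)) {
        w <- st$bmol[m, j]
        # skip unbound, deduplicate, and reject self-bonds: the two
        # pattern molecules must map to distinct molecules
        if (w == 0L || w <= m) next
        p2 <- st$bcomp[m, j]
        ok <- (local_assign_forced(st, cpat, e[1L], m, e[2L], j,
                                   sig = sig_by_mol[[as.character(m)]])$n > 0L &&
               local_assign_forced(st, cpat, e[3L], w, e[4L], p2,
                                   sig = sig_by_mol[[as.character(w)]])$n > 0L) ||
              (local_assign_forced(st, cpat, e[1L], w, e[2L], p2,
                                   sig = sig_by_mol[[as.character(w)]])$n > 0L &&
               local_assign_forced(st, cpat, e[3L], m, e[4L], j,
                                   sig = sig_by_mol[[as.character(m)]])$n > 0L)
        if (ok) rows[[length(rows) + 1L]] <- c(m, j, w, p2)
      }
    }
    cand <- if (length(rows)) do.call(rbind, rows)
  } else {
    ms <- generic_matches(st, cpat, members)
    if (length(ms)) {
      raw <- t(vapply(ms, function(mt) {
        a <- c(mt$mols[ctr[1L, 1L]], mt$slots[[ctr[1L, 1L]]][ctr[1L, 2L]])
        b <- c(mt$mols[ctr[2L, 1L]], mt$slots[[ctr[2L, 1L]]][ctr[2L, 2L]])
        if (a[1L] > b[1L] || (a[1L] == b[1L] && a[2L] > b[2L])) c(b, a)
        else c(a, b)
      }, integer(4L)))
      cand <- unique(raw)
    }
  }
  if (is.null(cand) || nrow(cand) == 0L)
    return(list(n = 0L, centers = NULL))
  # product-count application condition
  nb <- sum(st$bmol[members, , drop = FALSE] > 0L) / 2L
  if (nb == length(members) - 1L) {        # tree: every bond is a bridge
    keep <- rep(nprod == 2L, nrow(cand))
  } else {
    keep <- vapply(seq_len(nrow(cand)), function(r)
      bond_cut_products(st, members, cand[r, 1L], cand[r, 2L],
                        cand[r, 3L], cand[r, 4L]) == nprod, TRUE)
  }
  cand <- cand[keep, , drop = FALSE]
  list(n = nrow(cand), centers = if (enumerate) cand)
}

# distinct unordered center pairs of a ring-closure rule (same molecule
# for RING_MONO, different molecules of one species for RING_NONMONO)
centers_ring <- function(st, cpat, c1, c2, mono, members, enumerate = FALSE) {
  if (mono && cpat$plan == "local1") {
    # both centers in the single pattern molecule
    r1 <- c1[2L]; r2 <- c2[2L]
    sigs <- sig_of(st, members)
    n <- 0L
    rows <- if (enumerate) list()
    for (q in seq_along(members)) {
      m <- members[q]
      val <- local_assign(st, cpat, 1L, m, sig = sigs[q])
      if (val$n == 0L) next
      a <- val$mat[, r1]; b <- val$mat[, r2]
      keys <- paste(pmin(a, b), pmax(a, b))
      uq <- !duplicated(keys)
      n <- n + sum(uq)
      if (enumerate)
        rows[[length(rows) + 1L]] <-
          cbind(m, pmin(a, b)[uq], m, pmax(a, b)[uq])
    }
    return(list(n = n, centers = if (enumerate) do.call(rbind, rows)))
  }
  ms <- generic_matches(st, cpat, members)
  if (length(ms) == 0L) return(list(n = 0L, centers = NULL))
  raw <- t(vapply(ms, function(mt) {
    a <- c(mt$mols[c1[1L]], mt$slots[[c1[1L]]][c1[2L]])
    b <- c(mt$mols[c2[1L]], mt$slots[[c2[1L]]][c2[2L]])
    if (a[1L] > b[1L] || (a[1L] == b[1L] && a[2L] > b[2L])) c(b, a) else c(a, b)
  }, integer(4L)))
  img <- unique(raw)
  # distinct slots required (cannot bond a component to itself)
  img <- img[!(img[, 1L] == img[, 3L] & img[, 2L] == img[, 4L]), ,
             drop = FALSE]
  list(n = nrow(img), centers = if (enumerate) img)
}

# per-species contribution of a rule: single count, or c(v1, v2) for
# association
rule_contrib <- function(st, cr, members, enumerate = FALSE) {
  switch(cr$class,
    STATE_CHANGE = centers_single(st, cr$cpat, cr$center, members, enumerate),
    DISSOCIATION = centers_dissoc(st, cr$cpat, cr$center, cr$nprod, members,
                                  enumerate),
    ASSOCIATION = {
      a <- centers_single(st, cr$cpat1, cr$c1, members, enumerate)
      b <- centers_single(st, cr$cpat2, cr$c2, members, enumerate)
      list(n = c(a$n, b$n), centers = list(a$centers, b$centers))
    },
    RING_MONO = centers_ring(st, cr$cpat, cr$c1, cr$c2, TRUE, members,
                             enumerate),
    RING_NONMONO = centers_ring(st, cr$cpat, cr$c1, cr$c2, FALSE, members,
                                enumerate))
}

# ---------------------------------------------------------------------------
# Observable match numbers

compile_observable <- function(o, model, tinfo) {
  list(name = o$name, type = o$type,
       cpats = lapply(o$patterns, compile_pattern, model = model,
                      tinfo = tinfo))
}

# number of injections of one compiled pattern into a species
pattern_injections <- function(st, cpat, members) {
  if (cpat$plan == "local1") {
    n <- 0L
    sigs <- sig_of(st, members)
    for (q in seq_along(members))
      n <- n + local_assign(st, cpat, 1L, members[q], sig = sigs[q])$n
    return(n)
  }
  if (cpat$plan == "bond2") {
    e <- cpat$edges[[1L]]
    n <- 0L
    for (m in members) {
      nc <- st$tinfo[[st$mol_type[m]]]$ncomp
      for (j in seq_len(nc)) {
        w <- st$bmol[m, j]
        if (w == 0L || w == m) next   # distinct molecules required
        p2 <- st$bcomp[m, j]
        # both orientations arise by traversing the bond from each end
        n <- n + local_assign_forced(st, cpat, e[1L], m, e[2L], j)$n *
          local_assign_forced(st, cpat, e[3L], w, e[4L], p2)$n
      }
    }
    return(n)
  }
  length(generic_matches(st, cpat, members))
}

pattern_matched <- function(st, cpat, members) {
  if (cpat$plan == "local1") {
    sigs <- sig_of(st, members)
    for (q in seq_along(members))
      if (local_assign(st, cpat, 1L, members[q], sig = sigs[q])$n > 0L)
        return(TRUE)
    return(FALSE)
  }
  length(generic_matches(st, cpat, members, first_only = TRUE)) > 0L
}

# weight of one species instance for an observable (Eq.-style semantics:
# Molecules = number of injections; Species = 1 if any injection)
obs_weight <- function(st, cobs, members) {
  if (cobs$type == "Molecules") {
    sum(vapply(cobs$cpats, function(cp)
      as.numeric(pattern_injections(st, cp, members)), 0))
  } else {
    as.numeric(any(vapply(cobs$cpats, function(cp)
      pattern_matched(st, cp, members), TRUE)))
  }
}

#' Evaluate an observable against the current state
#'
#' `Molecules` observables count all injections of the pattern(s) across
#' species instances; `Species` observables count species instances with
#' at least one injection.
#'
#' @param st An `rk_state`.
#' @param obs An observable definition from `model$observables`, or an
#'   index into that list.
#' @return Nonnegative integer match number.
#' @export
eval_observable <- function(st, obs) {
  if (is.numeric(obs)) obs <- st$model$observables[[obs]]
  cobs <- compile_observable(obs, st$model, st$tinfo)
  total <- 0
  for (uid in state_uids(st))
    total <- total + obs_weight(st, cobs, st$sp_mols[[uid]])
  total
}

# ---------------------------------------------------------------------------
# Rule activity: incrementally maintained per-rule center bookkeeping

init_activity <- function(st) {
  model <- st$model
  act <- new.env(parent = emptyenv())
  act$crules <- lapply(model$rules, compile_rule, model = model,
                       tinfo = st$tinfo)
  act$cobs <- lapply(model$observables, compile_observable, model = model,
                     tinfo = st$tinfo)
  nr <- length(act$crules)
  act$nr <- nr
  act$cap <- max(16L, length(st$sp_mols))
  act$v1 <- lapply(seq_len(nr), function(i) numeric(act$cap))
  act$v2 <- lapply(seq_len(nr), function(i)
    if (act$crules[[i]]$class == "ASSOCIATION") numeric(act$cap))
  act$V1 <- numeric(nr); act$V2 <- numeric(nr); act$C <- numeric(nr)
  act$ow <- lapply(seq_along(act$cobs), function(o) numeric(act$cap))
  act$W <- numeric(length(act$cobs))
  recompute_activity(st, act)
  act
}

ensure_cap <- function(act, n) {
  if (n <= act$cap) return(invisible())
  newcap <- max(2L * act$cap, n)
  grow <- function(v) { length(v) <- newcap; v[is.na(v)] <- 0; v }
  act$v1 <- lapply(act$v1, grow)
  act$v2 <- lapply(act$v2, function(v) if (is.null(v)) NULL else grow(v))
  act$ow <- lapply(act$ow, grow)
  act$cap <- newcap
  invisible()
}

# de-novo recomputation of every rule's bookkeeping and every observable
recompute_activity <- function(st, act) {
  ensure_cap(act, max(st$n_uid, 1L))
  for (i in seq_len(act$nr)) {
    act$v1[[i]][] <- 0
    if (!is.null(act$v2[[i]])) act$v2[[i]][] <- 0
  }
  act$V1[] <- 0; act$V2[] <- 0; act$C[] <- 0
  for (o in seq_along(act$cobs)) act$ow[[o]][] <- 0
  act$W[] <- 0
  for (uid in state_uids(st)) add_contrib(st, act, uid)
  invisible(act)
}

add_contrib <- function(st, act, uid) {
  members <- st$sp_mols[[uid]]
  for (i in seq_len(act$nr)) {
    cr <- act$crules[[i]]
    cn <- rule_contrib(st, cr, members)$n
    if (cr$class == "ASSOCIATION") {
      act$v1[[i]][uid] <- cn[1L]
      act$v2[[i]][uid] <- cn[2L]
      act$V1[i] <- act$V1[i] + cn[1L]
      act$V2[i] <- act$V2[i] + cn[2L]
      act$C[i] <- act$C[i] + cn[1L] * cn[2L]
    } else {
      act$v1[[i]][uid] <- cn
      act$V1[i] <- act$V1[i] + cn
    }
  }
  for (o in seq_along(act$cobs)) {
    w <- obs_weight(st, act$cobs[[o]], members)
    act$ow[[o]][uid] <- w
    act$W[o] <- act$W[o] + w
  }
  invisible()
}

remove_contrib <- function(st, act, uid) {
  for (i in seq_len(act$nr)) {
    cr <- act$crules[[i]]
    if (cr$class == "ASSOCIATION") {
      a <- act$v1[[i]][uid]; b <- act$v2[[i]][uid]
      act$V1[i] <- act$V1[i] - a
      act$V2[i] <- act$V2[i] - b
      act$C[i] <- act$C[i] - a * b
      act$v1[[i]][uid] <- 0; act$v2[[i]][uid] <- 0
    } else {
      act$V1[i] <- act$V1[i] - act$v1[[i]][uid]
      act$v1[[i]][uid] <- 0
    }
  }
  for (o in seq_along(act$cobs)) {
    act$W[o] <- act$W[o] - act$ow[[o]][uid]
    act$ow[[o]][uid] <- 0
  }
  invisible()
}

# apply a state delta to the activity bookkeeping
update_activity <- function(st, act, removed, added) {
  for (uid in removed) remove_contrib(st, act, uid)
  ensure_cap(act, st$n_uid)
  for (uid in added) add_contrib(st, act, uid)
  r <- rule_rates(act)
  if (any(r < -1e-9 * max(sum(r), 1)))
    stop("internal error: negative rule rate after incremental update")
  invisible(act)
}

# cumulative rule rates r_i from the maintained sums
rule_rates <- function(act) {
  r <- numeric(act$nr)
  for (i in seq_len(act$nr)) {
    cr <- act$crules[[i]]
    r[i] <- if (cr$class == "ASSOCIATION")
      cr$f * cr$k * (act$V1[i] * act$V2[i] - act$C[i])
    else cr$k * act$V1[i]
  }
  r
}

# ---------------------------------------------------------------------------
# De-novo rate operations (class-specific, exported contracts)

rate_de_novo <- function(rule, st, expect_class = NULL) {
  if (!is.null(expect_class) && rule$class != expect_class)
    stop("rule '", rule$name, "' has class ", rule$class, ", expected ",
         expect_class, call. = FALSE)
  cr <- compile_rule(rule, st$model, st$tinfo)
  if (cr$class == "ASSOCIATION") {
    V1 <- 0; V2 <- 0; C <- 0
    for (uid in state_uids(st)) {
      cn <- rule_contrib(st, cr, st$sp_mols[[uid]])$n
      V1 <- V1 + cn[1L]; V2 <- V2 + cn[2L]; C <- C + cn[1L] * cn[2L]
    }
    cr$f * cr$k * (V1 * V2 - C)
  } else {
    V <- 0
    for (uid in state_uids(st))
      V <- V + rule_contrib(st, cr, st$sp_mols[[uid]])$n
    cr$k * V
  }
}

#' Cumulative rate of a rule against a state
#'
#' Computes the instantaneous cumulative rate `r_i` of a rule de novo from
#' the current particle state, using the class-specific center-counting
#' formula (with the over-counting correction for bimolecular association
#' and ring-closure classes).
#'
#' @param rule An `rk_rule` from `model$rules`.
#' @param st An `rk_state`.
#' @return Nonnegative real rate (units 1/time).
#' @export
rule_rate <- function(rule, st) rate_de_novo(rule, st)

#' @rdname rule_rate
#' @export
rate_state_change <- function(rule, st) rate_de_novo(rule, st, "STATE_CHANGE")

#' @rdname rule_rate
#' @export
rate_dissociation <- function(rule, st) rate_de_novo(rule, st, "DISSOCIATION")

#' @rdname rule_rate
#' @export
rate_association <- function(rule, st) rate_de_novo(rule, st, "ASSOCIATION")

#' @rdname rule_rate
#' @export
rate_ring_mono <- function(rule, st) rate_de_novo(rule, st, "RING_MONO")

#' @rdname rule_rate
#' @export
rate_ring_nonmono <- function(rule, st) rate_de_novo(rule, st, "RING_NONMONO")

# ---------------------------------------------------------------------------
# Reactant selection and event application

# weighted draw of a uid from a per-uid count vector; total must be > 0
draw_uid <- function(v, total, u) {
  cs <- cumsum(v)
  uid <- which(cs >= u * total)[1L]
  if (is.na(uid)) uid <- which(v > 0)[length(which(v > 0))]
  uid
}

# select species instance(s) and concrete reaction center(s) for rule i;
# center eligibility is re-derived for the chosen instance at event time
select_reactants <- function(st, act, i) {
  cr <- act$crules[[i]]
  n_uid <- st$n_uid
  if (cr$class == "ASSOCIATION") {
    v1 <- act$v1[[i]][seq_len(n_uid)]
    v2 <- act$v2[[i]][seq_len(n_uid)]
    # molecularity 2 without rejection: draw the first instance from the
    # corrected marginal v1(s) * (V2 - v2(s)), then the second from v2
    # with the first instance excluded
    w1 <- v1 * (act$V2[i] - v2)
    uid1 <- draw_uid(w1, act$V1[i] * act$V2[i] - act$C[i], stats::runif(1L))
    w2 <- v2; w2[uid1] <- 0
    uid2 <- draw_uid(w2, act$V2[i] - v2[uid1], stats::runif(1L))
    if (uid1 == uid2)
      stop("internal error: association selected one instance twice")
    en1 <- centers_single(st, cr$cpat1, cr$c1, st$sp_mols[[uid1]],
                          enumerate = TRUE)
    en2 <- centers_single(st, cr$cpat2, cr$c2, st$sp_mols[[uid2]],
                          enumerate = TRUE)
    if (en1$n == 0L || en2$n == 0L)
      stop("internal error: activity claims centers that do not exist")
    k1 <- floor(stats::runif(1L) * en1$n) + 1L
    k2 <- floor(stats::runif(1L) * en2$n) + 1L
    list(class = cr$class, uid = c(uid1, uid2),
         center = rbind(en1$centers[min(k1, en1$n), ],
                        en2$centers[min(k2, en2$n), ]))
  } else {
    v <- act$v1[[i]][seq_len(n_uid)]
    uid <- draw_uid(v, act$V1[i], stats::runif(1L))
    en <- rule_contrib(st, act$crules[[i]], st$sp_mols[[uid]],
                       enumerate = TRUE)
    if (en$n == 0L)
      stop("internal error: activity claims centers that do not exist")
    kk <- min(floor(stats::runif(1L) * en$n) + 1L, en$n)
    list(class = cr$class, uid = uid,
         center = en$centers[kk, ])
  }
}

# apply the graph rewrite for a selected event; returns the state delta
# list(removed = uids, added = uids); molecule instances are conserved
apply_rule_event <- function(st, act, i, sel) {
  cr <- act$crules[[i]]
  switch(cr$class,
    STATE_CHANGE = {
      m <- sel$center[1L]; p <- sel$center[2L]
      uid <- st$sp_of[m]
      st$cstate[m, p] <- cr$new_state
      list(removed = uid, added = uid)
    },
    DISSOCIATION = {
      m1 <- sel$center[1L]; p1 <- sel$center[2L]
      m2 <- sel$center[3L]; p2 <- sel$center[4L]
      uid <- st$sp_of[m1]
      st$bmol[m1, p1] <- 0L; st$bcomp[m1, p1] <- 0L
      st$bmol[m2, p2] <- 0L; st$bcomp[m2, p2] <- 0L
      members <- st$sp_mols[[uid]]
      if (cr$nprod == 2L) {
        st$sp_mols[uid] <- list(NULL)
        new_uids <- split_into_species(st, members)
        if (length(new_uids) != cr$nprod)
          stop("internal error: 2-product dissociation yielded ",
               length(new_uids), " product(s)")
        list(removed = uid, added = new_uids)
      } else {
        list(removed = uid, added = uid)   # ring opening keeps the instance
      }
    },
    ASSOCIATION = {
      m1 <- sel$center[1L, 1L]; p1 <- sel$center[1L, 2L]
      m2 <- sel$center[2L, 1L]; p2 <- sel$center[2L, 2L]
      u1 <- st$sp_of[m1]; u2 <- st$sp_of[m2]
      if (u1 == u2)
        stop("internal error: association event within one instance")
      st$bmol[m1, p1] <- m2; st$bcomp[m1, p1] <- p2
      st$bmol[m2, p2] <- m1; st$bcomp[m2, p2] <- p1
      members <- c(st$sp_mols[[u1]], st$sp_mols[[u2]])
      st$sp_mols[u1] <- list(NULL); st$sp_mols[u2] <- list(NULL)
      uid <- new_uid(st)
      st$sp_mols[[uid]] <- members
      st$sp_of[members] <- uid
      list(removed = c(u1, u2), added = uid)
    },
    {
      # ring closure (both flavours): intra-species bond creation
      m1 <- sel$center[1L]; p1 <- sel$center[2L]
      m2 <- sel$center[3L]; p2 <- sel$center[4L]
      uid <- st$sp_of[m1]
      if (st$sp_of[m2] != uid)
        stop("internal error: ring closure across two instances")
      st$bmol[m1, p1] <- m2; st$bcomp[m1, p1] <- p2
      st$bmol[m2, p2] <- m1; st$bcomp[m2, p2] <- p1
      list(removed = uid, added = uid)
    })
}
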