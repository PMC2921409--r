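# Model assembly: validation of graphs against declared molecule types,
# rule classification into the five supported classes, and rendering back
# to BNGL text.

RULE_CLASSES <- c("STATE_CHANGE", "DISSOCIATION", "ASSOCIATION",
                  "RING_MONO", "RING_NONMONO")

# Validate an rk_graph against the molecule-type table.
# concrete = TRUE enforces seed-species discipline: all declared components
# listed, states resolved, bonds explicit or absent.
validate_graph <- function(g, model, where = "graph", concrete = FALSE) {
  for (im in seq_along(g$mols)) {
    mol <- g$mols[[im]]
    ti <- model$type_index[mol$name]
    if (is.na(ti))
      stop(where, ": undeclared molecule '", mol$name, "'", call. = FALSE)
    ty <- model$types[[ti]]
    listed <- vapply(mol$comps, `[[`, "", "name")
    for (nm in unique(listed)) {
      have <- sum(listed == nm)
      declared <- sum(ty$comps == nm)
      if (declared == 0L)
        stop(where, ": undeclared component '", nm, "' in molecule '",
             mol$name, "'", call. = FALSE)
      if (have > declared)
        stop(where, ": component '", nm, "' listed ", have,
             " times but declared ", declared, " time(s) in '", mol$name,
             "'", call. = FALSE)
    }
    for (cc in mol$comps) {
      allowed <- ty$states[[match(cc$name, ty$comps)]]
      if (!is.na(cc$state)) {
        if (length(allowed) == 0L)
          stop(where, ": component '", cc$name, "' of '", mol$name,
               "' carries no internal state but '~", cc$state,
               "' was given", call. = FALSE)
        if (!cc$state %in% allowed)
          stop(where, ": state '~", cc$state, "' not among allowed states {",
               paste(allowed, collapse = ","), "} of ", mol$name, ".",
               cc$name, call. = FALSE)
      }
      if (concrete) {
        if (length(allowed) > 0L && is.na(cc$state))
          stop(where, ": seed species must resolve the state of ",
               mol$name, ".", cc$name, call. = FALSE)
        if (cc$bond < 0L)
          stop(where, ": seed species may not use bond wildcards",
               call. = FALSE)
      }
    }
    if (concrete && length(listed) != length(ty$comps))
      stop(where, ": seed species must list every component of '",
           mol$name, "' exactly once", call. = FALSE)
  }
  if (concrete && length(g$mols) > 1L) {
    # connectivity via explicit bonds
    adj <- lapply(seq_along(g$mols), function(i) integer())
    for (e in g$edges) {
      adj[[e[1L]]] <- c(adj[[e[1L]]], e[3L])
      adj[[e[3L]]] <- c(adj[[e[3L]]], e[1L])
    }
    seen <- logical(length(g$mols)); queue <- 1L; seen[1L] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen))
      stop(where, ": seed species graph is not connected", call. = FALSE)
  }
  invisible(g)
}

# Canonical text rendering of an rk_graph (bond labels renumbered in order
# of first appearance; molecules and components kept in given order).
render_graph <- function(g) {
  relab <- integer(0); nxt <- 1L
  lab_of <- function(lab) {
    key <- as.character(lab)
    if (is.null(names(relab)) || !key %in% names(relab)) {
      relab[key] <<- nxt; nxt <<- nxt + 1L
    }
    relab[[key]]
  }
  vapply(g$mols, function(mol) {
    comps <- vapply(mol$comps, function(cc) {
      s <- cc$name
      if (!is.na(cc$state)) s <- paste0(s, "~", cc$state)
      if (cc$bond > 0L) s <- paste0(s, "!", lab_of(cc$bond))
      else if (cc$bond == BOND_ANY) s <- paste0(s, "!+")
      else if (cc$bond == BOND_WILD) s <- paste0(s, "!?")
      s
    }, "")
    paste0(mol$name, "(", paste(comps, collapse = ","), ")")
  }, "") |> paste(collapse = ".")
}

# Derive the graph transformation of a rule by aligning the concatenated
# LHS molecules with the concatenated RHS molecules, then classify it.
build_rule <- function(raw, model, idx) {
  where <- paste0("rule ", if (!is.null(raw$name)) raw$name else idx,
                  " (line ", raw$line, ")")
  for (g in raw$lhs) validate_graph(g, model, where)
  for (g in raw$rhs) validate_graph(g, model, where)
  lmols <- do.call(c, lapply(raw$lhs, `[[`, "mols"))
  rmols <- do.call(c, lapply(raw$rhs, `[[`, "mols"))
  if (length(lmols) != length(rmols))
    stop(where, ": RHS inconsistent with LHS (different molecule counts)",
         call. = FALSE)
  # map global molecule index -> (pattern, mol-within-pattern)
  side_index <- function(side) {
    out <- list(); k <- 0L
    for (p in seq_along(side)) for (m in seq_along(side[[p]]$mols)) {
      k <- k + 1L; out[[k]] <- c(p, m)
    }
    out
  }
  lidx <- side_index(raw$lhs); ridx <- side_index(raw$rhs)
  state_changes <- list(); lhs_bonded <- list(); rhs_bonded <- list()
  for (t in seq_along(lmols)) {
    lm <- lmols[[t]]; rm <- rmols[[t]]
    if (lm$name != rm$name)
      stop(where, ": molecule ", t, " is '", lm$name, "' on LHS but '",
           rm$name, "' on RHS", call. = FALSE)
    lnames <- vapply(lm$comps, `[[`, "", "name")
    rnames <- vapply(rm$comps, `[[`, "", "name")
    if (!identical(lnames, rnames))
      stop(where, ": component lists of molecule ", t,
           " differ between LHS and RHS", call. = FALSE)
    for (j in seq_along(lm$comps)) {
      lc <- lm$comps[[j]]; rc <- rm$comps[[j]]
      if (!identical(lc$state, rc$state)) {
        if (is.na(lc$state) || is.na(rc$state))
          stop(where, ": state of ", lm$name, ".", lc$name,
               " must be explicit on both sides to change", call. = FALSE)
        state_changes[[length(state_changes) + 1L]] <-
          list(t = t, j = j, from = lc$state, to = rc$state)
      }
      lb <- lc$bond; rb <- rc$bond
      if (lb > 0L && rb <= 0L) {
        if (rb != BOND_FREE)
          stop(where, ": bond of ", lm$name, ".", lc$name,
               " may only open to unbound", call. = FALSE)
        lhs_bonded[[length(lhs_bonded) + 1L]] <- c(t, j, lb)
      } else if (lb == BOND_FREE && rb > 0L) {
        rhs_bonded[[length(rhs_bonded) + 1L]] <- c(t, j, rb)
      } else if (lb != rb && !(lb > 0L && rb > 0L)) {
        stop(where, ": unsupported bond transformation on ", lm$name, ".",
             lc$name, call. = FALSE)
      }
    }
  }
  n_state <- length(state_changes)
  n_cut <- length(lhs_bonded)
  n_new <- length(rhs_bonded)
  unsupported <- function(msg)
    stop(where, ": unsupported rule (", msg, "); a rule must change one ",
         "component state, delete one bond, or create one bond",
         call. = FALSE)

  rule <- list(name = if (!is.null(raw$name)) raw$name else paste0("R", idx),
               lhs = raw$lhs, rhs = raw$rhs, k = raw$k, f = 1,
               line = raw$line)
  if (n_state == 1L && n_cut == 0L && n_new == 0L) {
    if (length(raw$lhs) != 1L || length(raw$rhs) != 1L)
      unsupported("state change must have one LHS and one RHS pattern")
    sc <- state_changes[[1L]]
    rule$class <- "STATE_CHANGE"
    rule$center <- c(mol = lidx[[sc$t]][2L], comp = sc$j)
    rule$new_state <- sc$to
  } else if (n_state == 0L && n_cut == 2L && n_new == 0L) {
    if (length(raw$lhs) != 1L)
      unsupported("bond deletion requires a single LHS pattern")
    lab <- vapply(lhs_bonded, `[`, 0L, 3L)
    if (lab[1L] != lab[2L])
      unsupported("the two opened components do not share one bond")
    if (!length(raw$rhs) %in% 1:2)
      unsupported("dissociation must yield 1 or 2 product patterns")
    e1 <- lhs_bonded[[1L]]; e2 <- lhs_bonded[[2L]]
    rule$class <- "DISSOCIATION"
    rule$center <- rbind(c(lidx[[e1[1L]]][2L], e1[2L]),
                         c(lidx[[e2[1L]]][2L], e2[2L]))
    rule$nprod <- length(raw$rhs)
  } else if (n_state == 0L && n_cut == 0L && n_new == 2L) {
    lab <- vapply(rhs_bonded, `[`, 0L, 3L)
    if (lab[1L] != lab[2L])
      unsupported("the two bonding components do not share one bond")
    if (length(raw$rhs) != 1L)
      unsupported("bond creation must yield a single product pattern")
    e1 <- rhs_bonded[[1L]]; e2 <- rhs_bonded[[2L]]
    p1 <- lidx[[e1[1L]]]; p2 <- lidx[[e2[1L]]]
    if (length(raw$lhs) == 2L) {
      if (p1[1L] == p2[1L])
        unsupported("association centers must sit in different reactant patterns")
      rule$class <- "ASSOCIATION"
      # order centers as (pattern 1, pattern 2)
      if (p1[1L] > p2[1L]) { tmp <- p1; p1 <- p2; p2 <- tmp
                             tmp <- e1; e1 <- e2; e2 <- tmp }
      rule$center1 <- c(mol = p1[2L], comp = e1[2L])
      rule$center2 <- c(mol = p2[2L], comp = e2[2L])
      t1 <- render_graph(raw$lhs[[1L]]); t2 <- render_graph(raw$lhs[[2L]])
      rule$f <- if (identical(t1, t2)) 0.5 else 1
    } else if (length(raw$lhs) == 1L) {
      rule$class <- if (p1[2L] == p2[2L]) "RING_MONO" else "RING_NONMONO"
      rule$center1 <- c(mol = p1[2L], comp = e1[2L])
      rule$center2 <- c(mol = p2[2L], comp = e2[2L])
    } else {
      unsupported("bond creation needs 1 or 2 LHS patterns")
    }
  } else {
    unsupported(paste0(n_state, " state change(s), ", n_cut / 2,
                       " bond deletion(s), ", n_new / 2,
                       " bond creation(s)"))
  }
  class(rule) <- "rk_rule"
  rule
}

#' Rule class of a parsed rule
#'
#' One of `"STATE_CHANGE"`, `"DISSOCIATION"`, `"ASSOCIATION"`,
#' `"RING_MONO"` or `"RING_NONMONO"`.
#'
#' @param rule An `rk_rule`, as found in `model$rules`.
#' @return A character scalar.
#' @export
rule_class <- function(rule) rule$class

build_model <- function(params, types, seeds_raw, rules_raw, obs_raw,
                        actions) {
  type_index <- stats::setNames(seq_along(types),
                                vapply(types, `[[`, "", "name"))
  if (anyDuplicated(names(type_index)))
    stop("duplicate molecule type declaration", call. = FALSE)
  model <- structure(list(parameters = params, types = types,
                          type_index = type_index),
                     class = "rk_model")
  # infer missing molecule types from seed species (types block optional)
  if (length(types) == 0L) {
    inferred <- list()
    for (s in seeds_raw) {
      g <- parse_graph_expr(s$expr, where = paste0("line ", s$line))
      for (mol in g$mols) {
        if (!mol$name %in% vapply(inferred, `[[`, "", "name"))
          inferred[[length(inferred) + 1L]] <- list(
            name = mol$name,
            comps = vapply(mol$comps, `[[`, "", "name"),
            states = lapply(mol$comps, function(cc)
              if (is.na(cc$state)) character() else cc$state))
      }
    }
    model$types <- inferred
    model$type_index <- stats::setNames(seq_along(inferred),
                                        vapply(inferred, `[[`, "", "name"))
  }

  seeds <- lapply(seeds_raw, function(s) {
    g <- parse_graph_expr(s$expr, where = paste0("line ", s$line))
    validate_graph(g, model, where = paste0("line ", s$line), concrete = TRUE)
    list(graph = g, count = s$count)
  })
  rules <- list()
  expanded <- expand_reversible(rules_raw)
  for (i in seq_along(expanded))
    rules[[i]] <- build_rule(expanded[[i]], model, i)
  observables <- lapply(obs_raw, function(o) {
    pats <- lapply(o$patterns, function(p) {
      g <- parse_graph_expr(p, where = paste0("line ", o$line))
      validate_graph(g, model, where = paste0("line ", o$line))
      g
    })
    list(name = o$name, type = o$type, patterns = pats)
  })
  model$seed_species <- seeds
  model$rules <- rules
  model$observables <- observables
  model$actions <- actions
  model
}

#' Render a model as BNGL-subset text
#'
#' Produces text that [parse_model()] reads back into an equivalent model
#' (rules already expanded to unidirectional form).
#'
#' @param model An `rk_model`.
#' @return A character vector of lines.
#' @export
model_to_bngl <- function(model) {
  out <- c("begin parameters")
  for (nm in names(model$parameters))
    out <- c(out, sprintf("  %s %.17g", nm, model$parameters[[nm]]))
  out <- c(out, "end parameters", "begin molecule types")
  for (ty in model$types) {
    comps <- vapply(seq_along(ty$comps), function(j) {
      paste0(ty$comps[j], paste0(vapply(ty$states[[j]],
                                        function(s) paste0("~", s), ""),
                                 collapse = ""))
    }, "")
    out <- c(out, paste0("  ", ty$name, "(", paste(comps, collapse = ","), ")"))
  }
  out <- c(out, "end molecule types", "begin species")
  for (s in model$seed_species)
    out <- c(out, paste0("  ", render_graph(s$graph), " ", s$count))
  out <- c(out, "end species", "begin reaction rules")
  for (r in model$rules) {
    lhs <- paste(vapply(r$lhs, render_graph, ""), collapse = " + ")
    rhs <- paste(vapply(r$rhs, render_graph, ""), collapse = " + ")
    out <- c(out, sprintf("  %s: %s -> %s %.17g", r$name, lhs, rhs, r$k))
  }
  out <- c(out, "end reaction rules", "begin observables")
  for (o in model$observables)
    out <- c(out, paste0("  ", o$type, " ", o$name, " ",
                         paste(vapply(o$patterns, render_graph, ""),
                               collapse = " ")))
  out <- c(out, "end observables")
  act <- model$actions
  if (!is.na(act$t_end)) {
    args <- sprintf("t_end=>%g", act$t_end)
    if (!is.na(act$n_report)) args <- paste0(args, sprintf(",n_steps=>%d",
                                                           act$n_report))
    if (!is.na(act$seed)) args <- paste0(args, sprintf(",seed=>%d", act$seed))
    out <- c(out, paste0("simulate_rm({", args, "})"))
  }
  out
}

#' @export
print.rk_model <- function(x, ...) {
  cat("BNGL-subset model:", length(x$types), "molecule type(s),",
      length(x$seed_species), "seed species,",
      length(x$rules), "unidirectional rule(s),",
      length(x$observables), "observable(s)\n")
  for (r in x$rules)
    cat(sprintf("  %-12s %-14s k=%g f=%g\n", r$name, r$class, r$k, r$f))
  invisible(x)
}
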