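# Parsing of the BNGL-subset model dialect.
#
# Supported graph syntax: internal states "~s", explicit bonds "!n",
# bound-to-anything "!+", unspecified bond "!?", molecule concatenation ".",
# reactant separation "+", arrows "->" and "<->".  An explicitly listed
# component with no "!" is required to be unbound; omitted components are
# wildcards (any state, any bond status).

# bond requirement codes used throughout the package
BOND_FREE <- 0L   # component listed with no "!": must be unbound
BOND_ANY  <- -1L  # "!+": must be bonded, partner unspecified
BOND_WILD <- -2L  # "!?": bond status unconstrained
# positive integers are explicit bond labels, paired within one expression

.name_re <- "[A-Za-z_][A-Za-z0-9_]*"

#' Parse a site-graph expression
#'
#' Parses a BNGL species or pattern expression such as
#' `"A(b!1,y~P).B(a!1)"` into an unvalidated graph structure: a list of
#' molecules, each with named components carrying an optional internal
#' state and a bond requirement.
#'
#' @param text A single graph expression (no `"+"` separators).
#' @param where Context string used in error messages.
#' @return A list of class `rk_graph` with elements `mols` (list of
#'   molecules, each `list(name, comps)`) and `edges` (explicit bond pairs
#'   as `c(mol1, comp1, mol2, comp2)` index quadruples).
#' @export
parse_graph_expr <- function(text, where = "graph expression") {
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) stop(where, ": empty graph expression", call. = FALSE)
  pieces <- split_top_level(s, ".")
  mols <- vector("list", length(pieces))
  bond_ends <- list() # label -> list of c(mol, comp)
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    m <- regmatches(p, regexec(paste0("^(", .name_re, ")(\\((.*)\\))?$"), p))[[1]]
    if (length(m) == 0)
      stop(where, ": cannot parse molecule '", p, "'", call. = FALSE)
    mol_name <- m[2]
    comp_str <- if (length(m) >= 4) m[4] else ""
    comps <- list()
    if (nzchar(comp_str)) {
      for (cs in strsplit(comp_str, ",", fixed = TRUE)[[1]]) {
        if (!nzchar(cs))
          stop(where, ": empty component in '", p, "'", call. = FALSE)
        cm <- regmatches(cs, regexec(
          paste0("^(", .name_re, ")((~[A-Za-z0-9_]+|!(?:[0-9]+|\\+|\\?))*)$"), cs))[[1]]
        if (length(cm) == 0)
          stop(where, ": cannot parse component '", cs, "' in '", p, "'",
               call. = FALSE)
        cname <- cm[2]
        state <- NA_character_
        bond <- BOND_FREE
        sufs <- regmatches(cm[3],
          gregexpr("~[A-Za-z0-9_]+|![0-9]+|!\\+|!\\?", cm[3]))[[1]]
        n_state <- 0L; n_bond <- 0L
        for (sf in sufs) {
          if (startsWith(sf, "~")) {
            n_state <- n_state + 1L
            state <- substring(sf, 2)
          } else {
            n_bond <- n_bond + 1L
            b <- substring(sf, 2)
            bond <- switch(b, "+" = BOND_ANY, "?" = BOND_WILD,
                           as.integer(b))
            if (is.numeric(bond) && bond > 0L) {
              key <- as.character(bond)
              bond_ends[[key]] <- c(bond_ends[[key]],
                                    list(c(i, length(comps) + 1L)))
            }
          }
        }
        if (n_state > 1L || n_bond > 1L)
          stop(where, ": component '", cs, "' has repeated state or bond",
               call. = FALSE)
        comps[[length(comps) + 1L]] <- list(name = cname, state = state,
                                            bond = bond)
      }
    }
    mols[[i]] <- list(name = mol_name, comps = comps)
  }
  edges <- list()
  for (key in names(bond_ends)) {
    ends <- bond_ends[[key]]
    if (length(ends) != 2L)
      stop(where, ": dangling bond index !", key,
           " (appears ", length(ends), " time(s))", call. = FALSE)
    edges[[length(edges) + 1L]] <- c(ends[[1L]], ends[[2L]])
  }
  structure(list(mols = mols, edges = edges, text = s), class = "rk_graph")
}

# Split `s` on single-character separator `sep` at parenthesis depth 0.
# A "+" immediately preceded by "!" is a bond wildcard, never a separator.
split_top_level <- function(s, sep) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L; start <- 1L; out <- character()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == sep && depth == 0L &&
             !(sep == "+" && k > 1L && chars[k - 1L] == "!")) {
      out <- c(out, substr(s, start, k - 1L))
      start <- k + 1L
    }
  }
  c(out, substr(s, start, nchar(s)))
}

# Safe arithmetic evaluation of parameter expressions (+ - * / and parens).
safe_eval_expr <- function(text, params, where = "expression") {
  e <- tryCatch(str2lang(text),
                error = function(err) stop(where, ": cannot parse '", text,
                                           "'", call. = FALSE))
  check <- function(x) {
    if (is.numeric(x)) return(invisible())
    if (is.name(x)) {
      nm <- as.character(x)
      if (!nm %in% names(params))
        stop(where, ": unknown parameter '", nm, "'", call. = FALSE)
      return(invisible())
    }
    if (is.call(x)) {
      op <- as.character(x[[1L]])
      if (!op %in% c("+", "-", "*", "/", "("))
        stop(where, ": operator '", op, "' not allowed", call. = FALSE)
      for (i in seq_along(x)[-1L]) check(x[[i]])
      return(invisible())
    }
    stop(where, ": invalid term in '", text, "'", call. = FALSE)
  }
  check(e)
  eval(e, envir = as.list(params), enclos = baseenv())
}

#' Parse a BNGL-subset model
#'
#' Reads the blocks `parameters`, `molecule types`, `species` (or
#' `seed species`), `reaction rules`, `observables` and an optional
#' `actions` block / bare action commands, and returns a fully resolved
#' model.  Reversible (`<->`) rules are expanded into two unidirectional
#' rules.  Unknown blocks raise an error naming the block; unsupported
#' action commands are ignored with a warning.
#'
#' @param text Model source as a single string or a character vector of
#'   lines.
#' @return An object of class `rk_model`.
#' @seealso [read_model()] to parse from a file, [model_to_bngl()] for the
#'   inverse rendering.
#' @examples
#' mdl <- parse_model(c(
#'   "begin parameters", "k 2", "n0 5", "end parameters",
#'   "begin molecule types", "X(y~0~1)", "end molecule types",
#'   "begin species", "X(y~0) n0", "end species",
#'   "begin reaction rules", "X(y~0) -> X(y~1) k", "end reaction rules",
#'   "begin observables", "Molecules X0 X(y~0)", "end observables"))
#' length(mdl$rules)
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  # strip comments, keep line numbers
  raw <- sub("#.*$", "", lines)
  blocks <- list(parameters = list(), `molecule types` = list(),
                 species = list(), `reaction rules` = list(),
                 observables = list(), actions = list())
  known <- names(blocks)
  cur <- NULL
  loose_actions <- list()
  for (i in seq_along(raw)) {
    ln <- trimws(raw[i])
    if (!nzchar(ln)) next
    bm <- regmatches(ln, regexec("^begin\\s+(.*)$", ln))[[1L]]
    if (length(bm)) {
      bname <- trimws(bm[2L])
      if (bname == "seed species") bname <- "species"
      if (!bname %in% known)
        stop("line ", i, ": unknown block '", bname, "'", call. = FALSE)
      if (!is.null(cur))
        stop("line ", i, ": 'begin ", bname, "' inside block '", cur, "'",
             call. = FALSE)
      cur <- bname
      next
    }
    em <- regmatches(ln, regexec("^end\\s+(.*)$", ln))[[1L]]
    if (length(em)) {
      ename <- trimws(em[2L])
      if (ename == "seed species") ename <- "species"
      if (is.null(cur) || ename != cur)
        stop("line ", i, ": 'end ", ename, "' does not match open block",
             call. = FALSE)
      cur <- NULL
      next
    }
    if (is.null(cur)) {
      loose_actions[[length(loose_actions) + 1L]] <- list(line = i, text = ln)
    } else {
      blocks[[cur]][[length(blocks[[cur]]) + 1L]] <- list(line = i, text = ln)
    }
  }
  if (!is.null(cur))
    stop("block '", cur, "' is never closed", call. = FALSE)

  params <- numeric()
  for (entry in blocks$parameters) {
    ln <- entry$text
    ln <- sub("^[0-9]+\\s+", "", ln)  # optional BNGL index column
    m <- regmatches(ln, regexec(paste0("^(", .name_re, ")\\s*=?\\s*(\\S.*)$"),
                                ln))[[1L]]
    if (length(m) == 0)
      stop("line ", entry$line, ": cannot parse parameter '", ln, "'",
           call. = FALSE)
    val <- safe_eval_expr(gsub("[[:space:]]", "", m[3L]), params,
                          where = paste0("line ", entry$line))
    params[m[2L]] <- val
  }

  types <- list()
  for (entry in blocks$`molecule types`) {
    ln <- sub("^[0-9]+\\s+", "", entry$text)
    # "~a~b" in a declaration lists allowed states; strip for the
    # structural parse, re-extract below
    g <- parse_graph_expr(gsub("~[A-Za-z0-9_]+", "", ln),
                          where = paste0("line ", entry$line))
    if (length(g$mols) != 1L)
      stop("line ", entry$line, ": one molecule type per line", call. = FALSE)
    mol <- g$mols[[1L]]
    comp_names <- vapply(mol$comps, `[[`, "", "name")
    # in a type declaration "~a~b" lists the allowed states; parse_graph_expr
    # keeps only the last "~" token, so re-extract them here
    states <- lapply(strsplit(sub(paste0("^", .name_re, "\\((.*)\\)$"), "\\1",
                                  gsub("[[:space:]]", "", ln)),
                              ",", fixed = TRUE)[[1L]],
                     function(cs) {
                       st <- regmatches(cs, gregexpr("~[A-Za-z0-9_]+", cs))[[1L]]
                       substring(st, 2L)
                     })
    if (!grepl("\\(", ln)) states <- list()
    if (length(states) != length(comp_names))
      stop("line ", entry$line, ": malformed molecule type", call. = FALSE)
    # identically named components must declare identical state sets
    for (nm in unique(comp_names)) {
      ss <- states[comp_names == nm]
      if (length(unique(vapply(ss, paste, "", collapse = "~"))) > 1L)
        stop("line ", entry$line, ": component '", nm,
             "' repeated with different allowed states", call. = FALSE)
    }
    types[[length(types) + 1L]] <-
      list(name = mol$name, comps = comp_names, states = states)
  }

  seeds_raw <- list()
  for (entry in blocks$species) {
    ln <- sub("^[0-9]+\\s+", "", entry$text)
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1L]]
    if (length(m) == 0)
      stop("line ", entry$line, ": species line needs '<graph> <count>'",
           call. = FALSE)
    cnt <- safe_eval_expr(m[3L], params, where = paste0("line ", entry$line))
    if (!is.finite(cnt) || cnt < 0 || abs(cnt - round(cnt)) > 1e-9)
      stop("line ", entry$line, ": seed copy number must be a nonnegative ",
           "integer, got ", m[3L], call. = FALSE)
    seeds_raw[[length(seeds_raw) + 1L]] <-
      list(line = entry$line, expr = m[2L], count = as.integer(round(cnt)))
  }

  rules_raw <- list()
  for (entry in blocks$`reaction rules`) {
    rules_raw[[length(rules_raw) + 1L]] <-
      parse_rule_line(entry$text, params, entry$line)
  }
  obs_raw <- list()
  for (entry in blocks$observables) {
    ln <- sub("^[0-9]+\\s+", "", entry$text)
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) < 3L || !toks[1L] %in% c("Molecules", "Species"))
      stop("line ", entry$line,
           ": observable line needs 'Molecules|Species <name> <pattern>...'",
           call. = FALSE)
    obs_raw[[length(obs_raw) + 1L]] <-
      list(line = entry$line, type = toks[1L], name = toks[2L],
           patterns = toks[-(1:2)])
  }

  actions <- list(t_end = NA_real_, n_report = NA_integer_, seed = NA_integer_)
  all_actions <- c(blocks$actions, loose_actions)
  for (entry in all_actions) {
    ln <- entry$text
    am <- regmatches(ln, regexec(paste0("^(", .name_re, ")\\s*\\(\\{?(.*?)\\}?\\)\\s*;?$"),
                                 ln))[[1L]]
    if (length(am) == 0)
      stop("line ", entry$line, ": cannot parse action '", ln, "'",
           call. = FALSE)
    cmd <- am[2L]
    if (grepl("^simulate", cmd)) {
      for (kv in strsplit(am[3L], ",", fixed = TRUE)[[1L]]) {
        kvm <- regmatches(kv, regexec("^\\s*([A-Za-z_]+)\\s*=>\\s*\"?([^\"]*)\"?\\s*$",
                                      kv))[[1L]]
        if (length(kvm) == 0) next
        key <- kvm[2L]; val <- kvm[3L]
        if (key == "t_end") actions$t_end <- as.numeric(val)
        else if (key %in% c("n_steps", "n_report"))
          actions$n_report <- as.integer(val)
        else if (key == "seed") actions$seed <- as.integer(val)
        # other arguments (method, atol, ...) are accepted and ignored
      }
    } else {
      warning("ignoring unsupported action '", cmd, "' (line ", entry$line,
              ")", call. = FALSE)
    }
  }

  build_model(params, types, seeds_raw, rules_raw, obs_raw, actions)
}

#' Read a BNGL-subset model from a file
#'
#' @param path Path to a `.bngl` file.
#' @return An object of class `rk_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  parse_model(readLines(path, warn = FALSE))
}

# Parse one reaction-rule line into an unexpanded form.
parse_rule_line <- function(text, params, lineno) {
  ln <- trimws(sub("^[0-9]+\\s+", "", trimws(text)))
  # optional "name:" prefix
  name <- NULL
  nm <- regmatches(ln, regexec(paste0("^(", .name_re, ")\\s*:\\s*(.*)$"), ln))[[1L]]
  if (length(nm)) { name <- nm[2L]; ln <- nm[3L] }
  ln <- gsub("\\s*,\\s*", ",", ln)
  toks <- strsplit(ln, "\\s+")[[1L]]
  if (length(toks) < 2L)
    stop("line ", lineno, ": cannot parse rule '", text, "'", call. = FALSE)
  rate_tok <- toks[length(toks)]
  body <- paste(toks[-length(toks)], collapse = " ")
  rev_split <- regmatches(body, regexpr("<->", body, fixed = TRUE))
  reversible <- length(rev_split) > 0L
  arrow <- if (reversible) "<->" else "->"
  sides <- strsplit(body, arrow, fixed = TRUE)[[1L]]
  if (length(sides) != 2L)
    stop("line ", lineno, ": rule must have exactly one '", arrow, "'",
         call. = FALSE)
  rates <- strsplit(rate_tok, ",", fixed = TRUE)[[1L]]
  if (reversible && length(rates) != 2L)
    stop("line ", lineno, ": reversible rule needs two rates 'kf, kr'",
         call. = FALSE)
  if (!reversible && length(rates) != 1L)
    stop("line ", lineno, ": irreversible rule needs exactly one rate",
         call. = FALSE)
  kvals <- vapply(rates, function(r)
    safe_eval_expr(r, params, where = paste0("line ", lineno)), 0)
  if (any(!is.finite(kvals) | kvals < 0))
    stop("line ", lineno, ": rule rate must resolve to a nonnegative real",
         call. = FALSE)
  parse_side <- function(sidetext) {
    pieces <- split_top_level(gsub("[[:space:]]", "", sidetext), "+")
    lapply(pieces, parse_graph_expr, where = paste0("line ", lineno))
  }
  list(line = lineno, name = name, reversible = reversible,
       lhs = parse_side(sides[1L]), rhs = parse_side(sides[2L]),
       k = unname(kvals))
}

#' Expand reversible rule forms
#'
#' Each `<->` form yields two unidirectional rules (forward first, with the
#' first rate; then the reverse with LHS/RHS swapped and the second rate).
#' `->` forms pass through unchanged.  Input order is preserved.
#'
#' @param rules_raw List of parsed rule forms (as produced internally by
#'   [parse_model()]).
#' @return A list of unidirectional rule forms.
#' @export
expand_reversible <- function(rules_raw) {
  out <- list()
  for (r in rules_raw) {
    if (isTRUE(r$reversible)) {
      if (length(r$k) != 2L)
        stop("reversible rule form needs exactly two rates", call. = FALSE)
      fwd <- r; fwd$reversible <- FALSE; fwd$k <- r$k[1L]
      if (!is.null(r$name)) fwd$name <- r$name
      rev <- r; rev$reversible <- FALSE; rev$k <- r$k[2L]
      rev$lhs <- r$rhs; rev$rhs <- r$lhs
      if (!is.null(r$name)) rev$name <- paste0(r$name, "_rev")
      out[[length(out) + 1L]] <- fwd
      out[[length(out) + 1L]] <- rev
    } else {
      if (length(r$k) != 1L)
        stop("irreversible rule form must carry exactly one rate",
             call. = FALSE)
      out[[length(out) + 1L]] <- r
    }
  }
  out
}
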