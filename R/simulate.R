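# Rejection-free network-free simulation loop.  Every step executes one
# real reaction event: waiting times are exponential in the total rate,
# the rule is chosen by a linear scan proportional to cumulative rule
# rates, reactants proportional to reaction-center counts.
#
# RNG deviate-consumption order per event (fixed, for reproducibility):
#   1. waiting time tau
#   2. rule index
#   3. reactant instance(s): one draw per LHS pattern
#   4. reaction center(s): one draw per selected instance

#' Exponential waiting time to the next reaction event
#'
#' @param r_tot Total cumulative rate (sum of all rule rates), must be
#'   positive.
#' @param u Uniform deviate in (0,1).
#' @return Waiting time `log(1/u) / r_tot`.
#' @export
sample_tau <- function(r_tot, u) {
  if (!is.finite(r_tot) || r_tot <= 0)
    stop("sample_tau: r_tot must be positive (no further events)",
         call. = FALSE)
  log(1 / u) / r_tot
}

#' Select the next rule by linear scan
#'
#' Returns the smallest index `I` whose cumulative rate reaches
#' `u * sum(rates)`; rules with zero rate are never selected.
#'
#' @param rates Numeric vector of per-rule cumulative rates.
#' @param u Uniform deviate in (0,1).
#' @return Integer rule index.
#' @export
select_rule <- function(rates, u) {
  tot <- sum(rates)
  if (tot <= 0) stop("select_rule: all rates are zero", call. = FALSE)
  cs <- cumsum(rates)
  i <- which(cs >= u * tot)[1L]
  if (is.na(i)) i <- which(rates > 0)[sum(rates > 0)]
  i
}

#' Initialize a network-free simulation
#'
#' Instantiates the seed species as particle copies, computes every rule's
#' cumulative rate de novo (the only de-novo computation of a run) and the
#' initial observable match numbers.
#'
#' @param model An `rk_model`.
#' @return An environment of class `rk_sim` with fields `st` (state),
#'   `act` (rule activity and observables).
#' @export
nf_init <- function(model) {
  st <- init_state(model)
  act <- init_activity(st)
  sim <- new.env(parent = emptyenv())
  sim$st <- st
  sim$act <- act
  sim$refresh_every <- 1e6   # periodic de-novo safety refresh
  class(sim) <- c("rk_sim", "environment")
  sim
}

#' Execute one reaction event
#'
#' Advances time by an exponential waiting time, selects a rule and
#' reactants, applies the graph rewrite and updates all rule rates and
#' observable match numbers incrementally.  Rejection-free: each call
#' changes the system state and increments the event count by one.
#'
#' @param sim An `rk_sim` environment from [nf_init()].
#' @return Invisibly, the sampled waiting time, or `NA` if the total rate
#'   is zero (absorbing state; nothing happens).
#' @export
nf_step <- function(sim) {
  st <- sim$st; act <- sim$act
  r <- rule_rates(act)
  rtot <- sum(r)
  if (rtot <= 0) return(invisible(NA_real_))
  u <- stats::runif(1L)
  while (u <= 0) u <- stats::runif(1L)
  tau <- sample_tau(rtot, u)
  i <- select_rule(r, stats::runif(1L))
  sel <- select_reactants(st, act, i)
  delta <- apply_rule_event(st, act, i, sel)
  update_activity(st, act, delta$removed, delta$added)
  st$t <- st$t + tau
  st$events <- st$events + 1L
  if (st$events %% sim$refresh_every == 0L) recompute_activity(st, act)
  invisible(tau)
}

#' Run a network-free stochastic simulation
#'
#' Simulates the model from `t = 0` to `t_end`, reporting observables at
#' the requested times.  The value reported at report time `t_r` is the
#' state after the last event at time `<= t_r` (the jump process is
#' right-continuous piecewise-constant).  With a fixed seed the trajectory
#' is reproducible bit for bit.
#'
#' @param model An `rk_model`.
#' @param t_end End time; defaults to the model's simulate action.
#' @param n_report Number of report intervals (report times are
#'   `seq(0, t_end, length.out = n_report + 1)`); defaults to the model's
#'   action block, else 20.
#' @param report_times Explicit report times (overrides `n_report`).
#' @param seed Integer RNG seed; defaults to the model's action block.
#' @param max_events Optional guard on the number of events.
#' @return A `data.frame` of class `nf_trajectory` with column `time` and
#'   one column per observable; attributes `event_count` (reaction events
#'   executed) and `truncated` (`TRUE` if `max_events` was reached before
#'   `t_end`, with remaining report rows frozen at the final state).
#' @examples
#' mdl <- make_dimerization(k_plus = 0.1, k_minus = 1, n0 = 20)
#' tr <- simulate_nf(mdl, t_end = 2, n_report = 10, seed = 1)
#' tr$Dimer
#' @export
simulate_nf <- function(model, t_end = NULL, n_report = NULL,
                        report_times = NULL, seed = NULL,
                        max_events = Inf) {
  if (is.null(t_end)) t_end <- model$actions$t_end
  if (is.null(t_end) || is.na(t_end))
    stop("t_end not given and no simulate action in the model",
         call. = FALSE)
  if (is.null(n_report)) {
    n_report <- model$actions$n_report
    if (is.null(n_report) || is.na(n_report)) n_report <- 20L
  }
  if (is.null(report_times))
    report_times <- seq(0, t_end, length.out = n_report + 1L)
  if (is.unsorted(report_times) || any(report_times < 0) ||
      any(report_times > t_end))
    stop("report_times must be sorted within [0, t_end]", call. = FALSE)
  if (is.null(seed) && !is.na(model$actions$seed))
    seed <- model$actions$seed
  if (!is.null(seed)) set.seed(seed)

  sim <- nf_init(model)
  st <- sim$st; act <- sim$act
  nrep <- length(report_times)
  nobs <- length(act$cobs)
  vals <- matrix(NA_real_, nrep, nobs)
  next_rep <- 1L
  truncated <- FALSE
  record_through <- function(tt) {
    while (next_rep <= nrep && report_times[next_rep] < tt) {
      vals[next_rep, ] <<- act$W
      next_rep <<- next_rep + 1L
    }
  }
  repeat {
    r <- rule_rates(act)
    rtot <- sum(r)
    if (rtot <= 0) {
      record_through(Inf)            # absorbing state: freeze to t_end
      st$t <- t_end
      break
    }
    u <- stats::runif(1L)
    while (u <= 0) u <- stats::runif(1L)
    tau <- sample_tau(rtot, u)
    t_next <- st$t + tau
    if (t_next > t_end) {
      record_through(Inf)
      st$t <- t_end
      break
    }
    record_through(t_next)           # pre-event state for t_r < t_next
    i <- select_rule(r, stats::runif(1L))
    sel <- select_reactants(st, act, i)
    delta <- apply_rule_event(st, act, i, sel)
    update_activity(st, act, delta$removed, delta$added)
    st$t <- t_next
    st$events <- st$events + 1L
    if (st$events %% sim$refresh_every == 0L) recompute_activity(st, act)
    if (st$events >= max_events) {
      record_through(Inf)
      truncated <- TRUE
      warning("max_events reached at t = ", signif(st$t, 6),
              " before t_end", call. = FALSE)
      break
    }
  }
  out <- data.frame(time = report_times)
  for (o in seq_len(nobs)) out[[act$cobs[[o]]$name]] <- vals[, o]
  attr(out, "event_count") <- st$events
  attr(out, "truncated") <- truncated
  attr(out, "final_state") <- st
  class(out) <- c("nf_trajectory", "data.frame")
  out
}

#' @export
print.nf_trajectory <- function(x, ...) {
  cat("network-free trajectory:", nrow(x), "report times,",
      attr(x, "event_count"), "reaction events",
      if (isTRUE(attr(x, "truncated"))) "(truncated)" else "", "\n")
  print.data.frame(utils::head(as.data.frame(x), 12L), ...)
  if (nrow(x) > 12L) cat("...\n")
  invisible(x)
}
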