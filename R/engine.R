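# Generic discrete-time Markov cohort machinery: model containers,
# validation, expected-value propagation, and an individual-level
# Monte-Carlo simulator used as a validation oracle.

#' Construct a discrete-time Markov transition model
#'
#' A transition model is an ordered set of named states together with a
#' per-cycle transition law. Transitions may depend on the cycle index,
#' which is how screening-pattern timing (e.g. biennial mammograms in
#' cycles 1, 3, 5) is encoded.
#'
#' @param states Character vector of unique state names, in order.
#' @param transitions One of: a single square matrix (time-homogeneous),
#'   a list of matrices of length `n_cycles`, or a function
#'   `function(cycle)` returning the transition matrix for that cycle.
#'   Rows index the origin state, columns the destination; each row must
#'   be a probability distribution.
#' @param n_cycles Number of cycles the model is run for.
#' @param absorbing Character vector naming absorbing states. Absorbing
#'   states must map to themselves with probability 1.
#' @param cycle_length Label for the cycle unit, `"year"` or `"month"`.
#'
#' @return An object of class `transition_model` with elements `states`,
#'   `P` (list of transition matrices, one per cycle), `n_cycles`,
#'   `absorbing` and `cycle_length`.
#' @seealso [validate_model()], [run_cohort()], [run_microsim()]
#' @export
transition_model <- function(states, transitions, n_cycles,
                             absorbing = character(),
                             cycle_length = c("year", "month")) {
  cycle_length <- match.arg(cycle_length)
  states <- as.character(states)
  if (anyDuplicated(states)) {
    stop("state names must be unique; duplicated: ",
         paste(unique(states[duplicated(states)]), collapse = ", "))
  }
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (!all(absorbing %in% states)) {
    stop("absorbing states not in state set: ",
         paste(setdiff(absorbing, states), collapse = ", "))
  }

  fix_dimnames <- function(P, cycle) {
    P <- as.matrix(P)
    if (nrow(P) != length(states) || ncol(P) != length(states)) {
      stop("transition matrix for cycle ", cycle, " is ", nrow(P), "x",
           ncol(P), ", expected ", length(states), "x", length(states))
    }
    dimnames(P) <- list(states, states)
    P
  }
  P <- if (is.function(transitions)) {
    lapply(seq_len(n_cycles), function(t) fix_dimnames(transitions(t), t))
  } else if (is.list(transitions)) {
    if (length(transitions) != n_cycles) {
      stop("need one transition matrix per cycle (", n_cycles, "), got ",
           length(transitions))
    }
    lapply(seq_len(n_cycles), function(t) fix_dimnames(transitions[[t]], t))
  } else {
    P1 <- fix_dimnames(transitions, 1L)
    rep(list(P1), n_cycles)
  }

  structure(
    list(states = states, P = P, n_cycles = n_cycles,
         absorbing = absorbing, cycle_length = cycle_length),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> ", length(x$states), " states, ",
      x$n_cycles, " ", x$cycle_length, "-cycles\n", sep = "")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  if (length(x$absorbing)) {
    cat("  absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a transition model
#'
#' Checks every per-cycle transition matrix for negative entries, row
#' sums different from 1, non-self-absorbing states declared absorbing,
#' and (when an initial distribution is supplied) states that can never
#' be occupied. This is a reporting operation: it always returns, and
#' callers decide whether to abort.
#'
#' @param model A [transition_model()].
#' @param initial Optional initial distribution; enables the
#'   unreachable-state check.
#' @param tol Numeric tolerance on row sums. Probabilities supplied by
#'   configuration files are normalised upstream when within `1e-6` of
#'   1; after that, row sums must match 1 to this tolerance.
#' @return An object of class `validation_report`: list with logical
#'   `ok` and a data frame `violations` (columns `type`, `state`,
#'   `cycle`, `detail`).
#' @export
validate_model <- function(model, initial = NULL, tol = 1e-9) {
  stopifnot(inherits(model, "transition_model"))
  v <- list()
  add <- function(type, state, cycle, detail) {
    v[[length(v) + 1L]] <<- data.frame(
      type = type, state = state, cycle = cycle, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  for (t in seq_len(model$n_cycles)) {
    P <- model$P[[t]]
    neg <- which(P < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      for (i in unique(neg[, 1L])) {
        add("negative", model$states[i], t,
            sprintf("negative transition probability from '%s'",
                    model$states[i]))
      }
    }
    rs <- rowSums(P)
    bad <- which(abs(rs - 1) > tol)
    for (i in bad) {
      add("row-sum", model$states[i], t,
          sprintf("row for '%s' sums to %.12f", model$states[i], rs[i]))
    }
    for (a in model$absorbing) {
      if (abs(P[a, a] - 1) > tol) {
        add("absorbing", a, t,
            sprintf("absorbing state '%s' has exit probability %.6g",
                    a, 1 - P[a, a]))
      }
    }
  }
  if (!is.null(initial)) {
    reach <- as.numeric(initial) > 0
    for (t in seq_len(model$n_cycles)) {
      reach <- reach | (colSums(model$P[[t]] * reach) > 0)
    }
    for (s in model$states[!reach]) {
      add("unreachable", s, NA_integer_,
          sprintf("state '%s' has zero occupancy at every cycle", s))
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(), state = character(),
               cycle = integer(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("<validation_report> PASS\n")
  } else {
    cat("<validation_report> FAIL:", nrow(x$violations), "violation(s)\n")
    for (d in x$violations$detail) cat("  -", d, "\n")
  }
  invisible(x)
}

#' Per-state, per-cycle reward schedule
#'
#' Rewards live on independent named channels (e.g. `utility`,
#' `direct_cost`, `days`): evaluating one channel never alters another.
#' State rewards are credited at the end of each cycle to the state then
#' occupied, after that cycle's transition has resolved. Optional
#' transition rewards are one-off adjustments credited per unit of
#' probability flow along a specific transition in a specific cycle
#' (used for treatment disutility and treatment cost in the year of
#' diagnosis).
#'
#' Individuals who move into a death state during a cycle accrue
#' `death_cycle_fraction` of the *origin* state's reward in that cycle,
#' on the channels listed in `death_credit_channels` (by convention the
#' utility channel: someone dying mid-cycle accumulates part of the
#' cycle's quality-adjusted time, while the survival channel counts only
#' completed cycles).
#'
#' @param state_rewards 3-d numeric array `[state, channel, cycle]` with
#'   dimnames, e.g. built with [reward_array()]. A `[state, channel]`
#'   matrix is recycled across cycles.
#' @param transition_rewards `NULL`, or a list of length `n_cycles`
#'   whose element `t` is a named list mapping channel name to an
#'   n-state square matrix of extra reward per unit flow.
#' @param death_states Character vector of states treated as death for
#'   the partial-cycle credit (must be absorbing in the model).
#' @param death_cycle_fraction Fraction in `[0, 1]` of a cycle's reward
#'   accrued in the cycle of death.
#' @param death_credit_channels Channels receiving the partial credit.
#' @return Object of class `reward_schedule`.
#' @export
reward_schedule <- function(state_rewards, transition_rewards = NULL,
                            death_states = "Dead",
                            death_cycle_fraction = 0.5,
                            death_credit_channels = "utility") {
  if (length(dim(state_rewards)) == 2L) {
    state_rewards <- array(
      state_rewards,
      dim = c(dim(state_rewards), 1L),
      dimnames = c(dimnames(state_rewards), list(NULL))
    )
  }
  stopifnot(length(dim(state_rewards)) == 3L)
  if (is.null(dimnames(state_rewards)[[1]]) ||
      is.null(dimnames(state_rewards)[[2]])) {
    stop("state_rewards needs state and channel dimnames")
  }
  if (death_cycle_fraction < 0 || death_cycle_fraction > 1) {
    stop("death_cycle_fraction must lie in [0, 1]")
  }
  channels <- dimnames(state_rewards)[[2]]
  if ("utility" %in% channels) {
    u <- state_rewards[, "utility", , drop = FALSE]
    if (any(u < -1 | u > 1)) {
      stop("utility channel values must lie in [-1, 1] per cycle")
    }
  }
  death_credit_channels <- intersect(death_credit_channels, channels)
  structure(
    list(state_rewards = state_rewards,
         transition_rewards = transition_rewards,
         channels = channels,
         death_states = death_states,
         death_cycle_fraction = death_cycle_fraction,
         death_credit_channels = death_credit_channels),
    class = "reward_schedule"
  )
}

#' Zero-filled reward array
#'
#' @param states,channels Character vectors of dimension names.
#' @param n_cycles Number of cycles.
#' @return A zero array `[state, channel, cycle]` with dimnames.
#' @export
reward_array <- function(states, channels, n_cycles) {
  array(0, dim = c(length(states), length(channels), n_cycles),
        dimnames = list(states, channels, NULL))
}

state_reward_slice <- function(rewards, t) {
  d <- dim(rewards$state_rewards)
  tt <- if (d[3L] == 1L) 1L else t
  matrix(rewards$state_rewards[, , tt], d[1L], d[2L],
         dimnames = dimnames(rewards$state_rewards)[1:2])
}

check_initial <- function(initial, model) {
  if (!is.null(names(initial))) {
    miss <- setdiff(names(initial), model$states)
    if (length(miss)) stop("unknown states in initial: ",
                           paste(miss, collapse = ", "))
    x <- stats::setNames(numeric(length(model$states)), model$states)
    x[names(initial)] <- initial
    initial <- x
  }
  if (length(initial) != length(model$states)) {
    stop("initial distribution has length ", length(initial),
         ", expected ", length(model$states))
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-9) {
    stop("initial must be a probability distribution over states ",
         "(nonnegative, summing to 1)")
  }
  stats::setNames(as.numeric(initial), model$states)
}

#' Run a Markov model as a cohort (expected-value propagation)
#'
#' Propagates the expected state occupancy through the per-cycle
#' transition matrices (no sampling) and accumulates occupancy-weighted
#' state rewards plus flow-weighted transition rewards on every channel.
#' With a survival channel that rewards 1 for every live state at each
#' cycle end, the cumulative total is life expectancy on the 0 to
#' `n_cycles` scale.
#'
#' @param model A [transition_model()]; must pass [validate_model()].
#' @param rewards A [reward_schedule()].
#' @param initial Initial distribution over states (named or positional).
#' @param discount_rate Per-cycle discount rate applied to all channels
#'   (default 0: no discounting).
#' @return Object of class `cohort_trace`: `occupancy` (matrix, row
#'   `cycle 0` = initial distribution), `cycle_rewards` (per-cycle
#'   channel gains), `cumulative` (running totals per channel, row per
#'   cycle starting at 0) and `per_person` (final expectations per
#'   channel).
#' @export
run_cohort <- function(model, rewards, initial, discount_rate = 0) {
  stopifnot(inherits(model, "transition_model"),
            inherits(rewards, "reward_schedule"))
  rep <- validate_model(model)
  if (!rep$ok) {
    stop("invalid model: ", rep$violations$detail[1L],
         if (nrow(rep$violations) > 1L)
           sprintf(" (and %d more)", nrow(rep$violations) - 1L))
  }
  initial <- check_initial(initial, model)

  n <- length(model$states)
  nc <- model$n_cycles
  channels <- rewards$channels
  death_idx <- match(intersect(rewards$death_states, model$states),
                     model$states)
  live_idx <- setdiff(seq_len(n), death_idx)
  frac <- rewards$death_cycle_fraction
  credit_ch <- rewards$death_credit_channels

  occupancy <- matrix(0, nc + 1L, n,
                      dimnames = list(paste0("cycle", 0:nc), model$states))
  occupancy[1L, ] <- initial
  cycle_rewards <- matrix(0, nc, length(channels),
                          dimnames = list(paste0("cycle", 1:nc), channels))

  for (t in seq_len(nc)) {
    P <- model$P[[t]]
    flow <- occupancy[t, ] * P
    occupancy[t + 1L, ] <- colSums(flow)
    R <- state_reward_slice(rewards, t)
    g <- colSums(occupancy[t + 1L, ] * R)
    if (length(death_idx) && frac > 0 && length(credit_ch)) {
      dying <- rowSums(flow[live_idx, death_idx, drop = FALSE])
      for (ch in credit_ch) {
        g[ch] <- g[ch] + frac * sum(dying * R[live_idx, ch])
      }
    }
    tr <- rewards$transition_rewards[[t]]
    for (ch in names(tr)) {
      g[ch] <- g[ch] + sum(flow * tr[[ch]])
    }
    cycle_rewards[t, ] <- g / (1 + discount_rate)^t
  }

  cum <- apply(cycle_rewards, 2L, cumsum)
  if (is.null(dim(cum))) {
    cum <- matrix(cum, nrow = nc, dimnames = list(NULL, channels))
  }
  cumulative <- rbind(0, cum)
  dimnames(cumulative) <- list(paste0("cycle", 0:nc), channels)
  structure(
    list(occupancy = occupancy, cycle_rewards = cycle_rewards,
         cumulative = cumulative,
         per_person = stats::setNames(cumulative[nc + 1L, ], channels),
         states = model$states, channels = channels),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", nrow(x$cycle_rewards), " cycles, ",
      length(x$states), " states\n", sep = "")
  cat("per-person expectations:\n")
  print(round(x$per_person, 6))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  nc <- nrow(x$occupancy)
  data.frame(cycle = 0:(nc - 1L), x$occupancy, x$cumulative,
             check.names = FALSE, row.names = NULL)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle; state-occupancy columns followed by cumulative
#' channel columns.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Individual-level Monte-Carlo simulation of a Markov model
#'
#' Simulates independent trajectories under exactly the same transition
#' and reward law as [run_cohort()], as a validation oracle: sample
#' means estimate the cohort per-person expectations, with standard
#' error = sample SD / sqrt(n). Deterministic given `seed`.
#'
#' @inheritParams run_cohort
#' @param n_individuals Number of trajectories (>= 1).
#' @param seed Integer seed.
#' @return Object of class `microsim_result`: `n_individuals`, `seed`,
#'   `mean` and `se` per channel, and `terminal` (state counts after the
#'   final cycle).
#' @export
run_microsim <- function(model, rewards, initial, n_individuals, seed) {
  stopifnot(inherits(model, "transition_model"),
            inherits(rewards, "reward_schedule"))
  n_individuals <- as.integer(n_individuals)
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  rep <- validate_model(model)
  if (!rep$ok) stop("invalid model: ", rep$violations$detail[1L])
  initial <- check_initial(initial, model)

  set.seed(as.integer(seed))
  n_states <- length(model$states)
  channels <- rewards$channels
  death_idx <- match(intersect(rewards$death_states, model$states),
                     model$states)
  frac <- rewards$death_cycle_fraction
  credit_ch <- rewards$death_credit_channels

  state <- sample.int(n_states, n_individuals, replace = TRUE,
                      prob = initial)
  acc <- matrix(0, n_individuals, length(channels),
                dimnames = list(NULL, channels))

  for (t in seq_len(model$n_cycles)) {
    P <- model$P[[t]]
    nxt <- state
    for (s in unique(state)) {
      row <- P[s, ]
      idx <- which(state == s)
      if (abs(row[s] - 1) < 1e-15) next  # absorbing: stay put
      nxt[idx] <- sample.int(n_states, length(idx), replace = TRUE,
                             prob = row)
    }
    R <- state_reward_slice(rewards, t)
    acc <- acc + R[nxt, , drop = FALSE]
    if (length(death_idx) && frac > 0 && length(credit_ch)) {
      died <- (nxt %in% death_idx) & !(state %in% death_idx)
      if (any(died)) {
        acc[died, credit_ch] <- acc[died, credit_ch] +
          frac * R[state[died], credit_ch, drop = FALSE]
      }
    }
    tr <- rewards$transition_rewards[[t]]
    for (ch in names(tr)) {
      acc[, ch] <- acc[, ch] + tr[[ch]][cbind(state, nxt)]
    }
    state <- nxt
  }

  terminal <- table(factor(model$states[state], levels = model$states))
  structure(
    list(n_individuals = n_individuals, seed = as.integer(seed),
         mean = colMeans(acc),
         se = apply(acc, 2L, stats::sd) / sqrt(n_individuals),
         terminal = terminal),
    class = "microsim_result"
  )
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result> n =", x$n_individuals, " seed =", x$seed, "\n")
  print(data.frame(mean = x$mean, se = x$se))
  invisible(x)
}

# --- path-enumeration helper used by the model builders ----------------

# Builders describe a cycle's dynamics for one origin state as a list of
# paths: each path has a destination, a probability, and optional named
# per-channel extras. This collapses the paths into a transition-matrix
# row plus flow-averaged transition-reward rows (expected extra reward
# per unit of flow into each destination). Averaging over paths sharing
# a destination leaves cohort expectations exact; the micro-simulator
# uses the same averaged law, so the two routes stay comparable.
row_from_paths <- function(paths, states, channels) {
  p <- stats::setNames(numeric(length(states)), states)
  num <- matrix(0, length(states), length(channels),
                dimnames = list(states, channels))
  for (path in paths) {
    if (path$prob < 0) stop("negative path probability")
    if (path$prob == 0) next
    p[path$dest] <- p[path$dest] + path$prob
    ex <- path$extras
    if (!is.null(ex) && length(ex)) {
      num[path$dest, names(ex)] <- num[path$dest, names(ex)] +
        path$prob * ex
    }
  }
  tr <- num
  nz <- p > 0
  tr[nz, ] <- tr[nz, , drop = FALSE] / p[nz]
  tr[!nz, ] <- 0
  list(p = p, tr = tr)
}

path <- function(dest, prob, extras = NULL) {
  list(dest = dest, prob = prob, extras = extras)
}
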