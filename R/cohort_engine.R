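# Monthly Markov cohort simulation with on-/off-treatment strata, transient
# hHF and adverse events, and an absorbing death state split into CV and
# non-CV causes.
#
# Within-cycle order: (1) CV and non-CV death removal per state and stratum;
# (2) transition matrix of the stratum's effective arm among survivors;
# (3) discontinuation flow from the on- to the off-treatment stratum.
# Discontinuers use comparator matrices, risks, adverse-event profile and
# drug cost from the next cycle onward. Transient-event tallies (hHF,
# adverse events) use the cycle-start alive mass net of half the cycle's
# deaths, consistent with the trapezoid half-cycle correction.

#' Stratified cohort distribution
#'
#' @param ps Parameter set (provides state labels).
#' @param arm `"intervention"` (starts 100% on treatment) or `"comparator"`
#'   (no on-treatment stratum, ever).
#' @return List with named alive-mass vectors `on`, `off` and scalars
#'   `dead_cv`, `dead_ncv`; masses sum to 1.
#' @export
initial_distribution <- function(ps, arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  states <- ps$state_space$alive_states
  zero <- stats::setNames(numeric(length(states)), states)
  init <- ps$cohort$initial_distribution[states]
  if (arm == "intervention") {
    list(on = init, off = zero, dead_cv = 0, dead_ncv = 0)
  } else {
    list(on = zero, off = init, dead_cv = 0, dead_ncv = 0)
  }
}

#' Select the transition matrix governing a cycle
#'
#' Periods are contiguous from cycle 1 and the final period is open-ended
#' (months 9+ in the base parameterisation).
#'
#' @param periods One arm's ordered period list (elements with `first`,
#'   `last`, `matrix`).
#' @param cycle_index 1-based month.
#' @return The period's matrix.
#' @export
select_matrix <- function(periods, cycle_index) {
  if (cycle_index < 1) stop("cycle_index must be >= 1", call. = FALSE)
  for (p in periods) {
    if (cycle_index >= p$first && (is.na(p$last) || cycle_index <= p$last))
      return(p$matrix)
  }
  stop("no transition period covers cycle ", cycle_index, call. = FALSE)
}

# Vectorised per-state conditional event probability over one cycle.
cycle_prob_vec <- function(model, cycle_index, treatment, states) {
  co <- model$coefficients
  eta <- co$intercept + treatment * co$treatment + co$state[states]
  g <- model$shape
  dH <- exp(eta) * (cycle_index^g - (cycle_index - 1)^g)
  stats::setNames(1 - exp(-dH), states)
}

hhf_rate_vec <- function(model, treatment, states) {
  co <- model$coefficients
  stats::setNames(exp(co$intercept + treatment * co$treatment + co$state[states]),
                  states)
}

#' Advance the cohort by one cycle
#'
#' Applies death removal, health-state transitions and treatment
#' discontinuation in that order, and tallies expected transient events on
#' the exposure mass (start mass net of half the cycle's deaths).
#'
#' @param dist A stratified distribution (see [initial_distribution()]).
#' @param cycle_index 1-based month.
#' @param ps Parameter set.
#' @param arm The arm being simulated.
#' @return List with `dist` (end-of-cycle distribution) and `tally`:
#'   per-cycle new CV/non-CV deaths, expected hHF admissions, expected
#'   adverse events by type, discontinuation flow, person-time (years), and
#'   start/end occupancy vectors per stratum.
#' @export
step <- function(dist, cycle_index, ps, arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  states <- ps$state_space$alive_states
  age <- ps$cohort$starting_age + (cycle_index - 1) / 12
  q <- life_table_q(ps$life_table, age, ps$cohort$proportion_male)
  lt_floor <- q[["all_cause"]] - q[["cv"]]

  start <- list(on = dist$on, off = dist$off)
  deaths_cv <- deaths_ncv <- 0
  exposure <- list()
  survivors <- list()

  for (stratum in c("on", "off")) {
    mass <- start[[stratum]]
    trt <- if (stratum == "on") 1 else 0
    cv_p <- cycle_prob_vec(ps$survival$cv, cycle_index, trt, states)
    ac_p <- cycle_prob_vec(ps$survival$all_cause, cycle_index, trt, states)
    ncv_p <- pmax(ac_p - cv_p, lt_floor)
    tot <- cv_p + ncv_p
    if (any(tot > 1 + 1e-9)) {
      bad <- states[which(tot > 1 + 1e-9)[1]]
      stop(sprintf("death probabilities sum to %.6f > 1 in state %s, cycle %d",
                   max(tot), bad, cycle_index), call. = FALSE)
    }
    # the life-table floor can push the total over 1 by rounding only
    over <- tot > 1
    if (any(over)) {
      cv_p[over] <- cv_p[over] / tot[over]
      ncv_p[over] <- ncv_p[over] / tot[over]
    }
    d_cv <- mass * cv_p
    d_ncv <- mass * ncv_p
    deaths_cv <- deaths_cv + sum(d_cv)
    deaths_ncv <- deaths_ncv + sum(d_ncv)
    exposure[[stratum]] <- mass - 0.5 * (d_cv + d_ncv)
    survivors[[stratum]] <- mass - d_cv - d_ncv
  }

  # transitions among survivors; on-treatment stratum only exists in the
  # intervention arm and uses that arm's matrices, discontinuers use the
  # comparator's
  M_on <- select_matrix(ps$transitions$intervention, cycle_index)
  M_off <- select_matrix(ps$transitions$comparator, cycle_index)
  end_on <- as.numeric(survivors$on %*% M_on)
  end_off <- as.numeric(survivors$off %*% M_off)
  names(end_on) <- names(end_off) <- states

  # discontinuation flow (post-transition state determines the profile)
  disc_flow <- 0
  if (arm == "intervention" && sum(end_on) > 0) {
    p_disc <- cycle_prob_vec(ps$discontinuation, cycle_index, 1, states)
    flow <- end_on * p_disc
    disc_flow <- sum(flow)
    end_on <- end_on - flow
    end_off <- end_off + flow
  }

  # transient events on exposure mass
  hhf <- sum(exposure$on * hhf_rate_vec(ps$hhf, 1, states)) +
    sum(exposure$off * hhf_rate_vec(ps$hhf, 0, states))
  ae <- sum(exposure$on) * ps$ae$incidence$intervention +
    sum(exposure$off) * ps$ae$incidence$comparator

  alive_start <- sum(start$on) + sum(start$off)
  alive_end <- sum(end_on) + sum(end_off)
  person_time <- (alive_start + alive_end) / 2 / 12

  new_dist <- list(on = end_on, off = end_off,
                   dead_cv = dist$dead_cv + deaths_cv,
                   dead_ncv = dist$dead_ncv + deaths_ncv)
  tally <- list(deaths_cv = deaths_cv, deaths_ncv = deaths_ncv,
                hhf = hhf, ae = ae, discontinuations = disc_flow,
                person_time = person_time, age = age,
                start_on = start$on, start_off = start$off,
                end_on = end_on, end_off = end_off)
  list(dist = new_dist, tally = tally)
}

#' Run the full cohort simulation for one arm
#'
#' Iterates [step()] from the arm's initial distribution until the horizon
#' is reached, the alive mass falls below the stopping tolerance, or the
#' cohort reaches the maximum age — whichever comes first. A hard cap of
#' 2,400 cycles guards against non-termination.
#'
#' @param ps Validated parameter set.
#' @param arm `"intervention"` or `"comparator"`.
#' @return A `hfcem_trace`: per-cycle start/end occupancy matrices by
#'   stratum, new deaths by cause, expected hHF and adverse-event counts,
#'   discontinuations, person-time and cohort age.
#' @export
run_cohort <- function(ps, arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  states <- ps$state_space$alive_states
  ec <- ps$econ
  max_cycles <- if (identical(ec$horizon, "lifetime")) {
    ceiling((ec$max_age - ps$cohort$starting_age) * 12)
  } else {
    as.integer(ec$horizon)
  }
  if (max_cycles > 2400)
    stop("cycle cap exceeded (", max_cycles, " > 2400): check horizon/ages",
         call. = FALSE)

  dist <- initial_distribution(ps, arm)
  tallies <- vector("list", max_cycles)
  k <- 0
  while (k < max_cycles) {
    alive <- sum(dist$on) + sum(dist$off)
    if (alive < ec$alive_tolerance) break
    k <- k + 1
    out <- step(dist, k, ps, arm)
    dist <- out$dist
    tallies[[k]] <- out$tally
  }
  tallies <- tallies[seq_len(k)]

  grab <- function(f) vapply(tallies, function(t) t[[f]], numeric(1))
  grab_vec <- function(f) {
    m <- do.call(rbind, lapply(tallies, `[[`, f))
    colnames(m) <- states
    m
  }
  ae <- do.call(rbind, lapply(tallies, `[[`, "ae"))
  colnames(ae) <- AE_TYPES

  trace <- list(
    arm = arm, states = states, n_cycles = k,
    cycle = seq_len(k), age = grab("age"),
    start_on = grab_vec("start_on"), start_off = grab_vec("start_off"),
    end_on = grab_vec("end_on"), end_off = grab_vec("end_off"),
    deaths_cv = grab("deaths_cv"), deaths_ncv = grab("deaths_ncv"),
    hhf = grab("hhf"), ae = ae,
    discontinuations = grab("discontinuations"),
    person_time = grab("person_time"),
    final_dist = dist
  )
  class(trace) <- "hfcem_trace"
  trace
}

#' @export
print.hfcem_trace <- function(x, ...) {
  cat("<hfcem_trace> arm:", x$arm, "|", x$n_cycles, "cycles |",
      "final alive mass:",
      format(sum(x$final_dist$on) + sum(x$final_dist$off), digits = 4), "\n")
  invisible(x)
}

#' Flatten a cohort trace to a cycle-level data frame
#'
#' One row per cycle: age, per-state start occupancy by stratum, deaths by
#' cause, expected events, discontinuations and person-time. Suitable for
#' CSV export and plotting.
#'
#' @param x A `hfcem_trace`.
#' @param ... Unused.
#' @return A data.frame with `n_cycles` rows.
#' @export
as.data.frame.hfcem_trace <- function(x, ...) {
  df <- data.frame(cycle = x$cycle, age = x$age)
  for (s in x$states) {
    df[[paste0("start_on_", s)]] <- x$start_on[, s]
    df[[paste0("start_off_", s)]] <- x$start_off[, s]
  }
  df$deaths_cv <- x$deaths_cv
  df$deaths_ncv <- x$deaths_ncv
  df$hhf <- x$hhf
  for (a in colnames(x$ae)) df[[paste0("ae_", a)]] <- x$ae[, a]
  df$discontinuations <- x$discontinuations
  df$person_time <- x$person_time
  df
}
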