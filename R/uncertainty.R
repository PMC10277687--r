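# Deterministic (one-way) and probabilistic sensitivity analysis, the
# cost-effectiveness acceptability curve, and scenario runs.

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Each entry is a dotted parameter path (e.g. `"costs.drug.intervention"`)
#' with a low and a high value; the model is re-run in full at each, with
#' everything else at base. Rows are sorted by descending ICER span.
#'
#' @param ps Validated parameter set.
#' @param spec Data frame with columns `path`, `low`, `high` (see
#'   [dsa_default_spec()]); `low <= high` required.
#' @return Data frame `path, low, high, icer_low, icer_high, nmb_low,
#'   nmb_high, span`, sorted by descending span, with the base-case ICER in
#'   attribute `"base_icer"` (and the base NMB in `"base_nmb"`).
#' @export
run_dsa <- function(ps, spec) {
  stopifnot(all(c("path", "low", "high") %in% names(spec)))
  if (any(spec$low > spec$high))
    stop("DSA entries must have low <= high", call. = FALSE)
  base <- run_ce(ps)$ce
  eval_at <- function(path, value) {
    run_ce(ps_set(ps, path, value))$ce
  }
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    lo <- eval_at(spec$path[i], spec$low[i])
    hi <- eval_at(spec$path[i], spec$high[i])
    data.frame(path = spec$path[i], low = spec$low[i], high = spec$high[i],
               icer_low = lo$icer_per_qaly, icer_high = hi$icer_per_qaly,
               nmb_low = lo$nmb, nmb_high = hi$nmb,
               span = abs(hi$icer_per_qaly - lo$icer_per_qaly),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$path, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer_per_qaly
  attr(out, "base_nmb") <- base$nmb
  out
}

#' Default one-way sensitivity ranges
#'
#' Costs are varied by +/-30% (mirroring the drug-cost variation of the
#' deterministic analysis), utilities by +/-20% bounded to [0,1], the
#' treatment effects (log-scale coefficients) of the hHF and CV-death
#' equations by +/-30% on the coefficient scale, and the outcome discount
#' rate from 0 to 5%.
#'
#' @param ps Parameter set supplying the base values.
#' @return A DSA spec data frame.
#' @export
dsa_default_spec <- function(ps) {
  rows <- list()
  add <- function(path, low, high) {
    rows[[length(rows) + 1]] <<- data.frame(path = path, low = low,
                                            high = high,
                                            stringsAsFactors = FALSE)
  }
  for (arm in ARMS) {
    b <- ps$costs$drug[[arm]]
    add(paste0("costs.drug.", arm), 0.7 * b, 1.3 * b)
  }
  for (nm in c("hhf_admission", "cv_death")) {
    b <- ps$costs[[nm]]
    add(paste0("costs.", nm), 0.7 * b, 1.3 * b)
  }
  for (s in ps$state_space$alive_states) {
    b <- ps$utilities$state[[s]]
    add(paste0("utilities.state.", s), max(0, 0.8 * b), min(1, 1.2 * b))
    b <- ps$costs$management[[s]]
    add(paste0("costs.management.", s), 0.7 * b, 1.3 * b)
  }
  b <- ps$utilities$hhf_decrement
  add("utilities.hhf_decrement", 0.8 * b, 1.2 * b)
  for (m in c("hhf.coefficients.treatment", "survival.cv.coefficients.treatment",
              "survival.all_cause.coefficients.treatment")) {
    b <- ps_get(ps, m)
    add(m, min(1.3 * b, 0.7 * b), max(1.3 * b, 0.7 * b))
  }
  add("econ.discount_outcome", 0, 0.05)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- PSA ----------------------------------------------------------------

#' Probabilistic sensitivity analysis specification
#'
#' Distribution families follow decision-model convention for each
#' parameter's support: Dirichlet for transition-matrix rows, beta for
#' probabilities/utilities, gamma for costs, normal for risk-equation
#' coefficients.
#'
#' @param entries List of entries, each a list with `path`, `family`
#'   (`"beta"`, `"gamma"`, `"normal"`, `"lognormal"`, `"dirichlet"`) and a
#'   dispersion hyperparameter: `se` (standard error around the base value)
#'   for the scalar families, `n` (effective sample size) for Dirichlet.
#' @param iterations Number of draws (base 1,000).
#' @param seed RNG seed; together with the spec and parameter set it fully
#'   determines the result.
#' @return A `hfcem_psa_spec` list.
#' @export
psa_spec <- function(entries, iterations = 1000, seed = 1L) {
  stopifnot(iterations >= 1)
  fams <- vapply(entries, `[[`, "", "family")
  bad <- setdiff(fams, c("beta", "gamma", "normal", "lognormal", "dirichlet"))
  if (length(bad))
    stop("unsupported PSA families: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  structure(list(entries = entries, iterations = iterations,
                 seed = as.integer(seed)),
            class = "hfcem_psa_spec")
}

#' Default PSA specification for a parameter set
#'
#' Gamma on all cost scalars (15% relative SE), beta on state utilities
#' (SE 0.04) and adverse-event incidences (30% relative SE), normal on the
#' treatment coefficients of the hHF and death equations (SE 0.05-0.10),
#' gamma on the utility decrements (20% relative SE), and Dirichlet
#' (effective n = 500) on every transition-matrix row of both arms.
#'
#' @param ps Parameter set supplying base values.
#' @param iterations,seed Passed to [psa_spec()].
#' @return A `hfcem_psa_spec`.
#' @export
psa_default_spec <- function(ps, iterations = 1000, seed = 1L) {
  e <- list()
  add <- function(path, family, se = NULL, n = NULL) {
    e[[length(e) + 1]] <<- list(path = path, family = family, se = se, n = n)
  }
  for (arm in ARMS)
    add(paste0("costs.drug.", arm), "gamma", se = 0.15 * ps$costs$drug[[arm]])
  for (nm in c("hhf_admission", "cv_death"))
    add(paste0("costs.", nm), "gamma", se = 0.15 * ps$costs[[nm]])
  for (s in ps$state_space$alive_states) {
    add(paste0("costs.management.", s), "gamma",
        se = 0.15 * ps$costs$management[[s]])
    add(paste0("utilities.state.", s), "beta", se = 0.04)
  }
  add("utilities.hhf_decrement", "gamma",
      se = 0.2 * ps$utilities$hhf_decrement)
  for (arm in ARMS) for (a in AE_TYPES)
    add(sprintf("ae.incidence.%s.%s", arm, a), "beta",
        se = 0.3 * ps$ae$incidence[[arm]][[a]])
  add("hhf.coefficients.treatment", "normal", se = 0.10)
  add("survival.cv.coefficients.treatment", "normal", se = 0.05)
  add("survival.all_cause.coefficients.treatment", "normal", se = 0.05)
  for (arm in ARMS)
    for (p in seq_along(ps$transitions[[arm]]))
      add(sprintf("transitions.%s.%d.matrix", arm, p), "dirichlet", n = 500)
  psa_spec(e, iterations = iterations, seed = seed)
}

# non-scalar path resolution (matrices) for the Dirichlet family
ps_get_node <- function(ps, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- ps
  for (p in parts) {
    idx <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    node <- node[[idx]]
    if (is.null(node))
      stop("cannot resolve path '", path, "' at '", p, "'", call. = FALSE)
  }
  node
}

ps_set_node <- function(ps, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, parts) {
    p <- parts[1]
    idx <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    if (length(parts) == 1) node[[idx]] <- value
    else node[[idx]] <- rec(node[[idx]], parts[-1])
    node
  }
  out <- rec(unclass(ps), parts)
  class(out) <- class(ps)
  out
}

draw_scalar <- function(base, family, se) {
  if (is.null(se) || se == 0) return(base)
  switch(family,
    normal = stats::rnorm(1, base, se),
    lognormal = exp(stats::rnorm(1, log(base), se)),
    gamma = {
      if (base <= 0) return(base)
      shape <- (base / se)^2
      stats::rgamma(1, shape = shape, rate = shape / base)
    },
    beta = {
      if (base <= 0 || base >= 1) return(base)
      v <- se^2
      if (v >= base * (1 - base))
        stop("beta SE implies out-of-support variance for base ", base,
             call. = FALSE)
      k <- base * (1 - base) / v - 1
      stats::rbeta(1, base * k, (1 - base) * k)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Draw one random parameter set
#'
#' Consumes the current RNG state; identical states produce identical
#' draws. Dirichlet entries resample entire transition matrices row-wise
#' (rows stay stochastic by construction); scalar families perturb single
#' leaves around their base values. Zero dispersion reproduces the base
#' value exactly.
#'
#' @param ps Base parameter set.
#' @param spec A `hfcem_psa_spec`.
#' @return A `hfcem_params` draw (not yet validated).
#' @export
sample_draw <- function(ps, spec) {
  out <- ps
  for (ent in spec$entries) {
    if (ent$family == "dirichlet") {
      if (is.null(ent$n) || ent$n <= 0) next
      M <- ps_get_node(ps, ent$path)
      D <- t(apply(M, 1, function(row) rdirichlet_row(pmax(row, 1e-12) * ent$n)))
      dimnames(D) <- dimnames(M)
      out <- ps_set_node(out, ent$path, D)
    } else {
      base <- ps_get(ps, ent$path)
      out <- ps_set(out, ent$path, draw_scalar(base, ent$family, ent$se))
    }
  }
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `spec$iterations` random parameter sets, evaluates the full model
#' for both arms on each, and summarises the incremental cost/QALY cloud:
#' cost-effectiveness-plane quadrant shares, the mean ICER over
#' trade-off draws in the north-east quadrant (with the ratio of means as a
#' companion), and the CEAC over a threshold grid. Draws failing validation
#' are rejected and redrawn (counted in `redraws`). Fully reproducible from
#' `spec$seed`.
#'
#' @param ps Validated base parameter set.
#' @param spec A `hfcem_psa_spec`.
#' @param thresholds Threshold grid for the CEAC (RM/QALY); defaults to 0
#'   to twice the CET in 50 steps.
#' @return A `hfcem_psa_result`: `draws` data frame (`delta_cost`,
#'   `delta_qaly`, `icer`), `quadrant_shares`, `mean_icer_ne`,
#'   `icer_ratio_of_means`, `prob_ce_at_cet`, `ceac` data frame, `redraws`.
#' @export
run_psa <- function(ps, spec, thresholds = NULL) {
  assert_valid(ps)
  if (is.null(thresholds))
    thresholds <- seq(0, 2 * ps$econ$cet, length.out = 51)
  n <- spec$iterations
  dC <- dQ <- numeric(n)
  redraws <- 0
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      repeat {
        draw <- sample_draw(ps, spec)
        if (nrow(validate_parameter_set(draw)) == 0) break
        redraws <- redraws + 1
        if (redraws > 100 * n)
          stop("PSA rejected too many draws; check the spec", call. = FALSE)
      }
      ce <- run_ce(draw)$ce
      dC[i] <- ce$delta_cost
      dQ[i] <- ce$delta_qaly
    }
  })
  draws <- data.frame(draw = seq_len(n), delta_cost = dC, delta_qaly = dQ,
                      icer = ifelse(abs(dQ) > 1e-12, dC / dQ, NA_real_))
  ne <- dC > 0 & dQ > 0
  quadrants <- c(ne = mean(ne), se = mean(dC <= 0 & dQ > 0),
                 nw = mean(dC > 0 & dQ <= 0), sw = mean(dC <= 0 & dQ <= 0))
  cet <- ps$econ$cet
  res <- list(
    draws = draws,
    quadrant_shares = quadrants,
    mean_icer_ne = if (any(ne)) mean(draws$icer[ne]) else NA_real_,
    icer_ratio_of_means = if (abs(mean(dQ)) > 1e-12) mean(dC) / mean(dQ)
                          else NA_real_,
    prob_ce_at_cet = ceac(draws, cet)$probability,
    prob_icer_below_cet_ne = if (any(ne)) mean(draws$icer[ne] < cet)
                             else NA_real_,
    ceac = ceac(draws, thresholds),
    cet = cet, iterations = n, seed = spec$seed, redraws = redraws
  )
  class(res) <- "hfcem_psa_result"
  res
}

#' @export
print.hfcem_psa_result <- function(x, ...) {
  cat("<hfcem_psa_result>", x$iterations, "draws (seed", x$seed, ")\n",
      sprintf("  NE quadrant share %.1f%% | P(cost-effective at CET) %.1f%%\n",
              100 * x$quadrant_shares[["ne"]], 100 * x$prob_ce_at_cet),
      sprintf("  mean NE ICER RM %.0f | ratio of means RM %.0f\n",
              x$mean_icer_ne, x$icer_ratio_of_means))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold `lambda`, the fraction of draws with strictly
#' positive net monetary benefit `lambda * dE - dC`; an NMB of exactly 0
#' counts as not cost-effective.
#'
#' @param draws Data frame with columns `delta_cost` and `delta_qaly`.
#' @param thresholds Numeric threshold grid (RM/QALY).
#' @return Data frame `threshold`, `probability`.
#' @export
ceac <- function(draws, thresholds) {
  if (!nrow(draws)) stop("empty draw set", call. = FALSE)
  prob <- vapply(thresholds, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

# ---- scenarios ----------------------------------------------------------

#' Run a scenario analysis
#'
#' Overrides are applied to a copy of the base parameter set and the full
#' deterministic analysis is re-run. Supported overrides: `state_space =
#' "NYHA"` (requires the `nyha` alternatives block), `horizon_years`
#' (numeric, or `"lifetime"`), `prices` (label into `alternatives$prices`),
#' `starting_age`, `survival_distribution = "exponential"` (requires the
#' `survival_exponential` block).
#'
#' @param ps Validated parameter set carrying the needed alternative blocks.
#' @param scenario Named list of overrides; empty list reproduces the base
#'   case exactly.
#' @return As [run_ce()]: `intervention`, `comparator`, `ce`.
#' @export
run_scenario <- function(ps, scenario = list()) {
  known <- c("state_space", "horizon_years", "prices", "starting_age",
             "survival_distribution")
  bad <- setdiff(names(scenario), known)
  if (length(bad))
    stop("unknown scenario overrides: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(scenario$state_space)) {
    if (!identical(scenario$state_space, "NYHA"))
      stop("only the NYHA state-space override is defined", call. = FALSE)
    ny <- ps$alternatives$nyha
    if (is.null(ny))
      stop("no NYHA alternative block in this parameter set", call. = FALSE)
    ps$state_space <- state_space("NYHA")
    ps$cohort$initial_distribution <- ny$initial_distribution
    ps$transitions <- ny$transitions
    ps$survival <- ny$survival
    ps$hhf <- ny$hhf
    ps$discontinuation <- ny$discontinuation
    ps$utilities$state <- ny$utilities_state
    ps$costs$management <- ny$management
  }
  if (!is.null(scenario$survival_distribution) &&
      !identical(scenario$survival_distribution, "weibull")) {
    if (!identical(scenario$survival_distribution, "exponential"))
      stop("survival_distribution must be 'weibull' or 'exponential'",
           call. = FALSE)
    alt <- ps$alternatives$survival_exponential
    if (is.null(alt))
      stop("no exponential-survival alternative block", call. = FALSE)
    ps$survival <- alt
  }
  if (!is.null(scenario$horizon_years)) {
    ps$econ$horizon <- if (identical(scenario$horizon_years, "lifetime"))
      "lifetime" else as.integer(round(scenario$horizon_years * 12))
  }
  if (!is.null(scenario$prices)) {
    pr <- ps$alternatives$prices[[scenario$prices]]
    if (is.null(pr))
      stop("unknown price set label: ", scenario$prices, call. = FALSE)
    ps <- apply_price_set(ps, pr)
  }
  if (!is.null(scenario$starting_age))
    ps$cohort$starting_age <- scenario$starting_age
  run_ce(ps)
}
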