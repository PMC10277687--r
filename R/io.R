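# Serialisation of parameter sets to/from YAML or JSON, and dotted-path
# access into a parameter set (used by the sensitivity-analysis machinery).

#' Read a parameter set from a YAML or JSON configuration file
#'
#' The format is chosen by extension (`.yaml`/`.yml` or `.json`). The life
#' table may be inline (list of row records) or a path to a CSV file with
#' columns `age, sex, monthly_all_cause_q, monthly_cv_q`, resolved relative
#' to the configuration file. Transition-matrix rows whose sums deviate from
#' 1 by at most 1e-6 are renormalised; larger deviations are treated as data
#' corruption and rejected. Unknown top-level keys are rejected. Defaults
#' (3% discounting, RM 47,439/QALY threshold, 1-month cycles) fill only the
#' optional `econ` fields.
#'
#' @param path Configuration file path.
#' @return A validated `hfcem_params` object.
#' @seealso [write_parameter_set()], [generate_parameter_set()]
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("state_space", "cohort", "transitions", "survival", "hhf",
             "discontinuation", "life_table", "ae", "costs", "utilities",
             "econ", "alternatives")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(setdiff(known, c("econ", "alternatives")), names(raw))
  if (length(miss))
    stop("missing configuration sections: ", paste(miss, collapse = ", "),
         call. = FALSE)

  ss <- state_space(raw$state_space$name)
  states <- ss$alive_states
  ps <- parameter_set(
    state_space = ss,
    cohort = list(
      starting_age = as.numeric(raw$cohort$starting_age),
      proportion_male = as.numeric(raw$cohort$proportion_male),
      initial_distribution = named_numeric(raw$cohort$initial_distribution,
                                           states, "cohort.initial_distribution")
    ),
    transitions = decode_transitions(raw$transitions, states),
    survival = list(
      all_cause = decode_risk_model(raw$survival$all_cause, states),
      cv = decode_risk_model(raw$survival$cv, states)
    ),
    hhf = list(coefficients = decode_coefficients(raw$hhf$coefficients, states)),
    discontinuation = decode_risk_model(raw$discontinuation, states),
    life_table = decode_life_table(raw$life_table, dirname(path)),
    ae = list(incidence = list(
      intervention = named_numeric(raw$ae$incidence$intervention, AE_TYPES,
                                   "ae.incidence.intervention"),
      comparator = named_numeric(raw$ae$incidence$comparator, AE_TYPES,
                                 "ae.incidence.comparator")
    )),
    costs = list(
      drug = named_numeric(raw$costs$drug, ARMS, "costs.drug"),
      hhf_admission = as.numeric(raw$costs$hhf_admission),
      cv_death = as.numeric(raw$costs$cv_death),
      management = decode_management(raw$costs$management, states),
      ae = named_numeric(raw$costs$ae, AE_TYPES, "costs.ae"),
      currency_year = as.integer(raw$costs$currency_year %||% 2021L)
    ),
    utilities = list(
      state = named_numeric(raw$utilities$state, states, "utilities.state"),
      hhf_decrement = as.numeric(raw$utilities$hhf_decrement),
      ae_decrement = named_numeric(raw$utilities$ae_decrement, AE_TYPES,
                                   "utilities.ae_decrement")
    ),
    econ = do.call(econ_settings, lapply(raw$econ %||% list(), unlist_scalar)),
    alternatives = decode_alternatives(raw$alternatives, states)
  )
  assert_valid(ps)
  ps
}

#' Write a parameter set to a YAML or JSON configuration file
#'
#' Writes the documented schema with full numeric precision so that
#' `load_parameter_set(write_parameter_set(ps, f))` reproduces `ps`
#' field-for-field (write -> read idempotence). The life table is inlined.
#'
#' @param ps A `hfcem_params` object.
#' @param path Destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  raw <- encode_parameter_set(ps)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  } else {
    writeLines(yaml::as.yaml(raw, precision = 15), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unlist_scalar <- function(x) if (is.list(x)) unlist(x) else x

named_numeric <- function(x, expected, where) {
  x <- unlist(x)
  miss <- setdiff(expected, names(x))
  if (length(miss))
    stop(where, ": missing entries ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- as.numeric(x[expected])
  names(out) <- expected
  out
}

decode_coefficients <- function(co, states) {
  list(intercept = as.numeric(co$intercept %||% 0),
       treatment = as.numeric(co$treatment %||% 0),
       state = named_numeric(co$state, states, "coefficients.state"))
}

decode_risk_model <- function(m, states) {
  risk_model(distribution = m$distribution, shape = as.numeric(m$shape %||% 1),
             intercept = as.numeric(m$coefficients$intercept %||% 0),
             treatment = as.numeric(m$coefficients$treatment %||% 0),
             state = named_numeric(m$coefficients$state, states,
                                   "coefficients.state"))
}

decode_transitions <- function(tr, states) {
  out <- list()
  for (arm in ARMS) {
    periods <- tr[[arm]]
    if (is.null(periods)) stop("transitions missing arm: ", arm, call. = FALSE)
    out[[arm]] <- lapply(seq_along(periods), function(i) {
      p <- periods[[i]]
      M <- do.call(rbind, lapply(p$matrix, function(r) as.numeric(unlist(r))))
      dimnames(M) <- list(states, states)
      rs <- rowSums(M)
      bad <- which(abs(rs - 1) > 1e-6)
      if (length(bad))
        stop(sprintf("transitions.%s period %d row %d (%s) sums to %.8f",
                     arm, i, bad[1], states[bad[1]], rs[bad[1]]),
             call. = FALSE)
      M <- M / rs  # renormalise away rounding noise <= 1e-6
      last <- p$last
      list(first = as.integer(p$first),
           last = if (is.null(last) || is.na(last)) NA_integer_
                  else as.integer(last),
           matrix = M)
    })
  }
  out
}

decode_life_table <- function(lt, base_dir) {
  if (is.character(lt) && length(lt) == 1) {
    f <- if (file.exists(lt)) lt else file.path(base_dir, lt)
    if (!file.exists(f)) stop("life-table CSV not found: ", lt, call. = FALSE)
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(lt, function(r) as.data.frame(r,
                                                              stringsAsFactors = FALSE)))
  }
  df$age <- as.integer(df$age)
  df <- df[order(df$sex, df$age), c("age", "sex", "monthly_all_cause_q",
                                    "monthly_cv_q")]
  rownames(df) <- NULL
  df
}

decode_management <- function(m, states) {
  m <- unlist(m)
  if (length(m) == 1 && is.null(names(m))) {
    out <- rep(as.numeric(m), length(states))
    names(out) <- states
    out
  } else {
    named_numeric(m, states, "costs.management")
  }
}

decode_alternatives <- function(alt, states) {
  if (is.null(alt)) return(list())
  out <- list()
  if (!is.null(alt$prices))
    out$prices <- lapply(alt$prices, function(p) named_numeric(p, ARMS,
                                                               "alternatives.prices"))
  if (!is.null(alt$survival_exponential))
    out$survival_exponential <- list(
      all_cause = decode_risk_model(alt$survival_exponential$all_cause, states),
      cv = decode_risk_model(alt$survival_exponential$cv, states)
    )
  if (!is.null(alt$nyha)) {
    nst <- state_space("NYHA")$alive_states
    out$nyha <- list(
      initial_distribution = named_numeric(alt$nyha$initial_distribution, nst,
                                           "alternatives.nyha.initial_distribution"),
      transitions = decode_transitions(alt$nyha$transitions, nst),
      survival = list(all_cause = decode_risk_model(alt$nyha$survival$all_cause, nst),
                      cv = decode_risk_model(alt$nyha$survival$cv, nst)),
      hhf = list(coefficients = decode_coefficients(alt$nyha$hhf$coefficients, nst)),
      discontinuation = decode_risk_model(alt$nyha$discontinuation, nst),
      utilities_state = named_numeric(alt$nyha$utilities_state, nst,
                                      "alternatives.nyha.utilities_state"),
      management = decode_management(alt$nyha$management, nst)
    )
  }
  out
}

encode_risk_model <- function(m) {
  list(distribution = m$distribution, shape = m$shape,
       coefficients = list(intercept = m$coefficients$intercept,
                           treatment = m$coefficients$treatment,
                           state = as.list(m$coefficients$state)))
}

encode_transitions <- function(tr) {
  lapply(tr, function(periods) lapply(periods, function(p) {
    list(first = p$first, last = if (is.na(p$last)) NULL else p$last,
         matrix = lapply(seq_len(nrow(p$matrix)),
                         function(i) as.list(unname(p$matrix[i, ]))))
  }))
}

encode_parameter_set <- function(ps) {
  lt <- ps$life_table
  alt <- list()
  if (!is.null(ps$alternatives$prices))
    alt$prices <- lapply(ps$alternatives$prices, as.list)
  if (!is.null(ps$alternatives$survival_exponential))
    alt$survival_exponential <- lapply(ps$alternatives$survival_exponential,
                                       encode_risk_model)
  if (!is.null(ps$alternatives$nyha)) {
    ny <- ps$alternatives$nyha
    alt$nyha <- list(
      initial_distribution = as.list(ny$initial_distribution),
      transitions = encode_transitions(ny$transitions),
      survival = lapply(ny$survival, encode_risk_model),
      hhf = list(coefficients = list(
        intercept = ny$hhf$coefficients$intercept,
        treatment = ny$hhf$coefficients$treatment,
        state = as.list(ny$hhf$coefficients$state))),
      discontinuation = encode_risk_model(ny$discontinuation),
      utilities_state = as.list(ny$utilities_state),
      management = as.list(ny$management)
    )
  }
  list(
    state_space = list(name = ps$state_space$name),
    cohort = list(starting_age = ps$cohort$starting_age,
                  proportion_male = ps$cohort$proportion_male,
                  initial_distribution = as.list(ps$cohort$initial_distribution)),
    transitions = encode_transitions(ps$transitions),
    survival = lapply(ps$survival, encode_risk_model),
    hhf = list(coefficients = list(
      intercept = ps$hhf$coefficients$intercept,
      treatment = ps$hhf$coefficients$treatment,
      state = as.list(ps$hhf$coefficients$state))),
    discontinuation = encode_risk_model(ps$discontinuation),
    life_table = lapply(seq_len(nrow(lt)), function(i)
      list(age = lt$age[i], sex = lt$sex[i],
           monthly_all_cause_q = lt$monthly_all_cause_q[i],
           monthly_cv_q = lt$monthly_cv_q[i])),
    ae = list(incidence = lapply(ps$ae$incidence, as.list)),
    costs = list(drug = as.list(ps$costs$drug),
                 hhf_admission = ps$costs$hhf_admission,
                 cv_death = ps$costs$cv_death,
                 management = as.list(ps$costs$management),
                 ae = as.list(ps$costs$ae),
                 currency_year = ps$costs$currency_year),
    utilities = list(state = as.list(ps$utilities$state),
                     hhf_decrement = ps$utilities$hhf_decrement,
                     ae_decrement = as.list(ps$utilities$ae_decrement)),
    econ = ps$econ,
    alternatives = alt
  )
}

# ---- dotted-path access -------------------------------------------------

# Resolve "costs.drug.intervention"-style paths into nested lists / named
# vectors. The final component must address a numeric scalar.
ps_get <- function(ps, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- ps
  for (p in parts) {
    idx <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    if (is.list(node)) {
      if (is.character(idx) && !idx %in% names(node))
        stop("cannot resolve path '", path, "' at '", p, "'", call. = FALSE)
      node <- node[[idx]]
    } else if (is.numeric(node) && !is.null(names(node)) && is.character(idx)) {
      if (!idx %in% names(node))
        stop("cannot resolve path '", path, "' at '", p, "'", call. = FALSE)
      node <- node[[idx]]
    } else {
      stop("cannot resolve path '", path, "' at '", p, "'", call. = FALSE)
    }
    if (is.null(node))
      stop("cannot resolve path '", path, "' at '", p, "'", call. = FALSE)
  }
  if (!is.numeric(node) || length(node) != 1)
    stop("path '", path, "' does not address a numeric scalar", call. = FALSE)
  as.numeric(node)
}

ps_set <- function(ps, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  ps_get(ps, path)  # existence + scalar check
  rec <- function(node, parts) {
    p <- parts[1]
    idx <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    if (length(parts) == 1) {
      node[[idx]] <- value
    } else {
      node[[idx]] <- rec(node[[idx]], parts[-1])
    }
    node
  }
  out <- rec(unclass(ps), parts)
  class(out) <- class(ps)
  out
}
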