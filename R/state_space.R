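#' Health-state spaces
#'
#' A state space is an ordered set of alive health states plus a single
#' absorbing dead state. Two spaces are built in: KCCQ-CSS quartiles
#' (Q1 0-54, Q2 55-74, Q3 75-89, Q4 90-100 -- higher score, less disease
#' burden) and NYHA functional classes (I, II, III/IV, with III and IV
#' pooled). Alive states are ordered from most to least severe.
#'
#' @param name `"KCCQ-CSS"` or `"NYHA"`.
#' @return An object of class `hfcem_state_space`: a list with `name`,
#'   `alive_states` (character), `bounds` (data.frame of score bounds, KCCQ
#'   only), and `dead_state`.
#' @export
#' @examples
#' state_space("KCCQ-CSS")$alive_states
state_space <- function(name = c("KCCQ-CSS", "NYHA")) {
  name <- match.arg(name)
  if (name == "KCCQ-CSS") {
    ss <- list(
      name = name,
      alive_states = c("Q1", "Q2", "Q3", "Q4"),
      bounds = data.frame(
        state = c("Q1", "Q2", "Q3", "Q4"),
        lower = c(0, 55, 75, 90),
        upper = c(54, 74, 89, 100),
        stringsAsFactors = FALSE
      ),
      dead_state = "Dead"
    )
  } else {
    ss <- list(
      name = name,
      alive_states = c("I", "II", "III_IV"),
      bounds = NULL,
      dead_state = "Dead"
    )
  }
  class(ss) <- "hfcem_state_space"
  ss
}

#' Build a non-standard state space
#'
#' For reduced or experimental state structures (e.g. a two-alive-state
#' toy model used in validation); the built-in KCCQ-CSS and NYHA spaces
#' come from [state_space()].
#'
#' @param alive_states Ordered character vector (length >= 2), most to
#'   least severe.
#' @param dead_state Label of the absorbing state.
#' @param name Display name.
#' @return An `hfcem_state_space`.
#' @export
custom_state_space <- function(alive_states, dead_state = "Dead",
                               name = "custom") {
  ss <- list(name = name, alive_states = alive_states, bounds = NULL,
             dead_state = dead_state)
  class(ss) <- "hfcem_state_space"
  ss
}

#' @export
print.hfcem_state_space <- function(x, ...) {
  cat("<hfcem_state_space> ", x$name, ": ",
      paste(x$alive_states, collapse = " < "),
      " | ", x$dead_state, "\n", sep = "")
  invisible(x)
}

n_alive <- function(ss) length(ss$alive_states)

# Internal: structural checks, returning violation rows (see validate_parameter_set)
check_state_space <- function(ss, where = "state_space") {
  v <- violations()
  if (length(ss$alive_states) < 2)
    v <- add_violation(v, "state_space/too_few_alive", where,
                       "need at least 2 alive states")
  if (!is.character(ss$dead_state) || length(ss$dead_state) != 1)
    v <- add_violation(v, "state_space/dead_state", where,
                       "exactly one absorbing dead state required")
  if (anyDuplicated(c(ss$alive_states, ss$dead_state)))
    v <- add_violation(v, "state_space/duplicate_labels", where,
                       "state labels must be unique")
  if (!is.null(ss$bounds)) {
    b <- ss$bounds[order(ss$bounds$lower), , drop = FALSE]
    covered <- b$lower[1] == 0 && b$upper[nrow(b)] == 100 &&
      all(b$lower[-1] == b$upper[-nrow(b)] + 1)
    if (!covered)
      v <- add_violation(v, "state_space/bounds", where,
                         "score bounds must be disjoint and cover 0-100")
  }
  v
}
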