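## Cell state codes.  0 = empty substrate; 1 = exponential growth;
## 2 = early stationary (elevated quorum production, aging towards maturity);
## 3 = mature stationary (odor production, absorbing); 4 = refractory growth
## (odor-triggered, quorum-insensitive, signal-silent).

#' Cell state codes of the colony automaton
#'
#' Integer codes used in state vectors and serialized traces, named by the
#' phase they denote: `EMPTY = 0`, `S1_EXPONENTIAL = 1`,
#' `S2_EARLY_STATIONARY = 2`, `S3_MATURE_STATIONARY = 3`,
#' `S4_REFRACTORY = 4`.
#'
#' @format A named integer vector of length 5.
#' @export
CELL_STATES <- c(EMPTY = 0L, S1_EXPONENTIAL = 1L, S2_EARLY_STATIONARY = 2L,
                 S3_MATURE_STATIONARY = 3L, S4_REFRACTORY = 4L)

#' Construct a dish snapshot
#'
#' A `colony_state` is a full snapshot of the simulated dish: per-site layer
#' thickness, cell state and stationary age, the per-site substrate quorum
#' concentration, the single global odor level, and the generation counter.
#'
#' @param thickness Integer vector of bacteria counts per site (`0..N`).
#' @param state Integer vector of cell state codes (see [CELL_STATES]).
#' @param age Numeric vector of generations spent in early stationary phase;
#'   `NA` wherever the site is not in state 2.  Defaults to 0 for state-2
#'   sites and `NA` elsewhere.
#' @param quorum Numeric vector of per-site quorum concentrations
#'   (default all zero).
#' @param odor Single nonnegative odor level shared by all sites (default 0).
#' @param generation Generation counter (default 0).
#'
#' @return An object of class `colony_state`.
#' @seealso [build_inoculum()] for constructing inocula from geometry specs.
#' @export
colony_state <- function(thickness, state, age = NULL, quorum = NULL,
                         odor = 0, generation = 0L) {
  L <- length(thickness)
  if (is.null(quorum)) quorum <- numeric(L)
  if (is.null(age)) age <- ifelse(state == 2L, 0, NA_real_)
  st <- structure(list(generation = as.integer(generation),
                       thickness = as.numeric(thickness),
                       state = as.integer(state),
                       age = as.numeric(age),
                       quorum = as.numeric(quorum),
                       odor = as.numeric(odor)),
                  class = "colony_state")
  validate_state(st)
  st
}

## Structural validation; `params` adds the thickness <= N check.
validate_state <- function(s, params = NULL) {
  L <- length(s$thickness)
  for (f in c("state", "age", "quorum"))
    if (length(s[[f]]) != L)
      stop("malformed state: field '", f, "' has length ", length(s[[f]]),
           " but 'thickness' has length ", L, call. = FALSE)
  if (length(s$odor) != 1L || !is.finite(s$odor) || s$odor < 0)
    stop("malformed state: field 'odor' must be a single nonnegative finite number",
         call. = FALSE)
  if (any(!is.finite(s$quorum)) || any(s$quorum < 0))
    stop("malformed state: field 'quorum' has negative or non-finite entries",
         call. = FALSE)
  if (any(s$thickness < 0))
    stop("malformed state: field 'thickness' has negative entries", call. = FALSE)
  if (!all(s$state %in% 0:4))
    stop("malformed state: field 'state' has codes outside 0..4", call. = FALSE)
  if (any((s$thickness == 0) != (s$state == 0L)))
    stop("malformed state: 'thickness' is zero exactly where 'state' is EMPTY",
         call. = FALSE)
  if (any(is.na(s$age) != (s$state != 2L)))
    stop("malformed state: 'age' must be defined exactly at state-2 sites",
         call. = FALSE)
  if (any(!is.na(s$age) & s$age < 0))
    stop("malformed state: field 'age' has negative entries", call. = FALSE)
  if (!is.null(params) && any(s$thickness > params$N))
    stop("malformed state: field 'thickness' exceeds N = ", params$N,
         call. = FALSE)
  invisible(s)
}

#' @export
print.colony_state <- function(x, ...) {
  occ <- x$state != 0L
  cat(sprintf("Colony automaton state: generation %d, %d/%d sites occupied\n",
              x$generation, sum(occ), length(x$thickness)))
  cat(sprintf("  biomass %g, peak thickness %g, total quorum %g, odor %g\n",
              sum(x$thickness), max(x$thickness), sum(x$quorum), x$odor))
  tab <- table(factor(x$state[occ], levels = 1:4,
                      labels = names(CELL_STATES)[2:5]))
  if (any(occ))
    cat("  states: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
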