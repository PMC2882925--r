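#' Evaluate cell states against signals, age and thickness
#'
#' Step (1) of the generation loop.  Every occupied site is re-evaluated
#' synchronously against the same pre-step snapshot; only `state` and `age`
#' change — thickness and both signals are untouched.
#'
#' Transition rules, in precedence order per site:
#' \enumerate{
#'   \item Growing (state 1) or early-stationary (state 2) cells at odor
#'     `>= Olim1` become refractory (state 4).  Refractory cells no longer
#'     respond to the quorum signal, so this check precedes the quorum check.
#'   \item State-1 cells at quorum `>= Qlim`, or at maximum thickness `N`,
#'     enter early stationary phase (state 2) with age 0.
#'   \item State-2 cells with age `>= A` mature (state 3); otherwise age
#'     increments by one.
#'   \item State-4 cells at odor `>= Olim2`, or at maximum thickness `N`,
#'     mature (state 3).
#'   \item State 3 is absorbing; empty sites are untouched.
#' }
#'
#' @param state A [colony_state()].
#' @param params A [colony_params()].
#' @return The updated `colony_state`.
#' @export
evaluate_states <- function(state, params) {
  validate_state(state, params)
  st <- state$state
  th <- state$thickness
  to_s4     <- (st == 1L | st == 2L) & state$odor >= params$Olim1
  to_s2     <- st == 1L & !to_s4 & (state$quorum >= params$Qlim | th >= params$N)
  s2_mature <- st == 2L & !to_s4 & state$age >= params$A
  s2_stay   <- st == 2L & !to_s4 & state$age < params$A
  s4_mature <- st == 4L & (state$odor >= params$Olim2 | th >= params$N)

  new_st <- st
  new_st[to_s4] <- 4L
  new_st[to_s2] <- 2L
  new_st[s2_mature | s4_mature] <- 3L

  new_age <- rep(NA_real_, length(st))
  new_age[to_s2] <- 0
  new_age[s2_stay] <- state$age[s2_stay] + 1

  state$state <- new_st
  state$age <- new_age
  state
}

#' Divide growing cells and colonize adjacent empty sites
#'
#' Step (2) of the generation loop.  Growing sites (states 1 and 4) double
#' their thickness, capped at `N`; non-growing sites are unchanged.  Then
#' every empty site adjacent to at least one growing occupied site receives
#' exactly one daughter bacterium and adopts the colonizer's state, provided
#' the diffusible-limitation check passes at the empty site: a
#' quorum-sensitive (state 1) colonizer is blocked when the target's quorum
#' is `>= Qlim`; a refractory (state 4) colonizer ignores quorum but is
#' blocked when odor is `>= Olim2`.  When both neighbors could colonize, the
#' left neighbor donates (deterministic tie-break).  Donors lose one
#' bacterium per exported daughter, never dropping below thickness 1
#' (disable via the `decrement_donor` parameter).
#'
#' @inheritParams evaluate_states
#' @return The updated `colony_state`.
#' @export
divide_and_migrate <- function(state, params) {
  validate_state(state, params)
  st <- state$state
  th <- state$thickness
  L <- length(st)

  growing <- st == 1L | st == 4L
  th[growing] <- pmin(2 * th[growing], params$N)

  ## Colonization: targets are the sites empty *before* this step, so newly
  ## seeded sites cannot chain within one generation (synchronous update).
  can_donate <- function(j, i) {
    # site j colonizes empty site i if growing and not signal-blocked at i
    growing[j] & (
      (st[j] == 1L & state$quorum[i] < params$Qlim) |
      (st[j] == 4L & state$odor < params$Olim2))
  }
  empty <- which(st == 0L)
  if (length(empty)) {
    left  <- empty - 1L
    right <- empty + 1L
    from_left  <- left >= 1L  & can_donate(pmax(left, 1L), empty)
    from_right <- right <= L & can_donate(pmin(right, L), empty)
    donor <- ifelse(from_left, left, ifelse(from_right, right, NA_integer_))
    seeded <- empty[!is.na(donor)]
    donor <- donor[!is.na(donor)]
    if (length(seeded)) {
      th[seeded] <- 1
      st[seeded] <- st[donor]
      if (params$decrement_donor) {
        exports <- table(donor)
        j <- as.integer(names(exports))
        th[j] <- pmax(th[j] - as.integer(exports), 1)
      }
    }
  }

  state$thickness <- th
  state$state <- st
  state
}

#' Produce quorum and odor signals
#'
#' Step (3) of the generation loop.  State-1 sites add `P * thickness` to
#' their local quorum; state-2 sites add `S * P * thickness`; state-3 sites
#' jointly add `O * total state-3 thickness` to the global odor pool.
#' Refractory (state 4) and empty sites produce nothing.  Neither signal
#' decays.
#'
#' @inheritParams evaluate_states
#' @return The updated `colony_state`.
#' @export
produce_signals <- function(state, params) {
  validate_state(state, params)
  st <- state$state
  th <- state$thickness
  q <- state$quorum
  s1 <- st == 1L
  s2 <- st == 2L
  q[s1] <- q[s1] + params$P * th[s1]
  q[s2] <- q[s2] + params$S * params$P * th[s2]
  state$quorum <- q
  state$odor <- state$odor + params$O * sum(th[st == 3L])
  state
}

#' Diffuse the quorum signal along the lattice
#'
#' Step (4) of the generation loop: `G` iterations of an explicit pairwise
#' exchange.  Each iteration moves a fraction `D` of the concentration
#' difference between every adjacent pair down the gradient, with all fluxes
#' computed from the iteration's starting values and applied simultaneously.
#' The dish walls are zero-flux: boundary sites exchange only with their
#' single interior neighbor.  Total quorum is conserved exactly up to
#' floating-point roundoff; for `D <= 0.5` the scheme is monotone (the field
#' maximum never increases, the minimum never decreases).
#'
#' @param quorum Numeric vector of nonnegative per-site concentrations.
#' @param params A [colony_params()] (uses `D` and `G`).
#' @return The diffused concentration vector.
#' @examples
#' p <- colony_params(Qlim = 1, Olim1 = 1, Olim2 = 1, G = 1)
#' diffuse_quorum(c(1, 0), p)  # 0.505 0.495
#' @export
diffuse_quorum <- function(quorum, params) {
  if (params$D > 0.5 || params$D < 0)
    stop("parameter 'D' must lie in [0, 0.5]", call. = FALSE)
  if (any(!is.finite(quorum)) || any(quorum < 0))
    stop("malformed state: field 'quorum' has negative or non-finite entries",
         call. = FALSE)
  q <- quorum
  if (length(q) < 2L || params$D == 0) return(q)
  for (k in seq_len(params$G)) {
    flux <- -params$D * diff(q)     # flux[i]: amount moved from site i to i+1
    # net inflow per site is formed before the update so that mirrored
    # fields diffuse bit-identically
    q <- q + (c(0, flux) - c(flux, 0))
  }
  q
}

#' Advance the automaton by one generation
#'
#' Applies the four steps in their fixed order — state evaluation, division
#' and migration, signal production, quorum diffusion — and increments the
#' generation counter.
#'
#' @inheritParams evaluate_states
#' @return The `colony_state` one generation later.
#' @seealso [run_simulation()] for full runs with trace recording.
#' @export
step_generation <- function(state, params) {
  state <- evaluate_states(state, params)
  state <- divide_and_migrate(state, params)
  state <- produce_signals(state, params)
  state$quorum <- diffuse_quorum(state$quorum, params)
  state$generation <- state$generation + 1L
  state
}
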