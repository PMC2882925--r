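# Naive, obviously-correct transcription of one full generation of the
# automaton: scalar loops, one site at a time, no vectorization.  Kept
# deliberately independent of the package's optimized step so it can serve
# as an oracle.

naive_generation <- function(state, params) {
  L <- length(state$thickness)

  # (1) state evaluation, all sites against the same starting snapshot
  old <- state
  for (i in seq_len(L)) {
    st <- old$state[i]
    if (st == 0L) next
    if ((st == 1L || st == 2L) && old$odor >= params$Olim1) {
      state$state[i] <- 4L
      state$age[i] <- NA_real_
    } else if (st == 1L &&
               (old$quorum[i] >= params$Qlim || old$thickness[i] >= params$N)) {
      state$state[i] <- 2L
      state$age[i] <- 0
    } else if (st == 2L) {
      if (old$age[i] >= params$A) {
        state$state[i] <- 3L
        state$age[i] <- NA_real_
      } else {
        state$age[i] <- old$age[i] + 1
      }
    } else if (st == 4L &&
               (old$odor >= params$Olim2 || old$thickness[i] >= params$N)) {
      state$state[i] <- 3L
    }
  }

  # (2) division, then colonization of pre-step empty sites
  for (i in seq_len(L))
    if (state$state[i] == 1L || state$state[i] == 4L)
      state$thickness[i] <- min(2 * state$thickness[i], params$N)
  pre_st <- state$state
  pre_th <- state$thickness
  for (i in seq_len(L)) {
    if (pre_st[i] != 0L) next
    donor <- NA_integer_
    for (j in c(i - 1L, i + 1L)) {          # left neighbor gets first refusal
      if (j < 1L || j > L) next
      if (pre_st[j] != 1L && pre_st[j] != 4L) next
      blocked <- if (pre_st[j] == 1L) state$quorum[i] >= params$Qlim
                 else state$odor >= params$Olim2
      if (!blocked) { donor <- j; break }
    }
    if (!is.na(donor)) {
      state$thickness[i] <- 1
      state$state[i] <- pre_st[donor]
      if (params$decrement_donor)
        state$thickness[donor] <- max(state$thickness[donor] - 1, 1)
    }
  }

  # (3) signal production
  s3_total <- 0
  for (i in seq_len(L)) {
    if (state$state[i] == 1L)
      state$quorum[i] <- state$quorum[i] + params$P * state$thickness[i]
    else if (state$state[i] == 2L)
      state$quorum[i] <- state$quorum[i] + params$S * params$P * state$thickness[i]
    else if (state$state[i] == 3L)
      s3_total <- s3_total + state$thickness[i]
  }
  state$odor <- state$odor + params$O * s3_total

  # (4) nested diffusion: all pairwise fluxes from the iteration's starting
  # values, then the net change applied per site
  q <- state$quorum
  for (it in seq_len(params$G)) {
    f <- numeric(L + 1L)                  # f[i]: flux from site i-1 into site i
    for (i in seq_len(L - 1L))
      f[i + 1L] <- params$D * (q[i] - q[i + 1L])
    qn <- q
    for (i in seq_len(L))
      qn[i] <- q[i] + (f[i] - f[i + 1L])
    q <- qn
  }
  state$quorum <- q

  state$generation <- state$generation + 1L
  state
}

# Random well-formed small states and parameter sets for property tests.
random_params <- function(L = sample(3:30, 1)) {
  o1 <- stats::runif(1, 0, 5)
  colony_params(
    N = sample(c(4, 16, 140), 1),
    P = 1, S = 10,
    A = sample(0:5, 1),
    O = 0.01,
    D = stats::runif(1, 0, 0.5),
    G = sample(1:5, 1),
    Qlim = stats::runif(1, 0, 50),
    Olim1 = o1,
    Olim2 = o1 + stats::runif(1, 0, 5),
    L = L, max_generations = 100)
}

random_state <- function(params) {
  L <- params$L
  th <- sample(0:params$N, L, replace = TRUE) *
    sample(0:1, L, replace = TRUE, prob = c(0.3, 0.7))
  st <- integer(L)
  occ <- th > 0
  st[occ] <- sample(1:4, sum(occ), replace = TRUE)
  age <- ifelse(st == 2L, sample(0:6, L, replace = TRUE), NA_real_)
  colony_state(th, st, age = age,
               quorum = stats::runif(L, 0, 60),
               odor = stats::runif(1, 0, 8))
}

# Strip class/attributes for bit-exact comparison of state components.
state_fields <- function(s) {
  list(generation = as.integer(s$generation),
       thickness = as.numeric(s$thickness),
       state = as.integer(s$state),
       age = as.numeric(s$age),
       quorum = as.numeric(s$quorum),
       odor = as.numeric(s$odor))
}
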