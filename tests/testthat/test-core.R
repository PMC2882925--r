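# Per-step behavior of the four generation-loop operations.

params3 <- function(...) {
  args <- list(...)
  defaults <- list(Qlim = 10, Olim1 = 5, Olim2 = 8, N = 140, L = 3,
                   max_generations = 100)
  do.call(colony_params, utils::modifyList(defaults, args))
}

test_that("state evaluation follows the transition rules and precedence", {
  p <- params3()

  # no trigger crossed: site unchanged
  s <- colony_state(c(0, 5, 0), c(0L, 1L, 0L))
  expect_identical(evaluate_states(s, p)$state, s$state)

  # maturation at age A (hand-enumerated one-site trajectory through S2)
  p2 <- params3(A = 2, Olim1 = 100, Olim2 = 100)
  s <- colony_state(c(0, 5, 0), c(0L, 2L, 0L), age = c(NA, 0, NA))
  ages <- c(); states <- c()
  for (k in 1:3) {
    s <- evaluate_states(s, p2)
    ages <- c(ages, s$age[2]); states <- c(states, s$state[2])
  }
  expect_identical(states, c(2L, 2L, 3L))   # age 0 -> 1 -> 2 (= A) -> mature
  expect_identical(ages, c(1, 2, NA))

  # odor precedence: a site crossing Qlim and Olim1 together turns
  # refractory (still growing), not early-stationary
  s <- colony_state(c(0, 5, 0), c(0L, 1L, 0L), quorum = c(0, 20, 0), odor = 6)
  out <- evaluate_states(s, p)
  expect_identical(out$state[2], 4L)
  grown <- divide_and_migrate(out, p)
  # refractory cells keep dividing: 5 doubles, one daughter to each flank
  expect_identical(grown$thickness, c(1, 8, 1))

  # quorum trigger alone sends a growing site to early stationary, age 0
  s <- colony_state(c(0, 5, 0), c(0L, 1L, 0L), quorum = c(0, 20, 0))
  out <- evaluate_states(s, p)
  expect_identical(out$state[2], 2L)
  expect_identical(out$age[2], 0)

  # thickness at N triggers the same transition
  s <- colony_state(c(0, 140, 0), c(0L, 1L, 0L))
  expect_identical(evaluate_states(s, p)$state[2], 2L)

  # refractory maturation at Olim2 or at N
  s <- colony_state(c(0, 5, 0), c(0L, 4L, 0L), odor = 9)
  expect_identical(evaluate_states(s, p)$state[2], 3L)
  s <- colony_state(c(0, 140, 0), c(0L, 4L, 0L), odor = 6)
  expect_identical(evaluate_states(s, p)$state[2], 3L)

  # mature stationary is absorbing whatever the signals
  s <- colony_state(c(0, 5, 0), c(0L, 3L, 0L), quorum = c(99, 99, 99), odor = 99)
  expect_identical(evaluate_states(s, p)$state[2], 3L)
})

test_that("division doubles growing sites up to N and spares others", {
  p <- params3()
  s <- colony_state(c(0, 4, 0), c(0L, 1L, 0L))
  out <- divide_and_migrate(s, p)
  # 4 doubles to 8, one daughter exported to each empty flank
  expect_identical(out$thickness, c(1, 6, 1))
  expect_identical(out$state, c(1L, 1L, 1L))

  # cap at N
  s <- colony_state(c(0, 140, 0), c(0L, 1L, 0L), quorum = c(99, 99, 99))
  expect_identical(divide_and_migrate(s, p)$thickness[2], 140)

  # early stationary sites neither divide nor migrate
  s <- colony_state(c(0, 4, 0), c(0L, 2L, 0L), age = c(NA, 0, NA))
  expect_identical(divide_and_migrate(s, p)$thickness, c(0, 4, 0))

  # donor decrement can be disabled (daughter created ex nihilo)
  p2 <- params3(decrement_donor = FALSE)
  s <- colony_state(c(0, 4, 0), c(0L, 1L, 0L))
  expect_identical(divide_and_migrate(s, p2)$thickness, c(1, 8, 1))
})

test_that("colonization respects signal blocks and the left tie-break", {
  p <- params3()

  # quorum at the target blocks a quorum-sensitive colonizer
  s <- colony_state(c(0, 4, 0), c(0L, 1L, 0L), quorum = c(20, 0, 0))
  out <- divide_and_migrate(s, p)
  expect_identical(out$state[1], 0L)
  expect_identical(out$thickness, c(0, 7, 1))

  # refractory colonizers ignore quorum but are blocked by odor >= Olim2
  s <- colony_state(c(0, 4, 0), c(0L, 4L, 0L), quorum = c(20, 0, 20), odor = 6)
  out <- divide_and_migrate(s, p)
  expect_identical(out$state, c(4L, 4L, 4L))
  s <- colony_state(c(0, 4, 0), c(0L, 4L, 0L), odor = 9)
  out <- divide_and_migrate(s, p)
  expect_identical(out$state, c(0L, 4L, 0L))

  # both neighbors growing: the left neighbor donates and sets the state
  s <- colony_state(c(4, 0, 4), c(1L, 0L, 4L))
  out <- divide_and_migrate(s, p)
  expect_identical(out$state[2], 1L)
  expect_identical(out$thickness, c(7, 1, 8))

  # left neighbor blocked, right eligible: colonization still happens
  s <- colony_state(c(4, 0, 4), c(1L, 0L, 4L), quorum = c(0, 20, 0))
  out <- divide_and_migrate(s, p)
  expect_identical(out$state[2], 4L)
  expect_identical(out$thickness, c(8, 1, 7))
})

test_that("signal production follows per-state rates and pools odor globally", {
  p <- params3(L = 5, Olim1 = 100, Olim2 = 100)

  # no producers: nothing changes
  s <- colony_state(numeric(5), integer(5))
  out <- produce_signals(s, p)
  expect_identical(out$quorum, numeric(5))
  expect_identical(out$odor, 0)

  # S1 at P, S2 at S*P, S3 into odor, S4 silent
  s <- colony_state(c(10, 10, 140, 10, 0), c(1L, 2L, 3L, 4L, 0L),
                    age = c(NA, 0, NA, NA, NA))
  out <- produce_signals(s, p)
  expect_identical(out$quorum, c(10, 100, 0, 0, 0))
  expect_identical(out$odor, 0.01 * 140)

  # odor pools the total over all mature sites: 0.01 * 3 * 140 = 4.2
  s <- colony_state(rep(140, 5), rep(3L, 5))
  s$thickness[4:5] <- 0; s$state[4:5] <- 0L
  expect_equal(produce_signals(s, p)$odor, 4.2)
})

test_that("diffusion moves fixed fractions down gradients and conserves mass", {
  p1 <- colony_params(Qlim = 1, Olim1 = 1, Olim2 = 1, D = 0.495, G = 1, L = 3)

  # single hand-computed flux on a two-site field
  expect_identical(diffuse_quorum(c(1, 0), p1), c(0.505, 0.495))

  # uniform field is a fixed point
  expect_identical(diffuse_quorum(rep(3.7, 10), p1), rep(3.7, 10))

  # zero-flux walls: all mass stays on the lattice
  set.seed(42)
  for (rep in 1:20) {
    L <- sample(3:200, 1)
    q <- stats::runif(L, 0, 100)
    p <- colony_params(Qlim = 1, Olim1 = 1, Olim2 = 1,
                       D = stats::runif(1, 0, 0.5), G = sample(1:10, 1), L = L)
    out <- diffuse_quorum(q, p)
    expect_equal(sum(out), sum(q), tolerance = 1e-12)
    expect_true(all(out >= 0))
    # smoothing: extremes contract monotonically per iteration
    q1 <- q
    for (it in seq_len(p$G)) {
      q2 <- diffuse_quorum(q1, colony_params(Qlim = 1, Olim1 = 1, Olim2 = 1,
                                             D = p$D, G = 1, L = L))
      expect_true(max(q2) <= max(q1) + 1e-12)
      expect_true(min(q2) >= min(q1) - 1e-12)
      q1 <- q2
    }
  }

  # stability guard
  expect_error(colony_params(Qlim = 1, Olim1 = 1, Olim2 = 1, D = 0.51),
               "unstable|\\[0, 0.5\\]")
})

test_that("optimized generation step matches the naive transcription bit-exactly", {
  set.seed(101)
  for (k in 1:400) {
    p <- random_params()
    s <- random_state(p)
    expect_identical(state_fields(step_generation(s, p)),
                     state_fields(naive_generation(s, p)))
  }
})

test_that("a generation step on an empty dish is a fixed point", {
  p <- params3(L = 7)
  s <- colony_state(numeric(7), integer(7))
  out <- step_generation(s, p)
  expect_identical(out$thickness, numeric(7))
  expect_identical(out$state, integer(7))
  expect_identical(out$generation, 1L)
})
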