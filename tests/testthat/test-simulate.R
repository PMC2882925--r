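# Whole-run behavior: trace structure, termination, invariants, symmetry.

# Legal per-site state changes between consecutive generations.
LEGAL <- matrix(c(0, 0, 0, 1, 0, 1, 0, 4, 1, 1, 1, 2, 1, 4, 2, 2, 2, 3,
                  2, 4, 3, 3, 4, 4, 4, 3), ncol = 2, byrow = TRUE)

expect_legal_trace <- function(tr) {
  N <- tr$params$N
  expect_true(all(tr$thickness >= 0 & tr$thickness <= N))
  expect_true(all(diff(tr$odor_series) >= 0))
  expect_true(all((tr$thickness == 0) == (tr$state == 0L)))
  for (g in seq_len(nrow(tr$state) - 1L)) {
    from <- tr$state[g, ]; to <- tr$state[g + 1L, ]
    changed <- from != to
    if (any(changed)) {
      pairs <- paste(from[changed], to[changed])
      expect_true(all(pairs %in% paste(LEGAL[, 1], LEGAL[, 2])),
                  label = paste("legal transitions at generation", g))
    }
  }
  # mature stationary sites never change again
  for (g in seq_len(nrow(tr$state) - 1L)) {
    s3 <- tr$state[g, ] == 3L
    expect_true(all(tr$state[g + 1L, s3] == 3L))
    expect_true(all(tr$thickness[g + 1L, s3] == tr$thickness[g, s3]))
  }
}

test_that("trace bookkeeping: snapshots, series, termination flag", {
  p <- reference_params()
  tr <- run_simulation(build_inoculum(inoculum_spec("POINT", 101), p), p)

  expect_false(is.na(tr$terminated_at))
  n <- tr$terminated_at
  expect_identical(length(tr$extent_series), n + 1L)       # includes gen 0
  expect_identical(nrow(tr$thickness), n + 1L)
  expect_identical(tr$generations, 0:n)
  expect_identical(tr$extent_series,
                   as.integer(rowSums(tr$state != 0L)))
  expect_identical(tr$biomass_series, rowSums(tr$thickness))
  # all occupied sites mature at the end, and not one generation earlier
  expect_true(all(tr$state[n + 1L, tr$state[n + 1L, ] != 0L] == 3L))
  occ <- tr$state[n, ] != 0L
  expect_false(all(tr$state[n, occ] == 3L))
})

test_that("structural invariants hold along a full reference trace", {
  p <- reference_params()
  tr <- run_simulation(build_inoculum(inoculum_spec("POINT", 101), p), p)
  expect_legal_trace(tr)
})

test_that("runs are deterministic: identical inputs give identical traces", {
  p <- reference_params()
  s <- build_inoculum(inoculum_spec("POINT", 101), p)
  t1 <- run_simulation(s, p)
  t2 <- run_simulation(s, p)
  expect_identical(t1[setdiff(names(t1), "params")],
                   t2[setdiff(names(t2), "params")])
})

test_that("unconstrained growth fronts advance one site per flank per generation", {
  # generous thresholds: nothing but the lattice limits lateral spread
  p <- colony_params(Qlim = 1e9, Olim1 = 1e9, Olim2 = 1e9, L = 31,
                     max_generations = 10)
  s <- build_inoculum(inoculum_spec("POINT", 16), p)
  for (k in 1:5) {
    s <- step_generation(s, p)
    expect_identical(sum(s$state != 0L), 1L + 2L * k)
    occ <- which(s$state != 0L)
    expect_identical(occ, seq.int(16L - k, 16L + k))
  }
})

test_that("degenerate odor thresholds collapse development within a few generations", {
  p <- colony_params(Qlim = 100, Olim1 = 0, Olim2 = 0, L = 21,
                     max_generations = 50)
  tr <- run_simulation(build_inoculum(inoculum_spec("POINT", 11), p), p)
  # odor 0 >= Olim1 makes the inoculum refractory at once; it then matures
  # at Olim2 = 0, so everything is mature within a couple of generations
  expect_false(is.na(tr$terminated_at))
  expect_lte(tr$terminated_at, 5L)
  expect_legal_trace(tr)
})

test_that("an all-mature inoculum terminates immediately with no growth", {
  p <- colony_params(Qlim = 10, Olim1 = 5, Olim2 = 8, L = 11,
                     max_generations = 50)
  s <- colony_state(c(rep(0, 4), rep(7, 3), rep(0, 4)),
                    c(rep(0L, 4), rep(3L, 3), rep(0L, 4)))
  tr <- run_simulation(s, p)
  expect_identical(tr$terminated_at, 0L)
  expect_identical(nrow(tr$thickness), 1L)
  expect_identical(tr$biomass_series, 21)
})

test_that("empty inocula are rejected and caps are flagged, not errors", {
  p <- colony_params(Qlim = 10, Olim1 = 5, Olim2 = 8, L = 11,
                     max_generations = 3)
  expect_error(run_simulation(colony_state(numeric(11), integer(11)), p),
               "empty inoculum")
  # huge thresholds: growth never stops, cap is reached
  p2 <- colony_params(Qlim = 1e9, Olim1 = 1e9, Olim2 = 1e9, L = 11,
                      max_generations = 3)
  tr <- run_simulation(build_inoculum(inoculum_spec("POINT", 6), p2), p2)
  expect_true(is.na(tr$terminated_at))
  expect_identical(nrow(tr$thickness), 4L)
})

test_that("mirror-symmetric inocula develop mirror-symmetrically forever", {
  # an even ring gap closes 2 sites per generation without ever leaving a
  # single shared empty site, so the colonization tie-break never fires
  cases <- list(list(L = 151, spec = inoculum_spec("POINT", 76)),
                list(L = 151, spec = inoculum_spec("BLOCK", 76, width = 5)),
                list(L = 150,
                     spec = inoculum_spec("RING_SECTION", 76, width = 3,
                                          gap = 10)))
  for (case in cases) {
    p <- reference_params(L = case$L)
    tr <- run_simulation(build_inoculum(case$spec, p), p)
    for (g in seq_len(nrow(tr$thickness))) {
      expect_identical(tr$thickness[g, ], rev(tr$thickness[g, ]))
      expect_identical(tr$state[g, ], rev(tr$state[g, ]))
      expect_identical(tr$quorum[g, ], rev(tr$quorum[g, ]))
    }
  }
})

test_that("shifting the inoculum shifts the whole trace", {
  p <- reference_params(L = 301)
  k <- 17L
  t0 <- run_simulation(build_inoculum(inoculum_spec("POINT", 120), p), p)
  t1 <- run_simulation(build_inoculum(inoculum_spec("POINT", 120 + k), p), p)
  expect_identical(t0$terminated_at, t1$terminated_at)
  # the colony stays >= 20 sites clear of both walls in both runs
  occ0 <- which(t0$state[nrow(t0$state), ] != 0L)
  expect_gte(min(occ0), 21L)
  expect_lte(max(occ0) + k, 281L)
  L <- p$L
  expect_identical(t1$thickness[, (k + 1):L], t0$thickness[, 1:(L - k)])
  expect_identical(t1$state[, (k + 1):L], t0$state[, 1:(L - k)])
  # quorum reaches the (differently placed) walls at trace amounts, so the
  # shifted fields agree to the field scale rather than bitwise
  qa <- t1$quorum[, (k + 1):L]; qb <- t0$quorum[, 1:(L - k)]
  expect_lt(max(abs(qa - qb)), 1e-9 * max(qb))
})
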