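# Scenario runs are deterministic but take a second or two; compute each
# once per test session and share across test files.

.scenario_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .scenario_cache))
    assign(name, fn(), envir = .scenario_cache)
  get(name, envir = .scenario_cache)
}

cached_pair <- function() cached("pair", scenario_rimmed_vs_rimless)

cached_encounters <- function()
  cached("encounters", function() scenario_encounters(seq(10, 120, by = 10)))

cached_sweep <- function()
  cached("sweep", function() scenario_inoculum_sweep(seq(1, 41, by = 2)))

cached_tuning <- function() cached("tuning", tune_thresholds)

# Minimal stand-in trace for classifier tests on synthetic profiles:
# carries exactly the fields classify_phenotype() consults.
fixture_trace <- function(profile, params, terminated_at = 10L) {
  st <- ifelse(profile > 0, 3L, 0L)
  structure(list(
    params = params,
    generations = c(0L, terminated_at),
    thickness = rbind(profile, profile),
    state = rbind(st, st),
    quorum = rbind(numeric(length(profile)), numeric(length(profile))),
    odor = c(0, 1),
    extent_series = rep(sum(profile > 0), 2),
    biomass_series = rep(sum(profile), 2),
    odor_series = c(0, 1),
    terminated_at = terminated_at,
    final = colony_state(profile, st, odor = 1,
                         generation = terminated_at)
  ), class = "colony_trace")
}

reference_params <- function(L = 201, max_generations = 500) {
  th <- default_rimmed_thresholds()
  colony_params(Qlim = th$Qlim, Olim1 = th$Olim1, Olim2 = th$Olim2,
                L = L, max_generations = max_generations)
}
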