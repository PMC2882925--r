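#' Shipped sensitivity-threshold triples
#'
#' The growth and production rates of the reference parameter set are fixed,
#' but the three sensitivity thresholds (`Qlim`, `Olim1`, `Olim2`) of the
#' reference rimmed clone are not fixed by the rates alone: any triple for
#' which a single-point inoculum terminates and classifies RIMMED is
#' admissible (see [tune_thresholds()]).  `default_rimmed_thresholds()`
#' returns the shipped triple — tuned by the grid search, then selected from
#' the feasible set as the triple with the most balanced navel /
#' interstitial / rim anatomy, which also reproduces the encounter and
#' inoculum-size phenomenology.  `default_rimless_thresholds()` returns a
#' triple differing from it only in an effectively infinite `Qlim` (a
#' quorum-insensitive clone), which yields a rimless colony with every other
#' parameter unchanged.
#'
#' @return A named list with elements `Qlim`, `Olim1`, `Olim2`.
#' @export
default_rimmed_thresholds <- function() {
  list(Qlim = 1000, Olim1 = 100, Olim2 = 1000)
}

#' @rdname default_rimmed_thresholds
#' @export
default_rimless_thresholds <- function() {
  list(Qlim = 1e6, Olim1 = 100, Olim2 = 1000)
}

## Reference parameter object with a threshold triple filled in.
params_with_thresholds <- function(thresholds, L = 201,
                                   max_generations = 500, ...) {
  colony_params(Qlim = thresholds$Qlim, Olim1 = thresholds$Olim1,
                Olim2 = thresholds$Olim2, L = L,
                max_generations = max_generations, ...)
}

## One single-point run -> list(trace, report or NULL).
point_run <- function(params, position = (params$L + 1L) %/% 2L,
                      macula_width = NA) {
  tr <- run_simulation(build_inoculum(inoculum_spec("POINT", position), params),
                       params)
  rep <- if (is.na(tr$terminated_at)) NULL else
    tryCatch(classify_phenotype(segment_zones(final_profile(tr), params), tr,
                                macula_width = macula_width),
             error = function(e) NULL)
  list(trace = tr, report = rep)
}

#' Grid-search sensitivity thresholds for the rimmed phenotype
#'
#' The sensitivity thresholds of the reference clone are not determined by
#' the production and diffusion rates; this grid search makes their choice
#' auditable.  Every combination of the supplied `Qlim`, `Olim1`, `Olim2`
#' values with `Olim1 <= Olim2` is run from a single-point inoculum under
#' `params_base`'s rates; a triple is feasible when the run terminates and
#' the mature profile classifies RIMMED.
#'
#' The default grids are logarithmic over the scales the rates imply: quorum
#' accrual per generation is at most `S * P * N` per site, and odor rises by
#' `O * N` per mature site per generation, so thresholds spanning roughly
#' 0.1x to 2x of those scales cover the transition from immediate arrest to
#' no arrest.
#'
#' @param params_base A [colony_params()] carrying the non-threshold
#'   parameters (its own thresholds are ignored).  Defaults to the reference
#'   rates on a 201-site lattice.
#' @param Qlim_grid,Olim1_grid,Olim2_grid Numeric grids for the three
#'   thresholds.
#'
#' @return A list of class `threshold_tuning`:
#'   \describe{
#'     \item{feasible}{data frame of feasible triples in deterministic grid
#'       order, with colony morphometrics.}
#'     \item{phase_table}{the full grid outcome: one row per triple, with
#'       `terminated`, `classification` and morphometrics.}
#'     \item{best}{the first feasible triple (grid order).}
#'   }
#' @seealso [default_rimmed_thresholds()] for the shipped triple.
#' @export
tune_thresholds <- function(params_base = NULL,
                            Qlim_grid = c(100, 300, 1000, 3000),
                            Olim1_grid = c(3, 10, 30, 100),
                            Olim2_grid = c(100, 300, 1000, 3000)) {
  if (is.null(params_base))
    params_base <- params_with_thresholds(list(Qlim = 1, Olim1 = 1, Olim2 = 1))
  grid <- expand.grid(Qlim = Qlim_grid, Olim1 = Olim1_grid,
                      Olim2 = Olim2_grid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$Olim1 <= grid$Olim2, , drop = FALSE]
  grid <- grid[order(grid$Qlim, grid$Olim1, grid$Olim2), , drop = FALSE]
  rownames(grid) <- NULL

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params_with_thresholds(as.list(grid[i, ]), L = params_base$L,
                                max_generations = params_base$max_generations,
                                N = params_base$N, P = params_base$P,
                                S = params_base$S, A = params_base$A,
                                O = params_base$O, D = params_base$D,
                                G = params_base$G)
    r <- point_run(p)
    if (is.null(r$report))
      return(data.frame(terminated = !is.na(r$trace$terminated_at),
                        classification = "NONE", generations = NA_integer_,
                        navel = NA_real_, interstitial = NA_real_,
                        rim = NA_real_, total = NA_real_))
    d <- r$report$diameters[1, ]
    data.frame(terminated = TRUE,
               classification = r$report$classification,
               generations = r$trace$terminated_at,
               navel = d[["navel"]], interstitial = d[["interstitial"]],
               rim = d[["rim"]], total = d[["total"]])
  })
  phase <- cbind(grid, do.call(rbind, rows))
  feasible <- phase[phase$classification == "RIMMED", , drop = FALSE]
  if (nrow(feasible) == 0L)
    stop("threshold tuning: no feasible (RIMMED) triple in the grid; ",
         "widen the Qlim/Olim grids", call. = FALSE)
  structure(list(feasible = feasible, phase_table = phase,
                 best = as.list(feasible[1L, c("Qlim", "Olim1", "Olim2")])),
            class = "threshold_tuning")
}

#' @export
print.threshold_tuning <- function(x, ...) {
  cat(sprintf("Threshold tuning: %d/%d grid triples feasible (RIMMED)\n",
              nrow(x$feasible), nrow(x$phase_table)))
  cat(sprintf("  first feasible: Qlim=%g, Olim1=%g, Olim2=%g\n",
              x$best$Qlim, x$best$Olim1, x$best$Olim2))
  invisible(x)
}

#' Rimmed versus rimless by sensitivity thresholds alone
#'
#' Runs two single-point simulations whose parameters differ only in the
#' sensitivity triple (`Qlim`, `Olim1`, `Olim2`): the rimmed reference
#' clone and a rimless clone.  Demonstrates that the rimless phenotype
#' arises solely from changed signal sensitivities.
#'
#' @param rimmed,rimless Threshold triples (named lists with `Qlim`,
#'   `Olim1`, `Olim2`).
#' @param L Lattice length.
#' @param max_generations Generation cap.
#' @return A list with elements `rimmed` and `rimless`, each holding
#'   `params`, `trace` and `report`.
#' @export
scenario_rimmed_vs_rimless <- function(rimmed = default_rimmed_thresholds(),
                                       rimless = default_rimless_thresholds(),
                                       L = 201, max_generations = 500) {
  out <- lapply(list(rimmed = rimmed, rimless = rimless), function(th) {
    p <- params_with_thresholds(th, L = L, max_generations = max_generations)
    r <- point_run(p)
    list(params = p, trace = r$trace, report = r$report)
  })
  class(out) <- "scenario_pair"
  out
}

#' Encounters of rimmed colonies
#'
#' Plants two point inocula at each separation (plus a singleton control)
#' and reports, per separation, the overall classification, the number of
#' distinct colonies, per-colony total diameters and generations to
#' maturity.  Colonies sharing the dish pool their odor, so pairs arrest
#' earlier — smaller and sooner-maturing than the singleton — and
#' sufficiently close pairs fuse under a common rim (CONFLUENT_RIMMED).
#'
#' @param separations Integer vector of center-to-center distances (sites).
#' @param thresholds Sensitivity triple (default: shipped rimmed clone).
#' @param L Lattice length (default 301, roomy enough for two colonies).
#' @param max_generations Generation cap.
#' @return A list of class `encounter_scenario`: `singleton` (run of one
#'   point inoculum), `table` (one row per separation: classification,
#'   colonies, max colony diameter, generations to maturity), `runs`, and
#'   `crossover` — the largest swept separation classifying
#'   CONFLUENT_RIMMED, or `NA` if none.
#' @export
scenario_encounters <- function(separations = seq(10, 120, by = 10),
                                thresholds = default_rimmed_thresholds(),
                                L = 301, max_generations = 500) {
  p <- params_with_thresholds(thresholds, L = L,
                              max_generations = max_generations)
  center <- (L + 1L) %/% 2L
  singleton <- point_run(p, center)
  if (is.null(singleton$report))
    stop("encounter scenario: singleton run did not terminate or classify",
         call. = FALSE)

  runs <- lapply(separations, function(sep) {
    pos <- c(center - sep %/% 2L, center - sep %/% 2L + sep)
    r <- run_simulation(build_inoculum(inoculum_spec("MULTI", pos), p), p)
    rep <- if (is.na(r$terminated_at)) NULL else
      classify_phenotype(segment_zones(final_profile(r), p), r)
    list(trace = r, report = rep)
  })
  tab <- do.call(rbind, lapply(seq_along(separations), function(i) {
    rep <- runs[[i]]$report
    data.frame(separation = separations[i],
               terminated = !is.na(runs[[i]]$trace$terminated_at),
               classification = if (is.null(rep)) NA_character_ else rep$classification,
               colonies = if (is.null(rep)) NA_integer_ else rep$colony_count,
               max_diameter = if (is.null(rep)) NA_real_ else max(rep$diameters[, "total"]),
               generations = runs[[i]]$trace$terminated_at)
  }))
  conf <- tab$separation[!is.na(tab$classification) &
                           tab$classification == "CONFLUENT_RIMMED"]
  structure(list(singleton = singleton, table = tab, runs = runs,
                 crossover = if (length(conf)) max(conf) else NA_real_),
            class = "encounter_scenario")
}

#' Inoculum-size sweep
#'
#' Runs BLOCK inocula of increasing width (simulated planting by dropping)
#' and tabulates, per width, generations to maturity, navel / interstitial /
#' rim diameters and the classification.  As the planting widens the navel
#' expands at the expense of the interstitial ring until the rim is lost and
#' the body grows towards a macula.  The macula reference width is the
#' singleton control's interstitial outer diameter (navel + interstitial).
#'
#' @param widths Integer vector of block widths (sites), ascending.
#' @param thresholds Sensitivity triple (default: shipped rimmed clone).
#' @param L Lattice length.
#' @param max_generations Generation cap.
#' @return A list of class `inoculum_sweep`: `table` (one row per width),
#'   `macula_width` (the reference diameter used), `singleton` and `runs`.
#' @export
scenario_inoculum_sweep <- function(widths = seq(1, 41, by = 2),
                                    thresholds = default_rimmed_thresholds(),
                                    L = 301, max_generations = 500) {
  p <- params_with_thresholds(thresholds, L = L,
                              max_generations = max_generations)
  center <- (L + 1L) %/% 2L
  singleton <- point_run(p, center)
  if (is.null(singleton$report) ||
      singleton$report$classification != "RIMMED")
    stop("inoculum sweep: singleton control is not a rimmed colony under ",
         "these thresholds", call. = FALSE)
  d <- singleton$report$diameters[1, ]
  macula_width <- d[["navel"]] + d[["interstitial"]]

  runs <- lapply(widths, function(w) {
    spec <- inoculum_spec("BLOCK", center, width = w)
    r <- run_simulation(build_inoculum(spec, p), p)
    rep <- if (is.na(r$terminated_at)) NULL else
      classify_phenotype(segment_zones(final_profile(r), p), r,
                         macula_width = macula_width)
    list(trace = r, report = rep)
  })
  tab <- do.call(rbind, lapply(seq_along(widths), function(i) {
    rep <- runs[[i]]$report
    if (is.null(rep))
      return(data.frame(width = widths[i], terminated = FALSE,
                        classification = NA_character_, generations = NA_integer_,
                        navel = NA_real_, interstitial = NA_real_,
                        rim = NA_real_, total = NA_real_,
                        imperfect_rim = NA))
    dd <- rep$diameters[1, ]
    data.frame(width = widths[i], terminated = TRUE,
               classification = rep$classification,
               generations = rep$generations_to_maturity,
               navel = dd[["navel"]], interstitial = dd[["interstitial"]],
               rim = dd[["rim"]], total = dd[["total"]],
               imperfect_rim = rep$imperfect_rim)
  }))
  structure(list(table = tab, macula_width = macula_width,
                 singleton = singleton, runs = runs),
            class = "inoculum_sweep")
}

#' @export
print.encounter_scenario <- function(x, ...) {
  cat("Encounter scenario (two point inocula vs singleton)\n")
  cat(sprintf("  singleton: diameter %g sites, mature at generation %d\n",
              x$singleton$report$diameters[1, "total"],
              x$singleton$trace$terminated_at))
  cat(sprintf("  confluence crossover separation: %s sites\n", x$crossover))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
print.inoculum_sweep <- function(x, ...) {
  cat("Inoculum-size sweep (BLOCK widths)\n")
  cat(sprintf("  macula reference width: %g sites\n", x$macula_width))
  print(x$table, row.names = FALSE)
  invisible(x)
}
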