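#' Run the colony automaton to maturity
#'
#' Iterates [step_generation()] from an initial lattice until either every
#' occupied site has reached mature stationary phase (state 3) — at which
#' point no further change is possible, since state 3 is absorbing and
#' produces no quorum — or the `max_generations` cap is hit.  The full
#' per-generation history is recorded.
#'
#' @param inoculum A [colony_state()] with at least one occupied site,
#'   typically from [build_inoculum()].
#' @param params A [colony_params()]; `params$L` must equal the inoculum
#'   length.
#' @param thin Snapshot thinning interval: keep every `thin`-th generation
#'   (plus generation 0 and the final one).  Summary series are always kept
#'   at every generation.  Default 1 (keep everything).
#'
#' @return An object of class `colony_trace` with components:
#' \describe{
#'   \item{params}{the parameter object used.}
#'   \item{generations}{integer vector of recorded snapshot generations.}
#'   \item{thickness, state, quorum}{matrices with one row per recorded
#'     snapshot and one column per site.}
#'   \item{odor}{odor level per recorded snapshot (end-of-generation value).}
#'   \item{extent_series, biomass_series, odor_series}{per-generation
#'     summaries over all executed generations (index 1 = generation 0):
#'     occupied-site count, total thickness, odor level.}
#'   \item{terminated_at}{generation at which every occupied site was mature,
#'     or `NA` if the cap was reached first.}
#'   \item{final}{the final `colony_state`.}
#' }
#' @examples
#' p <- colony_params(Qlim = 400, Olim1 = 30, Olim2 = 1200, L = 101,
#'                    max_generations = 500)
#' tr <- run_simulation(build_inoculum(inoculum_spec("POINT", 51), p), p)
#' tr
#' @export
run_simulation <- function(inoculum, params, thin = 1L) {
  validate_state(inoculum, params)
  if (length(inoculum$thickness) != params$L)
    stop("inoculum length ", length(inoculum$thickness),
         " does not match params$L = ", params$L, call. = FALSE)
  if (all(inoculum$state == 0L))
    stop("empty inoculum: at least one site must be occupied", call. = FALSE)
  thin <- max(1L, as.integer(thin))

  all_mature <- function(s) {
    occ <- s$state != 0L
    all(s$state[occ] == 3L)
  }

  cap <- params$max_generations
  s <- inoculum
  keep <- list(s)                       # generation-0 snapshot always kept
  gens <- s$generation
  extent <- integer(cap + 1L)
  biomass <- numeric(cap + 1L)
  odors <- numeric(cap + 1L)
  extent[1L] <- sum(s$state != 0L)
  biomass[1L] <- sum(s$thickness)
  odors[1L] <- s$odor

  terminated_at <- if (all_mature(s)) s$generation else NA_integer_
  n_done <- 0L
  if (is.na(terminated_at)) {
    for (g in seq_len(cap)) {
      s <- step_generation(s, params)
      n_done <- g
      extent[g + 1L] <- sum(s$state != 0L)
      biomass[g + 1L] <- sum(s$thickness)
      odors[g + 1L] <- s$odor
      done <- all_mature(s)
      if (g %% thin == 0L || done || g == cap) {
        keep[[length(keep) + 1L]] <- s
        gens <- c(gens, s$generation)
      }
      if (done) {
        terminated_at <- s$generation
        break
      }
    }
  }

  n <- n_done + 1L
  structure(list(
    params = params,
    generations = gens,
    thickness = do.call(rbind, lapply(keep, `[[`, "thickness")),
    state = do.call(rbind, lapply(keep, `[[`, "state")),
    quorum = do.call(rbind, lapply(keep, `[[`, "quorum")),
    odor = vapply(keep, `[[`, numeric(1), "odor"),
    extent_series = extent[seq_len(n)],
    biomass_series = biomass[seq_len(n)],
    odor_series = odors[seq_len(n)],
    terminated_at = terminated_at,
    final = s
  ), class = "colony_trace")
}

#' @export
print.colony_trace <- function(x, ...) {
  n <- length(x$extent_series) - 1L
  cat(sprintf("Colony automaton trace: %d generations on %d sites\n",
              n, x$params$L))
  if (is.na(x$terminated_at))
    cat(sprintf("  NOT terminated (cap %d generations reached)\n",
                x$params$max_generations))
  else
    cat(sprintf("  terminated at generation %d (all occupied sites mature)\n",
                x$terminated_at))
  cat(sprintf("  final extent %d sites, biomass %g, odor %g\n",
              x$extent_series[n + 1L], x$biomass_series[n + 1L],
              x$odor_series[n + 1L]))
  invisible(x)
}

#' @export
summary.colony_trace <- function(object, tall_fraction = 0.5, ...) {
  rep <- tryCatch(
    classify_phenotype(segment_zones(final_profile(object), object$params,
                                     tall_fraction), object),
    error = function(e) NULL)
  out <- list(trace = object, report = rep)
  class(out) <- "summary.colony_trace"
  out
}

#' @export
print.summary.colony_trace <- function(x, ...) {
  print(x$trace)
  if (!is.null(x$report)) print(x$report) else cat("  (no classifiable colony)\n")
  invisible(x)
}

#' Final thickness profile of a trace
#'
#' @param trace A `colony_trace`.
#' @return Numeric vector of final per-site thickness.
#' @export
final_profile <- function(trace) {
  trace$final$thickness
}

#' Plot colony development from a trace
#'
#' Draws the thickness and quorum cross-section profiles at selected
#' generations together with the colony-extent and odor time series.
#'
#' @param x A `colony_trace`.
#' @param generations Generations whose profiles to draw; must be present in
#'   the recorded snapshots.  Default: five snapshots evenly spaced through
#'   the run.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.colony_trace <- function(x, generations = NULL, ...) {
  if (is.null(generations)) {
    idx <- unique(round(seq(1, length(x$generations), length.out = 5)))
    generations <- x$generations[idx]
  }
  missing <- setdiff(generations, x$generations)
  if (length(missing))
    stop("generation(s) ", paste(missing, collapse = ", "),
         " not recorded; available: ",
         paste(utils::head(x$generations, 50), collapse = ", "),
         if (length(x$generations) > 50) " ..." else "", call. = FALSE)
  rows <- match(generations, x$generations)

  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  site <- seq_len(x$params$L)
  cols <- grDevices::hcl.colors(max(length(rows), 2L), "Zissou 1")

  graphics::matplot(site, t(x$thickness[rows, , drop = FALSE]), type = "l",
                    lty = 1, col = cols, xlab = "site", ylab = "thickness",
                    main = "Colony cross-section")
  graphics::legend("topright", legend = paste("gen", generations), col = cols,
                   lty = 1, cex = 0.7, bty = "n")
  graphics::matplot(site, t(x$quorum[rows, , drop = FALSE]), type = "l",
                    lty = 1, col = cols, xlab = "site", ylab = "quorum",
                    main = "Quorum concentration")
  gen_axis <- seq_along(x$extent_series) - 1L
  graphics::plot(gen_axis, x$extent_series, type = "l", xlab = "generation",
                 ylab = "extent (sites)", main = "Colony size and odor")
  graphics::par(new = TRUE)
  graphics::plot(gen_axis, x$odor_series, type = "l", col = "red3", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col.axis = "red3")
  graphics::mtext("odor", side = 4, line = -1.2, col = "red3", cex = 0.7)
  invisible(x)
}
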