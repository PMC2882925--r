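#' Model parameters for a simulated clone
#'
#' Bundles every rate, threshold and lattice/run control of the colony
#' automaton into a validated parameter object.  All quantities are in the
#' model's relative units: thickness in bacteria per lattice site, quorum in
#' quorum units, odor in odor units, time in generations.
#'
#' @param N Maximum colony thickness (bacteria per site).  Growth at a site
#'   stops when its thickness reaches `N`; this approximates nutrient
#'   limitation.
#' @param P Quorum production factor: quorum units produced per exponentially
#'   growing bacterium per generation.
#' @param S Stationary-to-exponential quorum production ratio: early
#'   stationary sites produce `S * P` quorum units per bacterium per
#'   generation.
#' @param A Quorum production window: generations a site spends in early
#'   stationary phase before maturing.
#' @param O Odor production factor: odor units produced per mature stationary
#'   bacterium per generation, pooled globally.
#' @param D Normalized diffusion factor: fraction of the pairwise quorum
#'   concentration difference exchanged per diffusion iteration.  Must lie in
#'   `[0, 0.5]`; larger values make the explicit scheme oscillate.
#' @param G Diffusion iterations nested inside each generation.
#' @param Qlim Limiting quorum concentration: at or above it quorum-sensitive
#'   growing cells stop dividing (enter early stationary phase), and
#'   colonization of an empty site by a quorum-sensitive neighbor is blocked.
#' @param Olim1 Limiting odor level for growth reactivation: at or above it
#'   growing and early-stationary cells enter the refractory growing state.
#' @param Olim2 Limiting odor level for growth inhibition: at or above it
#'   refractory cells mature and stop growing.  `Olim1 <= Olim2`.
#' @param L Lattice length (number of sites across the dish).
#' @param max_generations Hard cap on the number of generations simulated.
#' @param decrement_donor Should a site that exports a daughter bacterium to
#'   an empty neighbor lose one bacterium per export (floored at 1)?  If
#'   `FALSE` the migrating daughter is created without debiting the donor.
#'
#' @details The default rates and run controls (`N = 140`, `P = 1`,
#'   `O = 0.01`, `S = 10`, `A = 5`, `D = 0.495`, `G = 5`) are the reference
#'   parameter set under which a single-site inoculum develops into a rimmed
#'   colony for suitable sensitivity thresholds; see
#'   [default_rimmed_thresholds()] for the shipped threshold triple and
#'   [tune_thresholds()] for how such triples are found.
#'
#' @return An object of class `colony_params`: a named list of the validated
#'   fields.
#' @seealso [run_simulation()], [build_inoculum()], [tune_thresholds()]
#' @examples
#' p <- colony_params(Qlim = 400, Olim1 = 30, Olim2 = 1200)
#' p
#' @export
colony_params <- function(N = 140, P = 1, S = 10, A = 5, O = 0.01,
                          D = 0.495, G = 5,
                          Qlim, Olim1, Olim2,
                          L = 201, max_generations = 10000,
                          decrement_donor = TRUE) {
  p <- list(N = N, P = P, S = S, A = A, O = O, D = D, G = G,
            Qlim = Qlim, Olim1 = Olim1, Olim2 = Olim2,
            L = L, max_generations = max_generations,
            decrement_donor = isTRUE(decrement_donor))
  validate_params(p)
  p$N <- as.integer(N); p$G <- as.integer(G)
  p$L <- as.integer(L); p$max_generations <- as.integer(max_generations)
  for (f in c("P", "S", "A", "O", "D", "Qlim", "Olim1", "Olim2"))
    p[[f]] <- as.numeric(p[[f]])
  class(p) <- "colony_params"
  p
}

validate_params <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", field, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", field, "' must be nonnegative (got ", v, ")", call. = FALSE)
    v
  }
  for (f in c("N", "P", "S", "A", "O", "D", "G", "Qlim", "Olim1", "Olim2",
              "L", "max_generations")) num1(f)
  if (p$N < 1) stop("parameter 'N' must be >= 1", call. = FALSE)
  if (p$G < 1) stop("parameter 'G' must be >= 1", call. = FALSE)
  if (p$L < 3) stop("parameter 'L' must be >= 3", call. = FALSE)
  if (p$max_generations < 1)
    stop("parameter 'max_generations' must be >= 1", call. = FALSE)
  if (p$D > 0.5)
    stop("parameter 'D' must lie in [0, 0.5]: the pairwise exchange scheme ",
         "is unstable for D > 0.5 (got ", p$D, ")", call. = FALSE)
  if (p$Olim1 > p$Olim2)
    stop("parameter 'Olim1' (", p$Olim1, ") must not exceed 'Olim2' (",
         p$Olim2, ")", call. = FALSE)
  invisible(p)
}

#' @export
print.colony_params <- function(x, ...) {
  cat("Colony automaton parameters\n")
  cat(sprintf("  growth:      N = %d (max thickness), donor decrement %s\n",
              x$N, if (x$decrement_donor) "on" else "off"))
  cat(sprintf("  quorum:      P = %g, S = %g, A = %g, Qlim = %g\n",
              x$P, x$S, x$A, x$Qlim))
  cat(sprintf("  odor:        O = %g, Olim1 = %g, Olim2 = %g\n",
              x$O, x$Olim1, x$Olim2))
  cat(sprintf("  diffusion:   D = %g over G = %d iterations per generation\n",
              x$D, x$G))
  cat(sprintf("  run:         L = %d sites, cap %d generations\n",
              x$L, x$max_generations))
  invisible(x)
}
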