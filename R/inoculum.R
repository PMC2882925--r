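#' Specify an inoculum geometry
#'
#' Describes where and how thickly bacteria are planted on the lattice.
#' Supported kinds:
#' \describe{
#'   \item{POINT}{single-site inocula at each position ("dotting").}
#'   \item{BLOCK}{a contiguous run of `width` sites centered at each
#'     position ("dropping"; wider drops model larger planting areas).}
#'   \item{MULTI}{alias for several POINT inocula (encounter experiments).}
#'   \item{RING_SECTION}{the 1-D cross-section of a ring planting: two
#'     blocks of `width` sites separated by `gap` empty sites, centered at
#'     each position.}
#'   \item{BACKGROUND}{single-site inocula at a fixed `stride` across the
#'     whole lattice (exploratory dense-sowing backgrounds).}
#' }
#'
#' @param kind One of `"POINT"`, `"BLOCK"`, `"MULTI"`, `"RING_SECTION"`,
#'   `"BACKGROUND"`.
#' @param positions Integer site indices (1-based centers), one per planted
#'   element.  Ignored for `BACKGROUND`.
#' @param width Occupied sites per element (BLOCK / RING_SECTION).  Even
#'   widths take the extra site on the left of the center.
#' @param gap Empty sites between the two blocks of a RING_SECTION.
#' @param initial_thickness Starting bacteria per occupied site (default 1).
#' @param stride Site spacing for BACKGROUND plantings (default 10).
#'
#' @return An object of class `inoculum_spec`.
#' @seealso [build_inoculum()]
#' @export
inoculum_spec <- function(kind, positions = integer(), width = 1L, gap = 0L,
                          initial_thickness = 1L, stride = 10L) {
  kind <- match.arg(toupper(kind),
                    c("POINT", "BLOCK", "MULTI", "RING_SECTION", "BACKGROUND"))
  if (kind != "BACKGROUND" && length(positions) == 0L)
    stop("inoculum: 'positions' must name at least one planting center",
         call. = FALSE)
  if (width < 1L) stop("inoculum: 'width' must be >= 1", call. = FALSE)
  if (gap < 0L) stop("inoculum: 'gap' must be >= 0", call. = FALSE)
  if (initial_thickness < 1L)
    stop("inoculum: 'initial_thickness' must be >= 1", call. = FALSE)
  if (stride < 1L) stop("inoculum: 'stride' must be >= 1", call. = FALSE)
  structure(list(kind = kind, positions = as.integer(positions),
                 width = as.integer(width), gap = as.integer(gap),
                 initial_thickness = as.integer(initial_thickness),
                 stride = as.integer(stride)),
            class = "inoculum_spec")
}

## Sites covered by a width-w element centered at p: even widths take the
## extra site on the left.
element_sites <- function(p, w) {
  start <- p - ceiling((w - 1) / 2)
  seq.int(start, start + w - 1L)
}

#' Build the initial lattice from an inoculum specification
#'
#' Every planted site starts with `initial_thickness` bacteria in
#' exponential growth (state 1); all other sites are empty.  Quorum is zero
#' everywhere, odor is zero, and the generation counter starts at 0.
#'
#' @param spec An [inoculum_spec()].
#' @param params A [colony_params()] supplying the lattice length `L` and
#'   the thickness bound `N`.
#' @return A [colony_state()] of length `params$L`.
#' @examples
#' p <- colony_params(Qlim = 400, Olim1 = 30, Olim2 = 1200, L = 101)
#' s <- build_inoculum(inoculum_spec("RING_SECTION", 51, width = 3, gap = 11), p)
#' which(s$thickness > 0)
#' @export
build_inoculum <- function(spec, params) {
  if (!inherits(spec, "inoculum_spec")) stop("spec must be an inoculum_spec")
  L <- params$L
  if (spec$initial_thickness > params$N)
    stop("inoculum: 'initial_thickness' (", spec$initial_thickness,
         ") exceeds N = ", params$N, call. = FALSE)

  occupied <- switch(spec$kind,
    POINT = ,
    MULTI = lapply(spec$positions, element_sites, w = 1L),
    BLOCK = lapply(spec$positions, element_sites, w = spec$width),
    RING_SECTION = {
      unlist(lapply(spec$positions, function(p) {
        # two symmetric segments flanking a central gap
        left_end <- p - ceiling((spec$gap - 1) / 2) - 1L
        right_start <- left_end + spec$gap + 1L
        list(seq.int(left_end - spec$width + 1L, left_end),
             seq.int(right_start, right_start + spec$width - 1L))
      }), recursive = FALSE)
    },
    BACKGROUND = as.list(seq.int(1L, L, by = spec$stride))
  )
  sites <- unlist(occupied)
  if (any(sites < 1L | sites > L))
    stop("inoculum: planted sites ",
         paste(range(sites), collapse = ".."),
         " fall outside the lattice [1, ", L, "]", call. = FALSE)
  if (anyDuplicated(sites))
    stop("inoculum: planted elements overlap at site ",
         sites[anyDuplicated(sites)], call. = FALSE)

  thickness <- numeric(L)
  state <- integer(L)
  thickness[sites] <- spec$initial_thickness
  state[sites] <- 1L
  colony_state(thickness, state)
}
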