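## Config dialect: one YAML document, versioned, three blocks.
##   params:   every colony_params field; max_generations and
##             decrement_donor optional (defaults 10000 / true)
##   inoculum: kind + positions (+ width, gap, initial_thickness, stride)
##   output:   optional; trace / summary / report paths, thin, plot
## Unknown keys anywhere are an error.

CONFIG_VERSION <- 1L

REQUIRED_PARAM_KEYS <- c("N", "P", "S", "A", "O", "D", "G",
                         "Qlim", "Olim1", "Olim2", "L")
OPTIONAL_PARAM_KEYS <- c("max_generations", "decrement_donor")
INOCULUM_KEYS <- c("kind", "positions", "width", "gap",
                   "initial_thickness", "stride")
OUTPUT_KEYS <- c("trace", "summary", "report", "thin", "plot")

#' Load and validate a run configuration
#'
#' Reads the package's YAML configuration dialect: a `params` block holding
#' every model parameter (`max_generations` defaults to 10000,
#' `decrement_donor` to true), an `inoculum` block describing the planting
#' geometry, and an optional `output` block (paths, snapshot thinning,
#' plot toggle).  Validation is strict: unknown keys, missing mandatory
#' keys, type mismatches and invariant violations are all rejected with the
#' offending key named.
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `run_config` with elements `params`
#'   ([colony_params()]), `inoculum` ([inoculum_spec()]) and `output`
#'   (named list).
#' @seealso [write_config()], [default_config_path()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_blocks <- c("version", "params", "inoculum", "output")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    stop("config: unknown top-level key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (blk in c("params", "inoculum"))
    if (is.null(raw[[blk]]))
      stop("config: missing mandatory block '", blk, "'", call. = FALSE)

  pk <- raw$params
  # YAML 1.1 reads the bare key `N` as the boolean FALSE; map it back
  names(pk)[names(pk) == "FALSE"] <- "N"
  unknown <- setdiff(names(pk), c(REQUIRED_PARAM_KEYS, OPTIONAL_PARAM_KEYS))
  if (length(unknown))
    stop("config: unknown key(s) in 'params': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(REQUIRED_PARAM_KEYS, names(pk))
  if (length(missing))
    stop("config: missing mandatory key(s) in 'params': ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (k in setdiff(names(pk), "decrement_donor"))
    if (!is.numeric(pk[[k]]) || length(pk[[k]]) != 1L)
      stop("config: key 'params.", k, "' must be a single number",
           call. = FALSE)
  params <- colony_params(
    N = pk$N, P = pk$P, S = pk$S, A = pk$A, O = pk$O, D = pk$D, G = pk$G,
    Qlim = pk$Qlim, Olim1 = pk$Olim1, Olim2 = pk$Olim2, L = pk$L,
    max_generations = if (is.null(pk$max_generations)) 10000L else pk$max_generations,
    decrement_donor = if (is.null(pk$decrement_donor)) TRUE else pk$decrement_donor)

  ik <- raw$inoculum
  unknown <- setdiff(names(ik), INOCULUM_KEYS)
  if (length(unknown))
    stop("config: unknown key(s) in 'inoculum': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(ik$kind))
    stop("config: missing mandatory key 'inoculum.kind'", call. = FALSE)
  inoculum <- inoculum_spec(
    kind = ik$kind,
    positions = if (is.null(ik$positions)) integer() else ik$positions,
    width = if (is.null(ik$width)) 1L else ik$width,
    gap = if (is.null(ik$gap)) 0L else ik$gap,
    initial_thickness = if (is.null(ik$initial_thickness)) 1L else ik$initial_thickness,
    stride = if (is.null(ik$stride)) 10L else ik$stride)

  ok <- raw$output
  unknown <- setdiff(names(ok), OUTPUT_KEYS)
  if (length(unknown))
    stop("config: unknown key(s) in 'output': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  output <- list(trace = ok$trace, summary = ok$summary, report = ok$report,
                 thin = if (is.null(ok$thin)) 1L else as.integer(ok$thin),
                 plot = isTRUE(ok$plot))

  # inoculum must fit the lattice: build once to trigger geometry checks
  build_inoculum(inoculum, params)

  structure(list(params = params, inoculum = inoculum, output = output),
            class = "run_config")
}

#' Write a run configuration
#'
#' Serializes a parameter object and an inoculum specification back to the
#' YAML config dialect, such that [load_config()] reproduces an identical
#' lattice.
#'
#' @param params A [colony_params()].
#' @param inoculum An [inoculum_spec()].
#' @param path Output file path.
#' @param output Optional output block (named list).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, inoculum, path, output = NULL) {
  doc <- list(version = CONFIG_VERSION,
              params = list(N = params$N, P = params$P, S = params$S,
                            A = params$A, O = params$O, D = params$D,
                            G = params$G, Qlim = params$Qlim,
                            Olim1 = params$Olim1, Olim2 = params$Olim2,
                            L = params$L,
                            max_generations = params$max_generations,
                            decrement_donor = params$decrement_donor),
              inoculum = list(kind = inoculum$kind,
                              positions = inoculum$positions,
                              width = inoculum$width, gap = inoculum$gap,
                              initial_thickness = inoculum$initial_thickness,
                              stride = inoculum$stride))
  if (!is.null(output)) doc$output <- output
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Path to the shipped default configuration
#'
#' The shipped config runs the reference rimmed clone (reference rates plus
#' the tuned sensitivity triple of [default_rimmed_thresholds()]) from a
#' single-point inoculum at the center of a 201-site dish.
#'
#' @return File path of the installed default YAML config.
#' @export
default_config_path <- function() {
  system.file("extdata", "rimmed_point.yaml", package = "colonysim",
              mustWork = TRUE)
}
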