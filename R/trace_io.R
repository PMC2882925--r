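## Trace TSV dialect (versioned, header comments carry metadata):
##   site file:    generation  site_index  thickness  state  quorum
##   summary file: generation  extent  biomass  odor
## Floating values are written with 12 significant digits; states are the
## integer codes of CELL_STATES; site_index is 1-based.  Stationary ages are
## not serialized (a trace is a record, not a restart checkpoint).

TRACE_VERSION <- 1L

fmt12 <- function(x) sprintf("%.12g", x)

#' Write a simulation trace to tab-separated files
#'
#' Writes the per-(generation, site) table to `path` and the per-generation
#' summary series (extent, biomass, odor) to `summary_path`.  Header
#' comment lines (`#`-prefixed) carry the dialect version, the full
#' parameter set and the termination generation, so [read_trace()] can
#' rebuild the trace object.
#'
#' @param trace A `colony_trace`.
#' @param path Output path for the site table.
#' @param summary_path Output path for the summary table; default: `path`
#'   with a `_summary.tsv` suffix.
#' @param thin Keep every `thin`-th recorded snapshot (plus the first and
#'   last) in the site table.  The summary table is never thinned.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, summary_path = NULL, thin = 1L) {
  if (is.null(summary_path)) summary_path <- default_summary_path(path)
  thin <- max(1L, as.integer(thin))
  p <- trace$params

  keep <- unique(c(which(trace$generations %% thin == 0L),
                   1L, length(trace$generations)))
  keep <- sort(keep)
  gens <- trace$generations[keep]

  hdr <- c(sprintf("# colonysim trace v%d", TRACE_VERSION),
           sprintf("# param %s=%s",
                   c("N", "P", "S", "A", "O", "D", "G", "Qlim", "Olim1",
                     "Olim2", "L", "max_generations", "decrement_donor"),
                   c(fmt12(c(p$N, p$P, p$S, p$A, p$O, p$D, p$G, p$Qlim,
                             p$Olim1, p$Olim2, p$L, p$max_generations)),
                     tolower(p$decrement_donor))),
           sprintf("# terminated_at=%s", trace$terminated_at),
           sprintf("# thin=%d", thin))

  L <- p$L
  body <- unlist(lapply(seq_along(keep), function(i) {
    r <- keep[i]
    paste(gens[i], seq_len(L), fmt12(trace$thickness[r, ]),
          trace$state[r, ], fmt12(trace$quorum[r, ]), sep = "\t")
  }))
  writeLines(c(hdr, "generation\tsite_index\tthickness\tstate\tquorum", body),
             path)

  n <- length(trace$extent_series)
  writeLines(c(sprintf("# colonysim trace summary v%d", TRACE_VERSION),
               "generation\textent\tbiomass\todor",
               paste(seq_len(n) - 1L, trace$extent_series,
                     fmt12(trace$biomass_series), fmt12(trace$odor_series),
                     sep = "\t")),
             summary_path)
  invisible(path)
}

default_summary_path <- function(path) {
  paste0(sub("\\.tsv$", "", path), "_summary.tsv")
}

#' Read a simulation trace from tab-separated files
#'
#' Inverse of [write_trace()]: rebuilds a `colony_trace` from the site and
#' summary tables.  Snapshot matrices, summary series, parameters and the
#' termination generation round-trip exactly at the serialized precision
#' (12 significant digits); per-site stationary ages are not serialized and
#' come back undefined in the `final` state.
#'
#' @param path Path of the site table written by [write_trace()].
#' @param summary_path Path of the summary table; default as in
#'   [write_trace()].
#' @return A `colony_trace`.
#' @export
read_trace <- function(path, summary_path = NULL) {
  if (is.null(summary_path)) summary_path <- default_summary_path(path)
  for (f in c(path, summary_path))
    if (!file.exists(f)) stop("trace file not found: ", f, call. = FALSE)

  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("^# colonysim trace v", hdr[1L]))
    stop("parse error in ", path, " line 1: not a colonysim trace file",
         call. = FALSE)
  meta <- parse_header(hdr)
  p <- meta$params

  first_data <- length(hdr) + 2L          # header comments + column line
  col_line <- lines[length(hdr) + 1L]
  if (!identical(col_line, "generation\tsite_index\tthickness\tstate\tquorum"))
    stop("parse error in ", path, " line ", length(hdr) + 1L,
         ": unexpected column header", call. = FALSE)
  body <- lines[first_data:length(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop("parse error in ", path, " line ", first_data + bad[1L] - 1L,
         ": expected 5 tab-separated fields", call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 5L, byrow = TRUE)
  if (anyNA(m))
    stop("parse error in ", path, ": non-numeric field", call. = FALSE)

  L <- p$L
  gens <- unique(m[, 1L])
  nsnap <- length(gens)
  if (nrow(m) != nsnap * L)
    stop("parse error in ", path, ": expected ", nsnap * L,
         " site rows, found ", nrow(m), call. = FALSE)
  thick <- matrix(m[, 3L], nrow = nsnap, ncol = L, byrow = TRUE)
  state <- matrix(as.integer(m[, 4L]), nrow = nsnap, ncol = L, byrow = TRUE)
  quorum <- matrix(m[, 5L], nrow = nsnap, ncol = L, byrow = TRUE)

  slines <- readLines(summary_path)
  sbody <- slines[!grepl("^#", slines)][-1L]
  sparts <- strsplit(sbody, "\t", fixed = TRUE)
  bad <- which(lengths(sparts) != 4L)
  if (length(bad))
    stop("parse error in ", summary_path, ": expected 4 tab-separated fields",
         call. = FALSE)
  sm <- matrix(as.numeric(unlist(sparts)), ncol = 4L, byrow = TRUE)

  last <- nsnap
  final_state <- state[last, ]
  final <- list(generation = as.integer(gens[last]),
                thickness = thick[last, ],
                state = final_state,
                age = ifelse(final_state == 2L, 0, NA_real_),
                quorum = quorum[last, ],
                odor = sm[nrow(sm), 4L])
  class(final) <- "colony_state"

  structure(list(params = p,
                 generations = as.integer(gens),
                 thickness = thick, state = state, quorum = quorum,
                 odor = sm[match(gens, sm[, 1L]), 4L],
                 extent_series = as.integer(sm[, 2L]),
                 biomass_series = sm[, 3L],
                 odor_series = sm[, 4L],
                 terminated_at = meta$terminated_at,
                 final = final),
            class = "colony_trace")
}

parse_header <- function(hdr) {
  kv <- sub("^# param ", "", grep("^# param ", hdr, value = TRUE))
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  named <- stats::setNames(as.list(vals), keys)
  need <- c("N", "P", "S", "A", "O", "D", "G", "Qlim", "Olim1", "Olim2", "L")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("parse error: trace header lacks parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(k, default = NULL) {
    if (is.null(named[[k]])) return(default)
    as.numeric(named[[k]])
  }
  params <- colony_params(
    N = num("N"), P = num("P"), S = num("S"), A = num("A"), O = num("O"),
    D = num("D"), G = num("G"), Qlim = num("Qlim"), Olim1 = num("Olim1"),
    Olim2 = num("Olim2"), L = num("L"),
    max_generations = num("max_generations", 10000),
    decrement_donor = !identical(named[["decrement_donor"]], "false"))
  term_line <- grep("^# terminated_at=", hdr, value = TRUE)
  term <- sub("^# terminated_at=", "", term_line[1L])
  list(params = params,
       terminated_at = if (term == "NA") NA_integer_ else as.integer(term))
}

#' Write a phenotype report as structured YAML
#'
#' Schema (all keys always present): `classification` (string),
#' `colony_count` (int), `generations_to_maturity` (int or null),
#' `imperfect_rim` (bool), `colonies` (list; per colony `navel`,
#' `interstitial`, `rim`, `total` diameters in sites), `zones` (list; per
#' zone `colony`, `zone`, `start`, `end`, `width`, `mean_thickness`).
#'
#' @param report A [classify_phenotype()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  seg <- report$segmentation
  doc <- list(
    version = TRACE_VERSION,
    classification = report$classification,
    colony_count = report$colony_count,
    generations_to_maturity = report$generations_to_maturity,
    imperfect_rim = report$imperfect_rim,
    colonies = lapply(seq_len(nrow(report$diameters)), function(i)
      as.list(report$diameters[i, ])),
    zones = lapply(seq_len(nrow(seg)), function(i)
      list(colony = seg$colony[i], zone = seg$zone[i],
           start = seg$start[i], end = seg$end[i], width = seg$width[i],
           mean_thickness = seg$mean_thickness[i])))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Render trace profiles to an image file
#'
#' Writes the thickness and quorum profiles at the requested generations,
#' plus the extent and odor time series, to a PDF (default) or PNG file
#' chosen by the file extension.
#'
#' @param trace A `colony_trace`.
#' @param generations Generations to draw; must be recorded in the trace.
#' @param path Output image path (`.pdf` or `.png`).
#' @return `path`, invisibly.
#' @export
plot_profiles <- function(trace, generations, path) {
  if (length(generations) == 0L)
    stop("no generations requested", call. = FALSE)
  absent <- setdiff(generations, trace$generations)
  if (length(absent))
    stop("generation(s) ", paste(absent, collapse = ", "),
         " not recorded; available: ",
         paste(trace$generations, collapse = ", "), call. = FALSE)
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (ext == "png") grDevices::png(path, width = 900, height = 900)
  else grDevices::pdf(path, width = 7, height = 9)
  on.exit(grDevices::dev.off())
  plot(trace, generations = generations)
  invisible(path)
}
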