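#' Segment a thickness profile into colony zones
#'
#' Occupied sites are labeled TALL when their thickness is at least
#' `tall_fraction * N` and THIN otherwise; maximal runs of equal labels are
#' merged, and within each connected colony the tall runs are assigned
#' anatomical zone labels outward from the colony center:
#' \itemize{
#'   \item a single tall run is the NAVEL;
#'   \item with two tall runs the one nearer the colony center is the NAVEL
#'     and the other the RIM;
#'   \item with three or more the outermost two are the RIM pair and every
#'     interior tall run is a NAVEL (two or more navels inside one rim pair
#'     mark a confluent body).
#' }
#' Thin runs between a navel and a rim are INTERSTITIAL; thin runs outside
#' the outermost rims (freshly colonized edge sites) are absorbed into the
#' adjacent rim zone, so that zone diameters add up to the colony diameter.
#' A colony with no tall run at all becomes a single INTERSTITIAL (flat)
#' zone.  Colonies are maximal runs of occupied sites: a single empty site
#' separates colonies.
#'
#' @param profile Numeric vector of per-site thickness (typically
#'   [final_profile()] of a terminated trace).
#' @param params The [colony_params()] of the run (for `N`).
#' @param tall_fraction Thickness cut separating tall from thin zones, as a
#'   fraction of `N`; strictly between 0 and 1 (default 0.5).
#'
#' @return An object of class `zone_segmentation`: a data frame with columns
#'   `colony`, `zone` (NAVEL / INTERSTITIAL / RIM), `start`, `end`,
#'   `width`, `mean_thickness`, ordered left to right.
#' @examples
#' p <- colony_params(Qlim = 1, Olim1 = 1, Olim2 = 1, N = 140)
#' segment_zones(zone_profile(c(5, 8, 3), c(140, 30, 120), L = 30), p)
#' @export
segment_zones <- function(profile, params, tall_fraction = 0.5) {
  if (tall_fraction <= 0 || tall_fraction >= 1)
    stop("'tall_fraction' must lie strictly between 0 and 1", call. = FALSE)
  if (all(profile <= 0)) stop("no colony: profile is all empty", call. = FALSE)
  cut <- tall_fraction * params$N

  occ_runs <- runs_of(profile > 0)
  occ_runs <- occ_runs[occ_runs$value, , drop = FALSE]

  zones <- do.call(rbind, lapply(seq_len(nrow(occ_runs)), function(ci) {
    lo <- occ_runs$start[ci]; hi <- occ_runs$end[ci]
    seg <- profile[lo:hi]
    r <- runs_of(seg >= cut)
    tall_idx <- which(r$value)
    m <- length(tall_idx)
    lab <- character(nrow(r))
    if (m == 0L) {
      lab[] <- "INTERSTITIAL"
    } else {
      center <- (1 + length(seg)) / 2
      tl <- rep("NAVEL", m)
      if (m == 2L) {
        mid <- (r$start[tall_idx] + r$end[tall_idx]) / 2
        tl[order(abs(mid - center))[2L]] <- "RIM"
      } else if (m >= 3L) {
        tl[c(1L, m)] <- "RIM"
      }
      lab[tall_idx] <- tl
      # thin runs: interstitial inside the outer rims, edge otherwise
      first_tall <- tall_idx[1L]; last_tall <- tall_idx[m]
      for (k in which(!r$value)) {
        lab[k] <- if (k > first_tall && k < last_tall) "INTERSTITIAL" else "EDGE"
      }
      # absorb edge thin runs into the adjacent outermost tall zone
      for (k in which(lab == "EDGE" & seq_len(nrow(r)) < first_tall))
        r$start[first_tall] <- min(r$start[first_tall], r$start[k])
      for (k in which(lab == "EDGE" & seq_len(nrow(r)) > last_tall))
        r$end[last_tall] <- max(r$end[last_tall], r$end[k])
      keep <- lab != "EDGE"
      r <- r[keep, , drop = FALSE]
      lab <- lab[keep]
    }
    data.frame(colony = ci, zone = lab,
               start = r$start + lo - 1L, end = r$end + lo - 1L)
  }))

  zones$width <- zones$end - zones$start + 1L
  zones$mean_thickness <- vapply(seq_len(nrow(zones)), function(i)
    mean(profile[zones$start[i]:zones$end[i]]), numeric(1))
  rownames(zones) <- NULL
  structure(zones, class = c("zone_segmentation", "data.frame"),
            tall_fraction = tall_fraction, N = params$N)
}

## Run-length encoding with start/end indices.
runs_of <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = end - r$lengths + 1L, end = end)
}

#' Classify a segmented colony profile
#'
#' Maps a zone segmentation and its originating trace to one of the clone
#' phenotypes:
#' \describe{
#'   \item{RIMMED}{a colony with navel, interstitial ring and rim — or a
#'     single tall zone whose flanks rebound into a shallow peripheral ridge
#'     that stays below the tall cut (an "imperfect rim", flagged in
#'     `imperfect_rim`).}
#'   \item{CONFLUENT_RIMMED}{two or more navels sharing one outermost rim
#'     pair within a single connected body.}
#'   \item{MACULA}{a single tall plateau with no rim, wider than
#'     `macula_width` (typically the interstitial outer diameter of a
#'     rimmed control colony).}
#'   \item{RIMLESS}{a single tall zone whose flanks decay monotonically
#'     (plateaus allowed) with neither a thin ring nor a peripheral
#'     rebound.}
#'   \item{UNDEVELOPED}{total occupied extent below `min_extent` sites.}
#' }
#'
#' @param segmentation A [segment_zones()] result.
#' @param trace The `colony_trace` the profile came from; must be
#'   terminated, otherwise classification is refused.
#' @param macula_width Reference width (sites) above which a rimless plateau
#'   is called a MACULA; `NA` disables the macula call (pure shape-based
#'   classification).  Scenario drivers pass the rimmed-control interstitial
#'   outer diameter here.
#' @param min_extent Minimal total extent (sites) for a developed colony.
#'
#' @return An object of class `phenotype_report`: a list with
#'   `classification`, per-colony `diameters` (navel / interstitial / rim /
#'   total), `colony_count`, `generations_to_maturity`, `imperfect_rim`, and
#'   the `segmentation`.
#' @export
classify_phenotype <- function(segmentation, trace, macula_width = NA,
                               min_extent = 5L) {
  if (is.na(trace$terminated_at))
    stop("classification refused: trace did not terminate ",
         "(partial development; raise max_generations)", call. = FALSE)
  seg <- segmentation
  colonies <- unique(seg$colony)
  extent <- sum(seg$width)

  per_colony <- lapply(colonies, function(ci) {
    z <- seg[seg$colony == ci, , drop = FALSE]
    c(navel = sum(z$width[z$zone == "NAVEL"]),
      interstitial = sum(z$width[z$zone == "INTERSTITIAL"]),
      rim = sum(z$width[z$zone == "RIM"]),
      total = sum(z$width))
  })
  diameters <- do.call(rbind, per_colony)
  rownames(diameters) <- paste0("colony", colonies)

  imperfect <- FALSE
  classification <- if (extent < min_extent) {
    "UNDEVELOPED"
  } else {
    per <- vapply(colonies, function(ci) {
      z <- seg[seg$colony == ci, , drop = FALSE]
      n_nav <- sum(z$zone == "NAVEL")
      n_int <- sum(z$zone == "INTERSTITIAL")
      n_rim <- sum(z$zone == "RIM")
      if (n_nav >= 2L && n_rim >= 2L) return("CONFLUENT_RIMMED")
      if (n_nav >= 1L && n_int >= 1L && n_rim >= 1L) return("RIMMED")
      if (n_nav == 1L && n_rim == 0L) {
        prof <- final_profile(trace)
        cut <- attr(seg, "tall_fraction") * attr(seg, "N")
        shape <- plateau_shape(prof, min(z$start), max(z$end), cut)
        if (shape$rebound) return("RIMMED_IMPERFECT")
        if (!is.na(macula_width) && shape$plateau_width > macula_width)
          return("MACULA")
        return("RIMLESS")
      }
      "UNDEVELOPED"
    }, character(1))
    if (any(per == "CONFLUENT_RIMMED")) "CONFLUENT_RIMMED"
    else if (any(per == "MACULA")) "MACULA"
    else if (any(per == "RIMMED_IMPERFECT")) { imperfect <- TRUE; "RIMMED" }
    else if (any(per == "RIMMED")) "RIMMED"
    else if (any(per == "RIMLESS")) "RIMLESS"
    else "UNDEVELOPED"
  }

  structure(list(classification = classification,
                 diameters = diameters,
                 colony_count = length(colonies),
                 generations_to_maturity = trace$terminated_at,
                 imperfect_rim = imperfect,
                 segmentation = seg),
            class = "phenotype_report")
}

## Shape of a single-tall-zone colony over sites lo..hi: flanks decay
## monotonically (non-strictly) from the tall plateau to both colony edges,
## or rebound into a shallow sub-cut peripheral ridge.
plateau_shape <- function(profile, lo, hi, cut) {
  seg <- profile[lo:hi]
  tall <- which(seg >= cut)
  left <- rev(seg[seq_len(min(tall))])           # plateau edge -> colony edge
  right <- seg[seq.int(max(tall), length(seg))]
  rebound <- function(v) any(diff(v) > 0)        # any rise moving outward
  list(rebound = rebound(left) || rebound(right),
       plateau_width = max(tall) - min(tall) + 1L)
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("Colony phenotype report\n")
  cat(sprintf("  classification: %s%s\n", x$classification,
              if (x$imperfect_rim) " (imperfect, shallow rim)" else ""))
  cat(sprintf("  colonies: %d; generations to maturity: %s\n",
              x$colony_count, x$generations_to_maturity))
  cat("  zone diameters (sites):\n")
  print(x$diameters)
  invisible(x)
}

#' Build a synthetic thickness profile from a zone recipe
#'
#' Fixture generator for classifier tests: lays out consecutive zones of
#' given widths and thickness levels, centered on the lattice, with empty
#' substrate elsewhere.  No simulation involved.
#'
#' @param widths Integer vector of zone widths (sites), left to right.
#' @param levels Numeric vector of per-zone thickness levels, same length.
#' @param L Lattice length (default: total width + 10).
#' @return Numeric thickness profile of length `L`.
#' @examples
#' zone_profile(c(3, 8, 5, 8, 3), c(120, 30, 140, 30, 120), L = 41)
#' @export
zone_profile <- function(widths, levels, L = sum(widths) + 10L) {
  stopifnot(length(widths) == length(levels), all(widths >= 1))
  total <- sum(widths)
  if (total > L) stop("zones wider than lattice", call. = FALSE)
  prof <- numeric(L)
  start <- floor((L - total) / 2) + 1L
  prof[seq.int(start, start + total - 1L)] <- rep(levels, times = widths)
  prof
}
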