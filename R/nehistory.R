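# Piecewise-constant Ne trajectories: parsing and windowed mean summaries.

#' Construct an Ne trajectory from an epoch table
#'
#' @param start,end epoch boundaries (time before present, \code{start < end};
#'   the last \code{end} may be \code{Inf}).
#' @param ne diploid effective population size per epoch.
#' @param units time unit tag.
#' @return a [NeTrajectory-class]
#' @export
neTrajectory <- function(start, end, ne, units = "years") {
  keep <- is.finite(ne) & ne > 0
  if (!all(keep)) {
    warning(sprintf("dropped %d epoch(s) with zero/non-finite Ne", sum(!keep)))
    start <- start[keep]; end <- end[keep]; ne <- ne[keep]
  }
  new("NeTrajectory",
      epochs = data.frame(start = start, end = end, ne = ne),
      units = units)
}

#' Read an Ne trajectory from a .coal or TSV file
#'
#' Two dialects are accepted. The Relate-style \code{.coal} dialect has a
#' group-label line, a line of epoch start times, and one or more rows of
#' haploid coalescence rates whose leading fields identify the group pair;
#' Ne per epoch is \code{1 / (2 * rate)}, with zero/non-finite rates
#' dropped with a warning. The plain dialect is a 3-column table
#' (\code{start end ne}), whitespace- or tab-separated, with an optional
#' header.
#'
#' @param path path to the trajectory file.
#' @param units time unit tag (the trajectories used here are in years;
#'   the species is annual, so 1 generation = 1 year).
#' @return a [NeTrajectory-class]
#' @export
readCoal <- function(path, units = "years") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty trajectory file: ", path)
  toks <- strsplit(lines, "[ \t]+")
  is_num <- vapply(toks, function(x) all(!is.na(suppressWarnings(as.numeric(x)))),
                   logical(1))
  # plain TSV dialect: all (non-header) lines numeric with 3 fields
  n_fields <- lengths(toks)
  if (all(n_fields == 3L) && all(is_num[-1])) {
    skip <- if (is_num[1]) 0L else 1L
    tab <- read.table(path, header = skip == 1L)
    names(tab) <- c("start", "end", "ne")
    traj <- neTrajectory(tab$start, tab$end, tab$ne, units = units)
    .checkMonotoneEpochs(traj)
    return(traj)
  }
  # Relate .coal dialect
  i <- if (is_num[1]) 1L else 2L      # skip group-label line when present
  bounds <- as.numeric(toks[[i]])
  if (length(bounds) < 2L) stop("need at least 2 epoch boundaries")
  if (any(diff(bounds) <= 0)) stop("epoch boundaries must be strictly increasing")
  ratesline <- toks[[i + 1L]]
  vals <- suppressWarnings(as.numeric(ratesline))
  rates <- vals[!is.na(vals)]
  # leading group-index fields (e.g. "0 0") precede the per-epoch rates
  if (length(rates) > length(bounds))
    rates <- rates[(length(rates) - length(bounds) + 1L):length(rates)]
  starts <- bounds
  ends <- c(bounds[-1L], Inf)
  n <- min(length(rates), length(starts))
  ne <- 1 / (2 * rates[seq_len(n)])
  traj <- neTrajectory(starts[seq_len(n)], ends[seq_len(n)], ne, units = units)
  .checkMonotoneEpochs(traj)
  traj
}

.checkMonotoneEpochs <- function(traj) {
  e <- epochs(traj)
  if (nrow(e) > 1 && any(diff(e$start) <= 0))
    stop("epoch boundaries must be strictly increasing")
  invisible(traj)
}

#' Write an Ne trajectory as a 3-column TSV
#'
#' @param traj a [NeTrajectory-class]
#' @param path output path.
#' @return the path, invisibly
#' @export
writeCoalTsv <- function(traj, path) {
  write.table(epochs(traj), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Epoch overlaps with a window, returning durations and Ne values.
.windowOverlap <- function(traj, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  e <- epochs(traj)
  lo <- pmax(e$start, window[1])
  hi <- pmin(e$end, window[2])
  keep <- hi > lo
  if (!any(keep)) stop("window does not overlap the trajectory support")
  support <- c(min(e$start), max(e$end))
  if (window[1] < support[1] || window[2] > support[2])
    message(sprintf("window [%g, %g] clipped to trajectory support [%g, %g]",
                    window[1], window[2],
                    max(window[1], support[1]), min(window[2], support[2])))
  list(w = (hi - lo)[keep], ne = e$ne[keep])
}

#' Geometric mean Ne over a time window
#'
#' Exponential of the duration-weighted mean of log Ne over the
#' intersection of the window with the trajectory. Duration weighting is
#' the default because the epochs of coalescence-rate trajectories are
#' log-spaced in time; \code{weighting = "epoch"} weights every
#' overlapping epoch equally instead.
#'
#' @param traj a [NeTrajectory-class]
#' @param window numeric length-2, \code{c(t0, t1)} in trajectory units.
#' @param weighting \code{"duration"} (default) or \code{"epoch"}.
#' @return numeric Ne
#' @export
geometricMeanNe <- function(traj, window, weighting = c("duration", "epoch")) {
  weighting <- match.arg(weighting)
  ov <- .windowOverlap(traj, window)
  w <- if (weighting == "duration") ov$w else rep(1, length(ov$w))
  exp(weighted.mean(log(ov$ne), w))
}

#' Harmonic mean Ne over a time window
#'
#' Duration-weighted harmonic mean of Ne over the window intersection
#' (the summary that governs long-term coalescence rates).
#'
#' @inheritParams geometricMeanNe
#' @return numeric Ne
#' @export
harmonicMeanNe <- function(traj, window, weighting = c("duration", "epoch")) {
  weighting <- match.arg(weighting)
  ov <- .windowOverlap(traj, window)
  w <- if (weighting == "duration") ov$w else rep(1, length(ov$w))
  1 / weighted.mean(1 / ov$ne, w)
}
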