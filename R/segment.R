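#' Call bars and interbars on an intensity profile
#'
#' Implements run-length thresholding of a flank profile against its own mean
#' gray value. Scanning anterior to posterior in the interbar state, a bar
#' opens at the first pixel of the first run of at least \code{min_run}
#' consecutive values strictly below the mean. Once open, the bar closes when
#' a run of at least \code{min_run} consecutive values at or above the mean
#' occurs; the bar's end is the last below-mean pixel before that closing
#' run, so shorter above-mean interruptions stay inside the bar. A bar still
#' open at the end of the profile closes at the last pixel. All remaining
#' pixels, including leading and trailing stretches, form interbars. Values
#' exactly equal to the mean count as interbar, so a constant profile has no
#' bars.
#'
#' @param profile An \code{\link{intensity_profile}}, or a bare numeric
#'   vector of gray values.
#' @param min_run Minimum run length (pixels) to open or close a bar;
#'   default 5.
#' @return An object of class \code{"bar_segmentation"}: a list with
#'   \code{threshold} (the profile mean), \code{min_run}, \code{length_px},
#'   and \code{segments}, a data frame with columns \code{type}
#'   (\code{"bar"}/\code{"interbar"}), \code{start_px}, \code{end_px}
#'   (0-based, half-open), sorted and alternating, exactly covering the
#'   profile.
#' @export
segment_bars <- function(profile, min_run = 5L) {
  vals <- if (inherits(profile, "intensity_profile")) profile$values
          else as.numeric(profile)
  n <- length(vals)
  if (n < 1L) stop("cannot segment an empty profile")
  min_run <- as.integer(min_run)
  if (min_run < 1L) stop("min_run must be at least 1")
  thr <- mean(vals)
  below <- vals < thr

  bar_start <- integer(0); bar_end <- integer(0)  # 1-based inclusive
  state <- "interbar"
  open_at <- NA_integer_
  last_below <- NA_integer_
  i <- 1L
  while (i <= n) {
    # length of the homogeneous run starting at i
    j <- i
    while (j < n && below[j + 1L] == below[i]) j <- j + 1L
    run_len <- j - i + 1L
    if (state == "interbar") {
      if (below[i] && run_len >= min_run) {
        state <- "bar"
        open_at <- i
        last_below <- j
      }
    } else {
      if (below[i]) {
        last_below <- j
      } else if (run_len >= min_run) {
        bar_start <- c(bar_start, open_at)
        bar_end <- c(bar_end, last_below)
        state <- "interbar"
      }
    }
    i <- j + 1L
  }
  if (state == "bar") {  # open at profile end: close at the last pixel
    bar_start <- c(bar_start, open_at)
    bar_end <- c(bar_end, n)
  }

  segs <- .segments_from_bars(bar_start, bar_end, n)
  structure(list(threshold = thr, min_run = min_run, length_px = n,
                 segments = segs),
            class = "bar_segmentation")
}

# build the alternating bar/interbar partition from 1-based inclusive bars
.segments_from_bars <- function(bar_start, bar_end, n) {
  type <- character(0); start <- integer(0); end <- integer(0)
  pos <- 1L
  for (k in seq_along(bar_start)) {
    if (bar_start[k] > pos) {
      type <- c(type, "interbar")
      start <- c(start, pos - 1L); end <- c(end, bar_start[k] - 1L)
    }
    type <- c(type, "bar")
    start <- c(start, bar_start[k] - 1L); end <- c(end, bar_end[k])
    pos <- bar_end[k] + 1L
  }
  if (pos <= n) {
    type <- c(type, "interbar")
    start <- c(start, pos - 1L); end <- c(end, n)
  }
  data.frame(type = type, start_px = as.integer(start),
             end_px = as.integer(end), stringsAsFactors = FALSE)
}

#' Extract the bar intervals of a segmentation
#'
#' @param seg A \code{bar_segmentation}.
#' @return Data frame of bar rows only (\code{start_px}, \code{end_px}).
#' @export
bars <- function(seg) {
  stopifnot(inherits(seg, "bar_segmentation"))
  seg$segments[seg$segments$type == "bar", c("start_px", "end_px"),
               drop = FALSE]
}

#' @rdname bars
#' @export
interbars <- function(seg) {
  stopifnot(inherits(seg, "bar_segmentation"))
  seg$segments[seg$segments$type == "interbar", c("start_px", "end_px"),
               drop = FALSE]
}

#' @export
print.bar_segmentation <- function(x, ...) {
  nb <- sum(x$segments$type == "bar")
  cat("Bar segmentation:", nb, "bar(s) over", x$length_px, "px",
      sprintf("(threshold %.2f, min run %d)\n", x$threshold, x$min_run))
  if (nb > 0) {
    b <- bars(x)
    cat("  bars [start, end):",
        paste(sprintf("[%d, %d)", b$start_px, b$end_px), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
plot.bar_segmentation <- function(x, profile = NULL, ...) {
  if (!is.null(profile)) {
    plot(profile, ...)
  } else {
    graphics::plot(NULL, xlim = c(0, x$length_px), ylim = c(0, 255),
                   xlab = "position (px)", ylab = "gray value", ...)
  }
  b <- bars(x)
  if (nrow(b))
    graphics::rect(b$start_px, 0, b$end_px, 255,
                   col = grDevices::adjustcolor("grey20", alpha.f = 0.2),
                   border = NA)
  graphics::abline(h = x$threshold, lty = 2, col = "firebrick")
  invisible(x)
}

#' Write segmentation intervals as BED-like CSV
#'
#' One row per segment: \code{individual_id, segment_type, start_px, end_px}
#' with 0-based half-open coordinates.
#'
#' @param seg A \code{bar_segmentation}.
#' @param id Individual identifier for the first column.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_segments_csv <- function(seg, id, path) {
  stopifnot(inherits(seg, "bar_segmentation"))
  df <- data.frame(individual_id = id,
                   segment_type = seg$segments$type,
                   start_px = seg$segments$start_px,
                   end_px = seg$segments$end_px,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
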