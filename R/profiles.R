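#' Construct an intensity profile
#'
#' An intensity profile is one individual's one-dimensional series of gray
#' values (0 = pure black, 255 = pure white), read along the flank from
#' anterior to posterior. It is the unit on which bars are called and traits
#' are computed.
#'
#' @param values Numeric vector of gray values, each in \code{[0, 255]},
#'   ordered anterior to posterior.
#' @param scale_cm_per_px Physical scale of the image, centimeters per pixel.
#' @param id Individual identifier.
#' @param group Cohort label, one of \code{"parental_A"}, \code{"parental_M"},
#'   \code{"F2"}.
#' @param sex \code{"F"}, \code{"M"} or \code{"unknown"}.
#' @param standard_length_cm Standard length (snout to caudal peduncle) in
#'   centimeters, or \code{NA} if unmeasured.
#' @return An object of class \code{"intensity_profile"}: a list with elements
#'   \code{values}, \code{length_px}, \code{scale_cm_per_px}, \code{id},
#'   \code{group}, \code{sex}, \code{standard_length_cm}.
#' @export
intensity_profile <- function(values, scale_cm_per_px = 1, id = "unknown",
                              group = c("F2", "parental_A", "parental_M"),
                              sex = c("unknown", "F", "M"),
                              standard_length_cm = NA_real_) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("an intensity profile needs at least one value")
  if (anyNA(values))
    stop("intensity profile values must not be missing")
  if (any(values < 0 | values > 255))
    stop("intensity values must lie in [0, 255]")
  if (!is.numeric(scale_cm_per_px) || length(scale_cm_per_px) != 1L ||
      is.na(scale_cm_per_px) || scale_cm_per_px <= 0)
    stop("scale_cm_per_px must be a single positive number")
  if (!is.na(standard_length_cm) && standard_length_cm <= 0)
    stop("standard_length_cm must be positive when present")
  structure(
    list(values = values,
         length_px = length(values),
         scale_cm_per_px = scale_cm_per_px,
         id = as.character(id),
         group = group,
         sex = sex,
         standard_length_cm = as.numeric(standard_length_cm)),
    class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("Intensity profile '", x$id, "' (", x$group, ", sex ", x$sex, ")\n",
      sep = "")
  cat("  ", x$length_px, " px at ", signif(x$scale_cm_per_px, 4),
      " cm/px; gray range [", round(min(x$values), 1), ", ",
      round(max(x$values), 1), "]\n", sep = "")
  if (!is.na(x$standard_length_cm))
    cat("  standard length:", x$standard_length_cm, "cm\n")
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  graphics::plot(seq_along(x$values) - 1L, x$values, type = "l",
                 xlab = "position (px, anterior to posterior)",
                 ylab = "gray value", ylim = c(0, 255),
                 main = x$id, ...)
  graphics::abline(h = mean(x$values), lty = 2, col = "grey40")
  invisible(x)
}

#' Write an intensity profile to CSV
#'
#' The file carries metadata in \code{#}-prefixed header lines
#' (\code{id}, \code{group}, \code{sex}, \code{standard_length_cm},
#' \code{scale_cm_per_px}), a \code{position_px,gray_value} column header,
#' then one row per pixel column with 0-based positions.
#'
#' @param profile An \code{intensity_profile}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  header <- c(
    paste0("# id=", profile$id),
    paste0("# group=", profile$group),
    paste0("# sex=", profile$sex),
    paste0("# standard_length_cm=",
           ifelse(is.na(profile$standard_length_cm), "NA",
                  format(profile$standard_length_cm, digits = 15))),
    paste0("# scale_cm_per_px=", format(profile$scale_cm_per_px, digits = 15)),
    "position_px,gray_value")
  rows <- paste0(seq_along(profile$values) - 1L, ",",
                 format(profile$values, digits = 15, trim = TRUE,
                        scientific = FALSE))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an intensity profile from CSV
#'
#' Inverse of \code{\link{write_profile_csv}}; the round trip is lossless.
#' Malformed headers, non-numeric gray values and values outside
#' \code{[0, 255]} are rejected with the offending line number.
#'
#' @param path Path to a profile CSV.
#' @return An \code{intensity_profile}.
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  meta <- list(id = "unknown", group = "F2", sex = "unknown",
               standard_length_cm = NA_real_, scale_cm_per_px = 1)
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0L) stop("malformed header at line ", i, " of ", path)
    key <- trimws(substr(kv, 1L, eq - 1L))
    val <- trimws(substr(kv, eq + 1L, nchar(kv)))
    if (key %in% c("standard_length_cm", "scale_cm_per_px")) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num) && val != "NA")
        stop("non-numeric ", key, " at line ", i, " of ", path)
      meta[[key]] <- num
    } else if (key %in% c("id", "group", "sex")) {
      meta[[key]] <- val
    }
    i <- i + 1L
  }
  if (i > length(lines) || lines[i] != "position_px,gray_value")
    stop("expected 'position_px,gray_value' header at line ", i, " of ", path)
  body <- lines[-seq_len(i)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("no profile values in ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed row at line ", i + bad[1L], " of ", path)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(vals)) {
    j <- which(is.na(vals))[1L]
    stop("non-numeric or empty gray value at line ", i + j, " of ", path)
  }
  if (any(vals < 0 | vals > 255)) {
    j <- which(vals < 0 | vals > 255)[1L]
    stop("gray value outside [0, 255] at line ", i + j, " of ", path)
  }
  intensity_profile(vals,
                    scale_cm_per_px = meta$scale_cm_per_px,
                    id = meta$id, group = meta$group, sex = meta$sex,
                    standard_length_cm = meta$standard_length_cm)
}
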