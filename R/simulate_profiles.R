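#' Specification for a simulated barred intensity profile
#'
#' Describes a flank profile as alternating interbar/bar blocks on the 0-255
#' gray scale: \code{n_bars} dark bars of mean width \code{bar_width_px}
#' separated (and flanked) by lighter interbars of mean width
#' \code{interbar_width_px}, with optional per-segment width jitter, a linear
#' anterior-to-posterior background trend, optional Gaussian edge smoothing,
#' and iid Gaussian pixel noise. Values are clipped to \code{[0, 255]}.
#'
#' @param length_px Total profile length in pixels.
#' @param n_bars Number of bars (0 gives a constant background).
#' @param bar_width_px,interbar_width_px Mean segment widths in pixels.
#' @param width_jitter Fraction in \code{[0, 1)}; each segment width is drawn
#'   uniformly within \code{mean * (1 +/- width_jitter)}.
#' @param bar_level,interbar_level Gray levels of bars and interbars; bars
#'   must be darker (\code{bar_level < interbar_level}) when \code{n_bars >= 1}.
#' @param background_slope Gray units per pixel added linearly along the
#'   profile (anterior to posterior).
#' @param edge_sd Standard deviation (px) of an optional Gaussian blur of the
#'   block profile; 0 (default) keeps edges crisp so ground truth is exact.
#' @param noise_sd Standard deviation of iid Gaussian pixel noise, gray units.
#' @param scale_cm_per_px Centimeters per pixel carried into the profile.
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A \code{profile_spec} list.
#' @export
profile_spec <- function(length_px = 180L, n_bars = 6L, bar_width_px = 12L,
                         interbar_width_px = 14L, width_jitter = 0.2,
                         bar_level = 70, interbar_level = 180,
                         background_slope = 0, edge_sd = 0, noise_sd = 6,
                         scale_cm_per_px = 0.007, seed = NULL) {
  stopifnot(length_px >= 1, n_bars >= 0, bar_width_px >= 1,
            interbar_width_px >= 1, width_jitter >= 0, width_jitter < 1,
            bar_level >= 0, bar_level <= 255,
            interbar_level >= 0, interbar_level <= 255,
            edge_sd >= 0, noise_sd >= 0)
  if (n_bars >= 1 && bar_level >= interbar_level)
    stop("bars must be darker than interbars (bar_level < interbar_level)")
  structure(list(length_px = as.integer(length_px),
                 n_bars = as.integer(n_bars),
                 bar_width_px = bar_width_px,
                 interbar_width_px = interbar_width_px,
                 width_jitter = width_jitter,
                 bar_level = bar_level, interbar_level = interbar_level,
                 background_slope = background_slope,
                 edge_sd = edge_sd, noise_sd = noise_sd,
                 scale_cm_per_px = scale_cm_per_px, seed = seed),
            class = "profile_spec")
}

# integer widths summing exactly to `total`, proportional to `w` (each >= 1)
.apportion <- function(w, total) {
  k <- length(w)
  if (total < k) stop("segments do not fit: need at least ", k, " px")
  raw <- w / sum(w) * (total - k)
  f <- floor(raw)
  rem <- total - k - sum(f)
  if (rem > 0) {
    o <- order(raw - f, decreasing = TRUE)[seq_len(rem)]
    f[o] <- f[o] + 1
  }
  as.integer(f + 1L)
}

#' Simulate one barred intensity profile with ground-truth segments
#'
#' Paints the block layout described by a \code{\link{profile_spec}}, applies
#' background trend, optional edge smoothing and noise, clips to
#' \code{[0, 255]}, and returns both the profile and the exact bar/interbar
#' intervals that were painted.
#'
#' @param spec A \code{\link{profile_spec}}.
#' @param ... Metadata forwarded to \code{\link{intensity_profile}}.
#' @return A list with \code{profile} (an \code{intensity_profile}) and
#'   \code{truth}, a data frame of painted segments with columns \code{type}
#'   (\code{"bar"}/\code{"interbar"}), \code{start_px}, \code{end_px}
#'   (0-based, half-open).
#' @export
simulate_profile <- function(spec, ...) {
  stopifnot(inherits(spec, "profile_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$length_px
  nb <- spec$n_bars
  if (nb == 0L) {
    vals <- rep(spec$interbar_level, n)
    truth <- data.frame(type = "interbar", start_px = 0L, end_px = n,
                        stringsAsFactors = FALSE)
  } else {
    need <- nb * spec$bar_width_px + (nb + 1) * spec$interbar_width_px
    if (need > n)
      stop("requested segment widths (", need,
           " px) exceed profile length (", n, " px)")
    jit <- function(mu, k)
      mu * (1 + stats::runif(k, -spec$width_jitter, spec$width_jitter))
    bw <- jit(spec$bar_width_px, nb)
    iw <- jit(spec$interbar_width_px, nb + 1)
    # interleave: interbar, bar, interbar, ..., bar, interbar
    w <- numeric(2 * nb + 1)
    w[seq(1, 2 * nb + 1, by = 2)] <- iw
    w[seq(2, 2 * nb, by = 2)] <- bw
    widths <- .apportion(w, n)
    type <- rep(c("interbar", "bar"), length.out = 2 * nb + 1)
    end <- cumsum(widths)
    start <- c(0L, end[-length(end)])
    truth <- data.frame(type = type, start_px = as.integer(start),
                        end_px = as.integer(end), stringsAsFactors = FALSE)
    vals <- rep(spec$interbar_level, n)
    for (i in which(type == "bar"))
      vals[(start[i] + 1L):end[i]] <- spec$bar_level
  }
  vals <- vals + spec$background_slope * (seq_len(n) - 1L)
  if (spec$edge_sd > 0) {
    half <- max(1L, ceiling(3 * spec$edge_sd))
    kern <- stats::dnorm(-half:half, sd = spec$edge_sd)
    kern <- kern / sum(kern)
    padded <- c(rep(vals[1L], half), vals, rep(vals[n], half))
    vals <- as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n)]
  }
  if (spec$noise_sd > 0) vals <- vals + stats::rnorm(n, 0, spec$noise_sd)
  vals <- pmin(255, pmax(0, vals))
  list(profile = intensity_profile(vals,
                                   scale_cm_per_px = spec$scale_cm_per_px, ...),
       truth = truth)
}

#' Simulate cohorts of barred profiles with metadata
#'
#' Generates profile collections emulating an imaging study of two parental
#' species and their F2 hybrids: a high-contrast barred cohort, a
#' lower-contrast cohort, and a variable hybrid cohort. Each individual gets
#' a group label, a 50/50 sex assignment, and a lognormal standard length.
#'
#' @param n Named integer vector of cohort sizes, e.g.
#'   \code{c(parental_A = 10, parental_M = 6, F2 = 322)}. Names must be among
#'   \code{parental_A}, \code{parental_M}, \code{F2}; every requested cohort
#'   must be non-empty.
#' @param specs Optional named list of \code{\link{profile_spec}} templates
#'   per cohort; defaults give \code{parental_A} the larger bar/interbar
#'   contrast.
#' @param sl_mean_cm,sl_cv Mean and coefficient of variation of the lognormal
#'   standard-length distribution.
#' @param seed Integer seed for reproducibility.
#' @return A list of class \code{"profile_set"} with \code{profiles} (list of
#'   \code{intensity_profile}) and \code{truth} (list of ground-truth segment
#'   data frames, same order).
#' @export
simulate_population_profiles <- function(n = c(parental_A = 10, parental_M = 6,
                                               F2 = 322),
                                         specs = NULL,
                                         sl_mean_cm = 4.1, sl_cv = 0.15,
                                         seed = NULL) {
  if (is.null(names(n)) || !all(names(n) %in% c("parental_A", "parental_M", "F2")))
    stop("cohort sizes must be named parental_A, parental_M and/or F2")
  if (length(n) == 0L || any(n <= 0))
    stop("every requested cohort must contain at least one individual")
  if (!is.null(seed)) set.seed(seed)
  defaults <- list(
    parental_A = profile_spec(n_bars = 7, bar_width_px = 10,
                              interbar_width_px = 12, bar_level = 55,
                              interbar_level = 195, noise_sd = 5),
    parental_M = profile_spec(n_bars = 6, bar_level = 110, interbar_level = 170,
                              noise_sd = 5),
    F2 = profile_spec(n_bars = 6, bar_level = 85, interbar_level = 180,
                      noise_sd = 8))
  if (is.null(specs)) specs <- defaults
  sdlog <- sqrt(log(1 + sl_cv^2))
  meanlog <- log(sl_mean_cm) - sdlog^2 / 2
  profiles <- list(); truth <- list(); k <- 0L
  for (g in names(n)) {
    sp <- specs[[g]]
    if (is.null(sp)) sp <- defaults[[g]]
    sp$seed <- NULL  # cohort stream is driven by the master seed
    for (i in seq_len(n[[g]])) {
      k <- k + 1L
      sl <- stats::rlnorm(1, meanlog, sdlog)
      sex <- if (stats::runif(1) < 0.5) "F" else "M"
      out <- simulate_profile(sp, id = sprintf("%s_%03d", g, i), group = g,
                              sex = sex, standard_length_cm = sl)
      profiles[[k]] <- out$profile
      truth[[k]] <- out$truth
    }
  }
  structure(list(profiles = profiles, truth = truth), class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  groups <- vapply(x$profiles, `[[`, "", "group")
  cat("Profile set:", length(x$profiles), "individuals\n")
  print(table(group = groups))
  invisible(x)
}
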