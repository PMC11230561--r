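.trait_names <- c("darkest_intensity", "lightest_intensity", "range_intensity",
                  "covariance", "avg_bar_intensity", "avg_interbar_intensity",
                  "differential_intensity", "n_bars", "percent_barring",
                  "avg_bar_width_cm", "avg_interbar_width_cm")

#' Compute the eleven pigment and patterning traits of one profile
#'
#' Seven pigment-level measures on the 0-255 gray scale (larger = lighter):
#' darkest and lightest intensity, their range, the sample covariance of gray
#' value with 0-based anterior-posterior pixel position, the mean intensity
#' of bar pixels, the mean intensity of interbar pixels, and their
#' differential (interbar minus bar, so positive means bars darker than
#' background). Four patterning measures: number of bars, percent of the
#' profile classified as bar, and mean bar and interbar widths in
#' centimeters. Bar-dependent traits are missing (not zero) when the profile
#' has no bars.
#'
#' @param profile An \code{\link{intensity_profile}}.
#' @param seg The \code{\link{segment_bars}} result for that same profile.
#' @return Named numeric vector of the eleven traits.
#' @export
compute_traits <- function(profile, seg) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(seg, "bar_segmentation"))
  if (seg$length_px != profile$length_px)
    stop("segmentation length (", seg$length_px,
         ") does not match profile length (", profile$length_px, ")")
  v <- profile$values
  n <- length(v)
  pos <- seq_len(n) - 1
  covar <- if (n >= 2) stats::cov(pos, v) else NA_real_
  b <- bars(seg); ib <- interbars(seg)
  in_bar <- rep(FALSE, n)
  for (k in seq_len(nrow(b))) in_bar[(b$start_px[k] + 1L):b$end_px[k]] <- TRUE
  avg_bar <- if (nrow(b)) mean(v[in_bar]) else NA_real_
  avg_int <- if (nrow(ib)) mean(v[!in_bar]) else NA_real_
  sc <- profile$scale_cm_per_px
  c(darkest_intensity = min(v),
    lightest_intensity = max(v),
    range_intensity = max(v) - min(v),
    covariance = covar,
    avg_bar_intensity = avg_bar,
    avg_interbar_intensity = avg_int,
    differential_intensity = avg_int - avg_bar,
    n_bars = nrow(b),
    percent_barring = sum(b$end_px - b$start_px) / n,
    avg_bar_width_cm = if (nrow(b)) mean(b$end_px - b$start_px) * sc
                       else NA_real_,
    avg_interbar_width_cm = if (nrow(ib)) mean(ib$end_px - ib$start_px) * sc
                            else NA_real_)
}

#' Build a per-individual trait table from a set of profiles
#'
#' Segments each profile and computes its trait vector, assembling a data
#' frame with one row per individual: metadata columns (\code{id},
#' \code{group}, \code{sex}, \code{standard_length_cm}) followed by the
#' eleven traits.
#'
#' @param profiles A \code{profile_set} from
#'   \code{\link{simulate_population_profiles}}, or a list of
#'   \code{intensity_profile} objects.
#' @param min_run Minimum run length for \code{\link{segment_bars}}.
#' @return A data frame of class \code{"trait_table"}.
#' @export
trait_table <- function(profiles, min_run = 5L) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  if (inherits(profiles, "intensity_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles supplied")
  rows <- lapply(profiles, function(p) {
    tv <- compute_traits(p, segment_bars(p))
    cbind(data.frame(id = p$id, group = p$group, sex = p$sex,
                     standard_length_cm = p$standard_length_cm,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(tv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Remove allometric size effects from traits
#'
#' Fits, per trait, an ordinary least-squares regression of the trait on
#' standard length over the fit population (by default all rows, parentals
#' plus hybrids), and attaches each individual's residual from that
#' regression line as a new \code{<trait>_resid} column. Residuals are an
#' allometry-free measure of each trait; rows missing the trait or the
#' length get missing residuals. Residualizing residuals returns them
#' unchanged.
#'
#' @param table A \code{\link{trait_table}} (or any data frame with a
#'   \code{standard_length_cm} column).
#' @param fit Logical row filter selecting the population the regressions
#'   are fitted on; default all rows.
#' @param columns Trait columns to residualize; defaults to the eleven
#'   standard traits present in \code{table}.
#' @return \code{table} with \code{_resid} columns appended (replaced if
#'   already present).
#' @export
residualize <- function(table, fit = NULL, columns = NULL) {
  if (!"standard_length_cm" %in% names(table))
    stop("table has no standard_length_cm column")
  if (is.null(fit)) fit <- rep(TRUE, nrow(table))
  if (length(fit) != nrow(table)) stop("fit filter length mismatch")
  if (is.null(columns)) columns <- intersect(.trait_names, names(table))
  sl <- table$standard_length_cm
  for (tr in columns) {
    y <- table[[tr]]
    use <- fit & !is.na(y) & !is.na(sl) & sl > 0
    if (sum(use) < 3L)
      stop("fewer than 3 usable rows to fit the allometry of ", tr)
    if (stats::var(sl[use]) == 0)
      stop("standard length has zero variance in the fit population")
    co <- stats::coef(stats::lm(y[use] ~ sl[use]))
    pred <- co[1L] + co[2L] * sl
    table[[paste0(tr, "_resid")]] <- y - pred
  }
  table
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fixed-effects one-way analysis of variance of a trait across groups, with
#' all pairwise comparisons adjusted by Tukey's Honest Significant Difference
#' (studentized range distribution). The degenerate case of identically
#' constant data is reported as F = 0, p = 1.
#'
#' @param values Numeric trait values.
#' @param groups Group labels, same length; at least 2 groups with at least
#'   2 observations each.
#' @return A list with \code{f}, \code{p}, \code{df}, and \code{tukey}, a
#'   data frame of pairwise differences with adjusted p-values.
#' @export
group_compare <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L))
    stop("every group needs at least 2 observations; too few in: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  pairs_df <- function(m) {
    data.frame(comparison = rownames(m), diff = m[, "diff"],
               lwr = m[, "lwr"], upr = m[, "upr"], p_adj = m[, "p adj"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (stats::var(values) == 0) {
    cn <- utils::combn(levels(groups), 2)
    tk <- data.frame(comparison = paste(cn[2, ], cn[1, ], sep = "-"),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1,
                     stringsAsFactors = FALSE)
    return(list(f = 0, p = 1,
                df = c(length(counts) - 1L, length(values) - length(counts)),
                tukey = tk))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$groups
  list(f = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df = tab[, "Df"], tukey = pairs_df(tk))
}

#' Pairwise Pearson correlations among traits
#'
#' Computes pairwise-complete Pearson correlations with two-sided t-test
#' p-values across trait columns. By default the size-corrected
#' (\code{_resid}) trait values are used for trait-versus-trait cells, while
#' correlations against standard length itself use the raw trait values
#' (residuals are orthogonal to length by construction). Zero-variance
#' traits yield missing cells with a warning.
#'
#' @param table A \code{\link{trait_table}}, residualized if
#'   \code{use_residuals = TRUE}.
#' @param population Logical row filter (e.g. hybrids only); default all rows.
#' @param use_residuals Use \code{<trait>_resid} columns where present.
#' @param include_sl Append standard length as a final variable.
#' @return A list of matrices \code{r}, \code{p}, \code{n} (complete pairs).
#' @export
trait_correlations <- function(table, population = NULL,
                               use_residuals = TRUE, include_sl = TRUE) {
  if (is.null(population)) population <- rep(TRUE, nrow(table))
  tab <- table[population, , drop = FALSE]
  traits <- intersect(.trait_names, names(tab))
  cols <- lapply(traits, function(tr) {
    rc <- paste0(tr, "_resid")
    if (use_residuals && rc %in% names(tab)) tab[[rc]] else tab[[tr]]
  })
  names(cols) <- traits
  raw <- lapply(traits, function(tr) tab[[tr]])
  names(raw) <- traits
  vars <- traits
  if (include_sl && "standard_length_cm" %in% names(tab)) {
    cols$standard_length_cm <- tab$standard_length_cm
    raw$standard_length_cm <- tab$standard_length_cm
    vars <- c(vars, "standard_length_cm")
  }
  k <- length(vars)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) nm[i, i] <- sum(!is.na(cols[[vars[i]]]))
  warned <- character(0)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    # against standard length, correlate the raw trait
    sl_cell <- vars[j] == "standard_length_cm"
    x <- if (sl_cell) raw[[vars[i]]] else cols[[vars[i]]]
    y <- cols[[vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    nm[i, j] <- nm[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    degen <- c(vars[i], vars[j])[c(stats::var(x[ok]) == 0,
                                   stats::var(y[ok]) == 0)]
    if (length(degen)) {
      warned <- union(warned, degen)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (length(warned))
    warning("zero-variance variable(s) gave missing correlations: ",
            paste(warned, collapse = ", "))
  list(r = r, p = p, n = nm)
}

#' Write a trait table to CSV
#'
#' @param table A \code{\link{trait_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trait_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
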