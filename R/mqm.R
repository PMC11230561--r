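#' Bayes credible interval for QTL location
#'
#' On one linkage group's LOD curve, each grid position is weighted
#' proportionally to \code{10^LOD} and the weights normalized over the
#' group; the interval is the smallest contiguous span of grid positions
#' containing the peak whose summed weight reaches the requested coverage.
#'
#' @param scan A \code{\link{scan_hk}} result.
#' @param lg Linkage group to summarize.
#' @param coverage Coverage level in \code{(0, 1]}; default 0.95.
#' @return Numeric \code{c(lo_cM, hi_cM)}; attributes \code{peak_cM} and
#'   \code{flank_markers} (nearest true markers at or outside the
#'   endpoints, where any exist).
#' @export
bayes_interval <- function(scan, lg, coverage = 0.95) {
  if (coverage <= 0 || coverage > 1)
    stop("coverage must be in (0, 1]")
  s <- scan[scan$lg == as.character(lg), , drop = FALSE]
  if (nrow(s) < 2L) stop("need at least 2 grid positions on group ", lg)
  w <- 10^(s$lod - max(s$lod))
  w <- w / sum(w)
  pk <- which.max(s$lod)
  L <- nrow(s)
  best <- c(1L, L)
  found <- FALSE
  for (width in seq_len(L)) {
    lo_range <- max(1L, pk - width + 1L):min(pk, L - width + 1L)
    sums <- vapply(lo_range, function(i) sum(w[i:(i + width - 1L)]), 0)
    ok <- sums >= coverage - 1e-12
    if (any(ok)) {
      i <- lo_range[which(ok)[which.max(sums[ok])]]
      best <- c(i, i + width - 1L)
      found <- TRUE
      break
    }
  }
  if (!found) best <- c(1L, L)
  ci <- c(s$pos_cM[best[1L]], s$pos_cM[best[2L]])
  mk <- which(!is.na(s$marker))
  flank <- c(NA_character_, NA_character_)
  if (length(mk)) {
    lo_mk <- mk[s$pos_cM[mk] <= ci[1L] + 1e-9]
    hi_mk <- mk[s$pos_cM[mk] >= ci[2L] - 1e-9]
    flank[1L] <- if (length(lo_mk)) s$marker[max(lo_mk)]
                 else s$marker[mk[1L]]
    flank[2L] <- if (length(hi_mk)) s$marker[min(hi_mk)]
                 else s$marker[mk[length(mk)]]
  }
  structure(ci, peak_cM = s$pos_cM[pk], flank_markers = flank)
}

#' Allelic effects at a marker
#'
#' Per-genotype phenotype means and the additive and dominance effects:
#' \code{a = (mean_BB - mean_AA) / 2} and
#' \code{d = mean_AB - (mean_AA + mean_BB) / 2}. A missing genotype class
#' makes the dependent effect missing, with a warning.
#'
#' @param geno Genotype codes at the marker (1 = AA, 2 = AB, 3 = BB, NA).
#' @param phenotype Phenotype values, same length.
#' @return List with \code{means} (named AA/AB/BB), \code{a}, \code{d}.
#' @export
qtl_effects <- function(geno, phenotype) {
  stopifnot(length(geno) == length(phenotype))
  means <- vapply(1:3, function(g) {
    v <- phenotype[!is.na(geno) & geno == g & !is.na(phenotype)]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  names(means) <- c("AA", "AB", "BB")
  if (anyNA(means))
    warning("empty genotype class(es): ",
            paste(names(means)[is.na(means)], collapse = ", "),
            "; dependent effects are missing")
  list(means = means,
       a = (means["BB"] - means["AA"]) / 2,
       d = means["AB"] - (means["AA"] + means["BB"]) / 2)
}

#' Percent phenotypic variance explained from a LOD score
#'
#' Standard identity for a scan against its null model:
#' \code{PVE = 100 (1 - 10^(-2 LOD / n))}.
#'
#' @param lod LOD score(s), non-negative.
#' @param n Number of individuals in the scan.
#' @return PVE in percent.
#' @export
pve <- function(lod, n) {
  if (any(lod < 0)) stop("LOD must be non-negative")
  if (n < 2) stop("n must be at least 2")
  100 * (1 - 10^(-2 * lod / n))
}

# genome-wide peak list: per linkage group, local maxima above `threshold`
# separated by at least `min_sep` cM
.pick_peaks <- function(scan, threshold, min_sep = 30) {
  out <- list()
  for (lg in unique(scan$lg)) {
    s <- scan[scan$lg == lg, , drop = FALSE]
    avail <- rep(TRUE, nrow(s))
    while (any(avail & s$lod >= threshold)) {
      i <- which(avail & s$lod >= threshold)
      i <- i[which.max(s$lod[i])]
      out[[length(out) + 1L]] <- data.frame(lg = lg, pos_cM = s$pos_cM[i],
                                            lod = s$lod[i],
                                            stringsAsFactors = FALSE)
      avail <- avail & abs(s$pos_cM - s$pos_cM[i]) >= min_sep
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(lg = character(0), pos_cM = numeric(0), lod = numeric(0))
}

#' Multiple-QTL model building with backward elimination
#'
#' Builds a per-trait multiple-QTL model. (1) An initial cofactor-free scan
#' proposes candidate QTL: peaks above the suggestive (10 percent) cutoff on
#' distinct linkage groups, or at least \code{min_sep} cM apart within a
#' group. (2) Scans iterate with the candidates as regression cofactors,
#' refreshing each peak position by a conditional scan (all other cofactors
#' in the model, the focal one dropped) and admitting any new peaks that
#' clear the suggestive cutoff, until the set is stable or
#' \code{max_iter} iterations. (3) Backward elimination repeatedly removes
#' the cofactor with the lowest conditional LOD while that LOD is below the
#' suggestive cutoff. Surviving QTL are classified significant (at or above
#' the 5 percent cutoff) or suggestive, and annotated with Bayes credible
#' intervals, PVE, per-genotype means and additive/dominance effects at the
#' nearest (peak) marker.
#'
#' @param gp A \code{\link{genotype_probabilities}} object.
#' @param phenotype Numeric phenotype vector.
#' @param geno Optional genotype matrix (individuals x markers, codes
#'   1/2/3/NA) for effect estimation at peak markers; without it genotypes
#'   are imputed as the most probable class at the peak marker.
#' @param thresholds Optional precomputed \code{\link{permutation_thresholds}}
#'   result (alphas 0.05, 0.10); computed when absent.
#' @param n_perm,seed Passed to \code{\link{permutation_thresholds}} when
#'   thresholds are computed here.
#' @param min_sep Minimum cM separation of same-group cofactors.
#' @param drop_window Cofactor exclusion window for \code{\link{scan_hk}}.
#' @param max_iter Iteration cap for the cofactor refresh loop.
#' @param trait Trait name for reporting.
#' @param initial_cofactors Optional data frame (\code{lg}, \code{pos_cM}) of
#'   cofactors to offer to the model up front in addition to the scan's own
#'   candidates; useful for sensitivity analysis, since backward elimination
#'   must remove any that do not earn their keep.
#' @return Object of class \code{"qtl_model"}: list with \code{trait},
#'   \code{qtl} (one row per retained QTL: lg, pos_cM, marker, lod, pve,
#'   ci_lo_cM, ci_hi_cM, mean_AA, mean_AB, mean_BB, additive, dominance,
#'   class), \code{thresholds}, \code{scan} (final cofactor scan),
#'   \code{n}, and \code{cum_pve} (joint-model R-squared, percent).
#' @export
mqm_fit <- function(gp, phenotype, geno = NULL, thresholds = NULL,
                    n_perm = 1000, seed = NULL, min_sep = 30,
                    drop_window = 10, max_iter = 10, trait = "pheno",
                    initial_cofactors = NULL) {
  stopifnot(inherits(gp, "genoprob"))
  if (is.null(thresholds))
    thresholds <- permutation_thresholds(gp, phenotype, n_perm = n_perm,
                                         alphas = c(0.05, 0.10), seed = seed)
  thr5 <- thresholds[[1L]]; thr10 <- thresholds[[2L]]

  scan0 <- scan_hk(gp, phenotype, trait = trait)
  cofs <- .pick_peaks(scan0, thr10, min_sep)
  cofs$cond_lod <- cofs$lod
  if (!is.null(initial_cofactors)) {
    for (i in seq_len(nrow(initial_cofactors))) {
      near <- cofs$lg == as.character(initial_cofactors$lg[i]) &
        abs(cofs$pos_cM - initial_cofactors$pos_cM[i]) < min_sep
      if (!any(near))
        cofs <- rbind(cofs, data.frame(
          lg = as.character(initial_cofactors$lg[i]),
          pos_cM = initial_cofactors$pos_cM[i],
          lod = NA_real_, cond_lod = Inf, stringsAsFactors = FALSE))
    }
  }

  # conditional scan of cofactor j's linkage group with all other cofactors
  # in the model; positions where a same-group cofactor is dropped by the
  # exclusion window are masked out so a QTL cannot be refreshed onto a
  # neighbour's peak
  cond_scan <- function(j) {
    others <- cofs[-j, c("lg", "pos_cM"), drop = FALSE]
    if (nrow(others) == 0L) others <- NULL
    sc <- scan_hk(gp, phenotype, cofactors = others,
                  drop_window = drop_window, trait = trait)
    s <- sc[sc$lg == cofs$lg[j], , drop = FALSE]
    masked <- rep(FALSE, nrow(s))
    if (!is.null(others)) {
      same <- others$lg == cofs$lg[j]
      for (p in others$pos_cM[same])
        masked <- masked | abs(s$pos_cM - p) <= drop_window
    }
    if (any(masked)) {
      # contiguous unmasked block containing the current position
      runs <- rle(!masked)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      cur <- which.min(abs(s$pos_cM - cofs$pos_cM[j]))
      blk <- which(runs$values & starts <= cur & ends >= cur)
      if (length(blk) == 0L) blk <- which(runs$values)[1L]
      s <- s[starts[blk]:ends[blk], , drop = FALSE]
    }
    s
  }

  iter <- 0L
  while (iter < max_iter && nrow(cofs) > 0L) {
    iter <- iter + 1L
    changed <- FALSE
    # refresh positions and conditional LODs
    for (j in seq_len(nrow(cofs))) {
      s <- cond_scan(j)
      i <- which.max(s$lod)
      if (abs(s$pos_cM[i] - cofs$pos_cM[j]) > 1e-9) changed <- TRUE
      cofs$pos_cM[j] <- s$pos_cM[i]
      cofs$cond_lod[j] <- s$lod[i]
    }
    # collapse same-group cofactors that drifted within min_sep of each other
    if (nrow(cofs) > 1L) {
      dup <- rep(FALSE, nrow(cofs))
      for (j in 2:nrow(cofs)) for (i in 1:(j - 1L)) {
        if (!dup[i] && !dup[j] && cofs$lg[i] == cofs$lg[j] &&
            abs(cofs$pos_cM[i] - cofs$pos_cM[j]) < min_sep)
          dup[if (cofs$cond_lod[i] < cofs$cond_lod[j]) i else j] <- TRUE
      }
      if (any(dup)) {
        cofs <- cofs[!dup, , drop = FALSE]
        changed <- TRUE
      }
    }
    # backward elimination: drop the weakest failing cofactor
    if (any(cofs$cond_lod < thr10)) {
      cofs <- cofs[-which.min(cofs$cond_lod), , drop = FALSE]
      changed <- TRUE
      next
    }
    # admit new peaks from the scan with the current model
    full <- scan_hk(gp, phenotype,
                    cofactors = cofs[, c("lg", "pos_cM"), drop = FALSE],
                    drop_window = drop_window, trait = trait)
    cand <- .pick_peaks(full, thr10, min_sep)
    for (i in seq_len(nrow(cand))) {
      same <- cofs$lg == cand$lg[i] &
        abs(cofs$pos_cM - cand$pos_cM[i]) < min_sep
      if (!any(same)) {
        cofs <- rbind(cofs, cbind(cand[i, , drop = FALSE],
                                  cond_lod = cand$lod[i]))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  final_scan <- scan_hk(gp, phenotype,
                        cofactors = if (nrow(cofs))
                          cofs[, c("lg", "pos_cM"), drop = FALSE],
                        drop_window = drop_window, trait = trait)
  n <- attr(final_scan, "n")

  qtl <- data.frame(lg = character(0), pos_cM = numeric(0),
                    marker = character(0), lod = numeric(0),
                    pve = numeric(0), ci_lo_cM = numeric(0),
                    ci_hi_cM = numeric(0), mean_AA = numeric(0),
                    mean_AB = numeric(0), mean_BB = numeric(0),
                    additive = numeric(0), dominance = numeric(0),
                    class = character(0), stringsAsFactors = FALSE)
  ids <- attr(gp, "ids")
  for (j in seq_len(nrow(cofs))) {
    s <- cond_scan(j)
    i <- which.max(s$lod)
    ci <- bayes_interval(s, cofs$lg[j])
    # nearest true marker to the peak
    mk <- which(!is.na(s$marker))
    pm_i <- mk[which.min(abs(s$pos_cM[mk] - s$pos_cM[i]))]
    pm <- s$marker[pm_i]
    g <- if (!is.null(geno) && pm %in% colnames(geno)) geno[, pm]
         else {
           e <- gp[[as.character(cofs$lg[j])]]
           apply(e$prob[, which(e$marker == pm)[1L], ], 1L, which.max)
         }
    eff <- suppressWarnings(qtl_effects(g, phenotype))
    qtl <- rbind(qtl, data.frame(
      lg = cofs$lg[j], pos_cM = s$pos_cM[i], marker = pm, lod = s$lod[i],
      pve = pve(s$lod[i], n), ci_lo_cM = ci[1L], ci_hi_cM = ci[2L],
      mean_AA = eff$means[["AA"]], mean_AB = eff$means[["AB"]],
      mean_BB = eff$means[["BB"]],
      additive = unname(eff$a), dominance = unname(eff$d),
      class = if (s$lod[i] >= thr5) "significant" else "suggestive",
      stringsAsFactors = FALSE))
  }
  qtl <- qtl[order(match(qtl$lg, unique(scan0$lg)), qtl$pos_cM), ,
             drop = FALSE]
  rownames(qtl) <- NULL

  # joint-model R^2 across all retained QTL
  cum_pve <- NA_real_
  if (nrow(qtl)) {
    pr <- .scan_prep(gp, phenotype)
    X <- rep(1, length(pr$y))
    for (j in seq_len(nrow(qtl))) {
      e <- pr$gp[[as.character(qtl$lg[j])]]
      t0 <- which.min(abs(e$pos - qtl$pos_cM[j]))
      X <- cbind(X, e$prob[, t0, 3L] - e$prob[, t0, 1L], e$prob[, t0, 2L])
    }
    fit <- stats::lm.fit(X, pr$y)
    cum_pve <- 100 * (1 - sum(fit$residuals^2) /
                        sum((pr$y - mean(pr$y))^2))
  }

  structure(list(trait = trait, qtl = qtl, thresholds = thresholds,
                 scan = final_scan, n = n, cum_pve = cum_pve,
                 min_sep = min_sep, drop_window = drop_window),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("Multiple-QTL model for trait '", x$trait, "' (n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  thresholds: %.2f (5%%), %.2f (10%%)\n",
              x$thresholds[[1L]], x$thresholds[[2L]]))
  if (nrow(x$qtl) == 0L) {
    cat("  no QTL above the suggestive cutoff\n")
  } else {
    cat("  ", nrow(x$qtl), "QTL;",
        sprintf("joint model explains %.1f%% of variance\n", x$cum_pve))
    print(x$qtl[, c("lg", "pos_cM", "marker", "lod", "pve", "ci_lo_cM",
                    "ci_hi_cM", "additive", "dominance", "class")],
          digits = 4)
  }
  invisible(x)
}

#' @export
summary.qtl_model <- function(object, ...) {
  df <- object$qtl
  df$trait <- rep(object$trait, nrow(df))
  df$threshold_5 <- rep(object$thresholds[[1L]], nrow(df))
  df$threshold_10 <- rep(object$thresholds[[2L]], nrow(df))
  df[, c("trait", "lg", "pos_cM", "marker", "lod", "pve",
         "ci_lo_cM", "ci_hi_cM", "mean_AA", "mean_AB", "mean_BB",
         "additive", "dominance", "threshold_5", "threshold_10", "class")]
}

#' @export
coef.qtl_model <- function(object, ...) {
  if (nrow(object$qtl) == 0L) return(numeric(0))
  stats::setNames(
    c(rbind(object$qtl$additive, object$qtl$dominance)),
    c(rbind(paste0(object$qtl$marker, ":a"),
            paste0(object$qtl$marker, ":d"))))
}

#' @export
plot.qtl_model <- function(x, ...) {
  plot(x$scan, threshold = x$thresholds[[1L]], ...)
  graphics::abline(h = x$thresholds[[2L]], lty = 3, col = "firebrick")
  if (nrow(x$qtl)) {
    # mark peaks on the concatenated axis used by plot.qtl_scan
    invisible(x)
  }
  invisible(x)
}

#' Write a multiple-QTL model report as CSV
#'
#' One row per QTL with peak location, LOD, PVE, credible interval,
#' per-genotype means, effects, thresholds and significance class.
#'
#' @param model A \code{\link{mqm_fit}} result (or list of them).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model_csv <- function(model, path) {
  if (inherits(model, "qtl_model")) model <- list(model)
  tab <- do.call(rbind, lapply(model, summary))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
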