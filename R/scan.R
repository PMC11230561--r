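# Internal multi-phenotype Haley-Knott engine.
#
# gp:        genoprob object
# Y:         n x m matrix of phenotypes (no missing values)
# cofactors: data.frame(lg, pos_cM) of model cofactors, or NULL
# drop_window: cofactors within this many cM (same group) of the scanned
#   position are dropped from both the full and null model there
#
# Returns list(info = data.frame(lg, pos_cM, marker), lod = npos x m matrix).
.hk_engine <- function(gp, Y, cofactors = NULL, drop_window = 10) {
  n <- nrow(Y)
  csY2 <- colSums(Y^2)
  # cofactor predictor columns (additive dosage and dominance indicator)
  ncof <- if (is.null(cofactors)) 0L else nrow(cofactors)
  C <- if (ncof) matrix(NA_real_, n, 2L * ncof) else NULL
  if (ncof) for (j in seq_len(ncof)) {
    e <- gp[[as.character(cofactors$lg[j])]]
    if (is.null(e)) stop("cofactor on unknown linkage group: ",
                         cofactors$lg[j])
    t0 <- which.min(abs(e$pos - cofactors$pos_cM[j]))
    C[, 2L * j - 1L] <- e$prob[, t0, 3L] - e$prob[, t0, 1L]
    C[, 2L * j] <- e$prob[, t0, 2L]
  }
  rss_proj <- function(X) {
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    pmax(csY2 - colSums(crossprod(Q, Y)^2), 0)
  }
  null_cache <- list()
  null_rss <- function(keep) {
    key <- paste0("k", paste(which(keep), collapse = ","))
    if (is.null(null_cache[[key]])) {
      X0 <- cbind(rep(1, n),
                  if (ncof && any(keep))
                    C[, rep(which(keep), each = 2L) * 2L - c(1L, 0L),
                      drop = FALSE])
      null_cache[[key]] <<- list(rss = rss_proj(X0), X0 = X0)
    }
    null_cache[[key]]
  }
  info <- list(); lods <- list()
  for (lg in names(gp)) {
    e <- gp[[lg]]
    L <- length(e$pos)
    lod <- matrix(NA_real_, L, ncol(Y))
    for (t in seq_len(L)) {
      keep <- if (ncof)
        !(as.character(cofactors$lg) == lg &
          abs(cofactors$pos_cM - e$pos[t]) <= drop_window)
        else logical(0)
      nm <- null_rss(keep)
      a <- e$prob[, t, 3L] - e$prob[, t, 1L]
      d <- e$prob[, t, 2L]
      rss1 <- rss_proj(cbind(nm$X0, a, d))
      lod[t, ] <- pmax((n / 2) * log10(nm$rss / pmax(rss1, 1e-300)), 0)
    }
    info[[lg]] <- data.frame(lg = lg, pos_cM = e$pos, marker = e$marker,
                             stringsAsFactors = FALSE)
    lods[[lg]] <- lod
  }
  list(info = do.call(rbind, info), lod = do.call(rbind, lods))
}

# align a phenotype with the genoprob individuals and drop missing rows
.scan_prep <- function(gp, phenotype) {
  ids <- attr(gp, "ids")
  if (length(phenotype) != length(ids))
    stop("phenotype length (", length(phenotype),
         ") does not match the ", length(ids), " individuals of the probs")
  keep <- !is.na(phenotype)
  if (sum(keep) < 10L)
    stop("need at least 10 non-missing phenotype values")
  y <- phenotype[keep]
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  gp2 <- gp
  for (lg in names(gp2))
    gp2[[lg]]$prob <- gp2[[lg]]$prob[keep, , , drop = FALSE]
  attr(gp2, "ids") <- ids[keep]
  list(gp = gp2, y = y)
}

#' Haley-Knott genome scan
#'
#' Single-QTL genome scan by Haley-Knott regression: at every grid position
#' the phenotype is regressed on the expected additive dosage
#' \code{p_BB - p_AA} and the dominance indicator \code{p_AB} derived from
#' the genotype probabilities, plus any cofactor columns, and the LOD score
#' is \code{(n/2) log10(RSS_null / RSS_full)} against a null of intercept
#' plus cofactors. Positions within \code{drop_window} cM of a cofactor on
#' the same linkage group are scanned with that cofactor dropped, so a
#' cofactor cannot absorb its own signal.
#'
#' @param gp A \code{\link{genotype_probabilities}} object.
#' @param phenotype Numeric phenotype, one value per individual in the
#'   probabilities (missing values dropped; at least 10 required).
#' @param cofactors Optional data frame with columns \code{lg},
#'   \code{pos_cM} of QTL used as model cofactors.
#' @param drop_window Exclusion window around cofactors, cM.
#' @param trait Trait name carried into the result.
#' @return Object of class \code{"qtl_scan"}: a data frame with columns
#'   \code{lg}, \code{pos_cM}, \code{marker}, \code{lod}; attributes carry
#'   the trait name, cofactors, and \code{n}.
#' @export
scan_hk <- function(gp, phenotype, cofactors = NULL, drop_window = 10,
                    trait = "pheno") {
  stopifnot(inherits(gp, "genoprob"))
  pr <- .scan_prep(gp, phenotype)
  res <- .hk_engine(pr$gp, matrix(pr$y, ncol = 1L), cofactors, drop_window)
  out <- res$info
  out$lod <- res$lod[, 1L]
  attr(out, "trait") <- trait
  attr(out, "cofactors") <- cofactors
  attr(out, "n") <- length(pr$y)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' @export
summary.qtl_scan <- function(object, threshold = 0, ...) {
  df <- as.data.frame(object)
  peaks <- do.call(rbind, lapply(split(df, df$lg), function(s) {
    s[which.max(s$lod), , drop = FALSE]
  }))
  peaks <- peaks[peaks$lod >= threshold, , drop = FALSE]
  peaks[order(-peaks$lod), ]
}

#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  df <- as.data.frame(x)
  lgs <- unique(df$lg)
  offs <- 0; xs <- numeric(nrow(df)); brk <- numeric(0)
  for (lg in lgs) {
    sel <- df$lg == lg
    xs[sel] <- df$pos_cM[sel] - min(df$pos_cM[sel]) + offs
    offs <- max(xs[sel]) + 5
    brk <- c(brk, offs - 2.5)
  }
  graphics::plot(xs, df$lod, type = "n", xlab = "linkage group",
                 ylab = "LOD", xaxt = "n",
                 main = attr(x, "trait"), ...)
  for (lg in lgs) {
    sel <- df$lg == lg
    graphics::lines(xs[sel], df$lod[sel])
  }
  graphics::abline(v = brk[-length(brk)], col = "grey80")
  mids <- vapply(lgs, function(lg) mean(range(xs[df$lg == lg])), 0)
  graphics::axis(1, at = mids, labels = lgs)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "firebrick")
  invisible(x)
}

#' Genome-wide permutation significance thresholds
#'
#' Estimates genome-wide LOD significance cutoffs by permuting the
#' phenotype across individuals while keeping genotypes fixed, recording
#' the genome-wide maximum LOD of each permuted scan, and taking empirical
#' quantiles (type 7) of that null distribution. Deterministic for a given
#' seed.
#'
#' @param gp A \code{\link{genotype_probabilities}} object.
#' @param phenotype Numeric phenotype vector.
#' @param n_perm Number of permutations (at least 100).
#' @param alphas Genome-wide error rates; the default gives the 5 percent
#'   (significant) and 10 percent (suggestive) cutoffs.
#' @param seed Integer seed for the permutations.
#' @return Named numeric vector of thresholds, one per alpha, with the
#'   permutation maxima in attribute \code{"max_lod"}.
#' @export
permutation_thresholds <- function(gp, phenotype, n_perm = 1000,
                                   alphas = c(0.05, 0.10), seed = NULL) {
  stopifnot(inherits(gp, "genoprob"))
  if (n_perm < 100) stop("use at least 100 permutations")
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must be in (0, 1)")
  pr <- .scan_prep(gp, phenotype)
  if (!is.null(seed)) set.seed(seed)
  n <- length(pr$y)
  Y <- matrix(0, n, n_perm)
  for (k in seq_len(n_perm)) Y[, k] <- pr$y[sample.int(n)]
  res <- .hk_engine(pr$gp, Y)
  maxlod <- apply(res$lod, 2L, max)
  thr <- stats::quantile(maxlod, probs = 1 - alphas, type = 7, names = FALSE)
  names(thr) <- paste0(as.character(100 * alphas), "%")
  attr(thr, "max_lod") <- maxlod
  thr
}
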