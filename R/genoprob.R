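# F2 genotype transition matrix across a recombination fraction r:
# two independent gametes, each switching allele with probability r.
.f2_transition <- function(r) {
  matrix(c((1 - r)^2,       2 * r * (1 - r), r^2,
           r * (1 - r),     (1 - r)^2 + r^2, r * (1 - r),
           r^2,             2 * r * (1 - r), (1 - r)^2),
         nrow = 3L, byrow = TRUE)
}

#' Genotype probabilities on a pseudomarker grid
#'
#' Computes, per individual and linkage group, the posterior probabilities
#' of the hidden F2 genotypes AA/AB/BB at every marker and at pseudomarkers
#' every \code{step_cM}, by the forward-backward algorithm. The hidden chain
#' has initial distribution (1/4, 1/2, 1/4), transitions derived from two
#' independent gametes with Haldane recombination fractions between adjacent
#' grid points, and emissions that assign probability \code{1 - error_rate}
#' to the observed genotype code with the error mass split evenly over the
#' other two codes; missing genotypes are uninformative.
#'
#' @param cross An \code{\link{f2_cross}}.
#' @param step_cM Pseudomarker spacing in cM (> 0). Pseudomarkers run from
#'   the first to the last marker of each group; grid points coinciding with
#'   markers are merged.
#' @param error_rate Genotyping error probability per marker.
#' @return Object of class \code{"genoprob"}: a list with one element per
#'   linkage group, each holding \code{pos} (grid cM), \code{marker}
#'   (marker name or \code{NA} at pseudomarkers) and \code{prob}, an
#'   array individuals x grid x 3 (AA, AB, BB).
#' @export
genotype_probabilities <- function(cross, step_cM = 1, error_rate = 1e-4) {
  stopifnot(inherits(cross, "f2cross"))
  if (step_cM <= 0) stop("step_cM must be positive")
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  out <- list()
  n <- nrow(cross$geno)
  for (lg in unique(cross$map$lg)) {
    sel <- cross$map$lg == lg
    mpos <- cross$map$pos_cM[sel]
    mnames <- cross$map$marker[sel]
    grid <- sort(unique(round(c(mpos, seq(min(mpos), max(mpos),
                                          by = step_cM)), 6)))
    mk_at <- match(round(mpos, 6), grid)
    marker <- rep(NA_character_, length(grid))
    marker[mk_at] <- mnames  # later markers win exact-position ties
    L <- length(grid)

    # emissions, individuals x 3, per grid point
    emis <- vector("list", L)
    unif <- matrix(1, n, 3L)
    for (t in seq_len(L)) emis[[t]] <- unif
    for (j in seq_along(mnames)) {
      g <- cross$geno[, mnames[j]]
      e <- matrix(error_rate / 2, n, 3L)
      obs <- !is.na(g)
      e[cbind(which(obs), g[obs])] <- 1 - error_rate
      e[!obs, ] <- 1
      t0 <- mk_at[j]
      emis[[t0]] <- emis[[t0]] * e  # merged grid point may carry 2+ markers
    }

    trans <- lapply(haldane_r(diff(grid)), .f2_transition)

    alpha <- vector("list", L)
    a <- sweep(emis[[1L]], 2L, c(0.25, 0.5, 0.25), `*`)
    a <- a / rowSums(a)
    alpha[[1L]] <- a
    for (t in seq_len(L - 1L)) {
      a <- (a %*% trans[[t]]) * emis[[t + 1L]]
      a <- a / rowSums(a)
      alpha[[t + 1L]] <- a
    }
    prob <- array(NA_real_, c(n, L, 3L),
                  dimnames = list(rownames(cross$geno), NULL,
                                  c("AA", "AB", "BB")))
    b <- matrix(1, n, 3L)
    prob[, L, ] <- alpha[[L]]
    for (t in rev(seq_len(L - 1L))) {
      b <- (b * emis[[t + 1L]]) %*% t(trans[[t]])
      b <- b / rowSums(b)
      po <- alpha[[t]] * b
      prob[, t, ] <- po / rowSums(po)
    }
    out[[lg]] <- list(pos = grid, marker = marker, prob = prob)
  }
  structure(out, class = "genoprob",
            ids = rownames(cross$geno), step_cM = step_cM,
            error_rate = error_rate)
}

#' @export
print.genoprob <- function(x, ...) {
  npos <- sum(vapply(x, function(e) length(e$pos), 0L))
  cat("Genotype probabilities:", length(attr(x, "ids")), "individuals,",
      length(x), "linkage group(s),", npos, "grid positions",
      sprintf("(step %g cM, error rate %g)\n",
              attr(x, "step_cM"), attr(x, "error_rate")))
  invisible(x)
}
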