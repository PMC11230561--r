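#' Simulate an F2 intercross with planted QTL
#'
#' Simulates F2 genotypes by drawing, per individual, two independent
#' gametes from F1 parents heterozygous at every locus. Along each linkage
#' group the gamete is a two-state Markov chain: the allele at the first
#' locus is A or B with probability 1/2, and recombination between adjacent
#' loci occurs with the Haldane probability \code{\link{haldane_r}(d)} (no
#' crossover interference). Phenotypes are the sum of planted QTL effects
#' (\code{-a}, \code{d}, \code{+a} for AA, AB, BB at the QTL locus), an
#' allometric term in standard length, and Gaussian residual noise.
#' Standard length is drawn lognormal. Genotypes are then masked to missing
#' at the requested rate. QTL may sit between markers; their loci are
#' simulated on the gamete chain but excluded from the output genotypes.
#'
#' @param map A \code{\link{linkage_map}}.
#' @param n_individuals Number of F2 individuals.
#' @param qtl Planted QTL: a data frame with columns \code{lg},
#'   \code{pos_cM}, \code{trait}, \code{a}, \code{d}; \code{NULL} for a null
#'   cross. Each QTL's linkage group must exist in the map and its position
#'   must lie within that group's span.
#' @param traits Phenotype names to generate; defaults to the traits named
#'   in \code{qtl}, or \code{"pheno"} for a null cross.
#' @param residual_sd Residual standard deviation, scalar or named per trait;
#'   must be positive.
#' @param allometry_slope,allometry_intercept Linear dependence of each
#'   trait on standard length (trait units per cm, and offset); scalar or
#'   named per trait.
#' @param sl_mean_cm,sl_sd_cm Mean and SD of the lognormal standard-length
#'   distribution (cm).
#' @param missing_rate Fraction of genotypes masked to missing, in
#'   \code{[0, 1)}.
#' @param seed Integer seed; identical seeds give identical crosses.
#' @return An \code{\link{f2_cross}} whose \code{pheno} holds \code{id},
#'   \code{standard_length_cm} and one column per trait, plus a
#'   \code{truth} element recording the planted QTL and their simulated
#'   genotypes.
#' @export
simulate_f2_cross <- function(map, n_individuals, qtl = NULL, traits = NULL,
                              residual_sd = 1, allometry_slope = 0,
                              allometry_intercept = 0,
                              sl_mean_cm = 4.1, sl_sd_cm = 0.6,
                              missing_rate = 0, seed = NULL) {
  stopifnot(inherits(map, "linkage_map"), n_individuals >= 1)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl, stringsAsFactors = FALSE)
    need <- c("lg", "pos_cM", "trait", "a", "d")
    if (!all(need %in% names(qtl)))
      stop("qtl needs columns: ", paste(need, collapse = ", "))
    qtl$lg <- as.character(qtl$lg)
    absent <- setdiff(qtl$lg, unique(map$lg))
    if (length(absent))
      stop("QTL on linkage group(s) absent from the map: ",
           paste(absent, collapse = ", "))
    for (i in seq_len(nrow(qtl))) {
      span <- range(map$pos_cM[map$lg == qtl$lg[i]])
      if (qtl$pos_cM[i] < span[1L] || qtl$pos_cM[i] > span[2L])
        stop("QTL position ", qtl$pos_cM[i],
             " cM outside linkage group ", qtl$lg[i])
    }
  }
  if (is.null(traits))
    traits <- if (!is.null(qtl)) unique(qtl$trait) else "pheno"
  per_trait <- function(x, default) {
    out <- stats::setNames(rep(default, length(traits)), traits)
    if (length(x) == 1L && is.null(names(x))) out[] <- x
    else out[names(x)] <- x
    out
  }
  rsd <- per_trait(residual_sd, 1)
  if (any(rsd <= 0)) stop("residual_sd must be positive")
  slope <- per_trait(allometry_slope, 0)
  inter <- per_trait(allometry_intercept, 0)

  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_individuals)
  lgs <- unique(map$lg)
  geno_cols <- list()
  qtl_geno <- if (!is.null(qtl))
    matrix(NA_integer_, n, nrow(qtl)) else NULL
  for (lg in lgs) {
    mpos <- map$pos_cM[map$lg == lg]
    mnames <- map$marker[map$lg == lg]
    qidx <- if (!is.null(qtl)) which(qtl$lg == lg) else integer(0)
    locpos <- c(mpos, qtl$pos_cM[qidx])
    loctag <- c(rep(NA_integer_, length(mpos)), qidx)
    o <- order(locpos)
    locpos <- locpos[o]; loctag <- loctag[o]
    L <- length(locpos)
    g <- matrix(0L, n, L)  # genotype = gamete1 + gamete2 (B-allele dose)
    for (gam in 1:2) {
      al <- matrix(0L, n, L)
      al[, 1L] <- stats::rbinom(n, 1L, 0.5)
      if (L > 1L) {
        r <- haldane_r(diff(locpos))
        for (t in 2:L) {
          sw <- stats::rbinom(n, 1L, r[t - 1L])
          al[, t] <- bitwXor(al[, t - 1L], sw)
        }
      }
      g <- g + al
    }
    is_marker <- is.na(loctag)
    gm <- g[, is_marker, drop = FALSE] + 1L  # codes 1/2/3
    # restore map order of markers within the group
    mo <- order(order(mpos))
    colnames(gm) <- mnames[order(mpos)]
    geno_cols[[lg]] <- gm[, mnames, drop = FALSE]
    for (k in which(!is_marker)) qtl_geno[, loctag[k]] <- g[, k]
  }
  geno <- do.call(cbind, geno_cols)
  geno <- geno[, map$marker, drop = FALSE]

  sdlog <- sqrt(log(1 + (sl_sd_cm / sl_mean_cm)^2))
  meanlog <- log(sl_mean_cm) - sdlog^2 / 2
  sl <- stats::rlnorm(n, meanlog, sdlog)
  pheno <- data.frame(id = sprintf("F2_%04d", seq_len(n)),
                      standard_length_cm = sl, stringsAsFactors = FALSE)
  for (tr in traits) {
    y <- inter[tr] + slope[tr] * sl + stats::rnorm(n, 0, rsd[tr])
    if (!is.null(qtl)) for (q in which(qtl$trait == tr)) {
      eff <- c(-qtl$a[q], qtl$d[q], qtl$a[q])
      y <- y + eff[qtl_geno[, q] + 1L]
    }
    pheno[[tr]] <- y
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(geno)) < missing_rate, nrow = n)
    geno[mask] <- NA_integer_
  }
  cross <- f2_cross(map, geno, pheno)
  cross$truth <- list(qtl = qtl,
                      qtl_geno = if (!is.null(qtl_geno)) qtl_geno + 1L)
  cross
}
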