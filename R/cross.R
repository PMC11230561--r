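#' Construct a linkage map
#'
#' A linkage map is an ordered set of markers per linkage group with
#' positions in centiMorgans. Marker names must be unique across the map,
#' positions non-negative and non-decreasing within each group.
#'
#' @param marker Character vector of marker names.
#' @param lg Linkage group identifier per marker.
#' @param pos_cM Map position per marker, cM.
#' @return Data frame of class \code{"linkage_map"} with columns
#'   \code{marker}, \code{lg}, \code{pos_cM}, ordered by group then position.
#' @export
linkage_map <- function(marker, lg, pos_cM) {
  marker <- as.character(marker); lg <- as.character(lg)
  pos_cM <- as.numeric(pos_cM)
  if (length(lg) == 1L) lg <- rep(lg, length(marker))
  stopifnot(length(marker) == length(lg), length(lg) == length(pos_cM))
  if (length(marker) == 0L) stop("a linkage map needs at least one marker")
  if (anyDuplicated(marker)) stop("marker names must be unique")
  if (any(is.na(pos_cM)) || any(pos_cM < 0))
    stop("map positions must be non-negative")
  df <- data.frame(marker = marker, lg = lg, pos_cM = pos_cM,
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$lg, unique(df$lg)), df$pos_cM), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' Build an evenly spaced simulated linkage map
#'
#' @param n_lg Number of linkage groups.
#' @param n_mar Markers per group.
#' @param spacing_cM Distance between adjacent markers, cM.
#' @return A \code{\link{linkage_map}} with markers named
#'   \code{M<lg>_<index>} at positions \code{0, spacing, ...}.
#' @export
sim_map <- function(n_lg = 3L, n_mar = 30L, spacing_cM = 10) {
  stopifnot(n_lg >= 1, n_mar >= 1, spacing_cM >= 0)
  lg <- rep(seq_len(n_lg), each = n_mar)
  idx <- rep(seq_len(n_mar), times = n_lg)
  linkage_map(marker = sprintf("M%d_%02d", lg, idx),
              lg = as.character(lg),
              pos_cM = (idx - 1) * spacing_cM)
}

#' Haldane map function
#'
#' Converts map distance to recombination fraction assuming no crossover
#' interference: \code{r = (1 - exp(-2 d)) / 2} with \code{d} in Morgans.
#'
#' @param d_cM Map distance(s) in centiMorgans, non-negative.
#' @return Recombination fraction(s) in \code{[0, 0.5)}.
#' @export
haldane_r <- function(d_cM) {
  if (any(is.na(d_cM)) || any(d_cM < 0))
    stop("map distances must be non-negative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Assemble an F2 cross object
#'
#' Binds a linkage map, a genotype matrix and a phenotype table into the
#' unit the QTL engine consumes. Genotypes are coded \code{1, 2, 3} for
#' AA, AB, BB (A = granddam allele, B = grandsire allele), \code{NA} for
#' missing.
#'
#' @param map A \code{\link{linkage_map}}.
#' @param geno Integer matrix, individuals x markers, codes in
#'   \code{{1, 2, 3, NA}}; column names must match the map's markers.
#' @param pheno Data frame of phenotypes with an \code{id} column; one row
#'   per genotype row.
#' @return An object of class \code{"f2cross"}.
#' @export
f2_cross <- function(map, geno, pheno) {
  stopifnot(inherits(map, "linkage_map"), is.matrix(geno))
  if (is.null(colnames(geno)) || !identical(colnames(geno), map$marker))
    stop("genotype columns must match the map's markers, in map order")
  if (!all(geno %in% c(1L, 2L, 3L, NA)))
    stop("genotype codes must be 1 (AA), 2 (AB), 3 (BB) or NA")
  if (nrow(pheno) != nrow(geno))
    stop("phenotype rows must match genotype rows")
  if (!"id" %in% names(pheno)) stop("phenotypes need an 'id' column")
  rownames(geno) <- pheno$id
  structure(list(map = map, geno = geno, pheno = pheno),
            class = "f2cross")
}

#' @export
print.f2cross <- function(x, ...) {
  cat("F2 intercross:", nrow(x$geno), "individuals,",
      ncol(x$geno), "markers on", length(unique(x$map$lg)),
      "linkage group(s),",
      round(sum(tapply(x$map$pos_cM, x$map$lg, function(p) diff(range(p)))), 1),
      "cM total\n")
  ph <- setdiff(names(x$pheno), "id")
  cat("  phenotypes:", paste(ph, collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Marker segregation quality control
#'
#' Chi-square test of each marker's observed AA/AB/BB counts against the
#' 1:2:1 F2 expectation, with Bonferroni correction across tested markers.
#' Markers with Bonferroni-adjusted p below 0.05 are flagged for removal as
#' segregation-distorted. Markers with no non-missing genotypes are
#' untestable and kept, with a warning.
#'
#' @param cross An \code{\link{f2_cross}} (or a genotype matrix coded
#'   1/2/3/NA).
#' @param alpha Family-wise error rate for the drop flag.
#' @return Data frame with one row per marker: counts, \code{chisq},
#'   \code{p}, \code{p_bonf}, and logical \code{keep}.
#' @export
segregation_qc <- function(cross, alpha = 0.05) {
  geno <- if (inherits(cross, "f2cross")) cross$geno else cross
  m <- ncol(geno)
  cnt <- t(apply(geno, 2L, function(g) c(sum(g == 1L, na.rm = TRUE),
                                         sum(g == 2L, na.rm = TRUE),
                                         sum(g == 3L, na.rm = TRUE))))
  n <- rowSums(cnt)
  testable <- n > 0L
  if (any(!testable))
    warning(sum(!testable), " marker(s) with no genotypes are untestable; kept")
  expd <- cbind(n / 4, n / 2, n / 4)
  chisq <- rowSums((cnt - expd)^2 / expd)
  chisq[!testable] <- NA_real_
  p <- stats::pchisq(chisq, df = 2L, lower.tail = FALSE)
  p_bonf <- pmin(1, p * sum(testable))
  keep <- is.na(p_bonf) | p_bonf >= alpha
  data.frame(marker = colnames(geno), n = n,
             n_AA = cnt[, 1L], n_AB = cnt[, 2L], n_BB = cnt[, 3L],
             chisq = chisq, p = p, p_bonf = p_bonf, keep = keep,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Drop markers from a cross
#'
#' @param cross An \code{\link{f2_cross}}.
#' @param markers Marker names to remove.
#' @return The cross without those markers.
#' @export
drop_markers <- function(cross, markers) {
  stopifnot(inherits(cross, "f2cross"))
  keep <- !(cross$map$marker %in% markers)
  if (!any(keep)) stop("cannot drop every marker")
  map <- cross$map[keep, , drop = FALSE]
  class(map) <- c("linkage_map", "data.frame")
  f2_cross(map, cross$geno[, keep, drop = FALSE], cross$pheno)
}

#' Write an F2 cross to the cross-CSV dialect
#'
#' Layout: row 1 holds \code{id}, the trait names, then the marker names;
#' row 2 is blank under id/traits and carries the linkage-group label under
#' each marker; row 3 likewise carries the cM positions; subsequent rows are
#' one individual each, with empty cells for missing trait values and
#' genotype codes \code{A}, \code{H}, \code{B}, \code{-} for AA, AB, BB,
#' missing. UTF-8, comma separators, \code{.} decimal.
#'
#' @param cross An \code{\link{f2_cross}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cross_csv <- function(cross, path) {
  stopifnot(inherits(cross, "f2cross"))
  traits <- setdiff(names(cross$pheno), "id")
  mk <- cross$map$marker
  fmtnum <- function(x) ifelse(is.na(x), "",
                               format(x, digits = 15, trim = TRUE,
                                      scientific = FALSE))
  l1 <- paste(c("id", traits, mk), collapse = ",")
  l2 <- paste(c("", rep("", length(traits)), cross$map$lg), collapse = ",")
  l3 <- paste(c("", rep("", length(traits)), fmtnum(cross$map$pos_cM)),
              collapse = ",")
  code <- matrix(c("A", "H", "B")[cross$geno], nrow = nrow(cross$geno))
  code[is.na(code)] <- "-"
  body <- vapply(seq_len(nrow(cross$geno)), function(i) {
    ph <- vapply(traits, function(tr) fmtnum(cross$pheno[[tr]][i]), "")
    paste(c(cross$pheno$id[i], ph, code[i, ]), collapse = ",")
  }, "")
  writeLines(c(l1, l2, l3, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read an F2 cross from the cross-CSV dialect
#'
#' Inverse of \code{\link{write_cross_csv}}. Columns with a blank
#' linkage-group cell in row 2 are treated as phenotypes; the rest as
#' markers.
#'
#' @param path Path to a cross CSV.
#' @return An \code{\link{f2_cross}}.
#' @export
read_cross_csv <- function(path) {
  if (!file.exists(path)) stop("cross file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 4L) stop("cross file too short: ", path)
  split1 <- function(s) strsplit(s, ",", fixed = TRUE)[[1L]]
  pad <- function(v, k) c(v, rep("", max(0L, k - length(v))))
  hdr <- split1(lines[1L])
  k <- length(hdr)
  lgrow <- pad(split1(lines[2L]), k)
  posrow <- pad(split1(lines[3L]), k)
  if (hdr[1L] != "id") stop("first column must be 'id'")
  is_marker <- nzchar(lgrow)
  is_marker[1L] <- FALSE
  traits <- hdr[!is_marker][-1L]
  mk <- hdr[is_marker]
  if (length(mk) == 0L) stop("no marker columns found (blank row-2 cells?)")
  pos <- suppressWarnings(as.numeric(posrow[is_marker]))
  if (anyNA(pos)) stop("non-numeric cM position in row 3")
  map <- linkage_map(mk, lgrow[is_marker], pos)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  n <- length(body)
  geno <- matrix(NA_integer_, n, length(mk), dimnames = list(NULL, mk))
  ph <- matrix(NA_real_, n, length(traits),
               dimnames = list(NULL, traits))
  ids <- character(n)
  codes <- c(A = 1L, H = 2L, B = 3L)
  for (i in seq_len(n)) {
    f <- pad(split1(body[i]), k)
    ids[i] <- f[1L]
    tv <- f[!is_marker][-1L]
    tv[!nzchar(tv)] <- NA
    ph[i, ] <- suppressWarnings(as.numeric(tv))
    g <- f[is_marker]
    bad <- !(g %in% c("A", "H", "B", "-"))
    if (any(bad))
      stop("invalid genotype code '", g[bad][1L], "' for individual ", ids[i])
    geno[i, ] <- codes[g]
  }
  pheno <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (tr in traits) pheno[[tr]] <- ph[, tr]
  # reorder genotype columns into map order
  f2_cross(map, geno[, map$marker, drop = FALSE], pheno)
}
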