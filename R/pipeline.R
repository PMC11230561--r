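#' Run the full barring-to-QTL pipeline
#'
#' Orchestrates the analysis end to end from a configuration list (or a
#' JSON file holding one): reads profile CSVs, calls bars, computes and
#' residualizes traits, runs group comparisons and trait correlations; then
#' reads a cross CSV, applies marker segregation QC, computes genotype
#' probabilities, and per trait estimates permutation thresholds and fits
#' the multiple-QTL model. All reports are written as CSV into
#' \code{out_dir} together with a machine-readable \code{manifest.json} of
#' the parameters and seeds, so identical configurations reproduce
#' byte-identical outputs.
#'
#' Config fields (all optional except \code{out_dir}): \code{profiles}
#' (character vector of profile CSV paths, or a directory), \code{cross_csv}
#' (path), \code{traits} (phenotype columns to map; default all),
#' \code{min_run} (5), \code{step_cM} (1), \code{error_rate} (1e-4),
#' \code{n_perm} (1000), \code{drop_qc_failures} (TRUE), \code{seed}.
#'
#' @param config A named list, or path to a JSON file.
#' @return Invisibly, a list with the computed objects (\code{traits},
#'   \code{anova}, \code{correlations}, \code{qc}, \code{models}) and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- function(name, default) if (is.null(config[[name]])) default
                                 else config[[name]]
  min_run <- cfg("min_run", 5L)
  step_cM <- cfg("step_cM", 1)
  error_rate <- cfg("error_rate", 1e-4)
  n_perm <- cfg("n_perm", 1000L)
  seed <- cfg("seed", 1L)
  out <- list(paths = character(0))
  emit <- function(name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p)
    out$paths <<- c(out$paths, p)
    p
  }

  if (!is.null(config$profiles)) {
    paths <- config$profiles
    if (length(paths) == 1L && dir.exists(paths))
      paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files))
      stop("profile input not found: ", missing_files[1L])
    if (length(paths) == 0L) stop("no profile CSVs found")
    profiles <- lapply(sort(paths), read_profile_csv)
    segs <- lapply(profiles, segment_bars, min_run = min_run)
    seg_tab <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      data.frame(individual_id = profiles[[i]]$id,
                 segment_type = segs[[i]]$segments$type,
                 start_px = segs[[i]]$segments$start_px,
                 end_px = segs[[i]]$segments$end_px,
                 stringsAsFactors = FALSE)
    }))
    emit("segments.csv", function(p)
      utils::write.csv(seg_tab, p, row.names = FALSE, quote = FALSE))
    traits <- trait_table(profiles, min_run = min_run)
    if (any(!is.na(traits$standard_length_cm)))
      traits <- residualize(traits)
    out$traits <- traits
    emit("traits.csv", function(p) write_trait_csv(traits, p))
    if (length(unique(traits$group)) >= 2L &&
        all(table(traits$group) >= 2L)) {
      anova_rows <- lapply(intersect(.trait_names, names(traits)),
                           function(tr) {
        v <- traits[[paste0(tr, "_resid")]]
        if (is.null(v)) v <- traits[[tr]]
        if (sum(stats::complete.cases(v, traits$group)) < 4L) return(NULL)
        gc <- tryCatch(group_compare(v, traits$group),
                       error = function(e) NULL)
        if (is.null(gc)) return(NULL)
        data.frame(trait = tr, F = gc$f, p = gc$p,
                   stringsAsFactors = FALSE)
      })
      out$anova <- do.call(rbind, anova_rows)
      if (!is.null(out$anova))
        emit("anova.csv", function(p)
          utils::write.csv(out$anova, p, row.names = FALSE))
    }
    f2 <- traits$group == "F2"
    if (sum(f2) >= 10L) {
      cm <- trait_correlations(traits, population = f2)
      out$correlations <- cm
      emit("correlations_r.csv", function(p)
        utils::write.csv(cm$r, p))
      emit("correlations_p.csv", function(p)
        utils::write.csv(cm$p, p))
    }
  }

  if (!is.null(config$cross_csv)) {
    cross <- read_cross_csv(config$cross_csv)
    qc <- segregation_qc(cross)
    out$qc <- qc
    emit("segregation_qc.csv", function(p)
      utils::write.csv(qc, p, row.names = FALSE))
    if (isTRUE(cfg("drop_qc_failures", TRUE)) && any(!qc$keep))
      cross <- drop_markers(cross, qc$marker[!qc$keep])
    gp <- genotype_probabilities(cross, step_cM = step_cM,
                                 error_rate = error_rate)
    traits_to_map <- cfg("traits",
                         setdiff(names(cross$pheno),
                                 c("id", "standard_length_cm")))
    models <- list()
    scans <- list()
    for (k in seq_along(traits_to_map)) {
      tr <- traits_to_map[k]
      y <- cross$pheno[[tr]]
      if (is.null(y)) stop("trait not in cross phenotypes: ", tr)
      thr <- permutation_thresholds(gp, y, n_perm = n_perm,
                                    seed = seed + k)
      m <- mqm_fit(gp, y, geno = cross$geno, thresholds = thr, trait = tr)
      models[[tr]] <- m
      sc <- as.data.frame(m$scan)
      sc$trait <- tr
      scans[[tr]] <- sc[, c("trait", "lg", "pos_cM", "marker", "lod")]
    }
    out$models <- models
    emit("scans.csv", function(p)
      utils::write.csv(do.call(rbind, scans), p, row.names = FALSE))
    emit("qtl_model.csv", function(p) write_model_csv(models, p))
  }

  manifest <- list(package = "barqtl",
                   version = as.character(utils::packageVersion("barqtl")),
                   parameters = list(min_run = min_run, step_cM = step_cM,
                                     error_rate = error_rate,
                                     n_perm = n_perm, seed = seed),
                   inputs = list(profiles = config$profiles,
                                 cross_csv = config$cross_csv),
                   outputs = basename(out$paths))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
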