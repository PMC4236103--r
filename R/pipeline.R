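#' Configuration for the full analysis
#'
#' Collects the inputs, statistical settings and output location of a
#' complete run: stability summaries, zone/randomization tables for each
#' zone, selection-surface fits per dataset filter, and cumulative
#' trajectories. A configuration can also be read from a YAML file whose
#' keys mirror the arguments (\code{ddg_table}, \code{cds},
#' \code{experiment_registry}, \code{zones} as list of [lo, hi] pairs,
#' \code{reps}, \code{seed}, \code{output_dir}, \code{coarse_lattice}).
#'
#' @param ddgTable a [DdgTable-class] or path to a TSV table.
#' @param outputDir directory for the report bundle (created if absent).
#' @param cds optional coding DNA string or FASTA path, used for an
#'   accessibility cross-check.
#' @param experimentRegistry optional list of [Experiment-class] objects
#'   or path to a YAML registry; enables trajectory and
#'   temperature-filtered surface stages.
#' @param zones list of [StabilityZone-class]; defaults to [-2, 2] and
#'   [-3.5, 3.5].
#' @param reps randomization-test replicates (default 10000).
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @param lattice surface-scan lattice (default [surfaceLattice()]).
#' @param weighted logical; weight surface fits by experiment
#'   multiplicity when a registry is available.
#' @return an object of class \code{AnalysisConfig} (a validated list).
#' @export
analysisConfig <- function(ddgTable, outputDir, cds = NULL,
                           experimentRegistry = NULL,
                           zones = list(StabilityZone(-2, 2),
                                        StabilityZone(-3.5, 3.5)),
                           reps = 10000L, seed = 1L,
                           lattice = surfaceLattice(), weighted = TRUE) {
  stopifnot(reps >= 1L)
  lapply(zones, function(z) stopifnot(is(z, "StabilityZone")))
  structure(list(ddgTable = ddgTable, outputDir = outputDir, cds = cds,
                 experimentRegistry = experimentRegistry, zones = zones,
                 reps = as.integer(reps), seed = as.integer(seed),
                 lattice = lattice, weighted = isTRUE(weighted)),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file path.
#' @param outputDir overrides the file's \code{output_dir} when given.
#' @return an \code{AnalysisConfig}.
#' @export
readAnalysisConfig <- function(path, outputDir = NULL) {
  doc <- yaml::read_yaml(path)
  zones <- if (is.null(doc$zones))
    list(StabilityZone(-2, 2), StabilityZone(-3.5, 3.5))
  else lapply(doc$zones, function(z) StabilityZone(z[[1]], z[[2]]))
  analysisConfig(
    ddgTable = doc$ddg_table,
    outputDir = if (!is.null(outputDir)) outputDir else doc$output_dir,
    cds = doc$cds,
    experimentRegistry = doc$experiment_registry,
    zones = zones,
    reps = if (is.null(doc$reps)) 10000L else doc$reps,
    seed = if (is.null(doc$seed)) 1L else doc$seed,
    lattice = if (isTRUE(doc$coarse_lattice)) coarseSurfaceLattice()
              else surfaceLattice(),
    weighted = if (is.null(doc$weighted)) TRUE else isTRUE(doc$weighted))
}

writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full stability-selection analysis
#'
#' Orchestrates the pipeline on one configuration: (a) summary statistics
#' of the accessible and observed substitutions (destabilizing fractions,
#' fold-bind correlation, maximum observed deviation, individual-effect
#' radius); (b) a zone-membership and randomization-test table for every
#' configured zone and available observed dataset; (c) per-residue median
#' |ddG| effects; (d) selection-surface fits for the available dataset
#' filters (combined and wild from the table flags; high- and
#' normal-temperature ancestor-only sets from the registry, weighted by
#' experiment multiplicity); (e) cumulative trajectories per experiment;
#' and (f) a YAML manifest recording the seed, settings and every policy
#' actually exercised (clamping counts, density floors, skipped stages).
#' Stages whose inputs are missing are skipped with a message.
#'
#' All randomness derives from \code{config$seed}; two runs with the same
#' configuration produce byte-identical output files.
#'
#' @param config an \code{AnalysisConfig} from [analysisConfig()].
#' @return (invisibly) a list with the computed objects and file paths.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outputDir, f)
  paths <- character(0)
  manifest <- list(seed = config$seed, reps = config$reps,
                   zones = lapply(config$zones,
                                  function(z) c(z@lo, z@hi)),
                   zone_membership = "closed intervals",
                   tie_policy_surface =
                     "first maximum in lexicographic scan order",
                   skipped = list())

  tab <- config$ddgTable
  if (is.character(tab)) tab <- readDdgTable(tab)
  stopifnot(is(tab, "DdgTable"))
  acc <- accessibleSubs(tab)
  obsAll <- observedSubs(tab, "both")

  ## optional accessibility cross-check against the CDS
  if (!is.null(config$cds)) {
    cds <- if (file.exists(config$cds)) readCds(config$cds)
           else config$cds
    disc <- crossCheckAccessibility(tab, cds)
    manifest$accessibility_discrepancies <- nrow(disc)
    if (nrow(disc))
      paths <- c(paths, writeTsv(disc, out("accessibility_check.tsv")))
  }

  ## (a) summary statistics
  corr <- correlationFoldBind(acc)
  summary <- data.frame(
    statistic = c("n_substitutions", "n_accessible", "n_observed",
                  "n_wild_phage", "n_lab_experiment",
                  "frac_destabilizing_fold_accessible",
                  "frac_destabilizing_bind_accessible",
                  "r_squared_fold_bind_accessible",
                  "p_value_fold_bind_accessible",
                  "max_observed_deviation",
                  "individual_effect_radius"),
    value = c(nrow(ddgData(tab)), nrow(acc), nrow(obsAll),
              nrow(observedSubs(tab, "wild")),
              nrow(observedSubs(tab, "lab")),
              fractionDestabilizing(acc$ddg_fold),
              fractionDestabilizing(acc$ddg_bind),
              corr$r_squared, corr$p_value,
              if (nrow(obsAll))
                max(abs(c(obsAll$ddg_fold, obsAll$ddg_bind)))
              else NA_real_,
              if (nrow(obsAll)) individualEffectRadius(obsAll)
              else NA_real_))
  paths <- c(paths, writeTsv(summary, out("summary_stats.tsv")))

  ## (b) zone membership + randomization tests
  datasets <- list(accessible = acc)
  if (nrow(observedSubs(tab, "lab")))
    datasets$experimental <- observedSubs(tab, "lab")
  if (nrow(observedSubs(tab, "wild")))
    datasets$wild_phage <- observedSubs(tab, "wild")
  if (nrow(obsAll)) datasets$combined <- obsAll
  zoneRows <- list()
  randResults <- list()
  stageSeed <- config$seed
  for (zi in seq_along(config$zones)) {
    zone <- config$zones[[zi]]
    for (ds in names(datasets)) {
      d <- datasets[[ds]]
      zc <- zoneCounts(d, zone)
      row <- data.frame(
        zone_lo = zone@lo, zone_hi = zone@hi, dataset = ds,
        n = zc@nTotal,
        prop_fold = zc@nFoldIn / zc@nTotal, n_fold = zc@nFoldIn,
        p_fold = NA_real_,
        prop_bind = zc@nBindIn / zc@nTotal, n_bind = zc@nBindIn,
        p_bind = NA_real_,
        prop_joint = zc@nJointIn / zc@nTotal, n_joint = zc@nJointIn,
        p_joint = NA_real_)
      if (ds != "accessible") {
        stageSeed <- stageSeed + 1L
        rt <- randomizationTest(d, acc, zone, reps = config$reps,
                                seed = stageSeed)
        randResults[[paste(ds, zi, sep = "_")]] <- rt
        row$p_fold <- rt@pFold
        row$p_bind <- rt@pBind
        row$p_joint <- rt@pJoint
      }
      zoneRows[[length(zoneRows) + 1L]] <- row
    }
  }
  zoneTable <- do.call(rbind, zoneRows)
  paths <- c(paths, writeTsv(zoneTable, out("zone_randomization.tsv")))

  ## (c) per-residue median effects
  paths <- c(paths,
             writeResidueMedianEffects(tab, out("residue_medians.tsv")))

  ## registry-dependent inputs
  registry <- config$experimentRegistry
  if (is.character(registry)) registry <- readExperimentRegistry(registry)

  ## (d) selection-surface fits per dataset filter
  surfSets <- list()
  if (nrow(obsAll))
    surfSets$combined <- cbind(obsAll, weight = 1)
  if (nrow(observedSubs(tab, "wild")))
    surfSets$wild_phage <- cbind(observedSubs(tab, "wild"), weight = 1)
  if (!is.null(registry)) {
    for (cls in c("high", "normal")) {
      w <- experimentWeights(registry, temperatureClass = cls,
                             ancestorOnly = TRUE)
      if (nrow(w)) {
        dd <- lookupDdg(w$key, tab)
        surfSets[[paste0(cls, "_temperature_ancestor")]] <-
          cbind(w[c("site", "aa_from", "aa_to")], dd,
                weight = if (config$weighted) w$weight else 1)
      }
    }
  }
  fits <- list()
  if (length(surfSets) && nrow(acc)) {
    fitRows <- lapply(names(surfSets), function(ds) {
      fit <- fitSelectionSurface(acc, surfSets[[ds]],
                                 lattice = config$lattice,
                                 weighted = config$weighted)
      fits[[ds]] <<- fit
      b <- fit@best
      data.frame(dataset = ds, n_obs = nrow(surfSets[[ds]]),
                 total_weight = sum(surfSets[[ds]]$weight),
                 mu_fold = b@muFold, mu_bind = b@muBind,
                 sigma_fold = b@sigmaFold, sigma_bind = b@sigmaBind,
                 rho = b@rho, log_score = fit@logScore,
                 n_clamped = fit@nClamped, n_floored = fit@nFloored)
    })
    surfTable <- do.call(rbind, fitRows)
    paths <- c(paths, writeTsv(surfTable, out("surface_fits.tsv")))
    manifest$surface_clamped <-
      stats::setNames(as.list(surfTable$n_clamped), surfTable$dataset)
    manifest$surface_floored <-
      stats::setNames(as.list(surfTable$n_floored), surfTable$dataset)
  } else {
    manifest$skipped <- c(manifest$skipped, "selection_surface")
    message("selection-surface stage skipped: no observed substitutions")
  }

  ## (e) trajectories
  if (!is.null(registry)) {
    paths <- c(paths,
               writeTrajectories(registry, tab, out("trajectories.tsv")))
  } else {
    manifest$skipped <- c(manifest$skipped, "trajectories")
    message("trajectory stage skipped: no experiment registry")
  }

  ## (f) manifest
  manifest$n_substitutions <- nrow(ddgData(tab))
  manifest$n_accessible <- nrow(acc)
  manifest$outputs <- basename(paths)
  yaml::write_yaml(manifest, out("manifest.yaml"))
  paths <- c(paths, out("manifest.yaml"))

  invisible(list(table = tab, summary = summary, zoneTable = zoneTable,
                 randomization = randResults, surfaceFits = fits,
                 registry = registry, paths = paths,
                 manifest = manifest))
}
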