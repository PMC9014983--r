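## Config-driven orchestration of the full analysis: simulate (or load) ->
## exclusions -> per-condition GLM maps -> speed-controlled models -> load
## contrasts -> age-effect mask -> mediation -> genotype contrasts ->
## reports. Deterministic given the config seed; a JSON manifest records
## the config hash and per-stage wall times.

#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML with fields: `mode` ("simulate" or "real"),
#' `output_dir`, `seed` (required), `n_perm`, `alpha`, `age_split`,
#' `tfce` (h, e, steps, connectivity), `space` (dim, for simulate mode),
#' `cohort` (overrides for [cohortParams()]), `exclusions` (stages, rates),
#' and, in real mode, `paths` (mask, stack, subjects, optional labels).
#'
#' @param file YAML path, or a list with the same structure.
#' @return validated config list (class `wmRunConfig`).
#' @export
readRunConfig <- function(file) {
  cfg <- if (is.character(file)) yaml::read_yaml(file) else file
  defaults <- list(mode = "simulate", output_dir = "wmskeleton_run",
                   n_perm = 200L, alpha = 0.05, age_split = 60,
                   tfce = list(h = 2, e = 1, steps = 100,
                               connectivity = 26),
                   space = list(dim = c(12L, 10L, 6L), n_labels = 4L),
                   cohort = list(),
                   exclusions = list(
                     stages = c("medical", "morphology", "missing_dti",
                                "artifacts"),
                     rates = c(0.05, 0.02, 0.01, 0.03)))
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$seed)) stop("config validation error: seed is required")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config validation error: alpha must lie in (0, 1)")
  if (!cfg$mode %in% c("simulate", "real"))
    stop("config validation error: mode must be simulate or real")
  if (cfg$mode == "real") {
    need <- c("mask", "stack", "subjects")
    for (p in need)
      if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]]))
        stop("config validation error: missing input file for '", p, "'")
  }
  class(cfg) <- c("wmRunConfig", "list")
  cfg
}

## internal: one pipeline stage with wall-time logging
.stage <- function(log, name, expr) {
  t0 <- Sys.time()
  value <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log$stages[[name]] <- round(as.numeric(Sys.time() - t0, units = "secs"),
                              3)
  value
}

#' Run the full pipeline
#'
#' Executes every stage of the study replica and writes maps (NIfTI),
#' tables (TSV), summaries (JSON) and a manifest into the output
#' directory. All randomness derives from the config seed, so a repeated
#' run with the same config produces byte-identical TSV/JSON summaries.
#'
#' @param config a `wmRunConfig` (or a YAML path).
#' @param through last stage to run: "stack" (simulated data only), "glm"
#'   (adds the metric-behavior maps), "mediation", "genetics" or "reports"
#'   (everything, the default). Earlier stages always run.
#' @return invisibly, a list with the output directory, the manifest, and
#'   the in-memory stage results.
#' @export
runPipeline <- function(config, through = c("reports", "genetics",
                                            "mediation", "glm", "stack")) {
  through <- match.arg(through)
  stageOrder <- c(stack = 1, glm = 2, mediation = 3, genetics = 4,
                  reports = 5)
  lastStage <- stageOrder[[through]]
  if (is.character(config) || !inherits(config, "wmRunConfig"))
    config <- readRunConfig(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "maps"), showWarnings = FALSE)
  log <- new.env()
  log$stages <- list()
  seed <- as.integer(config$seed)
  tp <- tfceParams(config$tfce$h, config$tfce$e, config$tfce$steps,
                   config$tfce$connectivity)
  nPerm <- as.integer(config$n_perm)
  alpha <- config$alpha

  ## ---- cohort ----
  if (config$mode == "simulate") {
    cp <- do.call(cohortParams, c(config$cohort, list(seed = seed)))
    table <- .stage(log, "cohort", generateCohort(cp))
    space <- syntheticSkeletonSpace(unlist(config$space$dim),
                                    nLabels = config$space$n_labels %||% 0L)
  } else {
    space <- .stage(log, "cohort", readSkeletonSpace(
      config$paths$mask, config$paths$labels %||% NULL,
      config$paths$label_names %||% NULL))
    table <- read.delim(config$paths$subjects, stringsAsFactors = FALSE)
    for (g in intersect(c("taq1a", "c957t", "comt"), names(table)))
      table[[g]] <- factor(table[[g]])
  }

  ## ---- exclusions ----
  excl <- .stage(log, "exclusions", {
    stages <- config$exclusions$stages
    if (config$mode == "simulate") {
      set.seed(.subSeed(seed, 21))
      flags <- vapply(config$exclusions$rates,
                      function(r) runif(nrow(table)) < r,
                      logical(nrow(table)))
      colnames(flags) <- stages
      applyExclusions(table, flags)
    } else if (!is.null(table$exclusion_stage)) {
      applyExclusions(table,
                      ifelse(table$exclusion_stage == "", NA_character_,
                             table$exclusion_stage), stages)
    } else {
      list(table = table,
           ledger = new("ExclusionLedger", initial = nrow(table),
                        stages = setNames(integer(length(stages)), stages),
                        final = nrow(table)))
    }
  })
  table <- excl$table
  writeSubjectTable(table, file.path(out, "subjects.tsv"))
  writeExclusionLedger(excl$ledger, file.path(out, "exclusions.json"))

  ## ---- metric stack ----
  stack <- .stage(log, "stack", {
    if (config$mode == "simulate")
      generateMetricStack(table, space, seed = .subSeed(seed, 22))
    else
      readMetricStack(config$paths$stack, space, "FA", table$subject_id)
  })
  writeSkeletonSpace(space, file.path(out, "maps", "skeleton_mask.nii.gz"))

  conds <- c("manipulation", "maintenance", "control")
  wmCols <- paste0("wm_", conds)
  sigCounts <- list()
  glmStage <- speedStage <- loadStage <- genStage <- reports <- NULL
  mask <- NULL

  ## ---- per-condition FA-WM GLM (age + sex nuisance) ----
  if (lastStage >= 2) glmStage <- .stage(log, "glm_wm", {
    lapply(setNames(conds, conds), function(cn) {
      y <- table[[paste0("wm_", cn)]]
      keep <- complete.cases(y, table$age, table$sex)
      sub <- metricStack(stack@metric,
                         stack@values[keep, , drop = FALSE], space,
                         stack@subjects[keep])
      X <- cbind(intercept = 1, score = .std(y[keep]),
                 age = table$age[keep], sex = table$sex[keep])
      res <- permutationFWE(sub, X, "score", tp, nPerm,
                            .subSeed(seed, 23), "greater")
      writeStatMap(res@pMap,
                   file.path(out, "maps",
                             sprintf("fa_wm_%s_fwe_p.nii.gz", cn)))
      res
    })
  })
  for (cn in if (is.null(glmStage)) character(0) else conds)
    sigCounts[[paste0("fa_wm_", cn)]] <-
      sum(significantMask(glmStage[[cn]], alpha))

  ## ---- speed-controlled models ----
  if (lastStage >= 2) speedStage <- .stage(log, "glm_wm_speed", {
    lapply(setNames(conds, conds), function(cn) {
      y <- table[[paste0("wm_", cn)]]
      keep <- complete.cases(y, table$age, table$sex, table$speed)
      sub <- metricStack(stack@metric,
                         stack@values[keep, , drop = FALSE], space,
                         stack@subjects[keep])
      X <- cbind(intercept = 1, score = .std(y[keep]),
                 age = table$age[keep], sex = table$sex[keep],
                 speed = table$speed[keep])
      permutationFWE(sub, X, "score", tp, nPerm, .subSeed(seed, 24),
                     "greater")
    })
  })
  for (cn in if (is.null(speedStage)) character(0) else conds)
    sigCounts[[paste0("fa_wm_", cn, "_speed")]] <-
      sum(significantMask(speedStage[[cn]], alpha))

  ## ---- load contrasts ----
  if (lastStage >= 2) loadStage <- .stage(log, "load_contrasts", {
    pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
    lapply(pairs, function(pr) {
      keep <- complete.cases(table[[wmCols[pr[1]]]],
                             table[[wmCols[pr[2]]]],
                             table$age, table$sex)
      sub <- metricStack(stack@metric,
                         stack@values[keep, , drop = FALSE], space,
                         stack@subjects[keep])
      map <- compareConditionSlopes(
        sub, table[[wmCols[pr[1]]]][keep], table[[wmCols[pr[2]]]][keep],
        cbind(age = table$age[keep], sex = table$sex[keep]))
      list(pair = paste(conds[pr], collapse = "_vs_"),
           maxAbsT = max(abs(map@values)))
    })
  })

  ## ---- age-effect mask and mediation ----
  if (lastStage >= 3) {
    mask <- .stage(log, "age_mask",
                   ageEffectMask(stack, table$age,
                                 cbind(sex = table$sex), tp, nPerm,
                                 .subSeed(seed, 25), alpha = alpha))
    sigCounts$age_effect <- sum(mask)
  }
  med <- NULL
  effectChange <- NULL
  if (lastStage >= 3 && any(mask)) {
    med <- .stage(log, "mediation",
                  voxelwiseMediation(stack, table$age,
                                     table$wm_manipulation,
                                     cbind(sex = table$sex), mask, tp,
                                     nPerm, .subSeed(seed, 26)))
    writeStatMap(fwePMap(med),
                 file.path(out, "maps", "mediation_fwe_p.nii.gz"))
    sigCounts$mediation <- sum(med@p < alpha)
    effectChange <- changeInEffect(table$wm_manipulation, table$age,
                                   table$sex, stack@values[, med@peak])
  }

  ## ---- genotype contrasts and age x gene ----
  if (lastStage >= 4) genStage <- .stage(log, "genetics", {
    ageGroup <- factor(ifelse(table$age <= config$age_split, "younger",
                              "older"), levels = c("younger", "older"))
    lapply(setNames(c("taq1a", "c957t", "comt"),
                    c("taq1a", "c957t", "comt")), function(locus) {
      g <- table[[locus]]
      lv <- levels(droplevels(g))
      if (length(lv) < 2L || min(table(droplevels(g))) < 3L)
        return(NULL)
      pair <- lv[c(1L, 2L)]
      main <- groupContrast(stack, g, pair,
                            cbind(age = table$age, sex = table$sex))
      inter <- tryCatch(
        groupContrast(stack, g, pair, cbind(sex = table$sex),
                      interactionWith = ageGroup),
        error = function(e) NULL)
      list(pair = paste(pair, collapse = "_vs_"),
           maxAbsT = max(abs(main@values)),
           interactionMaxAbsT = if (is.null(inter)) NA_real_
                                else max(abs(inter@values)))
    })
  })

  ## ---- reports ----
  if (lastStage >= 5) reports <- .stage(log, "reports", {
    hwe <- lapply(setNames(c("taq1a", "c957t", "comt"),
                           c("taq1a", "c957t", "comt")), function(locus) {
      ct <- as.integer(table(table[[locus]]))
      h <- hweTest(ct)
      list(counts = ct, chisq = h$chisq, alleleFreq = h$alleleFreq)
    })
    prof <- sliceProfile(glmStage[[1]]@tMap, 2)
    write.table(prof, file.path(out, "slice_profile_ap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cov <- if (length(space@labels))
      tractCoverage(significantMask(glmStage[[1]], alpha), space)
    else NULL
    if (!is.null(cov))
      write.table(cov, file.path(out, "tract_coverage.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    demo <- demographicTests(
      table, "comt",
      numericVars = c("age", wmCols, "speed"))
    write.table(demo, file.path(out, "demographics_comt.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(hwe = hwe, coverage = cov)
  })

  ## ---- manifest ----
  cfgFile <- file.path(out, "config.yaml")
  yaml::write_yaml(unclass(config), cfgFile)
  # hash the analysis settings only, so runs differing just in where they
  # write remain recognizably the same analysis
  hashFile <- tempfile(fileext = ".yaml")
  hashCfg <- unclass(config)
  hashCfg$output_dir <- NULL
  yaml::write_yaml(hashCfg, hashFile)
  manifest <- list(
    package = "wmskeleton",
    version = as.character(utils::packageVersion("wmskeleton")),
    config_hash = unname(tools::md5sum(hashFile)),
    seed = seed, n_perm = nPerm, alpha = alpha,
    exclusions = list(initial = excl$ledger@initial,
                      final = excl$ledger@final,
                      stages = as.list(excl$ledger@stages)),
    significant_voxels = sigCounts,
    hwe = reports$hwe,
    load_contrasts = loadStage,
    genetics = genStage,
    mediation = if (!is.null(med))
      list(peak_column = med@peak, n_significant = sum(med@p < alpha),
           n_excluded = med@nExcluded,
           effect_change = effectChange) else NULL)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  # wall-time log kept out of the manifest so reruns stay byte-identical
  writeLines(sprintf("%-16s %8.3f s", names(log$stages),
                     unlist(log$stages)),
             file.path(out, "stages.log"))
  invisible(list(output_dir = out, manifest = manifest, table = table,
                 stack = stack, space = space, glm = glmStage,
                 mediation = med, mask = mask))
}
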