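# End-to-end orchestration: simulate -> moran -> fit -> compare -> effects
# -> timeseries, with a serialisable run configuration, derived seeds per
# stage, a manifest of produced artifacts, and resumable stages.

.requireFields <- function(x, fields, where) {
  miss <- setdiff(fields, names(x))
  if (length(miss))
    stop("run config is missing field(s) in ", where, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read and validate a run configuration
#'
#' Configurations are YAML (or JSON) with top-level fields
#' \code{output_dir}, \code{seed}, \code{stages} and per-stage blocks:
#' \code{simulate} (\code{rows}, \code{cols}, and optionally
#' \code{contiguity}, \code{years}, \code{likelihood}), \code{fit}
#' (\code{models}, \code{draws}, \code{warmup}, \code{chains}),
#' \code{moran} (\code{n_perm}), optional \code{groups_file} for the
#' time-series export, and \code{force} to re-run completed stages. The
#' schema is validated before any computation.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @return validated config list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(
      config, simplifyVector = TRUE) else yaml::read_yaml(config)
  }
  .requireFields(config, c("output_dir", "seed", "stages"), "top level")
  known <- c("simulate", "moran", "fit", "compare", "effects", "timeseries")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("simulate" %in% config$stages)
    .requireFields(config$simulate, c("rows", "cols"), "simulate")
  if ("fit" %in% config$stages)
    .requireFields(config$fit, c("models", "draws", "warmup", "chains"),
                   "fit")
  config$force <- isTRUE(config$force)
  config
}

.stageFiles <- function(cfg) {
  models <- if (!is.null(cfg$fit$models)) cfg$fit$models else integer()
  list(
    simulate = c("adjacency.csv", "covariates.csv", "populations.csv",
                 "panel_year.csv",
                 if (any(models >= 4)) "panel_month.csv", "truth.json"),
    moran = "moran.csv",
    fit = unlist(lapply(models, function(m)
      c(sprintf("fit_model%d_summary.csv", m),
        sprintf("fit_model%d_rates.csv", m),
        sprintf("fit_model%d_diagnostics.json", m)))),
    compare = "dic.csv",
    effects = c("vif.csv", "effects.csv"),
    timeseries = "timeseries.csv")
}

#' Run the full pipeline described by a configuration
#'
#' Executes the requested stages in order, writing every artifact under
#' \code{output_dir} and finally a \code{manifest.json} recording the
#' config, the seed, package and R versions, each stage's status and the
#' md5 checksum of every file written. Stages whose outputs already exist
#' are skipped unless \code{force}; every source of randomness is derived
#' from the config seed, so re-running a config reproduces its outputs
#' byte for byte.
#'
#' @param config see \code{\link{readRunConfig}}.
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  files <- .stageFiles(cfg)
  status <- list()
  writeNum <- function(df, f) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) signif(col, 12) else col)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  }
  done <- function(stage)
    length(files[[stage]]) > 0 && all(file.exists(out(files[[stage]])))

  models <- if (!is.null(cfg$fit$models)) as.integer(cfg$fit$models)
            else integer()
  years <- if (!is.null(cfg$simulate$years))
    as.integer(cfg$simulate$years) else 2018:2021
  window <- as.Date(c(sprintf("%d-01-01", min(years)),
                      sprintf("%d-12-31", max(years))))
  likelihood <- cfg$simulate$likelihood %||% "poisson"

  lattice <- panelYear <- panelMonth <- covars <- NULL
  loadInputs <- function() {
    lattice <<- suppressWarnings(readAdjacency(out("adjacency.csv"),
                                               mode = "edges"))
    covars <<- readCovariates(out("covariates.csv"))
    panelYear <<- readPanel(out("panel_year.csv"), out("populations.csv"))
    if (file.exists(out("panel_month.csv")))
      panelMonth <<- readPanel(out("panel_month.csv"),
                               out("populations.csv"))
  }

  for (stage in cfg$stages) {
    if (!cfg$force && done(stage)) {
      status[[stage]] <- "skipped (outputs exist)"
      if (stage == "simulate") loadInputs()
      next
    }
    res <- tryCatch({
      switch(stage,
        simulate = {
          set.seed(cfg$seed)
          lattice <- makeGridLattice(cfg$simulate$rows, cfg$simulate$cols,
                                     cfg$simulate$contiguity %||% "rook")
          covars <- simulateCovariates(lattice, years = years)
          pops <- simulatePopulations(lattice)
          specY <- modelSpec(1, likelihood = likelihood)
          truth <- simulationTruth(specY, lattice)
          panelYear <- simulatePanel(specY, truth, lattice, covars, pops,
                                     studyWindow = window)
          writeAdjacency(lattice, out("adjacency.csv"))
          writeCovariates(covars, out("covariates.csv"))
          writePanel(panelYear, out("panel_year.csv"),
                     out("populations.csv"))
          if (any(models >= 4)) {
            mYears <- as.integer(cfg$simulate$month_years %||% years)
            windowM <- as.Date(c(sprintf("%d-01-01", min(mYears)),
                                 sprintf("%d-12-31", max(mYears))))
            specM <- modelSpec(4, likelihood = likelihood)
            truthM <- simulationTruth(
              specM, lattice, T = 12L * length(mYears),
              beta0 = truth@beta0, beta = truth@beta,
              tauS = truth@tauS, tauV = truth@tauV)
            panelMonth <- simulatePanel(specM, truthM, lattice, covars,
                                        pops, studyWindow = windowM)
            writePanel(panelMonth, out("panel_month.csv"),
                       out("populations.csv"))
            writeTruth(truthM, out("truth.json"))
          } else writeTruth(truth, out("truth.json"))
          "ok"
        },
        moran = {
          yrs <- periodYears(panelYear)
          uy <- sort(unique(yrs))
          groups <- if (length(uy) >= 4)
            list(before = as.character(uy[1:2]),
                 during = as.character(uy[3:4]))
          else list(all = periodLabels(panelYear))
          tab <- moranTable(list(ALL = panelYear), lattice,
                            periodGroups = groups,
                            nPerm = cfg$moran$n_perm %||% 999,
                            seed = cfg$seed + 1L)
          writeNum(tab, out("moran.csv"))
          "ok"
        },
        fit = {
          for (m in models) {
            sp <- modelSpec(m, likelihood = likelihood)
            pn <- if (m >= 4) panelMonth else panelYear
            fit <- fitSTModel(sp, pn, covars, lattice,
                              draws = cfg$fit$draws,
                              warmup = cfg$fit$warmup,
                              chains = cfg$fit$chains,
                              seed = cfg$seed + 10L + m)
            su <- posteriorSummary(fit)
            writeNum(data.frame(parameter = su$parameter,
                                estimate = su$mean, q2.5 = su$q2.5,
                                q97.5 = su$q97.5),
                     out(sprintf("fit_model%d_summary.csv", m)))
            lam <- fittedRates(fit)
            writeNum(data.frame(
              tract_id = rep(rownames(lam), ncol(lam)),
              period = rep(colnames(lam), each = nrow(lam)),
              rate = as.vector(lam)),
              out(sprintf("fit_model%d_rates.csv", m)))
            jsonlite::write_json(
              c(dic(fit)[c("DIC", "Dbar", "pD")],
                list(converged = fit@converged,
                     maxRhat = fit@diagnostics$maxRhat,
                     minEss = fit@diagnostics$minEss)),
              out(sprintf("fit_model%d_diagnostics.json", m)),
              auto_unbox = TRUE, digits = NA)
          }
          "ok"
        },
        compare = {
          rows <- lapply(models, function(m) {
            d <- jsonlite::read_json(
              out(sprintf("fit_model%d_diagnostics.json", m)),
              simplifyVector = TRUE)
            data.frame(model = m, DIC = d$DIC, Dbar = d$Dbar, pD = d$pD)
          })
          tab <- do.call(rbind, rows)
          tab$similar <- tab$DIC - min(tab$DIC) <= 2
          writeNum(tab, out("dic.csv"))
          "ok"
        },
        effects = {
          writeNum(vifTable(covars), out("vif.csv"))
          m1 <- models[models <= 3][1]
          su <- utils::read.csv(out(sprintf("fit_model%d_summary.csv", m1)))
          keep <- su$parameter %in% covariateNames(covars)
          writeNum(effectsTable(setNames(su$estimate[keep],
                                         su$parameter[keep]), covars),
                   out("effects.csv"))
          "ok"
        },
        timeseries = {
          mm <- models[models >= 4]
          fits <- lapply(mm, function(m) {
            r <- utils::read.csv(
              out(sprintf("fit_model%d_rates.csv", m)),
              colClasses = c(tract_id = "character", period = "character"))
            lam <- matrix(r$rate, nTracts(lattice),
                          dimnames = list(unique(r$tract_id),
                                          unique(r$period)))
            lam
          })
          names(fits) <- paste0("model", mm)
          groups <- NULL
          if (!is.null(cfg$groups_file)) {
            gf <- utils::read.csv(cfg$groups_file,
                                  colClasses = "character")
            groups <- setNames(gf$group, gf$tract_id)
          }
          writeNum(exportTimeseries(fits, panelMonth, groups),
                   out("timeseries.csv"))
          "ok"
        })
    }, error = function(e) paste("failed:", conditionMessage(e)))
    status[[stage]] <- res
    if (!identical(res, "ok") &&
        !identical(res, "skipped (outputs exist)") &&
        startsWith(res, "failed")) break
  }

  written <- unlist(files[cfg$stages], use.names = FALSE)
  written <- written[file.exists(out(written))]
  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("stareal")),
    stages = status,
    files = lapply(setNames(written, written), function(f)
      unname(tools::md5sum(out(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Long-format export of observed and fitted monthly rates
#'
#' One row per (tract, month, series): the raw rate Y_it / P_i and each
#' supplied model's fitted rate, with an optional per-tract group label
#' (e.g. north/south) for faceted plotting.
#'
#' @param fits named list of fitted-rate matrices (n x T, e.g.
#'   \code{fittedRates} of monthly fits) or \linkS4class{STFit}s.
#' @param panel the monthly \linkS4class{CountPanel} the fits describe.
#' @param groups optional named character vector tract_id -> group label.
#' @return data.frame with columns tract_id, period, series, rate, group.
#' @export
exportTimeseries <- function(fits, panel, groups = NULL) {
  if (granularity(panel) != "month")
    stop("time-series export needs a monthly panel/fit")
  fits <- lapply(fits, function(f)
    if (methods::is(f, "STFit")) fittedRates(f) else f)
  ids <- tractIds(panel); pls <- periodLabels(panel)
  raw <- sweep(panelCounts(panel), 1, unname(populations(panel)), "/")
  series <- c(list(raw = raw), fits)
  out <- do.call(rbind, lapply(names(series), function(nm)
    data.frame(tract_id = rep(ids, times = length(pls)),
               period = rep(pls, each = length(ids)),
               series = nm, rate = as.vector(series[[nm]]))))
  out$group <- if (is.null(groups)) NA_character_
               else unname(groups[out$tract_id])
  out
}
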