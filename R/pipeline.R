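# End-to-end analysis: configuration, staged execution with logging, report
# writing and cross-taxon comparison.

#' Run configuration
#'
#' @param muscles Path to a muscle measurement table (CSV/JSON), or a data
#'   frame.
#' @param levers Path to a lever table (CSV/JSON), or a list with `inlever`
#'   and `outlever`.
#' @param model Optional path to a jaw-model JSON (or a [jaw_model()]);
#'   enables the gape stage.
#' @param params A [force_parameters()].
#' @param limits A [strain_limits()].
#' @param taxon Label carried into the report.
#' @param out_dir Optional directory: the report bundle is written there.
#' @param seed Integer echoed into the provenance block (the pipeline itself
#'   is deterministic).
#' @param verbose Emit stage messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(muscles, levers, model = NULL,
                       params = force_parameters(),
                       limits = strain_limits(),
                       taxon = "unnamed", out_dir = NULL, seed = NULL,
                       verbose = FALSE) {
  structure(list(muscles = muscles, levers = levers, model = model,
                 params = params, limits = limits, taxon = taxon,
                 out_dir = out_dir, seed = seed, verbose = verbose),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' File keys mirror the [run_config()] arguments; `params` and `limits` may
#' be given as nested maps (`stress_sigma`, `correction_factor`, `bilateral`;
#' `optimal`, `maximum`). Relative paths are resolved against the config
#' file's directory.
#'
#' @param path YAML (needs the yaml package) or JSON config file.
#' @param ... Overrides applied after reading (argument > file > default).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- if (tolower(tools::file_ext(path)) %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.character(p) && !file.exists(p) &&
                             file.exists(file.path(base, p)))
    file.path(base, p) else p
  run_config(
    muscles = resolve(cfg$muscles),
    levers = resolve(cfg$levers),
    model = resolve(cfg$model),
    params = if (is.list(cfg$params)) do.call(force_parameters, cfg$params)
             else cfg$params %||% force_parameters(),
    limits = if (is.list(cfg$limits)) do.call(strain_limits, cfg$limits)
             else cfg$limits %||% strain_limits(),
    taxon = cfg$taxon %||% "unnamed",
    out_dir = cfg$out_dir,
    seed = cfg$seed,
    verbose = isTRUE(cfg$verbose))
}

.stage <- function(config, name, expr) {
  if (isTRUE(config$verbose)) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage=", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full dry-skull pipeline
#'
#' Executes forces -> levers -> (optionally) gape on the configured inputs
#' and assembles a report that mirrors the standard table layouts: the
#' per-muscle force table, the per-bite-point bite-force table with
#' mechanical advantage, and the gape-limit summary when a 3D jaw model is
#' supplied. Every number in the report is regenerable from the config.
#'
#' @param config A [run_config()] (or path to a YAML/JSON config file).
#' @return A list of class `analysis_report` with `force_table`,
#'   `bite_table`, `mechanical_advantage`, `gape` (or `NULL`) and a
#'   `provenance` block (package version, taxon, parameter echo, seed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  muscles <- .stage(config, "forces",
                    if (is.data.frame(config$muscles)) config$muscles
                    else read_muscle_table(config$muscles))
  forces <- .stage(config, "forces", force_table(muscles, config$params))
  levers <- .stage(config, "levers",
                   if (is.list(config$levers) &&
                       !is.character(config$levers)) config$levers
                   else read_lever_table(config$levers))
  bite <- .stage(config, "levers",
                 bite_table(forces, levers$inlever, levers$outlever))
  gape <- NULL
  if (!is.null(config$model)) {
    model <- .stage(config, "gape",
                    if (inherits(config$model, "jaw_model")) config$model
                    else read_jaw_model(config$model))
    gape <- .stage(config, "gape", find_gape_limits(model, config$limits))
  }
  report <- structure(
    list(force_table = forces,
         bite_table = bite,
         mechanical_advantage = mechanical_advantage(bite),
         gape = gape,
         provenance = list(
           package = "dryskull",
           version = as.character(utils::packageVersion("dryskull")),
           taxon = config$taxon,
           stress_sigma = config$params$stress_sigma,
           correction_factor = config$params$correction_factor,
           bilateral = config$params$bilateral,
           strain_limits = unclass(config$limits),
           seed = config$seed)),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("dryskull analysis report:", x$provenance$taxon, "\n")
  tot <- attr(x$force_table, "totals")
  cat(sprintf("  sum Fmus = %.1f N, sum Fres = %.1f N\n",
              tot$fmus_N, tot$fres_N))
  cat("  bite totals (N):",
      paste(sprintf("%s = %.1f", names(x$bite_table$totals),
                    x$bite_table$totals), collapse = ", "), "\n")
  cat("  mechanical advantage:",
      paste(sprintf("%s = %.3f", names(x$mechanical_advantage),
                    x$mechanical_advantage), collapse = ", "), "\n")
  if (!is.null(x$gape)) print(x$gape)
  invisible(x)
}

#' Write a report bundle
#'
#' Emits `force_table.csv`, `bite_table.csv`, `mechanical_advantage.csv`,
#' optionally `strain_trace.csv`, and a `manifest.json` with the provenance
#' block and totals.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$force_table,
                   file.path(dir, "force_table.csv"), row.names = FALSE)
  bt <- report$bite_table
  bite_df <- data.frame(muscle = rownames(bt$fbite),
                        inlever_mm = if (is.null(bt$inlever)) NA else
                          as.numeric(bt$inlever),
                        round(bt$fbite, 6),
                        contribution_pct = as.numeric(bt$contribution_pct))
  utils::write.csv(bite_df, file.path(dir, "bite_table.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(bite_point = names(bt$totals),
                              total_fbite_N = as.numeric(bt$totals),
                              mechanical_advantage =
                                as.numeric(report$mechanical_advantage)),
                   file.path(dir, "mechanical_advantage.csv"),
                   row.names = FALSE)
  manifest <- list(provenance = report$provenance,
                   totals = c(attr(report$force_table, "totals"),
                              list(bite = as.list(bt$totals))))
  if (!is.null(report$gape)) {
    write_strain_trace(report$gape, file.path(dir, "strain_trace.csv"))
    manifest$gape <- list(
      theta_optimal = report$gape$theta_optimal,
      theta_maximum = report$gape$theta_maximum,
      constraining_cylinder_opt = report$gape$constraining_cylinder_opt,
      constraining_cylinder_max = report$gape$constraining_cylinder_max,
      depressor_factors = as.list(report$gape$depressor_factors))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Compare taxa against surface-area scaling of a reference
#'
#' For each taxon and bite point, how much its total bite force exceeds the
#' value predicted by scaling the reference taxon's bite force by the ratio
#' of cranial surface areas (see [scaled_comparison()]), plus an absolute
#' force ranking.
#'
#' @param reports Named list of `analysis_report`s (names = taxa).
#' @param surface_areas Named numeric, cranial surface area (square mm) per
#'   taxon; taxa without an area are skipped with a warning.
#' @param reference_taxon Name of the reference taxon (must have an area).
#' @return Data frame: `taxon`, `bite_point`, `fbite_N`,
#'   `percent_greater_than_scaled`, `rank` (1 = strongest at that point).
#' @export
compare_taxa <- function(reports, surface_areas, reference_taxon) {
  stopifnot(length(reports) >= 2, !is.null(names(reports)),
            reference_taxon %in% names(reports),
            reference_taxon %in% names(surface_areas))
  ref <- reports[[reference_taxon]]$bite_table$totals
  a_ref <- surface_areas[[reference_taxon]]
  rows <- list()
  for (tx in names(reports)) {
    if (!tx %in% names(surface_areas)) {
      warning("no surface area for taxon '", tx, "'; skipped")
      next
    }
    tot <- reports[[tx]]$bite_table$totals
    common <- intersect(names(tot), names(ref))
    rows[[tx]] <- data.frame(
      taxon = tx, bite_point = common,
      fbite_N = as.numeric(tot[common]),
      percent_greater_than_scaled = vapply(common, function(bp)
        scaled_comparison(tot[[bp]], ref[[bp]],
                          surface_areas[[tx]], a_ref), numeric(1)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rank <- stats::ave(-out$fbite_N, out$bite_point, FUN = rank)
  out
}
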