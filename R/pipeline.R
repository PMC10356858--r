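#' Pipeline configuration
#'
#' Assembles the full study configuration with the study defaults: the
#' five-layer skin model, the operating-parameter ranges, a 50-point
#' optimal Latin hypercube design, the RBF surrogate, the stated interval
#' radii and an RPDI level sweep over 0.9 / 1.0 / 1.1.
#'
#' @param model A [skin_model()].
#' @param domain A [design_domain()].
#' @param grid [grid_spec()] resolution for all solver runs.
#' @param dt Solver time step (s).
#' @param h_conv Surface heat-exchange coefficient (W m^-2 K^-1).
#' @param n_lhs Number of Latin hypercube design points.
#' @param seed Integer seed for every random stage (design and GA).
#' @param radii Named interval radii for the uncertainty analysis.
#' @param lambdas RPDI levels to optimize at.
#' @param b Surface-temperature constraint threshold (degrees C).
#' @param ga A [ga_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model = default_skin_model(),
                            domain = design_domain(),
                            grid = grid_spec(), dt = 1e-3, h_conv = 10,
                            n_lhs = 50, seed = 1,
                            radii = c(power = 0.25, spot_radius = 0.05,
                                      duration = 0.02, ambient = 1.25),
                            lambdas = c(0.9, 1.0, 1.1), b = 52,
                            ga = ga_config()) {
  stopifnot(inherits(model, "skin_model"), inherits(domain, "design_domain"),
            inherits(grid, "grid_spec"), inherits(ga, "ga_config"),
            n_lhs >= 5)
  structure(list(model = model, domain = domain, grid = grid, dt = dt,
                 h_conv = h_conv, n_lhs = n_lhs, seed = as.integer(seed),
                 radii = radii, lambdas = lambdas, b = b, ga = ga),
            class = "pipeline_config")
}

#' Coarse fixture configuration
#'
#' A configuration for smoke tests and examples: coarse grid, 5 ms steps
#' and a 12-point design. Results are qualitatively right but not at
#' reporting resolution.
#'
#' @param seed Integer seed.
#' @return A `pipeline_config`.
#' @export
fixture_config <- function(seed = 1) {
  pipeline_config(grid = coarse_grid_spec(), dt = 5e-3, n_lhs = 12,
                  seed = seed,
                  ga = ga_config(pop_size = 20, generations = 30))
}

#' Synthetic mini response table
#'
#' A deterministic 12-row design with smooth *synthetic* indicator
#' responses (closed-form expressions mimicking the solver's monotone
#' trends: heating grows with power and duration, falls with spot radius,
#' rises with ambient temperature). It exists so the surrogate and interval
#' modules can be exercised cheaply and deterministically; it is not solver
#' output.
#'
#' @param n Number of rows.
#' @param seed Seed for the underlying Latin hypercube.
#' @param domain A [design_domain()].
#' @return A `response_table` with `hpm` and `st` columns.
#' @export
fixture_response_table <- function(n = 12, seed = 1,
                                   domain = design_domain()) {
  des <- optimal_lhs(domain, n, seed = seed)
  synth <- synthetic_indicators(des)
  des$hpm <- synth$hpm
  des$st <- synth$st
  class(des) <- unique(c("response_table", class(des)))
  des
}

# smooth synthetic indicator surfaces (monotone like the solver)
synthetic_indicators <- function(x) {
  p <- x$power; s <- x$spot_radius; d <- x$duration; a <- x$ambient
  base <- 36.5 + 0.02 * (a - 25)
  rise <- 3.1 * p * d^0.45 / s^1.7 + 0.08 * (a - 25)
  list(hpm = base + rise, st = base + 1.03 * rise + 0.12)
}

#' Run the whole planning pipeline
#'
#' Executes the full workflow: the L9 orthogonal experiment with range and
#' variance analysis, the optimal Latin hypercube design with solver runs,
#' surrogate training with error metrics, the whole-domain uncertainty
#' sweep, and the RPDI-level optimization sweep. Writes CSV reports and a
#' JSON manifest (seeds, sizes, stage status) when `out_dir` is given;
#' identical configurations produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for reports, or `NULL` for none.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with elements `l9`, `range`, `anova`,
#'   `design`, `surrogate`, `metrics`, `uncertainty`, `optima`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  env <- environment_spec(config$h_conv)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = config$seed, n_lhs = config$n_lhs,
                   dt = config$dt, lambdas = config$lambdas,
                   stages = list())
  out <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      ok = ok, seconds = round(elapsed, 2),
      error = if (ok) NULL else conditionMessage(res))
    say("stage %-12s %s (%.1f s)", name, if (ok) "ok" else "FAILED", elapsed)
    if (!ok) NULL else res
  }

  out$l9 <- stage("orthogonal", {
    run_design(orthogonal_l9(), config$model, env, config$grid, config$dt)
  })
  if (!is.null(out$l9)) {
    out$range <- stage("range", range_analysis(out$l9))
    out$anova <- stage("anova", variance_analysis(out$l9))
  }
  out$design <- stage("lhs", {
    des <- optimal_lhs(config$domain, config$n_lhs, seed = config$seed)
    run_design(des, config$model, env, config$grid, config$dt)
  })
  if (!is.null(out$design)) {
    out$surrogate <- stage("surrogate", {
      train_rbf(out$design[design_factors()],
                as.matrix(out$design[c("hpm", "st")]), config$domain)
    })
  }
  if (!is.null(out$surrogate)) {
    out$metrics <- stage("metrics", {
      pred <- predict(out$surrogate, out$design[design_factors()])
      list(hpm = error_metrics(out$design$hpm, pred[, "hpm"]),
           st = error_metrics(out$design$st, pred[, "st"]))
    })
    out$uncertainty <- stage("uncertainty", {
      uncertainty_sweep(out$surrogate, config$domain)
    })
    out$optima <- stage("optimize", {
      lapply(config$lambdas, function(lam) {
        optimize_treatment(
          interval_problem(lambda = lam, radii = config$radii, b = config$b,
                           domain = config$domain),
          out$surrogate, config$ga, seed = config$seed + 1L)
      })
    })
  }
  out$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    if (!is.null(out$l9)) wcsv(as.data.frame(out$l9), "orthogonal_results.csv")
    if (!is.null(out$range)) {
      ra <- out$range
      wcsv(data.frame(statistic = c(paste0("K", 1:3), paste0("mean", 1:3),
                                    paste0("kbar", 1:3), "R"),
                      rbind(ra$K, ra$level_means, ra$kbar, ra$R)),
           "range_analysis.csv")
    }
    if (!is.null(out$anova)) wcsv(out$anova$table, "variance_analysis.csv")
    if (!is.null(out$design)) wcsv(as.data.frame(out$design), "lhs_results.csv")
    if (!is.null(out$metrics)) {
      m <- out$metrics
      wcsv(data.frame(response = c("hpm", "st"),
                      re_min = c(m$hpm$re_range[1], m$st$re_range[1]),
                      re_max = c(m$hpm$re_range[2], m$st$re_range[2]),
                      rmse = c(m$hpm$rmse, m$st$rmse),
                      r2 = c(m$hpm$r2, m$st$r2)),
           "surrogate_metrics.csv")
    }
    if (!is.null(out$uncertainty)) {
      u <- out$uncertainty
      wcsv(data.frame(response = names(u),
                      lower = vapply(u, `[[`, numeric(1), "lower"),
                      upper = vapply(u, `[[`, numeric(1), "upper")),
           "uncertainty_sweep.csv")
    }
    if (!is.null(out$optima)) {
      rows <- lapply(out$optima, function(o) {
        data.frame(lambda = o$lambda,
                   hpm_lower = o$objective_interval$lower,
                   hpm_upper = o$objective_interval$upper,
                   st_lower = o$constraint_interval$lower,
                   st_upper = o$constraint_interval$upper,
                   rpdi = o$rpdi_achieved, feasible = o$feasible,
                   t(o$midpoints))
      })
      wcsv(do.call(rbind, rows), "optimization_results.csv")
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration. Recognized top-level blocks:
#' `skin_model` (a file path or an inline model block as written by
#' [write_skin_model()]), `domain` (named list of `c(lower, upper)`),
#' `grid` (arguments of [grid_spec()]), `doe` (`n`, `seed`), `interval`
#' (`radii`, `lambdas`, `b`), `solver` (`dt`, `h_conv`) and `ga`
#' (arguments of [ga_config()]). Missing blocks keep the study defaults.
#'
#' @param path Configuration file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  model <- if (is.null(cfg$skin_model)) {
    default_skin_model()
  } else if (is.character(cfg$skin_model)) {
    read_skin_model(cfg$skin_model)
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(cfg$skin_model, tmp, auto_unbox = TRUE, digits = NA)
    read_skin_model(tmp)
  }
  domain <- if (is.null(cfg$domain)) design_domain() else {
    do.call(design_domain, lapply(cfg$domain, as.numeric))
  }
  grid <- if (is.null(cfg$grid)) grid_spec() else do.call(grid_spec, cfg$grid)
  ga <- if (is.null(cfg$ga)) ga_config() else do.call(ga_config, cfg$ga)
  doe <- cfg$doe %||% list()
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; recover it
  if (is.null(doe$n) && "FALSE" %in% names(doe)) doe$n <- doe[["FALSE"]]
  itv <- cfg$interval %||% list()
  slv <- cfg$solver %||% list()
  radii_default <- c(power = 0.25, spot_radius = 0.05, duration = 0.02,
                     ambient = 1.25)
  pipeline_config(
    model = model, domain = domain, grid = grid,
    dt = slv$dt %||% 1e-3, h_conv = slv$h_conv %||% 10,
    n_lhs = doe$n %||% 50, seed = doe$seed %||% 1,
    radii = if (is.null(itv$radii)) radii_default else unlist(itv$radii),
    lambdas = itv$lambdas %||% c(0.9, 1.0, 1.1), b = itv$b %||% 52,
    ga = ga
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
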