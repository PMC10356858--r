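#' Operating-parameter design domain
#'
#' The four-dimensional box of admissible operating parameters. Defaults are
#' the study ranges: laser power 5-10 W, spot radius 1-2 mm, irradiation
#' time 0.2-0.6 s, ambient temperature 10-35 degrees C.
#'
#' @param power,spot_radius,duration,ambient Length-2 numeric `c(lower,
#'   upper)` bounds.
#' @return An object of class `design_domain`: a 2 x 4 matrix with rows
#'   `lower`, `upper`.
#' @export
design_domain <- function(power = c(5, 10), spot_radius = c(1, 2),
                          duration = c(0.2, 0.6), ambient = c(10, 35)) {
  m <- cbind(power = power, spot_radius = spot_radius,
             duration = duration, ambient = ambient)
  if (any(m[1, ] >= m[2, ])) {
    stop("each lower bound must be below its upper bound", call. = FALSE)
  }
  rownames(m) <- c("lower", "upper")
  structure(m, class = "design_domain")
}

design_factors <- function() c("power", "spot_radius", "duration", "ambient")

#' Optimal Latin hypercube design
#'
#' Maximin-distance Latin hypercube sample over the design domain: each of
#' the `n` equal-probability strata of every dimension contains exactly one
#' point, and point placement maximizes the minimum inter-point distance via
#' seeded random improvement. Deterministic for a given seed.
#'
#' @param domain A [design_domain()].
#' @param n Number of design points (`>= 2`).
#' @param seed Integer seed controlling the sample.
#' @param iters Improvement sweeps passed to the maximin search.
#' @return A `design_table`: data frame of operating parameters with
#'   attributes `kind = "lhs"` and `seed`.
#' @export
optimal_lhs <- function(domain = design_domain(), n, seed = 1, iters = 50) {
  stopifnot(inherits(domain, "design_domain"))
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  set.seed(as.integer(seed))
  u <- lhs::maximinLHS(n, ncol(domain), dup = max(1L, as.integer(iters / 10)))
  x <- sweep(sweep(u, 2, domain["upper", ] - domain["lower", ], `*`),
             2, domain["lower", ], `+`)
  colnames(x) <- colnames(domain)
  out <- as.data.frame(x)
  attr(out, "kind") <- "lhs"
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("design_table", class(out))
  out
}

# standard L9(3^4) orthogonal array, rows x factors, level indices
l9_array <- function() {
  matrix(c(1, 1, 1, 1,
           1, 2, 2, 2,
           1, 3, 3, 3,
           2, 1, 2, 3,
           2, 2, 3, 1,
           2, 3, 1, 2,
           3, 1, 3, 2,
           3, 2, 1, 3,
           3, 3, 2, 1),
         nrow = 9, ncol = 4, byrow = TRUE,
         dimnames = list(NULL, design_factors()))
}

#' L9(3^4) orthogonal design
#'
#' The standard nine-run orthogonal array for four three-level factors, with
#' the study's level assignment (factor A = laser power, B = spot radius,
#' C = irradiation time, D = ambient temperature).
#'
#' @param levels Named list of length-3 level vectors, one per factor;
#'   defaults are the study levels.
#' @return A `design_table` with 9 rows, attributes `kind = "orthogonal"`
#'   and `levels` (the 9 x 4 level-index matrix).
#' @export
orthogonal_l9 <- function(levels = list(power = c(5, 7.5, 10),
                                        spot_radius = c(1, 1.5, 2),
                                        duration = c(0.2, 0.4, 0.6),
                                        ambient = c(10, 25, 35))) {
  if (!identical(sort(names(levels)), sort(design_factors())) ||
      any(lengths(levels) != 3)) {
    stop("levels must name the four factors with exactly 3 levels each",
         call. = FALSE)
  }
  arr <- l9_array()
  out <- as.data.frame(lapply(design_factors(), function(f) {
    levels[[f]][arr[, f]]
  }))
  names(out) <- design_factors()
  attr(out, "kind") <- "orthogonal"
  attr(out, "levels") <- arr
  class(out) <- c("design_table", class(out))
  out
}

#' Run the solver over a design table
#'
#' Simulates every row of a design and appends the two indicator responses.
#'
#' @param design A `design_table` (or data frame with the four factor
#'   columns).
#' @param model A [skin_model()].
#' @param env An [environment_spec()].
#' @param spec [grid_spec()] resolution for the runs.
#' @param dt Time step (s).
#' @param quiet Suppress per-row progress.
#' @param ... Further arguments passed to [simulate_treatment()].
#' @return The design with `hpm` and `st` columns appended (a
#'   `response_table`).
#' @export
run_design <- function(design, model = default_skin_model(),
                       env = environment_spec(), spec = grid_spec(),
                       dt = 1e-3, quiet = TRUE, ...) {
  stopifnot(all(design_factors() %in% names(design)))
  hpm <- st <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    op <- operating_point(design$power[i], design$spot_radius[i],
                          design$duration[i], design$ambient[i])
    res <- simulate_treatment(model, op, env, spec = spec, dt = dt, ...)
    hpm[i] <- res$hpm; st[i] <- res$st
    if (!quiet) {
      message(sprintf("run %d/%d: hpm = %.3f, st = %.3f",
                      i, nrow(design), hpm[i], st[i]))
    }
  }
  out <- design
  out$hpm <- hpm
  out$st <- st
  class(out) <- unique(c("response_table", class(out)))
  out
}

#' Single-factor sweep
#'
#' Varies one operating parameter over `values` while the other three stay
#' at the base point, running the solver for each setting. The base point
#' defaults to the centre of the design ranges.
#'
#' @param base An [operating_point()]; the swept factor's base value is
#'   ignored.
#' @param factor One of `"power"`, `"spot_radius"`, `"duration"`,
#'   `"ambient"`.
#' @param values Numeric values for the swept factor (may be empty).
#' @param domain Optional [design_domain()]; values outside it trigger a
#'   warning but still run.
#' @param model,env,spec,dt As in [run_design()].
#' @param ... Passed on to [simulate_treatment()].
#' @return A `response_table` with one row per value; the temperature rise
#'   curves at the probe depth are attached as attribute `traces` (a list of
#'   `data.frame(time, probe, surface)`).
#' @export
single_factor_sweep <- function(base = operating_point(7.5, 1.5, 0.4, 25),
                                factor, values, domain = design_domain(),
                                model = default_skin_model(),
                                env = environment_spec(),
                                spec = grid_spec(), dt = 1e-3, ...) {
  factor <- match.arg(factor, design_factors())
  if (length(values) == 0) {
    pts <- data.frame(power = numeric(0), spot_radius = numeric(0),
                      duration = numeric(0), ambient = numeric(0),
                      hpm = numeric(0), st = numeric(0))
    class(pts) <- unique(c("response_table", class(pts)))
    return(pts)
  }
  pts <- data.frame(power = rep(base$power, length(values)),
                    spot_radius = base$spot_radius,
                    duration = base$duration, ambient = base$ambient)
  pts[[factor]] <- values
  out_of_domain <- values < domain["lower", factor] |
    values > domain["upper", factor]
  if (any(out_of_domain)) {
    warning("some sweep values fall outside the design domain", call. = FALSE)
  }
  traces <- vector("list", length(values))
  hpm <- st <- numeric(length(values))
  for (i in seq_len(nrow(pts))) {
    op <- operating_point(pts$power[i], pts$spot_radius[i],
                          pts$duration[i], pts$ambient[i])
    res <- simulate_treatment(model, op, env, spec = spec, dt = dt, ...)
    hpm[i] <- res$hpm; st[i] <- res$st
    traces[[i]] <- data.frame(time = res$times, probe = res$probe_trace,
                              surface = res$surface_trace)
  }
  pts$hpm <- hpm; pts$st <- st
  attr(pts, "traces") <- traces
  attr(pts, "factor") <- factor
  class(pts) <- unique(c("response_table", class(pts)))
  pts
}

check_l9_responses <- function(responses, response) {
  stopifnot(is.data.frame(responses),
            all(design_factors() %in% names(responses)))
  if (nrow(responses) != 9) {
    stop("range/variance analysis requires the 9-run orthogonal design",
         call. = FALSE)
  }
  if (!response %in% names(responses)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  y <- responses[[response]]
  if (!all(is.finite(y))) stop("responses must be finite", call. = FALSE)
  lev <- vapply(design_factors(), function(f) {
    v <- responses[[f]]
    u <- sort(unique(v))
    if (length(u) != 3 || !all(table(match(v, u)) == 3)) {
      stop("factor '", f, "' must take 3 levels, 3 runs each", call. = FALSE)
    }
    match(v, u)
  }, integer(9))
  list(y = y, levels = lev)
}

#' Range analysis of an orthogonal experiment
#'
#' Classic Taguchi R-method on a nine-run three-level orthogonal experiment:
#' per factor, the level sums `K`, the level means `K/3`, the printed-table
#' convention `Kbar = K / 9`, and the range `R` (max minus min level mean).
#' Factors are ranked by `R` descending (ties broken by factor order) and
#' the optimal combination takes the level with the largest mean response
#' for every factor.
#'
#' @param responses A `response_table` from the L9 design.
#' @param response Response column to analyse (default `"hpm"`).
#' @return An object of class `range_analysis`: matrices `K`, `level_means`,
#'   `kbar` (3 x 4), vector `R`, `ranking` (factor names, most influential
#'   first), `optimal_levels` (indices) and `optimal_labels` (e.g. `"A3"`).
#' @export
range_analysis <- function(responses, response = "hpm") {
  chk <- check_l9_responses(responses, response)
  y <- chk$y; lev <- chk$levels
  K <- vapply(design_factors(), function(f) {
    vapply(1:3, function(l) sum(y[lev[, f] == l]), numeric(1))
  }, numeric(3))
  level_means <- K / 3
  R <- apply(level_means, 2, function(v) max(v) - min(v))
  ranking <- design_factors()[order(-R)]
  optimal_levels <- apply(level_means, 2, which.max)
  labels <- paste0(c(power = "A", spot_radius = "B", duration = "C",
                     ambient = "D")[design_factors()], optimal_levels)
  structure(
    list(response = response, K = K, level_means = level_means,
         kbar = K / 9, R = R, ranking = ranking,
         optimal_levels = optimal_levels, optimal_labels = labels),
    class = "range_analysis"
  )
}

#' @export
print.range_analysis <- function(x, ...) {
  cat("Range analysis of the L9 orthogonal experiment (response:",
      x$response, ")\n")
  tab <- rbind(x$K, x$level_means, x$R)
  rownames(tab) <- c(paste0("K", 1:3), paste0("mean", 1:3), "R")
  print(round(tab, 3))
  cat("factor ranking (most influential first):",
      paste(x$ranking, collapse = " > "), "\n")
  cat("optimal combination:", paste(x$optimal_labels, collapse = " "), "\n")
  invisible(x)
}

#' Variance analysis of an orthogonal experiment
#'
#' Fixed-effects ANOVA decomposition of a saturated L9(3^4) experiment:
#' per-factor sum of squares `SS = 3 * sum((level mean - grand mean)^2)`
#' with 2 degrees of freedom. A saturated design leaves no error degrees of
#' freedom, so the error term is formed by pooling (default: the factor with
#' the smallest SS); with `pooling = "none"` only the SS decomposition is
#' reported and F ratios are undefined.
#'
#' @param responses A `response_table` from the L9 design.
#' @param response Response column (default `"hpm"`).
#' @param pooling `"smallest"` (pool the smallest-SS factor as error) or
#'   `"none"`.
#' @return An object of class `anova_l9` with the SS table, pooled error,
#'   F ratios, p values and significance stars.
#' @export
variance_analysis <- function(responses, response = "hpm",
                              pooling = c("smallest", "none")) {
  pooling <- match.arg(pooling)
  chk <- check_l9_responses(responses, response)
  y <- chk$y; lev <- chk$levels
  gm <- mean(y)
  ss <- vapply(design_factors(), function(f) {
    lm <- vapply(1:3, function(l) mean(y[lev[, f] == l]), numeric(1))
    3 * sum((lm - gm)^2)
  }, numeric(1))
  ss_total <- sum((y - gm)^2)
  df <- rep(2, 4); names(df) <- design_factors()
  if (pooling == "none") {
    tab <- data.frame(factor = design_factors(), ss = ss, df = df,
                      ms = ss / df, F = NA_real_, p = NA_real_,
                      stars = "", row.names = NULL)
    return(structure(list(response = response, table = tab,
                          ss_total = ss_total, pooled = character(0),
                          note = "saturated design: F undefined without pooling"),
                     class = "anova_l9"))
  }
  pooled <- design_factors()[which.min(ss)]
  err_ss <- ss[pooled]; err_df <- 2
  keep <- setdiff(design_factors(), pooled)
  ms_err <- err_ss / err_df
  fval <- (ss[keep] / 2) / ms_err
  pval <- stats::pf(fval, 2, err_df, lower.tail = FALSE)
  stars <- cut(pval, c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
               labels = c("***", "**", "*", ".", ""))
  tab <- data.frame(factor = design_factors(), ss = ss, df = df,
                    ms = ss / df,
                    F = ifelse(design_factors() %in% keep,
                               fval[match(design_factors(), keep)], NA),
                    p = ifelse(design_factors() %in% keep,
                               pval[match(design_factors(), keep)], NA),
                    stars = ifelse(design_factors() %in% keep,
                                   as.character(stars[match(design_factors(),
                                                            keep)]), "error"),
                    row.names = NULL)
  structure(list(response = response, table = tab, ss_total = ss_total,
                 pooled = pooled, note = NULL),
            class = "anova_l9")
}

#' @export
print.anova_l9 <- function(x, ...) {
  cat("Variance analysis of the L9 orthogonal experiment (response:",
      x$response, ")\n")
  tab <- x$table
  tab$ss <- round(tab$ss, 3); tab$ms <- round(tab$ms, 3)
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (length(x$pooled)) cat("error term: pooled factor", x$pooled, "\n")
  if (!is.null(x$note)) cat(x$note, "\n")
  invisible(x)
}
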