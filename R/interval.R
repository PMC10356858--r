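# Interval-uncertainty representation and the reliability-based
# possibility degree of interval (RPDI), plus the nested optimizer:
# an outer real-coded genetic algorithm over interval midpoints and an
# inner bound search (multi-start local optimization with vertex seeds)
# that turns each candidate uncertainty box into response intervals.

#' Closed interval
#'
#' An uncertain scalar represented by its bounds, equivalently by midpoint
#' and radius.
#'
#' @param lower,upper Interval endpoints, `lower <= upper`.
#' @return An object of class `interval`.
#' @export
interval <- function(lower, upper) {
  stopifnot(is.finite(lower), is.finite(upper))
  if (lower > upper) stop("lower must not exceed upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "interval")
}

#' @rdname interval
#' @param center,radius Midpoint and (non-negative) radius.
#' @export
interval_from_center <- function(center, radius) {
  if (radius < 0) stop("radius must be non-negative", call. = FALSE)
  interval(center - radius, center + radius)
}

#' @rdname interval
#' @param x An `interval`.
#' @export
interval_mid <- function(x) (x$lower + x$upper) / 2

#' @rdname interval
#' @export
interval_radius <- function(x) (x$upper - x$lower) / 2

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("[%.6g, %.6g]  (mid %.6g, radius %.6g)\n",
              x$lower, x$upper, interval_mid(x), interval_radius(x)))
  invisible(x)
}

#' Reliability-based possibility degree of interval (RPDI)
#'
#' The degree to which interval `A` lies below interval `B`:
#' `p = (B_upper - A_lower) / (2 rad(A) + 2 rad(B))`, unbounded in
#' `(-Inf, Inf)`. Values `>= 1` mean `A` lies entirely at or below `B`'s
#' lower end; the complement identity `p(A <= B) = 1 - p(B <= A)` holds.
#' When both intervals are degenerate scalars the convention is 1 if
#' `A < B`, 0 if `A > B` and 0.5 on equality.
#'
#' @param a,b `interval` objects.
#' @return Scalar possibility degree.
#' @export
rpdi <- function(a, b) {
  stopifnot(inherits(a, "interval"), inherits(b, "interval"))
  denom <- 2 * interval_radius(a) + 2 * interval_radius(b)
  if (denom == 0) {
    am <- interval_mid(a); bm <- interval_mid(b)
    return(if (am < bm) 1 else if (am > bm) 0 else 0.5)
  }
  (b$upper - a$lower) / denom
}

#' RPDI of an interval against a scalar threshold
#'
#' Degenerate form used by the deterministic constraint transformation:
#' `p = (b - A_lower) / (2 rad(A))`. A zero-radius `A` returns `Inf` when
#' it satisfies the threshold and `-Inf` otherwise.
#'
#' @param a An `interval`.
#' @param b Scalar threshold.
#' @return Scalar possibility degree.
#' @export
rpdi_scalar <- function(a, b) {
  stopifnot(inherits(a, "interval"), is.finite(b))
  w <- interval_radius(a)
  if (w == 0) return(if (a$lower <= b) Inf else -Inf)
  (b - a$lower) / (2 * w)
}

#' Interval-valued design box
#'
#' A four-dimensional uncertainty box: one interval per operating
#' parameter, given by midpoints and fixed radii, constrained to lie inside
#' the design domain (`lower + radius <= mid <= upper - radius`).
#'
#' @param midpoints Named numeric vector of interval midpoints (factors
#'   `power`, `spot_radius`, `duration`, `ambient`).
#' @param radii Named numeric vector of non-negative interval radii.
#' @param domain A [design_domain()].
#' @return An object of class `design_box` with `lower`/`upper` vectors.
#' @export
design_box <- function(midpoints, radii, domain = design_domain()) {
  f <- design_factors()
  if (is.null(names(midpoints))) names(midpoints) <- f
  if (is.null(names(radii))) names(radii) <- f
  midpoints <- midpoints[f]; radii <- radii[f]
  stopifnot(all(is.finite(midpoints)), all(is.finite(radii)),
            all(radii >= 0))
  lo <- midpoints - radii; hi <- midpoints + radii
  if (any(lo < domain["lower", ] - 1e-9) ||
      any(hi > domain["upper", ] + 1e-9)) {
    stop("interval box extends outside the design domain", call. = FALSE)
  }
  structure(list(midpoints = midpoints, radii = radii,
                 lower = lo, upper = hi, domain = domain),
            class = "design_box")
}

# evaluate a response for any surrogate-like model:
# an rbf_surrogate, or a function(X) returning a matrix/vector
eval_responses <- function(model, x, response = NULL) {
  x <- as.matrix(x)
  y <- if (inherits(model, "rbf_surrogate")) {
    suppressWarnings(predict(model, x))
  } else if (is.function(model)) {
    model(x)
  } else {
    stop("model must be an rbf_surrogate or a function", call. = FALSE)
  }
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(x))
  if (!is.null(response)) {
    if (!is.null(colnames(y)) && response %in% colnames(y)) {
      y <- y[, response, drop = FALSE]
    } else {
      y <- y[, 1, drop = FALSE]
    }
  }
  y
}

# tensor grid of n points per dimension over [lower, upper]
box_grid <- function(lower, upper, n) {
  grids <- lapply(seq_along(lower), function(j) {
    if (upper[j] > lower[j]) seq(lower[j], upper[j], length.out = n)
    else lower[j]
  })
  as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
}

#' Response interval over an uncertainty box
#'
#' Inner bound search: the minimum and maximum of a (surrogate) response
#' over a 4-D interval box. `"multistart"` (default) polishes vertex,
#' centre and coarse-grid seeds with bound-constrained quasi-Newton local
#' optimization and returns the best certified bounds; `"grid"` uses a
#' dense tensor grid only (the robustness fallback). Deterministic.
#'
#' @param model An `rbf_surrogate` or a function of the design matrix.
#' @param box A [design_box()].
#' @param response Response name (e.g. `"st"` or `"hpm"`).
#' @param method `"multistart"` or `"grid"`.
#' @param n_grid Grid resolution per dimension for seeding (multistart) or
#'   for the dense fallback.
#' @return An `interval`, with attributes `argmin` and `argmax`.
#' @export
response_interval <- function(model, box, response,
                              method = c("multistart", "grid"),
                              n_grid = 5) {
  stopifnot(inherits(box, "design_box"))
  method <- match.arg(method)
  lo <- box$lower; hi <- box$upper
  if (all(hi - lo <= 0)) {
    y <- eval_responses(model, matrix(lo, nrow = 1), response)[1]
    out <- interval(y, y)
    attr(out, "argmin") <- attr(out, "argmax") <- lo
    return(out)
  }
  seeds <- unique(rbind(box_grid(lo, hi, 3),            # vertices + centre + edges
                        if (method == "grid") box_grid(lo, hi, max(n_grid, 9))))
  yv <- eval_responses(model, seeds, response)[, 1]
  best_min <- seeds[which.min(yv), ]; fmin <- min(yv)
  best_max <- seeds[which.max(yv), ]; fmax <- max(yv)

  if (method == "multistart") {
    f1 <- function(p) eval_responses(model, matrix(p, nrow = 1), response)[1]
    free <- hi > lo
    polish <- function(start, sign) {
      res <- tryCatch(
        stats::optim(start, function(p) sign * f1(p), method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(factr = 1e4, maxit = 200)),
        error = function(e) NULL)
      if (is.null(res)) NULL else list(par = res$par, value = sign * res$value)
    }
    starts <- unique(rbind(box_grid(lo, hi, 2), (lo + hi) / 2,
                           best_min, best_max))
    for (s in seq_len(nrow(starts))) {
      r <- polish(starts[s, ], 1)
      if (!is.null(r) && r$value < fmin) { fmin <- r$value; best_min <- r$par }
      r <- polish(starts[s, ], -1)
      if (!is.null(r) && r$value > fmax) { fmax <- r$value; best_max <- r$par }
    }
    if (!is.finite(fmin) || !is.finite(fmax)) {
      warning("local bound search failed; falling back to a dense grid",
              call. = FALSE)
      g <- box_grid(lo, hi, 11)
      yv <- eval_responses(model, g, response)[, 1]
      fmin <- min(yv); fmax <- max(yv)
      best_min <- g[which.min(yv), ]; best_max <- g[which.max(yv), ]
    }
  }
  out <- interval(fmin, fmax)
  attr(out, "argmin") <- best_min
  attr(out, "argmax") <- best_max
  out
}

#' Response ranges over the whole design domain
#'
#' The uncertainty sweep: response intervals with the box equal to the full
#' design domain, showing how far each indicator can stray when the
#' operating parameters roam their entire ranges.
#'
#' @param model An `rbf_surrogate` (or compatible function).
#' @param domain A [design_domain()].
#' @param responses Response names to sweep.
#' @return Named list of `interval`s.
#' @export
uncertainty_sweep <- function(model, domain = design_domain(),
                              responses = c("hpm", "st")) {
  mid <- (domain["lower", ] + domain["upper", ]) / 2
  rad <- (domain["upper", ] - domain["lower", ]) / 2
  box <- design_box(mid, rad, domain)
  out <- lapply(responses, function(rr) {
    response_interval(model, box, rr, method = "multistart", n_grid = 7)
  })
  names(out) <- responses
  out
}

#' Interval optimization problem
#'
#' The RPDI-transformed deterministic program: maximize the thermal
#' penetration interval (its midpoint by default) over interval midpoints,
#' with radii fixed at the stated operating uncertainties, subject to the
#' surface-temperature constraint holding with possibility degree at least
#' `lambda` against the damage threshold `b`.
#'
#' @param objective Response maximized (default `"hpm"`).
#' @param constraint Response constrained (default `"st"`).
#' @param b Constraint threshold in degrees C (default 52, the tissue
#'   damage threshold).
#' @param lambda Required RPDI level; `lambda >= 1` forces the whole
#'   constraint interval below `b`.
#' @param radii Named vector of fixed interval radii; defaults are the
#'   stated operating uncertainties (0.25 W, 0.05 mm, 0.02 s, 1.25 C).
#' @param domain A [design_domain()].
#' @param objective_disposition `"midpoint"` (default) or `"lower_bound"`
#'   (clinically conservative) scalarization of the objective interval.
#' @return An object of class `interval_problem`.
#' @export
interval_problem <- function(objective = "hpm", constraint = "st", b = 52,
                             lambda = 1,
                             radii = c(power = 0.25, spot_radius = 0.05,
                                       duration = 0.02, ambient = 1.25),
                             domain = design_domain(),
                             objective_disposition = c("midpoint",
                                                       "lower_bound")) {
  stopifnot(is.finite(lambda), b > 0, all(radii[design_factors()] >= 0))
  structure(
    list(objective = objective, constraint = constraint, b = b,
         lambda = lambda, radii = radii[design_factors()], domain = domain,
         objective_disposition = match.arg(objective_disposition)),
    class = "interval_problem"
  )
}

#' Genetic-algorithm settings for the outer optimizer
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param tournament Tournament size for parent selection.
#' @param crossover_eta SBX (simulated binary crossover) distribution index.
#' @param mutation_eta Polynomial-mutation distribution index.
#' @param mutation_rate Per-gene mutation probability; `NULL` means `1/d`.
#' @param penalty Penalty weight on RPDI constraint violation.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 60, generations = 100, tournament = 2,
                      crossover_eta = 15, mutation_eta = 20,
                      mutation_rate = NULL, penalty = 1e3) {
  stopifnot(pop_size >= 4, generations >= 1)
  structure(list(pop_size = pop_size, generations = generations,
                 tournament = tournament, crossover_eta = crossover_eta,
                 mutation_eta = mutation_eta, mutation_rate = mutation_rate,
                 penalty = penalty),
            class = "ga_config")
}

# SBX crossover of two parents within [lo, hi]
sbx_cross <- function(p1, p2, eta, lo, hi) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

# polynomial mutation in place
poly_mutate <- function(p, rate, eta, lo, hi) {
  m <- stats::runif(length(p)) < rate
  if (!any(m)) return(p)
  u <- stats::runif(sum(m))
  span <- (hi - lo)[m]
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  p[m] <- pmin(pmax(p[m] + delta * span, lo[m]), hi[m])
  p
}

#' Nested interval-uncertainty optimization
#'
#' Solves the RPDI-transformed program: the outer genetic algorithm
#' searches interval midpoints inside the radius-shrunk design domain; for
#' every candidate the inner bound search turns the uncertainty box into
#' objective and constraint intervals; the fitness is the objective
#' disposition penalized by any shortfall of the constraint RPDI below
#' `lambda`. During the GA the inner bounds use a fast tensor-grid
#' evaluation (the response surface is smooth and the boxes are small);
#' the returned optimum is re-certified with the multi-start local bound
#' search, and if the refined bounds violate the constraint the best
#' refined-feasible candidate of the final population is returned instead.
#'
#' @param problem An [interval_problem()].
#' @param model An `rbf_surrogate` (or a function of the design matrix
#'   returning columns named after the responses).
#' @param ga A [ga_config()].
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return An object of class `interval_opt_result`: optimal midpoints, the
#'   objective and constraint intervals (refined), the achieved RPDI,
#'   feasibility flag, and GA diagnostics (`history` of best penalized
#'   fitness per generation, evaluation count, seed).
#' @export
optimize_treatment <- function(problem, model, ga = ga_config(), seed = 1) {
  stopifnot(inherits(problem, "interval_problem"), inherits(ga, "ga_config"))
  set.seed(as.integer(seed))
  f <- design_factors()
  rad <- problem$radii
  lo <- problem$domain["lower", ] + rad
  hi <- problem$domain["upper", ] - rad
  if (any(lo > hi)) {
    stop("interval radii exceed the design ranges", call. = FALSE)
  }
  d <- length(f)
  mrate <- if (is.null(ga$mutation_rate)) 1 / d else ga$mutation_rate
  # fixed offsets of the fast inner evaluation: 3 levels per dimension
  offsets <- as.matrix(expand.grid(lapply(seq_len(d), function(j) {
    if (rad[j] > 0) c(-rad[j], 0, rad[j]) else 0
  })))
  dispose <- function(int) {
    if (problem$objective_disposition == "midpoint") interval_mid(int)
    else int$lower
  }
  evals <- 0L
  fitness <- function(mid) {
    pts <- sweep(offsets, 2, mid, `+`)
    y <- eval_responses(model, pts)
    evals <<- evals + nrow(pts)
    obj_col <- if (!is.null(colnames(y)) && problem$objective %in% colnames(y))
      y[, problem$objective] else y[, 1]
    con_col <- if (!is.null(colnames(y)) && problem$constraint %in% colnames(y))
      y[, problem$constraint] else y[, min(2, ncol(y))]
    obj_int <- interval(min(obj_col), max(obj_col))
    con_int <- interval(min(con_col), max(con_col))
    p <- rpdi_scalar(con_int, problem$b)
    list(fit = dispose(obj_int) -
           ga$penalty * max(0, problem$lambda - min(p, problem$lambda)),
         obj = obj_int, con = con_int, p = p)
  }

  pop <- t(replicate(ga$pop_size, lo + stats::runif(d) * (hi - lo)))
  evalpop <- function(P) lapply(seq_len(nrow(P)), function(i) fitness(P[i, ]))
  ev <- evalpop(pop)
  fit <- vapply(ev, `[[`, numeric(1), "fit")
  history <- numeric(ga$generations)
  for (g in seq_len(ga$generations)) {
    pick <- function() {
      cand <- sample.int(ga$pop_size, ga$tournament)
      cand[which.max(fit[cand])]
    }
    children <- matrix(0, ga$pop_size, d)
    i <- 1L
    while (i <= ga$pop_size) {
      pr <- sbx_cross(pop[pick(), ], pop[pick(), ], ga$crossover_eta, lo, hi)
      children[i, ] <- poly_mutate(pr[[1]], mrate, ga$mutation_eta, lo, hi)
      if (i + 1L <= ga$pop_size) {
        children[i + 1L, ] <- poly_mutate(pr[[2]], mrate, ga$mutation_eta,
                                          lo, hi)
      }
      i <- i + 2L
    }
    ev_c <- evalpop(children)
    fit_c <- vapply(ev_c, `[[`, numeric(1), "fit")
    # elitist merge: keep the best pop_size of parents + children
    allfit <- c(fit, fit_c)
    keep <- order(-allfit)[seq_len(ga$pop_size)]
    allpop <- rbind(pop, children)
    allev <- c(ev, ev_c)
    pop <- allpop[keep, , drop = FALSE]
    ev <- allev[keep]
    fit <- allfit[keep]
    history[g] <- fit[1]
  }

  # refined certification of the best candidates
  refine <- function(mid) {
    box <- design_box(stats::setNames(mid, f), rad, problem$domain)
    obj <- response_interval(model, box, problem$objective)
    con <- response_interval(model, box, problem$constraint)
    list(obj = obj, con = con, p = rpdi_scalar(con, problem$b))
  }
  ord <- order(-fit)
  chosen <- NULL
  for (i in ord[seq_len(min(10, length(ord)))]) {
    cand <- refine(pop[i, ])
    if (cand$p >= problem$lambda - 1e-9) { chosen <- list(mid = pop[i, ], r = cand); break }
    if (is.null(chosen)) chosen <- list(mid = pop[i, ], r = cand)  # best violator
  }
  feasible <- chosen$r$p >= problem$lambda - 1e-9
  if (!feasible) {
    warning("no candidate satisfies the RPDI level after refinement; ",
            "returning the least-violating one", call. = FALSE)
  }
  structure(
    list(midpoints = stats::setNames(chosen$mid, f),
         objective_interval = chosen$r$obj,
         constraint_interval = chosen$r$con,
         rpdi_achieved = chosen$r$p, feasible = feasible,
         lambda = problem$lambda, b = problem$b,
         objective = problem$objective, constraint = problem$constraint,
         history = history, evaluations = evals, seed = as.integer(seed)),
    class = "interval_opt_result"
  )
}

#' @export
print.interval_opt_result <- function(x, ...) {
  cat(sprintf("Interval optimization at lambda = %g (threshold b = %g C)\n",
              x$lambda, x$b))
  cat("  midpoints: ",
      paste(sprintf("%s = %.4g", names(x$midpoints), x$midpoints),
            collapse = ", "), "\n")
  cat(sprintf("  %s interval: [%.3f, %.3f]\n", x$objective,
              x$objective_interval$lower, x$objective_interval$upper))
  cat(sprintf("  %s interval: [%.3f, %.3f]  (RPDI %.3f, %s)\n", x$constraint,
              x$constraint_interval$lower, x$constraint_interval$upper,
              x$rpdi_achieved,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}
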