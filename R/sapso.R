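#' Swarm configuration
#'
#' Settings for the hybrid simulated-annealing/particle-swarm optimizer and
#' the plain-PSO baseline. Defaults follow the model's standard settings:
#' 20 particles, 200 iterations, a 4-dimensional search space over the mix
#' weight \eqn{\lambda \in [0, 1]}, box constraint \eqn{C \in [2^{-9}, 2^9]},
#' sigmoid regulation \eqn{a \in [2^{-7}, 2^7]} and displacement
#' \eqn{r \in [-3, 3]}, acceleration factors \eqn{c_1 = 1.5},
#' \eqn{c_2 = 1.7}, and per-component velocity clamps of \eqn{\pm 0.6}
#' times the upper range bound. The constriction factor defaults to the
#' canonical 0.729 (no value is prescribed by the method itself, and the
#' closed-form constriction formula is undefined at \eqn{c_1 + c_2 = 3.2}).
#'
#' @param n_particles swarm size (at least 2).
#' @param max_iters iteration budget.
#' @param ranges D x 2 matrix of per-component position bounds (rows named
#'   for the default space `lambda`, `C`, `a`, `r`).
#' @param c1,c2 acceleration factors toward the personal and global best.
#' @param phi constriction factor multiplying the previous velocity.
#' @param v_scale velocity clamp as a fraction of the upper range bound;
#'   clamps are symmetric (`+/- v_scale * max(|upper|, |lower|)`).
#' @param cooling_rate geometric cooling rate in \eqn{[0, 1]}.
#' @param gbest_mode `"roulette"` (one Boltzmann-roulette draw per iteration
#'   selects the surrogate global attractor G_plus among personal bests) or
#'   `"greedy"` (the plain global best attracts).
#' @param inertia two-vector; the plain-PSO inertia weight decays linearly
#'   from the first to the second value over the run.
#' @param log2_components indices of components searched on a log2 scale
#'   (positions are transformed before the objective sees them); empty by
#'   default (raw scale, as the printed ranges).
#' @param seed optional RNG seed fixed at the start of a run.
#' @return an object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 20L, max_iters = 200L,
                         ranges = default_ranges(),
                         c1 = 1.5, c2 = 1.7, phi = 0.729, v_scale = 0.6,
                         cooling_rate = 0.95,
                         gbest_mode = c("roulette", "greedy"),
                         inertia = c(0.9, 0.4),
                         log2_components = integer(0),
                         seed = NULL) {
  gbest_mode <- match.arg(gbest_mode)
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2L || any(ranges[, 1L] >= ranges[, 2L]))
    stop("'ranges' must be a D x 2 matrix with lower < upper")
  if (n_particles < 2L) stop("'n_particles' must be at least 2")
  if (c1 < 0 || c2 < 0) stop("acceleration factors must be nonnegative")
  if (cooling_rate < 0 || cooling_rate > 1)
    stop("'cooling_rate' must lie in [0, 1]")
  vmax <- v_scale * pmax(abs(ranges[, 2L]), abs(ranges[, 1L]))
  structure(
    list(n_particles = as.integer(n_particles),
         max_iters = as.integer(max_iters),
         dim = nrow(ranges), ranges = ranges, vmax = vmax,
         c1 = c1, c2 = c2, phi = phi, cooling_rate = cooling_rate,
         gbest_mode = gbest_mode, inertia = inertia,
         log2_components = as.integer(log2_components), seed = seed),
    class = "swarm_config")
}

#' Default hyperparameter search box
#'
#' @return 4 x 2 matrix of bounds for (lambda, C, a, r).
#' @export
default_ranges <- function() {
  m <- rbind(lambda = c(0, 1), C = c(2^-9, 2^9), a = c(2^-7, 2^7),
             r = c(-3, 3))
  colnames(m) <- c("lower", "upper")
  m
}

#' Initialize a swarm
#'
#' Positions are drawn uniformly inside the per-component ranges and
#' velocities uniformly inside the clamp bounds; personal bests start at the
#' initial positions (fitness unset until evaluated).
#'
#' @param config a [swarm_config()].
#' @return a list with matrices `position`, `velocity`, `pbest_position`
#'   (`n_particles` x D) and vector `pbest_fitness` (all `NA` until
#'   evaluation).
#' @export
init_swarm <- function(config) {
  n <- config$n_particles; D <- config$dim
  lo <- config$ranges[, 1L]; hi <- config$ranges[, 2L]
  pos <- matrix(runif(n * D), n, D, byrow = TRUE)
  pos <- sweep(sweep(pos, 2L, hi - lo, "*"), 2L, lo, "+")
  vel <- matrix(runif(n * D, -1, 1), n, D, byrow = TRUE)
  vel <- sweep(vel, 2L, config$vmax, "*")
  colnames(pos) <- colnames(vel) <- rownames(config$ranges)
  list(position = pos, velocity = vel,
       pbest_position = pos, pbest_fitness = rep(NA_real_, n))
}

#' Initial annealing temperature
#'
#' \eqn{T_0 = f_{Gbest} / \ln 5} from the fitness of the initial global
#' best.
#'
#' @param f_gbest nonnegative fitness of the global best.
#' @return temperature.
#' @export
init_temperature <- function(f_gbest) {
  if (!is.finite(f_gbest) || f_gbest < 0)
    stop("initial temperature requires a nonnegative fitness, got ",
         format(f_gbest))
  f_gbest / log(5)
}

#' Boltzmann selection weights over personal-best fitnesses
#'
#' \deqn{w_i = \frac{e^{-(P(i) - f_{Gbest})/T}}{\sum_j e^{-(P(j) - f_{Gbest})/T}}}
#' At the current temperature the weights favour particles whose personal
#' best lags the global best (the exponent is positive for them), which is
#' what lets the roulette pick a diversifying surrogate attractor; as
#' \eqn{T \to 0^+} all mass concentrates on the smallest personal-best
#' fitness. Computed with a stabilized softmax so cooled temperatures cannot
#' overflow.
#'
#' @param pbest_fitnesses personal-best fitness vector.
#' @param f_gbest the global-best fitness (the maximum of the personal
#'   bests).
#' @param T temperature, positive.
#' @return probability vector summing to 1.
#' @export
boltzmann_weights <- function(pbest_fitnesses, f_gbest, T) {
  if (!is.finite(T) || T <= 0) stop("temperature must be > 0, got ", format(T))
  e <- (f_gbest - pbest_fitnesses) / T
  e <- e - max(e)
  w <- exp(e)
  w / sum(w)
}

#' Roulette (fitness-proportionate) selection
#'
#' Returns the smallest index whose cumulative weight reaches the uniform
#' draw `u`.
#'
#' @param weights probability vector summing to 1.
#' @param u a uniform draw in \[0, 1).
#' @return 1-based selected index.
#' @export
roulette_select <- function(weights, u = runif(1)) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("roulette weights must sum to 1 (got ", format(sum(weights)), ")")
  if (u < 0 || u >= 1) stop("'u' must lie in [0, 1)")
  cw <- cumsum(weights)
  which(cw >= u)[1L]
}

#' Single particle velocity/position update
#'
#' \deqn{V \leftarrow \varphi V + c_1 r_1 (P_{best} - X) + c_2 r_2 (G_{plus} - X)}
#' followed by componentwise velocity clamping, \eqn{X \leftarrow X + V},
#' and clipping of the position to the search box. `r1`, `r2` are fresh
#' uniform \[0, 1\] scalars per update (drawn internally when `NULL`).
#'
#' @param position,velocity,pbest current particle state (D-vectors).
#' @param g_attr global attractor position (G_plus or G_best).
#' @param config a [swarm_config()].
#' @param inertia multiplier on the previous velocity (defaults to
#'   `config$phi`; the PSO baseline passes its inertia weight).
#' @param r1,r2 optional fixed uniforms, for deterministic testing.
#' @return list with updated `position` and `velocity`.
#' @export
update_particle <- function(position, velocity, pbest, g_attr, config,
                            inertia = config$phi, r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- runif(1)
  if (is.null(r2)) r2 <- runif(1)
  v <- inertia * velocity + config$c1 * r1 * (pbest - position) +
    config$c2 * r2 * (g_attr - position)
  v <- pmin(pmax(v, -config$vmax), config$vmax)
  x <- position + v
  x <- pmin(pmax(x, config$ranges[, 1L]), config$ranges[, 2L])
  list(position = x, velocity = v)
}

#' Geometric cooling step
#'
#' \eqn{T' = \mathrm{rate} \cdot T}; after k applications the temperature is
#' exactly \eqn{T_0 \cdot \mathrm{rate}^k}.
#'
#' @param T current temperature, nonnegative.
#' @param rate cooling rate in \eqn{[0, 1]}.
#' @return cooled temperature.
#' @export
cool <- function(T, rate) {
  if (!is.finite(T) || T < 0) stop("temperature must be nonnegative")
  if (!is.finite(rate) || rate < 0 || rate > 1)
    stop("cooling rate must lie in [0, 1], got ", format(rate))
  rate * T
}

as_objective <- function(ev) {
  if (inherits(ev, "fitness_evaluator")) {
    function(position) evaluate_fitness(position, ev)
  } else if (is.function(ev)) {
    ev
  } else stop("objective must be a function or a fitness_evaluator")
}

position_for_objective <- function(x, config) {
  if (length(config$log2_components)) {
    x[config$log2_components] <- 2^x[config$log2_components]
  }
  x
}

#' Hybrid simulated-annealing particle-swarm search
#'
#' Maximizes a fitness over the search box: initialize the swarm, evaluate
#' all particles, set the global best and the initial temperature
#' \eqn{T_0 = f_{Gbest}/\ln 5}; then per iteration compute Boltzmann weights
#' over the personal-best fitnesses, roulette-select the surrogate global
#' attractor G_plus, update every particle's velocity and position
#' (constriction \eqn{\varphi}, clamped, clipped), re-evaluate, accept only
#' improvements into the personal/global bests, and cool geometrically.
#' The best-fitness history is monotone non-decreasing, and a fixed
#' `config$seed` makes the whole run reproducible.
#'
#' @param objective a `function(position) -> fitness` to maximize, or a
#'   [fitness_evaluator()].
#' @param config a [swarm_config()].
#' @return an object of class `swarm_result`: `best_position`,
#'   `best_fitness`, `history` (data frame: iteration, best_fitness,
#'   temperature, one column per position component), `method`, `config`.
#' @examples
#' cfg <- swarm_config(n_particles = 10, max_iters = 40,
#'                     ranges = cbind(c(-5, -5), c(5, 5)), seed = 1)
#' res <- run_sapso(objective_sphere(c(1, 2)), cfg)
#' res$best_position
#' @export
run_sapso <- function(objective, config = swarm_config()) {
  objective <- as_objective(objective)
  if (!is.null(config$seed)) set.seed(config$seed)
  sw <- init_swarm(config)
  fit <- apply(sw$position, 1L, function(p)
    objective(position_for_objective(p, config)))
  sw$pbest_fitness <- fit
  gi <- which.max(fit)
  gbest_pos <- sw$position[gi, ]
  gbest_fit <- fit[gi]
  T <- init_temperature(gbest_fit)
  hist <- make_history(config, gbest_fit, T, gbest_pos)

  for (it in seq_len(config$max_iters)) {
    g_attr <- if (config$gbest_mode == "roulette") {
      # Metropolis weights on the energy scale (energy = -fitness): near
      # uniform while hot (diversified attractor), concentrating on the
      # best personal best as the system cools
      w <- boltzmann_weights(-sw$pbest_fitness, -gbest_fit,
                             max(T, .Machine$double.eps))
      sw$pbest_position[roulette_select(w, runif(1)), ]
    } else gbest_pos
    for (i in seq_len(config$n_particles)) {
      up <- update_particle(sw$position[i, ], sw$velocity[i, ],
                            sw$pbest_position[i, ], g_attr, config)
      sw$position[i, ] <- up$position
      sw$velocity[i, ] <- up$velocity
    }
    fit <- apply(sw$position, 1L, function(p)
      objective(position_for_objective(p, config)))
    better <- fit > sw$pbest_fitness
    sw$pbest_position[better, ] <- sw$position[better, , drop = FALSE]
    sw$pbest_fitness[better] <- fit[better]
    gi <- which.max(sw$pbest_fitness)
    if (sw$pbest_fitness[gi] > gbest_fit) {
      gbest_fit <- sw$pbest_fitness[gi]
      gbest_pos <- sw$pbest_position[gi, ]
    }
    T <- cool(T, config$cooling_rate)
    hist <- rbind(hist, make_history(config, gbest_fit, T, gbest_pos, it))
  }
  swarm_result(position_for_objective(gbest_pos, config), gbest_fit, hist,
               "sapso", config)
}

#' Plain particle-swarm baseline
#'
#' Classical PSO with a linearly decaying inertia weight and greedy global
#' best; velocity clamping and box clipping as in [run_sapso()]. Serves as
#' the ablation baseline for the hybrid optimizer.
#'
#' @inheritParams run_sapso
#' @return a `swarm_result` (the temperature column of the history is `NA`).
#' @export
run_pso <- function(objective, config = swarm_config()) {
  objective <- as_objective(objective)
  if (!is.null(config$seed)) set.seed(config$seed)
  sw <- init_swarm(config)
  fit <- apply(sw$position, 1L, function(p)
    objective(position_for_objective(p, config)))
  sw$pbest_fitness <- fit
  gi <- which.max(fit)
  gbest_pos <- sw$position[gi, ]
  gbest_fit <- fit[gi]
  hist <- make_history(config, gbest_fit, NA_real_, gbest_pos)

  for (it in seq_len(config$max_iters)) {
    frac <- if (config$max_iters > 1L) (it - 1) / (config$max_iters - 1) else 0
    w_it <- config$inertia[1L] - (config$inertia[1L] - config$inertia[2L]) * frac
    for (i in seq_len(config$n_particles)) {
      up <- update_particle(sw$position[i, ], sw$velocity[i, ],
                            sw$pbest_position[i, ], gbest_pos, config,
                            inertia = w_it)
      sw$position[i, ] <- up$position
      sw$velocity[i, ] <- up$velocity
    }
    fit <- apply(sw$position, 1L, function(p)
      objective(position_for_objective(p, config)))
    better <- fit > sw$pbest_fitness
    sw$pbest_position[better, ] <- sw$position[better, , drop = FALSE]
    sw$pbest_fitness[better] <- fit[better]
    gi <- which.max(sw$pbest_fitness)
    if (sw$pbest_fitness[gi] > gbest_fit) {
      gbest_fit <- sw$pbest_fitness[gi]
      gbest_pos <- sw$pbest_position[gi, ]
    }
    hist <- rbind(hist, make_history(config, gbest_fit, NA_real_, gbest_pos, it))
  }
  swarm_result(position_for_objective(gbest_pos, config), gbest_fit, hist,
               "pso", config)
}

#' Exhaustive grid search baseline
#'
#' Evaluates every point of the Cartesian grid and returns the argmax; ties
#' are broken by the first-encountered point in row-major order (the first
#' grid component varies slowest).
#'
#' @param objective as in [run_sapso()].
#' @param grid named list of per-component value vectors, e.g.
#'   `list(lambda = ..., C = ..., a = ..., r = ...)`.
#' @param seed optional RNG seed (the evaluation itself is deterministic;
#'   the seed covers stochastic objectives).
#' @return a `swarm_result` whose `history` is the full evaluation table.
#' @export
run_grid <- function(objective, grid, seed = NULL) {
  objective <- as_objective(objective)
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(grid) || !length(grid) || !all(lengths(grid) > 0))
    stop("'grid' must be a non-empty named list of value vectors")
  pts <- rev(expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE))
  fits <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) fits[k] <- objective(as.numeric(pts[k, ]))
  best <- which.max(fits)  # which.max returns the first maximum: row-major tie-break
  tab <- cbind(pts, fitness = fits)
  res <- swarm_result(as.numeric(pts[best, ]), fits[best], tab, "grid", NULL)
  names(res$best_position) <- names(grid)
  res
}

swarm_result <- function(position, fitness, history, method, config) {
  structure(list(best_position = position, best_fitness = fitness,
                 history = history, method = method, config = config),
            class = "swarm_result")
}

make_history <- function(config, best_fitness, T, pos, iteration = 0L) {
  d <- data.frame(iteration = iteration, best_fitness = best_fitness,
                  temperature = T)
  nm <- rownames(config$ranges)
  if (is.null(nm)) nm <- paste0("x", seq_along(pos))
  for (k in seq_along(pos)) d[[nm[k]]] <- pos[k]
  d
}

#' @export
print.swarm_result <- function(x, ...) {
  cat("Swarm search result (", x$method, ")\n", sep = "")
  cat("  best fitness:", signif(x$best_fitness, 6), "\n")
  cat("  best position:", paste(signif(x$best_position, 5), collapse = ", "),
      "\n")
  if (is.data.frame(x$history) && "iteration" %in% names(x$history))
    cat("  iterations:", max(x$history$iteration), "\n")
  invisible(x)
}

#' @export
plot.swarm_result <- function(x, ...) {
  if (!("iteration" %in% names(x$history)))
    stop("no iteration history to plot for method ", x$method)
  plot(x$history$iteration, x$history$best_fitness, type = "s",
       xlab = "iteration", ylab = "best fitness",
       main = paste("Fitness curve (", x$method, ")", sep = ""), ...)
  invisible(x)
}

#' Benchmark surrogate objectives
#'
#' Smooth (`objective_sphere`) and multimodal (`objective_rastrigin`)
#' surrogate fitnesses for optimizer benchmarking, wrapped as
#' \eqn{1/(1 + f(x))} so the fitness lies in (0, 1] with optimum 1 — the
#' annealing temperature \eqn{T_0 = f/\ln 5} requires a nonnegative fitness,
#' and position-based convergence checks are invariant to this monotone
#' transform.
#'
#' @param center optimum location.
#' @return a `function(position) -> fitness in (0, 1]`.
#' @export
objective_sphere <- function(center = c(0, 0)) {
  force(center)
  function(x) 1 / (1 + sum((x - center)^2))
}

#' @rdname objective_sphere
#' @export
objective_rastrigin <- function(center = c(0, 0)) {
  force(center)
  function(x) {
    z <- x - center
    f <- sum(z^2 - 10 * cos(2 * pi * z) + 10)
    1 / (1 + f)
  }
}

#' Write a swarm-search history as delimited text
#'
#' @param result a `swarm_result`.
#' @param path output CSV path.
#' @export
write_history <- function(result, path) {
  write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
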