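bench_ranges <- function() {
  rg <- cbind(c(-5.12, -5.12), c(5.12, 5.12))
  rownames(rg) <- c("x1", "x2")
  rg
}

test_that("swarm initialization is deterministic and respects the box", {
  cfg <- swarm_config(n_particles = 20, max_iters = 5, seed = NULL)
  set.seed(12); s1 <- init_swarm(cfg)
  set.seed(12); s2 <- init_swarm(cfg)
  expect_identical(s1, s2)
  expect_equal(dim(s1$position), c(20L, 4L))
  lo <- cfg$ranges[, 1]; hi <- cfg$ranges[, 2]
  expect_true(all(t(s1$position) >= lo & t(s1$position) <= hi))
  expect_true(all(abs(t(s1$velocity)) <= cfg$vmax))
  expect_identical(s1$pbest_position, s1$position)
})

test_that("initial temperature follows T = f / ln 5", {
  expect_equal(init_temperature(1), 1 / log(5))
  expect_equal(init_temperature(0), 0)
  expect_equal(init_temperature(0.8949), 0.8949 / log(5), tolerance = 1e-12)
  expect_equal(init_temperature(0.8949), 0.55603, tolerance = 1e-5)
  expect_error(init_temperature(-0.1), "nonnegative")
})

test_that("Boltzmann weights match the printed formula", {
  # equal fitnesses: uniform
  expect_equal(boltzmann_weights(rep(0.7, 5), 0.7, 0.2), rep(0.2, 5))
  # hand-computed two-particle case: exponents (0, 2), e^2 ~ 7.389
  w <- boltzmann_weights(c(1.0, 0.8), 1.0, 0.1)
  expect_equal(w, c(1, exp(2)) / (1 + exp(2)), tolerance = 1e-12)
  expect_equal(w, c(0.1192, 0.8808), tolerance = 1e-4)
  # very hot: uniform limit
  expect_equal(boltzmann_weights(c(0.9, 0.2, 0.5), 0.9, 1e6), rep(1 / 3, 3),
               tolerance = 1e-5)
  # always a probability vector
  set.seed(31)
  for (i in 1:20) {
    w <- boltzmann_weights(runif(8), 1, runif(1, 0.01, 2))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  expect_error(boltzmann_weights(c(0.5, 1), 1, 0), "temperature")
})

test_that("as T -> 0 the printed weights concentrate on the smallest fitness", {
  P <- c(0.95, 0.6, 0.8, 0.99)
  w <- boltzmann_weights(P, max(P), 1e-6)
  expect_equal(which.max(w), which.min(P))
  expect_gt(max(w), 1 - 1e-10)
})

test_that("roulette selection matches the cumulative-sum rule", {
  expect_equal(roulette_select(c(1, 0, 0), 0.99), 1L)
  expect_equal(roulette_select(c(0.2, 0.3, 0.5), 0.6), 3L)
  expect_equal(roulette_select(c(0.2, 0.3, 0.5), 0.1), 1L)
  expect_error(roulette_select(c(0.5, 0.2), 0.3), "sum to 1")
  # empirical frequencies within 3 standard errors of the weights
  w <- c(0.2, 0.3, 0.5)
  n <- 1e5
  set.seed(13)
  u <- runif(n)
  picks <- vapply(u, function(ui) roulette_select(w, ui), integer(1))
  freq <- tabulate(picks, 3) / n
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(freq - w) < 3 * se))
})

test_that("particle updates follow the constriction rule with clamp and clip", {
  cfg <- swarm_config(ranges = bench_ranges(), v_scale = 0.6)
  x <- c(1, 1); v <- c(1, 1)
  # r1 = r2 = 0: only the phi * V term survives
  up <- update_particle(x, v, c(3, 3), c(4, 4), cfg, r1 = 0, r2 = 0)
  expect_equal(up$velocity, c(0.729, 0.729))
  expect_equal(up$position, x + up$velocity)
  # X = Pbest = Gplus: attraction vanishes for any r1, r2
  up2 <- update_particle(x, v, x, x, cfg, r1 = 0.42, r2 = 0.9)
  expect_equal(up2$velocity, 0.729 * v)
  # violent update stays inside bounds
  up3 <- update_particle(c(5, 5), c(100, -100), c(-5, 5), c(5, -5), cfg,
                         r1 = 1, r2 = 1)
  expect_true(all(abs(up3$velocity) <= cfg$vmax + 1e-12))
  expect_true(all(up3$position >= cfg$ranges[, 1] &
                    up3$position <= cfg$ranges[, 2]))
})

test_that("cooling is exactly geometric", {
  expect_equal(cool(1, 0.95), 0.95)
  expect_equal(cool(0.4, 1), 0.4)
  T <- 0.7
  for (k in 1:25) T <- cool(T, 0.9)
  expect_equal(T, 0.7 * 0.9^25, tolerance = 1e-15)
  expect_error(cool(1, 1.2), "cooling rate")
  expect_error(cool(-1, 0.5), "nonnegative")
})

test_that("SAPSO converges on a smooth surrogate and is reproducible", {
  target <- c(1, 2)
  errs <- vapply(1:10, function(s) {
    cfg <- swarm_config(n_particles = 20, max_iters = 200,
                        ranges = bench_ranges(), seed = s)
    res <- run_sapso(objective_sphere(target), cfg)
    sqrt(sum((res$best_position - target)^2))
  }, numeric(1))
  expect_lt(median(errs), 1e-2)
  cfg <- swarm_config(n_particles = 15, max_iters = 50,
                      ranges = bench_ranges(), seed = 4)
  r1 <- run_sapso(objective_sphere(target), cfg)
  r2 <- run_sapso(objective_sphere(target), cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$history$best_fitness) >= 0))
  # temperature column follows the exact geometric schedule
  Ts <- r1$history$temperature
  expect_equal(Ts, Ts[1] * cfg$cooling_rate^(0:cfg$max_iters),
               tolerance = 1e-12)
})

test_that("plain PSO converges, freezes under degenerate dynamics, repeats", {
  target <- c(-2, 0.5)
  errs <- vapply(1:10, function(s) {
    cfg <- swarm_config(n_particles = 20, max_iters = 200,
                        ranges = bench_ranges(), seed = s)
    res <- run_pso(objective_sphere(target), cfg)
    sqrt(sum((res$best_position - target)^2))
  }, numeric(1))
  expect_lt(median(errs), 1e-2)
  # omega = 0 and c1 = c2 = 0: velocities null after the first update
  cfg0 <- swarm_config(n_particles = 5, max_iters = 10,
                       ranges = bench_ranges(), c1 = 0, c2 = 0,
                       inertia = c(0, 0), seed = 2)
  res0 <- run_pso(objective_sphere(target), cfg0)
  expect_equal(res0$history$best_fitness[2],
               res0$history$best_fitness[11])
  cfg <- swarm_config(n_particles = 10, max_iters = 30,
                      ranges = bench_ranges(), seed = 6)
  expect_identical(run_pso(objective_sphere(target), cfg),
                   run_pso(objective_sphere(target), cfg))
})

test_that("grid search enumerates exhaustively with row-major tie-breaks", {
  obj <- function(x) -sum(x^2)
  one <- run_grid(obj, list(a = 0.3, b = -0.1))
  expect_equal(one$best_position, c(a = 0.3, b = -0.1))
  expect_equal(nrow(one$history), 1L)
  # constant objective: ties resolve to the first row-major point
  tie <- run_grid(function(x) 1, list(a = c(1, 2), b = c(3, 4)))
  expect_equal(unname(tie$best_position), c(1, 3))
  expect_equal(nrow(tie$history), 4L)
  # first component varies slowest in the evaluation table
  expect_equal(tie$history$a, c(1, 1, 2, 2))
  expect_error(run_grid(obj, list()), "non-empty")
})

test_that("cross-validated fitness is deterministic, perfect on separable data, at chance under permutation", {
  tab <- make_separable_table(n_per_class = 25, delta = 8)
  ev <- fitness_evaluator(tab, k = 5, d = 2, seed = 1)
  f <- evaluate_fitness(c(0.5, 10, 0.01, 0), ev)
  expect_equal(f, 1.0)
  expect_identical(f, evaluate_fitness(c(0.5, 10, 0.01, 0), ev))
  # permuting the labels destroys the signal: fitness near chance.
  # with balanced classes and an uninformative classifier the pooled
  # ACC and SEN are both ~0.5, so F ~ 0.5
  set.seed(55)
  tabp <- gen_feature_table(100, dim = 5, delta = 6, seed = 8)
  tabp$y <- sample(tabp$y)
  evp <- fitness_evaluator(tabp, k = 5, d = 2, seed = 2)
  fp <- evaluate_fitness(c(0.5, 1, 0.01, 0), evp)
  expect_lt(abs(fp - 0.5), 0.15)
  expect_error(evaluate_fitness(c(2, 1, 0.1, 0), ev), "lambda")
  expect_error(evaluate_fitness(c(0.5, -1, 0.1, 0), ev), "positive")
})

test_that("a full tuning run on spec-scale data stays reproducible", {
  tab <- make_separable_table(n_per_class = 15, delta = 8)
  cfg <- swarm_config(n_particles = 8, max_iters = 6, seed = 21)
  t1 <- tune_mklsvm(tab, config = cfg, fold_seed = 1)
  t2 <- tune_mklsvm(tab, config = cfg, fold_seed = 1)
  expect_identical(t1$best_position, t2$best_position)
  expect_identical(t1$best_fitness, t2$best_fitness)
  expect_equal(t1$best_fitness, 1.0)
  expect_s3_class(t1$model, "mkl_svm")
})
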