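test_that("inverse point reflects through the box centre and is an involution", {
  sp <- search_space(c(-2, 0, 1), c(4, 10, 3))
  expect_equal(inverse_point(sp$lower, sp), sp$upper)
  expect_equal(inverse_point(sp$upper, sp), sp$lower)
  mid <- (sp$lower + sp$upper) / 2
  expect_equal(inverse_point(mid, sp), mid)
  set.seed(51)
  for (i in 1:50) {
    x <- stats::runif(3, sp$lower, sp$upper)
    xi <- inverse_point(x, sp)
    expect_equal(inverse_point(xi, sp), x, tolerance = 1e-12)
    expect_true(all(xi >= sp$lower & xi <= sp$upper))
  }
  expect_warning(inverse_point(c(99, 5, 2), sp), "clamped")
  expect_error(search_space(1, 1), "lower bounds")
})

test_that("opposition-based selection never keeps the worse point; ties keep c", {
  sp <- search_space(-1, 1)
  # symmetric objective: tie, keep c
  expect_equal(obl_select(0.3, sp, function(x) x^2), 0.3)
  # monotone objective on [0, 10]: 8 loses to its reflection 2
  sp10 <- search_space(0, 10)
  expect_equal(obl_select(8, sp10, function(x) x), 2)
  set.seed(52)
  for (i in 1:100) {
    a <- stats::runif(1, -2, 2); b <- stats::runif(1, -2, 2)
    f <- function(x) a * (x - b)^2 + x
    x <- stats::runif(1, 0, 10)
    got <- obl_select(x, sp10, f)
    xi <- 10 - x
    expect_equal(got, if (f(xi) < f(x)) xi else x)
    expect_lte(f(got), min(f(x), f(xi)) + 1e-12)
  }
  expect_error(obl_select(0.5, sp, function(x) NaN), "non-finite")
})

test_that("flow coefficient decays multiplicatively and hits zero at t = T", {
  st <- list(beta = 0.4, t = 0, T = 10)
  st1 <- update_flow_coefficient(st)
  expect_equal(st1$beta, 0.4) # t = 0 leaves beta unchanged
  expect_equal(st1$t, 1)
  st_end <- list(beta = 0.2, t = 10, T = 10)
  expect_equal(update_flow_coefficient(st_end)$beta, 0)
  # closed-form product oracle: beta_0 = 0.005, T = 1000, 100 steps
  st <- list(beta = 0.005, t = 0, T = 1000)
  for (i in 1:101) st <- update_flow_coefficient(st)
  direct <- 0.005 * prod(1 - (1:100) / 1000)
  expect_equal(st$beta, direct, tolerance = 1e-12)
  # frozen 50-digit reference of the same product
  expect_equal(st$beta, 2.6815169845082151699702250760758e-05,
               tolerance = 1e-12)
  # monotone non-increasing across the whole schedule
  st <- list(beta = 0.005, t = 0, T = 50)
  betas <- numeric(51)
  for (i in 1:51) { st <- update_flow_coefficient(st); betas[i] <- st$beta }
  expect_true(all(diff(betas) <= 0))
  expect_equal(betas[51], 0)
  expect_error(update_flow_coefficient(list(beta = 1, t = 0, T = 0)), "T")
})

test_that("raindrop pool keeps exactly the k smallest fitnesses ever seen", {
  set.seed(53)
  k <- 12
  init_fit <- stats::runif(k, 5, 10)
  pool <- raindrop_pool(matrix(stats::rnorm(k * 2), k, 2), init_fit)
  expect_equal(pool$fitness, sort(init_fit))
  # worse-than-all candidate: unchanged
  worse <- update_pool(pool, c(0, 0), 99)
  expect_identical(worse, pool)
  # better-than-all candidate: becomes the head, previous worst gone
  best <- update_pool(pool, c(1, 1), -1)
  expect_equal(best$fitness[1], -1)
  expect_false(max(init_fit) %in% best$fitness)
  expect_equal(length(best$fitness), k)
  # 1000 random updates against a full-sort oracle
  history <- init_fit
  for (i in 1:1000) {
    f <- stats::runif(1, 0, 12)
    pool <- update_pool(pool, stats::rnorm(2), f)
    history <- c(history, f)
    expect_equal(length(pool$fitness), k)          # size conserved
    expect_true(!is.unsorted(pool$fitness))        # sorted after every update
  }
  expect_equal(pool$fitness, sort(history)[1:k], tolerance = 1e-15)
})

test_that("gaussian perturbation has the prescribed scale and respects bounds", {
  sp <- search_space(-100, 100)
  expect_equal(gaussian_perturb(3, 0.1, 0, sp), 3) # beta = 0: unchanged
  set.seed(54)
  draws <- replicate(1e4, gaussian_perturb(0, 0.5, 0.01, sp))
  expect_equal(stats::sd(draws), 0.5 * 0.01 * 200, tolerance = 0.05)
  sp_tight <- search_space(0, 1)
  set.seed(55)
  pts <- replicate(500, gaussian_perturb(0.99, 5, 0.5, sp_tight))
  expect_true(all(pts >= 0 & pts <= 1))
  expect_error(gaussian_perturb(0, -1, 0.1, sp), "positive")
})

test_that("the optimizer finds a 1-D convex minimum and is deterministic", {
  sp <- search_space(0, 10)
  f <- function(x) (x - 3)^2
  hits <- 0L
  for (s in 1:30) {
    tr <- ara_optimize(f, sp, optimizer_config(iterations = 500, seed = s))
    if (abs(tr$best_position - 3) < 1e-3) hits <- hits + 1L
    expect_true(all(diff(tr$best_fitness) <= 0)) # monotone best-so-far
  }
  expect_gte(hits, 29)
  t1 <- ara_optimize(f, sp, optimizer_config(iterations = 100, seed = 77))
  t2 <- ara_optimize(f, sp, optimizer_config(iterations = 100, seed = 77))
  expect_identical(t1$best_fitness, t2$best_fitness)
  expect_identical(t1$best_position, t2$best_position)
  # constant objective: flat trace at that constant
  tc <- ara_optimize(function(x) 4.2, sp, optimizer_config(iterations = 50,
                                                           seed = 1))
  expect_true(all(tc$best_fitness == 4.2))
})

test_that("benchmark functions match their standard closed forms", {
  expect_equal(ackley(rep(0, 10)), 0, tolerance = 1e-12)
  expect_equal(rastrigin(rep(0, 10)), 0, tolerance = 1e-12)
  # frozen 50-digit reference for ackley at (1, ..., 1) in 10-D
  expect_equal(ackley(rep(1, 10)), 3.62538493844036282660128982762,
               tolerance = 1e-12)
  expect_equal(rastrigin(c(1, 2, 3)), sum(c(1, 4, 9)), tolerance = 1e-12)
  set.seed(56)
  for (i in 1:20) {
    x <- stats::runif(5, -5, 5)
    expect_equal(rastrigin(x),
                 10 * 5 + sum(x^2 - 10 * cos(2 * pi * x)), tolerance = 1e-12)
  }
})

test_that("comparison harness: shared budget, finite results, obl ablation", {
  sp <- search_space(rep(-32.768, 5), rep(32.768, 5))
  res <- compare_optimizers(ackley, sp, iterations = 60, n_runs = 2, seed = 3)
  expect_setequal(res$summary$algorithm, c("obl_ara", "ara", "de", "pso"))
  expect_true(all(is.finite(res$finals)))
  # plain-ARA entries are exactly reproducible with use_obl = FALSE
  cfg <- optimizer_config(iterations = 60, seed = 4, use_obl = FALSE)
  direct <- ara_optimize(ackley, sp, cfg)
  expect_equal(unname(res$finals[1, "ara"]), direct$final_fitness)
  # one-iteration budget still returns a valid summary
  tiny <- compare_optimizers(ackley, sp, iterations = 1, n_runs = 1, seed = 5,
                             algorithms = c("obl_ara", "de"))
  expect_true(all(is.finite(tiny$finals)))
})

test_that("optimizer configs are validated", {
  expect_error(optimizer_config(population = 0), ">= 1")
  expect_error(optimizer_config(beta0 = 0), "beta0")
  expect_error(optimizer_config(perturb_scale = -1), "perturb_scale")
})
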