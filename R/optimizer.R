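# Opposition-based-learning artificial raindrop algorithm (OBL+ARA).
#
# Candidate solutions ("raindrops") carry their objective value as potential
# energy. Each iteration every raindrop takes up to max_flow flow steps
# toward rank-biased members of a fixed-capacity elite pool, receives a
# Gaussian perturbation whose scale decays with the adaptive flow
# coefficient beta, is compared against its bound-reflected inverse point
# (opposition-based learning), and competes for a slot in the pool. Raindrops
# that fail to improve for max_stagnation iterations escape via their
# inverse point. The pool is kept sorted by a bubble pass, so it always
# holds the k best solutions seen.

#' Box-constrained search space
#'
#' @param lower,upper Numeric vectors of per-dimension bounds
#'   (`lower < upper` elementwise); recycled against each other.
#' @return A list of class `"search_space"` with `lower`, `upper`,
#'   `dimension`.
#' @export
search_space <- function(lower, upper) {
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(lower >= upper)) stop("lower bounds must be < upper bounds", call. = FALSE)
  structure(list(lower = lower, upper = upper, dimension = d),
            class = "search_space")
}

clamp <- function(x, space) pmin(pmax(x, space$lower), space$upper)

#' Inverse point of a candidate under opposition-based learning
#'
#' Component-wise reflection through the centre of the search box:
#' `c'_i = lower_i + upper_i - c_i`. Applying it twice returns the original
#' point; the box midpoint is its own inverse.
#'
#' @param c Numeric position vector.
#' @param space A [search_space()].
#' @return The reflected position (always within bounds for in-bounds
#'   input). Out-of-bounds input is clamped first, with a warning.
#' @export
inverse_point <- function(c, space) {
  if (any(c < space$lower - 1e-12) || any(c > space$upper + 1e-12)) {
    warning("position outside bounds; clamped before reflection")
    c <- clamp(c, space)
  }
  space$lower + space$upper - c
}

#' Opposition-based selection between a point and its inverse
#'
#' Evaluates the objective at `c` and its [inverse_point()] `c'` and keeps
#' the fitter of the two; an exact tie keeps `c`.
#'
#' @param c Numeric position vector.
#' @param space A [search_space()].
#' @param objective Function mapping a position to a finite scalar
#'   (minimized).
#' @return The selected position.
#' @export
obl_select <- function(c, space, objective) {
  ci <- inverse_point(c, space)
  fc <- objective(c)
  fci <- objective(ci)
  if (!is.finite(fc) || !is.finite(fci)) {
    bad <- if (!is.finite(fc)) c else ci
    stop(sprintf("non-finite objective value at (%s)",
                 paste(signif(bad, 6), collapse = ", ")), call. = FALSE)
  }
  if (fci < fc) ci else c
}

#' Advance the adaptive flow coefficient by one iteration
#'
#' `beta_{t+1} = beta_t * (1 - t / T)`: multiplicative decay that shifts the
#' search from global to local and reaches exactly 0 at `t = T`.
#'
#' @param state A list with `beta` (current coefficient), `t` (current
#'   iteration, `0 <= t <= T`) and `T` (maximum iterations, `> 0`).
#' @return The state with `beta` updated and `t` incremented.
#' @export
update_flow_coefficient <- function(state) {
  if (state$T <= 0) stop("T must be positive", call. = FALSE)
  if (state$t < 0 || state$t > state$T) stop("t must lie in [0, T]", call. = FALSE)
  state$beta <- state$beta * (1 - state$t / state$T)
  state$t <- state$t + 1
  state
}

#' Fixed-capacity raindrop pool
#'
#' Creates the elite pool from initial positions and fitnesses, sorted
#' ascending by potential energy (fitness).
#'
#' @param positions Matrix with one candidate per row.
#' @param fitness Numeric vector of objective values, one per row.
#' @return A list of class `"raindrop_pool"` with sorted `positions`,
#'   `fitness`, and `capacity`.
#' @export
raindrop_pool <- function(positions, fitness) {
  stopifnot(nrow(positions) == length(fitness), nrow(positions) >= 1)
  ord <- order(fitness)
  structure(list(positions = positions[ord, , drop = FALSE],
                 fitness = fitness[ord], capacity = length(fitness)),
            class = "raindrop_pool")
}

#' Offer a candidate to the raindrop pool
#'
#' If the candidate's potential energy is below the worst pool member's, the
#' worst member is removed and the candidate bubbled into its sorted slot;
#' otherwise the pool is unchanged. Pool size is invariant, and after any
#' sequence of updates the pool holds exactly the `capacity` smallest
#' fitnesses ever offered (including the initial ones).
#'
#' @param pool A [raindrop_pool()].
#' @param position Candidate position vector.
#' @param fitness Candidate objective value.
#' @return The updated pool.
#' @export
update_pool <- function(pool, position, fitness) {
  k <- pool$capacity
  if (fitness >= pool$fitness[k]) return(pool)
  # drop the worst, then a single bubble pass from the tail restores order
  pool$positions[k, ] <- position
  pool$fitness[k] <- fitness
  i <- k
  while (i > 1 && pool$fitness[i] < pool$fitness[i - 1]) {
    tmpf <- pool$fitness[i - 1]; pool$fitness[i - 1] <- pool$fitness[i]
    pool$fitness[i] <- tmpf
    tmpp <- pool$positions[i - 1, ]; pool$positions[i - 1, ] <- pool$positions[i, ]
    pool$positions[i, ] <- tmpp
    i <- i - 1
  }
  pool
}

#' Gaussian perturbation scaled by the flow coefficient
#'
#' Adds independent `N(0, (scale * beta_t * (upper - lower))^2)` noise to
#' each component and clamps to the bounds. With `beta_t = 0` the position
#' is returned unchanged.
#'
#' @param c Position vector.
#' @param scale Positive base scale (fraction of the box width).
#' @param beta_t Current flow coefficient.
#' @param space A [search_space()].
#' @return The perturbed, clamped position.
#' @export
gaussian_perturb <- function(c, scale, beta_t, space) {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  if (beta_t == 0) return(c)
  sd <- scale * beta_t * (space$upper - space$lower)
  clamp(c + stats::rnorm(length(c), 0, sd), space)
}

#' Optimizer configuration
#'
#' @param population Number of raindrops.
#' @param pool_capacity Elite pool size.
#' @param beta0 Initial adaptive flow coefficient.
#' @param max_stagnation Iterations without improvement before a raindrop is
#'   replaced by its inverse point (default 10).
#' @param max_flow Maximum flow steps per raindrop per iteration (default 3).
#' @param iterations Iteration budget `T` (also the horizon of the beta
#'   schedule).
#' @param perturb_scale Base scale of the Gaussian perturbation.
#' @param use_obl If `FALSE`, opposition-based learning is disabled (plain
#'   ARA): no inverse-point comparison of new drops and stagnation escape
#'   re-initializes uniformly instead of reflecting.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"optimizer_config"`.
#' @export
optimizer_config <- function(population = 30, pool_capacity = 20,
                             beta0 = 0.005, max_stagnation = 10,
                             max_flow = 3, iterations = 1000,
                             perturb_scale = 0.1, use_obl = TRUE, seed = 0) {
  cfg <- list(population = as.integer(population),
              pool_capacity = as.integer(pool_capacity),
              beta0 = as.numeric(beta0),
              max_stagnation = as.integer(max_stagnation),
              max_flow = as.integer(max_flow),
              iterations = as.integer(iterations),
              perturb_scale = as.numeric(perturb_scale),
              use_obl = isTRUE(use_obl),
              seed = as.integer(seed))
  if (cfg$population < 1 || cfg$pool_capacity < 1 || cfg$max_stagnation < 1 ||
      cfg$max_flow < 1 || cfg$iterations < 1) {
    stop("population, pool_capacity, max_stagnation, max_flow and iterations must be >= 1",
         call. = FALSE)
  }
  if (cfg$beta0 <= 0) stop("beta0 must be positive", call. = FALSE)
  if (cfg$perturb_scale <= 0) stop("perturb_scale must be positive", call. = FALSE)
  class(cfg) <- "optimizer_config"
  cfg
}

# Rank-biased pool member indices: P(rank r) proportional to
# capacity - r + 1, drawn by inverting the closed-form CDF
# F(r) = r (2k + 1 - r) / (k (k + 1)).
rank_biased_index <- function(capacity, n = 1) {
  u <- stats::runif(n)
  k <- capacity
  r <- ceiling(((2 * k + 1) - sqrt((2 * k + 1)^2 - 4 * u * k * (k + 1))) / 2)
  pmin(pmax(r, 1L), k)
}

#' Minimize an objective with the OBL+ARA raindrop algorithm
#'
#' Runs `iterations` rounds. Per round, for each raindrop: (1) up to
#' `max_flow` flow steps, each moving a uniform-random fraction of the way
#' toward a rank-biased pool member, followed by a [gaussian_perturb()];
#' (2) opposition-based selection against its inverse point (when
#' `use_obl`); (3) a pool update offer; (4) stagnation bookkeeping --- a
#' raindrop that has not improved for `max_stagnation` iterations is
#' replaced by its inverse point (or re-initialized uniformly when OBL is
#' disabled) and its counter reset; (5) the flow coefficient decays per
#' [update_flow_coefficient()].
#'
#' @param objective Function of a position vector returning a finite scalar
#'   to minimize.
#' @param space A [search_space()].
#' @param config An [optimizer_config()].
#' @return A list of class `"convergence_trace"`: `best_fitness`
#'   (per-iteration best-so-far, non-increasing), `best_position`,
#'   `evaluations` (total objective calls), `config`.
#' @examples
#' tr <- ara_optimize(function(x) sum((x - 3)^2), search_space(0, 10),
#'                    optimizer_config(iterations = 100, seed = 1))
#' tr$best_position
#' @export
ara_optimize <- function(objective, space, config = optimizer_config()) {
  stopifnot(inherits(space, "search_space"))
  d <- space$dimension
  np <- config$population
  with_local_seed(config$seed, {
    evals <- 0L
    eval_rows <- function(M) {
      evals <<- evals + nrow(M)
      apply(M, 1, objective)
    }
    pop <- matrix(stats::runif(np * d, space$lower, space$upper),
                  np, d, byrow = TRUE)
    fit <- eval_rows(pop)
    if (any(!is.finite(fit))) stop("non-finite objective at initialization", call. = FALSE)
    k <- min(config$pool_capacity, np)
    ord <- order(fit)[seq_len(k)]
    pool <- raindrop_pool(pop[ord, , drop = FALSE], fit[ord])
    stag <- integer(np)
    beta_state <- list(beta = config$beta0, t = 0, T = config$iterations)
    trace <- numeric(config$iterations)
    center <- space$lower + space$upper
    for (it in seq_len(config$iterations)) {
      # (1) flow steps toward rank-biased pool members, then perturbation
      X <- pop
      n_steps <- sample.int(config$max_flow, np, replace = TRUE)
      for (s in seq_len(config$max_flow)) {
        act <- which(n_steps >= s)
        if (length(act) == 0) next
        tgt <- pool$positions[rank_biased_index(pool$capacity,
                                                length(act)), , drop = FALSE]
        u <- stats::runif(length(act))
        X[act, ] <- X[act, ] + u * (tgt - X[act, , drop = FALSE])
      }
      if (beta_state$beta > 0) {
        sd <- config$perturb_scale * beta_state$beta *
          (space$upper - space$lower)
        X <- X + matrix(stats::rnorm(np * d, 0, 1), np, d, byrow = TRUE) *
          rep(sd, each = np)
        X <- pmin(pmax(X, rep(space$lower, each = np)),
                  rep(space$upper, each = np))
      }
      fx <- eval_rows(X)
      # (2) opposition-based selection of each new raindrop
      if (config$use_obl) {
        Xi <- rep(center, each = np) - X
        fxi <- eval_rows(Xi)
        take <- fxi < fx
        X[take, ] <- Xi[take, , drop = FALSE]
        fx[take] <- fxi[take]
      }
      # (3) pool offers, (4) stagnation bookkeeping and escape
      stag <- ifelse(fx < fit, 0L, stag + 1L)
      pop <- X
      fit <- fx
      for (i in seq_len(np)) pool <- update_pool(pool, pop[i, ], fit[i])
      esc <- which(stag > config$max_stagnation)
      if (length(esc) > 0) {
        E <- if (config$use_obl) {
          rep(center, each = length(esc)) - pop[esc, , drop = FALSE]
        } else {
          matrix(stats::runif(length(esc) * d, space$lower, space$upper),
                 length(esc), d, byrow = TRUE)
        }
        fe <- eval_rows(E)
        pop[esc, ] <- E
        fit[esc] <- fe
        stag[esc] <- 0L
        for (i in seq_along(esc)) pool <- update_pool(pool, E[i, ], fe[i])
      }
      # (5) flow-coefficient decay
      beta_state <- update_flow_coefficient(beta_state)
      trace[it] <- pool$fitness[1]
    }
    structure(
      list(best_fitness = trace, best_position = pool$positions[1, ],
           final_fitness = pool$fitness[1], evaluations = evals,
           config = config),
      class = "convergence_trace")
  })
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf("Convergence trace: %d iterations, %d evaluations\n",
              length(x$best_fitness), x$evaluations))
  cat(sprintf("  final best fitness: %.6g\n", x$final_fitness))
  invisible(x)
}

#' Ackley benchmark function
#'
#' Standard form with `a = 20`, `b = 0.2`, `c = 2*pi`; global minimum 0 at
#' the origin, usually evaluated on `[-32.768, 32.768]^d`.
#'
#' @param x Numeric position vector.
#' @return Function value.
#' @export
ackley <- function(x) {
  d <- length(x)
  20 + exp(1) -
    20 * exp(-0.2 * sqrt(mean(x^2))) -
    exp(mean(cos(2 * pi * x)))
}

#' Rastrigin benchmark function
#'
#' Standard form with `A = 10`; global minimum 0 at the origin, usually
#' evaluated on `[-5.12, 5.12]^d`.
#'
#' @inheritParams ackley
#' @return Function value.
#' @export
rastrigin <- function(x) {
  10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
}

# ---- Baseline optimizers for the comparison harness --------------------

# Differential evolution, rand/1/bin, F = 0.5, CR = 0.9. Runs until the
# evaluation budget is exhausted; returns per-generation best-so-far.
de_optimize <- function(objective, space, budget, population = 30, seed = 0) {
  d <- space$dimension
  np <- population
  with_local_seed(seed, {
    evals <- 0L
    eval_rows <- function(M) { evals <<- evals + nrow(M); apply(M, 1, objective) }
    pop <- matrix(stats::runif(np * d, space$lower, space$upper),
                  np, d, byrow = TRUE)
    fit <- eval_rows(pop)
    trace <- min(fit)
    ids <- seq_len(np)
    draw_distinct <- function() {
      # three donor indices per target, all distinct from it and each other
      r <- matrix(sample.int(np, 3 * np, replace = TRUE), np, 3)
      repeat {
        bad <- r[, 1] == ids | r[, 2] == ids | r[, 3] == ids |
          r[, 1] == r[, 2] | r[, 1] == r[, 3] | r[, 2] == r[, 3]
        if (!any(bad)) break
        r[bad, ] <- matrix(sample.int(np, 3 * sum(bad), replace = TRUE),
                           sum(bad), 3)
      }
      r
    }
    while (evals + np <= budget) {
      r <- draw_distinct()
      v <- pop[r[, 1], , drop = FALSE] +
        0.5 * (pop[r[, 2], , drop = FALSE] - pop[r[, 3], , drop = FALSE])
      cross <- matrix(stats::runif(np * d) < 0.9, np, d)
      cross[cbind(ids, sample.int(d, np, replace = TRUE))] <- TRUE
      u <- ifelse(cross, v, pop)
      u <- pmin(pmax(u, rep(space$lower, each = np)),
                rep(space$upper, each = np))
      fu <- eval_rows(u)
      sel <- fu <= fit
      pop[sel, ] <- u[sel, , drop = FALSE]
      fit[sel] <- fu[sel]
      trace <- c(trace, min(min(fit), trace[length(trace)]))
    }
    list(best_fitness = cummin(trace), final_fitness = min(fit),
         evaluations = evals)
  })
}

# Particle swarm with linearly decaying inertia 0.9 -> 0.4 over the budget,
# c1 = c2 = 2.
pso_optimize <- function(objective, space, budget, population = 30, seed = 0) {
  d <- space$dimension
  np <- population
  with_local_seed(seed, {
    evals <- 0L
    eval_rows <- function(M) { evals <<- evals + nrow(M); apply(M, 1, objective) }
    pop <- matrix(stats::runif(np * d, space$lower, space$upper),
                  np, d, byrow = TRUE)
    vmax <- 0.2 * (space$upper - space$lower)
    vel <- matrix(stats::runif(np * d, -1, 1), np, d, byrow = TRUE) *
      rep(vmax, each = np)
    fit <- eval_rows(pop)
    pbest <- pop; pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pop[g, ]; gbest_fit <- fit[g]
    trace <- gbest_fit
    n_gen <- max(1, floor((budget - np) / np))
    gen <- 0
    lo <- rep(space$lower, each = np)
    hi <- rep(space$upper, each = np)
    vmax_m <- rep(vmax, each = np)
    while (evals + np <= budget) {
      gen <- gen + 1
      w <- 0.9 - 0.5 * min(gen / n_gen, 1)
      r1 <- matrix(stats::runif(np * d), np, d)
      r2 <- matrix(stats::runif(np * d), np, d)
      G <- matrix(gbest, np, d, byrow = TRUE)
      vel <- w * vel + 2 * r1 * (pbest - pop) + 2 * r2 * (G - pop)
      vel <- pmin(pmax(vel, -vmax_m), vmax_m)
      pop <- pmin(pmax(pop + vel, lo), hi)
      fit <- eval_rows(pop)
      imp <- fit < pbest_fit
      pbest[imp, ] <- pop[imp, , drop = FALSE]
      pbest_fit[imp] <- fit[imp]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) { gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g] }
      trace <- c(trace, gbest_fit)
    }
    list(best_fitness = cummin(trace), final_fitness = gbest_fit,
         evaluations = evals)
  })
}

#' Compare OBL+ARA against plain ARA, DE and PSO baselines
#'
#' Runs each algorithm `n_runs` times on the objective under an equal
#' evaluation budget (the budget OBL+ARA consumes in `iterations`
#' iterations), and summarizes final best fitness per algorithm. Baselines:
#' differential evolution rand/1/bin (F = 0.5, CR = 0.9) and particle swarm
#' with linearly decaying inertia 0.9 to 0.4 --- conventional settings, not
#' tuned here.
#'
#' @param objective Objective function (minimized).
#' @param space A [search_space()].
#' @param iterations ARA iteration budget per run.
#' @param n_runs Number of independent runs per algorithm.
#' @param seed Base seed; run `r` of each algorithm uses `seed + r`.
#' @param population Population size shared by all algorithms.
#' @param algorithms Which algorithms to run; `"obl_ara"` is always
#'   included (it defines the evaluation budget).
#' @return A list with `summary` (data frame: algorithm, median / mean / sd
#'   of final fitness, evaluation budget) and `finals` (matrix of final
#'   fitnesses, one column per algorithm).
#' @export
compare_optimizers <- function(objective, space, iterations = 1000,
                               n_runs = 30, seed = 0, population = 30,
                               algorithms = c("obl_ara", "ara", "de", "pso")) {
  stopifnot(n_runs >= 1)
  algos <- union("obl_ara", match.arg(algorithms,
                                      c("obl_ara", "ara", "de", "pso"),
                                      several.ok = TRUE))
  finals <- matrix(NA_real_, n_runs, length(algos),
                   dimnames = list(NULL, algos))
  budget <- NA_integer_
  for (r in seq_len(n_runs)) {
    cfg <- optimizer_config(population = population, iterations = iterations,
                            seed = seed + r)
    tr <- ara_optimize(objective, space, cfg)
    finals[r, "obl_ara"] <- tr$final_fitness
    budget <- tr$evaluations
    if ("ara" %in% algos) {
      cfg$use_obl <- FALSE
      finals[r, "ara"] <- ara_optimize(objective, space, cfg)$final_fitness
    }
    if ("de" %in% algos) {
      finals[r, "de"] <- de_optimize(objective, space, budget,
                                     population, seed + r)$final_fitness
    }
    if ("pso" %in% algos) {
      finals[r, "pso"] <- pso_optimize(objective, space, budget,
                                       population, seed + r)$final_fitness
    }
  }
  summary <- data.frame(
    algorithm = algos,
    median_final = apply(finals, 2, stats::median),
    mean_final = colMeans(finals),
    sd_final = apply(finals, 2, stats::sd),
    budget = budget,
    stringsAsFactors = FALSE)
  list(summary = summary, finals = finals)
}
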