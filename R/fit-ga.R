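#' Genetic-algorithm configuration
#'
#' Settings for the real-coded GA that optimizes the free shape parameters
#' \eqn{a_i, b_i, \lambda_i} of each segment.  Defaults: population 50,
#' up to 200 generations, tournament selection of size 3, BLX-0.5 blend
#' crossover, per-gene Gaussian mutation with sigma = 10% of the bound
#' range, elitism of 1, parameter bounds \eqn{(0.05, 10]}.  Optimization of
#' a segment stops early once its error reaches `target_error`
#' (default \eqn{10^{-2}}).
#'
#' @param pop_size population size (>= 2).
#' @param generations maximum number of generations.
#' @param p_crossover probability a selected pair is recombined.
#' @param p_mutation per-gene mutation probability.
#' @param lower common lower bound for a, b and lambda (must be > 0 to keep
#'   the rational denominator positive and joins direction-preserving).
#' @param a_max,b_max,lambda_max upper bounds per parameter.
#' @param seed integer RNG seed; fixes the whole optimization run.
#' @param target_error stopping threshold on the normalized mean squares
#'   error of a segment.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, generations = 200L,
                      p_crossover = 0.9, p_mutation = 0.2,
                      lower = 0.05, a_max = 10, b_max = 10, lambda_max = 10,
                      seed = 1L, target_error = 1e-2) {
  pop_size <- as.integer(pop_size)
  generations <- as.integer(generations)
  if (pop_size < 2L) stop("`pop_size` must be >= 2", call. = FALSE)
  if (generations < 1L) stop("`generations` must be >= 1", call. = FALSE)
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  lower <- check_positive(lower, "lower")
  a_max <- check_positive(a_max, "a_max")
  b_max <- check_positive(b_max, "b_max")
  lambda_max <- check_positive(lambda_max, "lambda_max")
  if (any(c(a_max, b_max, lambda_max) <= lower)) {
    stop("upper bounds must exceed `lower`", call. = FALSE)
  }
  target_error <- check_positive(target_error, "target_error")
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 lower = lower, a_max = a_max, b_max = b_max,
                 lambda_max = lambda_max, seed = as.integer(seed),
                 target_error = target_error),
            class = "ga_config")
}

# one GA run over a box-bounded real vector; returns best genes/fitness.
# fitness must be deterministic; ties broken by individual index (stable).
run_ga <- function(fitness, lower, upper, cfg) {
  ndim <- length(lower)
  np <- cfg$pop_size
  sigma <- 0.1 * (upper - lower)

  pop <- matrix(stats::runif(np * ndim, rep(lower, each = np),
                             rep(upper, each = np)), np, ndim)
  # seed one individual at the neutral parameters (a = b = lambda = 1)
  pop[1L, ] <- pmin(pmax(rep(1, ndim), lower), upper)
  fit <- apply(pop, 1L, fitness)

  best_hist <- numeric(0)
  gens_used <- 0L
  for (gen in seq_len(cfg$generations)) {
    best_idx <- which.min(fit)       # which.min is stable: earliest minimum
    best_hist <- c(best_hist, fit[best_idx])
    gens_used <- gen
    if (fit[best_idx] <= cfg$target_error) break
    if (gen == cfg$generations) break

    tournament <- function() {
      idx <- sample.int(np, 3L, replace = np < 3L)
      idx[which.min(fit[idx])]
    }
    children <- matrix(NA_real_, np - 1L, ndim)
    i <- 1L
    while (i <= np - 1L) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      if (stats::runif(1) < cfg$p_crossover) {
        # BLX-alpha with alpha = 0.5
        lo <- pmin(p1, p2); hi <- pmax(p1, p2); d <- hi - lo
        c1 <- stats::runif(ndim, lo - 0.5 * d, hi + 0.5 * d)
        c2 <- stats::runif(ndim, lo - 0.5 * d, hi + 0.5 * d)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (ch in list(c1, c2)) {
        if (i > np - 1L) break
        mut <- stats::runif(ndim) < cfg$p_mutation
        ch[mut] <- ch[mut] + stats::rnorm(sum(mut), 0, sigma[mut])
        children[i, ] <- pmin(pmax(ch, lower), upper)
        i <- i + 1L
      }
    }
    elite <- pop[best_idx, , drop = FALSE]
    pop <- rbind(elite, children)
    fit <- c(fit[best_idx], apply(children, 1L, fitness))
  }
  best_idx <- which.min(fit)
  list(genes = pop[best_idx, ], fitness = fit[best_idx],
       generations = gens_used, best_history = best_hist)
}

#' Optimize the free parameters of rational Ball segments by GA
#'
#' Fits one rational cubic Ball segment to each element of `segments`.
#' Segment endpoints are pinned to the first/last data point; inner
#' coefficients come from the Q-weighted least squares of
#' [least_squares_controls()]; the weights \eqn{a_i, b_i} (and, for
#' connected segments, the GC1 ratio \eqn{\lambda_{i-1}}) are optimized by
#' a real-coded genetic algorithm minimizing the per-segment [nmse()].
#'
#' Connected segments are processed left to right: segment \eqn{i+1}'s `B`
#' coefficient is dictated by the GC1 link to the already-fitted segment
#' \eqn{i}, so its free genes are \eqn{(a_{i+1}, b_{i+1}, \lambda_i)}.  On
#' closed boundaries the loop is *not* closed with a GC1 constraint back at
#' the start knot; the first segment's `B` is free.
#'
#' @param segments list of m x 2 data matrices.  When `connected = TRUE`,
#'   the last point of segment i must equal the first point of segment i+1.
#' @param cfg a [ga_config()].
#' @param connected logical: treat segments as one connected boundary
#'   (GC1-coupled) or as independent open segments.
#' @return an object of class `fit_result`: components `chain` (a
#'   [build_chain()] object when connected, else `NULL`), `segments`,
#'   `weights`, `lambdas`, `errors` (per-segment \eqn{E^2}), `params`
#'   (chord parameters per segment), `converged`
#'   (max \eqn{E^2 \le} `target_error`), `generations`, `best_history`.
#' @export
ga_optimize <- function(segments, cfg = ga_config(), connected = TRUE) {
  stopifnot(inherits(cfg, "ga_config"))
  if (!is.list(segments) || length(segments) == 0L) {
    stop("`segments` must be a non-empty list of point matrices",
         call. = FALSE)
  }
  segments <- lapply(segments, as_points)
  k <- length(segments)
  if (connected && k > 1L) {
    for (i in seq_len(k - 1L)) {
      if (vnorm(segments[[i]][nrow(segments[[i]]), ] -
                segments[[i + 1L]][1L, ]) > 0) {
        stop("connected segments must share endpoints (segment ", i,
             " does not meet segment ", i + 1L, ")", call. = FALSE)
      }
    }
  }

  # localize RNG: deterministic under cfg$seed, restore caller state
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  params <- lapply(segments, chord_length_params)
  fitted <- vector("list", k)
  weights <- matrix(NA_real_, k, 2L, dimnames = list(NULL, c("a", "b")))
  lambdas <- numeric(0)
  errors <- numeric(k)
  gens <- integer(k)
  hist <- vector("list", k)

  prev <- NULL  # list(c_pt, b_w) of the previously fitted segment
  for (j in seq_len(k)) {
    pts <- segments[[j]]
    th <- params[[j]]
    f_j <- pts[1L, ]
    coupled <- connected && j > 1L

    make_seg <- function(genes) {
      a_w <- genes[1L]; b_w <- genes[2L]
      if (coupled) {
        b_fix <- link_gc1(f_j, a_w, prev$b_w, genes[3L], prev$c_pt)
        ls <- least_squares_controls(pts, th, a_w, b_w, b_fixed = b_fix)
      } else {
        ls <- least_squares_controls(pts, th, a_w, b_w)
      }
      rational_segment(pts[1L, ], ls$b_pt, ls$c_pt, pts[nrow(pts), ],
                       a_w, b_w)
    }
    fitness <- function(genes) nmse(make_seg(genes), pts, th)

    lower <- rep(cfg$lower, if (coupled) 3L else 2L)
    upper <- if (coupled) c(cfg$a_max, cfg$b_max, cfg$lambda_max) else
      c(cfg$a_max, cfg$b_max)
    res <- run_ga(fitness, lower, upper, cfg)

    fitted[[j]] <- make_seg(res$genes)
    weights[j, ] <- res$genes[1:2]
    if (coupled) lambdas <- c(lambdas, res$genes[3L])
    errors[j] <- res$fitness
    gens[j] <- res$generations
    hist[[j]] <- res$best_history
    prev <- list(c_pt = fitted[[j]]$c_pt, b_w = fitted[[j]]$b_w)
  }

  chain <- NULL
  if (connected) {
    knots <- rbind(segments[[1L]][1L, ],
                   do.call(rbind, lapply(segments, function(p) p[nrow(p), ])))
    chain <- build_chain(knots,
                         do.call(rbind, lapply(fitted, `[[`, "c_pt")),
                         fitted[[1L]]$b_pt, weights, lambdas)
  }
  structure(list(chain = chain, segments = fitted, weights = weights,
                 lambdas = lambdas, errors = errors, params = params,
                 converged = max(errors) <= cfg$target_error,
                 generations = gens, best_history = hist),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("rational Ball curve fit: %d segment(s)\n", length(x$segments)))
  cat(sprintf("  max E^2 = %.3g  (converged: %s)\n",
              max(x$errors), x$converged))
  cat("  generations:", paste(x$generations, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a segmented boundary with a GC1 rational Ball chain
#'
#' Splits an ordered boundary point chain at the given corner indices and
#' fits each piece with [ga_optimize()], returning a single GC1 chain over
#' all segments.  For a closed boundary the chain is rotated so the first
#' corner leads, and the final segment wraps back to it; at least one corner
#' is required to cut the loop.
#'
#' @param points N x 2 matrix of ordered boundary points.
#' @param corner_indices strictly increasing 1-based indices into `points`
#'   at which to split.
#' @param cfg a [ga_config()].
#' @param closed logical: is the boundary a closed loop?
#' @return a `fit_result`; see [ga_optimize()].
#' @export
fit_boundary <- function(points, corner_indices, cfg = ga_config(),
                         closed = TRUE) {
  pts <- as_points(points)
  n <- nrow(pts)
  ci <- as.integer(corner_indices)
  if (length(ci) && (is.unsorted(ci, strictly = TRUE) ||
                     ci[1L] < 1L || ci[length(ci)] > n)) {
    stop("`corner_indices` must be strictly increasing and within range",
         call. = FALSE)
  }
  if (closed) {
    if (length(ci) < 1L) {
      stop("cannot segment a closed boundary without at least one corner",
           call. = FALSE)
    }
    # rotate so the first corner is point 1
    ord <- c(ci[1L]:n, seq_len(ci[1L] - 1L))
    pts <- pts[ord, , drop = FALSE]
    ci <- ci - ci[1L] + 1L
    breaks <- c(ci, n + 1L)  # wrap sentinel
    segs <- lapply(seq_len(length(breaks) - 1L), function(kk) {
      idx <- breaks[kk]:min(breaks[kk + 1L], n)
      seg <- pts[idx, , drop = FALSE]
      if (kk == length(breaks) - 1L) seg <- rbind(seg, pts[1L, ])
      seg
    })
  } else {
    breaks <- sort(unique(c(1L, ci, n)))
    if (length(breaks) < 2L) stop("boundary too short", call. = FALSE)
    segs <- lapply(seq_len(length(breaks) - 1L), function(kk) {
      pts[breaks[kk]:breaks[kk + 1L], , drop = FALSE]
    })
  }
  ga_optimize(segs, cfg, connected = TRUE)
}
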