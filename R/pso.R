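#' Control settings for the SPSO2007 particle swarm optimizer
#'
#' Defaults follow the published SPSO2007 recommendations: swarm size
#' `10 + floor(2 * sqrt(D))`, inertia `w = 1/(2 ln 2)`, acceleration
#' `c = 0.5 + ln 2` for both the cognitive and the social term, and `K = 3`
#' informants per particle, re-drawn after any iteration that fails to
#' improve the swarm best.
#'
#' @param swarm_size number of particles (default `10 + floor(2 sqrt(D))`).
#' @param w inertia weight.
#' @param c_accel acceleration coefficient (cognitive and social).
#' @param k_informants informants drawn per particle.
#' @param max_iter iteration budget.
#' @param max_stagnant stop after this many iterations without improving
#'   the swarm best.
#' @param value_to_reach stop as soon as the best value is <= this.
#' @param seed integer seed; the whole trajectory is reproducible.
#' @param init optional matrix (rows = particles) of positions to seed into
#'   the initial swarm, e.g. a box-center particle.
#' @return a `pso_control` list.
#' @export
pso_control <- function(swarm_size = NULL, w = 1 / (2 * log(2)),
                        c_accel = 0.5 + log(2), k_informants = 3L,
                        max_iter = 100L, max_stagnant = 20L,
                        value_to_reach = -Inf, seed = NULL, init = NULL) {
  ctl <- list(swarm_size = swarm_size, w = w, c_accel = c_accel,
              k_informants = as.integer(k_informants),
              max_iter = as.integer(max_iter),
              max_stagnant = as.integer(max_stagnant),
              value_to_reach = value_to_reach, seed = seed, init = init)
  if (!is.null(swarm_size) && swarm_size < 2L) stop("swarm_size must be >= 2")
  if (ctl$k_informants < 1L || ctl$max_iter < 1L || ctl$max_stagnant < 1L) {
    stop("counts in pso_control must be positive")
  }
  structure(ctl, class = "pso_control")
}

#' Minimize a function with SPSO2007
#'
#' Standard Particle Swarm Optimization (2007 variant): particles move
#' under inertia plus stochastic attraction towards their personal best
#' and the best position among their informants.  Each particle is informed
#' by itself and `k_informants` uniformly drawn particles; the information
#' links are re-drawn after every iteration that does not improve the swarm
#' best.  Positions leaving the box are clamped to the violated bound and
#' the corresponding velocity component is zeroed.
#'
#' @param objective function mapping a length-`D` numeric vector to a
#'   finite value.
#' @param lower,upper box bounds (elementwise `lower < upper`).
#' @param control a [pso_control()] list.
#' @return list with `par` (best position), `value` (best value), `evals`
#'   (objective evaluations), `iterations`, and `trace` (best value after
#'   each iteration, starting with the initial swarm).
#' @examples
#' res <- pso_minimize(function(x) (x - 3)^2, -10, 10,
#'                     pso_control(max_iter = 50, seed = 1))
#' res$par
#' @export
pso_minimize <- function(objective, lower, upper, control = pso_control()) {
  D <- length(lower)
  if (length(upper) != D) stop("lower and upper differ in length")
  if (any(lower > upper)) stop("need lower <= upper elementwise")
  S <- control$swarm_size %||% (10L + floor(2 * sqrt(D)))
  K <- control$k_informants
  w <- control$w
  cc <- control$c_accel

  runner <- function() {
    X <- matrix(stats::runif(S * D, rep(lower, each = S), rep(upper, each = S)),
                nrow = S)
    V <- (matrix(stats::runif(S * D, rep(lower, each = S), rep(upper, each = S)),
                 nrow = S) - X) / 2
    if (!is.null(control$init)) {
      ini <- control$init
      if (is.null(dim(ini))) ini <- matrix(ini, nrow = 1L)
      n_ini <- min(nrow(ini), S)
      X[seq_len(n_ini), ] <- ini[seq_len(n_ini), , drop = FALSE]
    }
    evals <- 0L
    eval_fn <- function(x) {
      v <- objective(x)
      evals <<- evals + 1L
      if (!is.finite(v)) stop("objective returned a non-finite value")
      v
    }
    pval <- numeric(S)
    for (i in seq_len(S)) {
      pval[i] <- tryCatch(eval_fn(X[i, ]), error = function(e) {
        stop("objective failed at initialisation, particle ", i, ": ",
             conditionMessage(e))
      })
    }
    pbest <- X
    gbest_i <- which.min(pval)
    gbest_val <- pval[gbest_i]
    gbest_par <- pbest[gbest_i, ]
    trace <- gbest_val

    draw_links <- function() {
      # links[i, j] TRUE when particle i informs particle j
      links <- diag(TRUE, S)
      for (i in seq_len(S)) {
        links[i, sample.int(S, K, replace = TRUE)] <- TRUE
      }
      links
    }
    links <- draw_links()
    stagnant <- 0L
    iter <- 0L

    while (iter < control$max_iter && stagnant < control$max_stagnant &&
           gbest_val > control$value_to_reach) {
      iter <- iter + 1L
      improved <- FALSE
      for (i in seq_len(S)) {
        inf <- which(links[, i])
        li <- inf[which.min(pval[inf])]
        cog <- stats::runif(D, 0, cc) * (pbest[i, ] - X[i, ])
        if (li == i) {
          V[i, ] <- w * V[i, ] + cog
        } else {
          soc <- stats::runif(D, 0, cc) * (pbest[li, ] - X[i, ])
          V[i, ] <- w * V[i, ] + cog + soc
        }
        X[i, ] <- X[i, ] + V[i, ]
        lo <- X[i, ] < lower
        hi <- X[i, ] > upper
        if (any(lo)) { X[i, lo] <- lower[lo]; V[i, lo] <- 0 }
        if (any(hi)) { X[i, hi] <- upper[hi]; V[i, hi] <- 0 }
        val <- tryCatch(eval_fn(X[i, ]), error = function(e) {
          stop("objective failed at iteration ", iter, ", particle ", i,
               " (position ", paste(signif(X[i, ], 4), collapse = ", "),
               "): ", conditionMessage(e))
        })
        if (val < pval[i]) {
          pval[i] <- val
          pbest[i, ] <- X[i, ]
          if (val < gbest_val) {
            gbest_val <- val
            gbest_par <- X[i, ]
            improved <- TRUE
          }
        }
      }
      trace <- c(trace, gbest_val)
      if (improved) {
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        links <- draw_links()
      }
    }
    list(par = gbest_par, value = gbest_val, evals = evals,
         iterations = iter, trace = trace)
  }

  if (is.null(control$seed)) runner() else withr::with_seed(control$seed, runner())
}
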