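#' Coefficients of the parabolic disposition density
#'
#' The disposition distribution family is the parabola
#' y(x) = a (b - x)^2 + c on `[0, 1]`, pinned down by three conditions: unit
#' integral, y(0) = C1 and y(1) = C2. The symmetric case C2 = C1 is the
#' bimodal start of the forcing schedule (b = 1/2); decreasing C2 tilts the
#' density toward low dispositions until it is quasi-unimodal.
#'
#' The constraints are linear once b is known:
#' a (2b - 1) = C1 - C2 and a (b - 1/3) = C1 - 1, which gives b in closed
#' form; C2 = 2 - C1 (with C1 != 1) is the degenerate linear limit of the
#' family and is rejected.
#'
#' @param C1 density value at x = 0.
#' @param C2 density value at x = 1.
#' @return Named numeric vector `c(a, b, c)`.
#' @export
parabolic_density_params <- function(C1, C2) {
  if (abs(C1 - 1) < 1e-12 && abs(C2 - 1) < 1e-12) {
    coef <- c(a = 0, b = 0.5, c = 1)       # uniform limit
  } else if (abs(C1 - 1) < 1e-12) {
    b <- 1 / 3
    a <- 3 * (C2 - 1)
    coef <- c(a = a, b = b, c = C1 - a * b^2)
  } else {
    r <- (C1 - C2) / (C1 - 1)
    if (abs(2 - r) < 1e-10)
      stop(sprintf("no parabolic density with C1 = %g, C2 = %g (linear limit)",
                   C1, C2), call. = FALSE)
    b <- (1 - r / 3) / (2 - r)
    a <- (C1 - 1) / (b - 1 / 3)
    coef <- c(a = a, b = b, c = C1 - a * b^2)
  }
  if (parabolic_density_min(coef) < -1e-9)
    stop(sprintf("C1 = %g, C2 = %g yield a negative density", C1, C2),
         call. = FALSE)
  coef
}

parabolic_density_min <- function(coef) {
  a <- coef[["a"]]; b <- coef[["b"]]; cc <- coef[["c"]]
  vals <- c(a * b^2 + cc, a * (b - 1)^2 + cc)
  if (b >= 0 && b <= 1) vals <- c(vals, cc)
  min(vals)
}

#' Density, CDF and quantile function of the parabolic family
#'
#' @param x values in `[0, 1]` (for `dparab`/`pparab`) or probabilities (for
#'   `qparab`).
#' @param coef coefficients from [parabolic_density_params()].
#' @return Numeric vector.
#' @export
dparab <- function(x, coef) {
  ifelse(x < 0 | x > 1, 0,
         coef[["a"]] * (coef[["b"]] - x)^2 + coef[["c"]])
}

#' @rdname dparab
#' @export
pparab <- function(x, coef) {
  a <- coef[["a"]]; b <- coef[["b"]]; cc <- coef[["c"]]
  xx <- pmin(pmax(x, 0), 1)
  a * (b^3 - (b - xx)^3) / 3 + cc * xx
}

#' @rdname dparab
#' @export
qparab <- function(x, coef) {
  grid <- seq(0, 1, length.out = 4097)
  fg <- pparab(grid, coef)
  stats::approx(fg, grid, xout = pmin(pmax(x, 0), 1), ties = "ordered",
                rule = 2)$y
}

#' Forcing schedule of the disposition distribution
#'
#' The target density starts symmetric-bimodal (C2(0) = C1) and C2(t) is
#' reduced linearly to `C_f` over `steps` forcing steps, emulating the
#' gradual erosion of normative support for smoking. Defaults: C1 = 2.5
#' (clearly bimodal, density minimum 0.25 > 0), C_f = 0.25, 1000 steps.
#'
#' @param C1 fixed density value at x = 0.
#' @param C_f final density value at x = 1.
#' @param steps number of forcing steps.
#' @return A list of class `forcing_schedule` with the C2 value and the
#'   parabola coefficients for every step 0..steps.
#' @export
forcing_schedule <- function(C1 = 2.5, C_f = 0.25, steps = 1000L) {
  c2 <- C1 + (C_f - C1) * seq(0, steps) / max(steps, 1L)
  coefs <- t(vapply(c2, function(v) parabolic_density_params(C1, v),
                    numeric(3)))
  structure(list(C1 = C1, C_f = C_f, steps = as.integer(steps),
                 C2 = c2, coefficients = coefs),
            class = "forcing_schedule")
}

#' Noise parameters of the stochastic disposition forcing
#'
#' The per-round perturbation of a disposition is a log-normal magnitude
#' (median `step_scale`, log-sd `log_sd`) with deterministic sign toward the
#' local density deficit, linearly weighted by the CDF discrepancy at the
#' agent's own value. Rounds repeat until a one-sample Kolmogorov-Smirnov
#' test against the target density accepts at level `ks_alpha` (0.10, i.e. a
#' 90% significance criterion), or `max_inner_iterations` is reached.
#'
#' @param step_scale median absolute noise step.
#' @param log_sd log-normal shape parameter.
#' @param ks_alpha acceptance level of the KS criterion.
#' @param max_inner_iterations cap on perturbation rounds per time step.
#' @return A list of class `forcing_noise_params`.
#' @export
forcing_noise_params <- function(step_scale = 0.01, log_sd = 0.5,
                                 ks_alpha = 0.10,
                                 max_inner_iterations = 500L) {
  stopifnot(step_scale > 0, log_sd > 0, ks_alpha > 0, ks_alpha < 1,
            max_inner_iterations >= 1)
  structure(list(step_scale = step_scale, log_sd = log_sd,
                 ks_alpha = ks_alpha,
                 max_inner_iterations = as.integer(max_inner_iterations)),
            class = "forcing_noise_params")
}

ks_pvalue <- function(x, coef) {
  suppressWarnings(ks.test(x, function(q) pparab(q, coef))$p.value)
}

#' Draw the initial dispositions
#'
#' Inverse-CDF sampling from the symmetric bimodal density y(x; t = 0); the
#' draw is repeated (fresh uniforms) until the KS criterion at level
#' `ks_alpha` accepts, so the initial sample is itself consistent with the
#' target.
#'
#' @param n number of agents.
#' @param coef parabola coefficients of the initial target.
#' @param noise a [forcing_noise_params()] (for the KS level).
#' @param seed integer seed.
#' @return Numeric vector of n dispositions in `[0, 1]`.
#' @export
sample_initial_dispositions <- function(n, coef = parabolic_density_params(2.5, 2.5),
                                        noise = forcing_noise_params(),
                                        seed = 1L) {
  set.seed(seed)
  for (k in 1:100) {
    g <- qparab(runif(n), coef)
    if (ks_pvalue(g, coef) >= noise$ks_alpha) return(g)
  }
  warning("initial disposition draw did not reach the KS criterion")
  g
}

#' Evolve the dispositions one forcing step
#'
#' Stochastic Markov transformation dragging the previous disposition sample
#' toward the current target density: each value is perturbed by a
#' log-normal magnitude signed and linearly weighted by the signed
#' discrepancy between the empirical and target CDFs at that value (excess
#' empirical mass below a point pushes it up, deficit pushes it down).
#' Values are reflected at 0 and 1 to stay in range without piling up at the
#' bounds. Rounds repeat until the KS criterion accepts the sample as drawn
#' from the target, so the population-level distribution is externally
#' controlled while individual dispositions follow a Markov process.
#'
#' @param previous disposition vector from the previous step.
#' @param coef parabola coefficients of the current target.
#' @param noise a [forcing_noise_params()].
#' @return The updated disposition vector, attribute `iterations` giving the
#'   number of perturbation rounds used.
#' @export
evolve_dispositions <- function(previous, coef, noise = forcing_noise_params()) {
  g <- previous
  n <- length(g)
  it <- 0L
  while (ks_pvalue(g, coef) < noise$ks_alpha) {
    if (it >= noise$max_inner_iterations) {
      warning("disposition forcing: KS criterion not reached within ",
              noise$max_inner_iterations, " rounds")
      break
    }
    # signed CDF discrepancy at each agent's own value; midranks avoid the
    # self-counting bias of the plain empirical CDF
    dev <- (rank(g, ties.method = "average") - 0.5) / n - pparab(g, coef)
    eta <- rlnorm(n, meanlog = log(noise$step_scale), sdlog = noise$log_sd)
    g <- g + eta * dev
    g <- ifelse(g < 0, -g, g)
    g <- ifelse(g > 1, 2 - g, g)
    g <- pmin(pmax(g, 0), 1)
    it <- it + 1L
  }
  attr(g, "iterations") <- it
  g
}

#' Precompute the full disposition path of a run
#'
#' Draws the initial dispositions and applies the forcing schedule step by
#' step, returning the whole path as a matrix. Precomputing the path (on its
#' own random stream) lets every model variant of a run consume the
#' identical forcing realisation.
#'
#' @param n number of agents.
#' @param schedule a [forcing_schedule()].
#' @param noise a [forcing_noise_params()].
#' @param seed integer seed for the disposition stream.
#' @return Numeric matrix of dimension `(steps + 1) x n`; row t + 1 holds the
#'   dispositions after forcing step t.
#' @export
disposition_path <- function(n, schedule = forcing_schedule(),
                             noise = forcing_noise_params(), seed = 1L) {
  stopifnot(inherits(schedule, "forcing_schedule"))
  path <- matrix(NA_real_, schedule$steps + 1L, n)
  path[1L, ] <- sample_initial_dispositions(n, schedule$coefficients[1L, ],
                                            noise, seed = seed)
  if (schedule$steps > 0L) {
    for (t in seq_len(schedule$steps)) {
      g <- evolve_dispositions(path[t, ], schedule$coefficients[t + 1L, ],
                               noise)
      path[t + 1L, ] <- g
    }
  }
  path
}
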