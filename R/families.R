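# Registry of the nine count-distribution families used to describe the
# distribution of satellite-male counts around nesting pairs (and any other
# ordered count data). Each family supplies a pmf on {0, 1, 2, ...}, a
# free-parameter count (as used in the AIC), a method-of-moments starting
# value, and a bijection between the natural parameter scale and an
# unconstrained scale used by the optimizer (log for rates/sizes, logit for
# mixing weights), so that boundary values such as w = 0 or 1 are reached
# smoothly.

.logit <- function(p) stats::qlogis(pmin(pmax(p, 1e-8), 1 - 1e-8))

# truncated-at-zero negative binomial mass for the hurdle family
.dnbinom_pos <- function(x, size, mu) {
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  ifelse(x >= 1, stats::dnbinom(x, size = size, mu = mu) / (1 - p0), 0)
}

.family_defs <- local({
  defs <- list(
    Poisson = list(
      n_params = 1L, par_names = "lambda",
      pmf = function(x, th) stats::dpois(x, th[1]),
      to_nat = function(u) exp(u), to_unc = function(th) log(th),
      check = function(th) th[1] > 0,
      start = function(m, v, p0, p1) c(lambda = max(m, 1e-3))
    ),
    NegBin = list(
      n_params = 2L, par_names = c("size", "mu"),
      pmf = function(x, th) stats::dnbinom(x, size = th[1], mu = th[2]),
      to_nat = function(u) exp(u), to_unc = function(th) log(th),
      check = function(th) all(th > 0),
      start = function(m, v, p0, p1) {
        size <- if (v > m * 1.001) m^2 / (v - m) else 20
        c(size = size, mu = max(m, 1e-3))
      }
    ),
    ZIPoiss = list(
      n_params = 2L, par_names = c("w", "lambda"),
      pmf = function(x, th) th[1] * (x == 0) + (1 - th[1]) * stats::dpois(x, th[2]),
      to_nat = function(u) c(stats::plogis(u[1]), exp(u[2])),
      to_unc = function(th) c(.logit(th[1]), log(th[2])),
      check = function(th) th[1] >= 0 && th[1] <= 1 && th[2] > 0,
      start = function(m, v, p0, p1) {
        w <- min(max(p0 / 2, 0.02), 0.9)
        c(w = w, lambda = max(m / (1 - w), 1e-3))
      }
    ),
    ZINegBi = list(
      n_params = 3L, par_names = c("w", "size", "mu"),
      pmf = function(x, th) th[1] * (x == 0) +
        (1 - th[1]) * stats::dnbinom(x, size = th[2], mu = th[3]),
      to_nat = function(u) c(stats::plogis(u[1]), exp(u[2]), exp(u[3])),
      to_unc = function(th) c(.logit(th[1]), log(th[2]), log(th[3])),
      check = function(th) th[1] >= 0 && th[1] <= 1 && all(th[2:3] > 0),
      start = function(m, v, p0, p1) {
        size <- if (v > m * 1.001) m^2 / (v - m) else 20
        c(w = min(max(p0 / 2, 0.02), 0.9), size = size, mu = max(m, 1e-3))
      }
    ),
    HurdNBi = list(
      n_params = 3L, par_names = c("p0", "size", "mu"),
      pmf = function(x, th) ifelse(x == 0, th[1],
        (1 - th[1]) * .dnbinom_pos(x, th[2], th[3])),
      to_nat = function(u) c(stats::plogis(u[1]), exp(u[2]), exp(u[3])),
      to_unc = function(th) c(.logit(th[1]), log(th[2]), log(th[3])),
      check = function(th) th[1] >= 0 && th[1] <= 1 && all(th[2:3] > 0),
      start = function(m, v, p0, p1) {
        size <- if (v > m * 1.001) m^2 / (v - m) else 20
        c(p0 = min(max(p0, 0.02), 0.95), size = size, mu = max(m, 1e-3))
      }
    ),
    PoisNB = list(
      n_params = 4L, par_names = c("w", "lambda", "size", "mu"),
      pmf = function(x, th) th[1] * stats::dpois(x, th[2]) +
        (1 - th[1]) * stats::dnbinom(x, size = th[3], mu = th[4]),
      to_nat = function(u) c(stats::plogis(u[1]), exp(u[2]), exp(u[3]), exp(u[4])),
      to_unc = function(th) c(.logit(th[1]), log(th[2]), log(th[3]), log(th[4])),
      check = function(th) th[1] >= 0 && th[1] <= 1 && all(th[2:4] > 0),
      start = function(m, v, p0, p1)
        c(w = 0.5, lambda = max(0.6 * m, 1e-3), size = 5, mu = max(1.4 * m, 1e-3))
    ),
    # Same mixture family with the weight attached to the negative-binomial
    # component; maximum-likelihood-equivalent to PoisNB but kept as its own
    # registry entry (distinct name and starting values).
    NBPois = list(
      n_params = 4L, par_names = c("w", "size", "mu", "lambda"),
      pmf = function(x, th) th[1] * stats::dnbinom(x, size = th[2], mu = th[3]) +
        (1 - th[1]) * stats::dpois(x, th[4]),
      to_nat = function(u) c(stats::plogis(u[1]), exp(u[2]), exp(u[3]), exp(u[4])),
      to_unc = function(th) c(.logit(th[1]), log(th[2]), log(th[3]), log(th[4])),
      check = function(th) th[1] >= 0 && th[1] <= 1 && all(th[2:4] > 0),
      start = function(m, v, p0, p1)
        c(w = 0.5, size = 5, mu = max(0.6 * m, 1e-3), lambda = max(1.4 * m, 1e-3))
    ),
    OIPoiss = list(
      n_params = 2L, par_names = c("w", "lambda"),
      pmf = function(x, th) th[1] * (x == 1) + (1 - th[1]) * stats::dpois(x, th[2]),
      to_nat = function(u) c(stats::plogis(u[1]), exp(u[2])),
      to_unc = function(th) c(.logit(th[1]), log(th[2])),
      check = function(th) th[1] >= 0 && th[1] <= 1 && th[2] > 0,
      start = function(m, v, p0, p1)
        c(w = min(max(p1 / 2, 0.02), 0.9), lambda = max(m, 1e-3))
    ),
    OINegBi = list(
      n_params = 3L, par_names = c("w", "size", "mu"),
      pmf = function(x, th) th[1] * (x == 1) +
        (1 - th[1]) * stats::dnbinom(x, size = th[2], mu = th[3]),
      to_nat = function(u) c(stats::plogis(u[1]), exp(u[2]), exp(u[3])),
      to_unc = function(th) c(.logit(th[1]), log(th[2]), log(th[3])),
      check = function(th) th[1] >= 0 && th[1] <= 1 && all(th[2:3] > 0),
      start = function(m, v, p0, p1) {
        size <- if (v > m * 1.001) m^2 / (v - m) else 20
        c(w = min(max(p1 / 2, 0.02), 0.9), size = size, mu = max(m, 1e-3))
      }
    )
  )
  for (nm in names(defs)) defs[[nm]]$name <- nm
  defs
})

#' Names of the available count-model families
#'
#' The nine families form the default candidate set for satellite-male count
#' data: Poisson, negative binomial, zero-inflated Poisson and negative
#' binomial, a hurdle negative binomial, two Poisson/negative-binomial
#' two-component mixtures, and one-inflated Poisson and negative binomial.
#'
#' @return Character vector of the registered family names.
#' @export
#' @examples
#' model_families()
model_families <- function() names(.family_defs)

#' Look up a count-model family
#'
#' @param family A family name (see [model_families()]) or a family object
#'   returned by a previous call.
#' @return A list with elements `name`, `n_params`, `par_names`, and `pmf`
#'   (a function of a nonnegative integer vector and a parameter vector).
#' @export
#' @examples
#' fam <- get_family("Poisson")
#' fam$pmf(0:3, 1.5)
get_family <- function(family) {
  if (is.list(family) && !is.null(family$pmf)) return(family)
  if (!is.character(family) || length(family) != 1 || !family %in% names(.family_defs))
    stop("unknown model family '", paste(family, collapse = ","),
         "'; valid names: ", paste(names(.family_defs), collapse = ", "))
  .family_defs[[family]]
}

.check_theta <- function(fam, theta) {
  if (length(theta) != fam$n_params)
    stop(fam$name, " expects ", fam$n_params, " parameters, got ", length(theta))
  if (any(!is.finite(theta)) || !fam$check(theta))
    stop("invalid parameter vector for ", fam$name, ": ",
         paste(signif(theta, 6), collapse = ", "))
  invisible(TRUE)
}
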