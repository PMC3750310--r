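#' Fitted input/output distributions
#'
#' The Monte Carlo engine works with a small family of distributions: the
#' lognormal (the family reported as best-fitting for every simulated
#' exposure model), the degenerate point mass (a constant input, the
#' `sigma = 0` limit), and a Bernoulli-lognormal mixture that places a
#' point mass at exactly zero (non-consumers / non-smokers) alongside a
#' lognormal positive part.
#'
#' Two parameterizations are supported:
#'
#' * `lognormal_from_moments(mean, std)` — method of moments:
#'   `sigma^2 = log(1 + (std/mean)^2)`, `mu = log(mean) - sigma^2/2`.
#'   `std = 0` degenerates to a point mass at `mean`. This is the default
#'   route for per-food inputs, whose summary tables print mean and
#'   standard deviation.
#' * `lognormal_from_mean_median(mean, median)` — inverts the printed mean
#'   and median of a lognormal: `mu = log(median)`,
#'   `sigma = sqrt(2 * log(mean/median))`. This is the route for
#'   reconstructing *reported* simulation output distributions, which are
#'   published as mean/median pairs. Requires `mean >= median` (forced by
#'   the lognormal's shape); equality degenerates to a point mass.
#'
#' @param mean Distribution mean; must be positive.
#' @param std Standard deviation; must be non-negative.
#' @param median Distribution median; `0 < median <= mean`.
#' @return A `cad_dist` object with fields `family` (`"lognormal"`,
#'   `"point_mass"` or `"bernoulli_lognormal_mixture"`), `mu`, `sigma`,
#'   `mix_p` (mixture only: probability of the positive lognormal
#'   component) and `provenance` (`"from_moments"`, `"from_mean_median"`
#'   or `"direct"`).
#' @seealso [dist_cdf()], [dist_quantile()], [dist_sample()].
#' @export
#' @examples
#' d <- lognormal_from_mean_median(23.05, 18.24)
#' dist_cdf(d, 49.5) # ~0.928: below-PTDI probability of this model
lognormal_from_moments <- function(mean, std) {
  if (!is.finite(mean) || mean <= 0) {
    stop_domain("lognormal_from_moments: mean must be positive")
  }
  if (!is.finite(std) || std < 0) {
    stop_domain("lognormal_from_moments: std must be non-negative")
  }
  if (std == 0) {
    return(point_mass(mean, provenance = "from_moments"))
  }
  sigma2 <- log(1 + (std / mean)^2)
  new_cad_dist("lognormal", mu = log(mean) - sigma2 / 2,
               sigma = sqrt(sigma2), provenance = "from_moments")
}

#' @rdname lognormal_from_moments
#' @export
lognormal_from_mean_median <- function(mean, median) {
  if (!is.finite(median) || median <= 0) {
    stop_domain("lognormal_from_mean_median: median must be positive")
  }
  if (!is.finite(mean) || mean < median) {
    stop_domain("lognormal_from_mean_median: mean must be >= median ",
                "(a lognormal's mean never falls below its median)")
  }
  if (mean == median) {
    return(point_mass(mean, provenance = "from_mean_median"))
  }
  new_cad_dist("lognormal", mu = log(median),
               sigma = sqrt(2 * log(mean / median)),
               provenance = "from_mean_median")
}

#' @rdname lognormal_from_moments
#' @param value Location of the point mass; must be positive.
#' @param provenance Parameterization provenance tag.
#' @export
point_mass <- function(value, provenance = "direct") {
  if (!is.finite(value) || value <= 0) {
    stop_domain("point_mass: value must be positive")
  }
  new_cad_dist("point_mass", mu = log(value), sigma = 0,
               provenance = provenance)
}

#' @rdname lognormal_from_moments
#' @param p_positive Probability of the positive lognormal component; the
#'   complementary mass sits exactly at zero.
#' @param positive A lognormal `cad_dist` for the positive part.
#' @export
zero_inflated <- function(p_positive, positive) {
  if (!is.finite(p_positive) || p_positive < 0 || p_positive > 1) {
    stop_domain("zero_inflated: p_positive must lie in [0, 1]")
  }
  stopifnot(inherits(positive, "cad_dist"))
  if (positive$family == "bernoulli_lognormal_mixture") {
    stop_domain("zero_inflated: cannot nest mixtures")
  }
  new_cad_dist("bernoulli_lognormal_mixture", mu = positive$mu,
               sigma = positive$sigma, mix_p = p_positive,
               provenance = positive$provenance)
}

new_cad_dist <- function(family, mu, sigma, mix_p = NA_real_,
                         provenance = "direct") {
  structure(list(family = family, mu = mu, sigma = sigma, mix_p = mix_p,
                 provenance = provenance),
            class = "cad_dist")
}

#' @export
print.cad_dist <- function(x, ...) {
  cat(sprintf("<cad_dist %s: mu=%.4f sigma=%.4f%s (%s)>\n", x$family,
              x$mu, x$sigma,
              if (!is.na(x$mix_p)) sprintf(" mix_p=%.3f", x$mix_p) else "",
              x$provenance))
  invisible(x)
}

#' Distribution functionals
#'
#' Cumulative distribution function, quantile function, analytic mean and
#' standard deviation, and random sampling for `cad_dist` objects. For the
#' zero-inflated mixture the CDF is `(1 - mix_p) + mix_p * F_lognormal(x)`
#' for `x >= 0`, and quantiles below the zero mass return 0.
#'
#' @param dist A `cad_dist`.
#' @param x Evaluation point(s), `>= 0`.
#' @param p Probability(ies) in (0, 1).
#' @param n Number of draws.
#' @return `dist_cdf()`: probabilities; `dist_quantile()`: values;
#'   `dist_mean()`/`dist_sd()`: scalars; `dist_sample()`: a numeric vector
#'   of length `n`.
#' @export
dist_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "cad_dist"))
  if (any(x < 0)) {
    stop_domain("dist_cdf: x must be non-negative")
  }
  switch(dist$family,
    lognormal = stats::plnorm(x, dist$mu, dist$sigma),
    # tolerate exp(log(v)) float round-trip at the atom
    point_mass = as.numeric(x >= exp(dist$mu) * (1 - 1e-12)),
    bernoulli_lognormal_mixture =
      (1 - dist$mix_p) + dist$mix_p * stats::plnorm(x, dist$mu, dist$sigma)
  )
}

#' @rdname dist_cdf
#' @export
dist_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "cad_dist"))
  if (any(p <= 0 | p >= 1)) {
    stop_domain("dist_quantile: p must lie strictly in (0, 1)")
  }
  switch(dist$family,
    lognormal = stats::qlnorm(p, dist$mu, dist$sigma),
    point_mass = rep(exp(dist$mu), length(p)),
    bernoulli_lognormal_mixture = {
      out <- numeric(length(p))
      hi <- p > (1 - dist$mix_p)
      out[hi] <- stats::qlnorm((p[hi] - (1 - dist$mix_p)) / dist$mix_p,
                               dist$mu, dist$sigma)
      out
    }
  )
}

#' @rdname dist_cdf
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "cad_dist"))
  m <- exp(dist$mu + dist$sigma^2 / 2)
  if (dist$family == "bernoulli_lognormal_mixture") dist$mix_p * m else m
}

#' @rdname dist_cdf
#' @export
dist_sd <- function(dist) {
  stopifnot(inherits(dist, "cad_dist"))
  m <- exp(dist$mu + dist$sigma^2 / 2)
  v <- m^2 * (exp(dist$sigma^2) - 1)
  if (dist$family == "bernoulli_lognormal_mixture") {
    p <- dist$mix_p
    v <- p * (v + m^2) - (p * m)^2
  }
  sqrt(v)
}

#' @rdname dist_cdf
#' @export
dist_sample <- function(dist, n) {
  stopifnot(inherits(dist, "cad_dist"))
  if (n < 1) {
    stop_domain("dist_sample: n must be >= 1")
  }
  switch(dist$family,
    lognormal = stats::rlnorm(n, dist$mu, dist$sigma),
    point_mass = rep(exp(dist$mu), n),
    bernoulli_lognormal_mixture =
      stats::rbinom(n, 1L, dist$mix_p) *
        stats::rlnorm(n, dist$mu, dist$sigma)
  )
}

#' Serialize distributions to and from JSON
#'
#' Distributions serialize as `{family, mu, sigma, mix_p, provenance}`.
#' `dist_to_json()` returns a JSON string; `dist_from_json()` inverts it.
#'
#' @param dist A `cad_dist`.
#' @param json A JSON string produced by `dist_to_json()`.
#' @return A JSON string / a `cad_dist`.
#' @export
dist_to_json <- function(dist) {
  stopifnot(inherits(dist, "cad_dist"))
  jsonlite::toJSON(unclass(dist), auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname dist_to_json
#' @export
dist_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_cad_dist(x$family, mu = x$mu, sigma = x$sigma,
               mix_p = if (is.null(x$mix_p)) NA_real_ else x$mix_p,
               provenance = x$provenance)
}
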