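# Internal numeric helpers shared across modules.

# Round half away from zero (report convention; base round() is half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# nm^2 -> um^2 and nm^3 -> um^3
nm2_to_um2 <- function(x) x * 1e-6
nm3_to_um3 <- function(x) x * 1e-9

#' Truncated-normal sampler (inverse CDF)
#'
#' @param n number of draws
#' @param mean,sd parent normal parameters
#' @param lower,upper truncation bounds
#' @param stratified if TRUE, use one stratified (jittered, permuted) uniform
#'   per draw instead of iid uniforms; the marginal distribution is unchanged
#'   but the Monte-Carlo error of the sample mean is much reduced.
#' @return numeric vector of draws in (lower, upper)
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                       stratified = FALSE) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- if (stratified && n > 1) {
    sample((seq_len(n) - stats::runif(n)) / n)
  } else {
    stats::runif(n)
  }
  stats::qnorm(pl + u * (pu - pl), mean, sd)
}

# Mean of a normal(mu, sd) truncated to [lower, upper]. When the location is
# so far outside the interval that the normalising mass underflows, the
# truncated distribution collapses onto the nearer bound.
tnorm_mean <- function(mu, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  m <- mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  if (!is.finite(m) || z < 1e-14)
    m <- if (abs(mu - lower) < abs(mu - upper)) lower else upper
  min(max(m, lower), upper)
}

# Solve for the parent-normal location mu such that the truncated normal has
# the requested mean. Truncation shifts the mean (markedly so when the target
# is within ~1 SD of a bound), so sampling at the published location would
# bias the cohort; this keeps calibrated means honest.
match_tnorm_mu <- function(target_mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(target_mean)
  f <- function(mu) tnorm_mean(mu, sd, lower, upper) - target_mean
  span <- max(6 * sd, abs(target_mean) + 1)
  stats::uniroot(f, c(target_mean - span, target_mean + span),
                 tol = 1e-10)$root
}

# Mean of round(TN(mu, sd, lower, upper)) for count-valued draws.
dtnorm_round_mean <- function(mu, sd, lower = 0, upper = Inf) {
  hi <- ceiling(max(mu + 8 * sd, lower + 1))
  k <- seq(max(0, floor(lower)), hi)
  pl <- stats::pnorm(lower, mu, sd)
  pu <- stats::pnorm(upper, mu, sd)
  z <- pu - pl
  lo_edge <- pmax(k - 0.5, lower)
  hi_edge <- pmin(k + 0.5, upper)
  p <- (stats::pnorm(hi_edge, mu, sd) - stats::pnorm(lo_edge, mu, sd)) / z
  p[p < 0] <- 0
  sum(k * p)
}

# Location parameter so that rounded truncated-normal counts hit target_mean.
match_count_mu <- function(target_mean, sd, lower = 0, upper = Inf) {
  if (sd <= 0) return(target_mean)
  f <- function(mu) dtnorm_round_mean(mu, sd, lower, upper) - target_mean
  span <- max(6 * sd, abs(target_mean) + 1)
  lo <- target_mean - span
  stats::uniroot(f, c(lo, target_mean + span), tol = 1e-8)$root
}

# Integer counts with calibrated mean: stratified truncated normal, rounded.
rcount_calibrated <- function(n, target_mean, sd, lower = 0, upper = Inf,
                              stratified = TRUE) {
  if (sd <= 0) return(rep(round(max(target_mean, lower)), n))
  mu <- match_count_mu(target_mean, sd, lower, upper)
  pmax(round(rtruncnorm(n, mu, sd, lower, upper, stratified = stratified)),
       ceiling(lower))
}

# Continuous draws with calibrated post-truncation mean.
rpos_calibrated <- function(n, target_mean, sd, lower = 0, upper = Inf,
                            stratified = TRUE) {
  if (sd <= 0) return(rep(min(max(target_mean, lower), upper), n))
  mu <- match_tnorm_mu(target_mean, sd, lower, upper)
  rtruncnorm(n, mu, sd, lower, upper, stratified = stratified)
}

# Uniform directions within a cone of half-angle theta about unit axis u.
runif_cone <- function(n, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  cosa <- stats::runif(n, cos(theta), 1)
  sina <- sqrt(pmax(0, 1 - cosa^2))
  phi <- stats::runif(n, 0, 2 * pi)
  # local frame around axis
  a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(
    cosa * axis[1] + sina * (cos(phi) * e1[1] + sin(phi) * e2[1]),
    cosa * axis[2] + sina * (cos(phi) * e1[2] + sin(phi) * e2[2]),
    cosa * axis[3] + sina * (cos(phi) * e1[3] + sin(phi) * e2[3])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
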