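# Graded response model substrate.
#
# Boundary ("operating characteristic") curves: P(X >= k | theta) =
# plogis(a * (theta - b_k)), k = 1..K-1, with P(X >= 1-0) = 1 and
# P(X >= K+ ) = 0. Category probabilities are consecutive differences.
# All scoring runs on flat (a, b_lo, b_hi) triples, one per recorded
# response, vectorised over theta.

#' Normal prior specification for latent-state scoring
#'
#' @param mean Prior mean (default 0, the norming-population mean).
#' @param sd Prior standard deviation (default 1.0).
#' @export
prior_spec <- function(mean = 0, sd = 1.0) {
  if (!is_scalar_number(sd) || sd <= 0) {
    stop_jita("prior `sd` must be positive", "jitaema_argument_error")
  }
  structure(list(mean = mean, sd = sd), class = "prior_spec")
}

#' Latent-state estimate with its standard error
#'
#' @param theta Point estimate (latent z units).
#' @param se Standard error of measurement; positive.
#' @param n_items Number of items the estimate is based on.
#' @param method Scoring method; `"map"`.
#' @export
theta_estimate <- function(theta, se, n_items, method = "map") {
  if (!is_scalar_number(se) || se <= 0) {
    stop_jita("`se` must be positive", "jitaema_argument_error")
  }
  structure(list(theta = theta, se = se, n_items = as.integer(n_items),
                 method = method),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("<theta_estimate> theta = %.4f (se = %.4f), %d item(s), %s\n",
              x$theta, x$se, x$n_items, x$method))
  invisible(x)
}

# ---- internal triple machinery ---------------------------------------------

# Response (item idx, category k) -> (a, b_lo, b_hi); b_lo = -Inf at k = 1,
# b_hi = +Inf at k = K.
resp_triples <- function(pars, idx, cats) {
  n <- length(idx)
  if (n == 0L) {
    return(list(a = numeric(0), blo = numeric(0), bhi = numeric(0)))
  }
  K <- pars$K[idx]
  if (any(cats < 1L | cats > K)) {
    bad <- which(cats < 1L | cats > K)[1]
    stop_jita(sprintf("category %d out of range 1..%d for item '%s'",
                      cats[bad], K[bad], pars$ids[idx[bad]]),
              "jitaema_argument_error")
  }
  blo <- ifelse(cats == 1L, -Inf, pars$b[cbind(idx, pmax(cats - 1L, 1L))])
  bhi <- ifelse(cats == K, Inf, pars$b[cbind(idx, pmin(cats, K - 1L))])
  list(a = pars$a[idx], blo = blo, bhi = bhi)
}

# Stable category probability u - v where u = plogis(a(theta - blo)),
# v = plogis(a(theta - bhi)); complement form when both logits are positive
# (branchless select; xu = +Inf and xv = -Inf never co-occur since K >= 2).
grm_prob <- function(a, blo, bhi, theta) {
  xu <- a * (theta - blo)
  xv <- a * (theta - bhi)
  direct <- stats::plogis(xu) - stats::plogis(xv)
  compl <- stats::plogis(-xv) - stats::plogis(-xu)
  sel <- (xu + xv) > 0
  p <- compl * sel + direct * !sel
  p[p < 1e-300] <- 1e-300
  p
}

# Per-response score (d log P / d theta) and curvature (d2 log P / d theta2)
# contributions, vectorised over theta.
grm_score_terms <- function(a, blo, bhi, theta) {
  xu <- a * (theta - blo)
  xv <- a * (theta - bhi)
  u <- stats::plogis(xu); v <- stats::plogis(xv)
  mu <- stats::plogis(-xu); mv <- stats::plogis(-xv)
  wu <- u * mu   # u(1-u), accurate in the tails
  wv <- v * mv
  sel <- (xu + xv) > 0
  P <- (mv - mu) * sel + (u - v) * !sel
  P[P < 1e-300] <- 1e-300
  dP <- a * (wu - wv)
  d2P <- a * a * (wu * (1 - 2 * u) - wv * (1 - 2 * v))
  r <- dP / P
  list(score = r, curv = d2P / P - r * r)
}

# Sum score/curvature over a base response set (common triples) plus an
# optional elementwise extra response (one per theta element; used by MEI).
posterior_score <- function(base, theta, prior, extra = NULL) {
  s <- (prior$mean - theta) / prior$sd^2
  h <- rep_len(-1 / prior$sd^2, length(theta))
  for (j in seq_along(base$a)) {
    t <- grm_score_terms(base$a[j], base$blo[j], base$bhi[j], theta)
    s <- s + t$score
    h <- h + t$curv
  }
  if (!is.null(extra)) {
    t <- grm_score_terms(extra$a, extra$blo, extra$bhi, theta)
    s <- s + t$score
    h <- h + t$curv
  }
  list(score = s, hess = h)
}

# Damped Newton ascent of the (strictly concave) log posterior on [-6, 6],
# vectorised over independent problems that share `base` triples.
map_newton <- function(base, prior, extra = NULL, start = NULL, m = 1L,
                       tol = 1e-9, max_iter = 80L) {
  theta <- rep_len(if (is.null(start)) prior$mean else start, m)
  theta <- clamp(theta, -6, 6)
  for (iter in seq_len(max_iter)) {
    sh <- posterior_score(base, theta, prior, extra)
    step <- sh$score / pmax(-sh$hess, 1e-12)
    step <- clamp(step, -1.5, 1.5)  # trust region against tail overshoot
    new_theta <- clamp(theta + step, -6, 6)
    moved <- abs(new_theta - theta)
    theta <- new_theta
    at_bound <- (theta <= -6 & sh$score < 0) | (theta >= 6 & sh$score > 0)
    if (all(moved < tol | at_bound)) break
  }
  theta
}

# Fisher information of item `idx` (bank parameter table) at theta (vector).
# All K categories in one sweep over the boundary-curve matrix.
item_info_pars <- function(pars, idx, theta) {
  K <- pars$K[idx]
  a <- pars$a[idx]
  b <- pars$b[idx, seq_len(K - 1L)]
  m <- length(theta)
  x <- a * (rep(theta, times = K - 1L) - rep(b, each = m))  # m x (K-1) logits
  u <- stats::plogis(x)
  mu <- stats::plogis(-x)
  w <- u * mu
  dim(x) <- dim(u) <- dim(mu) <- dim(w) <- c(m, K - 1L)
  # boundary columns: P(X >= 1-0) = 1 (w = 0), P(X >= K+) = 0 (w = 0)
  x_lo <- cbind(Inf, x); x_hi <- cbind(x, -Inf)
  u_lo <- cbind(1, u); u_hi <- cbind(u, 0)
  m_lo <- cbind(0, mu); m_hi <- cbind(mu, 1)
  w_lo <- cbind(0, w); w_hi <- cbind(w, 0)
  sel <- (x_lo + x_hi) > 0
  P <- (m_hi - m_lo) * sel + (u_lo - u_hi) * !sel
  P[P < 1e-300] <- 1e-300
  dP <- a * (w_lo - w_hi)
  rowSums(dP * dP / P)
}

as_resp_df <- function(responses) {
  if (is.null(responses) || (is.data.frame(responses) && nrow(responses) == 0L)) {
    return(data.frame(item_id = character(0), category = integer(0)))
  }
  if (!is.data.frame(responses) ||
      !all(c("item_id", "category") %in% names(responses))) {
    stop_jita("`responses` must be a data.frame with columns item_id, category",
              "jitaema_argument_error")
  }
  responses
}

resp_idx <- function(pars, responses) {
  idx <- match(as.character(responses$item_id), pars$ids)
  if (anyNA(idx)) {
    stop_jita(sprintf("unknown item_id(s): %s",
                      paste(responses$item_id[is.na(idx)], collapse = ", ")),
              "jitaema_argument_error")
  }
  idx
}

# ---- exported operations ---------------------------------------------------

#' GRM category response probabilities
#'
#' Probability of each ordered response category given the latent state.
#'
#' @param item A [item()].
#' @param theta Latent state (scalar or vector, z units).
#' @return For scalar `theta`, a probability vector of length `K` summing to
#'   one; for vector `theta`, a `length(theta) x K` matrix.
#' @examples
#' category_probabilities(item("i", 2, c(-0.5, 0.5)), 0)
#' @export
category_probabilities <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  K <- item$n_categories
  b <- item$thresholds
  out <- sapply(seq_len(K), function(k) {
    blo <- if (k == 1L) -Inf else b[k - 1L]
    bhi <- if (k == K) Inf else b[k]
    grm_prob(item$discrimination, blo, bhi, theta)
  })
  if (length(theta) == 1L) as.numeric(out) else out
}

#' GRM item (Fisher) information
#'
#' \eqn{I(\theta) = \sum_k P_k'(\theta)^2 / P_k(\theta)} over the category
#' probabilities; nonnegative and vanishing as \eqn{|\theta| \to \infty}.
#'
#' @inheritParams category_probabilities
#' @return Information, same length as `theta`.
#' @export
item_information <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  pars <- bank_params(item_bank(list(item)))
  item_info_pars(pars, 1L, theta)
}

#' Log posterior of the latent state given responses
#'
#' Sum of GRM log category probabilities plus the log normal prior density.
#'
#' @param bank An [item_bank()].
#' @param responses Data frame with columns `item_id`, `category` (1-based);
#'   zero rows allowed (prior only).
#' @param theta Latent state value(s) at which to evaluate.
#' @param prior A [prior_spec()].
#' @return Numeric vector, same length as `theta`.
#' @export
log_posterior <- function(bank, responses, theta, prior = prior_spec()) {
  stopifnot(inherits(bank, "item_bank"), inherits(prior, "prior_spec"))
  responses <- as_resp_df(responses)
  pars <- bank_params(bank)
  idx <- resp_idx(pars, responses)
  tr <- resp_triples(pars, idx, as.integer(responses$category))
  lp <- stats::dnorm(theta, prior$mean, prior$sd, log = TRUE)
  for (j in seq_along(tr$a)) {
    lp <- lp + log(grm_prob(tr$a[j], tr$blo[j], tr$bhi[j], theta))
  }
  lp
}

#' Maximum a posteriori (MAP) latent-state estimate
#'
#' Locates the posterior mode on \[-6, 6\] and reports the standard error of
#' measurement as the inverse square root of (prior precision + summed item
#' Fisher information at the mode). With no responses the estimate is the
#' prior mean with `se = prior sd`.
#'
#' @inheritParams log_posterior
#' @return A [theta_estimate()].
#' @examples
#' b <- generate_synthetic_bank(seed = 1)
#' estimate_map(b, data.frame(item_id = "item01", category = 4L))
#' @export
estimate_map <- function(bank, responses, prior = prior_spec()) {
  stopifnot(inherits(bank, "item_bank"), inherits(prior, "prior_spec"))
  responses <- as_resp_df(responses)
  if (nrow(responses) == 0L) {
    return(theta_estimate(prior$mean, prior$sd, 0L))
  }
  pars <- bank_params(bank)
  idx <- resp_idx(pars, responses)
  tr <- resp_triples(pars, idx, as.integer(responses$category))
  theta <- map_newton(tr, prior)
  info <- 1 / prior$sd^2
  for (i in idx) info <- info + item_info_pars(pars, i, theta)
  theta_estimate(theta, 1 / sqrt(info), nrow(responses))
}

# Deterministic inverse-CDF response given a uniform draw; the keyed-stream
# device that lets simulation conditions share answers at matched prompts.
# P(X <= k) = plogis(-a (theta - b_k)), increasing in k.
response_from_uniform <- function(item, theta, u) {
  cdf <- stats::plogis(-item$discrimination * (theta - item$thresholds))
  1L + sum(u > cdf)
}

#' Simulate a GRM item response
#'
#' Draws a response category from [category_probabilities()] using R's
#' global random number stream (reproducible via [set.seed()]).
#'
#' @inheritParams category_probabilities
#' @return Integer category in `1..K`.
#' @export
sample_response <- function(item, theta) {
  response_from_uniform(item, theta, stats::runif(1))
}
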