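# Shared fixtures, built in code.

# Default 13-item, 5-category synthetic bank used across tests.
test_bank <- function(seed = 42L) generate_synthetic_bank(seed = seed)

# Tiny handmade 3-item bank with known parameters.
tiny_bank <- function() {
  item_bank(list(
    item("easy", 2.0, c(-1.5, -0.5, 0.5, 1.5)),
    item("mid", 1.5, c(-0.5, 0.0, 0.5, 1.0)),
    item("hard", 3.0, c(0.5, 1.0, 1.5, 2.0))
  ), name = "tiny")
}

# Independent GRM category probability oracle (direct logistic differences),
# written separately from the package's stable-difference implementation.
oracle_cat_probs <- function(a, b, theta) {
  pstar <- c(1, 1 / (1 + exp(-a * (theta - b))), 0)
  pstar[-length(pstar)] - pstar[-1]
}

# Independent log-posterior oracle: sum of log oracle probabilities plus
# log normal prior density.
oracle_log_post <- function(bank, items, cats, theta, mean = 0, sd = 1) {
  lp <- dnorm(theta, mean, sd, log = TRUE)
  for (j in seq_along(items)) {
    it <- get_item(bank, items[j])
    lp <- lp + log(oracle_cat_probs(it$discrimination, it$thresholds, theta)[cats[j]])
  }
  lp
}

# Independent MAP oracle: stats::optimize on the oracle log posterior.
oracle_map <- function(bank, items, cats, mean = 0, sd = 1) {
  optimize(function(th) oracle_log_post(bank, items, cats, th, mean, sd),
           c(-6, 6), maximum = TRUE, tol = 1e-9)$maximum
}

# A responder that answers from a fixed true theta using the global RNG.
theta_responder <- function(bank, theta) {
  function(item_id) sample_response(get_item(bank, item_id), theta)
}

# Brute-force MEI oracle, independent of the engine: per candidate, for
# every category, refit the MAP with stats::optimize on the test's own log
# posterior and weight the candidate's information (computed from finite
# differences of oracle probabilities) by predictive probabilities.
oracle_mei <- function(bank, admin_items, admin_cats, sel_theta, cand_id) {
  it <- get_item(bank, cand_id)
  a <- it$discrimination; b <- it$thresholds
  p_pred <- oracle_cat_probs(a, b, sel_theta)
  info_at <- function(th) {
    eps <- 1e-6
    dP <- (oracle_cat_probs(a, b, th + eps) - oracle_cat_probs(a, b, th - eps)) / (2 * eps)
    sum(dP^2 / oracle_cat_probs(a, b, th))
  }
  sum(vapply(seq_len(it$n_categories), function(k) {
    th_k <- oracle_map(bank, c(admin_items, cand_id), c(admin_cats, k))
    p_pred[k] * info_at(th_k)
  }, 0))
}
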