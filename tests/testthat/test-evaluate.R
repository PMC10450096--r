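# Build a minimal record table for evaluator tests.
fake_records <- function(n_persons = 10, prompts = 30, acc = 1, seed = 1,
                         condition = "test") {
  set.seed(seed)
  person <- rep(sprintf("p%02d", seq_len(n_persons)), each = prompts)
  true_class <- sample(c("above", "below"), length(person), replace = TRUE,
                       prob = c(0.2, 0.8))
  correct <- runif(length(person)) < acc
  obs <- ifelse(correct, true_class,
                ifelse(true_class == "above", "below", "above"))
  data.frame(person_id = person,
             day = rep(seq_len(prompts), n_persons) %/% 5 + 1,
             week = rep(rep(1:4, length.out = prompts), n_persons),
             condition = condition, true_class = true_class, obs_class = obs,
             classifiable = TRUE, n_items = sample(1:5, length(person), TRUE),
             true_cutoff = 1, obs_cutoff = 1, stringsAsFactors = FALSE)
}

test_that("confusion counts cross-tabulate truth against observation", {
  rec <- fake_records(acc = 1)
  cc <- confusion_counts(rec)
  expect_true(all(cc$fn == 0) && all(cc$fp == 0))
  expect_equal(sum(cc$tp + cc$tn + cc$fp + cc$fn), nrow(rec))
  # flipping observations swaps tp<->fn and tn<->fp
  flip <- rec
  flip$obs_class <- ifelse(rec$obs_class == "above", "below", "above")
  cf <- confusion_counts(flip)
  expect_identical(cf$fn, cc$tp)
  expect_identical(cf$fp, cc$tn)
})

test_that("kappa from rates equals the confusion-matrix identity", {
  expect_equal(kappa_from_rates(1, 1, 0.3), 1)
  expect_equal(kappa_from_rates(0.4, 0.6, 0.25), 0, tolerance = 1e-12)
  expect_equal(kappa_from_rates(0.8, 0.9, 0.3), 0.6934, tolerance = 1e-4)
  # exact algebraic identity against a directly built expected 2x2 table
  set.seed(12)
  for (rep in 1:50) {
    se <- runif(1, 0.05, 0.99); sp <- runif(1, 0.05, 0.99); p <- runif(1, 0.05, 0.95)
    n <- 1e6
    tp <- n * p * se; fn <- n * p * (1 - se)
    tn <- n * (1 - p) * sp; fp <- n * (1 - p) * (1 - sp)
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    expect_equal(kappa_from_rates(se, sp, p), (po - pe) / (1 - pe),
                 tolerance = 1e-12)
  }
  expect_error(kappa_from_rates(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(kappa_from_rates(1, 1, 1), "degenerate")
})

test_that("items variance decomposition matches a sums-of-squares oracle", {
  # constant counts: no variance anywhere
  rec <- fake_records()
  rec$n_items <- 3L
  vd <- items_variance_decomposition(rec)
  expect_equal(vd$between_sd, 0)
  expect_equal(vd$within_sd, 0)
  # distinct constant counts per person: purely between-person
  rec2 <- fake_records(n_persons = 4)
  rec2$n_items <- as.integer(factor(rec2$person_id))
  vd2 <- items_variance_decomposition(rec2)
  expect_equal(vd2$within_sd, 0)
  expect_gt(vd2$between_sd, 0)
  expect_equal(vd2$within_share, 0)
  # random unbalanced table vs direct one-way ANOVA arithmetic
  set.seed(3)
  y <- rpois(57, 3) + 1
  g <- sample(letters[1:7], 57, replace = TRUE)
  rec3 <- data.frame(person_id = g, n_items = y)
  vd3 <- items_variance_decomposition(rec3)
  fit <- anova(lm(y ~ g))
  ms_w <- fit$`Mean Sq`[2]
  ms_b <- fit$`Mean Sq`[1]
  n0 <- (57 - sum(table(g)^2) / 57) / (length(unique(g)) - 1)
  expect_equal(vd3$within_sd^2, ms_w, tolerance = 1e-10)
  expect_equal(vd3$between_sd^2, max(0, (ms_b - ms_w) / n0), tolerance = 1e-10)
})

test_that("quadrature random-intercept logistic matches dense integration", {
  set.seed(21)
  cl <- rep(sprintf("c%02d", 1:30), each = 20)
  eta <- rep(rnorm(30, 0.8, 0.7), each = 20)
  y <- runif(length(cl)) < plogis(eta)
  fit <- fit_random_intercept_logistic(y, cl)
  # dense trapezoid integration of the same collapsed likelihood
  k <- tapply(y, cl, sum); n <- tapply(y, cl, length)
  z <- seq(-8, 8, length.out = 10000)
  dz <- z[2] - z[1]
  mu <- fit$intercept_logit; sg <- sqrt(fit$intercept_var)
  ll_dense <- sum(vapply(seq_along(k), function(i) {
    p <- plogis(mu + sg * z)
    log(sum(dnorm(z) * p^k[i] * (1 - p)^(n[i] - k[i])) * dz)
  }, 0))
  expect_equal(fit$loglik, ll_dense, tolerance = length(k) * 1e-6)
  # median probability is the inverse-logit of the intercept
  expect_equal(fit$median_prob, plogis(fit$intercept_logit))
  expect_length(fit$per_cluster_eb, 30L)
})

test_that("random-intercept model degenerates and bounds sensibly", {
  # no between-cluster variance: intercept near the pooled logit
  set.seed(31)
  cl <- rep(sprintf("c%02d", 1:40), each = 25)
  y <- runif(length(cl)) < 0.7
  fit <- fit_random_intercept_logistic(y, cl)
  expect_equal(fit$intercept_logit, qlogis(mean(y)), tolerance = 0.1)
  expect_lt(fit$intercept_var, 0.05)
  # all-identical outcomes: boundary flag with continuity handling
  fit1 <- fit_random_intercept_logistic(rep(TRUE, 60), rep(1:6, each = 10))
  expect_true(fit1$boundary)
  expect_gt(fit1$median_prob, 0.99)
  expect_error(fit_random_intercept_logistic(c(TRUE, FALSE), c("a", "a")), "clusters")
})

test_that("quadrature estimates agree with lme4 on a shared dataset", {
  set.seed(55)
  cl <- rep(sprintf("c%03d", 1:60), each = 30)
  eta <- rep(rnorm(60, 1.0, 0.8), each = 30)
  y <- as.integer(runif(length(cl)) < plogis(eta))
  ours <- fit_random_intercept_logistic(y, cl)
  df <- data.frame(y = y, cl = cl)
  lfit <- lme4::glmer(y ~ 1 + (1 | cl), data = df, family = stats::binomial,
                      nAGQ = 21L)
  expect_equal(ours$intercept_logit, unname(lme4::fixef(lfit)[1]), tolerance = 0.02)
  expect_equal(sqrt(ours$intercept_var),
               attr(lme4::VarCorr(lfit)$cl, "stddev")[[1]], tolerance = 0.05)
})

test_that("condition summaries behave at the identity and null extremes", {
  perfect <- summarize_condition(fake_records(acc = 1), n_boot = 0)
  expect_gte(perfect$sensitivity, 0.99)
  expect_gte(perfect$specificity, 0.99)
  expect_gt(perfect$kappa, 0.95)
  # observation independent of truth: kappa near zero
  rec <- fake_records(n_persons = 40, prompts = 60, seed = 9)
  rec$obs_class <- sample(c("above", "below"), nrow(rec), TRUE)
  null_sum <- summarize_condition(rec, n_boot = 0)
  expect_lt(abs(null_sum$kappa), 0.05)
  # weekly summaries partition the classifiable records
  ws <- summarize_condition(rec, weekly = TRUE, n_boot = 0)
  expect_equal(sum(ws$by_week$n_classifiable), ws$n_classifiable)
  # bootstrap intervals cover the point estimate
  bs <- summarize_condition(fake_records(acc = 0.9, seed = 2), n_boot = 50,
                            boot_seed = 3)
  k_ci <- bs$ci[bs$ci$metric == "kappa", ]
  expect_true(k_ci$lo <= bs$kappa && bs$kappa <= k_ci$hi)
})

test_that("cutoff RMSE by day matches direct arithmetic", {
  rec <- fake_records(n_persons = 2, prompts = 10)
  rec$day <- rep(1:5, 4)
  expect_true(all(cutoff_rmse_by_day(rec)$rmse == 0))
  rec$obs_cutoff <- rec$true_cutoff + 0.25
  expect_equal(cutoff_rmse_by_day(rec)$rmse, rep(0.25, 5), tolerance = 1e-12)
  set.seed(10)
  rec20 <- rec[1:20, ]
  rec20$obs_cutoff <- rec20$true_cutoff + rnorm(20)
  got <- cutoff_rmse_by_day(rec20)
  for (d in got$day) {
    sel <- rec20$day == d
    expect_equal(got$rmse[got$day == d],
                 sqrt(mean((rec20$obs_cutoff[sel] - rec20$true_cutoff[sel])^2)),
                 tolerance = 1e-12)
  }
  by_p <- cutoff_rmse_by_day(rec20, by_person = TRUE)
  expect_true(all(c("person_id", "day", "rmse") %in% names(by_p)))
})

test_that("between-condition comparisons flag only real differences", {
  good <- fake_records(n_persons = 25, prompts = 40, acc = 0.97, seed = 5,
                       condition = "good")
  bad <- fake_records(n_persons = 25, prompts = 40, acc = 0.62, seed = 5,
                      condition = "bad")
  both <- rbind(good, bad)
  cmp <- compare_conditions(both, metric = "kappa", n_boot = 60, seed = 2)
  expect_equal(nrow(cmp), 1L)
  expect_true(cmp$flagged[1])
  expect_gt(cmp$diff[1], 0)
  # a condition against itself: zero difference, interval straddles 0
  same <- rbind(good, transform(good, condition = "good2"))
  cmp0 <- compare_conditions(same, metric = "kappa", n_boot = 60, seed = 2)
  expect_equal(cmp0$diff[1], 0, tolerance = 1e-12)
  expect_false(cmp0$flagged[1])
  # degenerate bootstrap: point difference only
  cmp1 <- compare_conditions(both, metric = "mean_items", n_boot = 1)
  expect_true(is.na(cmp1$lo))
})
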