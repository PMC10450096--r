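# Performance criteria for momentary classification: sensitivity and
# specificity from random-intercept logistic models (median person),
# kappa from (Se, Sp, prevalence), items-per-prompt statistics, weekly
# breakdowns, and cutoff RMSE by day.

# ---- Gauss-Hermite machinery ----------------------------------------------

# Physicists' Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue
# method (symmetric tridiagonal Jacobi matrix).
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

log_sum_exp_cols <- function(A) {
  m <- apply(A, 2, max)
  m + log(colSums(exp(sweep(A, 2, m))))
}

# Marginal log-likelihood of the logit-normal random-intercept model on
# per-cluster (k successes, n trials), by fixed Gauss-Hermite quadrature.
ri_loglik <- function(mu, sigma, k, n, gh) {
  z <- mu + sigma * sqrt(2) * gh$nodes
  lp <- stats::plogis(z, log.p = TRUE)          # log p_q
  lq <- stats::plogis(-z, log.p = TRUE)         # log (1 - p_q)
  A <- outer(lp, k) + outer(lq, n - k) + (log(gh$weights) - 0.5 * log(pi))
  sum(log_sum_exp_cols(A))
}

#' Random-intercept logistic model for clustered binary outcomes
#'
#' Maximum-likelihood logit-normal random-intercept model fitted with fixed
#' Gauss-Hermite quadrature (21 nodes by default). The inverse-logit of the
#' intercept is the median probability across clusters, the estimand used
#' for median sensitivity/specificity. Empirical-Bayes posterior-mode
#' intercepts per cluster are returned for distributional displays.
#'
#' @param outcome Logical (or 0/1) outcome vector.
#' @param cluster Cluster (person) id per outcome.
#' @param n_nodes Number of quadrature nodes (default 21).
#' @return List with `intercept_logit`, `intercept_var`, `median_prob`,
#'   `per_cluster_eb` (named logit vector), `boundary` (TRUE when all
#'   outcomes are identical and an Agresti-style continuity correction was
#'   applied), and `loglik`.
#' @export
fit_random_intercept_logistic <- function(outcome, cluster, n_nodes = 21L) {
  outcome <- as.logical(outcome)
  if (anyNA(outcome)) stop_jita("`outcome` contains NA", "jitaema_argument_error")
  cluster <- as.character(cluster)
  k <- tapply(outcome, cluster, sum)
  n <- tapply(outcome, cluster, length)
  ids <- names(k)
  if (length(ids) < 2L) {
    stop_jita("need >= 2 clusters", "jitaema_argument_error")
  }
  tot_k <- sum(k); tot_n <- sum(n)
  if (tot_k == 0 || tot_k == tot_n) {
    # all outcomes identical: continuity-corrected pooled proportion
    p <- (tot_k + 0.5) / (tot_n + 1)
    mu <- stats::qlogis(p)
    return(list(intercept_logit = mu, intercept_var = 0, median_prob = p,
                per_cluster_eb = stats::setNames(rep(mu, length(ids)), ids),
                boundary = TRUE, loglik = NA_real_))
  }
  gh <- gauss_hermite(n_nodes)
  negll <- function(par) -ri_loglik(par[1], exp(par[2]), k, n, gh)
  start <- c(stats::qlogis(clamp(tot_k / tot_n, 0.02, 0.98)), log(0.5))
  opt <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  eb <- vapply(seq_along(ids), function(i) {
    f <- function(z) {
      eta <- mu + sigma * z
      -(k[i] * stats::plogis(eta, log.p = TRUE) +
          (n[i] - k[i]) * stats::plogis(-eta, log.p = TRUE) - z^2 / 2)
    }
    mu + sigma * stats::optimize(f, c(-6, 6))$minimum
  }, 0)
  list(intercept_logit = mu, intercept_var = sigma^2,
       median_prob = stats::plogis(mu),
       per_cluster_eb = stats::setNames(eb, ids),
       boundary = FALSE, loglik = -opt$value)
}

# ---- confusion / kappa -----------------------------------------------------

classified_records <- function(records) {
  records[records$classifiable & !is.na(records$obs_class), , drop = FALSE]
}

#' Per-person confusion counts
#'
#' Cross-tabulates true vs observed classification over classifiable
#' prompts, per person.
#'
#' @param records Prompt records from one condition (see [run_condition()]).
#' @return Data frame `person_id`, `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(records) {
  cls <- classified_records(records)
  ta <- cls$true_class == "above"
  oa <- cls$obs_class == "above"
  agg <- function(x) as.integer(tapply(x, cls$person_id, sum))
  ids <- sort(unique(cls$person_id))
  data.frame(person_id = ids,
             tp = agg(ta & oa), fn = agg(ta & !oa),
             fp = agg(!ta & oa), tn = agg(!ta & !oa),
             stringsAsFactors = FALSE)
}

#' Cohen's kappa from sensitivity, specificity, and prevalence
#'
#' With `P` the prevalence of the positive class, the observed agreement is
#' `p_o = P*Se + (1-P)*Sp`, the marginal positive-call rate is
#' `q = P*Se + (1-P)(1-Sp)`, the chance agreement is
#' `p_e = P*q + (1-P)(1-q)`, and `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param sensitivity,specificity,prevalence Values in `[0, 1]`.
#' @export
kappa_from_rates <- function(sensitivity, specificity, prevalence) {
  vals <- c(sensitivity, specificity, prevalence)
  if (any(vals < 0 | vals > 1)) {
    stop_jita("all arguments must be in [0, 1]", "jitaema_argument_error")
  }
  p_o <- prevalence * sensitivity + (1 - prevalence) * specificity
  q <- prevalence * sensitivity + (1 - prevalence) * (1 - specificity)
  p_e <- prevalence * q + (1 - prevalence) * (1 - q)
  if (abs(1 - p_e) < 1e-12) {
    stop_jita("degenerate input: chance agreement equals 1", "jitaema_argument_error")
  }
  (p_o - p_e) / (1 - p_e)
}

#' One-way decomposition of items-per-prompt variance
#'
#' Method-of-moments random-effects decomposition of the number of items
#' administered per prompt into between-person and within-person components.
#'
#' @param records Prompt records from one condition.
#' @return List `mean`, `between_sd`, `within_sd`, `within_share`; for a
#'   single person the between component is `NA`.
#' @export
items_variance_decomposition <- function(records) {
  y <- records$n_items
  g <- as.character(records$person_id)
  N <- length(y); ids <- unique(g); kk <- length(ids)
  if (kk < 2L) {
    return(list(mean = mean(y), between_sd = NA_real_,
                within_sd = stats::sd(y), within_share = NA_real_))
  }
  ni <- tapply(y, g, length)
  mi <- tapply(y, g, mean)
  grand <- mean(y)
  ss_w <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  ss_b <- sum(ni * (mi - grand)^2)
  ms_w <- ss_w / (N - kk)
  ms_b <- ss_b / (kk - 1)
  n0 <- (N - sum(ni^2) / N) / (kk - 1)
  var_b <- max(0, (ms_b - ms_w) / n0)
  var_w <- ms_w
  list(mean = grand, between_sd = sqrt(var_b), within_sd = sqrt(var_w),
       within_share = var_w / (var_b + var_w))
}

# Point metrics on one condition's records (no uncertainty).
condition_metrics <- function(records) {
  cls <- classified_records(records)
  if (nrow(cls) == 0L) {
    return(list(sensitivity = NA_real_, specificity = NA_real_,
                kappa = NA_real_, prevalence = NA_real_,
                mean_items = mean(records$n_items)))
  }
  ta <- cls$true_class == "above"
  prev <- mean(ta)
  se <- if (any(ta)) {
    fit_random_intercept_logistic(cls$obs_class[ta] == "above",
                                  cls$person_id[ta])$median_prob
  } else NA_real_
  sp <- if (any(!ta)) {
    fit_random_intercept_logistic(cls$obs_class[!ta] == "below",
                                  cls$person_id[!ta])$median_prob
  } else NA_real_
  kap <- if (is.na(se) || is.na(sp)) NA_real_ else kappa_from_rates(se, sp, prev)
  list(sensitivity = se, specificity = sp, kappa = kap, prevalence = prev,
       mean_items = mean(records$n_items))
}

#' Summarize one condition's classification performance
#'
#' Median-person sensitivity and specificity come from random-intercept
#' logistic models ([fit_random_intercept_logistic()]); kappa from
#' [kappa_from_rates()] with the empirical prevalence of truly-above prompts
#' among classifiable records; items-per-prompt statistics from
#' [items_variance_decomposition()]. Confidence intervals are percentile
#' intervals from a seeded cluster (person-resampling) bootstrap.
#'
#' @param records Prompt records from one condition.
#' @param weekly Add per-week (1-4) sub-summaries.
#' @param n_boot Bootstrap draws (default 1000; 0 disables CIs).
#' @param boot_seed Bootstrap seed.
#' @param level CI level (default 0.95).
#' @return An `eval_summary` object.
#' @export
summarize_condition <- function(records, weekly = FALSE, n_boot = 1000L,
                                boot_seed = 1L, level = 0.95) {
  if (nrow(records) == 0L) stop_jita("no records", "jitaema_argument_error")
  condition <- unique(records$condition)
  if (length(condition) != 1L) {
    stop_jita("records must come from a single condition", "jitaema_argument_error")
  }
  pm <- condition_metrics(records)
  vd <- items_variance_decomposition(records)
  ci <- NULL
  if (n_boot > 0L) {
    stats_b <- with_seed(boot_seed, {
      ids <- unique(records$person_id)
      by_person <- split(seq_len(nrow(records)), records$person_id)
      vapply(seq_len(n_boot), function(b) {
        take <- sample(ids, length(ids), replace = TRUE)
        rows <- unlist(by_person[take], use.names = FALSE)
        # resampled persons get fresh ids so repeated draws stay distinct clusters
        rec <- records[rows, , drop = FALSE]
        rec$person_id <- rep(seq_along(take),
                             vapply(by_person[take], length, 0L))
        m <- condition_metrics(rec)
        c(m$sensitivity, m$specificity, m$kappa, m$mean_items)
      }, numeric(4))
    })
    alpha <- (1 - level) / 2
    qs <- apply(stats_b, 1, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE)
    ci <- data.frame(metric = c("sensitivity", "specificity", "kappa", "mean_items"),
                     lo = qs[1, ], hi = qs[2, ], row.names = NULL)
  }
  by_week <- NULL
  if (weekly) {
    weeks <- sort(unique(records$week))
    by_week <- do.call(rbind, lapply(weeks, function(w) {
      m <- condition_metrics(records[records$week == w, , drop = FALSE])
      data.frame(week = w, sensitivity = m$sensitivity,
                 specificity = m$specificity, kappa = m$kappa,
                 mean_items = m$mean_items,
                 n_classifiable = nrow(classified_records(
                   records[records$week == w, , drop = FALSE])))
    }))
  }
  structure(
    list(condition = condition, n_prompts = nrow(records),
         n_classifiable = nrow(classified_records(records)),
         prevalence = pm$prevalence, sensitivity = pm$sensitivity,
         specificity = pm$specificity, kappa = pm$kappa,
         mean_items = vd$mean, items_between_sd = vd$between_sd,
         items_within_sd = vd$within_sd, items_within_share = vd$within_share,
         ci = ci, by_week = by_week),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> %s: %d prompts (%d classifiable)\n",
              x$condition, x$n_prompts, x$n_classifiable))
  cat(sprintf("  mean items %.2f (between SD %.2f, within SD %.2f, within share %.0f%%)\n",
              x$mean_items, x$items_between_sd, x$items_within_sd,
              100 * x$items_within_share))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, kappa %.3f (prevalence %.3f)\n",
              x$sensitivity, x$specificity, x$kappa, x$prevalence))
  if (!is.null(x$ci)) {
    for (i in seq_len(nrow(x$ci))) {
      cat(sprintf("    %s CI [%.3f, %.3f]\n", x$ci$metric[i], x$ci$lo[i], x$ci$hi[i]))
    }
  }
  invisible(x)
}

#' Summary table over all conditions of a study
#'
#' @param study A `jita_study` from [run_study()] (or its `records`).
#' @inheritParams summarize_condition
#' @return Data frame, one row per condition.
#' @export
summarize_study <- function(study, weekly = FALSE, n_boot = 0L, boot_seed = 1L) {
  records <- if (inherits(study, "jita_study")) study$records else study
  out <- lapply(split(records, records$condition), function(rec) {
    s <- summarize_condition(rec, weekly = weekly, n_boot = n_boot,
                             boot_seed = boot_seed)
    data.frame(condition = s$condition, mean_items = s$mean_items,
               items_between_sd = s$items_between_sd,
               items_within_sd = s$items_within_sd,
               items_within_share = s$items_within_share,
               sensitivity = s$sensitivity, specificity = s$specificity,
               kappa = s$kappa, prevalence = s$prevalence,
               n_prompts = s$n_prompts, n_classifiable = s$n_classifiable)
  })
  out <- do.call(rbind, out)
  ord <- match(c("fixed2", "fixed3", "fixed5", "variable", "jita"), out$condition)
  out <- out[ord[!is.na(ord)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RMSE of observed vs true classification cutoffs by study day
#'
#' @param records Dynamic-cutoff prompt records (one condition).
#' @param by_person Also break down by person.
#' @return Data frame `day`, `rmse`, `n` (plus `person_id` when
#'   `by_person = TRUE`), over classifiable prompts.
#' @export
cutoff_rmse_by_day <- function(records, by_person = FALSE) {
  cls <- records[records$classifiable & !is.na(records$obs_cutoff), , drop = FALSE]
  err2 <- (cls$obs_cutoff - cls$true_cutoff)^2
  if (by_person) {
    key <- interaction(cls$person_id, cls$day, drop = TRUE)
    out <- data.frame(
      person_id = tapply(as.character(cls$person_id), key, `[`, 1),
      day = as.integer(tapply(cls$day, key, `[`, 1)),
      rmse = sqrt(tapply(err2, key, mean)),
      n = as.integer(tapply(err2, key, length)), row.names = NULL)
    out[order(out$person_id, out$day), ]
  } else {
    days <- sort(unique(cls$day))
    data.frame(day = days,
               rmse = sqrt(tapply(err2, cls$day, mean)[as.character(days)]),
               n = as.integer(tapply(err2, cls$day, length)[as.character(days)]),
               row.names = NULL)
  }
}

#' Paired between-condition comparisons with cluster-bootstrap intervals
#'
#' Resamples persons (jointly across conditions, preserving the shared-truth
#' pairing) and reports bootstrap percentile intervals for the
#' between-condition difference in a metric. A difference is flagged when
#' its interval excludes 0.
#'
#' @param records Long records over conditions (e.g. `study$records`).
#' @param metric `"kappa"`, `"sensitivity"`, `"specificity"`, or
#'   `"mean_items"`.
#' @param conditions Conditions to compare (default: all present, pairwise).
#' @param n_boot Bootstrap draws; `n_boot <= 1` yields point differences only.
#' @param seed Bootstrap seed.
#' @param level Interval level.
#' @return Data frame `condition_a`, `condition_b`, `metric`, `diff`,
#'   `lo`, `hi`, `flagged`.
#' @export
compare_conditions <- function(records, metric = c("kappa", "sensitivity",
                                                   "specificity", "mean_items"),
                               conditions = NULL, n_boot = 500L, seed = 1L,
                               level = 0.95) {
  metric <- match.arg(metric)
  conditions <- conditions %||% unique(records$condition)
  if (!all(conditions %in% records$condition)) {
    stop_jita("condition(s) absent from records", "jitaema_argument_error")
  }
  persons <- lapply(conditions, function(cd) {
    sort(unique(records$person_id[records$condition == cd]))
  })
  if (length(unique(persons)) != 1L) {
    stop_jita("conditions do not share persons", "jitaema_argument_error")
  }
  mval <- function(rec) condition_metrics(rec)[[metric]]
  point <- vapply(conditions, function(cd) {
    mval(records[records$condition == cd, , drop = FALSE])
  }, 0)
  pairs <- utils::combn(conditions, 2)
  boot_diffs <- NULL
  if (n_boot > 1L) {
    ids <- persons[[1]]
    boot_diffs <- with_seed(seed, {
      sapply(seq_len(n_boot), function(b) {
        take <- sample(ids, length(ids), replace = TRUE)
        vals <- vapply(conditions, function(cd) {
          rec <- records[records$condition == cd, , drop = FALSE]
          by_person <- split(seq_len(nrow(rec)), rec$person_id)
          rows <- unlist(by_person[take], use.names = FALSE)
          sub <- rec[rows, , drop = FALSE]
          sub$person_id <- rep(seq_along(take),
                               vapply(by_person[take], length, 0L))
          mval(sub)
        }, 0)
        apply(pairs, 2, function(pr) {
          vals[match(pr[1], conditions)] - vals[match(pr[2], conditions)]
        })
      })
    })
    if (is.null(dim(boot_diffs))) boot_diffs <- matrix(boot_diffs, nrow = 1)
  }
  alpha <- (1 - level) / 2
  out <- data.frame(condition_a = pairs[1, ], condition_b = pairs[2, ],
                    metric = metric,
                    diff = point[match(pairs[1, ], conditions)] -
                      point[match(pairs[2, ], conditions)],
                    lo = NA_real_, hi = NA_real_, flagged = NA,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(boot_diffs)) {
    qs <- apply(boot_diffs, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    out$lo <- qs[1, ]
    out$hi <- qs[2, ]
    out$flagged <- out$lo > 0 | out$hi < 0
  }
  out
}
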