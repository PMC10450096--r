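# Synthetic EMA study machinery: a generative population of persons with
# diurnal fatigue cycles, prompt schedules, latent ("true") momentary states
# and cutoffs, and end-to-end execution of the five item-selection
# conditions over shared truth.

#' Hyperparameters of the synthetic population
#'
#' Persons carry a cosinor diurnal cycle on the z metric, a within-person
#' residual SD, and a day-to-day "wobble" SD perturbing the cycle's sine and
#' cosine coefficients each day. The defaults are calibrated so that the
#' marginal variance of generated momentary states is approximately 1
#' (z metric): `0.7^2 + E[A^2]/2 + E[within^2] + E[wobble^2] ~ 1.04`.
#'
#' @param beta0_sd SD of person mean levels (default 0.7).
#' @param amplitude_range Uniform range of cycle amplitudes (default `c(0, 0.8)`);
#'   phase is uniform on the clock.
#' @param within_sd_range Uniform range of within-person residual SDs
#'   (default `c(0.3, 0.9)`).
#' @param cycle_day_sd_range Uniform range of day-to-day cycle wobble SDs
#'   (default `c(0, 0.4)`).
#' @export
population_hyper <- function(beta0_sd = 0.7, amplitude_range = c(0, 0.8),
                             within_sd_range = c(0.3, 0.9),
                             cycle_day_sd_range = c(0, 0.4)) {
  if (beta0_sd < 0 || any(amplitude_range < 0) || diff(amplitude_range) < 0 ||
      within_sd_range[1] <= 0 || diff(within_sd_range) < 0 ||
      any(cycle_day_sd_range < 0) || diff(cycle_day_sd_range) < 0) {
    stop_jita("invalid population hyperparameters", "jitaema_argument_error")
  }
  structure(list(beta0_sd = beta0_sd, amplitude_range = amplitude_range,
                 within_sd_range = within_sd_range,
                 cycle_day_sd_range = cycle_day_sd_range),
            class = "population_hyper")
}

#' Generate a synthetic person population
#'
#' @param n Number of persons (default 106).
#' @param hyper A [population_hyper()].
#' @param seed Integer seed.
#' @return Data frame with one row per person: `person_id`, `beta0`,
#'   `beta1`, `beta2` (true cosinor cycle), `within_sd`, `cycle_day_sd`.
#' @export
generate_population <- function(n = 106L, hyper = population_hyper(), seed = 1L) {
  if (!is_scalar_number(n) || n < 1) stop_jita("`n` must be >= 1", "jitaema_argument_error")
  stopifnot(inherits(hyper, "population_hyper"))
  n <- as.integer(n)
  with_seed(seed, {
    amp <- stats::runif(n, hyper$amplitude_range[1], hyper$amplitude_range[2])
    phase <- stats::runif(n, 0, 2 * pi)
    data.frame(
      person_id = sprintf("p%03d", seq_len(n)),
      beta0 = stats::rnorm(n, 0, hyper$beta0_sd),
      beta1 = amp * cos(phase),
      beta2 = amp * sin(phase),
      within_sd = stats::runif(n, hyper$within_sd_range[1], hyper$within_sd_range[2]),
      cycle_day_sd = stats::runif(n, hyper$cycle_day_sd_range[1],
                                  hyper$cycle_day_sd_range[2]),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate an EMA prompt schedule
#'
#' Per person-day the prompt count is uniform on `prompts_per_day_range`;
#' hours are stratified across the waking window (one prompt per equal-width
#' bin, jittered uniformly within the bin) and each prompt is kept
#' independently with probability `compliance` (missing completely at
#' random).
#'
#' @param person_ids Character vector of person ids.
#' @param n_days Number of study days (default 28).
#' @param prompts_per_day_range Integer `(min, max)` prompts per day
#'   (default `c(5, 6)`).
#' @param compliance Completion probability per prompt (default 0.91).
#' @param waking Waking window hours (default `c(6, 22)`).
#' @param seed Integer seed.
#' @return Data frame `person_id`, `day`, `hour`, sorted by person, day,
#'   hour.
#' @export
generate_schedule <- function(person_ids, n_days = 28L,
                              prompts_per_day_range = c(5L, 6L),
                              compliance = 0.91, waking = c(6, 22), seed = 1L) {
  if (compliance < 0 || compliance > 1) {
    stop_jita("`compliance` must be in [0, 1]", "jitaema_argument_error")
  }
  n_days <- as.integer(n_days)
  lo <- as.integer(prompts_per_day_range[1]); hi <- as.integer(prompts_per_day_range[2])
  if (lo < 1L || hi < lo) {
    stop_jita("invalid `prompts_per_day_range`", "jitaema_argument_error")
  }
  with_seed(seed, {
    rows <- vector("list", length(person_ids))
    for (p in seq_along(person_ids)) {
      counts <- if (hi > lo) sample(lo:hi, n_days, replace = TRUE) else rep(lo, n_days)
      day <- rep(seq_len(n_days), counts)
      width <- (waking[2] - waking[1])
      hour <- unlist(lapply(counts, function(k) {
        bin <- width / k
        waking[1] + (seq_len(k) - 1) * bin + stats::runif(k, 0, bin)
      }))
      keep <- stats::runif(length(day)) <= compliance
      rows[[p]] <- data.frame(person_id = rep(person_ids[p], sum(keep)),
                              day = day[keep], hour = hour[keep],
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out[order(out$person_id, out$day, out$hour), , drop = FALSE]
  })
}

#' Generate true momentary states and true cutoffs
#'
#' Each person-day's cycle is the person's cosinor cycle with its sine and
#' cosine coefficients perturbed by `Normal(0, cycle_day_sd)`; the true state
#' adds `Normal(0, within_sd)` noise on top of the day cycle. The true
#' cutoff is the uniform z value (`kind = "uniform"`), or the person's
#' (unperturbed) cycle prediction at the prompt hour plus
#' `delta_sd * within_sd` (`kind = "dynamic"`). True classification is
#' `"above"` iff the true state strictly exceeds the true cutoff.
#'
#' @param population From [generate_population()].
#' @param schedule From [generate_schedule()].
#' @param cutoff A [cutoff_spec()].
#' @param seed Integer seed.
#' @return `schedule` augmented with `week`, `true_theta`, `true_cutoff`,
#'   `true_class`.
#' @export
generate_true_thetas <- function(population, schedule,
                                 cutoff = cutoff_spec("uniform"), seed = 1L) {
  stopifnot(inherits(cutoff, "cutoff_spec"))
  pid <- match(schedule$person_id, population$person_id)
  if (anyNA(pid)) stop_jita("schedule contains unknown person_id", "jitaema_argument_error")
  with_seed(seed, {
    key <- paste(schedule$person_id, schedule$day)
    uday <- !duplicated(key)
    d1 <- stats::rnorm(sum(uday)) ; d2 <- stats::rnorm(sum(uday))
    di <- cumsum(uday)  # person-day index per prompt row
    wsd <- population$cycle_day_sd[pid]
    b1 <- population$beta1[pid] + wsd * d1[di]
    b2 <- population$beta2[pid] + wsd * d2[di]
    x <- 2 * pi * schedule$hour / 24
    day_pred <- population$beta0[pid] + b1 * sin(x) + b2 * cos(x)
    true_theta <- day_pred + stats::rnorm(nrow(schedule), 0, population$within_sd[pid])
    person_pred <- population$beta0[pid] + population$beta1[pid] * sin(x) +
      population$beta2[pid] * cos(x)
    true_cutoff <- if (cutoff$kind == "uniform") {
      rep_len(cutoff$uniform_z, nrow(schedule))
    } else {
      person_pred + cutoff$delta_sd * population$within_sd[pid]
    }
    out <- schedule
    out$week <- as.integer(ceiling(out$day / 7))
    out$true_theta <- true_theta
    out$true_cutoff <- true_cutoff
    out$true_class <- ifelse(true_theta > true_cutoff, "above", "below")
    out
  })
}

#' Study configuration
#'
#' Bundles every knob of a simulated EMA study. The defaults describe the
#' reference design: 106 persons, 28 days, 5-6 prompts/day at 91%
#' compliance, a 13-item 5-category bank, N(0, 1) scoring prior, maximum 5
#' items per prompt, 95% classification confidence, and an SE < 0.3 stopping
#' rule for non-classifiable prompts.
#'
#' @param n_persons,n_days,prompts_per_day_range,compliance,waking Schedule
#'   parameters; see [generate_schedule()].
#' @param bank An [item_bank()], a path readable by [load_bank()], or `NULL`
#'   to generate the default synthetic bank (seeded from `master_seed`).
#' @param cutoff A [cutoff_spec()]; `"uniform"` selects the study-1 design,
#'   `"dynamic"` the study-2 design.
#' @param conditions Subset of
#'   `c("fixed2", "fixed3", "fixed5", "variable", "jita")`.
#' @param prior Scoring [prior_spec()].
#' @param hyper A [population_hyper()].
#' @param max_items,confidence,run_in_se Session stopping parameters.
#' @param master_seed Integer master seed; all stage seeds derive from it.
#' @export
study_config <- function(n_persons = 106L, n_days = 28L,
                         prompts_per_day_range = c(5L, 6L), compliance = 0.91,
                         waking = c(6, 22), bank = NULL,
                         cutoff = cutoff_spec("uniform"),
                         conditions = c("fixed2", "fixed3", "fixed5",
                                        "variable", "jita"),
                         prior = prior_spec(), hyper = population_hyper(),
                         max_items = 5L, confidence = 0.95, run_in_se = 0.3,
                         master_seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  stopifnot(inherits(cutoff, "cutoff_spec"), inherits(prior, "prior_spec"),
            inherits(hyper, "population_hyper"))
  structure(
    list(n_persons = as.integer(n_persons), n_days = as.integer(n_days),
         prompts_per_day_range = as.integer(prompts_per_day_range),
         compliance = compliance, waking = as.numeric(waking), bank = bank,
         cutoff = cutoff, conditions = conditions, prior = prior,
         hyper = hyper, max_items = as.integer(max_items),
         confidence = confidence, run_in_se = run_in_se,
         master_seed = as.integer(master_seed)),
    class = "study_config"
  )
}

condition_specs <- function(condition, config, cond_seed) {
  if (!condition %in% c("fixed2", "fixed3", "fixed5", "variable", "jita")) {
    stop_jita(sprintf("unknown condition '%s'", condition), "jitaema_argument_error")
  }
  fixed_n <- switch(condition, fixed2 = 2L, fixed3 = 3L, fixed5 = 5L, NULL)
  list(
    selector = selector_spec(if (condition == "jita") "mei" else "random"),
    fixed_n = fixed_n,
    adaptive_stop = is.null(fixed_n),
    cond_seed = cond_seed
  )
}

#' Run one item-selection condition over shared truth
#'
#' Executes a full CAT session at every scheduled prompt. Responses come
#' from a shared uniform-draw matrix keyed by (prompt, item), so conditions
#' administering the same item at the same prompt observe the same answer.
#' Under a dynamic [cutoff_spec()], the observed cutoff at each prompt is
#' estimated by cosinor regression on that condition's own previously
#' observed scores; run-in and nighttime prompts are assessed with the
#' SE-threshold rule and excluded from classification.
#'
#' @param condition One of `"fixed2"`, `"fixed3"`, `"fixed5"`,
#'   `"variable"`, `"jita"`.
#' @param truth Output of [generate_true_thetas()].
#' @param bank An [item_bank()].
#' @param config A [study_config()].
#' @param response_u Matrix `nrow(truth) x bank_size(bank)` of uniforms.
#' @param cond_seed Seed of the condition's private selection stream.
#' @return Data frame of prompt records (one row per prompt).
#' @export
run_condition <- function(condition, truth, bank, config, response_u, cond_seed = 1L) {
  stopifnot(inherits(config, "study_config"), inherits(bank, "item_bank"))
  cs <- condition_specs(condition, config, cond_seed)
  cut_spec <- config$cutoff
  dynamic <- cut_spec$kind == "dynamic"
  pars <- bank_params(bank)
  n <- nrow(truth)
  n_items_out <- integer(n); theta_out <- numeric(n); se_out <- numeric(n)
  items_out <- character(n); resp_out <- character(n); stop_out <- character(n)
  obs_cut_out <- rep(NA_real_, n); obs_class_out <- rep(NA_character_, n)
  classifiable_out <- logical(n)

  with_seed(cond_seed, {
    persons <- unique(truth$person_id)
    for (p in persons) {
      rows <- which(truth$person_id == p)
      hist_hours <- numeric(0); hist_thetas <- numeric(0)
      prev_theta <- config$prior$mean
      for (r in rows) {
        day <- truth$day[r]; hour <- truth$hour[r]
        classifiable <- is_classifiable(day, hour, cut_spec)
        obs_cutoff <- if (!dynamic) {
          cut_spec$uniform_z
        } else if (length(hist_thetas) == 0L) {
          classifiable <- FALSE
          NA_real_
        } else {
          dynamic_cutoff(hist_hours, hist_thetas, hour, cut_spec)
        }
        init_theta <- if (condition != "jita") {
          config$prior$mean
        } else if (!dynamic) {
          prev_theta
        } else if (length(hist_thetas) >= 3L) {
          fit <- tryCatch(fit_cosinor(hist_hours, hist_thetas),
                          jitaema_singular_fit = function(e) NULL)
          if (is.null(fit)) mean(hist_thetas) else predict_cosinor(fit, hour)
        } else if (length(hist_thetas) > 0L) {
          mean(hist_thetas)
        } else {
          config$prior$mean
        }
        stopping <- if (!is.null(cs$fixed_n)) {
          stopping_spec("fixed_length", max_items = config$max_items,
                        fixed_n = cs$fixed_n, confidence = config$confidence)
        } else if (classifiable) {
          stopping_spec("classification_confidence", max_items = config$max_items,
                        confidence = config$confidence)
        } else {
          stopping_spec("se_threshold", max_items = config$max_items,
                        se_threshold = config$run_in_se,
                        confidence = config$confidence)
        }
        session <- start_session(bank, config$prior, cs$selector, stopping,
                                 cutoff = if (classifiable) obs_cutoff else NULL,
                                 init_theta = init_theta)
        tt <- truth$true_theta[r]
        responder <- function(item_id) {
          i <- match(item_id, pars$ids)
          response_from_uniform(bank$items[[i]], tt, response_u[r, i])
        }
        res <- run_session(session, responder)
        n_items_out[r] <- res$estimate$n_items
        theta_out[r] <- res$estimate$theta
        se_out[r] <- res$estimate$se
        items_out[r] <- paste(res$administered$item_id, collapse = ";")
        resp_out[r] <- paste(res$administered$category, collapse = ";")
        stop_out[r] <- res$stop_reason
        obs_cut_out[r] <- obs_cutoff
        classifiable_out[r] <- classifiable
        if (classifiable) {
          obs_class_out[r] <- classify(res$estimate, obs_cutoff,
                                       config$confidence)$decision
        }
        prev_theta <- res$estimate$theta
        hist_hours <- c(hist_hours, hour)
        hist_thetas <- c(hist_thetas, res$estimate$theta)
      }
    }
  })
  out <- truth
  out$condition <- condition
  out$n_items <- n_items_out
  out$items <- items_out
  out$responses <- resp_out
  out$theta <- theta_out
  out$se <- se_out
  out$stop_reason <- stop_out
  out$obs_cutoff <- obs_cut_out
  out$obs_class <- obs_class_out
  out$classifiable <- classifiable_out
  out
}

resolve_bank <- function(config, bank_seed) {
  b <- config$bank
  if (is.null(b)) {
    generate_synthetic_bank(seed = bank_seed)
  } else if (inherits(b, "item_bank")) {
    b
  } else if (is.character(b)) {
    load_bank(b)
  } else {
    stop_jita("`bank` must be NULL, an item_bank, or a file path",
              "jitaema_argument_error")
  }
}

#' Run a full simulated EMA study
#'
#' Orchestrates population, schedule, truth and response generation, then
#' runs every configured condition over the same truth (identical persons,
#' prompts, true states, true cutoffs, and response draws at matched
#' (prompt, item) pairs).
#'
#' @param config A [study_config()].
#' @param true_thetas Optional externally supplied truth: a data frame with
#'   columns `person_id`, `day`, `hour`, `theta` that replaces the generated
#'   schedule and true states. True cutoffs are then derived per person from
#'   a cosinor fit to the supplied values (dynamic cutoffs) or the uniform z
#'   value.
#' @return A `jita_study` bundle: `records` (long data frame over all
#'   conditions), `truth`, `population` (NULL for external truth), `bank`,
#'   `config`, `seeds`.
#' @export
run_study <- function(config = study_config(), true_thetas = NULL) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(config$master_seed, 6L + length(config$conditions),
                        c("bank", "population", "schedule", "thetas", "responses",
                          "spare", paste0("cond_", config$conditions)))
  bank <- resolve_bank(config, seeds[["bank"]])
  if (is.null(true_thetas)) {
    population <- generate_population(config$n_persons, config$hyper,
                                      seeds[["population"]])
    schedule <- generate_schedule(population$person_id, config$n_days,
                                  config$prompts_per_day_range,
                                  config$compliance, config$waking,
                                  seeds[["schedule"]])
    truth <- generate_true_thetas(population, schedule, config$cutoff,
                                  seeds[["thetas"]])
  } else {
    population <- NULL
    truth <- external_truth(true_thetas, config$cutoff)
  }
  response_u <- with_seed(seeds[["responses"]],
                          matrix(stats::runif(nrow(truth) * bank_size(bank)),
                                 nrow(truth), bank_size(bank)))
  records <- lapply(config$conditions, function(cond) {
    run_condition(cond, truth, bank, config, response_u,
                  seeds[[paste0("cond_", cond)]])
  })
  structure(
    list(records = do.call(rbind, records), truth = truth,
         population = population, bank = bank, config = config, seeds = seeds),
    class = "jita_study"
  )
}

# Externally supplied truth: one row per prompt; true cutoffs from a
# per-person cosinor fit to the supplied values (the known-truth analogue of
# estimating each person's cycle from their complete series).
external_truth <- function(true_thetas, cutoff) {
  req <- c("person_id", "day", "hour", "theta")
  if (!is.data.frame(true_thetas) || !all(req %in% names(true_thetas))) {
    stop_jita("external truth needs columns person_id, day, hour, theta",
              "jitaema_format_error")
  }
  out <- true_thetas[order(true_thetas$person_id, true_thetas$day,
                           true_thetas$hour), , drop = FALSE]
  names(out)[names(out) == "theta"] <- "true_theta"
  out$week <- as.integer(ceiling(out$day / 7))
  if (cutoff$kind == "uniform") {
    out$true_cutoff <- cutoff$uniform_z
  } else {
    out$true_cutoff <- NA_real_
    for (p in unique(out$person_id)) {
      rows <- out$person_id == p
      fit <- fit_cosinor(out$hour[rows], out$true_theta[rows])
      out$true_cutoff[rows] <- predict_cosinor(fit, out$hour[rows]) +
        cutoff$delta_sd * fit$resid_sd
    }
  }
  out$true_class <- ifelse(out$true_theta > out$true_cutoff, "above", "below")
  out
}

#' @export
print.jita_study <- function(x, ...) {
  cat(sprintf("<jita_study> %d prompts x %d condition(s) [%s cutoff], bank '%s' (%d items)\n",
              nrow(x$truth), length(x$config$conditions), x$config$cutoff$kind,
              x$bank$name, bank_size(x$bank)))
  invisible(x)
}
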