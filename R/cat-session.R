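# One adaptive (or nonadaptive) assessment session at a single EMA prompt:
# item selection, interim MAP scoring, stopping, classification.

#' Item-selector specification
#'
#' @param kind `"random"` (uniform over unadministered items), `"max_info"`
#'   (argmax Fisher information at the current selection theta), or `"mei"`
#'   (maximum expected information).
#' @param rng_seed Optional integer seed for the session's private random
#'   stream (random selection and tie-breaking); `NULL` uses the global RNG.
#' @export
selector_spec <- function(kind = c("mei", "max_info", "random"), rng_seed = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, rng_seed = rng_seed), class = "selector_spec")
}

#' Stopping-rule specification
#'
#' Three stopping rules: `fixed_length` stops after exactly `fixed_n` items;
#' `se_threshold` stops once the standard error of measurement drops below
#' `se_threshold`; `classification_confidence` stops as soon as the Wald
#' confidence interval around the interim estimate excludes the
#' classification cutoff. All rules are capped at `max_items`.
#'
#' @param kind One of `"classification_confidence"`, `"se_threshold"`,
#'   `"fixed_length"`.
#' @param max_items Hard cap on items per prompt (default 5).
#' @param fixed_n Required for `fixed_length`.
#' @param se_threshold Required for `se_threshold` (e.g. 0.3, i.e.
#'   reliability 1 - 0.3^2 = 0.91).
#' @param confidence Confidence level of the classification interval
#'   (default 0.95).
#' @export
stopping_spec <- function(kind = c("classification_confidence", "se_threshold",
                                   "fixed_length"),
                          max_items = 5L, fixed_n = NULL, se_threshold = NULL,
                          confidence = 0.95) {
  kind <- match.arg(kind)
  max_items <- as.integer(max_items)
  if (max_items < 1L) stop_jita("`max_items` must be >= 1", "jitaema_argument_error")
  if (kind == "fixed_length") {
    if (is.null(fixed_n)) {
      stop_jita("`fixed_n` is required for fixed_length stopping",
                "jitaema_argument_error")
    }
    fixed_n <- as.integer(fixed_n)
    if (fixed_n < 1L || fixed_n > max_items) {
      stop_jita("`fixed_n` must be in 1..max_items", "jitaema_argument_error")
    }
  }
  if (kind == "se_threshold") {
    if (is.null(se_threshold) || !is_scalar_number(se_threshold) || se_threshold <= 0) {
      stop_jita("positive `se_threshold` is required for se_threshold stopping",
                "jitaema_argument_error")
    }
  }
  if (!is_scalar_number(confidence) || confidence <= 0 || confidence >= 1) {
    stop_jita("`confidence` must be in (0, 1)", "jitaema_argument_error")
  }
  structure(list(kind = kind, max_items = max_items, fixed_n = fixed_n,
                 se_threshold = se_threshold, confidence = confidence),
            class = "stopping_spec")
}

# private RNG stream helpers --------------------------------------------------

rng_state_init <- function(seed) {
  if (is.null(seed)) return(NULL)
  with_seed(seed, get(".Random.seed", envir = globalenv()))
}

# Evaluate `expr` under the session stream; returns list(value, state).
rng_draw <- function(state, expr) {
  if (is.null(state)) return(list(value = force(expr), state = NULL))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", state, envir = globalenv())
  value <- force(expr)
  new_state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  list(value = value, state = new_state)
}

#' Start a CAT session for one EMA prompt
#'
#' The scoring prior stays as given (normal, by default N(0, 1)) throughout
#' the session; `init_theta` seeds only the selection state used to pick the
#' first item (e.g. the previous prompt's estimate, or a cosinor prediction
#' for the current time of day).
#'
#' @param bank An [item_bank()] (nonempty).
#' @param prior A [prior_spec()].
#' @param selector A [selector_spec()].
#' @param stopping A [stopping_spec()].
#' @param cutoff Classification cutoff for this prompt (latent z units), or
#'   `NULL` when the prompt is not classified.
#' @param init_theta Starting selection theta (default: prior mean).
#' @return A `cat_session` object.
#' @export
start_session <- function(bank, prior = prior_spec(),
                          selector = selector_spec(),
                          stopping = stopping_spec(),
                          cutoff = NULL, init_theta = prior$mean) {
  stopifnot(inherits(bank, "item_bank"), inherits(prior, "prior_spec"),
            inherits(selector, "selector_spec"), inherits(stopping, "stopping_spec"))
  if (bank_size(bank) == 0L) {
    stop_jita("cannot start a session on an empty bank", "jitaema_argument_error")
  }
  structure(
    list(bank = bank, pars = bank_params(bank), prior = prior,
         selector = selector, stopping = stopping, cutoff = cutoff,
         init_theta = init_theta,
         administered = list(item_id = character(0), category = integer(0)),
         triples = list(a = numeric(0), blo = numeric(0), bhi = numeric(0)),
         interim = theta_estimate(prior$mean, prior$sd, 0L),
         sel_theta = init_theta,
         rng = rng_state_init(selector$rng_seed)),
    class = "cat_session"
  )
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf("<cat_session> %s selector, %s stopping; %d item(s); theta = %.3f (se %.3f)\n",
              x$selector$kind, x$stopping$kind, length(x$administered$item_id),
              x$interim$theta, x$interim$se))
  invisible(x)
}

unadministered_idx <- function(session) {
  which(!(session$pars$ids %in% session$administered$item_id))
}

# Expected-information scores for all candidates at once; one vectorised
# Newton solve over every (candidate, category) hypothetical update.
mei_scores_all <- function(session, cand_idx) {
  pars <- session$pars
  Ks <- pars$K[cand_idx]
  pair_item <- rep(cand_idx, Ks)
  pair_cat <- unlist(lapply(Ks, seq_len))
  extra <- resp_triples(pars, pair_item, pair_cat)
  theta_k <- map_newton(session$triples, session$prior, extra = extra,
                        start = session$sel_theta, m = length(pair_item))
  pred_p <- grm_prob(extra$a, extra$blo, extra$bhi, session$sel_theta)
  info_k <- numeric(length(pair_item))
  for (ci in cand_idx) {
    sel <- pair_item == ci
    info_k[sel] <- item_info_pars(pars, ci, theta_k[sel])
  }
  # normalise predictive probabilities per candidate (guards the 1e-300 floor)
  as.numeric(rowsum(pred_p * info_k, pair_item) / rowsum(pred_p, pair_item))
}

#' Maximum-expected-information score of a candidate item
#'
#' Weighted sum, over the candidate's response categories, of the item's
#' Fisher information at the MAP estimate updated as if that category had
#' been answered, weighted by the predictive category probability at the
#' current selection theta.
#'
#' @param session A `cat_session`.
#' @param item_id Unadministered candidate item.
#' @return Nonnegative expected information.
#' @export
mei_score <- function(session, item_id) {
  stopifnot(inherits(session, "cat_session"))
  idx <- match(item_id, session$pars$ids)
  if (is.na(idx)) stop_jita(sprintf("unknown item '%s'", item_id),
                            "jitaema_argument_error")
  if (item_id %in% session$administered$item_id) {
    stop_jita(sprintf("item '%s' already administered", item_id),
              "jitaema_argument_error")
  }
  mei_scores_all(session, idx)
}

#' Select the next item to administer
#'
#' @param session A `cat_session`.
#' @return The selected `item_id`. Ties in the argmax criteria are broken
#'   uniformly at random with the session's random stream.
#' @export
select_next_item <- function(session) {
  stopifnot(inherits(session, "cat_session"))
  remaining <- unadministered_idx(session)
  if (length(remaining) == 0L) {
    stop_jita("no unadministered items left in the bank", "jitaema_bank_exhausted")
  }
  if (length(remaining) == 1L) {
    return(list(item_id = session$pars$ids[remaining], session = session))
  }
  if (session$selector$kind == "random") {
    d <- rng_draw(session$rng, remaining[sample.int(length(remaining), 1L)])
    session$rng <- d$state
    return(list(item_id = session$pars$ids[d$value], session = session))
  }
  crit <- if (session$selector$kind == "max_info") {
    vapply(remaining, function(i) item_info_pars(session$pars, i, session$sel_theta), 0)
  } else {
    mei_scores_all(session, remaining)
  }
  top <- which(crit >= max(crit) - 1e-12)
  pick <- if (length(top) == 1L) top else {
    d <- rng_draw(session$rng, top[sample.int(length(top), 1L)])
    session$rng <- d$state
    d$value
  }
  list(item_id = session$pars$ids[remaining[pick]], session = session)
}

#' Record a response and rescore the session
#'
#' Appends the response, recomputes the interim MAP estimate over all
#' recorded responses, and moves the selection theta to the new estimate.
#'
#' @param session A `cat_session`.
#' @param item_id The administered item.
#' @param category Response category (1-based).
#' @return The updated session.
#' @export
record_response <- function(session, item_id, category) {
  stopifnot(inherits(session, "cat_session"))
  idx <- match(item_id, session$pars$ids)
  if (is.na(idx)) stop_jita(sprintf("unknown item '%s'", item_id),
                            "jitaema_argument_error")
  if (item_id %in% session$administered$item_id) {
    stop_jita(sprintf("item '%s' already administered in this prompt", item_id),
              "jitaema_argument_error")
  }
  category <- as.integer(category)
  tr <- resp_triples(session$pars, idx, category)  # validates the category
  session$administered$item_id <- c(session$administered$item_id, item_id)
  session$administered$category <- c(session$administered$category, category)
  session$triples <- list(a = c(session$triples$a, tr$a),
                          blo = c(session$triples$blo, tr$blo),
                          bhi = c(session$triples$bhi, tr$bhi))
  theta <- map_newton(session$triples, session$prior, start = session$interim$theta)
  info <- 1 / session$prior$sd^2
  admin_idx <- match(session$administered$item_id, session$pars$ids)
  for (i in admin_idx) info <- info + item_info_pars(session$pars, i, theta)
  session$interim <- theta_estimate(theta, 1 / sqrt(info),
                                    length(session$administered$item_id))
  session$sel_theta <- theta
  session
}

#' Classify an estimate against a cutoff
#'
#' The decision is `"above"` iff the point estimate strictly exceeds the
#' cutoff (forced decision when not confident); the confidence flag records
#' whether the symmetric Wald interval excludes the cutoff.
#'
#' @param estimate A [theta_estimate()].
#' @param cutoff Classification cutoff.
#' @param confidence Interval confidence level (default 0.95).
#' @return A `classification_result` with fields `decision`, `confident`,
#'   `ci_lo`, `ci_hi`.
#' @export
classify <- function(estimate, cutoff, confidence = 0.95) {
  stopifnot(inherits(estimate, "theta_estimate"))
  z <- stats::qnorm((1 + confidence) / 2)
  ci_lo <- estimate$theta - z * estimate$se
  ci_hi <- estimate$theta + z * estimate$se
  structure(
    list(decision = if (estimate$theta > cutoff) "above" else "below",
         confident = (cutoff < ci_lo) || (cutoff > ci_hi),
         ci_lo = ci_lo, ci_hi = ci_hi),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s (%sconfident), CI [%.3f, %.3f]\n",
              x$decision, if (x$confident) "" else "not ", x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Evaluate the session's stopping rule
#'
#' @param session A `cat_session`.
#' @return `list(stop = logical, reason = character)`; `reason` is
#'   `"continue"`, `"fixed_length"`, `"se_threshold"`, `"confident"`, or
#'   `"max_items"`. No rule ever allows more than `max_items` items.
#' @export
check_stop <- function(session) {
  stopifnot(inherits(session, "cat_session"))
  st <- session$stopping
  n <- session$interim$n_items
  if (st$kind == "fixed_length") {
    return(list(stop = n >= st$fixed_n,
                reason = if (n >= st$fixed_n) "fixed_length" else "continue"))
  }
  if (st$kind == "se_threshold") {
    if (session$interim$se < st$se_threshold) {
      return(list(stop = TRUE, reason = "se_threshold"))
    }
    if (n >= st$max_items) return(list(stop = TRUE, reason = "max_items"))
    return(list(stop = FALSE, reason = "continue"))
  }
  # classification_confidence
  if (is.null(session$cutoff)) {
    stop_jita("classification_confidence stopping requires a session cutoff",
              "jitaema_config_error")
  }
  if (n > 0L) {
    cl <- classify(session$interim, session$cutoff, st$confidence)
    if (cl$confident) return(list(stop = TRUE, reason = "confident"))
  }
  if (n >= st$max_items) return(list(stop = TRUE, reason = "max_items"))
  list(stop = FALSE, reason = "continue")
}

#' Run a full session against a responder
#'
#' Alternates [select_next_item()], [record_response()] and [check_stop()]
#' until the stopping rule fires (or the bank is exhausted).
#'
#' @param session A fresh `cat_session`.
#' @param responder Function `item_id -> category` supplying the answer to
#'   any administered item.
#' @return A list with `administered` (data frame), `estimate`
#'   ([theta_estimate()]), `stop_reason`, and, when the session has a cutoff,
#'   `classification` ([classify()] result).
#' @export
run_session <- function(session, responder) {
  stopifnot(inherits(session, "cat_session"), is.function(responder))
  repeat {
    sel <- select_next_item(session)
    session <- sel$session
    session <- record_response(session, sel$item_id, responder(sel$item_id))
    chk <- check_stop(session)
    if (chk$stop) {
      reason <- chk$reason
      break
    }
    if (length(unadministered_idx(session)) == 0L) {
      reason <- "bank_exhausted"
      break
    }
  }
  out <- list(administered = data.frame(item_id = session$administered$item_id,
                                        category = session$administered$category,
                                        stringsAsFactors = FALSE),
              estimate = session$interim, stop_reason = reason, session = session)
  if (!is.null(session$cutoff)) {
    out$classification <- classify(session$interim, session$cutoff,
                                   session$stopping$confidence)
  }
  class(out) <- "prompt_result"
  out
}

#' @export
print.prompt_result <- function(x, ...) {
  cat(sprintf("<prompt_result> %d item(s) [%s], stopped: %s\n",
              x$estimate$n_items, paste(x$administered$item_id, collapse = ", "),
              x$stop_reason))
  print(x$estimate)
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}
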