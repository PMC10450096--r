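#' Construct a graded-response-model item
#'
#' An item under the graded response model (GRM) is described by a positive
#' discrimination (slope) parameter `a` and `K - 1` strictly increasing
#' category thresholds `b` on the latent z metric, where `K` is the number of
#' ordered response categories.
#'
#' @param item_id Character scalar, unique within a bank.
#' @param discrimination Positive logit slope ("a").
#' @param thresholds Numeric vector of length `n_categories - 1`, strictly
#'   increasing ("b" parameters, latent z units).
#' @param n_categories Integer number of response categories, `K >= 2`.
#'   Defaults to `length(thresholds) + 1`.
#' @param label Optional item wording.
#' @return An object of class `grm_item`.
#' @examples
#' item("fat1", 2.0, c(-0.5, 0.5))
#' @export
item <- function(item_id, discrimination, thresholds,
                 n_categories = length(thresholds) + 1L, label = NA_character_) {
  if (!is.character(item_id) || length(item_id) != 1L || is.na(item_id) ||
      !nzchar(item_id)) {
    stop_jita("`item_id` must be a non-empty string", "jitaema_validation_error")
  }
  if (!is_scalar_number(discrimination) || discrimination <= 0) {
    stop_jita(sprintf("item '%s': discrimination must be a positive number", item_id),
              "jitaema_validation_error")
  }
  thresholds <- as.numeric(thresholds)
  if (anyNA(thresholds) || any(!is.finite(thresholds))) {
    stop_jita(sprintf("item '%s': thresholds must be finite", item_id),
              "jitaema_validation_error")
  }
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L) {
    stop_jita(sprintf("item '%s': n_categories must be >= 2", item_id),
              "jitaema_validation_error")
  }
  if (length(thresholds) != n_categories - 1L) {
    stop_jita(sprintf("item '%s': expected %d thresholds, got %d",
                      item_id, n_categories - 1L, length(thresholds)),
              "jitaema_validation_error")
  }
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop_jita(sprintf("item '%s': thresholds must be strictly increasing", item_id),
              "jitaema_validation_error")
  }
  structure(
    list(item_id = item_id, discrimination = discrimination,
         thresholds = thresholds, n_categories = n_categories,
         label = as.character(label)),
    class = "grm_item"
  )
}

#' @export
print.grm_item <- function(x, ...) {
  cat(sprintf("<grm_item> %s: a = %.3f, b = [%s], K = %d\n", x$item_id,
              x$discrimination, paste(sprintf("%.3f", x$thresholds), collapse = ", "),
              x$n_categories))
  invisible(x)
}

#' Construct an item bank
#'
#' @param items List of [item()] objects.
#' @param name Bank name.
#' @param metadata Named character list of free-form metadata.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items, name = "bank", metadata = list()) {
  if (!is.list(items) || (length(items) > 0 && !all(vapply(items, inherits, TRUE, "grm_item")))) {
    stop_jita("`items` must be a list of grm_item objects", "jitaema_validation_error")
  }
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids)) {
    stop_jita(sprintf("duplicate item_id(s): %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "jitaema_validation_error")
  }
  structure(
    list(items = items, name = as.character(name), metadata = metadata),
    class = "item_bank"
  )
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> '%s': %d items\n", x$name, length(x$items)))
  for (it in x$items) print(it)
  invisible(x)
}

#' @rdname item_bank
#' @param bank An `item_bank`.
#' @export
bank_size <- function(bank) length(bank$items)

#' @rdname item_bank
#' @export
item_ids <- function(bank) vapply(bank$items, `[[`, "", "item_id")

#' Look up an item by id
#' @param bank An `item_bank`.
#' @param item_id Item identifier.
#' @export
get_item <- function(bank, item_id) {
  idx <- match(item_id, item_ids(bank))
  if (is.na(idx)) {
    stop_jita(sprintf("no item '%s' in bank '%s'", item_id, bank$name),
              "jitaema_validation_error")
  }
  bank$items[[idx]]
}

# bank as flat parameter table used by the fast scoring engine:
# a (n), K (n), b (n x max(K-1)) padded with NA.
bank_params <- function(bank) {
  n <- bank_size(bank)
  K <- vapply(bank$items, `[[`, 0L, "n_categories")
  a <- vapply(bank$items, `[[`, 0, "discrimination")
  b <- matrix(NA_real_, n, max(c(K - 1L, 1L)))
  for (i in seq_len(n)) b[i, seq_len(K[i] - 1L)] <- bank$items[[i]]$thresholds
  list(ids = item_ids(bank), a = a, K = K, b = b)
}

bank_to_df <- function(bank) {
  pars <- bank_params(bank)
  nb <- ncol(pars$b)
  df <- data.frame(
    item_id = pars$ids, model = rep("graded", length(pars$ids)),
    n_categories = pars$K,
    a = pars$a, stringsAsFactors = FALSE
  )
  for (j in seq_len(nb)) df[[paste0("b", j)]] <- pars$b[, j]
  df$label <- vapply(bank$items, function(it) it$label %||% NA_character_, "")
  df
}

df_to_bank <- function(df, name = "bank", metadata = list()) {
  req <- c("item_id", "model", "n_categories", "a")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_jita(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
              "jitaema_format_error")
  }
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  items <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!identical(as.character(df$model[i]), "graded")) {
      stop_jita(sprintf("row %d: unsupported model '%s' (only 'graded')",
                        i, df$model[i]), "jitaema_format_error")
    }
    K <- as.integer(df$n_categories[i])
    b <- as.numeric(unlist(df[i, bcols, drop = TRUE]))
    b <- b[!is.na(b)]
    items[[i]] <- item(
      item_id = as.character(df$item_id[i]),
      discrimination = as.numeric(df$a[i]),
      thresholds = b, n_categories = K,
      label = if ("label" %in% names(df)) as.character(df$label[i]) else NA_character_
    )
  }
  item_bank(items, name = name, metadata = metadata)
}

#' Read an item bank from CSV or JSON
#'
#' The CSV dialect is comma-separated UTF-8 with header
#' `item_id,model,n_categories,a,b1..b{K-1},label`; `model` is fixed to
#' `graded`. The JSON form carries `name`, `metadata` and an `items` array
#' with the same fields.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @return A validated [item_bank()]; item order preserved.
#' @export
load_bank <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop_jita(sprintf("file not found: %s", path), "jitaema_format_error")
  }
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
      error = function(e) stop_jita(sprintf("cannot parse CSV '%s': %s",
                                            path, conditionMessage(e)),
                                    "jitaema_format_error")
    )
    df_to_bank(df, name = sub("\\.[^.]*$", "", basename(path)))
  } else {
    obj <- tryCatch(
      jsonlite::read_json(path, simplifyVector = FALSE),
      error = function(e) stop_jita(sprintf("cannot parse JSON '%s': %s",
                                            path, conditionMessage(e)),
                                    "jitaema_format_error")
    )
    items <- lapply(obj$items, function(x) {
      item(item_id = x$item_id, discrimination = x$a,
           thresholds = unlist(x$b), n_categories = x$n_categories,
           label = x$label %||% NA_character_)
    })
    item_bank(items, name = obj$name %||% "bank",
              metadata = lapply(obj$metadata %||% list(), as.character))
  }
}

#' Write an item bank to CSV or JSON
#'
#' @inheritParams load_bank
#' @param bank An [item_bank()].
#' @return Invisibly, `path`. The file round-trips losslessly through
#'   [load_bank()] (parameters written at full double precision).
#' @export
save_bank <- function(bank, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(bank, "item_bank"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- bank_to_df(bank)
    # full-precision doubles so load_bank() reproduces parameters bit-exactly
    num <- vapply(df, is.numeric, TRUE) & !(names(df) %in% "n_categories")
    for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    obj <- list(
      name = bank$name, metadata = bank$metadata,
      items = lapply(bank$items, function(it) {
        list(item_id = it$item_id, model = "graded",
             n_categories = it$n_categories, a = it$discrimination,
             b = it$thresholds, label = it$label)
      })
    )
    # digits = I(17): enough significant digits for bit-exact double round trips
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  }
  invisible(path)
}

#' Generate a synthetic GRM item bank
#'
#' Emulates a short polytomous fatigue bank: by default 13 items with five
#' ordered response categories, discriminations drawn uniformly from
#' `a_range`, and thresholds placed symmetrically around a per-item center
#' drawn from `b_center_range`, with gaps proportional to `b_spread`. The
#' defaults put the bulk of the information above average severity, the
#' typical calibration profile of symptom banks.
#'
#' @param n_items Number of items (default 13).
#' @param n_categories Categories per item (default 5).
#' @param a_range Range for uniform discrimination draws (default `c(1.5, 3.5)`).
#' @param b_center_range Range for uniform threshold-center draws
#'   (default `c(-1, 2)`).
#' @param b_spread Positive scale of inter-threshold gaps (default 0.5);
#'   gaps are `b_spread * U(0.5, 1.5)`.
#' @param seed Integer seed; generation is a pure function of the arguments.
#' @param name Bank name.
#' @return An [item_bank()] whose items all satisfy the GRM invariants.
#' @examples
#' b <- generate_synthetic_bank(seed = 1)
#' bank_size(b)
#' @export
generate_synthetic_bank <- function(n_items = 13L, n_categories = 5L,
                                    a_range = c(1.5, 3.5),
                                    b_center_range = c(-1, 2),
                                    b_spread = 0.5, seed = 1L,
                                    name = "synthetic_bank") {
  if (!is_scalar_number(n_items) || n_items < 1) {
    stop_jita("`n_items` must be >= 1", "jitaema_argument_error")
  }
  if (!is_scalar_number(n_categories) || n_categories < 2) {
    stop_jita("`n_categories` must be >= 2", "jitaema_argument_error")
  }
  if (length(a_range) != 2L || a_range[1] <= 0 || diff(a_range) < 0) {
    stop_jita("`a_range` must be (lo, hi) with 0 < lo <= hi", "jitaema_argument_error")
  }
  if (length(b_center_range) != 2L || diff(b_center_range) < 0) {
    stop_jita("`b_center_range` must be (lo, hi) with lo <= hi", "jitaema_argument_error")
  }
  if (!is_scalar_number(b_spread) || b_spread <= 0) {
    stop_jita("`b_spread` must be positive", "jitaema_argument_error")
  }
  n_items <- as.integer(n_items)
  n_categories <- as.integer(n_categories)
  items <- with_seed(seed, {
    lapply(seq_len(n_items), function(i) {
      a <- stats::runif(1, a_range[1], a_range[2])
      center <- stats::runif(1, b_center_range[1], b_center_range[2])
      gaps <- b_spread * stats::runif(n_categories - 2L, 0.5, 1.5)
      b <- if (n_categories == 2L) center else {
        cum <- c(0, cumsum(gaps))
        center + cum - mean(cum)
      }
      item(sprintf("item%02d", i), a, b, n_categories)
    })
  })
  item_bank(items, name = name,
            metadata = list(generator = "generate_synthetic_bank",
                            seed = as.character(seed)))
}
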