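# Two-group linear discriminant machinery with Wilks-lambda stepwise
# descriptor selection. The discriminant function is the Fisher linear
# discriminant with pooled covariance and equal priors, with the intercept
# placed so that the decision boundary sits at DF = 0: DF > 0 predicts
# "active", DF < 0 predicts "inactive".

#' Construct a discriminant model object
#'
#' @param descriptors Character vector of descriptor names, in order.
#' @param coefficients Numeric vector, one per descriptor (may be `NA` for
#'   published models whose coefficients were not released in usable form).
#' @param intercept Intercept term a0.
#' @param stats Named list with `N`, `wilks_lambda`, `F`, `p` (any may be
#'   `NA`).
#' @param provenance `"fitted"` or `"published"`.
#' @param name Optional model name (e.g. `"DF_gen"`).
#' @return A `discriminant_model` object.
#' @export
discriminant_model <- function(descriptors, coefficients, intercept,
                               stats = list(N = NA, wilks_lambda = NA,
                                            F = NA, p = NA),
                               provenance = c("fitted", "published"),
                               name = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(length(descriptors) == length(coefficients))
  if (!is.na(stats$wilks_lambda))
    stopifnot(stats$wilks_lambda >= 0, stats$wilks_lambda <= 1)
  structure(
    list(name = name, descriptors = as.character(descriptors),
         coefficients = as.numeric(coefficients),
         intercept = as.numeric(intercept),
         stats = stats, provenance = provenance),
    class = "discriminant_model"
  )
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model%s> %s, %d descriptor(s)\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$provenance, length(x$descriptors)))
  if (!anyNA(x$coefficients)) {
    terms <- paste(sprintf("%+.4g*%s", x$coefficients, x$descriptors),
                   collapse = " ")
    cat("  DF =", sprintf("%.4g", x$intercept), terms, "\n")
  } else {
    cat("  descriptors:", paste(x$descriptors, collapse = ", "),
        "(coefficients unavailable)\n")
  }
  s <- x$stats
  cat(sprintf("  N = %s, Wilks lambda = %s, F = %s, p = %s\n",
              format(s$N), format(s$wilks_lambda), format(s$F), format(s$p)))
  invisible(x)
}

#' Evaluate a discriminant function over a library
#'
#' Computes `DF = a0 + sum(a_i * descriptor_i)` for every row. The sign of
#' DF is the binary class: positive means predicted active.
#'
#' @param data A data frame with one column per model descriptor (extra
#'   columns pass through), or a single named numeric vector.
#' @param model A `discriminant_model`.
#' @param col Name of the output column (default `"df"`).
#' @return `data` as a tibble with the DF column appended (or a single
#'   number when `data` was a named vector).
#' @export
#' @examples
#' m <- discriminant_model(c("x", "y"), c(1, -1), 0)
#' evaluate_df(c(x = 2, y = 2), m)  # boundary: 0
evaluate_df <- function(data, model, col = "df") {
  stopifnot(inherits(model, "discriminant_model"))
  if (anyNA(model$coefficients))
    stop("model has no usable coefficients (published registry entry); ",
         "fit a model or supply coefficients", call. = FALSE)
  if (is.numeric(data) && !is.null(names(data))) {
    missing <- setdiff(model$descriptors, names(data))
    if (length(missing))
      stop("missing descriptor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    return(model$intercept +
             sum(model$coefficients * data[model$descriptors]))
  }
  missing <- setdiff(model$descriptors, names(data))
  if (length(missing))
    stop("missing descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(dplyr::select(tibble::as_tibble(data),
                               dplyr::all_of(model$descriptors)))
  df <- drop(X %*% model$coefficients) + model$intercept
  out <- tibble::as_tibble(data)
  out[[col]] <- df
  out
}

# internal: X matrix + 0/1 active indicator from a labeled library
.design <- function(data, descriptors, label_col = "label",
                    active = "active") {
  stopifnot(all(descriptors %in% names(data)))
  y <- data[[label_col]] == active
  if (!any(y) || all(y))
    stop("both classes must be non-empty", call. = FALSE)
  X <- as.matrix(dplyr::select(tibble::as_tibble(data),
                               dplyr::all_of(descriptors)))
  storage.mode(X) <- "double"
  list(X = X, y = y)
}

#' Wilks' lambda of a descriptor subset
#'
#' `det(W) / det(T)` with `W` the pooled within-group scatter and `T` the
#' total scatter over the selected descriptor columns. 0 means perfect
#' separation, 1 none.
#'
#' @param data Labeled library: data frame with descriptor columns and a
#'   label column.
#' @param descriptors Character vector of descriptor column names.
#' @param label_col Name of the label column (default `"label"`).
#' @param active Label value denoting the active class.
#' @return Lambda in \[0, 1\].
#' @export
wilks_lambda <- function(data, descriptors, label_col = "label",
                         active = "active") {
  d <- .design(data, descriptors, label_col, active)
  X <- d$X; y <- d$y
  center <- function(M) sweep(M, 2, colMeans(M))
  Tm <- crossprod(center(X))
  W <- crossprod(center(X[y, , drop = FALSE])) +
       crossprod(center(X[!y, , drop = FALSE]))
  dT <- det(Tm)
  if (abs(dT) < .Machine$double.eps^0.9)
    stop("singular total scatter matrix: descriptors are collinear or ",
         "constant", call. = FALSE)
  lam <- det(W) / dT
  min(max(lam, 0), 1)
}

#' Convert Wilks' lambda to an F statistic (two groups)
#'
#' `F = ((N - p - 1) / p) * ((1 - lambda) / lambda)` with
#' `(p, N - p - 1)` degrees of freedom, the exact transformation for a
#' two-group discriminant with `p` variables.
#'
#' @param lambda Wilks' lambda in \[0, 1\].
#' @param N Total number of observations.
#' @param p Number of descriptors in the model.
#' @return List with `F`, `p_value`, `df1`, `df2`.
#' @export
#' @examples
#' wilks_to_f(0.686, 101, 3)  # F close to 14.8
wilks_to_f <- function(lambda, N, p) {
  stopifnot(N > p + 1, lambda >= 0, lambda <= 1)
  df1 <- p
  df2 <- N - p - 1
  if (lambda == 0)
    return(list(F = Inf, p_value = 0, df1 = df1, df2 = df2))
  Fv <- (df2 / df1) * ((1 - lambda) / lambda)
  list(F = Fv, p_value = pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Fit a two-group Fisher discriminant on a fixed descriptor set
#'
#' Pooled-covariance linear discriminant with equal priors; the intercept
#' places the boundary at DF = 0 halfway between the class centroids, and
#' the sign is oriented so actives score positive.
#'
#' @inheritParams wilks_lambda
#' @param name Optional model name.
#' @return A `discriminant_model` with training statistics.
#' @export
fit_discriminant <- function(data, descriptors, label_col = "label",
                             active = "active", name = NULL) {
  d <- .design(data, descriptors, label_col, active)
  X <- d$X; y <- d$y
  na <- sum(y); ni <- sum(!y); N <- na + ni
  mu_a <- colMeans(X[y, , drop = FALSE])
  mu_i <- colMeans(X[!y, , drop = FALSE])
  center <- function(M) sweep(M, 2, colMeans(M))
  Sp <- (crossprod(center(X[y, , drop = FALSE])) +
         crossprod(center(X[!y, , drop = FALSE]))) / (N - 2)
  coef <- drop(solve(Sp, mu_a - mu_i))
  intercept <- -sum(coef * (mu_a + mu_i) / 2)
  lam <- wilks_lambda(data, descriptors, label_col, active)
  ft <- wilks_to_f(lam, N, length(descriptors))
  discriminant_model(
    descriptors, coef, intercept,
    stats = list(N = N, wilks_lambda = lam, F = ft$F, p = ft$p_value),
    provenance = "fitted", name = name
  )
}

# partial F test for adding/removing one variable (two groups):
# partial lambda = lambda_big / lambda_small over nested models,
# F = (N - q - 1) * (1 - pl) / pl with (1, N - q - 1) df, q the size of
# the larger model
.partial_f <- function(lambda_small, lambda_big, N, q) {
  pl <- lambda_big / lambda_small
  pl <- min(max(pl, .Machine$double.eps), 1)
  df2 <- N - q - 1
  Fv <- df2 * (1 - pl) / pl
  c(F = Fv, p = pf(Fv, 1, df2, lower.tail = FALSE))
}

#' Hybrid stepwise descriptor selection by Wilks' lambda
#'
#' Forward-backward selection: at each step the candidate whose addition
#' minimizes Wilks' lambda enters if its partial-F p-value is below
#' `p_enter`; afterwards any included descriptor whose removal p-value
#' exceeds `p_remove` leaves. Stops at convergence or `max_terms`
#' descriptors. Ties are broken by descriptor name so runs are
#' deterministic. Candidates with (near-)zero variance or whose addition
#' makes the scatter singular are skipped.
#'
#' @inheritParams wilks_lambda
#' @param candidates Descriptor columns to consider (default: every numeric
#'   column except the label and an `id` column).
#' @param p_enter,p_remove Entry/removal p-value thresholds (default 0.05).
#' @param max_terms Maximum number of descriptors (default 20).
#' @param verbose Print the selection path?
#' @return A fitted `discriminant_model`; intercept-only (no descriptors)
#'   with a warning when nothing passes entry.
#' @export
stepwise_select <- function(data, candidates = NULL, p_enter = 0.05,
                            p_remove = 0.05, max_terms = 20,
                            label_col = "label", active = "active",
                            verbose = FALSE, name = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(candidates)) {
    candidates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                          c(label_col, "id"))
  }
  keep <- vapply(candidates, function(v) {
    s <- stats::sd(data[[v]])
    is.finite(s) && s > 1e-12
  }, TRUE)
  candidates <- sort(candidates[keep])
  N <- nrow(data)

  selected <- character(0)
  lam_cur <- 1
  repeat {
    changed <- FALSE
    # forward step
    if (length(selected) < max_terms) {
      pool <- setdiff(candidates, selected)
      lams <- vapply(pool, function(v) {
        tryCatch(wilks_lambda(data, c(selected, v), label_col, active),
                 error = function(e) NA_real_)
      }, 0)
      ok <- !is.na(lams)
      if (any(ok)) {
        pool <- pool[ok]; lams <- lams[ok]
        best <- pool[order(lams, pool)][1]
        lam_new <- lams[match(best, pool)]
        pf_ <- .partial_f(lam_cur, lam_new, N, length(selected) + 1L)
        if (pf_["p"] < p_enter) {
          selected <- c(selected, best)
          lam_cur <- lam_new
          changed <- TRUE
          if (verbose)
            message(sprintf("+ %s  (lambda = %.4f, p = %.3g)",
                            best, lam_new, pf_["p"]))
        }
      }
    }
    # backward step
    if (length(selected) > 1L) {
      repeat {
        ps <- vapply(selected, function(v) {
          lam_wo <- wilks_lambda(data, setdiff(selected, v),
                                 label_col, active)
          .partial_f(lam_wo, lam_cur, N, length(selected))["p"]
        }, 0)
        worst <- selected[order(-ps, selected)][1]
        if (ps[match(worst, selected)] > p_remove) {
          selected <- setdiff(selected, worst)
          lam_cur <- wilks_lambda(data, selected, label_col, active)
          changed <- TRUE
          if (verbose) message(sprintf("- %s  (p = %.3g)", worst,
                                       ps[match(worst, selected)]))
        } else break
        if (length(selected) <= 1L) break
      }
    }
    if (!changed || length(selected) >= max_terms) break
  }

  if (length(selected) == 0L) {
    warning("no descriptor passed the entry threshold; ",
            "returning an intercept-only model")
    y <- data[[label_col]] == active
    return(discriminant_model(character(0), numeric(0),
                              intercept = mean(y) - 0.5,
                              stats = list(N = N, wilks_lambda = 1,
                                           F = 0, p = 1),
                              provenance = "fitted", name = name))
  }
  fit_discriminant(data, selected, label_col, active, name = name)
}

#' Classification table of a discriminant model
#'
#' Tabulates predicted class by true class with percent-correct rounded to
#' integers, matching the layout of published QSAR classification tables,
#' plus a `total` row with the overall rate.
#'
#' @inheritParams wilks_lambda
#' @param model A `discriminant_model` with coefficients.
#' @return A tibble with columns `group`, `n_active`, `n_inactive`,
#'   `pct_correct`.
#' @export
confusion_summary <- function(data, model, label_col = "label",
                              active = "active") {
  scored <- evaluate_df(data, model, col = ".df")
  truth <- data[[label_col]] == active
  pred_active <- scored$.df > 0
  row <- function(sel, correct_is_active, group) {
    n_act <- sum(pred_active[sel])
    n_ina <- sum(!pred_active[sel])
    n_ok <- if (correct_is_active) n_act else n_ina
    tibble::tibble(group = group, n_active = n_act, n_inactive = n_ina,
                   pct_correct = round(100 * n_ok / sum(sel)))
  }
  total_ok <- sum(pred_active == truth)
  dplyr::bind_rows(
    row(truth, TRUE, "active"),
    row(!truth, FALSE, "inactive"),
    tibble::tibble(group = "total", n_active = sum(pred_active),
                   n_inactive = sum(!pred_active),
                   pct_correct = round(100 * total_ok / length(truth)))
  )
}

#' Leave-some-out cross-validation
#'
#' Repeats `folds` times: hold out `holdout_fraction` of each class
#' (holdout size rounded up, folds cycling through a seeded stratified
#' shuffle so they are as disjoint as the fraction permits), refit the
#' discriminant coefficients on the retained compounds over the model's
#' descriptor set, score the holdout, and recompute Wilks' lambda
#' (lambda') on the retained set. Degenerate folds (a class absent from
#' the training part) are skipped with a warning.
#'
#' @inheritParams confusion_summary
#' @param folds Number of repeats (default 10).
#' @param holdout_fraction Fraction held out per fold (default 0.2).
#' @param seed Integer seed for the stratified shuffle.
#' @return A list with `folds` (per-fold tibble: fold, n_holdout,
#'   pct_correct, lambda_prime) and `summary` (mean holdout percent
#'   correct, mean lambda').
#' @export
lsocv <- function(data, model, folds = 10, holdout_fraction = 0.2,
                  seed = 1L, label_col = "label", active = "active") {
  stopifnot(inherits(model, "discriminant_model"),
            length(model$descriptors) > 0L)
  data <- tibble::as_tibble(data)
  y <- data[[label_col]] == active
  idx_a <- which(y); idx_i <- which(!y)
  h_a <- max(1L, ceiling(holdout_fraction * length(idx_a)))
  h_i <- max(1L, ceiling(holdout_fraction * length(idx_i)))
  if (h_a >= length(idx_a) || h_i >= length(idx_i))
    stop("library too small for the requested holdout fraction",
         call. = FALSE)
  set.seed(seed)
  ord_a <- sample(idx_a); ord_i <- sample(idx_i)
  take <- function(ord, h, f) {
    pos <- ((f - 1L) * h + seq_len(h) - 1L) %% length(ord) + 1L
    ord[pos]
  }
  res <- purrr::map_dfr(seq_len(folds), function(f) {
    hold <- c(take(ord_a, h_a, f), take(ord_i, h_i, f))
    train <- setdiff(seq_len(nrow(data)), hold)
    ytr <- y[train]
    if (!any(ytr) || all(ytr)) {
      warning(sprintf("fold %d skipped: single-class training set", f))
      return(tibble::tibble(fold = f, n_holdout = length(hold),
                            pct_correct = NA_real_,
                            lambda_prime = NA_real_))
    }
    m <- fit_discriminant(data[train, ], model$descriptors,
                          label_col, active)
    scored <- evaluate_df(data[hold, ], m, col = ".df")
    acc <- mean((scored$.df > 0) == y[hold])
    tibble::tibble(fold = f, n_holdout = length(hold),
                   pct_correct = 100 * acc,
                   lambda_prime = m$stats$wilks_lambda)
  })
  list(folds = res,
       summary = tibble::tibble(
         mean_pct_correct = mean(res$pct_correct, na.rm = TRUE),
         mean_lambda_prime = mean(res$lambda_prime, na.rm = TRUE),
         n_folds_used = sum(!is.na(res$pct_correct))))
}

#' @export
#' @importFrom generics tidy
#' @method tidy discriminant_model
tidy.discriminant_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$descriptors),
    estimate = c(x$intercept, x$coefficients)
  )
}

#' @export
#' @importFrom generics glance
#' @method glance discriminant_model
glance.discriminant_model <- function(x, ...) {
  tibble::tibble(
    name = if (is.null(x$name)) NA_character_ else x$name,
    n_descriptors = length(x$descriptors),
    N = x$stats$N,
    wilks_lambda = x$stats$wilks_lambda,
    statistic = x$stats$F,
    p_value = x$stats$p,
    provenance = x$provenance
  )
}

#' Write / read a discriminant model as JSON
#'
#' @param model A `discriminant_model`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "discriminant_model"))
  jsonlite::write_json(
    list(name = model$name, descriptors = model$descriptors,
         coefficients = model$coefficients, intercept = model$intercept,
         stats = model$stats, provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats <- lapply(x$stats, function(v) if (is.null(v)) NA else v)
  discriminant_model(
    descriptors = x$descriptors %||% character(0),
    coefficients = x$coefficients %||% numeric(0),
    intercept = x$intercept,
    stats = stats,
    provenance = x$provenance,
    name = x$name
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
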