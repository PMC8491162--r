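# Pharmacological distribution diagrams: histogram of DF values per class
# with activity/inactivity expectancies, and the activity windows derived
# from them.

#' Build a pharmacological distribution diagram
#'
#' Bins the DF values of actives and inactives on a common uniform grid
#' and computes, per bin, the class fractions `a` and `i` (each summing to
#' 1 over the histogram) and the expectancies
#' \deqn{E_a = a / (i + 1), \qquad E_i = i / (a + 1).}
#' High `E_a` bins are DF regions where finding an active is most likely.
#'
#' @param data A data frame with a DF column and a label column, e.g. the
#'   output of [evaluate_df()].
#' @param df_col Name of the DF column (default `"df"`).
#' @param label_col Name of the label column (default `"label"`).
#' @param active Label value denoting actives.
#' @param bin_width Uniform bin width (default 0.25; bin edges are aligned
#'   to multiples of the width).
#' @return A `pdd_histogram`: tibble with columns `bin_lo`, `bin_hi`,
#'   `mid`, `a`, `i`, `e_a`, `e_i`, carrying the bin width and class sizes
#'   as attributes.
#' @export
build_pdd <- function(data, df_col = "df", label_col = "label",
                      active = "active", bin_width = 0.25) {
  stopifnot(bin_width > 0)
  df <- data[[df_col]]
  if (is.null(df) || length(df) == 0L)
    stop("no DF values to bin", call. = FALSE)
  y <- data[[label_col]] == active
  if (!any(y) || all(y))
    stop("both classes must be represented", call. = FALSE)
  lo <- floor(min(df) / bin_width) * bin_width
  hi <- ceiling(max(df) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  cut_idx <- pmin(pmax(findInterval(df, edges, rightmost.closed = TRUE), 1L),
                  length(edges) - 1L)
  n_bin <- length(edges) - 1L
  a <- tabulate(cut_idx[y], n_bin) / sum(y)
  i <- tabulate(cut_idx[!y], n_bin) / sum(!y)
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    mid = (edges[-1] + edges[-length(edges)]) / 2,
    a = a, i = i,
    e_a = a / (i + 1),
    e_i = i / (a + 1)
  )
  structure(out, class = c("pdd_histogram", class(out)),
            bin_width = bin_width, n_active = sum(y), n_inactive = sum(!y))
}

#' Activity windows container
#'
#' Bundles the DF intervals in which a model's prediction is taken at face
#' value: `active` intervals (assignment), optional `overlap` intervals
#' (assignment shared with other subtypes), and the classifiable range
#' `nc_bounds` outside of which a compound is non-classifiable (outside
#' the model's applicability domain).
#'
#' @param active A two-column matrix / data frame / list of `c(lo, hi)`
#'   intervals.
#' @param nc_bounds `c(lower, upper)` classifiable bounds.
#' @param overlap Optional intervals flagged as subtype-ambiguous.
#' @param model Optional model name.
#' @return An `activity_windows` object.
#' @export
activity_windows <- function(active, nc_bounds = c(-Inf, Inf),
                             overlap = NULL, model = NULL) {
  as_int <- function(x) {
    if (is.null(x)) return(matrix(numeric(0), 0, 2))
    if (is.list(x)) x <- do.call(rbind, x)
    x <- matrix(as.numeric(x), ncol = 2)
    stopifnot(all(x[, 1] <= x[, 2]))
    x[order(x[, 1]), , drop = FALSE]
  }
  act <- as_int(active)
  ovl <- as_int(overlap)
  if (nrow(act) > 1L && any(act[-1, 1] < act[-nrow(act), 2]))
    stop("active intervals overlap each other", call. = FALSE)
  if (nrow(act) && (min(act) < nc_bounds[1] || max(act) > nc_bounds[2]))
    stop("active intervals must lie inside the classifiable bounds",
         call. = FALSE)
  structure(list(model = model, active = act, overlap = ovl,
                 nc_bounds = as.numeric(nc_bounds)),
            class = "activity_windows")
}

#' @export
print.activity_windows <- function(x, ...) {
  fmt <- function(m) if (nrow(m) == 0) "none"
    else paste(sprintf("[%g, %g]", m[, 1], m[, 2]), collapse = " U ")
  cat(sprintf("<activity_windows%s>\n",
              if (is.null(x$model)) "" else paste0(" ", x$model)))
  cat("  active:      ", fmt(x$active), "\n")
  cat("  overlap:     ", fmt(x$overlap), "\n")
  cat(sprintf("  classifiable: [%g, %g]\n", x$nc_bounds[1], x$nc_bounds[2]))
  invisible(x)
}

#' Derive activity windows from a PDD
#'
#' Candidate windows are the maximal runs of bins in which actives are
#' denser than inactives (`a > i`, equivalently bin-level `E_a > E_i`),
#' the way the published diagrams delimit their activity regions. Each
#' run is then qualified by the range-level expectancy — `E_a = a/(i+1)`
#' with `a`, `i` the class fractions falling in the whole run — and kept
#' when it exceeds `expectancy_threshold` or when the run contains no
#' inactive density at all (a pure-active satellite region, like the
#' narrow secondary window of the published general model). Runs where
#' both range-level expectancies pass the threshold are additionally
#' reported as overlap intervals. The classifiable range is the observed
#' support of the histogram — beyond it a DF value is outside the
#' applicability domain.
#'
#' @param h A `pdd_histogram` from [build_pdd()].
#' @param expectancy_threshold Minimum range-level `E_a` (default 0.5).
#' @param model Optional model name stored in the result.
#' @return An `activity_windows` object.
#' @export
derive_windows <- function(h, expectancy_threshold = 0.5, model = NULL) {
  stopifnot(inherits(h, "pdd_histogram"))
  runs <- function(sel) {
    if (!any(sel)) return(list())
    r <- rle(sel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    lapply(keep, function(k) c(starts[k], ends[k]))
  }
  # empty bins are neutral: runs extend through zero-density gaps (sparse
  # histogram tails), then get trimmed back to bins with density
  sel <- h$a > h$i | (h$a == 0 & h$i == 0)
  cand <- lapply(runs(sel), function(rn) {
    dens <- which(h$a[rn[1]:rn[2]] > 0 | h$i[rn[1]:rn[2]] > 0)
    if (length(dens) == 0L) return(NULL)
    c(rn[1] + min(dens) - 1L, rn[1] + max(dens) - 1L)
  })
  cand <- Filter(Negate(is.null), cand)
  stats <- lapply(cand, function(rn) {
    sel <- rn[1]:rn[2]
    a <- sum(h$a[sel]); i <- sum(h$i[sel])
    list(iv = c(h$bin_lo[rn[1]], h$bin_hi[rn[2]]),
         e_a = a / (i + 1), e_i = i / (a + 1), i = i)
  })
  act <- lapply(Filter(function(s) s$e_a > expectancy_threshold || s$i == 0,
                       stats), `[[`, "iv")
  ovl <- lapply(Filter(function(s) s$e_a > expectancy_threshold &&
                         s$e_i > expectancy_threshold, stats), `[[`, "iv")
  support <- which(h$a > 0 | h$i > 0)
  nc <- c(h$bin_lo[min(support)], h$bin_hi[max(support)])
  activity_windows(active = if (length(act)) act else NULL, nc_bounds = nc,
                   overlap = if (length(ovl)) ovl else NULL, model = model)
}

#' Serialize / deserialize activity windows as JSON
#'
#' @param windows An `activity_windows` object, or (for writing) a named
#'   list of them.
#' @param path File path.
#' @return `path` (write) or an `activity_windows` / named list (read).
#' @export
write_windows <- function(windows, path) {
  enc <- function(w) list(
    model = w$model,
    active = apply(w$active, 1, function(r) as.list(r), simplify = FALSE),
    overlap = apply(w$overlap, 1, function(r) as.list(r), simplify = FALSE),
    nc_bounds = w$nc_bounds
  )
  payload <- if (inherits(windows, "activity_windows")) enc(windows)
             else lapply(windows, enc)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  x <- jsonlite::read_json(path)
  dec <- function(e) {
    ints <- function(l) if (length(l) == 0) NULL
      else lapply(l, function(p) as.numeric(c(p[[1]], p[[2]])))
    activity_windows(active = ints(e$active),
                     nc_bounds = as.numeric(unlist(e$nc_bounds)),
                     overlap = ints(e$overlap),
                     model = e$model)
  }
  if (!is.null(x$nc_bounds)) dec(x) else lapply(x, dec)
}

#' Plot a pharmacological distribution diagram
#'
#' Class-fraction bars for actives and inactives with the activity
#' expectancy overlaid, the standard way these diagrams are read when
#' choosing screening windows.
#'
#' @param object A `pdd_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdd_histogram
#' @export
autoplot.pdd_histogram <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("mid", "a", "i")],
    cols = c("a", "i"), names_to = "class", values_to = "fraction")
  long$class <- ifelse(long$class == "a", "active", "inactive")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55,
                      width = attr(object, "bin_width")) +
    ggplot2::geom_step(
      data = tibble::as_tibble(object),
      mapping = ggplot2::aes(x = .data$bin_lo, y = .data$e_a),
      inherit.aes = FALSE, linewidth = 0.4) +
    ggplot2::labs(x = "discriminant function value",
                  y = "class fraction / activity expectancy",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
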