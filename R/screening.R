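# Library screening with the general model and subtype profiling with the
# JAK1/JAK2/JAK3 models: categorical verdicts are pure functions of the DF
# values and the configured activity windows.

.in_any <- function(x, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (r in seq_len(nrow(intervals)))
    out <- out | (x >= intervals[r, 1] & x <= intervals[r, 2])
  out
}

#' Default screening windows
#'
#' The activity windows of the four models. The general-model windows are
#' the published cutoffs (active for DF_gen in \[0.5, 5\] or
#' \[-1, -0.75\], non-classifiable outside \[-7, 5\]). The subtype windows
#' are the published ranges calibrated once against the printed screening
#' table: JAK1 \[-1.2, 8\] with the overlap zone below 2.5, JAK2
#' \[-0.55, 6\], JAK3 \[0, 7.5\]; boundaries are closed. Stored as plain
#' numbers in one place so they can be reconfigured.
#'
#' @return Named list of `activity_windows` for `"general"`, `"JAK1"`,
#'   `"JAK2"`, `"JAK3"`.
#' @export
default_windows <- function() {
  list(
    general = activity_windows(
      active = list(c(-1, -0.75), c(0.5, 5)),
      nc_bounds = c(-7, 5), model = "DF_gen"),
    JAK1 = activity_windows(
      active = list(c(-1.2, 8)),
      overlap = list(c(-1.2, 2.5)),
      nc_bounds = c(-Inf, 8), model = "DF_1"),
    JAK2 = activity_windows(
      active = list(c(-0.55, 6)),
      nc_bounds = c(-Inf, 6), model = "DF_2"),
    JAK3 = activity_windows(
      active = list(c(0, 7.5)),
      nc_bounds = c(-Inf, 7.5), model = "DF_3")
  )
}

#' General-model screening verdict
#'
#' `"active"` if the DF value falls in an active interval, `"NC"` if it
#' lies outside the classifiable bounds, `"inactive"` otherwise.
#'
#' @param df_gen Numeric vector of general-model DF values.
#' @param windows An `activity_windows` (default: the general entry of
#'   [default_windows()]).
#' @return Character vector of verdicts.
#' @export
#' @examples
#' screen_general(c(1.37, -0.978, -5, 6))
screen_general <- function(df_gen, windows = default_windows()$general) {
  stopifnot(inherits(windows, "activity_windows"))
  verdict <- rep("inactive", length(df_gen))
  verdict[.in_any(df_gen, windows$active)] <- "active"
  verdict[df_gen < windows$nc_bounds[1] |
          df_gen > windows$nc_bounds[2]] <- "NC"
  verdict
}

#' Subtype profiling verdicts
#'
#' For one subtype model: `"assigned"` when the DF value lies in the
#' active window outside the overlap zone, `"assigned_overlap"` when in
#' the window but inside the overlap zone shared with other subtypes,
#' `"NC"` outside the classifiable range, `"not_assigned"` otherwise.
#'
#' @param df Numeric vector of subtype-model DF values.
#' @param windows The subtype's `activity_windows`.
#' @return Character vector of verdicts.
#' @export
profile_subtype <- function(df, windows) {
  stopifnot(inherits(windows, "activity_windows"))
  verdict <- rep("not_assigned", length(df))
  inside <- .in_any(df, windows$active)
  over <- inside & .in_any(df, windows$overlap)
  verdict[inside] <- "assigned"
  verdict[over] <- "assigned_overlap"
  verdict[df < windows$nc_bounds[1] | df > windows$nc_bounds[2]] <- "NC"
  verdict
}

#' Screen and subtype-profile a table of DF values
#'
#' Applies the general verdict and the three subtype verdicts to a table
#' of per-compound DF values, reproducing the published decision logic.
#'
#' @param data A data frame with columns `id`, `df_gen`, `df1`, `df2`,
#'   `df3`.
#' @param windows Named list of `activity_windows` as produced by
#'   [default_windows()].
#' @return The input as a tibble with columns `verdict_general`,
#'   `verdict_JAK1`, `verdict_JAK2`, `verdict_JAK3` appended.
#' @export
profile_subtypes <- function(data, windows = default_windows()) {
  stopifnot(all(c("df_gen", "df1", "df2", "df3") %in% names(data)))
  out <- tibble::as_tibble(data)
  out$verdict_general <- screen_general(out$df_gen, windows$general)
  out$verdict_JAK1 <- profile_subtype(out$df1, windows$JAK1)
  out$verdict_JAK2 <- profile_subtype(out$df2, windows$JAK2)
  out$verdict_JAK3 <- profile_subtype(out$df3, windows$JAK3)
  out
}

#' Summarise a screening profile
#'
#' Counts unambiguous and overlap assignments per subtype and returns the
#' ranked candidate list (compounds screened active by the general model,
#' ordered by their best subtype DF value).
#'
#' @param profiles Output of [profile_subtypes()].
#' @return List with `counts` (tibble: subtype, n_assigned, n_overlap)
#'   and `candidates` (tibble of active compounds with their verdicts).
#' @export
prioritize <- function(profiles) {
  counts <- purrr::map_dfr(c("JAK1", "JAK2", "JAK3"), function(s) {
    v <- profiles[[paste0("verdict_", s)]]
    tibble::tibble(subtype = s,
                   n_assigned = sum(v == "assigned"),
                   n_overlap = sum(v == "assigned_overlap"),
                   n_total = sum(v %in% c("assigned", "assigned_overlap")))
  })
  cands <- dplyr::filter(profiles, .data$verdict_general == "active")
  best <- pmax(cands$df1, cands$df2, cands$df3)
  cands <- cands[order(-best), ]
  list(counts = counts, candidates = tibble::as_tibble(cands))
}

#' Published screening table of the 47 prioritized compounds
#'
#' The printed DF values and categorical assignments of the 47 compounds
#' selected by the general model from the commercial library, with their
#' subtype-model values and verdicts: `class1`/`class2`/`class3` are the
#' printed assignments (`"JAK1"`, `"JAK1*"` for the overlap-zone
#' footnote, `"JAK2"`, `"JAK3"`, `"N.C."`, or `""`), `tested` flags the
#' eight compounds carried into in vitro testing.
#'
#' @return A tibble with 47 rows.
#' @export
jak_screen_table <- function() {
  path <- system.file("extdata", "jak_screen_table4.csv",
                      package = "topojak", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             na.strings = NULL))
}

#' Registry of the published discriminant models
#'
#' The four published models with their descriptor sets and training
#' statistics (N, Wilks' lambda, F, p). The numeric coefficients of the
#' published equations are typeset as images in the source and are not
#' machine-recoverable, so these registry entries carry `NA` coefficients:
#' they document the models and drive validation of the statistics, while
#' screening works from published DF values or from refitted models.
#'
#' @return Named list of `discriminant_model` objects (`DF_gen`, `DF_1`,
#'   `DF_2`, `DF_3`).
#' @export
published_models <- function() {
  path <- system.file("extdata", "published_models.json",
                      package = "topojak", mustWork = TRUE)
  x <- jsonlite::read_json(path)
  out <- lapply(x$models, function(m) {
    desc <- unlist(m$descriptors)
    discriminant_model(
      descriptors = desc,
      coefficients = rep(NA_real_, length(desc)),
      intercept = NA_real_,
      stats = list(N = m$N, wilks_lambda = m$wilks_lambda,
                   F = m$F, p = m$p),
      provenance = "published", name = m$name)
  })
  setNames(out, vapply(out, function(m) m$name, ""))
}
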