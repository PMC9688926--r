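#' Normalized projected area (NPA) curve of one organoid
#'
#' Divides a complete track's per-frame projected luminal areas by the mean
#' area over the first `window` time points (default 5), so every organoid
#' starts at NPA ~ 1 and the curve reads as a relative size change.
#'
#' @param areas numeric vector of per-frame areas (um^2) of one complete
#'   track, or a one-organoid `entries` subset from [link_frames()].
#' @param window number of baseline frames.
#' @param organoid_id,condition carried into the result.
#' @return An object of class `npa_curve`: list with `organoid_id`,
#'   `condition`, `baseline_area_um2`, `npa` (numeric vector), `window`.
#' @examples
#' compute_npa(c(90, 100, 110, 100, 100, 200))$baseline_area_um2 # 100
#' @export
compute_npa <- function(areas, window = 5L, organoid_id = NA,
                        condition = NA_character_) {
  if (is.data.frame(areas)) {
    df <- areas[order(areas$frame), , drop = FALSE]
    if (is.na(organoid_id) && "organoid_id" %in% names(df))
      organoid_id <- df$organoid_id[1]
    areas <- df$area_um2
  }
  stopifnot(is.numeric(areas), window >= 1, window <= length(areas))
  if (anyNA(areas))
    stop("track has missing frames; NPA is defined only for complete tracks")
  baseline <- mean(areas[seq_len(window)])
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline area over the first ", window, " frames must be > 0")
  structure(list(organoid_id = organoid_id, condition = condition,
                 baseline_area_um2 = baseline, npa = areas / baseline,
                 window = as.integer(window)),
            class = "npa_curve")
}

#' NPA curves for every complete track
#'
#' @param tracks an `organoid_tracks` object (already complete-filtered or
#'   not; incomplete tracks are dropped with the completeness rule).
#' @param window number of baseline frames.
#' @param condition condition name attached to every curve.
#' @return List of [compute_npa()] curves.
#' @export
npa_curves <- function(tracks, window = 5L, condition = NA_character_) {
  tracks <- filter_complete(tracks)
  ids <- tracks$summary$organoid_id
  lapply(ids, function(i)
    compute_npa(tracks$entries[tracks$entries$organoid_id == i, ,
                               drop = FALSE],
                window = window, organoid_id = i, condition = condition))
}

#' Per-frame median NPA of one condition
#'
#' The condition's growth readout: the median across organoids of the NPA at
#' each time point (for an even number of organoids, the midpoint of the two
#' central order statistics).
#'
#' @param curves list of `npa_curve`s of equal length.
#' @param condition condition name (defaults to the curves' common one).
#' @return An object of class `condition_summary`: list with `condition`,
#'   `median_npa` (per-frame vector), `final_npa`, `n_organoids`,
#'   `n_frames`.
#' @export
condition_median_curve <- function(curves, condition = NULL) {
  stopifnot(length(curves) >= 1)
  lens <- vapply(curves, function(cv) length(cv$npa), integer(1))
  if (length(unique(lens)) != 1)
    stop("curves have differing lengths")
  if (is.null(condition)) condition <- curves[[1]]$condition
  mat <- vapply(curves, function(cv) cv$npa, numeric(lens[1]))
  mat <- matrix(mat, nrow = lens[1])
  med <- apply(mat, 1, median)
  structure(list(condition = condition, median_npa = med,
                 final_npa = med[length(med)],
                 n_organoids = length(curves), n_frames = lens[1]),
            class = "condition_summary")
}

# integer rounding, half away from zero (display convention of the
# relative-size table)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Relative final organoid sizes across conditions
#'
#' The endpoint summary of the growth analysis: each condition's final
#' median NPA expressed as an integer percentage of the reference
#' condition's, plus the signed difference vs 100% (a size
#' reduction/increase), and optionally a high-dose vs low-dose ratio row.
#' Percentages are computed from the NPA values as given (full precision if
#' you pass full precision) and rounded half away from zero.
#'
#' @param summaries list of `condition_summary` objects, or a named numeric
#'   vector of final NPA values.
#' @param reference name of the reference condition (percent = 100).
#' @param dose_pair optional `c(high, low)` condition names for a
#'   high-dose/low-dose ratio row.
#' @return A data frame of class `relative_size_table` with columns
#'   `condition`, `final_npa`, `percent_vs_reference`,
#'   `diff_vs_reference`; the dose-ratio row (if requested) has condition
#'   `"<high>/<low>"` and `final_npa = NA`.
#' @examples
#' relative_size_table(
#'   c(untreated = 2.27, `SOR 4 uM` = 1.11), reference = "untreated")
#' @export
relative_size_table <- function(summaries, reference, dose_pair = NULL) {
  if (is.list(summaries) && !is.data.frame(summaries) &&
      all(vapply(summaries, inherits, logical(1), "condition_summary"))) {
    finals <- vapply(summaries, function(s) s$final_npa, numeric(1))
    names(finals) <- vapply(summaries, function(s) s$condition,
                            character(1))
  } else {
    finals <- summaries
    stopifnot(is.numeric(finals), !is.null(names(finals)))
  }
  if (!reference %in% names(finals))
    stop("reference condition '", reference, "' not present")
  ref <- finals[[reference]]
  pct <- round_half_away(100 * finals / ref)
  out <- data.frame(condition = names(finals),
                    final_npa = unname(finals),
                    percent_vs_reference = unname(pct),
                    diff_vs_reference = unname(pct) - 100,
                    stringsAsFactors = FALSE)
  if (!is.null(dose_pair)) {
    stopifnot(length(dose_pair) == 2,
              all(dose_pair %in% names(finals)))
    ratio <- round_half_away(100 * finals[[dose_pair[1]]] /
                               finals[[dose_pair[2]]])
    out <- rbind(out, data.frame(
      condition = paste(dose_pair, collapse = "/"),
      final_npa = NA_real_,
      percent_vs_reference = ratio,
      diff_vs_reference = ratio - 100, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  class(out) <- c("relative_size_table", "data.frame")
  out
}

#' Plot per-condition median NPA curves
#'
#' @param x list of `condition_summary` objects.
#' @param interval_h recording interval used for the time axis.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_median_curves <- function(x, interval_h = 0.5, ...) {
  stopifnot(length(x) >= 1)
  mat <- vapply(x, function(s) s$median_npa, numeric(x[[1]]$n_frames))
  tt <- (seq_len(nrow(mat)) - 1) * interval_h
  graphics::matplot(tt, mat, type = "l", lty = 1, lwd = 2,
                    xlab = "time [h]", ylab = "median NPA", ...)
  graphics::legend("topleft", legend = vapply(x, `[[`, character(1),
                                              "condition"),
                   col = seq_len(ncol(mat)), lty = 1, lwd = 2, bty = "n")
  invisible(mat)
}
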