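#' Parameters for frame-to-frame region linking
#'
#' Organoids embedded in the matrix barely move between 0.5 h frames, so a
#' greedy intersection-over-union (IoU) matcher replaces manual identity
#' bookkeeping. Pairs below `min_iou` or whose centroids moved more than
#' `max_centroid_shift_um` are not linked.
#'
#' @param min_iou minimum IoU for a link, in `[0, 1]`.
#' @param max_centroid_shift_um maximum centroid displacement per link.
#' @return An object of class `linking_params`.
#' @export
linking_params <- function(min_iou = 0.3, max_centroid_shift_um = 50) {
  stopifnot(min_iou >= 0, min_iou <= 1, max_centroid_shift_um > 0)
  structure(list(min_iou = min_iou,
                 max_centroid_shift_um = max_centroid_shift_um),
            class = "linking_params")
}

#' Link per-frame regions into per-organoid tracks
#'
#' Greedy one-to-one matching between the open tracks (each remembering its
#' most recent detection, possibly several frames back) and the regions of
#' the current frame, by descending pairwise IoU of the label masks.
#' Candidates below `min_iou` or beyond the centroid-shift bound are
#' rejected; ties break deterministically by higher IoU, then smaller
#' incumbent track id, then smaller region label. Unmatched regions start
#' new tracks; unmatched open tracks record a MISSING frame but stay open,
#' so an organoid that drops out for a frame can be re-acquired.
#'
#' @param frames list of `labeled_frame`s in temporal order.
#' @param regions morphometry table from [measure_frames()] (computed
#'   internally when omitted).
#' @param params a [linking_params()].
#' @param pixel_size_um pixel edge length, needed when `regions` is omitted.
#' @return An object of class `organoid_tracks`: list with
#'   \describe{
#'   \item{entries}{data frame `organoid_id`, `frame`, `label` (NA when
#'     missing), `area_um2`, `cx_um`, `cy_um`, `missing`.}
#'   \item{summary}{data frame `organoid_id`, `first_frame`, `n_detected`,
#'     `complete`.}
#'   \item{n_frames}{number of frames linked.}
#'   }
#' @export
link_frames <- function(frames, regions = NULL,
                        params = linking_params(), pixel_size_um = NULL) {
  if (length(frames) == 0) stop("no frames to link")
  nf <- length(frames)
  if (is.null(regions)) {
    stopifnot(!is.null(pixel_size_um))
    regions <- measure_frames(frames, pixel_size_um)
  }
  lab_of <- function(f) frames[[f]]$labels
  entries <- list()
  # open tracks: id, last frame seen, last label, last centroid
  open <- data.frame(id = integer(), last_frame = integer(),
                     last_label = integer(), cx = numeric(), cy = numeric())
  next_id <- 1L

  for (f in seq_len(nf)) {
    reg_f <- regions[regions$frame == f, , drop = FALSE]
    cur <- lab_of(f)
    assigned_track <- integer(0)
    assigned_label <- integer(0)

    if (nrow(open) && nrow(reg_f)) {
      cand <- list()
      for (ti in seq_len(nrow(open))) {
        prev <- lab_of(open$last_frame[ti])
        idx <- which(prev == open$last_label[ti])
        a_n <- length(idx)
        hits <- cur[idx]
        hits <- hits[hits > 0]
        if (!length(hits)) next
        tab <- table(hits)
        for (k in seq_along(tab)) {
          lb <- as.integer(names(tab)[k])
          inter <- as.integer(tab[k])
          b_n <- sum(cur == lb)
          iou <- inter / (a_n + b_n - inter)
          rr <- reg_f[reg_f$label == lb, ]
          shift <- sqrt((rr$cx_um - open$cx[ti])^2 +
                        (rr$cy_um - open$cy[ti])^2)
          if (iou >= params$min_iou &&
              shift <= params$max_centroid_shift_um)
            cand[[length(cand) + 1L]] <-
              data.frame(ti = ti, id = open$id[ti], label = lb, iou = iou)
        }
      }
      if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(-cand$iou, cand$id, cand$label), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          if (cand$id[k] %in% assigned_track ||
              cand$label[k] %in% assigned_label) next
          assigned_track <- c(assigned_track, cand$id[k])
          assigned_label <- c(assigned_label, cand$label[k])
          ti <- cand$ti[k]
          rr <- reg_f[reg_f$label == cand$label[k], ]
          entries[[length(entries) + 1L]] <- data.frame(
            organoid_id = cand$id[k], frame = f, label = cand$label[k],
            area_um2 = rr$area_um2, cx_um = rr$cx_um, cy_um = rr$cy_um,
            missing = FALSE)
          open$last_frame[ti] <- f
          open$last_label[ti] <- cand$label[k]
          open$cx[ti] <- rr$cx_um
          open$cy[ti] <- rr$cy_um
        }
      }
    }
    # unmatched open tracks: MISSING for this frame, stay open
    for (ti in which(!(open$id %in% assigned_track))) {
      entries[[length(entries) + 1L]] <- data.frame(
        organoid_id = open$id[ti], frame = f, label = NA_integer_,
        area_um2 = NA_real_, cx_um = NA_real_, cy_um = NA_real_,
        missing = TRUE)
    }
    # unmatched regions start new tracks (ordered by label)
    new_labs <- setdiff(reg_f$label, assigned_label)
    for (lb in sort(new_labs)) {
      rr <- reg_f[reg_f$label == lb, ]
      entries[[length(entries) + 1L]] <- data.frame(
        organoid_id = next_id, frame = f, label = lb,
        area_um2 = rr$area_um2, cx_um = rr$cx_um, cy_um = rr$cy_um,
        missing = FALSE)
      open <- rbind(open, data.frame(id = next_id, last_frame = f,
                                     last_label = lb, cx = rr$cx_um,
                                     cy = rr$cy_um))
      next_id <- next_id + 1L
    }
  }

  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(organoid_id = integer(), frame = integer(),
               label = integer(), area_um2 = numeric(), cx_um = numeric(),
               cy_um = numeric(), missing = logical())
  entries <- entries[order(entries$organoid_id, entries$frame), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  ids <- unique(entries$organoid_id)
  summary <- data.frame(
    organoid_id = ids,
    first_frame = vapply(ids, function(i)
      min(entries$frame[entries$organoid_id == i]), integer(1)),
    n_detected = vapply(ids, function(i)
      sum(!entries$missing[entries$organoid_id == i]), integer(1))
  )
  summary$complete <- summary$n_detected == nf
  structure(list(entries = entries, summary = summary, n_frames = nf),
            class = "organoid_tracks")
}

#' @export
print.organoid_tracks <- function(x, ...) {
  cat(sprintf(
    "<organoid_tracks> %d track(s) over %d frame(s); %d complete, %d excluded by the all-frames rule\n",
    nrow(x$summary), x$n_frames, sum(x$summary$complete),
    sum(!x$summary$complete)))
  invisible(x)
}

#' Keep only organoids detected in every frame
#'
#' The completeness rule of the growth analysis: an organoid missing from
#' at least one of the `n_frames` time points is excluded entirely.
#'
#' @param tracks an `organoid_tracks` object from [link_frames()].
#' @param n_frames number of frames a complete track must cover (defaults
#'   to the linked frame count).
#' @return An `organoid_tracks` object containing only complete tracks;
#'   input order is preserved.
#' @export
filter_complete <- function(tracks, n_frames = tracks$n_frames) {
  stopifnot(inherits(tracks, "organoid_tracks"))
  keep <- tracks$summary$organoid_id[tracks$summary$n_detected ==
                                       n_frames]
  structure(list(
    entries = tracks$entries[tracks$entries$organoid_id %in% keep, ,
                             drop = FALSE],
    summary = tracks$summary[tracks$summary$organoid_id %in% keep, ,
                             drop = FALSE],
    n_frames = tracks$n_frames
  ), class = "organoid_tracks")
}
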