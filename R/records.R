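# Archive ingestion and track assembly: validated CSV readers, the
# multi-target and no-image exclusion filters, and reviewer adjudication.
#
# A record is one ~1 Hz observation of one target; records sharing a
# track_id form a track, the unit of determination. Determinations are
# per-track and inherited by every record of the track, because all rates
# downstream are computed over records.

VALID_LABELS <- c("eagle", "non-eagle")

parse_utc <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

format_utc <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Read an archived record stream
#'
#' Expects a UTF-8 CSV with header
#' `track_id,tower_id,timestamp,x_m,y_m,z_m,system_label,confidence,has_image,target_index`.
#' Timestamps are ISO-8601 UTC (`2018-06-21T08:00:00Z`); labels are
#' lower-case `eagle` / `non-eagle`; confidence is a probability. Any
#' malformed row aborts with an error naming the first offending row.
#'
#' @param path File path.
#' @return A data frame of records, input order preserved, with `timestamp`
#'   parsed to POSIXct (UTC) and `has_image` logical.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(track_id = "character",
                                       tower_id = "character"))
  need <- c("track_id", "tower_id", "timestamp", "x_m", "y_m", "z_m",
            "system_label", "confidence", "has_image", "target_index")
  if (!all(need %in% names(df))) {
    stop("records file must have columns: ", paste(need, collapse = ", "))
  }
  ts <- parse_utc(df$timestamp)
  if (anyNA(ts)) {
    stop("malformed timestamp at row ", which(is.na(ts))[1])
  }
  df$timestamp <- ts
  for (col in c("x_m", "y_m", "z_m", "confidence")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("malformed number in ", col, " at row ",
                       which(is.na(v))[1])
    df[[col]] <- v
  }
  bad <- which(df$confidence < 0 | df$confidence > 1)
  if (length(bad)) stop("confidence outside [0,1] at row ", bad[1])
  bad <- which(!df$system_label %in% VALID_LABELS)
  if (length(bad)) stop("unknown system_label at row ", bad[1])
  df$has_image <- as.logical(df$has_image)
  if (anyNA(df$has_image)) {
    stop("malformed has_image at row ", which(is.na(df$has_image))[1])
  }
  df$target_index <- as.integer(df$target_index)
  validate_records(df)
  df
}

#' Validate a record data frame
#'
#' Checks the record invariants: confidence in \[0,1\], known labels, and
#' non-decreasing timestamps within each track.
#'
#' @param records A record data frame.
#' @return The input, invisibly.
#' @export
validate_records <- function(records) {
  stopifnot(all(records$confidence >= 0 & records$confidence <= 1),
            all(records$system_label %in% VALID_LABELS))
  ord <- order(records$track_id, records$timestamp)
  by_track <- split(as.numeric(records$timestamp), records$track_id)
  mono <- vapply(by_track, function(t) !is.unsorted(t), logical(1))
  if (!all(mono)) {
    stop("timestamps decrease within track ", names(by_track)[!mono][1])
  }
  invisible(records)
}

#' Write a record data frame to CSV
#'
#' Inverse of [read_records()]; a round trip is lossless to the second.
#'
#' @param records Record data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  out$timestamp <- format_utc(out$timestamp)
  out$has_image <- ifelse(out$has_image, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop secondary targets from multi-target instants
#'
#' When a single image contains more than one bird, the archive carries one
#' row per unique target at the same (track, timestamp). Only the first
#' target (`target_index == 0`, archive ingestion order) is retained at
#' those instants; single-target rows pass through untouched. The operation
#' is idempotent and never fabricates rows.
#'
#' @param records Record data frame.
#' @return The filtered record data frame.
#' @export
filter_multi_target <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$track_id, as.numeric(records$timestamp))
  multi <- key %in% key[duplicated(key)]
  keep <- !multi | records$target_index == 0L
  records[keep, , drop = FALSE]
}

#' Separate tracks that never recorded an image
#'
#' Tracks whose records all lack an image cannot be reviewed, so they are
#' excluded from every rate denominator but kept as a tally (the bookkeeping
#' row of the confusion table). Tracks with at least one image are kept.
#'
#' @param records Record data frame.
#' @return A list with elements `kept` (records of reviewable tracks) and
#'   `no_image` (records of image-less tracks). Row counts are conserved:
#'   `nrow(kept) + nrow(no_image) == nrow(records)`.
#' @export
filter_no_image_tracks <- function(records) {
  if (nrow(records) == 0L) {
    return(list(kept = records, no_image = records))
  }
  any_img <- tapply(records$has_image, records$track_id, any)
  img_tracks <- names(any_img)[any_img]
  is_kept <- records$track_id %in% img_tracks
  list(kept = records[is_kept, , drop = FALSE],
       no_image = records[!is_kept, , drop = FALSE])
}

#' Read a reviewer determination table
#'
#' Expects a UTF-8 CSV with header
#' `track_id,reviewer_1,reviewer_2,reviewer_3`; labels lower-case
#' `eagle` / `non-eagle`. The third reviewer's label must be present exactly
#' when the first two disagree.
#'
#' @param path File path.
#' @return A data frame of review sets.
#' @export
read_reviews <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(track_id = "character"),
                        na.strings = "")
  need <- c("track_id", "reviewer_1", "reviewer_2", "reviewer_3")
  if (!all(need %in% names(df))) {
    stop("reviews file must have columns: ", paste(need, collapse = ", "))
  }
  validate_reviews(df)
  df
}

#' @rdname read_reviews
#' @param reviews A review-set data frame.
#' @export
validate_reviews <- function(reviews) {
  for (col in c("reviewer_1", "reviewer_2")) {
    bad <- which(!reviews[[col]] %in% VALID_LABELS)
    if (length(bad)) stop("unknown label in ", col, " at row ", bad[1])
  }
  r3 <- reviews$reviewer_3
  bad <- which(!is.na(r3) & !r3 %in% VALID_LABELS)
  if (length(bad)) stop("unknown label in reviewer_3 at row ", bad[1])
  split_ <- reviews$reviewer_1 != reviews$reviewer_2
  if (any(split_ & is.na(r3))) {
    stop("reviewers disagree without a tiebreaker at row ",
         which(split_ & is.na(r3))[1])
  }
  if (any(!split_ & !is.na(r3))) {
    stop("reviewer_3 present although reviewers agree at row ",
         which(!split_ & !is.na(r3))[1])
  }
  invisible(reviews)
}

#' Adjudicate reviewer determinations
#'
#' A unanimous pair of primary reviews stands; a split is decided by the
#' third reviewer.
#'
#' @param reviews A review-set data frame (see [read_reviews()]).
#' @return A data frame `track_id`, `determination`.
#' @examples
#' adjudicate(data.frame(track_id = "t1", reviewer_1 = "eagle",
#'                       reviewer_2 = "eagle", reviewer_3 = NA))
#' @export
adjudicate <- function(reviews) {
  validate_reviews(reviews)
  det <- ifelse(reviews$reviewer_1 == reviews$reviewer_2,
                reviews$reviewer_1, reviews$reviewer_3)
  data.frame(track_id = reviews$track_id, determination = det,
             stringsAsFactors = FALSE)
}

#' Assemble per-track determinations
#'
#' Applies the exclusion filters and adjudication in the published order:
#' secondary targets at multi-target instants are dropped, image-less tracks
#' get determination `no-image`, and the remaining tracks take the
#' adjudicated reviewer label.
#'
#' @param records Record data frame.
#' @param reviews Review-set data frame covering every reviewable track.
#' @return A list with `records` (the multi-target-filtered records),
#'   `determinations` (data frame `track_id`, `tower_id`, `determination`
#'   with levels eagle / non-eagle / no-image), and `dropped_multi_target`
#'   (row count removed by the multi-target filter).
#' @export
assemble_tracks <- function(records, reviews) {
  n0 <- nrow(records)
  recs <- filter_multi_target(records)
  parts <- filter_no_image_tracks(recs)
  adj <- adjudicate(reviews)
  kept_ids <- unique(parts$kept$track_id)
  missing <- setdiff(kept_ids, adj$track_id)
  if (length(missing)) {
    stop("no review for track ", missing[1])
  }
  det <- rbind(
    adj[adj$track_id %in% kept_ids, , drop = FALSE],
    data.frame(track_id = unique(parts$no_image$track_id),
               determination = rep("no-image",
                                   length(unique(parts$no_image$track_id))),
               stringsAsFactors = FALSE)
  )
  tower <- records$tower_id[!duplicated(records$track_id)]
  names(tower) <- records$track_id[!duplicated(records$track_id)]
  det$tower_id <- unname(tower[det$track_id])
  list(records = recs,
       determinations = det[, c("track_id", "tower_id", "determination")],
       dropped_multi_target = n0 - nrow(recs))
}
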