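# Programmatic track correction: a replayable edit log standing in for
# interactive curation of the automated pre-tracking result. Edits are
# applied in order; a failed edit is recorded and leaves the track set
# unchanged.

#' Build an edit command
#'
#' @param verb one of `"SPLIT"`, `"MERGE"`, `"DELETE"`, `"REASSIGN"`
#' @param track_id primary track operand
#' @param track_id2 second track (MERGE target, REASSIGN destination)
#' @param frame frame operand (SPLIT point, REASSIGN frame)
#' @return a one-row data frame (edit record)
#' @export
edit_command <- function(verb = c("SPLIT", "MERGE", "DELETE", "REASSIGN"),
                         track_id, track_id2 = NA_integer_,
                         frame = NA_integer_) {
  verb <- match.arg(verb)
  data.frame(verb = verb, track_id = as.integer(track_id),
             track_id2 = as.integer(track_id2), frame = as.integer(frame))
}

#' Apply an ordered list of edits to a track set
#'
#' * `SPLIT(track, frame)` moves the rows at `frame` and later into a new
#'   track.
#' * `MERGE(a, b)` appends temporally disjoint track `b` to `a`; merging
#'   temporally overlapping tracks is rejected.
#' * `DELETE(track)` removes the track.
#' * `REASSIGN(a, b, frame)` moves the single point of `a` at `frame` into
#'   `b` (which must not already occupy that frame).
#'
#' Manual edits may exceed the automatic displacement gate; such joins are
#' flagged in the `gate_exceeded` column rather than rejected.
#'
#' @param trackset a `track_set`
#' @param edits data frame of edit records (rows applied in order), e.g.
#'   built with [edit_command()] / `rbind`, or read with [read_edits()]
#' @return the edited `track_set`; per-edit failures are recorded in
#'   `attr(, "edit_errors")`
#' @export
apply_edits <- function(trackset, edits) {
  ts <- as.data.frame(trackset)
  errors <- character(0)
  fail <- function(k, msg) errors <<- c(errors, sprintf("edit %d (%s): %s",
                                                        k, edits$verb[k], msg))
  for (k in seq_len(nrow(edits))) {
    verb <- edits$verb[k]; a <- edits$track_id[k]; b <- edits$track_id2[k]
    f <- edits$frame[k]
    ra <- which(ts$track_id == a)
    if (!length(ra)) { fail(k, paste("no track", a)); next }
    if (verb == "SPLIT") {
      mv <- ra[ts$frame[ra] >= f]
      if (!length(mv) || length(mv) == length(ra)) {
        fail(k, "split frame outside track"); next
      }
      ts$track_id[mv] <- max(ts$track_id) + 1L
    } else if (verb == "DELETE") {
      ts <- ts[-ra, ]
    } else if (verb == "MERGE") {
      rb <- which(ts$track_id == b)
      if (!length(rb)) { fail(k, paste("no track", b)); next }
      if (length(intersect(ts$frame[ra], ts$frame[rb]))) {
        fail(k, "tracks overlap in time"); next
      }
      ts$track_id[rb] <- a
    } else if (verb == "REASSIGN") {
      src <- ra[ts$frame[ra] == f]
      if (length(src) != 1L) { fail(k, "no point at frame"); next }
      rb <- which(ts$track_id == b)
      if (!length(rb)) { fail(k, paste("no track", b)); next }
      if (f %in% ts$frame[rb]) { fail(k, "destination occupied at frame"); next }
      ts$track_id[src] <- b
    }
  }
  ts <- ts[order(ts$track_id, ts$frame), ]
  rownames(ts) <- NULL
  px <- attr(trackset, "pixel_size_um") %||% 1
  params <- attr(trackset, "params")
  ts$gate_exceeded <- FALSE
  if (!is.null(params) && nrow(ts) > 1) {
    gate_px <- params$max_disp_um / px
    same <- ts$track_id[-1] == ts$track_id[-nrow(ts)]
    disp <- sqrt(diff(ts$x_px)^2 + diff(ts$y_px)^2)
    lim <- gate_px * diff(ts$frame)
    ts$gate_exceeded[c(FALSE, same & disp > lim)] <- TRUE
  }
  structure(ts, class = c("track_set", "data.frame"), pixel_size_um = px,
            params = params, edit_errors = errors)
}

#' Write / read an edit log as CSV
#' @param edits edit records (see [edit_command()])
#' @param path CSV path
#' @return `read_edits`: an edit data frame ordered by its `order` column
#' @export
write_edits <- function(edits, path) {
  write.csv(cbind(order = seq_len(nrow(edits)), edits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edits
#' @export
read_edits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("verb", "track_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed edits CSV: missing columns ", paste(miss, collapse = ", "))
  if (!is.null(df$order)) df <- df[order(df$order), ]
  df
}
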