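#' Construct a chest landmark set
#'
#' @param upperLeft,upperRight pixels (u, v) on the anterior axillary lines
#'   at nipple height.
#' @param lowerLeft,lowerRight pixels (u, v) at the chest contour edges at
#'   sub-xiphoid height.
#' @param frameIndex frame the landmarks belong to; `NA` (default) applies
#'   them to every selected frame of the recording.
#' @return A [LandmarkSet-class] object.
#' @export
landmarkSet <- function(upperLeft, upperRight, lowerLeft, lowerRight,
                        frameIndex = NA_integer_) {
  new("LandmarkSet",
      upperLeft = as.numeric(upperLeft), upperRight = as.numeric(upperRight),
      lowerLeft = as.numeric(lowerLeft), lowerRight = as.numeric(lowerRight),
      frameIndex = as.integer(frameIndex))
}

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet%s: upper (%g,%g)-(%g,%g) lower (%g,%g)-(%g,%g)\n",
              if (is.na(object@frameIndex)) "" else
                sprintf(" [frame %d]", object@frameIndex),
              object@upperLeft[1], object@upperLeft[2],
              object@upperRight[1], object@upperRight[2],
              object@lowerLeft[1], object@lowerLeft[2],
              object@lowerRight[1], object@lowerRight[2]))
})

.landmarkRoles <- c("upper_left", "upper_right", "lower_left", "lower_right")

#' Read landmark sets from CSV
#'
#' Expected columns: `recording_id`, `role` (one of `upper_left`,
#' `upper_right`, `lower_left`, `lower_right`), `u`, `v`, and optionally
#' `frame_index`.
#'
#' @param path path to the landmark CSV.
#' @return Named list of [LandmarkSet-class] objects, one per recording.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("recording_id", "role", "u", "v")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("landmark CSV missing columns: ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$recording_id), function(g) {
    missingRoles <- setdiff(.landmarkRoles, g$role)
    if (length(missingRoles))
      stop(sprintf("recording '%s' is missing landmark role(s): %s",
                   g$recording_id[1], paste(missingRoles, collapse = ", ")))
    px <- function(role) {
      r <- g[g$role == role, , drop = FALSE][1L, ]
      c(r$u, r$v)
    }
    fi <- if ("frame_index" %in% names(g)) g$frame_index[1] else NA
    landmarkSet(px("upper_left"), px("upper_right"),
                px("lower_left"), px("lower_right"),
                frameIndex = if (is.null(fi) || is.na(fi)) NA_integer_ else fi)
  })
  out
}

#' Write landmark sets to CSV
#'
#' @param landmarks named list of [LandmarkSet-class] objects (names are
#'   recording ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  rows <- do.call(rbind, lapply(names(landmarks), function(id) {
    lm <- landmarks[[id]]
    px <- rbind(lm@upperLeft, lm@upperRight, lm@lowerLeft, lm@lowerRight)
    data.frame(recording_id = id, role = .landmarkRoles,
               u = px[, 1], v = px[, 2],
               frame_index = lm@frameIndex)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
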