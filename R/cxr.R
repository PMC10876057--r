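#' Rib-edge distance on a chest radiograph
#'
#' 2D Euclidean distance between the left and right lateral rib-edge pixels
#' scaled by the detector pixel spacing.  Radiographs are projections, so no
#' geodesic analogue exists; only straight-line distances are reported.
#'
#' @param left,right pixels (u, v) of the left and right lateral rib edges.
#' @param pixelSpacingMm detector pixel spacing in mm/px.
#' @return Distance in cm.
#' @examples
#' cxrDistance(c(100, 300), c(400, 300), 0.5)  # 15 cm
#' @export
cxrDistance <- function(left, right, pixelSpacingMm) {
  if (pixelSpacingMm <= 0) stop("pixel spacing must be positive")
  d <- sqrt(sum((as.numeric(right) - as.numeric(left))^2)) * pixelSpacingMm
  if (d == 0) warning("degenerate input: coincident rib-edge points")
  d / 10
}

#' Upper/lower rib-distance ratio
#'
#' @param upperCm,lowerCm rib-edge distances (cm) at the upper and lower
#'   level of a pair (2nd/9th or 4th/8th ribs).
#' @return Dimensionless ratio; spacing-independent since both distances
#'   share the pixel spacing.
#' @export
cxrRatio <- function(upperCm, lowerCm) {
  if (is.na(upperCm) || is.na(lowerCm)) stop("missing level for ratio")
  if (upperCm <= 0 || lowerCm <= 0) stop("distances must be positive")
  upperCm / lowerCm
}

#' Per-subject radiograph distances and ratios
#'
#' Takes long-format rib landmarks (one row per subject, level and side)
#' and returns one row per subject with the distances at rib levels 2, 4,
#' 8 and 9 (cm) and the 2nd/9th and 4th/8th ratios.  Levels a subject lacks
#' yield `NA` distances and (where an endpoint of the pair is absent) `NA`
#' ratios.
#'
#' @param df data.frame with columns `subject_id`, `level` (2, 4, 8 or 9),
#'   `side` (`left`/`right`), `u`, `v`, `pixel_spacing_mm`, and optionally
#'   `group`.
#' @return data.frame with one row per subject: `subject_id`, optional
#'   `group`, `dist2Cm`, `dist4Cm`, `dist8Cm`, `dist9Cm`, `ratio29`,
#'   `ratio48`.
#' @export
cxrTable <- function(df) {
  need <- c("subject_id", "level", "side", "u", "v", "pixel_spacing_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CXR CSV missing columns: ", paste(missing, collapse = ", "))
  if (any(!df$level %in% c(2, 4, 8, 9)))
    stop("rib level must be one of 2, 4, 8, 9")
  out <- lapply(split(df, df$subject_id), function(g) {
    lev <- function(l) {
      sub <- g[g$level == l, , drop = FALSE]
      if (!nrow(sub)) return(NA_real_)
      left <- sub[sub$side == "left", , drop = FALSE]
      right <- sub[sub$side == "right", , drop = FALSE]
      if (nrow(left) != 1L || nrow(right) != 1L)
        stop(sprintf("subject '%s' rib %d needs exactly one left and one right point",
                     g$subject_id[1], l))
      if (left$u >= right$u)
        stop(sprintf("subject '%s' rib %d: left edge must lie left of the right edge",
                     g$subject_id[1], l))
      cxrDistance(c(left$u, left$v), c(right$u, right$v),
                  left$pixel_spacing_mm)
    }
    d <- vapply(c(2, 4, 8, 9), lev, numeric(1))
    ratio <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else a / b
    data.frame(subject_id = g$subject_id[1],
               group = if ("group" %in% names(g)) g$group[1] else NA,
               dist2Cm = d[1], dist4Cm = d[2], dist8Cm = d[3], dist9Cm = d[4],
               ratio29 = ratio(d[1], d[4]), ratio48 = ratio(d[2], d[3]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (all(is.na(res$group))) res$group <- NULL
  res
}
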