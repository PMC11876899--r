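#' Score the six-item social value orientation slider measure
#'
#' The SVO angle is `atan((mean_other - 50) / (mean_self - 50))` in degrees,
#' where the means are taken over the six chosen self/other allocations.
#' Categories: altruist (> 57.15), prosocial (22.45, 57.15], individualist
#' ((-12.04, 22.45]), competitive (<= -12.04); the binary split groups
#' altruists with prosocials above 22.45 and the rest as individualistic.
#'
#' @param self,other numeric vectors of the six chosen allocations to self
#'   and other (instrument units, nominally around 50..100).
#' @return list of class `svo_result`: `mean_self`, `mean_other`,
#'   `angle_deg`, `category`, `binary_group`, `flagged`.
#' @export
svo_score <- function(self, other) {
  if (length(self) != 6 || length(other) != 6)
    stopf("svo_score expects exactly six allocation pairs")
  ms <- mean(self); mo <- mean(other)
  flagged <- FALSE
  if (abs(ms - 50) < 1e-12 && abs(mo - 50) < 1e-12) {
    return(structure(list(mean_self = ms, mean_other = mo,
                          angle_deg = NA_real_, category = NA_character_,
                          binary_group = NA_character_, flagged = TRUE),
                     class = "svo_result"))
  }
  angle <- if (abs(ms - 50) < 1e-12) 90 * sign(mo - 50)
           else atan((mo - 50) / (ms - 50)) * 180 / pi
  structure(list(mean_self = ms, mean_other = mo, angle_deg = angle,
                 category = svo_category(angle),
                 binary_group = svo_binary_group(angle),
                 flagged = flagged),
            class = "svo_result")
}

#' Classify an SVO angle into the four canonical categories
#'
#' @param angle_deg SVO angle in degrees.
#' @return `"altruist"`, `"prosocial"`, `"individualist"` or
#'   `"competitive"`.
#' @export
svo_category <- function(angle_deg) {
  vapply(angle_deg, function(a) {
    if (is.na(a)) NA_character_
    else if (a > 57.15) "altruist"
    else if (a >= 22.45) "prosocial"
    else if (a >= -12.04) "individualist"
    else "competitive"
  }, "")
}

#' Binary prosocial / individualistic split of an SVO angle
#'
#' Altruists and prosocials pool into `"prosocial"` (angle >= 22.45
#' degrees); individualists and competitive types into
#' `"individualistic"`.
#'
#' @param angle_deg SVO angle in degrees.
#' @return `"prosocial"` or `"individualistic"`.
#' @export
svo_binary_group <- function(angle_deg) {
  vapply(angle_deg, function(a) {
    if (is.na(a)) NA_character_
    else if (a >= 22.45) "prosocial"
    else "individualistic"
  }, "")
}

#' @export
print.svo_result <- function(x, ...) {
  cat(sprintf("SVO: angle %.2f deg (self %.1f, other %.1f) -> %s [%s]\n",
              x$angle_deg, x$mean_self, x$mean_other, x$category,
              x$binary_group))
  invisible(x)
}
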