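#' Eye-motion alphabet
#'
#' The five gaze motions used by the input protocol: looking up, down, left,
#' right, and straight ahead ("center").  All motion sequences handled by the
#' package are drawn from this alphabet; the optional silence symbol
#' `"sil"` (no motion performed) is used only for recording padding and is
#' never part of a protocol code.
#'
#' @return Character vector of the five motion labels.
#' @export
motion_alphabet <- function() c("up", "down", "left", "right", "center")

#' Silence label used for recording padding
#' @return The string `"sil"`.
#' @export
sil_label <- function() "sil"

#' Gaze target positions on the unit circle
#'
#' 2-D latent gaze positions for each motion: up = (0, 1), down = (0, -1),
#' left = (1, 0), right = (-1, 0), center = (0, 0).  The horizontal axis is
#' positive towards the user's left so that the sign convention matches the
#' derived two-channel feature (CH2 - CH5 is positive when looking left).
#'
#' @return A 5 x 2 numeric matrix with rownames `up, down, left, right,
#'   center` and columns `h` (horizontal) and `v` (vertical).
#' @export
gaze_targets <- function() {
  m <- rbind(
    up     = c(0,  1),
    down   = c(0, -1),
    left   = c(1,  0),
    right  = c(-1, 0),
    center = c(0,  0)
  )
  colnames(m) <- c("h", "v")
  m
}

#' Validate a motion sequence
#'
#' Checks that all labels belong to the motion alphabet and that no two
#' adjacent motions are identical.  The adjacency rule comes from the input
#' protocol: a motion repeated immediately (e.g. "up" then "up" again) has no
#' detectable boundary in the EOG signal, so such sequences are never used.
#'
#' @param motions Character vector of motion labels.
#' @param allow_empty If `FALSE` (default), an empty sequence is an error.
#' @return The sequence, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_motion_sequence <- function(motions, allow_empty = FALSE) {
  if (length(motions) == 0) {
    if (allow_empty) return(invisible(motions))
    stop("motion sequence is empty")
  }
  bad <- setdiff(motions, motion_alphabet())
  if (length(bad) > 0) {
    stop("unknown motion label(s): ", paste(unique(bad), collapse = ", "))
  }
  if (length(motions) > 1) {
    rep_at <- which(motions[-1] == motions[-length(motions)])
    if (length(rep_at) > 0) {
      stop(
        "adjacent identical motions at position ", rep_at[1], ": '",
        motions[rep_at[1]], "' followed by itself"
      )
    }
  }
  invisible(motions)
}

#' Sample a random valid motion sequence
#'
#' Draws a sequence uniformly over sequences with no two adjacent motions
#' identical: the first motion is uniform over the alphabet and every
#' subsequent motion is uniform over the four motions differing from its
#' predecessor.
#'
#' @param len Sequence length (>= 1).
#' @return Character vector of motion labels.
#' @export
random_motion_sequence <- function(len) {
  stopifnot(len >= 1)
  ab <- motion_alphabet()
  out <- character(len)
  out[1] <- sample(ab, 1)
  if (len > 1) {
    for (i in 2:len) out[i] <- sample(setdiff(ab, out[i - 1]), 1)
  }
  out
}
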