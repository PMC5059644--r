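#' Edit-distance alignment and error counting
#'
#' Aligns a hypothesis to a reference by minimum edit distance with unit
#' costs and reports the substitution (S), deletion (D) and insertion (I)
#' counts of the optimal alignment, as used for character and motion error
#' rates.  Ties in the dynamic program are broken in the order substitution
#' > deletion > insertion, which does not change S + D + I.
#'
#' @param ref Character vector, the reference symbols (may be empty).
#' @param hyp Character vector, the hypothesis symbols (may be empty).
#' @return A list of class `eog_error_counts` with integer fields `S`, `D`,
#'   `I`, and `N` (reference length).
#' @export
align_and_count <- function(ref, hyp) {
  n <- length(ref); m <- length(hyp)
  # dp cost plus backtrace of (S, D, I) counts along an optimal path
  S <- matrix(0L, n + 1, m + 1); D <- S; I <- S
  cost <- matrix(0L, n + 1, m + 1)
  if (n > 0) { cost[2:(n + 1), 1] <- 1:n; D[2:(n + 1), 1] <- 1:n }
  if (m > 0) { cost[1, 2:(m + 1)] <- 1:m; I[1, 2:(m + 1)] <- 1:m }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- ref[i] == hyp[j]
      c_sub <- cost[i, j] + !hit
      c_del <- cost[i, j + 1] + 1L
      c_ins <- cost[i + 1, j] + 1L
      best <- min(c_sub, c_del, c_ins)
      cost[i + 1, j + 1] <- best
      if (c_sub == best) {           # prefer (correct or) substitution
        S[i + 1, j + 1] <- S[i, j] + (!hit)
        D[i + 1, j + 1] <- D[i, j]
        I[i + 1, j + 1] <- I[i, j]
      } else if (c_del == best) {    # then deletion
        S[i + 1, j + 1] <- S[i, j + 1]
        D[i + 1, j + 1] <- D[i, j + 1] + 1L
        I[i + 1, j + 1] <- I[i, j + 1]
      } else {                       # then insertion
        S[i + 1, j + 1] <- S[i + 1, j]
        D[i + 1, j + 1] <- D[i + 1, j]
        I[i + 1, j + 1] <- I[i + 1, j] + 1L
      }
    }
  }
  structure(
    list(S = as.integer(S[n + 1, m + 1]), D = as.integer(D[n + 1, m + 1]),
         I = as.integer(I[n + 1, m + 1]), N = as.integer(n)),
    class = "eog_error_counts"
  )
}

#' @export
print.eog_error_counts <- function(x, ...) {
  cat(sprintf("S=%d D=%d I=%d N=%d", x$S, x$D, x$I, x$N))
  if (x$N > 0) cat(sprintf("  rate=%.1f%%", error_rate(x)))
  cat("\n")
  invisible(x)
}

#' Error rate from alignment counts
#'
#' The character (or motion) error rate: `100 * (S + D + I) / N`, where N is
#' the reference length.  Insertion-dominated hypotheses can push the rate
#' above 100%.
#'
#' @param counts An `eog_error_counts` object (or a list with S, D, I, N).
#' @return The error rate in percent.
#' @export
error_rate <- function(counts) {
  if (counts$N <= 0) stop("reference length N must be positive")
  100 * (counts$S + counts$D + counts$I) / counts$N
}

#' Pooled corpus-level error rate
#'
#' Pools the S/D/I/N counts across all utterance pairs and reports the
#' single pooled rate `100 * (sum S + sum D + sum I) / (sum N)` — the speech
#' scoring convention, not the mean of per-utterance rates.
#'
#' @param outputs List of hypothesis symbol vectors.
#' @param references List of reference symbol vectors, same length.
#' @return A list with the pooled `counts` (`eog_error_counts`), the pooled
#'   `rate` in percent, and a `per_utterance` data frame (S, D, I, N, rate).
#' @export
evaluate_corpus <- function(outputs, references) {
  if (length(outputs) != length(references))
    stop("outputs and references differ in length (",
         length(outputs), " vs ", length(references), ")")
  if (length(outputs) == 0) stop("empty corpus")
  counts <- Map(function(h, r) align_and_count(r, h), outputs, references)
  per <- data.frame(
    S = vapply(counts, `[[`, integer(1), "S"),
    D = vapply(counts, `[[`, integer(1), "D"),
    I = vapply(counts, `[[`, integer(1), "I"),
    N = vapply(counts, `[[`, integer(1), "N")
  )
  per$rate <- ifelse(per$N > 0, 100 * (per$S + per$D + per$I) / per$N, NA)
  pooled <- structure(
    list(S = sum(per$S), D = sum(per$D), I = sum(per$I), N = sum(per$N)),
    class = "eog_error_counts"
  )
  list(counts = pooled, rate = error_rate(pooled), per_utterance = per)
}

#' Relative error-rate reduction
#'
#' `100 * (a - b) / a`: the percentage by which an error rate `b` improves
#' on a baseline rate `a`.
#'
#' @param a Baseline error rate (> 0).
#' @param b Improved error rate.
#' @return Relative reduction in percent.
#' @export
relative_reduction <- function(a, b) {
  stopifnot(a > 0)
  100 * (a - b) / a
}

#' Write a score report TSV (per-utterance and pooled S/D/I/N/rate)
#' @param eval Result of [evaluate_corpus()].
#' @param path Output path.
#' @export
write_score_report <- function(eval, path) {
  df <- eval$per_utterance
  df <- rbind(df, data.frame(S = eval$counts$S, D = eval$counts$D,
                             I = eval$counts$I, N = eval$counts$N,
                             rate = eval$rate))
  df$utterance <- c(seq_len(nrow(df) - 1), "pooled")
  utils::write.table(df[, c("utterance", "S", "D", "I", "N", "rate")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
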