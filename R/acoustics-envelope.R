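#' RMS amplitude envelope
#'
#' Root-mean-square amplitude over sliding frames with hop = frame/2, the
#' prerequisite for amplitude-threshold call segmentation. The envelope is
#' homogeneous of degree one: `envelope(k * x) = k * envelope(x)` for
#' `k > 0`, which is what makes the downstream relative thresholds
#' scale-invariant.
#'
#' @param clip an [audio_clip()].
#' @param frame_ms frame length in ms (> 0). A frame longer than the clip
#'   degenerates to a single whole-clip frame.
#' @return an object of class `env_series`: list with `values`, frame-center
#'   `times_s`, `frame_s` and `hop_s`.
#' @export
amplitude_envelope <- function(clip, frame_ms = 5) {
  if (frame_ms <= 0) stopf("frame_ms must be > 0")
  x <- clip$samples
  sr <- clip$sample_rate_hz
  n <- length(x)
  frame <- min(n, max(2L, as.integer(round(frame_ms / 1000 * sr))))
  hop <- max(1L, frame %/% 2L)
  starts <- seq.int(1L, max(1L, n - frame + 1L), by = hop)
  cs <- c(0, cumsum(x^2))
  vals <- sqrt((cs[starts + frame] - cs[starts]) / frame)
  structure(list(values = vals,
                 times_s = (starts - 1 + frame / 2) / sr,
                 frame_s = frame / sr,
                 hop_s = hop / sr), class = "env_series")
}

# Local maxima of `v` with topographic prominence >= min_prominence and
# index spacing >= min_spacing, kept greedily from the highest peak down.
# Returns the surviving peak indices, sorted.
find_peaks <- function(v, min_prominence = 0, min_spacing = 1) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- v[i]
    left <- h; j <- i - 1L
    while (j >= 1 && v[j] <= h) { left <- min(left, v[j]); j <- j - 1L }
    if (j < 1) left <- min(v[1:i])
    right <- h; j <- i + 1L
    while (j <= n && v[j] <= h) { right <- min(right, v[j]); j <- j + 1L }
    if (j > n) right <- min(v[i:n])
    h - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  keep <- keep[order(v[keep], decreasing = TRUE)]
  out <- integer(0)
  for (i in keep) {
    if (!length(out) || all(abs(out - i) >= min_spacing)) out <- c(out, i)
  }
  sort(out)
}
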