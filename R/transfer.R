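#' S-shaped transfer functions
#'
#' The four sigmoids used to map a real-valued particle velocity to a
#' bit-flip probability in binary swarm optimization:
#' \deqn{S_1(v) = 1/(1+e^{-2v}),\; S_2(v) = 1/(1+e^{-v}),\;
#'       S_3(v) = 1/(1+e^{-v/2}),\; S_4(v) = 1/(1+e^{-v/3}).}
#' All four map 0 to 0.5, are strictly increasing, and are ordered by
#' steepness at the origin (slopes 1/2, 1/4, 1/8, 1/12).
#'
#' @param tf_id one of `"S1"`, `"S2"`, `"S3"`, `"S4"`
#' @param v numeric velocity (vectorized)
#' @return probabilities strictly in (0,1)
#' @export
transfer_value <- function(tf_id, v) {
  scale <- switch(tf_id,
                  S1 = 2, S2 = 1, S3 = 1 / 2, S4 = 1 / 3,
                  stop("unknown transfer function: ", tf_id, call. = FALSE))
  stats::plogis(scale * v)
}
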