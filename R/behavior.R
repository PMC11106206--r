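#' Cylinder-test asymmetry score
#'
#' `score = ((R - L) / (R + L + B)) * 100`, where R, L and B count rears
#' initiated with the right, left and both forelimbs over a session
#' (typically 20 rears). A higher score indicates stronger reliance on the
#' unimpaired forelimb, i.e. worse neuronal function.
#'
#' @param r,l,b Rear counts (right, left, both). Vectorised.
#' @return Signed percent in `[-100, 100]`.
#' @export
cylinder_score <- function(r, l, b) {
  assert_that(all(r >= 0 & l >= 0 & b >= 0), "counts must be nonnegative")
  total <- r + l + b
  assert_that(all(total > 0), "all-zero rear counts give an undefined score",
              class = "ichwmi_undefined_score_error")
  (r - l) / total * 100
}

#' Success-proportion score
#'
#' `successes / trials * 100`; used for the forelimb placing and corner
#' turn tests, each repeated 10 times per animal.
#'
#' @param successes Success counts (vectorised).
#' @param trials Trial counts (default 10).
#' @return Percent in `[0, 100]`.
#' @export
proportion_score <- function(successes, trials = 10) {
  assert_that(all(trials > 0), "trials must be positive")
  assert_that(all(successes >= 0 & successes <= trials),
              "successes must lie in [0, trials]")
  successes / trials * 100
}

#' Score a table of behavioural trials
#'
#' Applies [proportion_score()] to a trial table as produced by
#' [gen_behavior_trials()] (columns `group`, `mouse`, `successes`,
#' `trials`).
#'
#' @param trials Data frame of per-animal trial counts.
#' @return The input with a `percent` column appended.
#' @export
score_behavior <- function(trials) {
  assert_that(all(c("successes", "trials") %in% colnames(trials)),
              "need 'successes' and 'trials' columns")
  trials$percent <- proportion_score(trials$successes, trials$trials)
  trials
}
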