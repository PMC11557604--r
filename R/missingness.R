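#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Draw per-specimen missing-element counts from a clipped normal
#'
#' The percentage of missing data per specimen is drawn from a normal
#' distribution with the scenario mean and standard deviation, clipped to
#' \[0, 100\]: draws below 0% are set to 0% and draws above 100% are capped at
#' 100%. The clipped percentage is converted to a whole number of the 48
#' cranial elements with half-away-from-zero rounding (elements are atomic).
#'
#' @param n Number of draws.
#' @param mean_pct Scenario mean missingness in percent (0-100).
#' @param sd_pct Standard deviation in percent (>= 0).
#' @param n_elements Number of recording elements (default 48).
#' @return Integer vector of length `n` with values in `0:n_elements`.
#'   Uses the current RNG state.
#' @export
draw_missing_count <- function(n, mean_pct, sd_pct, n_elements = 48L) {
  if (mean_pct < 0 || mean_pct > 100) stop("`mean_pct` must be in [0, 100]")
  if (sd_pct < 0) stop("`sd_pct` must be >= 0")
  x <- stats::rnorm(n, mean_pct, sd_pct)
  x <- pmin(pmax(x, 0), 100)
  as.integer(round_half_away(x / 100 * n_elements))
}

#' Element removal weights from bone effective sample sizes
#'
#' Maps bone-level effective sample sizes to per-element probability weights
#' for the allocation of missing values. Bones that are poorly represented in
#' the archaeological record (low ESS) receive a higher removal weight for
#' each of their elements; well-represented bones a lower one. All elements
#' of a bone share its weight, and weights are normalized to sum to one, so
#' only ESS ratios matter.
#'
#' @param schema A [cranial_schema()] object.
#' @param bone_ess Named numeric vector of positive ESS values covering all
#'   14 bones (see [read_bone_ess()]).
#' @param transform How to turn ESS into a raw weight: `"inverse"` (default)
#'   uses `1/ess`; `"max_complement"` uses `max(ess) - ess + min(ess)`;
#'   `"rank"` uses the reverse rank of ess.
#' @return Named numeric vector of 48 positive weights summing to 1, in
#'   schema element order.
#' @export
element_removal_weights <- function(schema, bone_ess,
                                    transform = c("inverse", "max_complement",
                                                  "rank")) {
  stopifnot_schema(schema)
  transform <- match.arg(transform)
  missing_b <- setdiff(schema$bones, names(bone_ess))
  if (length(missing_b))
    stop("bone_ess missing bone(s): ", paste(missing_b, collapse = ", "))
  ess <- as.numeric(bone_ess[schema$bones])
  if (any(!is.finite(ess)) || any(ess <= 0))
    stop("all ESS values must be positive and finite")
  w_bone <- switch(transform,
    inverse        = 1 / ess,
    max_complement = max(ess) - ess + min(ess),
    rank           = rank(-ess))
  names(w_bone) <- schema$bones
  w <- w_bone[schema$bone_of[schema$elements]]
  names(w) <- schema$elements
  w / sum(w)
}

#' Allocate missing values to cranial elements by weighted sampling
#'
#' Sets the requested number of elements to missing (`NA`) in each specimen,
#' chosen by successive weighted draws without replacement (weights
#' renormalized over the remaining elements after each draw). Surviving
#' elements keep their trauma state, so a fracture spanning several elements
#' may be partially preserved.
#'
#' @param state Specimen state: either a single 48-long integer vector or an
#'   `n x 48` matrix as returned by [generate_sample()].
#' @param count Integer number of elements to remove per specimen (0-48);
#'   scalar or vector of length `n`.
#' @param weights Positive removal weights of length 48 (see
#'   [element_removal_weights()]).
#' @return Same shape as `state` with exactly `count` entries per specimen set
#'   to `NA`. Uses the current RNG state.
#' @export
allocate_missing <- function(state, count, weights) {
  vec <- is.null(dim(state))
  if (vec) state <- matrix(state, nrow = 1)
  n_el <- ncol(state)
  if (length(weights) != n_el) stop("`weights` must have length ", n_el)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all weights must be positive")
  count <- as.integer(rep_len(count, nrow(state)))
  if (any(count < 0 | count > n_el))
    stop("`count` must be between 0 and ", n_el)
  for (i in seq_len(nrow(state))) {
    if (count[i] > 0L) {
      # base sample() without replacement applies `prob` sequentially with
      # renormalization, exactly the scheme required here
      drop <- sample.int(n_el, count[i], prob = weights)
      state[i, drop] <- NA_integer_
    }
  }
  if (vec) state[1, ] else state
}

#' Summarize specimens as completeness and trauma presence
#'
#' Reduces element-level specimen states to the two quantities the estimators
#' consume: completeness, the percentage of the 48 elements still present,
#' and a binary trauma score, 1 if any surviving element carries trauma.
#' A fully missing specimen (0% complete) scores trauma 0 vacuously.
#'
#' @param state 48-long vector or `n x 48` matrix of element states
#'   (`NA` missing, `0` present without trauma, `1` present with trauma).
#' @param sample_label Optional label attached as a `sample` column.
#' @return data.frame with columns `completeness` (percent) and `trauma`
#'   (integer 0/1), plus `sample` if a label was given.
#' @export
summarize_specimens <- function(state, sample_label = NULL) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  n_el <- ncol(state)
  completeness <- 100 * rowSums(!is.na(state)) / n_el
  trauma <- as.integer(rowSums(state == 1L, na.rm = TRUE) > 0)
  out <- data.frame(completeness = completeness, trauma = trauma)
  if (!is.null(sample_label))
    out <- cbind(sample = sample_label, out, stringsAsFactors = FALSE)
  out
}

#' Mean of a normal distribution clipped to an interval
#'
#' Closed-form mean of `min(max(X, lo), hi)` for `X ~ Normal(mean, sd)`.
#' Clipping mass onto the bounds shifts the mean towards the interval's
#' interior, e.g. a nominal 80% missingness scenario with sd 20 realizes a
#' mean below 80%.
#'
#' @param mean,sd Normal parameters (`sd >= 0`).
#' @param lo,hi Clipping bounds.
#' @return The mean of the clipped variable.
#' @export
clipped_normal_mean <- function(mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(min(max(mean, lo), hi))
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    mean * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

#' Probability that a specimen survives a completeness threshold
#'
#' Under the clipped-normal missingness model, a specimen passes a
#' completeness threshold `thr` (percent) iff its missing-element count is at
#' most `floor(n_elements * (1 - thr/100))`. With half-away-from-zero
#' rounding of the clipped percentage, that event is `X < (m + 0.5) /
#' n_elements * 100` for the unclipped normal draw `X` (clipping at 0 only
#' moves draws deeper into the passing region). This closed form is the
#' analytic reference for crude-frequency production rates: the probability
#' that at least one of `n` specimens passes is `1 - (1 - p)^n`.
#'
#' @param mean_pct,sd_pct Missingness distribution parameters (percent).
#' @param threshold Completeness threshold in percent (default 75).
#' @param n_elements Number of recording elements (default 48).
#' @return Probability in \[0, 1\] that a single specimen passes.
#' @export
completeness_pass_prob <- function(mean_pct, sd_pct, threshold = 75,
                                   n_elements = 48L) {
  m <- floor(n_elements * (1 - threshold / 100))
  cut <- (m + 0.5) / n_elements * 100
  if (sd_pct == 0) return(as.numeric(mean_pct < cut))
  stats::pnorm(cut, mean_pct, sd_pct)
}
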