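#' Generate a once-complete cranial sample with assigned trauma
#'
#' Creates `n` complete specimens (no missing elements) and assigns trauma to
#' an exact fraction of them. `n * prevalence / 100` must be a whole number:
#' the benchmark prevalence is fixed by design, not binomially sampled, so the
#' generated sample carries the true rate exactly. Affected specimens receive
#' an injury pattern drawn uniformly *with replacement* from the 40-case
#' reference pool, so each case has the same chance in every draw and may
#' appear several times or not at all; which specimens are affected is
#' uniformly random.
#'
#' @param schema A [cranial_schema()] object.
#' @param pool A [read_trauma_pool()] object.
#' @param n Number of specimens (>= 1).
#' @param prevalence Trauma prevalence in percent (0-100).
#' @return Integer matrix `n` x 48 of element states: `0` = present without
#'   trauma, `1` = present with trauma (missing elements, introduced later,
#'   are `NA`). Attribute `"case_idx"` gives, for each specimen, the pool row
#'   of its assigned case (`NA` for unaffected specimens). Uses the current
#'   RNG state.
#' @export
generate_sample <- function(schema, pool, n, prevalence) {
  stopifnot_schema(schema)
  if (!inherits(pool, "trauma_pool")) stop("`pool` must be a trauma_pool")
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer")
  if (prevalence < 0 || prevalence > 100)
    stop("`prevalence` must be in [0, 100]")
  m <- n * prevalence / 100
  if (abs(m - round(m)) > 1e-8)
    stop("n * prevalence / 100 must be a whole number (got ", m, ")")
  m <- as.integer(round(m))

  state <- matrix(0L, nrow = n, ncol = length(schema$elements),
                  dimnames = list(NULL, schema$elements))
  case_idx <- rep(NA_integer_, n)
  if (m > 0) {
    hit <- sample.int(n, m)
    cases <- sample.int(nrow(pool$patterns), m, replace = TRUE)
    state[hit, ] <- pool$patterns[cases, , drop = FALSE]
    case_idx[hit] <- cases
  }
  attr(state, "case_idx") <- case_idx
  state
}
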