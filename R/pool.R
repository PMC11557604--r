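#' Path to a default fixture shipped with the package
#'
#' @param which `"pool"` for the trauma-case pool, `"ess"` for the bone
#'   effective-sample-size table.
#' @return File path of the installed fixture.
#' @export
default_fixture <- function(which = c("pool", "ess")) {
  which <- match.arg(which)
  fn <- switch(which, pool = "trauma_pool.csv", ess = "bone_ess_synthetic.csv")
  path <- system.file("extdata", fn, package = "traumasim")
  if (!nzchar(path)) stop("fixture ", fn, " not found in installed package")
  path
}

#' Load and validate the reference pool of cranial trauma cases
#'
#' The pool holds 40 real-life blunt-force trauma cases (interpersonal
#' violence, falls from a height, animal encounters, projectile/arrow
#' injuries, and clinical cases), each recorded as a binary pattern over the
#' 48 cranial elements of [cranial_schema()]. Severity ranges from a single
#' injured element to extensive comminuted fracture patterns covering most of
#' the skull. The shipped fixture reconstructs each case's element pattern
#' from its verbal fracture description and injured-element count; the
#' within-bone region assignment follows the fixed conventions documented in
#' [cranial_schema()] and is editable (the fixture is a plain CSV).
#'
#' Validation enforces: exactly 40 cases; each pattern sums to the declared
#' injured-element count; injured elements lie only on the bones named for
#' the case; all element ids belong to the schema.
#'
#' @param schema A [cranial_schema()] object.
#' @param path CSV with columns `case_id`, `category`, `n_injured`, `bones`
#'   (semicolon-separated bone ids) and `injured_elements` (semicolon-separated
#'   element ids). Defaults to the shipped fixture.
#' @return An object of class `"trauma_pool"`: list with `cases` (data.frame
#'   of case metadata) and `patterns` (40 x 48 binary integer matrix, rows
#'   named by case id, columns in schema element order).
#' @export
read_trauma_pool <- function(schema = cranial_schema(),
                             path = default_fixture("pool")) {
  stopifnot_schema(schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "category", "n_injured", "bones", "injured_elements")
  if (!all(need %in% names(raw)))
    stop("trauma pool fixture must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(raw$case_id))
    stop("duplicate case_id in trauma pool fixture")

  n_el <- length(schema$elements)
  patterns <- matrix(0L, nrow = nrow(raw), ncol = n_el,
                     dimnames = list(raw$case_id, schema$elements))
  for (i in seq_len(nrow(raw))) {
    els <- strsplit(raw$injured_elements[i], ";", fixed = TRUE)[[1]]
    els <- trimws(els)
    bad <- setdiff(els, schema$elements)
    if (length(bad))
      stop("case ", raw$case_id[i], ": unknown element(s) ",
           paste(bad, collapse = ", "))
    if (anyDuplicated(els))
      stop("case ", raw$case_id[i], ": duplicated injured element")
    if (length(els) != raw$n_injured[i])
      stop("case ", raw$case_id[i], ": pattern has ", length(els),
           " injured elements but declares n_injured = ", raw$n_injured[i])
    allowed <- trimws(strsplit(raw$bones[i], ";", fixed = TRUE)[[1]])
    off <- setdiff(unique(schema$bone_of[els]), allowed)
    if (length(off))
      stop("case ", raw$case_id[i], ": injured elements on bone(s) ",
           paste(off, collapse = ", "), " not named in its description")
    patterns[i, els] <- 1L
  }
  if (nrow(raw) != 40L)
    stop("trauma pool must contain exactly 40 cases, found ", nrow(raw))

  structure(list(cases = raw[, c("case_id", "category", "n_injured", "bones")],
                 patterns = patterns),
            class = "trauma_pool")
}

#' @export
print.trauma_pool <- function(x, ...) {
  cat("Trauma-case reference pool:", nrow(x$patterns), "cases,",
      sum(x$patterns), "injured elements in total\n")
  print(table(x$cases$category))
  invisible(x)
}

#' Walker's effective sample size from completeness-category counts
#'
#' Converts counts of bone elements preserved at the four ordinal completeness
#' scores (25%, 50%, 75%, 100%) into a fractional count of "complete" bones:
#' the number preserved in each category multiplied by the category score and
#' summed. Partially preserved bones thereby contribute fractionally to the
#' sample total.
#'
#' @param counts Named numeric vector of non-negative integer counts; names
#'   must be a subset of `"0.25"`, `"0.5"`, `"0.75"`, `"1"`. An empty vector
#'   yields 0.
#' @return The effective sample size (non-negative real).
#' @examples
#' effective_sample_size(c("1" = 10))                      # 10
#' effective_sample_size(c("0.25" = 4, "0.5" = 2, "1" = 1)) # 3
#' @export
effective_sample_size <- function(counts) {
  if (length(counts) == 0) return(0)
  scores <- c("0.25" = 0.25, "0.5" = 0.5, "0.75" = 0.75, "1" = 1)
  if (is.null(names(counts)) || !all(names(counts) %in% names(scores)))
    stop("counts must be named with completeness categories 0.25, 0.5, 0.75, 1")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  sum(counts * scores[names(counts)])
}

#' Load and validate per-bone effective sample sizes
#'
#' Reads the bone-level effective-sample-size (ESS) table used to weight
#' which elements go missing. The shipped default is a synthetic stand-in
#' emulating the completeness ranking of Upper Paleolithic cranial samples:
#' vault bones and the mandible well represented, mid-facial bones (nasal,
#' zygomatic) poorly represented. Only ratios matter for the removal weights,
#' so any rescaling of the table is equivalent.
#'
#' @param schema A [cranial_schema()] object.
#' @param path CSV with columns `bone`, `ess`. Defaults to the shipped
#'   synthetic fixture.
#' @return Named numeric vector of ESS values (class `"bone_ess"`), one per
#'   bone, in schema bone order.
#' @export
read_bone_ess <- function(schema = cranial_schema(),
                          path = default_fixture("ess")) {
  stopifnot_schema(schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bone", "ess") %in% names(raw)))
    stop("bone ESS fixture must have columns bone, ess")
  missing_b <- setdiff(schema$bones, raw$bone)
  if (length(missing_b))
    stop("bone ESS fixture missing bone(s): ", paste(missing_b, collapse = ", "))
  extra <- setdiff(raw$bone, schema$bones)
  if (length(extra))
    stop("bone ESS fixture has unknown bone(s): ", paste(extra, collapse = ", "))
  ess <- stats::setNames(raw$ess, raw$bone)[schema$bones]
  if (any(!is.finite(ess)) || any(ess <= 0))
    stop("all ESS values must be positive and finite")
  structure(ess, class = c("bone_ess", "numeric"))
}
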