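#' Cranial recording schema: 48 elements on 14 bones
#'
#' Builds the fixed partition of the skull used both for recording trauma and
#' for allocating missing values. The skull is divided into 14 major bones:
#' the unpaired frontal and occipital, and the paired parietal, temporal,
#' maxilla, mandible, zygomatic and nasal bones. Each bone contributes four
#' roughly equal regions, except the small nasal and zygomatic bones which
#' contribute two each, for a total of 48 elements.
#'
#' Element ordering is fixed and anatomical, left before right:
#' frontal, parietal (L, R), temporal (L, R), occipital, nasal (L, R),
#' zygomatic (L, R), maxilla (L, R), mandible (L, R); regions are numbered
#' within each bone (`<bone>_<region>`). All 48-long vectors in the package
#' (trauma patterns, specimen states, removal weights) use this order.
#'
#' Region conventions used by the shipped trauma-case fixture:
#' mandible 1 = body, 2 = angle, 3 = ramus, 4 = condylar/subcondylar area;
#' maxilla 1 = frontal process, 2 = zygomatic process, 3 = alveolar process,
#' 4 = sinus/palatine region; temporal 1 = squama, 2 = petrous, 3 = mastoid,
#' 4 = zygomatic process; occipital 1/2 = left/right squama, 3 = basilar part
#' and foramen magnum rim, 4 = condyles; frontal 1/2 = left/right squama,
#' 3 = glabella/sinus region, 4 = orbital roofs; parietal 1-4 = quadrants;
#' zygomatic 1 = body (zygoma), 2 = temporal process (arch); nasal 1 = upper,
#' 2 = lower half.
#'
#' @return An object of class `"cranial_schema"`: a list with
#'   \item{elements}{character vector of the 48 element identifiers, in order}
#'   \item{bone_of}{named character vector mapping element -> bone}
#'   \item{bones}{character vector of the 14 bone identifiers}
#'   \item{regions_per_bone}{named integer vector, bone -> number of regions}
#' @examples
#' sch <- cranial_schema()
#' length(sch$elements)          # 48
#' table(sch$bone_of)[["frontal"]]
#' @export
cranial_schema <- function() {
  four <- c("frontal", "parietal_L", "parietal_R", "temporal_L", "temporal_R",
            "occipital")
  two  <- c("nasal_L", "nasal_R", "zygomatic_L", "zygomatic_R")
  four2 <- c("maxilla_L", "maxilla_R", "mandible_L", "mandible_R")

  bones <- c(four, two, four2)
  regions_per_bone <- stats::setNames(
    ifelse(bones %in% two, 2L, 4L), bones)

  elements <- unlist(lapply(bones, function(b)
    paste(b, seq_len(regions_per_bone[[b]]), sep = "_")), use.names = FALSE)
  bone_of <- stats::setNames(rep(bones, regions_per_bone), elements)

  structure(
    list(elements = elements, bone_of = bone_of, bones = bones,
         regions_per_bone = regions_per_bone),
    class = "cranial_schema")
}

#' @export
print.cranial_schema <- function(x, ...) {
  cat("Cranial recording schema:", length(x$elements), "elements on",
      length(x$bones), "bones\n")
  cat("Bones:", paste(x$bones, collapse = ", "), "\n")
  invisible(x)
}

stopifnot_schema <- function(schema) {
  if (!inherits(schema, "cranial_schema"))
    stop("`schema` must be a cranial_schema object", call. = FALSE)
  invisible(schema)
}
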