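#' Landmark label vocabulary
#'
#' The closed set of 36 named landmark points annotated on a pantomogram.
#' Labels follow FDI tooth numbering (13 = upper right canine; 43, 45, 46,
#' 47 = lower right canine, second premolar, first and second molar).
#' Prefixes: `C` = crown point, `A` = root apex, `M` = mandibular-border
#' point, `P` = projected reference counterpart of the apex, `CeM`/`CeD` =
#' mesial/distal cemento-enamel junction points, `PCeM`/`PCeD` = their
#' projected reference counterparts.  These readings are descriptive only;
#' the package's contract with the labels is purely geometric.
#'
#' @return Character vector of the 36 labels, in canonical order.
#' @export
#' @examples
#' landmark_vocabulary()
landmark_vocabulary <- function() {
  c("C13", "C15", "C16", "C17",
    "C43", "C45", "C46", "C47",
    "A43", "A45", "A46", "A47",
    "P43", "P45", "P46", "P47",
    "M43", "M45", "M46", "M47",
    "CeM43", "CeD43", "CeM45", "CeD45",
    "CeM46", "CeD46", "CeM47", "CeD47",
    "PCeM43", "PCeD43", "PCeM45", "PCeD45",
    "PCeM46", "PCeD46", "PCeM47", "PCeD47")
}

#' Indicator names
#'
#' @return Character vector `X01` .. `X21`.
#' @export
indicator_names <- function() sprintf("X%02d", 1:21)

#' Segment definitions of the 21 ratio indicators
#'
#' Each indicator is the ratio of two Euclidean segment lengths between
#' named landmarks: `|num_a num_b| / |den_a den_b|`.  X01-X06 relate the
#' four cross-arch canine/premolar/molar crown distances; X07-X10 compare
#' crown-to-apex root length against a projected apex reference; X11-X14
#' compare crown width at the cemento-enamel junction against a projected
#' reference width; X15-X18 relate the crown-to-mandibular-border distance
#' to the apex-to-border distance; X19-X21 compare apex-to-border
#' distances across teeth.
#'
#' @return A data.frame with columns `indicator`, `num_a`, `num_b`,
#'   `den_a`, `den_b`.
#' @export
#' @examples
#' indicator_definitions()
indicator_definitions <- function() {
  defs <- rbind(
    c("X01", "C13", "C43", "C15", "C45"),
    c("X02", "C13", "C43", "C16", "C46"),
    c("X03", "C13", "C43", "C17", "C47"),
    c("X04", "C15", "C45", "C16", "C46"),
    c("X05", "C15", "C45", "C17", "C47"),
    c("X06", "C16", "C46", "C17", "C47"),
    c("X07", "C43", "A43", "P43", "A43"),
    c("X08", "C45", "A45", "P45", "A45"),
    c("X09", "C46", "A46", "P46", "A46"),
    c("X10", "C47", "A47", "P47", "A47"),
    c("X11", "CeM43", "CeD43", "PCeM43", "PCeD43"),
    c("X12", "CeM45", "CeD45", "PCeM45", "PCeD45"),
    c("X13", "CeM46", "CeD46", "PCeM46", "PCeD46"),
    c("X14", "CeM47", "CeD47", "PCeM47", "PCeD47"),
    c("X15", "C43", "M43", "A43", "M43"),
    c("X16", "C45", "M45", "A45", "M45"),
    c("X17", "C46", "M46", "A46", "M46"),
    c("X18", "C47", "M47", "A47", "M47"),
    c("X19", "A43", "M43", "A45", "M45"),
    c("X20", "A43", "M43", "A46", "M46"),
    c("X21", "A45", "M45", "A46", "M46")
  )
  out <- as.data.frame(defs, stringsAsFactors = FALSE)
  names(out) <- c("indicator", "num_a", "num_b", "den_a", "den_b")
  out
}

# Valid age window (months) for the method's target population.
AGE_MIN_MONTHS <- 48L
AGE_MAX_MONTHS <- 144L

# run code with a temporary RNG seed, restoring prior state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
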