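#' Euclidean length of a landmark segment
#'
#' @param s A [landmark_set()].
#' @param a,b Landmark labels (segment endpoints).
#' @return Segment length in pixels.
#' @export
#' @examples
#' s <- landmark_set("c1", "F", NA, rbind(C13 = c(0, 0), C43 = c(3, 4)))
#' segment_length(s, "C13", "C43")  # 5
segment_length <- function(s, a, b) {
  stopifnot(inherits(s, "landmark_set"))
  for (lab in c(a, b))
    if (!lab %in% rownames(s$points))
      stop("landmark \"", lab, "\" absent from case ", s$case_id,
           call. = FALSE)
  d <- s$points[a, ] - s$points[b, ]
  sqrt(sum(d^2))
}

#' Compute the 21 ratio indicators for one case
#'
#' Evaluates every indicator whose four endpoint landmarks are present.
#' Ratios are dimensionless, so the result is invariant under translation,
#' rotation, and uniform scaling of the coordinates.  An indicator whose
#' denominator segment has zero length is flagged degenerate: its value is
#' `NA` and a warning is raised (not an error), since downstream models
#' simply require complete feature vectors.
#'
#' @param s A [landmark_set()].
#' @return Named numeric vector `X01..X21` (`NA` where not computable),
#'   with attributes `case_id`, `sex`, `age_months`.
#' @seealso [indicator_definitions()], [indicator_table()]
#' @export
compute_indicators <- function(s) {
  stopifnot(inherits(s, "landmark_set"))
  defs <- indicator_definitions()
  have <- rownames(s$points)
  vals <- setNames(rep(NA_real_, nrow(defs)), defs$indicator)
  degenerate <- character(0)
  for (i in seq_len(nrow(defs))) {
    pts <- c(defs$num_a[i], defs$num_b[i], defs$den_a[i], defs$den_b[i])
    if (!all(pts %in% have)) next
    den <- segment_length(s, defs$den_a[i], defs$den_b[i])
    if (den == 0) {
      degenerate <- c(degenerate, defs$indicator[i])
      next
    }
    vals[i] <- segment_length(s, defs$num_a[i], defs$num_b[i]) / den
  }
  if (length(degenerate))
    warning("degenerate (zero-length denominator) indicator(s) for case ",
            s$case_id, ": ", paste(degenerate, collapse = ", "),
            call. = FALSE)
  attr(vals, "case_id") <- s$case_id
  attr(vals, "sex") <- s$sex
  attr(vals, "age_months") <- s$age_months
  vals
}

#' Indicator table for a list of cases
#'
#' @param cases List of `landmark_set` objects.
#' @return Data.frame with columns `case_id`, `sex`, `age_months`,
#'   `X01..X21`.
#' @export
indicator_table <- function(cases) {
  rows <- lapply(cases, function(cs) {
    v <- compute_indicators(cs)
    cbind(data.frame(case_id = cs$case_id, sex = cs$sex,
                     age_months = cs$age_months,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble model-ready feature vectors
#'
#' Builds the feature matrix fed to the RBF engine from an indicator
#' table.  The default combined-sex layout has 22 inputs ordered
#' `X01..X21, SEX` with sex encoded 0 (F) / 1 (M); sex-specific layouts
#' omit `SEX` (21 inputs).  A `retained` list (for example the variables
#' kept after sensitivity pruning) restricts and reorders the inputs to
#' that list.  Cases with any missing retained feature are dropped with a
#' message, since the networks require complete inputs.
#'
#' @param ind Indicator table (data.frame from [indicator_table()],
#'   [generate_cohort()] or [read_indicators()]).
#' @param include_sex Include the `SEX` input (ignored when `retained`
#'   is given, which then decides).
#' @param retained Optional character vector of input names (subset of
#'   `X01..X21`, `SEX`) fixing order and content.
#' @return Object of class `feature_set`: list with `x` (numeric matrix,
#'   rownames = case ids), `y` (age in months, `NA` allowed), `names`.
#' @export
assemble_features <- function(ind, include_sex = TRUE, retained = NULL) {
  xnames <- if (!is.null(retained)) {
    retained <- as.character(retained)
    bad <- setdiff(retained, c(indicator_names(), "SEX"))
    if (length(bad))
      stop("unknown feature name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(retained))
      stop("duplicate feature name(s) in `retained`", call. = FALSE)
    retained
  } else if (include_sex) c(indicator_names(), "SEX") else indicator_names()

  n <- nrow(ind)
  x <- matrix(NA_real_, n, length(xnames),
              dimnames = list(ind$case_id, xnames))
  for (nm in xnames) {
    x[, nm] <- if (nm == "SEX") ifelse(ind$sex == "M", 1, 0)
               else ind[[nm]]
  }
  keep <- stats::complete.cases(x)
  if (!all(keep))
    message("dropping ", sum(!keep),
            " case(s) with incomplete features")
  structure(list(x = x[keep, , drop = FALSE],
                 y = setNames(as.numeric(ind$age_months[keep]),
                              ind$case_id[keep]),
                 names = xnames),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>", nrow(x$x), "cases x", ncol(x$x), "inputs (",
      paste(utils::head(x$names, 3), collapse = ", "),
      if (length(x$names) > 3) ", ..." else "", ")\n", sep = " ")
  invisible(x)
}

# subset a feature_set to the rows whose case ids are in `ids`
feature_rows <- function(features, ids) {
  i <- match(ids, rownames(features$x))
  if (anyNA(i))
    stop("case id(s) not present in feature set: ",
         paste(ids[is.na(i)][1:min(3, sum(is.na(i)))], collapse = ", "),
         call. = FALSE)
  list(x = features$x[i, , drop = FALSE], y = features$y[i])
}
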