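#' Construct a landmark set for one case
#'
#' A landmark set holds one case's named 2-D points (pixel coordinates in
#' image convention: origin top-left, y increasing downward) together with
#' sex and, optionally, chronological age in months.  Because all derived
#' indicators are length ratios, the coordinate convention and pixel scale
#' never affect results.
#'
#' @param case_id Opaque case identifier (non-empty string).
#' @param sex `"F"` or `"M"`.
#' @param age_months Integer age in months, or `NA` if unknown.  When
#'   present it must lie in \[48, 144\] unless `validate_age = FALSE`.
#' @param points Numeric matrix with two columns (x, y) and row names drawn
#'   from [landmark_vocabulary()], or a named list of length-2 numeric
#'   vectors.
#' @param validate_age Enforce the 48-144 month validity window.
#' @return An object of class `landmark_set`.
#' @export
#' @examples
#' pts <- rbind(C13 = c(10, 5), C43 = c(10, 45))
#' landmark_set("case1", "F", 96, pts)
landmark_set <- function(case_id, sex, age_months = NA, points,
                         validate_age = TRUE) {
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id))
    stop("`case_id` must be a non-empty string", call. = FALSE)
  sex <- as.character(sex)
  if (!sex %in% c("F", "M"))
    stop("`sex` must be \"F\" or \"M\"", call. = FALSE)
  if (is.list(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("`points` must have two columns (x, y)", call. = FALSE)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  labs <- rownames(points)
  if (is.null(labs) && nrow(points) > 0L)
    stop("`points` rows must be named with landmark labels", call. = FALSE)
  bad <- setdiff(labs, landmark_vocabulary())
  if (length(bad))
    stop("unknown landmark label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate landmark label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  age_months <- if (is.na(age_months)) NA_integer_ else as.integer(age_months)
  if (validate_age && !is.na(age_months) &&
      (age_months < AGE_MIN_MONTHS || age_months > AGE_MAX_MONTHS))
    stop("age_months ", age_months, " outside the validity window [",
         AGE_MIN_MONTHS, ", ", AGE_MAX_MONTHS,
         "]; use validate_age = FALSE to override", call. = FALSE)
  structure(list(case_id = case_id, sex = sex, age_months = age_months,
                 points = points),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> case", x$case_id, "sex", x$sex,
      if (is.na(x$age_months)) "age NA" else paste("age", x$age_months, "mo"),
      "-", nrow(x$points), "of", length(landmark_vocabulary()),
      "landmarks\n")
  invisible(x)
}

#' Is a landmark set complete?
#'
#' Complete means all 36 vocabulary labels are present.
#'
#' @param x A `landmark_set`.
#' @return Logical.
#' @export
is_complete <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  all(landmark_vocabulary() %in% rownames(x$points))
}

LANDMARK_COLUMNS <- c("case_id", "sex", "age_months", "label", "x", "y")

#' Read landmark measurements from CSV
#'
#' Reads the package's landmark interchange format: one row per annotated
#' point with columns `case_id,sex,age_months,label,x,y` (the shape of an
#' ImageJ point-measurement export joined to the patient register).  Rows
#' are grouped into one [landmark_set()] per case, in order of first
#' appearance.
#'
#' @param path CSV file path.
#' @param strict If `TRUE` (default) an unknown label aborts with an error
#'   naming the offending row; if `FALSE` such rows are skipped with a
#'   warning.  Silent data loss is considered worse than failure, hence
#'   the strict default.
#' @param validate_age Enforce the 48-144 month window on ingestion.
#' @return List of `landmark_set` objects.
#' @seealso [write_landmarks()]
#' @export
read_landmarks <- function(path, strict = TRUE, validate_age = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), LANDMARK_COLUMNS)) {
    missing <- setdiff(LANDMARK_COLUMNS, names(df))
    extra <- setdiff(names(df), LANDMARK_COLUMNS)
    stop("malformed landmark file header",
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  known <- df$label %in% landmark_vocabulary()
  if (!all(known)) {
    rows <- which(!known) + 1L  # +1 for the header line
    if (strict) {
      stop("unknown landmark label \"", df$label[!known][1L],
           "\" at file row ", rows[1L], call. = FALSE)
    }
    warning("skipping ", sum(!known), " row(s) with unknown labels (",
            paste(unique(df$label[!known]), collapse = ", "), ")",
            call. = FALSE)
    df <- df[known, , drop = FALSE]
  }
  dup <- duplicated(df[, c("case_id", "label")])
  if (any(dup))
    stop("duplicate (case_id, label) pair: ", df$case_id[dup][1L], "/",
         df$label[dup][1L], call. = FALSE)
  ids <- unique(df$case_id)
  lapply(ids, function(id) {
    sub <- df[df$case_id == id, , drop = FALSE]
    sexes <- unique(sub$sex)
    if (length(sexes) != 1L)
      stop("case ", id, " has inconsistent sex values", call. = FALSE)
    ages <- unique(sub$age_months)
    if (length(ages) != 1L)
      stop("case ", id, " has inconsistent age values", call. = FALSE)
    age <- if (is.na(ages) || ages == "") NA_integer_ else as.integer(ages)
    pts <- cbind(x = as.numeric(sub$x), y = as.numeric(sub$y))
    rownames(pts) <- sub$label
    landmark_set(id, sexes, age, pts, validate_age = validate_age)
  })
}

#' Write landmark sets to CSV
#'
#' Inverse of [read_landmarks()]: cases in input order, labels within a
#' case in vocabulary order, absent ages as empty fields.  Writing then
#' re-reading recovers the input field for field, and a second write is
#' byte-identical.
#'
#' @param cases List of `landmark_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(cases, path) {
  stopifnot(all(vapply(cases, inherits, logical(1), "landmark_set")))
  vocab <- landmark_vocabulary()
  rows <- lapply(cases, function(cs) {
    labs <- vocab[vocab %in% rownames(cs$points)]
    if (!length(labs)) return(NULL)
    data.frame(case_id = cs$case_id, sex = cs$sex,
               age_months = if (is.na(cs$age_months)) "" else
                 as.character(cs$age_months),
               label = labs,
               x = format(cs$points[labs, "x"], trim = TRUE, digits = 15),
               y = format(cs$points[labs, "y"], trim = TRUE, digits = 15),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    as.data.frame(setNames(rep(list(character(0)), 6L), LANDMARK_COLUMNS))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read an indicator table from CSV
#'
#' Columns `case_id,sex,age_months,X01..X21`; empty fields become `NA`.
#'
#' @param path CSV file path.
#' @return A data.frame (one row per case).
#' @export
read_indicators <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("case_id", "sex", "age_months", indicator_names())
  if (!identical(names(df), want))
    stop("malformed indicator file header; expected columns ",
         paste(want, collapse = ","), call. = FALSE)
  df$case_id <- as.character(df$case_id)
  df$age_months <- as.integer(df$age_months)
  for (nm in indicator_names()) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write an indicator table to CSV
#'
#' @param ind Data.frame as returned by [indicator_table()] or
#'   [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(ind, path) {
  want <- c("case_id", "sex", "age_months", indicator_names())
  stopifnot(all(want %in% names(ind)))
  utils::write.csv(ind[, want], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read a sensitivity-quotient table
#'
#' Two-column CSV `variable,quotient` (a rank column, if present, is
#' ignored on input since ranks are recomputed).  File order is preserved,
#' which matters for stable tie-breaking in [rank_quotients()].
#'
#' @param path CSV file path.
#' @return Named numeric vector of quotients in file order.
#' @export
#' @examples
#' f <- system.file("extdata", "quotients_female.csv", package = "dentage")
#' read_quotient_table(f)
read_quotient_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L || !all(c("variable", "quotient") %in% names(df)))
    stop("quotient file must have columns variable,quotient", call. = FALSE)
  if (nrow(df) == 0L) return(setNames(numeric(0), character(0)))
  q <- suppressWarnings(as.numeric(df$quotient))
  if (anyNA(q))
    stop("non-numeric quotient at file row ", which(is.na(q))[1L] + 1L,
         call. = FALSE)
  setNames(q, df$variable)
}

#' Write a sensitivity report to CSV
#'
#' Emits `variable,quotient,rank` rows in rank order.
#'
#' @param report Data.frame from [rank_quotients()] or
#'   [sensitivity_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(report, path) {
  stopifnot(all(c("variable", "quotient", "rank") %in% names(report)))
  utils::write.csv(report[, c("variable", "quotient", "rank")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
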