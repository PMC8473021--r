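#' Default growth trajectories for the synthetic cohort
#'
#' The generator emulates dental maturation between 48 and 144 months
#' with monotone age-response curves.  Root- and crown-maturation ratios
#' (X07-X18) follow logistic curves rising toward an asymptote (mimicking
#' progressive apex closure), each with its own midpoint so that later
#' teeth mature later.  The arch-width ratios (X01-X06) and cross-tooth
#' apex-border ratios (X19-X21) are *derived* from latent segment-length
#' trajectories (gentle linear growth) rather than drawn independently:
#' these nine indicators share segment endpoints, so only latent-level
#' generation keeps every generated vector geometrically realizable (for
#' example X04 = X02/X01 must hold exactly).  Noise for direct indicators
#' is Gaussian with s.d. = `noise` x the curve's range; latent lengths
#' receive noise at half that relative level, which keeps each derived
#' ratio's dispersion near the same 5%-of-range default.
#'
#' @return List with elements `direct` (data.frame: indicator, start,
#'   end, midpoint, steepness, floor) and `latent` (data.frame: name,
#'   start, end).  Latent names: `S13/S15/S16/S17` are the cross-arch
#'   crown distances (numerators/denominators of X01-X06); `d43/d45/d46/
#'   d47` the apex-to-mandibular-border distances (X19-X21 and the
#'   denominators of X15-X18).
#' @export
default_trajectories <- function() {
  direct <- data.frame(
    indicator = sprintf("X%02d", 7:18),
    start = c(0.55, 0.60, 0.50, 0.65,   # X07-X10 root-length ratios
              0.70, 0.72, 0.68, 0.75,   # X11-X14 crown-width ratios
              1.15, 1.18, 1.12, 1.20),  # X15-X18 crown/apex border ratios
    end = c(1.25, 1.30, 1.20, 1.35,
            1.05, 1.08, 1.02, 1.10,
            1.60, 1.62, 1.55, 1.65),
    midpoint = c(88, 96, 84, 104,
                 80, 92, 78, 100,
                 86, 94, 82, 102),
    steepness = c(rep(0.07, 4), rep(0.06, 8)),
    floor = 0.05,
    stringsAsFactors = FALSE)
  latent <- data.frame(
    name = c("S13", "S15", "S16", "S17", "d43", "d45", "d46", "d47"),
    start = c(49, 62, 54, 60, 30, 33, 28, 30),
    end = c(84, 66, 66, 88, 45, 38, 48, 46),
    stringsAsFactors = FALSE)
  list(direct = direct, latent = latent)
}

#' Synthetic cohort parameters
#'
#' Defaults emulate the study population: 296 female and 323 male cases
#' (619 in total), integer ages uniform on 48-144 months, low noise
#' (s.d. 5% of each curve's range), and a -3 month curve-midpoint shift
#' for females (earlier maturation).
#'
#' @param n_female,n_male Cohort composition.
#' @param age_min,age_max Age range in months; in emulation mode (the
#'   default) restricted to \[48, 144\].
#' @param noise Noise s.d. as a fraction of each indicator's range.
#' @param sex_shift Midpoint shift (months) applied to female curves.
#' @param seed Integer seed.
#' @param trajectories Trajectory tables; see [default_trajectories()].
#' @param emulate Enforce the 48-144 month study window.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_female = 296L, n_male = 323L,
                          age_min = 48L, age_max = 144L,
                          noise = 0.05, sex_shift = -3,
                          seed = 1L,
                          trajectories = default_trajectories(),
                          emulate = TRUE) {
  n_female <- as.integer(n_female); n_male <- as.integer(n_male)
  if (n_female < 0L || n_male < 0L)
    stop("cohort sizes must be non-negative", call. = FALSE)
  if (age_min > age_max)
    stop("age_min must not exceed age_max", call. = FALSE)
  if (emulate && (age_min < AGE_MIN_MONTHS || age_max > AGE_MAX_MONTHS))
    stop("study-emulation mode requires ages within [", AGE_MIN_MONTHS,
         ", ", AGE_MAX_MONTHS, "]", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  stopifnot(is.list(trajectories),
            all(c("direct", "latent") %in% names(trajectories)))
  structure(list(n_female = n_female, n_male = n_male,
                 age_min = as.integer(age_min),
                 age_max = as.integer(age_max),
                 noise = noise, sex_shift = sex_shift,
                 seed = as.integer(seed),
                 trajectories = trajectories),
            class = "cohort_params")
}

#' Read cohort parameters from a plain-text config file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Recognised
#' keys: `n_female`, `n_male`, `age_min`, `age_max`, `noise`,
#' `sex_shift`, `seed`.  Unknown keys are an error.
#'
#' @param path Config file path.
#' @return A [cohort_params()] object.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line: \"", lines[bad][1L], "\"", call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  allowed <- c("n_female", "n_male", "age_min", "age_max", "noise",
               "sex_shift", "seed")
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(cohort_params, args)
}

# logistic curve between start and end with midpoint shift for females
logistic_curve <- function(age, start, end, midpoint, steepness, shift) {
  start + (end - start) / (1 + exp(-steepness * (age - (midpoint + shift))))
}

# latent linear growth over the study window, midpoint-shifted for females
latent_curve <- function(age, start, end, shift) {
  start + (end - start) * (age - shift - AGE_MIN_MONTHS) /
    (AGE_MAX_MONTHS - AGE_MIN_MONTHS)
}

# ratios of latent lengths that define the derived indicators
DERIVED_MAP <- list(
  X01 = c("S13", "S15"), X02 = c("S13", "S16"), X03 = c("S13", "S17"),
  X04 = c("S15", "S16"), X05 = c("S15", "S17"), X06 = c("S16", "S17"),
  X19 = c("d43", "d45"), X20 = c("d43", "d46"), X21 = c("d45", "d46"))

#' Generate a synthetic indicator cohort
#'
#' Draws ages uniformly (integers) over the configured window, evaluates
#' every trajectory at each case's age and sex, and adds seeded Gaussian
#' noise.  Deterministic for a fixed seed.  With zero noise every
#' indicator is strictly monotone in age within each sex.
#'
#' @param params A [cohort_params()] object.
#' @return Indicator table: data.frame `case_id`, `sex`, `age_months`,
#'   `X01..X21`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_female = 5, n_male = 5))
#' dim(cohort)
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_female + params$n_male
  sex <- c(rep("F", params$n_female), rep("M", params$n_male))
  id <- sprintf("%s%04d", sex, c(seq_len(params$n_female),
                                 seq_len(params$n_male)))
  tra <- params$trajectories
  out <- with_seed(params$seed, {
    age <- if (n) sample(seq(params$age_min, params$age_max), n,
                         replace = TRUE) else integer(0)
    shift <- ifelse(sex == "F", params$sex_shift, 0)
    vals <- matrix(NA_real_, n, 21,
                   dimnames = list(NULL, indicator_names()))
    # latent segment lengths with noise at half the relative level
    lat <- matrix(NA_real_, n, nrow(tra$latent),
                  dimnames = list(NULL, tra$latent$name))
    for (i in seq_len(nrow(tra$latent))) {
      row <- tra$latent[i, ]
      mu <- latent_curve(age, row$start, row$end, shift)
      sd <- 0.5 * params$noise * abs(row$end - row$start)
      lat[, i] <- pmax(mu + if (sd > 0) stats::rnorm(n, 0, sd) else 0, 1)
    }
    for (nm in names(DERIVED_MAP))
      vals[, nm] <- lat[, DERIVED_MAP[[nm]][1]] / lat[, DERIVED_MAP[[nm]][2]]
    for (i in seq_len(nrow(tra$direct))) {
      row <- tra$direct[i, ]
      mu <- logistic_curve(age, row$start, row$end, row$midpoint,
                           row$steepness, shift)
      sd <- params$noise * abs(row$end - row$start)
      vals[, row$indicator] <-
        pmax(mu + if (sd > 0) stats::rnorm(n, 0, sd) else 0, row$floor)
    }
    cbind(data.frame(case_id = id, sex = sex, age_months = age,
                     stringsAsFactors = FALSE),
          as.data.frame(vals))
  })
  rownames(out) <- NULL
  out
}

# tolerance for the algebraic consistency that geometry imposes on a
# realizable indicator vector
REALIZABILITY_TOL <- 1e-6

#' Reconstruct a landmark set realizing an indicator vector
#'
#' Places the 36 vocabulary points on a parametric jaw template so that
#' [compute_indicators()] recovers the given values to 1e-6.  Denominator
#' segments are fixed by the template; numerator endpoints are positioned
#' to realize each ratio.  Per tooth, crown (C), apex (A), and border (M)
#' points form a triangle with |AM| set by the template, |CM| = X15-group
#' ratio x |AM|, and |CA| chosen feasibly; the projected apex reference P
#' then realizes the X07-group ratio.  Because X01-X06 and X19-X21 share
#' segments, an arbitrary vector is only realizable when it satisfies the
#' implied identities (e.g. `X04 = X02/X01`); vectors from
#' [generate_cohort()] always do.
#'
#' @param values Named numeric vector with all 21 indicators present and
#'   positive.
#' @param case_id,sex,age_months Case metadata for the resulting set.
#' @param base Template scale factor (> 0); indicators are scale-free, so
#'   any value recovers the same vector.
#' @return A [landmark_set()].
#' @export
generate_landmarks <- function(values, case_id = "synthetic", sex = "F",
                               age_months = NA, base = 1) {
  values <- values[indicator_names()]
  if (anyNA(values) || any(values <= 0))
    stop("all 21 indicators must be present and > 0", call. = FALSE)
  if (base <= 0) stop("`base` must be > 0", call. = FALSE)
  chk <- function(lhs, rhs, what) {
    if (abs(lhs - rhs) > REALIZABILITY_TOL * max(abs(rhs), 1))
      stop("indicator vector is not geometrically realizable: ", what,
           " inconsistent", call. = FALSE)
  }
  v <- as.list(values)
  # cross-arch crown distances from the template anchor S16
  S16 <- 60 * base
  S13 <- v$X02 * S16
  S15 <- S13 / v$X01
  S17 <- S16 / v$X06
  chk(v$X03, S13 / S17, "X03 = X02*X06")
  chk(v$X04, S15 / S16, "X04 = X02/X01")
  chk(v$X05, S15 / S17, "X05 = X04*X06")
  # apex-to-border distances from the template anchor d43
  d43 <- 40 * base
  d45 <- d43 / v$X19
  d46 <- d43 / v$X20
  chk(v$X21, d45 / d46, "X21 = X20/X19")
  d47 <- 38 * base

  teeth <- c("43", "45", "46", "47")
  d <- c(`43` = d43, `45` = d45, `46` = d46, `47` = d47)
  q <- c(v$X07, v$X08, v$X09, v$X10)       # |CA| / |PA|
  m <- c(v$X15, v$X16, v$X17, v$X18)       # |CM| / |AM|
  wr <- c(v$X11, v$X12, v$X13, v$X14)      # |CeM CeD| / |PCeM PCeD|
  names(q) <- names(m) <- names(wr) <- teeth
  xpos <- c(`43` = 100, `45` = 170, `46` = 240, `47` = 310) * base
  pw <- c(`43` = 9, `45` = 10, `46` = 11, `47` = 12) * base
  yM <- 420 * base

  pts <- matrix(NA_real_, 0, 2)
  add <- function(label, x, y) {
    p <- matrix(c(x, y), 1, 2, dimnames = list(label, c("x", "y")))
    pts <<- rbind(pts, p)
  }
  for (t in teeth) {
    dt <- d[[t]]
    ct <- m[[t]] * dt                     # |CM|
    # |CA|: any feasible triangle side; max(|CM|, |AM|) is always interior
    at <- max(ct, dt)
    bt <- at / q[[t]]                     # |PA|
    Mx <- xpos[[t]]; My <- yM
    Ax <- Mx; Ay <- yM - dt
    cy <- (ct^2 - at^2 + dt^2) / (2 * dt) # C's height above M along AM
    dx <- sqrt(max(ct^2 - cy^2, 0))
    Cx <- Mx + dx; Cy <- My - cy
    add(paste0("M", t), Mx, My)
    add(paste0("A", t), Ax, Ay)
    add(paste0("C", t), Cx, Cy)
    add(paste0("P", t), Ax + bt, Ay)
    wt <- wr[[t]] * pw[[t]]
    yce <- Cy + 6 * base
    add(paste0("CeM", t), Mx - wt / 2, yce)
    add(paste0("CeD", t), Mx + wt / 2, yce)
    add(paste0("PCeM", t), Mx - pw[[t]] / 2, yce + 10 * base)
    add(paste0("PCeD", t), Mx + pw[[t]] / 2, yce + 10 * base)
  }
  # upper crown points directly above their lower counterparts
  upper <- c(C13 = S13, C15 = S15, C16 = S16, C17 = S17)
  lower <- c(C13 = "C43", C15 = "C45", C16 = "C46", C17 = "C47")
  for (nm in names(upper))
    add(nm, pts[lower[[nm]], "x"], pts[lower[[nm]], "y"] - upper[[nm]])
  # translate into the positive quadrant (ratios are unaffected)
  lo <- pmin(apply(pts, 2, min), 0)
  pts <- sweep(pts, 2, lo, "-")
  landmark_set(case_id, sex, age_months, pts)
}

#' Landmark sets for a whole synthetic cohort
#'
#' @param cohort Indicator table from [generate_cohort()].
#' @param base Template scale factor.
#' @return List of [landmark_set()] objects.
#' @export
cohort_landmarks <- function(cohort, base = 1) {
  lapply(seq_len(nrow(cohort)), function(i) {
    v <- unlist(cohort[i, indicator_names()])
    generate_landmarks(v, case_id = cohort$case_id[i],
                       sex = cohort$sex[i],
                       age_months = cohort$age_months[i], base = base)
  })
}
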