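#' Random 2:1:1 cohort split
#'
#' Shuffles the case ids with a seeded generator and allocates
#' `floor(n/2)` to training, `floor(n/4)` to validation, and the
#' remainder to testing — the standard 50/25/25 protocol.  The split is
#' deterministic for a fixed seed.
#'
#' @param ids Character or integer vector of case ids (length >= 4).
#' @param seed Integer seed.
#' @return Object of class `data_split`: list `train`, `valid`, `test`.
#' @export
#' @examples
#' s <- split_cohort(paste0("c", 1:400), seed = 1)
#' lengths(s)  # 200 100 100
split_cohort <- function(ids, seed) {
  n <- length(ids)
  if (n < 4L) stop("need at least 4 cases to split 2:1:1", call. = FALSE)
  if (anyDuplicated(ids)) stop("case ids must be unique", call. = FALSE)
  shuffled <- with_seed(seed, sample(ids))
  n_train <- floor(n / 2)
  n_valid <- floor(n / 4)
  structure(list(train = shuffled[seq_len(n_train)],
                 valid = shuffled[n_train + seq_len(n_valid)],
                 test = shuffled[(n_train + n_valid + 1L):n]),
            class = "data_split")
}

#' Min-max scaling to the unit interval
#'
#' Affine map of `v` from \[lo, hi\] onto \[0, 1\] and its inverse.  The
#' bounds are always fitted on the training partition only, so validation
#' and test values may fall outside \[0, 1\]; that is intentional.  A
#' zero-span target is mapped with span 1 (constant targets are legal); a
#' zero-span input column is an error.
#'
#' @param v Numeric vector.
#' @param lo,hi Scaling bounds (training minimum and maximum).
#' @return Scaled (resp. unscaled) numeric vector.
#' @export
minimax_scale <- function(v, lo, hi) {
  span <- hi - lo
  if (span <= 0) span <- 1
  (v - lo) / span
}

#' @rdname minimax_scale
#' @export
minimax_unscale <- function(v, lo, hi) {
  span <- hi - lo
  if (span <= 0) span <- 1
  lo + v * span
}

# fit per-column input bounds and output bounds on training data
fit_scale_params <- function(x, y) {
  xmin <- apply(x, 2, min)
  xmax <- apply(x, 2, max)
  if (any(xmax - xmin <= 0))
    stop("degenerate (constant) input column(s): ",
         paste(colnames(x)[xmax - xmin <= 0], collapse = ", "),
         "; drop them before fitting", call. = FALSE)
  list(xmin = xmin, xmax = xmax, ymin = min(y), ymax = max(y))
}

scale_inputs <- function(x, scale) {
  sweep(sweep(x, 2, scale$xmin, "-"), 2,
        pmax(scale$xmax - scale$xmin, .Machine$double.eps), "/")
}

#' Parse and format RBF topology strings
#'
#' Topology strings have the form `"RBF I:I-H-O:O"`, e.g.
#' `"RBF 22:22-15-1:1"` for 22 inputs, 15 hidden radial units, and one
#' linear output.  `format_topology()` is the exact inverse.
#'
#' @param s Topology string.
#' @return Named integer vector `c(inputs, hidden, outputs)`.
#' @export
#' @examples
#' parse_topology("RBF 22:22-15-1:1")
parse_topology <- function(s) {
  m <- regmatches(s, regexec("^RBF ([0-9]+):([0-9]+)-([0-9]+)-([0-9]+):([0-9]+)$",
                             s))[[1]]
  if (length(m) != 6L)
    stop("malformed topology string: \"", s, "\"", call. = FALSE)
  v <- as.integer(m[-1])
  if (v[1] != v[2] || v[4] != v[5])
    stop("malformed topology string (layer counts must repeat): \"", s,
         "\"", call. = FALSE)
  c(inputs = v[1], hidden = v[3], outputs = v[4])
}

#' @rdname parse_topology
#' @param inputs,hidden,outputs Layer sizes.
#' @export
format_topology <- function(inputs, hidden, outputs = 1L) {
  sprintf("RBF %d:%d-%d-%d:%d", inputs, inputs, hidden, outputs, outputs)
}

# Gaussian activations of scaled inputs xs (n x p) for given centers/widths
rbf_activations <- function(xs, centers, widths) {
  n <- nrow(xs)
  H <- nrow(centers)
  phi <- matrix(0, n, H)
  for (j in seq_len(H)) {
    d2 <- rowSums(sweep(xs, 2, centers[j, ], "-")^2)
    phi[, j] <- exp(-d2 / (2 * widths[j]^2))
  }
  phi
}

# choose H centers on scaled training inputs: seeded k-means with a
# fallback to sampling distinct training points
choose_centers <- function(xs, H, seed) {
  ux <- unique(xs)
  if (H > nrow(xs))
    stop("H (", H, ") exceeds the number of training cases (", nrow(xs),
         ")", call. = FALSE)
  with_seed(seed, {
    if (H >= nrow(ux)) {
      ux[sample(nrow(ux), min(H, nrow(ux))), , drop = FALSE]
    } else {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(xs, centers = H, nstart = 2,
                                       iter.max = 50)),
        error = function(e) NULL)
      if (is.null(km)) ux[sample(nrow(ux), H), , drop = FALSE]
      else km$centers
    }
  })
}

# unit widths: nearest-other-center spacing (max spread of the data for a
# single unit) times the spread factor
choose_widths <- function(centers, xs, spread) {
  H <- nrow(centers)
  if (H == 1L) {
    d <- sqrt(rowSums(sweep(xs, 2, centers[1, ], "-")^2))
    base <- max(d, 1)
  } else {
    dm <- as.matrix(stats::dist(centers))
    diag(dm) <- Inf
    base <- apply(dm, 1, min)
  }
  pmax(base, 1e-8) * spread
}

# solve the output layer: A = [phi, 1]; ridge penalises the H unit
# weights, never the bias.  ridge = 0 takes a minimum-norm SVD
# least-squares path so exact interpolation (H = n_train) is possible.
solve_output_weights <- function(phi, ys, ridge) {
  H <- ncol(phi)
  A <- cbind(phi, 1)
  if (ridge > 0) {
    M <- crossprod(A) + ridge * diag(c(rep(1, H), 0))
    w <- tryCatch(solve(M, crossprod(A, ys)),
                  error = function(e)
                    stop("singular output-layer system; increase `ridge`",
                         call. = FALSE))
    return(drop(w))
  }
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  if (!any(keep))
    stop("degenerate hidden-layer activations; use ridge > 0",
         call. = FALSE)
  drop(sv$v[, keep, drop = FALSE] %*%
         (crossprod(sv$u[, keep, drop = FALSE], ys) / sv$d[keep]))
}

#' Fit an RBF regression network
#'
#' Single hidden layer of Gaussian radial units with a linear output
#' neuron.  Inputs and the target are min-max scaled to \[0, 1\] using
#' bounds fitted on the supplied (training) data.  Hidden-unit centers
#' are chosen by seeded k-means on the scaled inputs (falling back to
#' sampling distinct training points when k-means degenerates); each
#' unit's width is its nearest-other-center distance times `spread`.
#' Output weights and bias solve the ridge-regularised least-squares
#' problem mapping hidden activations to scaled targets.  Deterministic
#' for a fixed seed.
#'
#' @param x Numeric feature matrix (training cases x inputs, named
#'   columns).
#' @param y Target age in months.
#' @param H Number of hidden units (1 <= H <= nrow(x)).
#' @param seed Integer seed for center selection.
#' @param ridge Ridge penalty on unit weights (default `1e-8`; `0`
#'   requests exact least squares, enabling interpolation when
#'   `H = nrow(x)`).
#' @param spread Width multiplier on nearest-center spacing (default 2).
#' @return Object of class `rbf_model`.
#' @export
fit_rbf <- function(x, y, H, seed = 1L, ridge = 1e-8, spread = 2) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    stop("feature matrix must have column names", call. = FALSE)
  stopifnot(length(y) == nrow(x))
  if (anyNA(x) || anyNA(y))
    stop("features and targets must be complete", call. = FALSE)
  H <- as.integer(H)
  if (H < 1L) stop("H must be >= 1", call. = FALSE)
  if (H > nrow(x))
    stop("H (", H, ") exceeds the number of training cases (", nrow(x),
         ")", call. = FALSE)
  if (ridge < 0) stop("ridge must be >= 0", call. = FALSE)

  scale <- fit_scale_params(x, y)
  xs <- scale_inputs(x, scale)
  ys <- minimax_scale(y, scale$ymin, scale$ymax)

  centers <- choose_centers(xs, H, seed)
  dimnames(centers) <- list(NULL, colnames(x))
  widths <- unname(choose_widths(centers, xs, spread))
  phi <- rbf_activations(xs, centers, widths)
  weights <- solve_output_weights(phi, ys, ridge)

  structure(list(
    input_names = colnames(x),
    centers = centers,
    widths = widths,
    weights = unname(weights),       # H unit weights then bias
    scale = scale,
    input_means = colMeans(x),       # training means, raw units
    topology = format_topology(ncol(x), H),
    seed = as.integer(seed),
    ridge = ridge,
    spread = spread),
    class = "rbf_model")
}

#' @export
print.rbf_model <- function(x, ...) {
  cat("<rbf_model>", x$topology, "- inputs:",
      paste(utils::head(x$input_names, 5), collapse = ", "),
      if (length(x$input_names) > 5) "..." else "", "\n")
  invisible(x)
}

#' Predict age in months
#'
#' Evaluates the network on new cases and inverse-scales the linear
#' output back to months.  No clamping is applied by default; `clamp`
#' limits predictions to the 48-144 month validity window.
#'
#' @param object A fitted `rbf_model`.
#' @param newdata Numeric matrix or data.frame containing (at least) the
#'   model's input columns, or a `feature_set`.
#' @param clamp Clamp predictions to \[48, 144\] months.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (months).
#' @export
predict.rbf_model <- function(object, newdata, clamp = FALSE, ...) {
  if (inherits(newdata, "feature_set")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$input_names, colnames(newdata))
  if (length(missing))
    stop("missing model input(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- newdata[, object$input_names, drop = FALSE]
  if (anyNA(x)) stop("features must be complete", call. = FALSE)
  xs <- scale_inputs(x, object$scale)
  phi <- rbf_activations(xs, object$centers, object$widths)
  H <- length(object$widths)
  ys <- drop(phi %*% object$weights[seq_len(H)]) + object$weights[H + 1L]
  out <- minimax_unscale(ys, object$scale$ymin, object$scale$ymax)
  if (clamp) out <- pmin(pmax(out, AGE_MIN_MONTHS), AGE_MAX_MONTHS)
  unname(out)
}

#' Model quality on a partition
#'
#' Quality is the Pearson linear correlation between predicted and
#' observed age: a scale-free agreement measure in \[-1, 1\], with values
#' approaching 1 indicating a better network.
#'
#' @param predictions,targets Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
quality <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets))
  if (length(targets) < 2L)
    stop("quality needs at least 2 cases", call. = FALSE)
  if (stats::sd(targets) == 0 || stats::sd(predictions) == 0)
    stop("quality undefined: zero variance in predictions or targets",
         call. = FALSE)
  stats::cor(predictions, targets)
}

#' Scaled root-mean-square error
#'
#' RMSE between predictions and targets after min-max scaling both with
#' the model's output bounds, i.e. the error expressed as a fraction of
#' the training age range (an error of 0.036 on a 96-month range is
#' about 3.5 months).
#'
#' @param model A fitted `rbf_model`.
#' @param x Feature matrix (or `feature_set`).
#' @param y Observed ages in months.
#' @return Non-negative scalar.
#' @export
rmse_scaled <- function(model, x, y) {
  if (inherits(x, "feature_set")) { y <- x$y; x <- x$x }
  if (length(y) == 0L) stop("empty case set", call. = FALSE)
  pred <- predict(model, x)
  ps <- minimax_scale(pred, model$scale$ymin, model$scale$ymax)
  ys <- minimax_scale(y, model$scale$ymin, model$scale$ymax)
  sqrt(mean((ps - ys)^2))
}

#' Automatic designer: seeded candidate search
#'
#' Emulates an automatic network designer: trains `n_test` candidate
#' networks with hidden counts drawn (seeded) from `H_candidates` and
#' per-candidate center seeds, ranks them by validation RMSE, and retains
#' up to `n_retain`, balancing error against architectural diversity: at
#' most `ceiling(n_retain / 2)` retained networks may share one hidden
#' count.  The default protocol tests 20 candidates and keeps the top 10.
#'
#' @param features A `feature_set` covering the whole cohort.
#' @param split A `data_split` of the cohort's case ids.
#' @param H_candidates Integer vector of hidden counts to draw from.
#' @param n_test Number of candidates to train (default 20).
#' @param n_retain Maximum number to retain (default 10).
#' @param seed Integer seed driving the whole search.
#' @param ridge,spread Passed to [fit_rbf()].
#' @return List of retained candidates, each a list `model`,
#'   `valid_rmse`, `H`, sorted by validation RMSE (best first).
#' @export
designer_search <- function(features, split, H_candidates,
                            n_test = 20L, n_retain = 10L, seed = 1L,
                            ridge = 1e-8, spread = 2) {
  if (!length(H_candidates))
    stop("H_candidates must be non-empty", call. = FALSE)
  if (n_retain < 1L || n_test < n_retain)
    stop("need n_test >= n_retain >= 1", call. = FALSE)
  tr <- feature_rows(features, split$train)
  va <- feature_rows(features, split$valid)
  H_candidates <- pmin(as.integer(H_candidates), nrow(tr$x))
  draws <- with_seed(seed, list(
    H = sample(rep(H_candidates, length.out = n_test)),
    seeds = sample.int(.Machine$integer.max - 1L, n_test)))
  cands <- lapply(seq_len(n_test), function(i) {
    m <- fit_rbf(tr$x, tr$y, H = draws$H[i], seed = draws$seeds[i],
                 ridge = ridge, spread = spread)
    list(model = m, valid_rmse = rmse_scaled(m, va$x, va$y),
         H = draws$H[i])
  })
  ord <- order(vapply(cands, `[[`, numeric(1), "valid_rmse"))
  cap <- ceiling(n_retain / 2)
  kept <- list()
  used <- integer(0)
  for (i in ord) {
    h <- cands[[i]]$H
    if (sum(used == h) >= cap) next
    kept <- c(kept, cands[i])
    used <- c(used, h)
    if (length(kept) == n_retain) break
  }
  kept
}

#' Six-number model report
#'
#' Quality (correlation) and scaled RMSE on the training, validation,
#' and testing partitions — the standard characteristics table of a
#' fitted network.
#'
#' @param model A fitted `rbf_model`.
#' @param features A `feature_set` covering the cohort.
#' @param split A `data_split`.
#' @return Data.frame with columns `metric`, `value` (six rows:
#'   training/validation/testing quality, then errors).
#' @export
model_report <- function(model, features, split) {
  parts <- list(training = split$train, validation = split$valid,
                testing = split$test)
  qs <- es <- setNames(numeric(3), names(parts))
  for (p in names(parts)) {
    fr <- feature_rows(features, parts[[p]])
    qs[p] <- quality(predict(model, fr$x), fr$y)
    es[p] <- rmse_scaled(model, fr$x, fr$y)
  }
  data.frame(
    metric = c(paste(names(parts), "quality"), paste(names(parts), "error")),
    value = c(qs, es),
    row.names = NULL)
}

RBF_SCHEMA_VERSION <- 1L

#' Save / load a fitted model as JSON
#'
#' The JSON document carries every model field at full precision and a
#' schema version; a reloaded model predicts identically (to 1e-12) and
#' two saves of one model are byte-identical.
#'
#' @param model A fitted `rbf_model`.
#' @param path File path.
#' @return `save_rbf`: `path` invisibly; `load_rbf`: the `rbf_model`.
#' @export
save_rbf <- function(model, path) {
  stopifnot(inherits(model, "rbf_model"))
  doc <- list(
    schema = "dentage-rbf",
    schema_version = RBF_SCHEMA_VERSION,
    topology = model$topology,
    input_names = model$input_names,
    centers = unname(model$centers),
    widths = model$widths,
    weights = model$weights,
    scale = model$scale,
    input_means = as.list(model$input_means),
    seed = model$seed,
    ridge = model$ridge,
    spread = model$spread)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_rbf
#' @export
load_rbf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  if (!identical(doc$schema, "dentage-rbf") ||
      !identical(as.integer(doc$schema_version), RBF_SCHEMA_VERSION))
    stop("unrecognised model file schema/version", call. = FALSE)
  need <- c("input_names", "centers", "widths", "weights", "scale",
            "input_means", "topology")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  centers <- matrix(as.numeric(doc$centers), ncol = length(doc$input_names),
                    dimnames = list(NULL, doc$input_names))
  structure(list(
    input_names = as.character(doc$input_names),
    centers = centers,
    widths = as.numeric(doc$widths),
    weights = as.numeric(doc$weights),
    scale = lapply(doc$scale, function(v)
      if (length(names(v))) unlist(v) else as.numeric(v)),
    input_means = unlist(doc$input_means),
    topology = as.character(doc$topology),
    seed = as.integer(doc$seed),
    ridge = as.numeric(doc$ridge),
    spread = as.numeric(doc$spread)),
    class = "rbf_model")
}
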