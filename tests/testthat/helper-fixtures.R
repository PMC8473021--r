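# shared fixtures, all generated in code

# hand-placed cross-arch fixture: |C13C43| = 40, |C15C45| = 20,
# |C16C46| = 25, |C17C47| = 50
arch_fixture <- function() {
  pts <- rbind(C13 = c(0, 0), C43 = c(0, 40),
               C15 = c(10, 0), C45 = c(10, 20),
               C16 = c(20, 0), C46 = c(20, 25),
               C17 = c(30, 0), C47 = c(30, 50))
  landmark_set("arch", "F", 96, pts)
}

# a small consistent cohort for model tests
small_cohort <- function(n_f = 40, n_m = 40, seed = 7, noise = 0.05) {
  generate_cohort(cohort_params(n_female = n_f, n_male = n_m,
                                seed = seed, noise = noise))
}

# one complete landmark set realizing a generated indicator vector
complete_case <- function(seed = 11) {
  co <- generate_cohort(cohort_params(n_female = 1, n_male = 0, seed = seed))
  generate_landmarks(unlist(co[1, indicator_names()]),
                     case_id = sprintf("syn%03d", seed), sex = co$sex[1],
                     age_months = co$age_months[1])
}

# tiny regression problem with named columns
tiny_features <- function(n = 8, p = 3, seed = 5) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("c%02d", seq_len(n)),
                              sprintf("V%d", seq_len(p))))
  y <- 60 + 50 * x[, 1] + rnorm(n, 0, 0.5)
  list(x = x, y = y)
}

# independently recompute Gaussian activations from a fitted model
oracle_activations <- function(model, x) {
  xs <- sweep(sweep(x[, model$input_names, drop = FALSE], 2,
                    model$scale$xmin, "-"),
              2, model$scale$xmax - model$scale$xmin, "/")
  H <- length(model$widths)
  phi <- matrix(0, nrow(xs), H)
  for (i in seq_len(nrow(xs)))
    for (j in seq_len(H))
      phi[i, j] <- exp(-sum((xs[i, ] - model$centers[j, ])^2) /
                         (2 * model$widths[j]^2))
  phi
}
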