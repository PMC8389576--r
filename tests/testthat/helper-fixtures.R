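# Shared fixtures, all generated in code.

# noise-free single-plant parameter set used by recovery tests
nf_params <- function(n_per_cell = 1) {
  default_sim_params(n_per_cell = n_per_cell, seed = 7, noise_cv = 0)
}

cell_2x10 <- list(cytotype = "2x", photoperiod_h = 10)

# random, internally consistent KC landmark set (F0' consistent via the
# package estimator is not required for pure ratio-invariance checks)
rand_kc_landmark_values <- function(seed) {
  set.seed(seed)
  F0 <- runif(1, 200, 800)
  FM <- F0 * runif(1, 2.5, 6)
  FMp <- runif(1, F0 * 1.3, FM)
  FMpp <- runif(1, FMp, FM)
  F0p <- pamkit::f0_prime(F0, FM, FMp)
  Ft <- runif(1, F0p * 1.01, FMp * 0.99)
  list(F0 = F0, FM = FM, FMp = FMp, FMpp = FMpp, Ft = Ft, F0p = F0p)
}

# long coefficient table with one value per plant drawn from per-cell
# normal distributions; `shift` adds an offset (in SD units) to chosen cells
make_norm_table <- function(seed, n_per_cell = 8, sd = 1, mean = 10,
                            shift_cells = character(), shift_sd = 0,
                            coefficient = "phi_max") {
  set.seed(seed)
  design <- make_design(n_per_cell, seed)
  key <- paste(design$cytotype, design$photoperiod_h, sep = ":")
  mu <- rep(mean, nrow(design))
  mu[key %in% shift_cells] <- mean + shift_sd * sd
  coefficient_table(tibble::tibble(
    plant_id = design$plant_id,
    cytotype = design$cytotype,
    photoperiod_h = design$photoperiod_h,
    coefficient = coefficient,
    value = stats::rnorm(nrow(design), mu, sd)
  ))
}

# letters consistency: groups share a letter iff not significantly different
letters_consistent <- function(letters_map, sig_matrix) {
  groups <- rownames(sig_matrix)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i >= j) next
      share <- length(intersect(
        strsplit(letters_map[[groups[i]]], "")[[1]],
        strsplit(letters_map[[groups[j]]], "")[[1]])) > 0
      if (share == sig_matrix[i, j]) return(FALSE)
    }
  }
  TRUE
}

# canonical (alphabetical) group order so matrices from different methods
# can be compared elementwise
posthoc_sig_matrix <- function(ph) {
  groups <- sort(ph$groups$group)
  m <- matrix(FALSE, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (r in seq_len(nrow(ph$comparisons))) {
    a <- ph$comparisons$group_a[r]; b <- ph$comparisons$group_b[r]
    m[a, b] <- m[b, a] <- m[a, b] | ph$comparisons$significant[r]
  }
  m
}
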