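# Shared helpers: all fixtures are generated in code at test time.

# Small, fast phantom cohort kept in memory.
tiny_phantom_config <- function(n_patients = 6, noise_sd = 0, seed = 7, ...) {
  phantom_config(
    n_patients = n_patients,
    mvi_fraction = 0.5,
    volume_shape = c(48L, 48L, 48L),
    tumor_radius_range = c(7, 10),
    noise_sd = noise_sd,
    seed = seed,
    ...
  )
}

# Brute-force AUC: concordant-pair fraction with 1/2 credit for ties.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# A random z-scored 16^3 cube.
random_cube <- function(seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(4096), c(16, 16, 16)))
}

# Named list of random cubes for the given phases.
random_cubes <- function(phases, seed = 1) {
  out <- lapply(seq_along(phases), function(i) random_cube(seed + i))
  names(out) <- phases
  out
}
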