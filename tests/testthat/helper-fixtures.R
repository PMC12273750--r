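## Small fixtures shared across tests; everything is generated in code.

desk_config <- function(n = 12L, seed = 1L, ...) {
  cohort_config(n_patients = n, cube_shape = c(16L, 16L, 40L),
                sites = "palm", seed = seed, ...)
}

tiny_state <- function(...) {
  args <- utils::modifyList(
    list(oxy_fraction = 0.72, thb = 1, water_fraction = 0.55), list(...))
  do.call(chromophore_state, args)
}

random_cube <- function(H = 6L, W = 6L, B = 10L, seed = 1L) {
  set.seed(seed)
  hsi_cube(array(runif(H * W * B, 0.05, 0.95), c(H, W, B)),
           wavelength_grid(B), "palm", "TEST")
}

## brute-force AUROC by exhaustive pairwise comparison
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
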