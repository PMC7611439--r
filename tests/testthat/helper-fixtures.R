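# Shared fixtures, built once per test run.  Everything is generated in
# code; no binary fixtures on disk.

fix_lib <- make_part_library(4, 64, seed = 11)
fix_set <- compose_two_part_objects(fix_lib)

# one symmetric (AA) and one asymmetric (AB) object
fix_aa <- fix_set$images[[which(fix_set$meta$left_part == 1 &
                                fix_set$meta$right_part == 1)]]
fix_ab <- fix_set$images[[which(fix_set$meta$left_part == 1 &
                                fix_set$meta$right_part == 2)]]

# centered disk, soft enough for oblique-axis interpolation checks
make_disk <- function(n = 64, radius = n / 3) {
  c0 <- (n + 1) / 2
  r <- outer(seq_len(n), seq_len(n),
             function(i, j) sqrt((i - c0)^2 + (j - c0)^2))
  pmin(pmax(radius + 0.5 - r, 0), 1)
}

# random feature table + simulated pair table over a stimulus set
make_sim_world <- function(set, d = 6, beta_sym = 0, beta_area = 0,
                           noise_sd = 0, seed = 5,
                           weights = seq(d, 1) / d) {
  set.seed(seed)
  x <- feature_table(matrix(rnorm(length(set$images) * d), ncol = d),
                     set$meta$image_id)
  model <- dissim_model(weights = weights, beta_sym = beta_sym,
                        beta_area = beta_area, noise_sd = noise_sd,
                        floor = 1e-6, seed = seed + 1)
  list(features = x, model = model,
       pairs = simulate_dissimilarities(set, x, model))
}

flatten_set <- function(set) {
  t(vapply(set$images, as.numeric, numeric(length(set$images[[1]]))))
}
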