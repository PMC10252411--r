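# Balanced-effect latent dryness equation on the five routine-assay
# variables: each coefficient is scaled so its standardized effect (slope *
# predictor SD) is `effect` scale units, with the intercept centering the
# latent scores at 4 on the 0-8 scale. Reference moments come from one large
# seeded draw of the default chemistry population.
balanced_equation <- function(effect = 0.7) {
  vars <- dryness_model_variables("model3")
  ref <- generate_chemistry(synthetic_config(n_samples = 3000, seed = 101))
  sds <- vapply(ref[vars], stats::sd, numeric(1))
  mns <- vapply(ref[vars], mean, numeric(1))
  co <- effect / sds
  dryness_equation(4 - sum(co * mns), co)
}

# random full-rank regression problem for PLS-vs-OLS oracle checks
random_regression <- function(seed, n_max = 20, p_max = 6) {
  set.seed(seed)
  n <- sample(8:n_max, 1)
  p <- sample(2:min(p_max, n - 2), 1)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  beta <- rnorm(p, sd = 2)
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, n = n, p = p)
}
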