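#' Configuration for the synthetic cider-chemistry generator
#'
#' Describes a simulated population of ciders: per-variable marginal
#' distributions, rank-correlation targets between chemically linked pairs,
#' a latent linear dryness equation, and the panel noise added on top of it.
#' The defaults emulate the packaged calibration-set summaries (see
#' `load_fixture("table3_calibration")`): right-skewed concentrations get a
#' log-normal marginal truncated hard at the observed min/max, its parameters
#' solved so that the truncated distribution's median and upper quartile hit
#' the summary values (residual sugar: median ~362 mg/100 mL, Q3 ~1739);
#' malic acid and titratable acidity
#' get triangular marginals (min, median as mode, max); pH is uniform over
#' the observed 3.26-3.99 range. Tannins have no published summary and
#' default to uniform on 0-5000 mg/L, the span of the tannin-correction
#' narrative — treat that marginal as unanchored. Dependence is induced by a
#' Gaussian copula on three pairs with an obvious chemical basis:
#' polyphenols with abs 280 nm, hydroxycinnamic acids with abs 320 nm, and
#' malic acid with titratable acidity.
#'
#' @param n_samples number of ciders to simulate (at least 4).
#' @param seed integer seed; the whole pipeline is reproducible from it
#'   (panel noise uses `seed + 1` so chemistry and noise come from
#'   independent streams).
#' @param marginals named list of marginal specs, each a list with `family`
#'   (`"lognormal"`, `"triangular"`, `"uniform"`) and its parameters
#'   (`median`/`q3`/`min`/`max` for lognormal, `min`/`mode`/`max` for
#'   triangular, `min`/`max` for uniform). Defaults as above.
#' @param correlation data frame with columns `var1`, `var2`, `rho`
#'   (Spearman rank-correlation targets, strictly inside (-1, 1)).
#' @param true_equation the latent [dryness_equation()] generating sensory
#'   scores; defaults to [cider_dryness_equation()].
#' @param panel_noise_sd SD of the Gaussian panel noise, 0-8 scale units.
#' @return object of class `"synthetic_config"`.
#' @examples
#' cfg <- synthetic_config(n_samples = 50, seed = 42)
#' chem <- generate_chemistry(cfg)
#' scores <- generate_panel_scores(chem, cfg)
#' @export
synthetic_config <- function(n_samples = 76, seed = 1, marginals = NULL,
                             correlation = NULL,
                             true_equation = cider_dryness_equation(),
                             panel_noise_sd = 0.5) {
  stopifnot(n_samples >= 4, is.numeric(seed), length(seed) == 1,
            inherits(true_equation, "dryness_equation"),
            panel_noise_sd >= 0)
  if (is.null(marginals)) marginals <- default_marginals()
  if (is.null(correlation)) correlation <- default_correlation()
  stopifnot(is.data.frame(correlation),
            all(c("var1", "var2", "rho") %in% names(correlation)))
  if (any(abs(correlation$rho) >= 1))
    stop("correlation targets must lie strictly inside (-1, 1)",
         call. = FALSE)
  for (v in names(marginals)) check_marginal(marginals[[v]], v)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 marginals = marginals, correlation = correlation,
                 true_equation = true_equation,
                 panel_noise_sd = panel_noise_sd),
            class = "synthetic_config")
}

default_marginals <- function() {
  s <- load_fixture("table3_calibration")
  rownames(s) <- s$variable
  ln <- function(v) list(family = "lognormal", median = s[v, "median"],
                         q3 = s[v, "q3"], min = s[v, "min"], max = s[v, "max"])
  tri <- function(v) list(family = "triangular", min = s[v, "min"],
                          mode = s[v, "median"], max = s[v, "max"])
  list(
    alcohol = ln("alcohol"),
    ph = list(family = "uniform", min = 3.26, max = 3.99),
    malic_acid = tri("malic_acid"),
    titratable_acidity = tri("titratable_acidity"),
    residual_sugar = ln("residual_sugar"),
    polyphenols = ln("polyphenols"),
    hydroxybenzoic = ln("hydroxybenzoic"),
    hydroxycinnamic = ln("hydroxycinnamic"),
    abs280 = ln("abs280"),
    abs320 = ln("abs320"),
    tannins = list(family = "uniform", min = 0, max = 5000)
  )
}

default_correlation <- function() {
  data.frame(
    var1 = c("polyphenols", "hydroxycinnamic", "malic_acid"),
    var2 = c("abs280", "abs320", "titratable_acidity"),
    rho = c(0.8, 0.7, 0.7)
  )
}

check_marginal <- function(m, v) {
  fam <- m$family
  ok <- switch(fam,
    lognormal = m$median > 0 && m$q3 >= m$median && m$min >= 0 &&
                m$max >= m$min,
    triangular = m$min <= m$mode && m$mode <= m$max,
    uniform = m$min <= m$max,
    FALSE)
  if (!isTRUE(ok))
    stop("infeasible marginal parameters for variable ", v, call. = FALSE)
  invisible(m)
}

# quantile transform of u in [0,1] under a marginal spec
q_marginal <- function(m, u) {
  switch(m$family,
    uniform = m$min + u * (m$max - m$min),
    triangular = {
      a <- m$min; cc <- m$mode; b <- m$max
      if (b == a) return(rep(a, length(u)))
      fc <- (cc - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (cc - a)),
             b - sqrt((1 - u) * (b - a) * (b - cc)))
    },
    lognormal = {
      if (m$q3 == m$median || m$min == m$max) return(rep(m$median, length(u)))
      par <- fit_truncated_lognormal(m$median, m$q3, m$min, m$max)
      plo <- stats::plnorm(max(m$min, 1e-12), par[1], par[2])
      phi <- stats::plnorm(m$max, par[1], par[2])
      stats::qlnorm(plo + u * (phi - plo), par[1], par[2])
    },
    stop("unknown marginal family: ", m$family, call. = FALSE))
}

# choose (meanlog, sdlog) so that the [lo, hi]-truncated log-normal hits the
# target median and upper quartile; truncation otherwise drags both down
fit_truncated_lognormal <- function(med, q3, lo, hi) {
  obj <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    plo <- stats::plnorm(max(lo, 1e-12), mu, s)
    phi <- stats::plnorm(hi, mu, s)
    if (phi - plo < 1e-6) return(1e6)
    m_hat <- stats::qlnorm(plo + 0.50 * (phi - plo), mu, s)
    q_hat <- stats::qlnorm(plo + 0.75 * (phi - plo), mu, s)
    log(m_hat / med)^2 + log(q_hat / q3)^2
  }
  start <- c(log(med), log(log(q3 / med) / stats::qnorm(0.75)))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(fit$par[1], exp(fit$par[2]))
}

#' Simulate a cider chemistry table
#'
#' Draws `config$n_samples` ciders from the configured marginals under a
#' Gaussian copula hitting the configured rank-correlation targets. All
#' values respect the marginal min/max bounds by construction (hard
#' truncation of the quantile transform). Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return chemistry data frame (columns `sample_id` + [chemistry_units()]
#'   variables) accepted by every reader/scorer in the package.
#' @export
generate_chemistry <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vars <- names(config$marginals)
  p <- length(vars)
  n <- config$n_samples
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  for (k in seq_len(nrow(config$correlation))) {
    v1 <- config$correlation$var1[k]; v2 <- config$correlation$var2[k]
    if (!(v1 %in% vars) || !(v2 %in% vars))
      stop("correlation target names unknown variable: ", v1, "/", v2,
           call. = FALSE)
    # Spearman target -> Pearson correlation of the latent Gaussians
    r <- 2 * sin(pi * config$correlation$rho[k] / 6)
    R[v1, v2] <- R[v2, v1] <- r
  }
  U <- tryCatch(chol(R),
                error = function(e) stop("correlation targets are not ",
                                         "jointly feasible", call. = FALSE))
  Z <- with_seed(config$seed, matrix(stats::rnorm(n * p), n, p) %*% U)
  Un <- stats::pnorm(Z)
  out <- data.frame(sample_id = sprintf("SYN%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) out[[vars[j]]] <- q_marginal(config$marginals[[j]], Un[, j])
  validate_chemistry(out)
  out
}

#' Simulate panel dryness scores for a chemistry table
#'
#' Evaluates the configured latent dryness equation on each sample, adds
#' homoscedastic Gaussian panel noise (SD `config$panel_noise_sd`,
#' emulating the averaged judgment of a trained panel) and clips to the 0-8
#' sensory scale. With zero noise the scores are exactly the equation values
#' (clipped), so category conversions of scores and of equation predictions
#' agree sample by sample.
#'
#' @param chemistry a chemistry data frame providing every variable of
#'   `config$true_equation`.
#' @param config a [synthetic_config()].
#' @return numeric vector of sensory scores in `[0, 8]`.
#' @export
generate_panel_scores <- function(chemistry, config) {
  stopifnot(inherits(config, "synthetic_config"))
  latent <- predict_dryness(config$true_equation, chemistry, clip = FALSE)
  noise <- if (config$panel_noise_sd > 0)
    with_seed(config$seed + 1L,
              stats::rnorm(length(latent), 0, config$panel_noise_sd))
  else 0
  pmin(pmax(latent + noise, 0), 8)
}

#' Inject gross outliers into a chemistry table
#'
#' Displaces chosen samples along the first principal direction of the
#' autoscaled chemistry by a stated number of score standard deviations —
#' the canonical way to plant a multivariate outlier that a Hotelling
#' T-squared screen on PLS scores should flag. Displaced concentrations are
#' floored at zero and pH kept inside (0, 14) so the table stays valid.
#'
#' @param chemistry chemistry data frame.
#' @param n_outliers how many samples to displace (0 returns the table
#'   unchanged).
#' @param displacement shift along the first principal direction, in units
#'   of the PC1 score SD. Must be positive.
#' @param seed integer seed choosing which samples are displaced.
#' @return the chemistry table with displaced rows and attribute
#'   `"outlier_ids"` listing the affected sample ids.
#' @export
inject_outliers <- function(chemistry, n_outliers, displacement = 10,
                            seed = 1) {
  stopifnot(is.data.frame(chemistry))
  n <- nrow(chemistry)
  if (n_outliers == 0) {
    attr(chemistry, "outlier_ids") <- character(0)
    return(chemistry)
  }
  if (displacement <= 0) stop("displacement must be positive", call. = FALSE)
  if (n_outliers > n)
    stop("more outliers requested than samples", call. = FALSE)
  vars <- intersect(chemistry_vars(), names(chemistry))
  vars <- vars[vapply(vars, function(v) !anyNA(chemistry[[v]]) &&
                        stats::sd(chemistry[[v]]) > 0, logical(1))]
  M <- as.matrix(chemistry[, vars])
  ctr <- colMeans(M); scl <- apply(M, 2, stats::sd)
  A <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(A, center = FALSE, scale. = FALSE)
  v1 <- pc$rotation[, 1]
  shift <- displacement * pc$sdev[1]
  idx <- with_seed(seed, sample(n, n_outliers))
  A[idx, ] <- A[idx, , drop = FALSE] +
    matrix(shift * v1, n_outliers, length(v1), byrow = TRUE)
  M2 <- sweep(sweep(A, 2, scl, "*"), 2, ctr, "+")
  for (j in seq_along(vars)) {
    v <- vars[j]
    chemistry[[v]] <- M2[, j]
    if (v == "ph") chemistry[[v]] <- pmin(pmax(chemistry[[v]], 0.01), 13.99)
    else chemistry[[v]] <- pmax(chemistry[[v]], 0)
  }
  attr(chemistry, "outlier_ids") <- chemistry$sample_id[idx]
  chemistry
}
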