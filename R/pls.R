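#' Fit a single-response PLS regression by NIPALS
#'
#' From-scratch PLS1 calibration as used throughout chemometrics: latent
#' factors are extracted by the NIPALS algorithm, each factor maximizing
#' covariance between the (centered, optionally autoscaled) predictor block
#' and the centered response, with rank-one deflation of X between factors.
#' Autoscaling (unit-variance predictors) is the default because the
#' chemistry variables live on wildly different unit scales (mg/100 mL of
#' sugar vs absorbance units); the coefficients in autoscaled space
#' (`b_weighted`, the "Bw" of chemometrics software) are then directly
#' comparable across variables, while `b_raw` and `intercept` express the
#' same model on the original measurement scales.
#'
#' Factor extraction stops with an error if more factors are requested than
#' the predictor block supports (residual X Frobenius norm below `1e-12` of
#' the original): rank deficiency is reported, never silently truncated.
#'
#' @param X numeric matrix or data frame of predictors, samples in rows.
#' @param y numeric response vector, one value per row of `X`.
#' @param n_factors number of latent factors to extract, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param autoscale scale predictor columns to unit variance? (centering is
#'   always applied; `y` is centered, never scaled).
#' @return an object of class `"pls1_fit"`: a list with centering/scaling
#'   vectors (`x_means`, `x_scales`, `y_mean`), NIPALS vectors (`w_weights`,
#'   `p_loadings`, `q_loadings`, `t_scores`), coefficients (`b_weighted`,
#'   `b_raw`, `intercept`, and `b_weighted_by_factor` for truncated-factor
#'   prediction), per-factor explained variance percentages
#'   (`explained_variance_x`, `explained_variance_y`), `fitted`, `residuals`
#'   and calibration metrics (`r2`, `rmsec`, `sec`).
#' @seealso [cross_validate()], [jackknife_uncertainty()], [hotelling_t2()],
#'   [make_equation()]
#' @examples
#' x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 2 * x[, 1] - x[, 3] + rnorm(20, sd = 0.1)
#' fit <- fit_pls1(x, y, n_factors = 3)
#' fit$r2
#' @export
fit_pls1 <- function(X, y, n_factors, autoscale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (n_factors < 1 || n_factors > min(n - 1, p))
    stop("n_factors must lie in [1, min(n - 1, p)] = [1, ",
         min(n - 1, p), "]", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)

  x_means <- colMeans(X)
  x_scales <- if (autoscale) sds else rep(1, p)
  Xa <- sweep(sweep(X, 2, x_means), 2, x_scales, "/")
  y_mean <- mean(y)
  ya <- y - y_mean
  ssx0 <- sum(Xa^2)
  ssy0 <- sum(ya^2)

  W <- P <- matrix(0, p, n_factors, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  evx <- evy <- numeric(n_factors)

  for (a in seq_len(n_factors)) {
    if (sum(Xa^2) < 1e-12 * ssx0)
      stop("predictor block exhausted after ", a - 1,
           " factor(s); fewer factors must be requested", call. = FALSE)
    u <- ya
    w <- crossprod(Xa, u)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300)
      stop("response has no covariance left with X at factor ", a,
           call. = FALSE)
    w <- w / nw
    # inner NIPALS loop; with a single response it converges in one pass,
    # the guard protects against pathological inputs
    for (it in seq_len(500)) {
      tt <- drop(Xa %*% w)
      qq <- sum(u * tt) / sum(tt^2)
      u_new <- ya / qq
      w_new <- crossprod(Xa, u_new)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      if (delta < 1e-10) break
    }
    tt <- drop(Xa %*% w)
    tt2 <- sum(tt^2)
    pp <- crossprod(Xa, tt) / tt2
    qq <- sum(ya * tt) / tt2
    Xa <- Xa - tcrossprod(tt, pp)
    ya <- ya - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
    evx[a] <- 100 * tt2 * sum(pp^2) / ssx0
    evy[a] <- 100 * qq^2 * tt2 / ssy0
  }

  # coefficients for every truncated factor count (columns a = 1..A)
  Bw_by_factor <- matrix(0, p, n_factors, dimnames = list(colnames(X), NULL))
  for (a in seq_len(n_factors)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Bw_by_factor[, a] <- drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
  }
  b_weighted <- Bw_by_factor[, n_factors]
  b_raw <- b_weighted / x_scales
  intercept <- y_mean - sum(b_raw * x_means)

  fitted <- drop(X %*% b_raw) + intercept
  res <- y - fitted
  fit <- list(
    x_means = x_means, x_scales = x_scales, y_mean = y_mean,
    autoscale = autoscale, n_factors = n_factors,
    w_weights = W, p_loadings = P, q_loadings = q, t_scores = Tm,
    b_weighted = b_weighted, b_weighted_by_factor = Bw_by_factor,
    b_raw = b_raw, intercept = intercept,
    explained_variance_x = evx, explained_variance_y = evy,
    fitted = fitted, residuals = res,
    r2 = 1 - sum(res^2) / ssy0,
    rmsec = sqrt(mean(res^2)),
    sec = sqrt(sum((res - mean(res))^2) / (length(res) - 1)),
    X = X, y = y,
    variables = colnames(X)
  )
  class(fit) <- "pls1_fit"
  fit
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat("PLS1 calibration (NIPALS):", length(x$y), "samples,",
      length(x$variables), "variables,", x$n_factors, "factor(s)\n")
  cat(sprintf("  R2 = %.4f  RMSEC = %.4f  SEC = %.4f\n", x$r2, x$rmsec, x$sec))
  cat("  explained variance (X / y, %):\n")
  for (a in seq_len(x$n_factors))
    cat(sprintf("    Factor-%d: %5.1f / %5.1f\n", a,
                x$explained_variance_x[a], x$explained_variance_y[a]))
  invisible(x)
}

#' @export
predict.pls1_fit <- function(object, newdata, n_factors = object$n_factors, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$variables, drop = FALSE])
  storage.mode(X) <- "double"
  if (n_factors == object$n_factors) {
    braw <- object$b_raw
  } else {
    stopifnot(n_factors >= 1, n_factors <= object$n_factors)
    braw <- object$b_weighted_by_factor[, n_factors] / object$x_scales
  }
  intercept <- object$y_mean - sum(braw * object$x_means)
  drop(X %*% braw) + intercept
}

#' Per-factor explained variance of a PLS1 fit
#'
#' @param model a [fit_pls1()] fit.
#' @return data frame with per-factor percentages of the centered (and
#'   scaled, if autoscaled) X and y sums of squares captured by each factor,
#'   plus cumulative columns.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "pls1_fit"))
  data.frame(
    factor = seq_len(model$n_factors),
    x_variance = model$explained_variance_x,
    y_variance = model$explained_variance_y,
    x_cumulative = cumsum(model$explained_variance_x),
    y_cumulative = cumsum(model$explained_variance_y)
  )
}

#' Pick the number of factors from a cross-validation curve
#'
#' Returns the smallest factor count after which the cross-validated error
#' stops improving: the first `k` whose relative RMSECV improvement from `k`
#' to `k + 1` falls below `plateau_tol`, capped at the curve length.
#'
#' @param cv_curve numeric vector of RMSECV values, one per factor count.
#' @param plateau_tol minimum relative improvement still counted as progress.
#' @return integer factor count.
#' @examples
#' select_n_factors(c(1.0, 0.5, 0.499, 0.498))  # 2
#' @export
select_n_factors <- function(cv_curve, plateau_tol = 0.01) {
  stopifnot(length(cv_curve) >= 1, all(is.finite(cv_curve)))
  K <- length(cv_curve)
  for (k in seq_len(K - 1)) {
    impr <- if (cv_curve[k] > 0) (cv_curve[k] - cv_curve[k + 1]) / cv_curve[k] else 0
    if (impr < plateau_tol) return(k)
  }
  K
}

#' Segmented cross-validation of a PLS1 calibration
#'
#' Randomly partitions the samples into `n_segments` segments (seeded, so a
#' given seed always yields the same split), refits the model with each
#' segment held out and predicts it, and reports the cross-validated RMSE
#' together with the full-data calibration metrics. `rmsec` uses the `n`
#' denominator; `sec` is the bias-corrected residual standard deviation
#' (mean-corrected residuals, `n - 1` denominator), hence slightly larger.
#' Setting `n_segments = nrow(X)` gives leave-one-out validation.
#'
#' @inheritParams fit_pls1
#' @param n_segments number of random segments, between 2 and `nrow(X)`.
#' @param seed integer seed for the segment assignment.
#' @return object of class `"pls1_cv"`: list with `metrics` (r2, rmsec, sec,
#'   rmsecv), `rmsecv_curve` (RMSECV per factor count 1..`n_factors`),
#'   `segments` (assignment vector), `submodels` (one `pls1_fit` per
#'   segment), `predictions` (held-out predictions) and `full` (the
#'   full-data fit).
#' @examples
#' x <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] + rnorm(30, sd = 0.2)
#' cv <- cross_validate(x, y, n_factors = 2, n_segments = 5, seed = 7)
#' cv$metrics$rmsecv
#' @export
cross_validate <- function(X, y, n_factors, n_segments = 20, seed = 1,
                           autoscale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_segments < 2 || n_segments > n)
    stop("n_segments must lie in [2, nrow(X)]", call. = FALSE)
  full <- fit_pls1(X, y, n_factors, autoscale = autoscale)
  seg <- with_seed(seed, sample(rep_len(seq_len(n_segments), n)))
  preds <- matrix(NA_real_, n, n_factors)
  submodels <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    hold <- which(seg == s)
    m <- fit_pls1(X[-hold, , drop = FALSE], y[-hold], n_factors,
                  autoscale = autoscale)
    submodels[[s]] <- m
    for (a in seq_len(n_factors))
      preds[hold, a] <- predict(m, X[hold, , drop = FALSE], n_factors = a)
  }
  rmsecv_curve <- sqrt(colMeans((preds - y)^2))
  out <- list(
    metrics = list(r2 = full$r2, rmsec = full$rmsec, sec = full$sec,
                   rmsecv = rmsecv_curve[n_factors]),
    rmsecv_curve = rmsecv_curve,
    segments = seg,
    submodels = submodels,
    predictions = preds[, n_factors],
    full = full
  )
  class(out) <- "pls1_cv"
  out
}

#' @export
print.pls1_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "PLS1 cross-validation: %d segments\n  R2 = %.4f  RMSEC = %.4f  SEC = %.4f  RMSECV = %.4f\n",
    length(x$submodels), m$r2, m$rmsec, m$sec, m$rmsecv))
  invisible(x)
}

#' Jackknife uncertainty of PLS regression coefficients
#'
#' Martens-style jackknife over cross-validation segments: for each variable
#' the squared deviations of the segment-model coefficient (autoscaled Bw)
#' from the full-model coefficient are summed and scaled by `(M - 1) / M`
#' over `M` segments, giving a standard error; limits are
#' `point +/- t(1 - alpha/2, M - 1) * SE`. A variable whose interval
#' excludes zero is flagged significant — the screening used to select
#' predictive chemistry variables.
#'
#' @param full_model the full-data [fit_pls1()] fit.
#' @param submodels list of segment fits (from [cross_validate()]`$submodels`),
#'   all sharing `full_model`'s variable set.
#' @param alpha significance level (default 0.05 for 95% limits).
#' @return data frame of class `"pls_uncertainty"` with columns `variable`,
#'   `coefficient` (Bw), `se`, `lower`, `upper`, `significant`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
#' y <- x[, 1] + rnorm(50, sd = 0.3)
#' cv <- cross_validate(x, y, n_factors = 2, n_segments = 10, seed = 3)
#' jackknife_uncertainty(cv$full, cv$submodels)
#' @export
jackknife_uncertainty <- function(full_model, submodels, alpha = 0.05) {
  stopifnot(inherits(full_model, "pls1_fit"))
  M <- length(submodels)
  if (M < 2) stop("need at least 2 submodels", call. = FALSE)
  vars <- full_model$variables
  for (m in submodels)
    if (!identical(m$variables, vars))
      stop("all submodels must share the full model's variable set",
           call. = FALSE)
  B <- vapply(submodels, function(m) m$b_weighted, numeric(length(vars)))
  dev2 <- rowSums((B - full_model$b_weighted)^2)
  se <- sqrt((M - 1) / M * dev2)
  tq <- stats::qt(1 - alpha / 2, df = M - 1)
  lower <- full_model$b_weighted - tq * se
  upper <- full_model$b_weighted + tq * se
  out <- data.frame(
    variable = vars,
    coefficient = unname(full_model$b_weighted),
    se = unname(se),
    lower = unname(lower),
    upper = unname(upper),
    significant = unname(lower > 0 | upper < 0),
    row.names = NULL
  )
  class(out) <- c("pls_uncertainty", "data.frame")
  out
}

#' Hotelling T-squared outlier screen on PLS factor scores
#'
#' Computes each sample's squared Mahalanobis distance from the center of the
#' model's factor-score space, using the empirical score covariance, and
#' flags samples whose T-squared exceeds the F-distribution critical value
#' `k (n - 1) / (n - k) * F(1 - alpha; k, n - k)` with `k` factors and `n`
#' samples — the routine screen for calibration outliers.
#'
#' @param model a [fit_pls1()] fit.
#' @param alpha significance level.
#' @param ids optional sample identifiers (defaults to row numbers).
#' @return list of class `"hotelling_t2"`: `t2` (per-sample statistic),
#'   `critical` (the cutoff), `flagged` (ids with `t2 > critical`), `ids`.
#' @examples
#' x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] + rnorm(40, sd = 0.2)
#' hotelling_t2(fit_pls1(x, y, n_factors = 2))
#' @export
hotelling_t2 <- function(model, alpha = 0.05, ids = NULL) {
  stopifnot(inherits(model, "pls1_fit"))
  Tm <- model$t_scores
  n <- nrow(Tm); k <- ncol(Tm)
  if (n <= k) stop("need more samples than factors", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  S <- stats::cov(Tm)
  if (k == 1 && S[1, 1] == 0 || k > 1 && abs(det(S)) < 1e-300)
    stop("singular factor-score covariance", call. = FALSE)
  t2 <- stats::mahalanobis(Tm, colMeans(Tm), S)
  crit <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  out <- list(t2 = stats::setNames(t2, ids), critical = crit,
              flagged = ids[t2 > crit], ids = ids, alpha = alpha)
  class(out) <- "hotelling_t2"
  out
}

#' @export
print.hotelling_t2 <- function(x, ...) {
  cat(sprintf("Hotelling T2 screen: critical value %.3f (alpha = %g)\n",
              x$critical, x$alpha))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  else cat("  no samples flagged\n")
  invisible(x)
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
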