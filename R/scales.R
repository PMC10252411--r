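#' IRF sugar-to-acid dryness ratio
#'
#' The IRF marketable scale scores a cider's dryness as the ratio of residual
#' sugar to malic acid, the idea being that sourness suppresses the perception
#' of sweetness. When malic acid is essentially absent the ratio blows up even
#' though the sugar itself may be negligible; rather than erroring, the score
#' is computed against a floor of `eps` and flagged, so callers can detect the
#' degenerate regime (commercial ciders do ship with 0.001 g/L malic acid).
#'
#' @param residual_sugar residual sugar, g/L. Non-negative.
#' @param malic_acid malic acid, g/L. Non-negative.
#' @param eps stability floor for the denominator, g/L.
#' @return numeric score vector with a logical attribute `"unstable"`
#'   marking entries where `malic_acid < eps`; retrieve it with
#'   [irf_unstable()].
#' @seealso [categorize_scale_score()], [nyca_score()]
#' @examples
#' irf_ratio(2, 1)
#' irf_unstable(irf_ratio(1.78, 0.001))
#' @export
irf_ratio <- function(residual_sugar, malic_acid, eps = 1e-6) {
  stop_if_negative(residual_sugar, "residual_sugar")
  stop_if_negative(malic_acid, "malic_acid")
  n <- max(length(residual_sugar), length(malic_acid))
  rs <- rep_len(residual_sugar, n)
  ma <- rep_len(malic_acid, n)
  unstable <- ma < eps
  score <- rs / pmax(ma, eps)
  attr(score, "unstable") <- unstable
  score
}

#' @rdname irf_ratio
#' @param score a score returned by [irf_ratio()].
#' @export
irf_unstable <- function(score) {
  u <- attr(score, "unstable")
  if (is.null(u)) rep(FALSE, length(score)) else u
}

#' Convert a scale score to a dryness category
#'
#' Categorizes an IRF or NYCA sugar-to-acid score on the marketable dryness
#' scale: dry for scores up to 1.0, semi-dry above 1.0 and below 2.2,
#' semi-sweet from 2.2 through 4.0, sweet above 4.0. The published guideline
#' prints the bands on a one-decimal grid (dry < 1.0, semi-dry 1.0-2.0,
#' semi-sweet 2.1-4.0, sweet > 4.0) with its boundary behaviour left implicit;
#' the closure used here is the one consistent with how the scale is applied
#' in practice (a score of exactly 1.000 is rated dry, 2.195 semi-dry,
#' 4.000 semi-sweet, 4.069 sweet).
#'
#' @param score non-negative scale score (dimensionless).
#' @return ordered factor of dryness categories (see [dryness_category()]).
#' @examples
#' categorize_scale_score(c(0.5, 1.0, 1.5, 2.195, 2.6, 4.0, 4.1))
#' @export
categorize_scale_score <- function(score) {
  score <- as.numeric(score)
  stop_if_negative(score, "score")
  lev <- ifelse(score <= 1.0, 0L,
         ifelse(score < 2.2, 1L,
         ifelse(score <= 4.0, 2L, 3L)))
  dryness_category(lev)
}

# Table of category shifts: base level, pH threshold, direction (+1 pH >= thr,
# -1 pH <= thr), shifted level. Ordered so the most extreme applicable
# threshold is found first within each base category.
.ph_shift_rules <- data.frame(
  base    = c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L),
  thr     = c(3.5, 3.3, 3.3, 2.9, 3.3, 2.8, 2.9, 2.8, 2.9),
  dir     = c(1, 1, 1, -1, 1, -1, -1, -1, -1),
  shifted = c(2L, 1L, 2L, 0L, 3L, 0L, 1L, 1L, 2L)
)

#' pH correction of the IRF dryness category
#'
#' The pH-corrected IRF scale shifts the base sugar-to-acid category as a
#' function of pH: high pH (low perceived acidity) pushes the rating toward
#' sweet, low pH toward dry. The shifts act on the category, not the score;
#' where two thresholds both apply (e.g. pH 2.7 under semi-sweet) the more
#' extreme shift wins.
#'
#' @param base base dryness categories (labels, levels or an ordered factor).
#' @param ph pH values, strictly between 0 and 14.
#' @return ordered factor of shifted categories.
#' @examples
#' irf_ph_adjust("dry", 3.6)       # -> semi-sweet
#' irf_ph_adjust("sweet", 2.8)     # -> semi-dry
#' irf_ph_adjust("semi-dry", 3.1)  # unchanged
#' @export
irf_ph_adjust <- function(base, ph) {
  if (any(!is.finite(ph) | ph <= 0 | ph >= 14))
    stop("ph must lie strictly between 0 and 14", call. = FALSE)
  lv <- dryness_level(base)
  n <- max(length(lv), length(ph))
  lv <- rep_len(lv, n)
  ph <- rep_len(ph, n)
  out <- lv
  for (i in seq_len(n)) {
    r <- .ph_shift_rules[.ph_shift_rules$base == lv[i], , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      hit <- if (r$dir[j] > 0) ph[i] >= r$thr[j] else ph[i] <= r$thr[j]
      if (hit) { out[i] <- r$shifted[j]; break }
    }
  }
  dryness_category(out)
}

#' Tannin deduction of the NYCA scale
#'
#' Tannin-driven astringency suppresses perceived sweetness, so the NYCA
#' scale deducts up to 3/4 of a unit from the sugar-to-acid ratio: no
#' deduction up to 500 mg/L of tannins, 0.25 up to 750, 0.5 up to 1000 and
#' 0.75 above 1000 mg/L. The brackets are half-open on the left so that the
#' deduction is a non-decreasing step function covering all of `[0, Inf)`.
#'
#' @param tannins tannin concentration, mg/L (catechin equivalents).
#' @return deduction in score units, one of 0, 0.25, 0.5, 0.75.
#' @examples
#' tannin_deduction(c(0, 600, 800, 5000))
#' @export
tannin_deduction <- function(tannins) {
  stop_if_negative(tannins, "tannins")
  ifelse(tannins <= 500, 0,
  ifelse(tannins <= 750, 0.25,
  ifelse(tannins <= 1000, 0.5, 0.75)))
}

#' NYCA tannin-corrected dryness score
#'
#' Subtracts the tannin deduction from the IRF sugar-to-acid score, flooring
#' at zero (a negative sugar-to-acid ratio has no meaning).
#'
#' @param irf_score IRF scale score (see [irf_ratio()]).
#' @param tannins tannin concentration, mg/L.
#' @return NYCA score; categorize with [categorize_scale_score()].
#' @examples
#' nyca_score(4.069, 5000)  # 3.319, rated semi-sweet
#' nyca_score(2.587, 1500)  # 1.837, rated semi-dry
#' @export
nyca_score <- function(irf_score, tannins) {
  irf_score <- as.numeric(irf_score)
  stop_if_negative(irf_score, "irf_score")
  pmax(irf_score - tannin_deduction(tannins), 0)
}

#' Convert a panel sensory score to a dryness category
#'
#' Trained panels rate dryness on an 8-level category scale anchored by
#' glucose reference standards; the four marketable categories partition it
#' as dry (0-2], semi-dry (2-4], semi-sweet (4-6], sweet (6-8].
#'
#' @param score sensory dryness score in `[0, 8]`.
#' @return ordered factor of dryness categories.
#' @examples
#' categorize_sensory_score(c(2.0, 3.6, 5.5, 6.3))
#' @export
categorize_sensory_score <- function(score) {
  score <- as.numeric(score)
  if (any(!is.finite(score) | score < 0 | score > 8))
    stop("sensory score must lie in [0, 8]", call. = FALSE)
  lev <- ifelse(score <= 2, 0L,
         ifelse(score <= 4, 1L,
         ifelse(score <= 6, 2L, 3L)))
  dryness_category(lev)
}

#' Sweetness anchor interpolation
#'
#' The panel's dryness scale is anchored by glucose reference standards in a
#' base cider: 9 g/L scores 2, 18 g/L scores 4, 45 g/L scores 6. This maps
#' any glucose level onto the 0-8 scale by piecewise-linear interpolation
#' through those anchors (and the origin), extrapolating linearly above
#' 45 g/L and capping at 8.
#'
#' @param glucose glucose concentration, g/L.
#' @return score on the 0-8 sensory scale.
#' @examples
#' anchor_score(c(9, 18, 45))
#' @export
anchor_score <- function(glucose) {
  stop_if_negative(glucose, "glucose")
  gx <- c(0, 9, 18, 45)
  gy <- c(0, 2, 4, 6)
  out <- stats::approx(gx, gy, xout = pmin(glucose, 45), rule = 2)$y
  over <- glucose > 45
  # extrapolate with the slope of the last segment, capped at the scale top
  out[over] <- 6 + (glucose[over] - 45) * (6 - 4) / (45 - 18)
  pmin(out, 8)
}

#' Score a chemistry table on the IRF and NYCA scales
#'
#' Convenience wrapper applying the full rule set to a table of cider
#' chemistry (as returned by [read_chemistry_csv()] or
#' [generate_chemistry()]). Residual sugar is stored in mg/100 mL and is
#' converted to g/L for the sugar-to-acid ratio. Samples without a tannin
#' measurement get no tannin deduction (NYCA equals IRF).
#'
#' @param chem data frame of cider chemistry with at least `sample_id`,
#'   `residual_sugar` (mg/100 mL), `malic_acid` (g/L), `ph`; optionally
#'   `tannins` (mg/L).
#' @return data frame with columns `sample_id`, `irf_score`, `irf_rating`,
#'   `irf_rating_ph`, `nyca_score`, `nyca_rating`, `irf_unstable`.
#' @export
score_samples <- function(chem) {
  stopifnot(is.data.frame(chem))
  need <- c("sample_id", "residual_sugar", "malic_acid", "ph")
  miss <- setdiff(need, names(chem))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rs_gl <- chem$residual_sugar / 100  # mg/100 mL -> g/L
  irf <- irf_ratio(rs_gl, chem$malic_acid)
  tan <- if ("tannins" %in% names(chem)) ifelse(is.na(chem$tannins), 0, chem$tannins) else 0
  ny <- nyca_score(as.numeric(irf), tan)
  base <- categorize_scale_score(as.numeric(irf))
  data.frame(
    sample_id = chem$sample_id,
    irf_score = as.numeric(irf),
    irf_rating = base,
    irf_rating_ph = irf_ph_adjust(base, chem$ph),
    nyca_score = ny,
    nyca_rating = categorize_scale_score(ny),
    irf_unstable = irf_unstable(irf),
    stringsAsFactors = FALSE
  )
}

stop_if_negative <- function(x, what) {
  if (any(!is.na(x) & (!is.finite(x) | x < 0)))
    stop(what, " must be non-negative and finite", call. = FALSE)
  invisible(x)
}
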