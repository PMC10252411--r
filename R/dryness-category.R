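#' Ordinal dryness categories
#'
#' Ciders are marketed in four ordered dryness categories,
#' `dry < semi-dry < semi-sweet < sweet`. `dryness_category()` builds an
#' ordered factor on that scale from labels (spelling variants such as
#' `"semidry"` and `"Semi-Dry"` are normalized) or from integer levels
#' 0 to 3. `dryness_level()` is the inverse label-to-level map.
#'
#' @param x character labels or integers in `0:3`.
#' @return `dryness_category()`: an ordered factor with levels
#'   `dry`, `semi-dry`, `semi-sweet`, `sweet`. `dryness_level()`: integer
#'   vector in `0:3`. `dryness_levels()`: the four canonical labels in order.
#' @examples
#' dryness_category(c("semidry", "sweet"))
#' dryness_level(dryness_category("semi-sweet"))
#' @export
dryness_category <- function(x) {
  lv <- dryness_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(!is.na(x) & (x < 0 | x > 3 | x != round(x))))
      stop("numeric dryness levels must be integers in 0..3", call. = FALSE)
    return(factor(lv[x + 1L], levels = lv, ordered = TRUE))
  }
  lab <- tolower(trimws(as.character(x)))
  lab <- gsub("[ _]", "-", lab)
  lab[lab == "semidry"] <- "semi-dry"
  lab[lab == "semisweet"] <- "semi-sweet"
  lab[lab == "medium-dry"] <- "semi-dry"
  lab[lab == "medium-sweet"] <- "semi-sweet"
  bad <- !is.na(lab) & !(lab %in% lv)
  if (any(bad))
    stop("unknown dryness label(s): ", paste(unique(lab[bad]), collapse = ", "),
         call. = FALSE)
  factor(lab, levels = lv, ordered = TRUE)
}

#' @rdname dryness_category
#' @export
dryness_levels <- function() c("dry", "semi-dry", "semi-sweet", "sweet")

#' @rdname dryness_category
#' @export
dryness_level <- function(x) {
  as.integer(dryness_category(x)) - 1L
}
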