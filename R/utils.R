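#' Haldane mapping function
#'
#' Convert between recombination fraction and additive map distance under the
#' assumption of no crossover interference: `d = -50 * log(1 - 2r)` cM and its
#' inverse `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param r recombination fraction in `[0, 0.5)`; values are clamped to 0.4999
#'   so that a fraction indistinguishable from independence maps to a large but
#'   finite distance.
#' @param d map distance in centimorgans (cM), `d >= 0`.
#' @return `haldane_cm()` returns distances in cM; `haldane_rf()` returns
#'   recombination fractions.
#' @examples
#' haldane_cm(0.1)       # 11.157 cM
#' haldane_rf(34.657)    # 0.25
#' @export
haldane_cm <- function(r) {
  -50 * log(1 - 2 * pmin(pmax(r, 0), 0.4999))
}

#' @rdname haldane_cm
#' @export
haldane_rf <- function(d) {
  (1 - exp(-2 * d / 100)) / 2
}

# structured validation error so callers can test by class
am_stop <- function(msg, class = "anchormap_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "error", "condition")))
}

am_check <- function(ok, msg, class = "anchormap_validation_error") {
  if (!isTRUE(ok)) am_stop(msg, class = class)
  invisible(TRUE)
}

# scalar finite numeric in [lo, hi]
check_num <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  am_check(is.numeric(x) && length(x) == 1L && is.finite(x),
           sprintf("'%s' must be a single finite number", name))
  am_check(x >= lo && x <= hi,
           sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x))
  if (integer) am_check(x == round(x), sprintf("'%s' must be an integer", name))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sort a pair of alleles into a canonical "X/Y" genotype string
geno_str <- function(a, b) {
  ifelse(is.na(a) | is.na(b), NA_character_,
         paste(pmin(a, b), pmax(a, b), sep = "/"))
}

split_geno <- function(g) {
  # "X/Y" -> c("X","Y"); NA -> c(NA, NA)
  if (is.na(g)) return(c(NA_character_, NA_character_))
  strsplit(g, "/", fixed = TRUE)[[1]]
}
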