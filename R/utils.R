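# internal validation / unit helpers

#' Convert micromolar doses to nanomolar
#'
#' All doses inside the package are carried in nM; this is the one
#' sanctioned conversion for user inputs quoted in uM.
#'
#' @param x Numeric vector of doses in uM.
#' @return Doses in nM.
#' @export
#' @examples
#' um_to_nm(2)    # 2000 nM
#' um_to_nm(0.1353)
um_to_nm <- function(x) {
  stopifnot(is.numeric(x))
  x * 1000
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single number in [%s, %s]%s.",
                  name, format(lower), format(upper),
                  if (allow_inf) " (Inf allowed)" else ""))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# grouping key shared by all time-course verbs: whichever of these
# label columns are present identify a single well's series
tc_keys <- function(df) {
  intersect(c("model_id", "drug_id", "treatment", "dose_nM", "well"),
            names(df))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) abort("need at least 2 points to integrate")
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
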