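#' Define a frequency band
#'
#' A band is a named closed frequency interval in Hz.  Band-power extraction
#' includes every frequency bin whose centre lies inside `[f_lo, f_hi]`.
#'
#' @param name band label, e.g. `"theta"`.
#' @param f_lo,f_hi band edges in Hz; `0 < f_lo < f_hi` required.
#' @return an object of class `band_definition`.
#' @examples
#' band_definition("alpha", 9, 14)
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is_number(f_lo), is_number(f_hi))
  if (!(f_lo > 0 && f_lo < f_hi))
    stop("band '", name, "': need 0 < f_lo < f_hi, got [", f_lo, ", ", f_hi, "]")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("band %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Standard oscillatory band set
#'
#' Theta, alpha and beta bands as used throughout the analysis: theta 2-7 Hz
#' (with a 4-7 Hz variant that excludes the delta range), alpha 9-14 Hz,
#' beta 15-30 Hz.
#'
#' @param theta_variant `"2-7"` (default) or `"4-7"`.
#' @return named list of [band_definition()] objects.
#' @export
band_set <- function(theta_variant = c("2-7", "4-7")) {
  theta_variant <- match.arg(theta_variant)
  theta_lo <- if (theta_variant == "2-7") 2 else 4
  list(theta = band_definition("theta", theta_lo, 7),
       alpha = band_definition("alpha", 9, 14),
       beta  = band_definition("beta", 15, 30))
}

# Bands must not overlap within one configuration (band labels partition the
# spectrum actually analysed).
check_bands <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1L)
  for (b in bands)
    if (!inherits(b, "band_definition")) stop("bands must be band_definition objects")
  nm <- vapply(bands, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate band names")
  if (length(bands) > 1L) {
    o <- order(vapply(bands, `[[`, 0, "f_lo"))
    bs <- bands[o]
    for (i in seq_len(length(bs) - 1L))
      if (bs[[i + 1L]]$f_lo < bs[[i]]$f_hi)
        stop("bands '", bs[[i]]$name, "' and '", bs[[i + 1L]]$name, "' overlap")
  }
  invisible(bands)
}
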