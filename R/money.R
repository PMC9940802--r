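#' Currency arithmetic in whole US cents
#'
#' All dollar amounts inside the engine are held as whole cents in doubles
#' (exact for magnitudes far beyond any hospital budget), so that savings
#' identities hold exactly with no floating-point accumulation of currency.
#' Conversions to display dollars use round-half-up, the convention of
#' commercial ledgers.
#'
#' @param dollars A numeric vector of dollar amounts.
#' @param x A numeric vector (cent amounts for [whole_dollars()]).
#' @return `cents()` returns whole-cent integers (as doubles); `dollars()`
#'   the dollar value of a cent amount; `round_half_up()` the nearest
#'   integer with ties going away from zero; `whole_dollars()` a cent
#'   amount rounded half-up to whole dollars.
#' @examples
#' cents(58.50)        # 5850
#' round_half_up(7312.5)  # 7313
#' whole_dollars(41931942)  # 419319
#' @name money
NULL

# Guard against binary floating-point droop at exact half-cent boundaries
# (e.g. 5850 / 0.8 evaluates to 7312.4999...95 in doubles). The guard is
# ~1e5 times smaller than the smallest meaningful difference (a cent).
.half_up_eps <- 1e-7

#' @rdname money
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5 + .half_up_eps)
}

#' @rdname money
#' @export
cents <- function(dollars) {
  round_half_up(dollars * 100)
}

#' @rdname money
#' @export
dollars <- function(x) {
  x / 100
}

#' @rdname money
#' @export
whole_dollars <- function(x) {
  round_half_up(x / 100)
}

# "$1,234.56" display of a cent amount
fmt_dollars <- function(x, digits = 2) {
  paste0(
    ifelse(x < 0, "-$", "$"),
    formatC(abs(x) / 100, format = "f", digits = digits, big.mark = ",")
  )
}

# one-decimal display used for per-day ratios
fmt_ratio1 <- function(x) {
  formatC(round_half_up(x * 10) / 10, format = "f", digits = 1)
}
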