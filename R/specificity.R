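#' Regulatory specificity profiles
#'
#' A specificity profile assigns each developmental stage `l` a regulatory
#' specificity `s(l)` in `[0, 1]`. A gene at stage `l` regulates a given gene
#' at stage `l + 1` with the complementary edge probability
#' `s'(l) = 1 - s(l)`, so higher specificity means sparser downstream
#' regulation. Three shapes are supported:
#'
#' * `constant`: `s(l) = value` for every stage;
#' * `linear`: `s(l) = l / L`, strictly increasing across development;
#' * `sigmoid`: `s(l) = 0.9 - 0.8 / (1 + exp(l - gamma_mid))`, a logistic
#'   ramp rising from 0.1 to 0.9 whose midpoint `gamma_mid` is the stage at
#'   which specificity equals 50%.
#'
#' @param kind One of `"constant"`, `"linear"`, `"sigmoid"`.
#' @param L Number of developmental stages (integer, at least 3).
#' @param value Constant specificity in `[0, 1]` (used by `kind =
#'   "constant"`).
#' @param gamma_mid Stage coordinate at which the sigmoid profile crosses
#'   50% specificity (used by `kind = "sigmoid"`).
#'
#' @return An object of class `specificity_profile`.
#' @examples
#' prof <- specificity_profile("linear", L = 10)
#' specificity(prof, 5)   # 0.5
#' edge_prob(prof, 5)     # 0.5
#' @export
specificity_profile <- function(kind = c("constant", "linear", "sigmoid"),
                                L, value = 0.5, gamma_mid = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(L), length(L) == 1, L >= 3, L == as.integer(L))
  L <- as.integer(L)
  if (kind == "constant") {
    stopifnot(is.numeric(value), length(value) == 1, value >= 0, value <= 1)
  }
  if (kind == "sigmoid") {
    if (is.null(gamma_mid)) {
      stop("`gamma_mid` must be supplied for a sigmoid profile", call. = FALSE)
    }
    stopifnot(is.numeric(gamma_mid), length(gamma_mid) == 1)
  }
  structure(
    list(kind = kind, L = L, value = value, gamma_mid = gamma_mid),
    class = "specificity_profile"
  )
}

#' @export
print.specificity_profile <- function(x, ...) {
  detail <- switch(x$kind,
    constant = sprintf("s(l) = %g", x$value),
    linear = sprintf("s(l) = l/%d", x$L),
    sigmoid = sprintf("s(l) = 0.9 - 0.8/(1 + exp(l - %g))", x$gamma_mid)
  )
  cat(sprintf("<specificity_profile> %s, L = %d, %s\n", x$kind, x$L, detail))
  invisible(x)
}

#' Evaluate a specificity profile at a stage
#'
#' `specificity()` returns `s(l)`; `edge_prob()` returns the downstream edge
#' probability `s'(l) = 1 - s(l)`. Edges originate from stages `1..L-1`
#' only, so `l` must lie in that range.
#'
#' @param profile A [specificity_profile()].
#' @param l Stage index (vectorised), `1 <= l <= L - 1`.
#' @return Numeric vector of probabilities.
#' @export
specificity <- function(profile, l) {
  stopifnot(inherits(profile, "specificity_profile"))
  if (any(l < 1 | l > profile$L - 1)) {
    stop(sprintf("stage index out of range 1..%d", profile$L - 1),
         call. = FALSE)
  }
  switch(profile$kind,
    constant = rep(profile$value, length(l)),
    linear = l / profile$L,
    sigmoid = 0.9 - 0.8 / (1 + exp(l - profile$gamma_mid))
  )
}

#' @rdname specificity
#' @export
edge_prob <- function(profile, l) {
  1 - specificity(profile, l)
}
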