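# Welford speed-accuracy law and per-element informational load.
#
# A single aimed movement of amplitude A (mm) toward a target of width W (mm)
# takes
#
#   MT = a + b * log2(A) + c * log2(W)      (seconds)
#
# where a, b, c are constants for one individual, effector and task
# condition. b >= 0 makes longer movements slower; c <= 0 makes smaller
# targets slower, so difficulty (in bits) raises movement time. The
# information-dependent part of MT, divided by a rate constant, is the
# buffer-unit load one sequence element places on working memory.

#' Skill parameters of the speed-accuracy law
#'
#' Bundles the individual/condition constants of the movement-time law
#' `MT = a + b*log2(A) + c*log2(W)`.
#'
#' @param a Intercept duration in seconds; must be >= 0.
#' @param b Amplitude coefficient in s/bit; must be >= 0.
#' @param c Width coefficient in s/bit; must be <= 0 (shrinking the target
#'   must never speed the movement).
#' @return An object of class `skill_params`.
#' @examples
#' p <- skill_params(a = 0.3, b = 0.2, c = -0.2)
#' movement_time(movement(A = 128, W = 8), p)  # 1.1 s
#' @export
skill_params <- function(a, b, c) {
  check_num1(a, "a"); check_num1(b, "b"); check_num1(c, "c")
  if (a < 0) stop_domain("a must be >= 0")
  if (b < 0) stop_domain("b must be >= 0")
  if (c > 0) stop_domain("c must be <= 0")
  structure(list(a = a, b = b, c = c), class = "skill_params")
}

#' @export
print.skill_params <- function(x, ...) {
  cat(sprintf("Skill parameters: a = %g s, b = %g s/bit, c = %g s/bit\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' A single aimed movement
#'
#' @param A Movement amplitude in mm; must be > 0.
#' @param W Target width in mm; must be > 0.
#' @return An object of class `movement`.
#' @export
movement <- function(A, W) {
  check_num1(A, "A"); check_num1(W, "W")
  if (A <= 0) stop_domain("A must be > 0")
  if (W <= 0) stop_domain("W must be > 0")
  structure(list(A = A, W = W), class = "movement")
}

#' Predicted movement time
#'
#' Evaluates `MT = a + b*log2(A) + c*log2(W)`. Pathological parameter
#' combinations can predict a negative duration; the result is then clamped
#' at `floor` with a warning, so parameter sweeps do not abort.
#'
#' @param m A [movement()], or a list with numeric fields `A` and `W`.
#' @param p A [skill_params()].
#' @param floor Lower clamp for the returned duration (s), default 0.
#' @return Movement time in seconds.
#' @export
movement_time <- function(m, p, floor = 0) {
  if (!inherits(m, "movement")) m <- movement(m$A, m$W)
  if (!inherits(p, "skill_params")) p <- skill_params(p$a, p$b, p$c)
  mt <- p$a + p$b * log2(m$A) + p$c * log2(m$W)
  if (mt < floor) {
    warning(sprintf("predicted movement time %.4g s below floor %g; clamped",
                    mt, floor))
    mt <- floor
  }
  mt
}

#' Informational load of one sequence element
#'
#' The buffer-unit cost of holding one movement element in working memory:
#' the information-dependent part of the movement-time law (MT minus the
#' intercept a), scaled by `k`, and floored at `e_min` so every element has
#' strictly positive load.
#'
#' @inheritParams movement_time
#' @param k Scale converting seconds of informational processing into buffer
#'   units (units/s); must be > 0.
#' @param e_min Minimum load in buffer units, default 0.1; must be > 0.
#' @return Element load in buffer units.
#' @export
element_load <- function(m, p, k = 1, e_min = 0.1) {
  check_num1(k, "k"); check_num1(e_min, "e_min")
  if (k <= 0) stop_domain("k must be > 0")
  if (e_min <= 0) stop_domain("e_min must be > 0")
  if (!inherits(p, "skill_params")) p <- skill_params(p$a, p$b, p$c)
  mt <- movement_time(m, p, floor = -Inf)
  max(e_min, k * (mt - p$a))
}

#' Write skill-parameter sets grouped by condition to a JSON config file
#'
#' @param params Named list of `skill_params` (names are condition labels,
#'   e.g. "younger.preferred.regular").
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_skill_config <- function(params, path) {
  stopifnot(is.list(params), length(names(params)) == length(params))
  out <- lapply(params, function(p) list(a = p$a, b = p$b, c = p$c))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read skill-parameter sets from a JSON config file
#'
#' @param path File written by [write_skill_config()].
#' @return Named list of [skill_params()].
#' @export
read_skill_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) skill_params(p$a, p$b, p$c))
}
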