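#' Effective side length of a dilated convolution kernel
#'
#' A `k x k` kernel with dilation (expansion) rate `r` spreads its taps over
#' an effective square of side `kd = k + (k - 1) * (r - 1)` pixels: `r - 1`
#' zeros are inserted between neighbouring taps.
#'
#' @param k Odd positive integer kernel size.
#' @param r Positive integer dilation rate.
#' @return Integer side length of the effective kernel.
#' @examples
#' dilated_kernel_size(3, 1)  # 3
#' dilated_kernel_size(3, 2)  # 5
#' dilated_kernel_size(3, 4)  # 9
#' @export
dilated_kernel_size <- function(k, r) {
  check_kernel_size(k)
  if (!is_count(r)) stop("`r` must be a positive integer", call. = FALSE)
  as.integer(k + (k - 1L) * (r - 1L))
}

#' Maximum gap between non-zero taps of stacked dilated convolutions
#'
#' For a stack of `n` dilated `k x k` convolutions with rates `r_1..r_n`,
#' the largest distance `M_i` between non-zero contributing positions at
#' level `i` follows the backward recursion
#' `M_i = max(M_{i+1} - 2 r_i, M_{i+1} - 2 (M_{i+1} - r_i), r_i)` with base
#' case `M_n = r_n`.  A stack is free of the gridding (lattice) effect when
#' `M_2 <= k`.
#'
#' @param k Odd positive integer kernel size (used only for validation
#'   context; the recursion itself depends on the rates).
#' @param rates Integer vector of dilation rates, innermost first.
#' @return Integer vector `M_1..M_n`.
#' @examples
#' max_nonzero_distances(3, c(1, 2, 5))      # M_2 = 2
#' max_nonzero_distances(3, c(1, 2, 7, 15))  # M_2 = 3
#' @export
max_nonzero_distances <- function(k, rates) {
  check_kernel_size(k)
  check_rates(rates)
  rates <- as.integer(rates)
  n <- length(rates)
  M <- integer(n)
  M[n] <- rates[n]
  if (n > 1L) {
    for (i in (n - 1L):1L) {
      Mi1 <- M[i + 1L]
      ri <- rates[i]
      M[i] <- max(Mi1 - 2L * ri, Mi1 - 2L * (Mi1 - ri), ri)
    }
  }
  M
}

#' Validate a dilation-rate schedule against the gridding effect
#'
#' A schedule passes when (a) the maximum tap gap at the second level
#' satisfies `M_2 <= k`, so the innermost kernel can fill the holes left by
#' the outer ones, and (b) the rates share no common factor greater than 1
#' (schedules such as 2, 4, 8 leave periodic holes regardless of `M_2`).
#'
#' @inheritParams max_nonzero_distances
#' @return Character verdict: `"valid"`, `"gridding"` (the `M_2 <= k` rule
#'   fails) or `"common_factor"`.
#' @examples
#' validate_rates(3, c(1, 2, 5))      # "valid"
#' validate_rates(3, c(1, 2, 9))      # "gridding"
#' validate_rates(3, c(2, 4, 8))      # "common_factor"
#' validate_rates(3, c(1, 2, 7, 15))  # "valid"
#' @export
validate_rates <- function(k, rates) {
  check_kernel_size(k)
  check_rates(rates)
  if (length(rates) > 1L && gcd_all(rates) > 1L) return("common_factor")
  M <- max_nonzero_distances(k, rates)
  M2 <- if (length(rates) >= 2L) M[2L] else M[1L]
  if (M2 <= k) "valid" else "gridding"
}

#' Build a dilation schedule with its validity verdict
#'
#' @inheritParams max_nonzero_distances
#' @return An object of class `dilation_schedule` with fields
#'   `kernel_size`, `rates`, `max_distances`, `verdict` and `valid`.
#' @export
dilation_schedule <- function(k, rates) {
  verdict <- validate_rates(k, rates)
  structure(
    list(kernel_size = as.integer(k), rates = as.integer(rates),
         max_distances = max_nonzero_distances(k, rates),
         verdict = verdict, valid = identical(verdict, "valid")),
    class = "dilation_schedule")
}

#' @export
print.dilation_schedule <- function(x, ...) {
  cat(sprintf("dilation schedule: k = %d, rates = [%s]\n",
              x$kernel_size, paste(x$rates, collapse = ", ")))
  cat(sprintf("  M_i = [%s]\n", paste(x$max_distances, collapse = ", ")))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Brute-force coverage check for a dilated-convolution stack
#'
#' Simulates the 1-D footprint of `n` stacked dilated convolutions: starting
#' from a single active position, each level spreads every active position
#' to its `k` taps spaced `r_i` apart.  The stack exhibits gridding when the
#' final footprint has interior holes.  This is an independent oracle for
#' [validate_rates()]; it knows nothing of the `M_i` recursion.
#'
#' @inheritParams max_nonzero_distances
#' @return `TRUE` when the footprint has no interior holes.
#' @export
footprint_covers <- function(k, rates) {
  check_kernel_size(k)
  check_rates(rates)
  half <- (k - 1L) %/% 2L
  taps <- -half:half
  pos <- 0L
  # apply outermost (last) rate first: receptive field composition
  for (r in rev(rates)) {
    pos <- unique(as.integer(outer(pos, taps * r, `+`)))
  }
  pos <- sort(pos)
  all(diff(pos) == 1L)
}

# ---- internal helpers -----------------------------------------------------

check_kernel_size <- function(k) {
  if (!is_count(k) || k %% 2L == 0L)
    stop("`k` must be a positive odd integer", call. = FALSE)
  invisible(k)
}

check_rates <- function(rates) {
  if (length(rates) == 0L || !all(vapply(rates, is_count, logical(1))))
    stop("`rates` must be a non-empty vector of positive integers",
         call. = FALSE)
  invisible(rates)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

gcd_all <- function(x) Reduce(gcd2, as.integer(x))
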