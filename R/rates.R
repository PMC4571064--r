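# Merger-rate kernels for the three coalescent families and event sampling.

#' Coalescent parameter
#'
#' Tags a numeric coalescent parameter with the family it selects. Dispatch is
#' by value: `NULL`, `NA`, `0` or `2` select the Kingman coalescent, a value in
#' `(0, 1]` is interpreted as the point-mass parameter `psi` (the fraction of
#' the population replaced by the offspring of a single parent in a sweepstakes
#' event), and a value in `(1, 2)` as the `alpha` parameter of the
#' Beta(2-alpha, alpha)-coalescent. `psi = 0` collapses exactly to Kingman, so
#' both endpoints of the dispatch rule are consistent.
#'
#' @param value numeric scalar in `[0, 2]`, or `NULL`/`NA` for Kingman.
#' @return an object of class `coalescent_parameter` with fields `family`
#'   (one of `"kingman"`, `"psi"`, `"beta"`) and `value`.
#' @examples
#' coalescent_parameter(0.1)  # psi point-mass coalescent
#' coalescent_parameter(1.5)  # Beta(0.5, 1.5)-coalescent
#' coalescent_parameter()     # Kingman
#' @export
coalescent_parameter <- function(value = NULL) {
  if (is.null(value) || length(value) == 0L || is.na(value)) {
    return(structure(list(family = "kingman", value = NA_real_),
                     class = "coalescent_parameter"))
  }
  if (!is.numeric(value) || length(value) != 1L) {
    stop("coalescent parameter must be a single numeric value", call. = FALSE)
  }
  value <- as.numeric(value)
  if (value < 0 || value > 2) {
    stop("coalescent parameter must lie in [0, 2], got ", value, call. = FALSE)
  }
  family <- if (value == 0 || value == 2) "kingman"
            else if (value <= 1) "psi"
            else "beta"
  structure(list(family = family, value = if (family == "kingman") NA_real_ else value),
            class = "coalescent_parameter")
}

#' @export
print.coalescent_parameter <- function(x, ...) {
  if (x$family == "kingman") cat("Kingman coalescent\n")
  else if (x$family == "psi") cat(sprintf("psi point-mass coalescent, psi = %g\n", x$value))
  else cat(sprintf("Beta(%g, %g)-coalescent, alpha = %g\n", 2 - x$value, x$value, x$value))
  invisible(x)
}

as_coalescent_parameter <- function(p) {
  if (inherits(p, "coalescent_parameter")) p else coalescent_parameter(p)
}

check_bk <- function(b, k = NULL) {
  if (length(b) != 1L || is.na(b) || b < 2 || b != round(b)) {
    stop("'b' must be a single integer >= 2", call. = FALSE)
  }
  if (!is.null(k) && (length(k) != 1L || is.na(k) || k < 2 || k > b || k != round(k))) {
    stop("'k' must be an integer with 2 <= k <= b", call. = FALSE)
  }
  invisible(TRUE)
}

#' Kingman pairwise coalescence rate
#'
#' Rate at which two of `b` active ancestral lineages coalesce under the
#' Kingman coalescent: `choose(b, 2)`. Mergers of more than two lineages have
#' rate zero in this family.
#'
#' @param b number of active lineages (integer, at least 2).
#' @return the rate `b * (b - 1) / 2`.
#' @export
rate_kingman <- function(b) {
  check_bk(b)
  choose(b, 2)
}

#' Point-mass (psi) coalescent merger rate
#'
#' Rate at which a given set of `k` out of `b` active lineages merges under the
#' psi point-mass coalescent derived from sweepstakes reproduction:
#' `choose(b, k) * psi^(k - 2) * (1 - psi)^(b - k)`. At `psi = 0` the rates
#' collapse exactly to Kingman (non-zero only at `k = 2`).
#'
#' @param b number of active lineages (integer, at least 2).
#' @param k merger size, `2 <= k <= b`.
#' @param psi point-mass parameter in `[0, 1]`.
#' @return the merger rate (non-negative real).
#' @export
rate_psi <- function(b, k, psi) {
  check_bk(b, k)
  if (length(psi) != 1L || is.na(psi) || psi < 0 || psi > 1) {
    stop("'psi' must lie in [0, 1]", call. = FALSE)
  }
  # 0^0 == 1 in R, giving the exact Kingman collapse at psi = 0
  choose(b, k) * psi^(k - 2) * (1 - psi)^(b - k)
}

#' Beta-coalescent merger rate
#'
#' Rate at which `k` out of `b` active lineages merge under the
#' Beta(2-alpha, alpha)-coalescent:
#' `choose(b, k) * B(k - alpha, b - k + alpha) / B(2 - alpha, alpha)`,
#' where `B` is the beta function. Evaluated in log space (via [lbeta()] and
#' [lchoose()]) for numerical stability at large `b`. The normalisation gives
#' `rate_beta(2, 2, alpha) == 1` for every `alpha`, i.e. pairs coalesce at
#' rate 1 on this family's timescale.
#'
#' @param b number of active lineages (integer, at least 2).
#' @param k merger size, `2 <= k <= b`.
#' @param alpha stability parameter in the open interval `(1, 2)`.
#' @return the merger rate (non-negative real).
#' @export
rate_beta <- function(b, k, alpha) {
  check_bk(b, k)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 1 || alpha >= 2) {
    stop("'alpha' must lie in the open interval (1, 2)", call. = FALSE)
  }
  exp(lchoose(b, k) + lbeta(k - alpha, b - k + alpha) - lbeta(2 - alpha, alpha))
}

# Vector of rates for k = 2..b under a (family, value) pair. Internal hot path.
rates_vector <- function(b, family, value) {
  k <- 2:b
  switch(family,
    kingman = c(choose(b, 2), numeric(b - 2L)),
    psi = choose(b, k) * value^(k - 2) * (1 - value)^(b - k),
    beta = exp(lchoose(b, k) + lbeta(k - value, b - k + value) - lbeta(2 - value, value))
  )
}

#' Merger rates for all merger sizes
#'
#' Returns the vector of merger rates `lambda[b, k]` for `k = 2, ..., b` under
#' the given coalescent parameter.
#'
#' @param b number of active lineages (integer, at least 2).
#' @param param a [coalescent_parameter()], or a bare numeric dispatched by the
#'   same rule.
#' @return numeric vector of length `b - 1`, named by merger size.
#' @export
merger_rates <- function(b, param = NULL) {
  check_bk(b)
  p <- as_coalescent_parameter(param)
  r <- rates_vector(b, p$family, p$value)
  names(r) <- as.character(2:b)
  r
}

#' Total coalescence rate
#'
#' Sum of the merger rates over all merger sizes `k = 2, ..., b`; the rate
#' parameter of the exponential waiting time until the next coalescence event.
#'
#' @inheritParams merger_rates
#' @return a positive real number.
#' @export
total_rate <- function(b, param = NULL) {
  sum(merger_rates(b, param))
}

#' Sample one coalescence event
#'
#' Draws the waiting time until the next merger (exponential with rate
#' [total_rate()]), the merger size `k` (with probability proportional to
#' `lambda[b, k]`), and a uniformly random `k`-subset of the active lineages.
#' Exactly one merger happens per event: Lambda-coalescents have no
#' simultaneous mergers. Uses R's global random number generator; seed with
#' [set.seed()] for reproducibility.
#'
#' @param lineages vector of lineage identifiers (length at least 2).
#' @param param a [coalescent_parameter()] or bare numeric.
#' @return a list with fields `waiting_time`, `k`, and `participants` (the
#'   merging subset of `lineages`).
#' @export
sample_event <- function(lineages, param = NULL) {
  b <- length(lineages)
  check_bk(b)
  p <- as_coalescent_parameter(param)
  rates <- rates_vector(b, p$family, p$value)
  tot <- sum(rates)
  w <- stats::rexp(1L, tot)
  k <- if (b == 2L || p$family == "kingman") 2L
       else sample.int(b - 1L, 1L, prob = rates) + 1L
  part <- if (k == b) lineages else lineages[sample.int(b, k)]
  list(waiting_time = w, k = k, participants = part)
}
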