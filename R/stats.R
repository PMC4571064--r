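# Summaries: analytic split-model F_ST in the low-mutation limit, the
# pairwise-difference F_ST estimator, gene-tree topology frequency tables,
# and monophyly classification for two populations.

#' Expected coalescence times under a two-population split model
#'
#' Two populations separated `tau` coalescent units ago, with pairwise
#' coalescence rate `lambda_A` within each daughter population and
#' `lambda_AB` in the common ancestral population. Returns the expected
#' coalescence time for two lineages drawn from the same population (`T_w`)
#' and from different populations (`T_b`):
#' \deqn{E[T_w] = (1 - e^{-\lambda_A \tau}) / \lambda_A +
#'       e^{-\lambda_A \tau} (\tau + 1/\lambda_{AB}), \quad
#'       E[T_b] = \tau + 1/\lambda_{AB}.}
#' For the Beta(2-alpha, alpha)-coalescent `lambda_A = 1` on its own
#' timescale; for the psi point-mass process the pairwise rate is a free
#' input here.
#'
#' @param tau divergence time in coalescent units (non-negative; vectorised).
#' @param lambda_A pairwise coalescence rate within each daughter population.
#' @param lambda_AB pairwise coalescence rate in the ancestral population.
#' @return a list with numeric components `T_w` and `T_b`.
#' @examples
#' expected_times(1)  # T_w = 1 + exp(-1), T_b = 2
#' @export
expected_times <- function(tau, lambda_A = 1, lambda_AB = 1) {
  if (any(tau < 0)) stop("'tau' must be non-negative", call. = FALSE)
  if (lambda_A <= 0 || lambda_AB <= 0) stop("rates must be positive", call. = FALSE)
  s <- exp(-lambda_A * tau)
  list(T_w = (1 - s) / lambda_A + s * (tau + 1 / lambda_AB),
       T_b = tau + 1 / lambda_AB)
}

#' Low-mutation-limit F_ST for a two-population split model
#'
#' Slatkin's approximation `F_ST -> 1 - E[T_w]/E[T_b]` as the mutation rate
#' tends to zero, which for the split model of [expected_times()] reduces to
#' \deqn{F_{ST}^{(0)} = (1 - e^{-\lambda_A \tau})
#'       \left(1 - \frac{1}{(\tau + 1/\lambda_{AB})\,\lambda_A}\right).}
#' The limits are 0 as `tau -> 0` and 1 as `tau -> Inf`.
#'
#' @inheritParams expected_times
#' @return F_ST values (same length as `tau`).
#' @examples
#' expected_fst(1)  # (1 - exp(-1)) / 2
#' @export
expected_fst <- function(tau, lambda_A = 1, lambda_AB = 1) {
  if (any(tau < 0)) stop("'tau' must be non-negative", call. = FALSE)
  if (lambda_A <= 0 || lambda_AB <= 0) stop("rates must be positive", call. = FALSE)
  (1 - exp(-lambda_A * tau)) * (1 - 1 / ((tau + 1 / lambda_AB) * lambda_A))
}

# Pairwise difference-count matrix for one 0/1 matrix (symmetric, zero diag).
pair_differences <- function(m) {
  m <- unclass(m)
  storage.mode(m) <- "double"
  if (ncol(m) == 0L) return(matrix(0, nrow(m), nrow(m),
                                   dimnames = list(rownames(m), rownames(m))))
  d <- m %*% t(1 - m)
  d + t(d)
}

#' Estimate F_ST from 0/1 haplotype data
#'
#' Computes the pairwise-difference F_ST estimator
#' `1 - (n/(n-1)) * H_w / H_b` for two populations. `H_b` is the average
#' number of pairwise differences over all `n1 * n2` between-population pairs.
#' `H_w = (H_w1 + H_w2)/2`, where `H_wi` is the average over all `ni^2`
#' ordered within-population pairs (self pairs, contributing zero, included);
#' the `n/(n-1)` factor exactly removes the downward bias this introduces, so
#' the estimator is centred on `1 - E[T_w]/E[T_b]` (cf. [expected_fst()]) for
#' every sample size. With unequal sample sizes `n = (n1 + n2)/2` is used in
#' the correction, with a warning.
#'
#' For multi-locus data pass a list of matrices with identical row sets:
#' difference counts are summed across loci per pair before averaging
#' (ratio-of-averages pooling).
#'
#' @param h a `haplotype_matrix` (or plain 0/1 matrix with row names), or a
#'   list of such matrices (loci).
#' @param populations population assignment for each row: a named vector
#'   (defaults to the matrix's `populations` attribute). Exactly two
#'   populations are required.
#' @param correction apply the `n/(n-1)` factor (requires at least 2 samples
#'   in each population). With `correction = FALSE` the raw ratio
#'   `1 - H_w/H_b` is returned, which is the only option at `n = 1`.
#' @return an object of class `fst_result`: a list with `H_w1`, `H_w2`,
#'   `H_w`, `H_b`, sample sizes `n1`, `n2`, `n`, `fst` (`NA` when `H_b = 0`,
#'   flagged by `defined = FALSE`).
#' @export
estimate_fst <- function(h, populations = NULL, correction = TRUE) {
  mats <- if (is.list(h) && !is.matrix(h)) h else list(h)
  if (is.null(populations)) populations <- attr(mats[[1L]], "populations")
  if (is.null(populations)) {
    stop("no population assignment found; pass 'populations'", call. = FALSE)
  }
  rn <- rownames(mats[[1L]])
  for (m in mats) {
    if (!identical(rownames(m), rn)) {
      stop("all loci must share the same samples in the same order", call. = FALSE)
    }
  }
  pops <- populations[rn]
  if (anyNA(pops)) stop("population assignment missing for some samples", call. = FALSE)
  lev <- unique(pops)
  if (length(lev) != 2L) {
    stop("exactly two populations are required, found ", length(lev), call. = FALSE)
  }
  i1 <- which(pops == lev[1L]); i2 <- which(pops == lev[2L])
  n1 <- length(i1); n2 <- length(i2)
  d <- Reduce(`+`, lapply(mats, pair_differences))
  H_w1 <- sum(d[i1, i1]) / n1^2
  H_w2 <- sum(d[i2, i2]) / n2^2
  H_w <- (H_w1 + H_w2) / 2
  H_b <- sum(d[i1, i2, drop = FALSE]) / (n1 * n2)
  n <- (n1 + n2) / 2
  if (correction) {
    if (min(n1, n2) < 2L) {
      stop("the n/(n-1) correction needs at least 2 samples per population; ",
           "use correction = FALSE", call. = FALSE)
    }
    if (n1 != n2) {
      warning("unequal sample sizes; using n = (n1 + n2)/2 = ", n,
              " in the correction", call. = FALSE)
    }
    factor <- n / (n - 1)
  } else {
    factor <- 1
  }
  defined <- H_b > 0
  fst <- if (defined) 1 - factor * H_w / H_b else NA_real_
  structure(list(H_w1 = H_w1, H_w2 = H_w2, H_w = H_w, H_b = H_b,
                 n1 = n1, n2 = n2, n = n,
                 populations = lev, corrected = correction,
                 fst = fst, defined = defined),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST between '%s' (n=%d) and '%s' (n=%d)\n",
              x$populations[1L], x$n1, x$populations[2L], x$n2))
  cat(sprintf("  H_w = %.6g (H_w1 = %.6g, H_w2 = %.6g), H_b = %.6g\n",
              x$H_w, x$H_w1, x$H_w2, x$H_b))
  if (x$defined) {
    cat(sprintf("  F_ST = %.6g%s\n", x$fst,
                if (x$corrected) "" else " (uncorrected)"))
  } else {
    cat("  F_ST undefined (H_b = 0)\n")
  }
  invisible(x)
}

# Canonical topology string: branch lengths stripped, children sorted by
# their smallest descendant tip label (radix order, locale-independent).
canonical_topology <- function(tree) {
  ch <- gene_tree_children(tree)
  rec <- function(i) {
    if (i <= tree$n_tip && !length(ch[[i]])) {
      return(list(str = tree$tip_labels[i], min = tree$tip_labels[i]))
    }
    subs <- lapply(ch[[i]], rec)
    mins <- vapply(subs, `[[`, "", "min")
    o <- order(mins, method = "radix")
    list(str = paste0("(", paste(vapply(subs[o], `[[`, "", "str"),
                                 collapse = ","), ")"),
         min = mins[o[1L]])
  }
  paste0(rec(gene_tree_root(tree))$str, ";")
}

#' Gene-tree topology frequency table
#'
#' Reduces each tree to a canonical topology string (branch lengths stripped,
#' children sorted by smallest descendant label) and tabulates counts and
#' relative frequencies.
#'
#' @param trees a list of `gene_tree` objects.
#' @return a data frame with columns `topology`, `count`, `frequency`
#'   (summing to 1), sorted by decreasing count.
#' @export
topology_table <- function(trees) {
  if (inherits(trees, "gene_tree")) trees <- list(trees)
  if (!length(trees)) stop("at least one tree is required", call. = FALSE)
  tops <- vapply(trees, canonical_topology, "")
  tab <- sort(table(tops), decreasing = TRUE)
  data.frame(topology = names(tab),
             count = as.integer(tab),
             frequency = as.numeric(tab) / length(tops),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a two-population gene tree as monophyletic, paraphyletic or
#' polyphyletic
#'
#' A population is monophyletic when its tips form an exclusive clade.
#' With two populations the tree shows reciprocal monophyly when both do,
#' paraphyly when exactly one does, and polyphyly when neither does.
#'
#' @param tree a `gene_tree`.
#' @param populations population of each tip: a vector named by tip label
#'   (defaults to the species of origin recorded at simulation).
#' @return one of `"reciprocal_monophyly"`, `"paraphyly"`, `"polyphyly"`.
#' @examples
#' classify_monophyly(read_gene_tree("((a_1,a_2),(b_1,b_2));"))
#' classify_monophyly(read_gene_tree("((a_1,b_1),(a_2,b_2));"))
#' @export
classify_monophyly <- function(tree, populations = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  if (is.null(populations)) {
    populations <- stats::setNames(tree$species, tree$tip_labels)
  }
  pops <- populations[tree$tip_labels]
  if (anyNA(pops)) stop("population assignment missing for some tips", call. = FALSE)
  lev <- unique(pops)
  if (length(lev) != 2L) {
    stop("exactly two populations are required, found ", length(lev), call. = FALSE)
  }
  sets <- gene_tree_tip_sets(tree)
  is_clade <- function(p) {
    want <- sort(unname(which(pops == p)))
    if (length(want) == 1L) return(TRUE)  # a single tip is trivially a clade
    any(vapply(sets, function(s) identical(s, want), TRUE))
  }
  mono <- is_clade(lev[1L]) + is_clade(lev[2L])
  c("polyphyly", "paraphyly", "reciprocal_monophyly")[mono + 1L]
}
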