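# Operations on species networks: ultrametricity check, unit conversion,
# per-branch attribute assignment.

# All root-to-node path lengths (root at 0, increasing tipward), one entry per
# distinct path through the DAG. Returns a list indexed by node.
node_path_depths <- function(net) {
  if (any(is.na(net$edges$length)) && nrow(net$edges)) {
    stop("all branch lengths must be set", call. = FALSE)
  }
  nn <- length(net$labels)
  depths <- vector("list", nn)
  depths[[net$root]] <- 0
  ord <- rev(network_topo_order(net))  # root first
  for (v in ord) {
    rows <- which(net$edges$parent == v)
    for (r in rows) {
      ch <- net$edges$child[r]
      depths[[ch]] <- c(depths[[ch]], depths[[v]] + net$edges$length[r])
    }
  }
  depths
}

#' Check that a species network is ultrametric
#'
#' Computes the length of every root-to-tip path (hybrid nodes give several
#' paths per tip) and compares each against the maximum. Simulation only
#' requires ultrametricity approximately; deviations produce warnings, not
#' errors, and simulation proceeds regardless.
#'
#' @param net a `species_network` with all branch lengths set.
#' @param tolerance allowed relative deviation from the maximum root-to-tip
#'   path length (relative to that maximum; absolute when the maximum is 0).
#' @return a character vector of warning messages, one per deviating
#'   root-to-tip path; empty for ultrametric networks.
#' @examples
#' check_ultrametric(parse_network("(A:1,B:1);"))   # character(0)
#' check_ultrametric(parse_network("(A:1,B:2);"))   # names tip A
#' @export
check_ultrametric <- function(net, tolerance = 1e-6) {
  stopifnot(inherits(net, "species_network"))
  depths <- node_path_depths(net)
  tips <- which(net$is_tip)
  all_d <- unlist(depths[tips])
  if (!length(all_d)) return(character(0))
  mx <- max(all_d)
  tol_abs <- if (mx > 0) tolerance * mx else tolerance
  out <- character(0)
  for (v in tips) {
    for (d in depths[[v]]) {
      if (abs(d - mx) > tol_abs) {
        out <- c(out, sprintf(
          "root-to-tip path to '%s' has length %.6g but the deepest tip is at %.6g",
          net$labels[v], d, mx))
      }
    }
  }
  out
}

# generations-per-coalescent-unit factor for each edge, given the network's
# timescale convention ("linear": N everywhere; "alpha": N^(alpha-1) on
# Beta-coalescent branches).
edge_gen_factor <- function(pop_size, param, timescale) {
  fam <- vapply(param, function(v) as_coalescent_parameter(v)$family, "")
  ifelse(timescale == "alpha" & fam == "beta", pop_size^(param - 1), pop_size)
}

#' Convert branch lengths between generations and coalescent units
#'
#' For a network tagged as being in generations, divides each branch length by
#' that branch's effective population size `N` to obtain coalescent units (and
#' conversely multiplies when the network is in coalescent units). On a branch
#' carrying a Beta-coalescent parameter `alpha`, the timescale of the process
#' is proportional to `N^(alpha - 1)`; with `alpha_timescale = TRUE` that
#' power of `N` is used as the divisor on such branches. The default uses
#' plain `N` on every branch. The choice is remembered by the network so that
#' generation-scaled simulation output inverts the conversion exactly.
#'
#' @param net a `species_network`.
#' @param pop_size optional population sizes to assign first (scalar, or a
#'   Newick specification as in [set_branch_attributes()]).
#' @param alpha_timescale logical; use `N^(alpha - 1)` on Beta-coalescent
#'   branches (default `FALSE`, plain division by `N`).
#' @return the network with converted branch lengths and the unit tag flipped.
#' @examples
#' net <- parse_network("(A:10000,B:10000);", unit = "generations")
#' convert_units(net, pop_size = 10000)$edges$length  # 1 1
#' @export
convert_units <- function(net, pop_size = NULL, alpha_timescale = FALSE) {
  stopifnot(inherits(net, "species_network"))
  if (!is.null(pop_size)) {
    net <- set_branch_attributes(net, pop_size, what = "pop_size")
  }
  if (any(is.na(net$edges$pop_size)) || any(net$edges$pop_size <= 0)) {
    stop("every branch needs a positive population size", call. = FALSE)
  }
  net$timescale <- if (alpha_timescale) "alpha" else "linear"
  f <- edge_gen_factor(net$edges$pop_size, net$edges$param, net$timescale)
  if (net$unit == "generations") {
    net$edges$length <- net$edges$length / f
    net$unit <- "coalescent"
  } else {
    net$edges$length <- net$edges$length * f
    net$unit <- "generations"
  }
  net
}

# A matching key per node: its label when present, otherwise the sorted set of
# descendant tip labels.
node_match_keys <- function(net) {
  nn <- length(net$labels)
  sets <- vector("list", nn)
  for (v in network_topo_order(net)) {
    if (net$is_tip[v]) {
      sets[[v]] <- net$labels[v]
    } else {
      kids <- net$edges$child[net$edges$parent == v]
      sets[[v]] <- sort(unique(unlist(sets[kids])), method = "radix")
    }
  }
  ifelse(nzchar(net$labels), net$labels,
         vapply(sets, paste, "", collapse = ","))
}

#' Assign coalescent parameters or population sizes to branches
#'
#' A scalar value is applied to every branch (and to the population above the
#' root). Alternatively, a Newick string with the same topology as `net`
#' carries per-branch values in the branch-length positions; branches are
#' matched by node label where present and by descendant tip set otherwise.
#'
#' Coalescent parameter values dispatch by the rule documented in
#' [coalescent_parameter()]: `(0, 1]` selects the psi point-mass coalescent,
#' `(1, 2)` the Beta(2-alpha, alpha)-coalescent, and `0`, `2` or unset the
#' Kingman coalescent.
#'
#' @param net a `species_network`.
#' @param value a single number, or an (extended) Newick string / parsed
#'   `species_network` whose branch lengths hold the per-branch values.
#' @param what which attribute to set: `"coalescent_param"` or `"pop_size"`.
#' @return the network with the attribute set.
#' @examples
#' net <- parse_network("(A:1,B:1);")
#' net <- set_branch_attributes(net, 1.9, "coalescent_param")
#' net <- set_branch_attributes(net, "(A:0.1,B:0.2);", "coalescent_param")
#' @export
set_branch_attributes <- function(net, value,
                                  what = c("coalescent_param", "pop_size")) {
  stopifnot(inherits(net, "species_network"))
  what <- match.arg(what)
  col <- if (what == "pop_size") "pop_size" else "param"
  validate <- function(v, where) {
    if (what == "pop_size") {
      if (any(is.na(v) | v <= 0)) {
        stop("population sizes must be positive (", where, ")", call. = FALSE)
      }
    } else {
      for (x in v) as_coalescent_parameter(x)  # range check
    }
  }
  if (is.numeric(value) && length(value) == 1L) {
    validate(value, "scalar")
    net$edges[[col]] <- rep(value, nrow(net$edges))
    if (what == "pop_size") net$root_pop_size <- value else net$root_param <- value
    return(net)
  }
  spec <- if (inherits(value, "species_network")) value
          else parse_spec_network(value)
  keys <- node_match_keys(net)
  skeys <- node_match_keys(spec)
  ekey <- paste(keys[net$edges$child], keys[net$edges$parent], sep = " -> ")
  sekey <- paste(skeys[spec$edges$child], skeys[spec$edges$parent], sep = " -> ")
  idx <- match(ekey, sekey)
  if (anyNA(idx)) {
    stop("branch attribute specification does not match the network topology: ",
         "no branch '", ekey[which(is.na(idx))[1L]], "' in the specification",
         call. = FALSE)
  }
  vals <- spec$edges$length[idx]
  if (anyNA(vals)) {
    stop("specification is missing a value for branch '",
         ekey[which(is.na(vals))[1L]], "'", call. = FALSE)
  }
  validate(vals, "per-branch values")
  net$edges[[col]] <- vals
  if (!is.na(spec$root_stem)) {
    validate(spec$root_stem, "root value")
    if (what == "pop_size") net$root_pop_size <- spec$root_stem
    else net$root_param <- spec$root_stem
  }
  net
}

# Parse an attribute-specification string; hybrid gamma tags in it are
# irrelevant (branch lengths carry the values), so missing symbolic gammas
# default silently.
parse_spec_network <- function(text) {
  s <- gsub("[\r\n\t ]+", "", paste(text, collapse = ""))
  # reuse the main parser but tolerate symbolic hybrid tags without gamma
  tryCatch(parse_network(s), error = function(e) {
    if (grepl("no inheritance probability", conditionMessage(e))) {
      # re-parse marking every symbolic tag with gamma 0.5 (value unused)
      tags <- unique(unlist(regmatches(s, gregexpr("#[A-Za-z][A-Za-z0-9_]*", s))))
      g <- rep(0.5, length(tags))
      names(g) <- sub("^#", "", tags)
      parse_network(s, gamma = g)
    } else {
      stop(e)
    }
  })
}
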