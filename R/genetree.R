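# Gene trees: rooted genealogies with node heights carried in two time
# scalings (coalescent units and generations). Multiple mergers appear as
# multifurcating nodes. Tips are numbered 1..n_tip and sit at height 0.

new_gene_tree <- function(parent, h_coal, h_gen, tip_labels, species, mu = NULL,
                          children = NULL) {
  structure(list(
    n_tip = length(tip_labels),
    tip_labels = tip_labels,
    species = species,       # species of origin, one per tip
    parent = parent,         # 0 at the root
    h_coal = h_coal,
    h_gen = h_gen,
    children = children,     # explicit child order (optional; else by index)
    mu = mu
  ), class = "gene_tree")
}

gene_tree_children <- function(tree) {
  if (!is.null(tree$children)) return(tree$children)
  n <- length(tree$parent)
  unname(split(seq_len(n)[tree$parent != 0],
               factor(tree$parent[tree$parent != 0], levels = seq_len(n))))
}

gene_tree_root <- function(tree) which(tree$parent == 0L)

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("Gene tree with %d tip(s), %d node(s); TMRCA %.4g coalescent units\n",
              x$n_tip, length(x$parent), max(x$h_coal)))
  cat("  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Write a gene tree as a Newick string
#'
#' Interior nodes are left unlabelled; multiple mergers are written as
#' polytomies. Branch lengths are taken from the requested time scaling:
#' coalescent units, generations, or expected numbers of mutations
#' (generations times the per-generation mutation rate `mu`).
#'
#' @param tree a `gene_tree`.
#' @param scaling one of `"coalescent"`, `"generations"`,
#'   `"expected_mutations"`.
#' @param mu per-generation mutation rate; required for the
#'   `"expected_mutations"` scaling (defaults to the rate attached by
#'   [rescale_tree()], if any).
#' @param digits significant digits for branch lengths.
#' @return a Newick string ending in `;`.
#' @export
write_newick <- function(tree, scaling = c("coalescent", "generations",
                                           "expected_mutations"),
                         mu = tree$mu, digits = 6) {
  stopifnot(inherits(tree, "gene_tree"))
  scaling <- match.arg(scaling)
  h <- switch(scaling,
    coalescent = tree$h_coal,
    generations = tree$h_gen,
    expected_mutations = {
      if (is.null(mu)) {
        stop("a mutation rate 'mu' is required for the expected_mutations scaling",
             call. = FALSE)
      }
      tree$h_gen * mu
    })
  newick_from_heights(tree, h, digits)
}

newick_from_heights <- function(tree, h, digits, lengths = NULL) {
  ch <- gene_tree_children(tree)
  fmt <- function(x) formatC(x, digits = digits, format = "g", width = 1)
  rec <- function(i) {
    lab <- if (i <= tree$n_tip) tree$tip_labels[i] else ""
    body <- if (length(ch[[i]])) {
      paste0("(", paste(vapply(ch[[i]], rec, ""), collapse = ","), ")", lab)
    } else {
      lab
    }
    if (tree$parent[i] == 0L) return(body)
    len <- if (is.null(lengths)) h[tree$parent[i]] - h[i] else lengths[i]
    paste0(body, ":", fmt(len))
  }
  paste0(rec(gene_tree_root(tree)), ";")
}

#' Read a gene tree from a Newick string
#'
#' Inverse of [write_newick()] for plain (hybrid-free) rooted trees. Node
#' heights are reconstructed from root-to-node depths, placing the deepest tip
#' at height 0. When the string carries no branch lengths at all, every branch
#' is given length 1. The species of origin of each tip is taken as the part
#' of its label before a trailing `_<number>` (so `a_1` belongs to species
#' `a`); labels without such a suffix are their own species.
#'
#' @param text a Newick string.
#' @return a `gene_tree` (heights identical in both time scalings).
#' @examples
#' read_gene_tree("((a_1:1,a_2:1):1,b_1:2);")
#' @export
read_gene_tree <- function(text) {
  net <- parse_network(text)
  if (any(net$is_hybrid)) stop("gene trees cannot contain hybrid nodes", call. = FALSE)
  if (all(is.na(net$edges$length)) && nrow(net$edges)) {
    net$edges$length <- 1
  }
  if (any(is.na(net$edges$length))) {
    stop("either all or none of the branch lengths may be omitted", call. = FALSE)
  }
  nn <- length(net$labels)
  depth <- numeric(nn)
  for (v in rev(network_topo_order(net))) {
    rows <- which(net$edges$parent == v)
    depth[net$edges$child[rows]] <- depth[v] + net$edges$length[rows]
  }
  height <- max(depth) - depth
  tips <- which(net$is_tip)
  # renumber: tips 1..n, internals after, in node-table order
  internals <- setdiff(seq_len(nn), tips)
  newid <- integer(nn)
  newid[tips] <- seq_along(tips)
  newid[internals] <- length(tips) + seq_along(internals)
  parent <- integer(nn)
  parent[newid[net$edges$child]] <- newid[net$edges$parent]
  h <- numeric(nn)
  h[newid] <- height
  # preserve the child order of the input string (edges are in string order)
  children <- rep(list(integer(0)), nn)
  for (r in seq_len(nrow(net$edges))) {
    p <- newid[net$edges$parent[r]]
    children[[p]] <- c(children[[p]], newid[net$edges$child[r]])
  }
  labs <- net$labels[tips]
  species <- sub("_[0-9]+$", "", labs)
  new_gene_tree(parent, h, h, labs, species, children = children)
}

#' Attach a mutation rate to a gene tree
#'
#' Gene trees already carry branch lengths in coalescent units and in
#' generations (accumulated branch by branch through the species network
#' during simulation, so population-size changes across populations are
#' respected). This attaches the per-generation mutation rate used for the
#' expected-mutations scaling: each branch's expected number of mutations is
#' its length in generations times `mu`.
#'
#' @param tree a `gene_tree`.
#' @param mu per-generation mutation rate (non-negative).
#' @return the tree with `mu` attached.
#' @export
rescale_tree <- function(tree, mu) {
  stopifnot(inherits(tree, "gene_tree"))
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0) {
    stop("'mu' must be a single non-negative number", call. = FALSE)
  }
  tree$mu <- mu
  tree
}

# Set of tip indices below each node (list over all nodes).
gene_tree_tip_sets <- function(tree) {
  n <- length(tree$parent)
  ch <- gene_tree_children(tree)
  sets <- vector("list", n)
  # children always have smaller heights; process by increasing height
  for (i in order(tree$h_coal)) {
    sets[[i]] <- if (i <= tree$n_tip) i else sort(unlist(sets[ch[[i]]]))
  }
  sets
}
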