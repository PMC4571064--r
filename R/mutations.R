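# Infinite-sites mutations: Poisson placement on branches, 0/1 haplotype
# matrices, and mutation-count-labelled Newick output.

#' Place infinite-sites mutations on a gene tree
#'
#' Each branch independently receives a Poisson number of mutations with mean
#' `mu` times the branch length in generations. Under the infinitely-many-sites
#' model every mutation hits a new site. No mutations are placed above the
#' grand most recent common ancestor, so the ancestral state (0) is known for
#' every site. Uses R's global random number generator.
#'
#' @param tree a `gene_tree` (carries a generations scaling from simulation).
#' @param mu per-generation mutation rate (non-negative).
#' @return an object of class `mutation_placement`: a list with `counts`
#'   (integer vector indexed by tree node, giving the number of mutations on
#'   the branch above that node; 0 for the root) and `mu`.
#' @export
place_mutations <- function(tree, mu) {
  stopifnot(inherits(tree, "gene_tree"))
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0) {
    stop("'mu' must be a single non-negative number", call. = FALSE)
  }
  if (is.null(tree$h_gen)) stop("tree has no generations scaling", call. = FALSE)
  n <- length(tree$parent)
  len_gen <- ifelse(tree$parent == 0L, 0,
                    tree$h_gen[pmax(tree$parent, 1L)] - tree$h_gen)
  counts <- integer(n)
  nz <- which(len_gen > 0 & mu > 0)
  counts[nz] <- stats::rpois(length(nz), mu * len_gen[nz])
  structure(list(counts = counts, mu = mu), class = "mutation_placement")
}

#' 0/1 haplotype matrix from placed mutations
#'
#' Each mutation becomes one column of a binary matrix with one row per
#' sampled tip; tips descending from the mutated branch carry 1, all others 0
#' (0 is the ancestral state). Since mutations are only placed below the grand
#' most recent common ancestor, every column is segregating: it has at least
#' one 0 and one 1. Columns are ordered oldest mutation first (by the height
#' of the node above the mutated branch, ties broken by node index); the
#' mutations of one branch are adjacent.
#'
#' @param tree a `gene_tree`.
#' @param placement a `mutation_placement` from [place_mutations()].
#' @return an integer matrix of class `haplotype_matrix` with the tip labels
#'   as row names and an attribute `populations` giving each tip's species of
#'   origin.
#' @export
haplotypes <- function(tree, placement) {
  stopifnot(inherits(tree, "gene_tree"), inherits(placement, "mutation_placement"))
  if (length(placement$counts) != length(tree$parent)) {
    stop("placement does not match the tree", call. = FALSE)
  }
  mutated <- which(placement$counts > 0L & tree$parent != 0L)
  # oldest first: branches hanging from higher parents come first
  mutated <- mutated[order(-tree$h_coal[tree$parent[mutated]], mutated)]
  sets <- gene_tree_tip_sets(tree)
  ncols <- sum(placement$counts[mutated])
  m <- matrix(0L, nrow = tree$n_tip, ncol = ncols,
              dimnames = list(tree$tip_labels, NULL))
  at <- 0L
  for (b in mutated) {
    for (j in seq_len(placement$counts[b])) {
      at <- at + 1L
      m[sets[[b]], at] <- 1L
    }
  }
  structure(m, populations = stats::setNames(tree$species, tree$tip_labels),
            class = c("haplotype_matrix", class(m)))
}

#' Newick string with per-branch mutation counts
#'
#' Writes the genealogy in Newick format with each branch's simulated mutation
#' count in the branch-length position, e.g. `(a_1:3,b_1:1);` for three
#' mutations on the branch above `a_1` and one above `b_1`.
#'
#' @inheritParams haplotypes
#' @return a Newick string.
#' @export
label_tree_with_mutations <- function(tree, placement) {
  stopifnot(inherits(tree, "gene_tree"), inherits(placement, "mutation_placement"))
  if (length(placement$counts) != length(tree$parent)) {
    stop("placement does not match the tree", call. = FALSE)
  }
  newick_from_heights(tree, tree$h_coal, digits = 12,
                      lengths = placement$counts)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("Haplotype matrix: %d sample(s) x %d segregating site(s)\n",
              nrow(x), ncol(x)))
  pops <- attr(x, "populations")
  if (!is.null(pops)) {
    cat("  populations:", paste(sprintf("%s (n=%d)", names(table(pops)), table(pops)),
                                collapse = ", "), "\n")
  }
  if (ncol(x)) {
    for (i in seq_len(min(nrow(x), 12L))) {
      cat(" ", rownames(x)[i], paste(x[i, ], collapse = ""), "\n")
    }
    if (nrow(x) > 12L) cat("  ...\n")
  }
  invisible(x)
}
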