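# Simulation of gene genealogies within a species tree or network.
#
# Lineages enter the network at the sampled tips, coalesce within each branch
# according to that branch's coalescent parameter, are pooled where branches
# join, are routed independently at hybrid nodes with the branch inheritance
# probabilities, and finish coalescing above the root under the root
# population's parameter. Lineages that fail to coalesce by the top of a
# branch are handed intact to the parent branch (censored coalescent).

# Precompute everything reusable across replicates.
prepare_network <- function(net) {
  if (net$unit != "coalescent") {
    stop("branch lengths are in generations; convert with convert_units() first",
         call. = FALSE)
  }
  if (any(is.na(net$edges$length)) && nrow(net$edges)) {
    stop("all branch lengths must be set before simulating", call. = FALSE)
  }
  nn <- length(net$labels)
  E <- net$edges
  ord <- network_topo_order(net)
  parent_edges <- split(seq_len(nrow(E)), factor(E$child, levels = seq_len(nn)))
  fam <- vapply(E$param, function(v) as_coalescent_parameter(v)$family, "")
  f <- edge_gen_factor(E$pop_size, E$param, net$timescale)
  root_p <- as_coalescent_parameter(net$root_param)
  root_f <- edge_gen_factor(net$root_pop_size, net$root_param, net$timescale)

  # node heights (coalescent units and generations), tips at 0; in a
  # non-ultrametric network the deeper path wins (max rule)
  h <- numeric(nn); g <- numeric(nn)
  for (v in ord) {
    rows <- which(E$parent == v)
    if (length(rows)) {
      h[v] <- max(h[E$child[rows]] + E$length[rows])
      g[v] <- max(g[E$child[rows]] + E$length[rows] * f[rows])
    }
  }

  list(nn = nn, order = ord, root = net$root,
       e_parent = E$parent, e_len = E$length, e_gamma = E$gamma,
       e_fam = fam, e_val = E$param, e_f = f,
       parent_edges = parent_edges,
       root_fam = root_p$family, root_val = root_p$value, root_f = root_f,
       h = h, g = g,
       is_tip = net$is_tip, labels = net$labels)
}

#' Simulate gene genealogies within a species network
#'
#' Simulates `n` independent gene trees for the given per-species sample
#' sizes. Within each branch the coalescent specified by that branch's
#' parameter runs for the branch's duration; at hybrid nodes each lineage
#' independently chooses the left parental population with the branch's
#' inheritance probability; above the root the root population's parameter
#' applies until the grand most recent common ancestor. Multiple-merger events
#' produce multifurcating nodes. Uses R's global random number generator.
#'
#' Non-ultrametric networks are simulated after a warning (all sampled tips
#' are still placed at the present).
#'
#' @param net a validated `species_network` in coalescent units.
#' @param samples sample sizes: a single count applied to every tip species,
#'   or a vector named by tip label. Species with count 0 are skipped.
#' @param n number of replicate genealogies.
#' @param warn_ultrametric check ultrametricity and emit warnings (once).
#' @return for `simulate_gene_trees` a list of `n` objects of class
#'   `gene_tree`; tip labels are `<species>_<index>` (`a_1`, `a_2`, ...).
#' @examples
#' net <- parse_network("(A:1,B:1);")
#' set.seed(1)
#' trees <- simulate_gene_trees(net, samples = 2, n = 3)
#' write_newick(trees[[1]])
#' @export
simulate_gene_trees <- function(net, samples, n = 1, warn_ultrametric = TRUE) {
  stopifnot(inherits(net, "species_network"))
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer", call. = FALSE)
  tips <- network_tips(net)
  if (length(samples) == 1L && is.null(names(samples))) {
    samples <- stats::setNames(rep(as.integer(samples), length(tips)), tips)
  }
  if (!all(names(samples) %in% tips)) {
    stop("unknown species in 'samples': ",
         paste(setdiff(names(samples), tips), collapse = ", "), call. = FALSE)
  }
  counts <- stats::setNames(integer(length(tips)), tips)
  counts[names(samples)] <- as.integer(samples)
  if (any(counts < 0) || sum(counts) < 1L) {
    stop("sample sizes must be non-negative and sum to at least 1", call. = FALSE)
  }
  if (warn_ultrametric && nrow(net$edges)) {
    for (w in check_ultrametric(net)) warning(w, call. = FALSE)
  }
  prep <- prepare_network(net)
  lapply(seq_len(n), function(i) sim_one_tree(prep, counts))
}

#' @rdname simulate_gene_trees
#' @export
simulate_gene_tree <- function(net, samples, warn_ultrametric = TRUE) {
  simulate_gene_trees(net, samples, n = 1, warn_ultrametric = warn_ultrametric)[[1L]]
}

# One replicate. `counts` is named by tip label in network tip order.
sim_one_tree <- function(prep, counts) {
  nt <- sum(counts)
  maxn <- 2L * nt
  parent <- integer(maxn)
  h <- numeric(maxn)
  g <- numeric(maxn)
  nxt <- nt + 1L

  # tip ids per species, in network tip order
  tip_nodes <- which(prep$is_tip)
  tip_ids <- vector("list", prep$nn)
  labels <- character(nt)
  species <- character(nt)
  at <- 0L
  for (v in tip_nodes) {
    cnt <- counts[[prep$labels[v]]]
    if (cnt > 0L) {
      ids <- at + seq_len(cnt)
      tip_ids[[v]] <- ids
      labels[ids] <- paste0(prep$labels[v], "_", seq_len(cnt))
      species[ids] <- prep$labels[v]
      at <- at + cnt
    }
  }

  # coalesce `L` within a branch starting at (t0, g0) for `dur` coalescent
  # units under (fam, val); `f` converts coalescent time to generations
  branch <- function(L, t0, g0, dur, fam, val, f) {
    b <- length(L)
    t <- t0
    while (b >= 2L) {
      rates <- rates_vector(b, fam, val)
      w <- stats::rexp(1L, sum(rates))
      if (w > dur - (t - t0)) break
      t <- t + w
      k <- if (b == 2L || fam == "kingman") 2L
           else sample.int(b - 1L, 1L, prob = rates) + 1L
      idx <- if (k == b) seq_len(b) else sample.int(b, k)
      node <- nxt; nxt <<- nxt + 1L
      parent[L[idx]] <<- node
      h[node] <<- t
      g[node] <<- g0 + (t - t0) * f
      L <- c(L[-idx], node)
      b <- b - k + 1L
    }
    L
  }

  arrivals <- vector("list", prep$nn)
  for (v in prep$order) {
    L <- c(arrivals[[v]], tip_ids[[v]])
    if (v == prep$root) {
      root_lineage <- branch(L, prep$h[v], prep$g[v], Inf,
                             prep$root_fam, prep$root_val, prep$root_f)
    } else {
      pe <- prep$parent_edges[[v]]
      parts <- if (length(pe) == 2L) {
        left <- stats::runif(length(L)) < prep$e_gamma[pe[1L]]
        list(L[left], L[!left])
      } else {
        list(L)
      }
      for (j in seq_along(pe)) {
        e <- pe[j]
        out <- branch(parts[[j]], prep$h[v], prep$g[v], prep$e_len[e],
                      prep$e_fam[e], prep$e_val[e], prep$e_f[e])
        pv <- prep$e_parent[e]
        arrivals[[pv]] <- c(arrivals[[pv]], out)
      }
    }
  }

  used <- nxt - 1L
  new_gene_tree(parent[seq_len(used)], h[seq_len(used)], g[seq_len(used)],
                labels, species)
}

#' Coalesce a set of lineages within one branch
#'
#' Runs a single-branch coalescent: exponential waiting times with the total
#' merger rate, merger sizes proportional to the merger-size rates, and
#' uniformly random participant subsets. Events beyond `duration` are censored
#' and the surviving lineages returned; with `duration = Inf` the process runs
#' until one lineage remains.
#'
#' @param lineages vector of lineage identifiers (any atomic labels).
#' @param duration branch duration in coalescent units (`Inf` allowed).
#' @param param a [coalescent_parameter()] or bare numeric.
#' @return a list with `survivors` (lineage labels, newly created ancestors
#'   are labelled `"anc<i>"`) and `events`, a list of records with fields
#'   `time` (since the branch bottom), `k`, and `participants`.
#' @export
simulate_within_branch <- function(lineages, duration, param = NULL) {
  if (duration < 0) stop("'duration' must be non-negative", call. = FALSE)
  p <- as_coalescent_parameter(param)
  L <- as.character(lineages)
  t <- 0
  events <- list()
  i <- 0L
  while (length(L) >= 2L) {
    ev <- sample_event(L, p)
    if (t + ev$waiting_time > duration) break
    t <- t + ev$waiting_time
    i <- i + 1L
    anc <- paste0("anc", i)
    events[[i]] <- list(time = t, k = ev$k, participants = ev$participants)
    L <- c(setdiff(L, ev$participants), anc)
  }
  list(survivors = L, events = events)
}

#' Route lineages at a hybrid node
#'
#' Each lineage independently derives from the left parental population with
#' probability `gamma`, otherwise from the right; the two returned sets
#' partition the input.
#'
#' @param lineages vector of lineage identifiers.
#' @param gamma inheritance probability of the left parental population, in
#'   `[0, 1]`.
#' @return a list with components `left` and `right`.
#' @export
route_lineages <- function(lineages, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("'gamma' must lie in [0, 1]", call. = FALSE)
  }
  left <- stats::runif(length(lineages)) < gamma
  list(left = lineages[left], right = lineages[!left])
}
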