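# (Extended) Newick parsing into a rooted species network.
#
# Hybrid nodes follow the Cardona-style `#` convention: the same hybrid label
# appears twice in the string and both occurrences resolve to a single node
# with two parent edges. Two dialects for the inheritance probability gamma
# are accepted: a symbolic tag (`h1#H1`, gamma supplied via the `gamma`
# argument) and an inline numeric tag (`h_2#.5`, gamma bound to the parent
# edge encountered first in a left-to-right scan of the string).

#' Parse an (extended) Newick species tree or network
#'
#' Parses a rooted species tree or hybridization network. Internal node labels
#' are kept; the two occurrences of a hybrid label (the name before `#`) are
#' merged into one node with two parent edges. An inheritance probability
#' written inline after `#` (e.g. `h_2#.5`) is stored as gamma for the
#' first-listed ("left") parent edge and `1 - gamma` for the other; for a
#' symbolic tag (e.g. `h1#H1`) gamma must be supplied through the `gamma`
#' argument, named by the tag.
#'
#' Every branch starts with the default attributes: effective population size
#' 1 and the Kingman coalescent; see [set_branch_attributes()] to override.
#'
#' @param text a single (extended) Newick string, ending in `;`.
#' @param gamma named numeric vector giving the inheritance probability for
#'   each symbolic hybrid tag (e.g. `c(H1 = 0.6)`); each value is the
#'   probability that a lineage at the hybrid node has its ancestry from the
#'   left (first-encountered) parental population.
#' @param unit unit of the branch lengths in the string: `"coalescent"`
#'   (default) or `"generations"` (convert with [convert_units()] before
#'   simulating).
#' @return an object of class `species_network`: a rooted DAG with fields
#'   `labels`, `is_tip`, `is_hybrid`, `root`, and an `edges` data frame with
#'   columns `parent`, `child`, `length`, `pop_size`, `param`, `gamma`.
#' @examples
#' net <- parse_network("((((B,C)s1)h1#H1,A)s2,(h1#H1,D)s3)r;", gamma = c(H1 = 0.6))
#' net
#' parse_network("(A:1,B:1);")
#' @seealso [read_network()] to read from a file, [check_ultrametric()],
#'   [simulate_gene_trees()]
#' @export
parse_network <- function(text, gamma = NULL, unit = c("coalescent", "generations")) {
  unit <- match.arg(unit)
  s <- gsub("[\r\n\t ]+", "", paste(text, collapse = ""))
  if (!nzchar(s)) stop("empty Newick string", call. = FALSE)
  if (substr(s, nchar(s), nchar(s)) != ";") {
    stop("Newick string must end in ';'", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L
  occ <- list()           # one record per occurrence in the string
  parent_occ <- integer() # occurrence index of the enclosing clade

  perr <- function(msg) {
    stop(sprintf("parse error at position %d ('%s'): %s",
                 pos, if (pos <= n) chars[pos] else "<end>", msg), call. = FALSE)
  }
  peek <- function() if (pos <= n) chars[pos] else ""
  label_chars <- c(LETTERS, letters, 0:9, "_", ".", "#", "-", "+", "'")
  read_label <- function() {
    start <- pos
    while (pos <= n && chars[pos] %in% label_chars) pos <<- pos + 1L
    if (pos > start) substr(s, start, pos - 1L) else ""
  }
  read_number <- function() {
    start <- pos
    while (pos <= n && (chars[pos] %in% c(0:9, ".", "-", "+", "e", "E"))) pos <<- pos + 1L
    x <- suppressWarnings(as.numeric(substr(s, start, pos - 1L)))
    if (pos == start || is.na(x)) { pos <<- start; perr("expected a branch length") }
    x
  }
  parse_clade <- function() {
    start_pos <- pos
    kids <- integer(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids <- c(kids, parse_clade())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        perr("expected ',' or ')'")
      }
    }
    lab <- read_label()
    if (!length(kids) && !nzchar(lab)) perr("expected a taxon label or '('")
    len <- NA_real_
    if (peek() == ":") { pos <<- pos + 1L; len <- read_number() }
    id <- length(occ) + 1L
    occ[[id]] <<- list(label = lab, length = len, kids = kids, pos = start_pos)
    for (k in kids) parent_occ[k] <<- id
    parent_occ[id] <<- NA_integer_
    id
  }

  root_occ <- parse_clade()
  if (peek() != ";") perr("expected ';'")
  if (pos != n) perr("trailing characters after ';'")

  build_network(occ, parent_occ, root_occ, gamma, unit)
}

# Assemble the node/edge tables from parsed occurrences, merging hybrids.
build_network <- function(occ, parent_occ, root_occ, gamma, unit,
                          allow_missing_gamma = FALSE) {
  labs <- vapply(occ, `[[`, "", "label")
  lens <- vapply(occ, `[[`, 0, "length")
  poss <- vapply(occ, `[[`, 0L, "pos")
  if (any(!is.na(lens) & lens < 0)) {
    stop("negative branch length in input", call. = FALSE)
  }
  has_tag <- grepl("#", labs, fixed = TRUE)
  name_part <- sub("#.*$", "", labs)
  tag_part <- ifelse(has_tag, sub("^[^#]*#", "", labs), NA_character_)

  # node key: hybrids merge on the name before '#'
  key <- ifelse(has_tag & nzchar(name_part), name_part,
                ifelse(has_tag, paste0("#", tag_part), NA_character_))

  node_of <- integer(length(occ))
  node_key <- character(0)
  node_label <- character(0)
  node_hybrid <- logical(0)
  for (i in order(poss)) {
    if (has_tag[i] && !is.na(key[i]) && key[i] %in% node_key) {
      node_of[i] <- match(key[i], node_key)
    } else {
      node_key <- c(node_key, if (has_tag[i]) key[i] else NA_character_)
      node_label <- c(node_label, if (has_tag[i]) name_part[i] else labs[i])
      node_hybrid <- c(node_hybrid, has_tag[i])
      node_of[i] <- length(node_key)
    }
  }
  nn <- length(node_key)

  # each hybrid name must appear exactly twice
  for (j in which(node_hybrid)) {
    cnt <- sum(node_of == j & has_tag)
    if (cnt != 2L) {
      stop(sprintf("hybrid label '%s' occurs %d time(s); it must occur exactly twice",
                   node_key[j], cnt), call. = FALSE)
    }
  }
  if (node_hybrid[node_of[root_occ]]) {
    stop("the root cannot be a hybrid node", call. = FALSE)
  }

  dup <- duplicated(node_label) & nzchar(node_label)
  if (any(dup)) {
    stop("duplicate label '", node_label[which(dup)[1]], "' in input", call. = FALSE)
  }

  # edges, ordered by string position of the child occurrence (left first)
  ord <- order(poss)
  ep <- integer(0); ec <- integer(0); el <- numeric(0); eocc <- integer(0)
  for (i in ord) {
    if (is.na(parent_occ[i])) next
    ep <- c(ep, node_of[parent_occ[i]])
    ec <- c(ec, node_of[i])
    el <- c(el, lens[i])
    eocc <- c(eocc, i)
  }

  # inheritance probabilities
  eg <- rep(NA_real_, length(ep))
  for (j in which(node_hybrid)) {
    rows <- which(ec == j)
    if (length(rows) != 2L) {
      stop(sprintf("hybrid node '%s' must have exactly 2 parent edges, found %d",
                   node_key[j], length(rows)), call. = FALSE)
    }
    tags <- tag_part[eocc[rows]]
    vals <- suppressWarnings(as.numeric(tags))
    if (all(!is.na(vals))) {          # inline numeric dialect
      if (abs(sum(vals) - 1) > 1e-9) {
        stop(sprintf("inheritance probabilities of hybrid '%s' sum to %g, not 1",
                     node_key[j], sum(vals)), call. = FALSE)
      }
      g <- vals[1L]
    } else if (all(is.na(vals))) {    # symbolic dialect
      if (tags[1L] != tags[2L]) {
        stop(sprintf("hybrid '%s' carries two different tags ('%s', '%s')",
                     node_key[j], tags[1L], tags[2L]), call. = FALSE)
      }
      if (!is.null(gamma) && tags[1L] %in% names(gamma)) {
        g <- unname(gamma[[tags[1L]]])
      } else if (allow_missing_gamma) {
        g <- 0.5
      } else {
        stop(sprintf(paste0("no inheritance probability supplied for hybrid tag '%s'; ",
                            "pass gamma = c(%s = <left-parent probability>)"),
                     tags[1L], tags[1L]), call. = FALSE)
      }
    } else {
      stop(sprintf("hybrid '%s' mixes inline and symbolic '#' tags", node_key[j]),
           call. = FALSE)
    }
    if (is.na(g) || g < 0 || g > 1) {
      stop(sprintf("inheritance probability of hybrid '%s' must lie in [0, 1], got %g",
                   node_key[j], g), call. = FALSE)
    }
    eg[rows[1L]] <- g
    eg[rows[2L]] <- 1 - g
  }

  n_parents <- tabulate(ec, nn)
  bad <- which(!node_hybrid & n_parents > 1L)
  if (length(bad)) {
    stop(sprintf("non-hybrid node '%s' has %d parent edges",
                 node_label[bad[1L]], n_parents[bad[1L]]), call. = FALSE)
  }

  has_children <- tabulate(ep, nn) > 0L
  is_tip <- !has_children
  if (any(is_tip & !nzchar(node_label))) {
    stop("every tip must be labelled", call. = FALSE)
  }

  net <- structure(list(
    labels = node_label,
    is_tip = is_tip,
    is_hybrid = node_hybrid,
    root = node_of[root_occ],
    edges = data.frame(parent = ep, child = ec, length = el,
                       pop_size = rep(1, length(ep)),
                       param = rep(NA_real_, length(ep)), gamma = eg),
    unit = unit,
    timescale = "linear",
    root_param = NA_real_,
    root_pop_size = 1,
    root_stem = lens[root_occ]
  ), class = "species_network")

  network_topo_order(net)  # errors on cycles / unreachable nodes
  net
}

#' Read a species network from a file
#'
#' @param file path to a file containing one (extended) Newick string.
#' @inheritParams parse_network
#' @inherit parse_network return
#' @export
read_network <- function(file, gamma = NULL, unit = c("coalescent", "generations")) {
  parse_network(paste(readLines(file, warn = FALSE), collapse = ""), gamma, unit)
}

#' Tip labels of a species network
#'
#' @param net a `species_network`.
#' @return character vector of tip (sampled species) labels, in the order the
#'   tips appear in the node table.
#' @export
network_tips <- function(net) {
  stopifnot(inherits(net, "species_network"))
  net$labels[net$is_tip]
}

# Topological order, tips first; validates that the graph is a connected DAG.
network_topo_order <- function(net) {
  nn <- length(net$labels)
  remaining <- tabulate(net$edges$parent, nn)  # unprocessed child edges
  queue <- which(remaining == 0L)              # tips
  ord <- integer(0)
  parents_of <- split(net$edges$parent, factor(net$edges$child, levels = seq_len(nn)))
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (p in parents_of[[v]]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(ord) != nn) {
    stop("species network is not a DAG (cycle through a hybrid node?)", call. = FALSE)
  }
  if (ord[length(ord)] != net$root && nn > 1L) {
    # root must be processed last among its component; reachability check below
  }
  # every node must reach the root
  reach <- logical(nn); reach[net$root] <- TRUE
  for (v in rev(ord)) {
    if (reach[v]) {
      kids <- net$edges$child[net$edges$parent == v]
      reach[kids] <- TRUE
    }
  }
  if (!all(reach)) {
    stop("node '", net$labels[which(!reach)[1L]], "' is not reachable from the root",
         call. = FALSE)
  }
  ord
}

#' @export
print.species_network <- function(x, ...) {
  cat(sprintf("Species %s with %d tip(s)%s\n",
              if (any(x$is_hybrid)) "network" else "tree",
              sum(x$is_tip),
              if (any(x$is_hybrid)) sprintf(" and %d hybrid node(s)", sum(x$is_hybrid)) else ""))
  cat("  tips:", paste(network_tips(x), collapse = ", "), "\n")
  if (any(x$is_hybrid)) {
    for (j in which(x$is_hybrid)) {
      g <- x$edges$gamma[x$edges$child == j][1L]
      cat(sprintf("  hybrid '%s': left-parent inheritance probability %g\n",
                  x$labels[j], g))
    }
  }
  cat(sprintf("  branch lengths in %s units; %d edge(s)\n", x$unit, nrow(x$edges)))
  invisible(x)
}
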