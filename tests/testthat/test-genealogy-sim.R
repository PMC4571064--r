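# Gene-genealogy simulation within trees and networks.

test_that("single-branch coalescent handles trivial and censored cases", {
  set.seed(21)
  expect_equal(simulate_within_branch("x", Inf, NULL)$survivors, "x")
  out <- simulate_within_branch(letters[1:5], 0, 0.5)
  expect_setequal(out$survivors, letters[1:5])
  expect_length(out$events, 0L)
  # 2 lineages, Kingman, unbounded: Exponential(1) coalescence time
  t2 <- replicate(5e3, simulate_within_branch(1:2, Inf, NULL)$events[[1]]$time)
  expect_true(within_se(t2, 1))
})

test_that("the pair marginal of a multiple-merger branch is a rate-1
           coalescent (sampling consistency)", {
  # with pairwise rate lambda_{2,2} = 1, a fixed pair among b = 10 lineages
  # must coalesce within duration tau with probability 1 - exp(-tau)
  set.seed(22)
  n <- 3000
  hit <- 0
  for (r in seq_len(n)) {
    res <- simulate_within_branch(as.character(1:10), 1, 1.5)
    memb <- stats::setNames(as.character(1:10), as.character(1:10))
    i <- 0
    for (ev in res$events) {
      i <- i + 1
      memb[memb %in% ev$participants] <- paste0("anc", i)
    }
    hit <- hit + (memb[["1"]] == memb[["2"]])
  }
  p <- 1 - exp(-1)
  expect_lt(abs(hit / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("hybrid routing partitions lineages with the inheritance probability", {
  set.seed(23)
  expect_equal(route_lineages(1:8, 1)$left, 1:8)
  expect_equal(route_lineages(1:8, 0)$right, 1:8)
  nleft <- sum(replicate(2000, length(route_lineages(1:5, 0.5)$left)))
  p <- nleft / 1e4
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_error(route_lineages(1:3, 1.2), "\\[0, 1\\]")
})

test_that("Kingman genealogies are strictly binary; multiple-merger
           parameters produce multifurcations", {
  net <- parse_network(FIG_NET_LENGTHS, gamma = c(H1 = 0.6))
  set.seed(24)
  samples <- c(A = 3, B = 1, C = 2, D = 1)
  kg <- simulate_gene_trees(net, samples, n = 200)
  n_children <- function(tr) tabulate(tr$parent[tr$parent != 0])
  expect_true(all(vapply(kg, function(tr) all(n_children(tr)[n_children(tr) > 0] == 2), TRUE)))
  psi_net <- set_branch_attributes(net, 0.23, "coalescent_param")
  ps <- simulate_gene_trees(psi_net, samples, n = 1000)
  multi <- vapply(ps, function(tr) any(n_children(tr) > 2), TRUE)
  expect_gt(sum(multi), 0)
})

test_that("lineage conservation and height ordering hold in every replicate", {
  net <- parse_network(FIG_NET_LENGTHS, gamma = c(H1 = 0.6))
  net <- set_branch_attributes(net, 0.23, "coalescent_param")
  set.seed(25)
  trees <- simulate_gene_trees(net, c(A = 3, B = 2, C = 2, D = 2), n = 200)
  for (tr in trees) {
    nch <- tabulate(tr$parent[tr$parent != 0], length(tr$parent))
    internal <- which(nch > 0)
    # tips minus sum(children - 1) over internal nodes leaves one root lineage
    expect_equal(tr$n_tip - sum(nch[internal] - 1L), 1L)
    expect_equal(sum(tr$parent == 0), 1L)
    # child heights strictly below parent heights; tips at zero
    expect_true(all(tr$h_coal[seq_len(tr$n_tip)] == 0))
    nonroot <- which(tr$parent != 0)
    expect_true(all(tr$h_coal[nonroot] < tr$h_coal[tr$parent[nonroot]]))
  }
})

test_that("no coalescence predates the divergence of the populations involved", {
  net <- parse_network("(A:1,B:1);")
  set.seed(26)
  trees <- simulate_gene_trees(net, c(A = 3, B = 3), n = 300)
  for (tr in trees) {
    sets <- lambdanet:::gene_tree_tip_sets(tr)
    for (v in (tr$n_tip + 1L):length(tr$parent)) {
      sp <- unique(tr$species[sets[[v]]])
      if (length(sp) > 1L) expect_gte(tr$h_coal[v], 1)
    }
  }
})

test_that("identical seeds reproduce genealogies exactly", {
  net <- parse_network(BIG_NET)
  net <- set_branch_attributes(net, 1.2, "coalescent_param")
  set.seed(99)
  a <- simulate_gene_trees(net, 2, n = 5)
  set.seed(99)
  b <- simulate_gene_trees(net, 2, n = 5)
  expect_identical(lapply(a, write_newick), lapply(b, write_newick))
})

test_that("mean time to the most recent common ancestor matches the
           single-population Kingman closed form", {
  net <- parse_network("A;")
  set.seed(27)
  tm <- vapply(simulate_gene_trees(net, c(A = 5), n = 4000),
               function(tr) max(tr$h_coal), 0)
  expect_true(within_se(tm, 2 * (1 - 1 / 5)))
})

test_that("generation heights accumulate per-branch population sizes", {
  net <- parse_network("(A:10000,B:10000);", unit = "generations")
  net <- convert_units(net, pop_size = 10000)
  set.seed(28)
  tr <- simulate_gene_tree(net, c(A = 2, B = 2))
  expect_equal(tr$h_gen, tr$h_coal * 10000, tolerance = 1e-12)
  # with the alpha timescale and a Beta parameter the factor is N^(alpha-1)
  nb <- parse_network("(A:100,B:100);", unit = "generations")
  nb <- set_branch_attributes(nb, 1.5, "coalescent_param")
  nb <- convert_units(nb, pop_size = 100, alpha_timescale = TRUE)
  set.seed(29)
  trb <- simulate_gene_tree(nb, c(A = 2, B = 2))
  expect_equal(trb$h_gen, trb$h_coal * 10, tolerance = 1e-12)
  # N = 1 everywhere: all scalings coincide
  n1 <- parse_network("(A:1,B:1);")
  set.seed(30)
  tr1 <- rescale_tree(simulate_gene_tree(n1, c(A = 2, B = 2)), mu = 1)
  expect_identical(tr1$h_gen, tr1$h_coal)
  expect_identical(write_newick(tr1, "expected_mutations"), write_newick(tr1))
})

test_that("non-ultrametric networks simulate after a warning", {
  net <- parse_network("(A:1,B:2);")
  set.seed(31)
  expect_warning(tr <- simulate_gene_tree(net, c(A = 1, B = 1)), "root-to-tip")
  expect_equal(tr$n_tip, 2L)
  expect_gte(max(tr$h_coal), 2)
})

test_that("simulation requires coalescent units and known tips", {
  gen <- parse_network("(A:100,B:100);", unit = "generations")
  expect_error(simulate_gene_trees(gen, 1), "convert_units")
  net <- parse_network("(A:1,B:1);")
  expect_error(simulate_gene_trees(net, c(A = 1, X = 1)), "unknown species")
  expect_error(simulate_gene_trees(net, 0), "at least 1")
})
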