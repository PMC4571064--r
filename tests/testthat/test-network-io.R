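# Parsing, validation, writing, unit conversion, branch attributes.

test_that("a hybridization network with a symbolic gamma tag parses correctly", {
  net <- parse_network(FIG_NET, gamma = c(H1 = 0.6))
  expect_setequal(network_tips(net), c("A", "B", "C", "D"))
  expect_equal(sum(net$is_hybrid), 1L)
  expect_equal(length(net$labels), 9L)  # 4 tips + s1,s2,s3,r + one hybrid
  hy <- which(net$is_hybrid)
  rows <- which(net$edges$child == hy)
  expect_length(rows, 2L)
  expect_equal(net$edges$gamma[rows], c(0.6, 0.4))   # left edge first
  expect_equal(sum(net$edges$gamma[rows]), 1)
  # the two occurrences alias a single node
  expect_equal(sum(net$labels == "h1"), 1L)
})

test_that("the seven-tip network with an inline gamma parses and is ultrametric", {
  net <- parse_network(BIG_NET)
  expect_setequal(network_tips(net), as.character(1:7))
  hy <- which(net$is_hybrid)
  expect_equal(net$labels[hy], "h_2")
  expect_equal(net$edges$gamma[net$edges$child == hy], c(0.5, 0.5))
  expect_length(check_ultrametric(net), 0L)
  # independent path-sum oracle on the printed lengths: every root-to-tip
  # path must equal the depth of tip 5, 8.31 + 0.1 = 8.41
  depths <- lambdanet:::node_path_depths(net)
  tip_depths <- unlist(depths[which(net$is_tip)])
  expect_equal(unname(tip_depths), rep(8.41, length(tip_depths)), tolerance = 1e-12)
})

test_that("plain species trees parse with defaults", {
  net <- parse_network("(A:1,B:1);")
  expect_false(any(net$is_hybrid))
  expect_equal(net$edges$length, c(1, 1))
  expect_equal(net$edges$pop_size, c(1, 1))          # default N = 1
  expect_true(all(is.na(net$edges$param)))           # default Kingman
  expect_equal(net$unit, "coalescent")
  one <- parse_network("A;")
  expect_equal(network_tips(one), "A")
})

test_that("malformed and invalid inputs are rejected with informative errors", {
  expect_error(parse_network("(A:1,B:1)"), "must end in ';'")
  expect_error(parse_network("(A:1,,B:1);"), "position")
  expect_error(parse_network("(A:x,B:1);"), "branch length")
  expect_error(parse_network("((A,B),C));"), "position")
  expect_error(parse_network("(A:-1,B:1);"), "negative")
  expect_error(parse_network(FIG_NET), "inheritance probability")
  expect_error(parse_network(FIG_NET, gamma = c(H1 = 1.3)), "\\[0, 1\\]")
  # a hybrid label occurring three times means three parents
  expect_error(parse_network("((h1#H1,A)x,(h1#H1,B)y,(h1#H1)z)r;",
                             gamma = c(H1 = 0.5)), "exactly twice")
  # inline probabilities that do not sum to one
  expect_error(parse_network("(((A)h1#.6,B)x,((C)h1#.3,D)y)r;"), "sum to")
  expect_error(parse_network("(A:1,A:2);"), "duplicate label")
})

test_that("write/read round-trips preserve topology and branch lengths", {
  set.seed(42)
  for (rep in 1:100) {
    tr <- random_gene_tree(sample(2:10, 1))
    nw <- write_newick(tr, digits = 12)
    back <- read_gene_tree(nw)
    expect_identical(write_newick(back, digits = 12), nw)
    # same canonical topology
    expect_equal(nrow(topology_table(list(tr, back))), 1L)
    # heights agree up to printing precision
    expect_equal(sort(back$h_coal), sort(tr$h_coal), tolerance = 1e-9)
  }
})

test_that("parsing of plain Newick agrees with ape", {
  skip_if_not_installed("ape")
  set.seed(7)
  for (rep in 1:20) {
    phy <- ape::rcoal(sample(3:12, 1))
    nw <- ape::write.tree(phy)
    net <- parse_network(nw)
    expect_equal(sum(net$is_tip), length(phy$tip.label))
    expect_setequal(network_tips(net), phy$tip.label)
    # root-to-tip depths match ape's edge-length accumulation
    dep <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
    mine <- unlist(lambdanet:::node_path_depths(net)[which(net$is_tip)])
    expect_equal(sort(unname(mine)), sort(dep), tolerance = 1e-6)
  }
})

test_that("ultrametricity check warns per deviating root-to-tip path", {
  expect_length(check_ultrametric(parse_network("(A:1,B:1);")), 0L)
  w <- check_ultrametric(parse_network("(A:1,B:2);"))
  expect_length(w, 1L)
  expect_match(w, "'A'")
  # within tolerance: no warning
  expect_length(check_ultrametric(parse_network("(A:1,B:1.0000001);"),
                                  tolerance = 1e-3), 0L)
})

test_that("unit conversion divides by N, optionally by N^(alpha-1) on Beta branches", {
  net <- parse_network("(A:10000,B:10000);", unit = "generations")
  cu <- convert_units(net, pop_size = 10000)
  expect_equal(cu$edges$length, c(1, 1))
  expect_equal(cu$unit, "coalescent")
  # N = 1 is the identity
  id <- convert_units(parse_network("(A:7,B:7);", unit = "generations"))
  expect_equal(id$edges$length, c(7, 7))
  # Beta branch with the alpha timescale: 100 / 100^0.5 = 10
  nb <- parse_network("(A:100,B:100);", unit = "generations")
  nb <- set_branch_attributes(nb, 1.5, "coalescent_param")
  nb <- convert_units(nb, pop_size = 100, alpha_timescale = TRUE)
  expect_equal(nb$edges$length, c(10, 10))
  # converting back with the same N recovers the lengths
  back <- convert_units(nb, alpha_timescale = TRUE)
  expect_equal(back$unit, "generations")
  expect_equal(back$edges$length, c(100, 100), tolerance = 1e-12)
})

test_that("branch attributes are set by scalar or by a matching Newick spec", {
  net <- parse_network("(A:1,B:1);")
  net19 <- set_branch_attributes(net, 1.9, "coalescent_param")
  expect_equal(net19$edges$param, c(1.9, 1.9))
  expect_equal(net19$root_param, 1.9)
  netp <- set_branch_attributes(net, "(A:0.1,B:0.2);", "coalescent_param")
  expect_equal(netp$edges$param[netp$edges$child == which(netp$labels == "A")], 0.1)
  expect_equal(netp$edges$param[netp$edges$child == which(netp$labels == "B")], 0.2)
  # population sizes through the same mechanism
  netN <- set_branch_attributes(net, "(A:100,B:200);", "pop_size")
  expect_equal(sort(netN$edges$pop_size), c(100, 200))
  expect_error(set_branch_attributes(net, "(A:0.1,C:0.2);", "coalescent_param"),
               "does not match")
  expect_error(set_branch_attributes(net, -2, "pop_size"), "positive")
  expect_error(set_branch_attributes(net, 2.5, "coalescent_param"), "\\[0, 2\\]")
  # works on a network with a hybrid node too
  big <- parse_network(BIG_NET)
  bigp <- set_branch_attributes(big, 0.1, "coalescent_param")
  expect_true(all(bigp$edges$param == 0.1))
})

test_that("gene trees are written with the requested scaling", {
  tr <- read_gene_tree("((a_1:1,a_2:1):1,b_1:2);")
  expect_equal(write_newick(tr), "((a_1:1,a_2:1):1,b_1:2);")
  tr$h_gen <- tr$h_coal * 100
  expect_equal(write_newick(tr, "generations"), "((a_1:100,a_2:100):100,b_1:200);")
  expect_equal(write_newick(tr, "expected_mutations", mu = 0.01),
               "((a_1:1,a_2:1):1,b_1:2);")
  expect_error(write_newick(tr, "expected_mutations"), "mu")
  single <- read_gene_tree("a_1;")
  expect_equal(write_newick(single), "a_1;")
})
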