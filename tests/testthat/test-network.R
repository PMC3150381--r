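test_that("hamming distances are computed on unambiguous columns", {
  expect_equal(max(hamming_matrix(c("ACG", "ACG"))), 0L)
  expect_equal(hamming_matrix(c("ACG", "ATG"))[1, 2], 1L)
  expect_equal(hamming_matrix(c("AAA", "TTT"))[1, 2], 3L)
  d <- hamming_matrix(c("AANA", "ATNT"))
  expect_equal(attr(d, "n_excluded_sites"), 1L)
  expect_equal(d[1, 2], 2L)
})

test_that("two haplotypes give a single edge labelled with their distance", {
  net <- median_joining_network(c("AAAA", "ATTA"))
  expect_equal(igraph::vcount(net), 2L)
  expect_equal(igraph::ecount(net), 1L)
  expect_equal(igraph::E(net)$mutations, 2L)
  expect_equal(count_nodes(net), tibble::tibble(observed = 2L, median = 0L))
})

test_that("a mutually connected triangle gains exactly one median node", {
  # pairwise distance 2 between all three; consensus is TTT
  net <- median_joining_network(c("ATT", "TAT", "TTA"))
  expect_equal(count_nodes(net), tibble::tibble(observed = 3L, median = 1L))
  med_state <- igraph::V(net)$state[igraph::V(net)$type == "median"]
  expect_equal(med_state, "TTT")
  # the median is the hub: connected to all three observed haplotypes
  expect_equal(sort(igraph::degree(net)), c(1L, 1L, 1L, 3L),
               ignore_attr = TRUE)
})

test_that("star-shaped data needs no median nodes", {
  center <- "AAAAAA"
  singletons <- c("TAAAAA", "ACAAAA", "AAGAAA", "AAATAA")
  net <- median_joining_network(c(center, singletons))
  expect_equal(count_nodes(net)$median, 0L)
  expect_equal(igraph::ecount(net), 4L)
  deg <- igraph::degree(net)
  expect_equal(unname(deg[igraph::V(net)$state == center]), 4)
})

test_that("empty and singleton inputs are handled", {
  expect_equal(count_nodes(median_joining_network(character())),
               tibble::tibble(observed = 0L, median = 0L))
  one <- median_joining_network("ACGT")
  expect_equal(count_nodes(one), tibble::tibble(observed = 1L, median = 0L))
})

test_that("every edge label equals the Hamming distance of its endpoints", {
  for (seed in 1:4) {
    seqs <- withr::with_seed(seed, {
      k <- sample(4:7, 1)
      vapply(seq_len(k), function(i)
        paste(sample(c("A", "T"), 10, replace = TRUE), collapse = ""), "")
    })
    seqs <- unique(seqs)
    net <- median_joining_network(seqs)
    el <- igraph::as_edgelist(net, names = FALSE)
    states <- igraph::V(net)$state
    for (e in seq_len(nrow(el))) {
      a <- strsplit(states[el[e, 1]], "")[[1]]
      b <- strsplit(states[el[e, 2]], "")[[1]]
      expect_equal(igraph::E(net)$mutations[e], sum(a != b))
      expect_gte(igraph::E(net)$mutations[e], 1L)
    }
    expect_true(igraph::is_connected(net))
  }
})

test_that("the network is invariant under input reordering", {
  seqs <- c("AAAA", "ATTA", "TTTA", "TTTT", "AATA")
  canon <- function(net) {
    el <- igraph::as_edgelist(net, names = FALSE)
    st <- igraph::V(net)$state
    pairs <- apply(el, 1L, function(r) paste(sort(st[r]), collapse = "|"))
    list(edges = sort(pairs), nodes = count_nodes(net),
         states = sort(st))
  }
  n1 <- median_joining_network(seqs)
  n2 <- median_joining_network(rev(seqs))
  expect_equal(canon(n1), canon(n2))
})

test_that("with distinct distances the observed subgraph contains an MST", {
  seqs <- c("AAAAAA", "AAAAAT", "AAATTT", "TTTTTT")
  net <- median_joining_network(seqs)
  obs <- which(igraph::V(net)$type == "observed")
  d <- hamming_matrix(seqs)
  mst_weight <- sum(igraph::E(igraph::mst(
    igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                        mode = "undirected")))$weight)
  # spanning tree within the network between observed nodes can't beat MST
  net_mst <- igraph::mst(net, weights = igraph::E(net)$mutations)
  expect_lte(sum(igraph::E(net_mst)$mutations), mst_weight + 1e-9)
})

test_that("network spanning length sits between Steiner and observed MST", {
  # tiny instances: brute-force Steiner over candidate median states
  cases <- list(
    c("AAAA", "ATTA", "TTTT"),
    c("AATT", "ATAT", "TTAA", "TATA"),
    c("AAA", "TTA", "ATT")
  )
  for (seqs in cases) {
    m <- do.call(rbind, strsplit(seqs, ""))
    candidates <- unique(apply(
      expand.grid(lapply(seq_len(ncol(m)), function(j) unique(m[, j]))),
      1L, paste0, collapse = ""))
    mst_len <- function(states) {
      d <- hamming_matrix(states)
      g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                               mode = "undirected")
      sum(igraph::E(igraph::mst(g))$weight)
    }
    steiner <- mst_len(seqs)
    extras <- setdiff(candidates, seqs)
    for (n_add in 1:min(2, length(extras))) {
      for (sub in utils::combn(extras, n_add, simplify = FALSE)) {
        steiner <- min(steiner, mst_len(c(seqs, sub)))
      }
    }
    net <- median_joining_network(seqs)
    net_tree_len <- sum(igraph::E(
      igraph::mst(net, weights = igraph::E(net)$mutations))$mutations)
    expect_gte(net_tree_len, steiner - 1e-9)
    expect_lte(net_tree_len, mst_len(seqs) + 1e-9)
  }
})
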