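# Weighted network around a fixed embedding so detection stages are testable
# in isolation.
weighted_fixture <- function(ppi, d = 6L, seed = 3L) {
  fd <- withr::with_seed(seed, matrix(rnorm(length(ppi$node_ids) * d),
                                      ncol = d))
  build_weighted_network(ppi, fd)
}

test_that("edge weights are cosines of embedding rows, clamped and guarded", {
  ppi <- path_ppi()
  fd <- rbind(c(1, 0), c(1, 0), c(0, 1))
  gw <- build_weighted_network(ppi, fd)
  expect_equal(gw$wmat["a", "b"], 1)   # identical rows
  expect_equal(gw$wmat["b", "c"], 0)   # orthogonal rows
  # direct formula oracle on random vectors
  fd2 <- withr::with_seed(4, matrix(rnorm(9), 3, 3))
  gw2 <- build_weighted_network(ppi, fd2)
  manual <- sum(fd2[1, ] * fd2[2, ]) / (sqrt(sum(fd2[1, ]^2)) * sqrt(sum(fd2[2, ]^2)))
  expect_equal(gw2$wmat["a", "b"], manual)
  expect_true(all(abs(gw2$weights) <= 1))
  # zero-norm row: weight defined as 0
  fd3 <- rbind(c(1, 1), c(0, 0), c(1, 0))
  gw3 <- build_weighted_network(ppi, fd3)
  expect_equal(gw3$wmat["a", "b"], 0)
})

test_that("maximal cliques match exhaustive subset enumeration", {
  gw <- weighted_fixture(triangle_ppi())
  cl <- enumerate_cliques(gw)
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$members, 1:3)

  k4 <- weighted_fixture(ppi_network(clique_edges(letters[1:4])))
  cl4 <- enumerate_cliques(k4)
  expect_length(cl4, 1L)
  expect_length(cl4[[1L]]$members, 4L)

  for (seed in 1:4) {
    ppi <- random_ppi(12, 0.35, seed = seed)
    gw <- weighted_fixture(ppi)
    got <- lapply(enumerate_cliques(gw), `[[`, "members")
    expect_identical(set_signature(got),
                     set_signature(brute_max_cliques(ppi)))
  }
})

test_that("candidate density is the sum of pairwise cosine weights", {
  gw <- weighted_fixture(triangle_ppi())
  cl <- enumerate_cliques(gw)
  manual <- gw$wmat[1, 2] + gw$wmat[1, 3] + gw$wmat[2, 3]
  expect_equal(cl[[1L]]$density, manual)
})

test_that("seed selection strips overlap and keeps only viable disjoint cores", {
  # two disjoint triangles: both survive
  ppi <- ppi_network(rbind(clique_edges(c("a", "b", "c")),
                           clique_edges(c("d", "e", "f"))))
  gw <- weighted_fixture(ppi)
  seeds <- select_seed_cores(enumerate_cliques(gw), gw)
  expect_length(seeds, 2L)
  # two triangles sharing one node: the loser drops below 3 and is discarded
  ppi2 <- ppi_network(rbind(clique_edges(c("a", "b", "c")),
                            clique_edges(c("c", "d", "e"))))
  gw2 <- weighted_fixture(ppi2)
  seeds2 <- select_seed_cores(enumerate_cliques(gw2), gw2)
  expect_length(seeds2, 1L)
  expect_length(seeds2[[1L]]$members, 3L)
  # seeds are pairwise disjoint on random inputs
  for (seed in 1:4) {
    ppi <- random_ppi(15, 0.35, seed = seed)
    gw <- weighted_fixture(ppi)
    cand <- enumerate_cliques(gw)
    if (length(cand) == 0L) next
    ss <- lapply(select_seed_cores(cand, gw), `[[`, "members")
    expect_equal(anyDuplicated(unlist(ss)), 0L)
  }
})

test_that("core growth admits only strict density increases", {
  # density formula boundaries
  expect_equal(hyperedge_density(c("a", "b", "c"), triangle_ppi()), 1)
  # triangle seed inside K4: adding the 4th node keeps density at 1,
  # which is not a strict increase, so the seed does not grow
  k4 <- ppi_network(clique_edges(letters[1:4]))
  grown <- grow_core(structure(list(members = 1:3, density = 1, stage = "seed"),
                               class = "core_cluster"), k4)
  expect_equal(grown$members, 1:3)
  # pendant neighbour would dilute density: rejected
  ppi <- ppi_network(rbind(clique_edges(c("a", "b", "c")), c("a", "d")))
  grown2 <- grow_core(structure(list(members = match(c("a", "b", "c"), ppi$node_ids),
                                     density = 1, stage = "seed"),
                                class = "core_cluster"), ppi)
  expect_length(grown2$members, 3L)
  # a near-clique neighbour that raises density is admitted: start from a
  # sparse 4-set and offer a node connected to all four
  ppi3 <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                            c("e", "a"), c("e", "b"), c("e", "c"), c("e", "d")))
  seed3 <- structure(list(members = match(c("a", "b", "c", "d"), ppi3$node_ids),
                          density = 0.5, stage = "seed"), class = "core_cluster")
  grown3 <- grow_core(seed3, ppi3)
  expect_true(match("e", ppi3$node_ids) %in% grown3$members)
})

test_that("core filtering applies the density threshold inclusively", {
  ppi <- ppi_network(rbind(clique_edges(c("a", "b", "c")),
                           c("d", "e"), c("e", "f"), c("d", "f"), c("d", "g")))
  cores <- list(
    structure(list(members = match(c("a", "b", "c"), ppi$node_ids),
                   density = 1, stage = "core"), class = "core_cluster"),
    structure(list(members = match(c("d", "e", "f", "g"), ppi$node_ids),
                   density = 4 / 6, stage = "core"), class = "core_cluster"))
  expect_length(filter_cores(cores, dens = 0, ppi = ppi), 2L)
  expect_length(filter_cores(cores, dens = 0.8, ppi = ppi), 1L)
  expect_length(filter_cores(cores, dens = 1, ppi = ppi), 1L)
})

test_that("hyperedge density and overlap follow their set formulas", {
  k4 <- ppi_network(clique_edges(letters[1:4]))
  expect_equal(hyperedge_density(letters[1:4], k4), 1)
  ppi <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(hyperedge_density(letters[1:4], ppi), 0.5)   # 3 edges / 6 pairs
  expect_error(hyperedge_density("a", ppi), "at least 2")

  expect_equal(hyperedge_overlap(c("a", "b"), list(c("a", "b"))), 1)
  expect_equal(hyperedge_overlap(c("a", "b"), list(c("x", "y"))), 0)
  expect_equal(hyperedge_overlap(c("a", "b", "c", "d"), list(c("c", "d", "e"))), 0.4)
  expect_equal(hyperedge_overlap(c("a", "b"), list()), 0)
})

test_that("attachment respects the density and overlap gates", {
  # triangle core with one candidate tied to two of its members
  ppi <- ppi_network(rbind(clique_edges(c("a", "b", "c")),
                           c("d", "a"), c("d", "b")))
  core <- list(structure(list(members = match(c("a", "b", "c"), ppi$node_ids),
                              density = 1, stage = "core"), class = "core_cluster"))
  # enlarged density = 5/6: admitted at epsilon 0.7, rejected at epsilon 1
  lax <- attach_peripherals(core, ppi, epsilon = 0.7, theta = 0.5)
  expect_setequal(lax$complexes[[1L]], c("a", "b", "c", "d"))
  strict <- attach_peripherals(core, ppi, epsilon = 1, theta = 0.5)
  expect_setequal(strict$complexes[[1L]], c("a", "b", "c"))
  # vacuous thresholds absorb every reachable candidate
  open <- attach_peripherals(core, ppi, epsilon = 0, theta = 1)
  expect_setequal(open$complexes[[1L]], c("a", "b", "c", "d"))
  # the overlap cap blocks admissions that blur two cores together
  ppi2 <- ppi_network(rbind(clique_edges(c("a", "b", "c")),
                            clique_edges(c("b", "c", "d")),
                            c("w", "a"), c("w", "b"), c("w", "c")))
  mk_core <- function(ids) {
    structure(list(members = match(ids, ppi2$node_ids), density = 1,
                   stage = "core"), class = "core_cluster")
  }
  cores2 <- list(mk_core(c("a", "b", "c")), mk_core(c("b", "c", "d")))
  # enlarging {a,b,c} by w gives density 1 and Jaccard 0.4 against {b,c,d}
  res_ok <- attach_peripherals(cores2, ppi2, epsilon = 0.9, theta = 0.5)
  expect_true(any(vapply(res_ok$complexes,
                         function(cc) setequal(cc, c("a", "b", "c", "w")), NA)))
  res_blocked <- attach_peripherals(cores2, ppi2, epsilon = 0.9, theta = 0.3)
  expect_false(any(vapply(res_blocked$complexes,
                          function(cc) "w" %in% cc, NA)))
})

test_that("the full pipeline recovers planted cliques and is deterministic", {
  ppi <- ppi_network(rbind(clique_edges(paste0("u", 1:6)),
                           clique_edges(paste0("v", 1:6)),
                           c("u1", "v1")))
  res <- run_hlca(ppi, seed = 2)
  expect_equal(res$report$n_complexes, 2L)
  expect_identical(set_signature(res$complexes$complexes),
                   set_signature(list(paste0("u", 1:6), paste0("v", 1:6))))

  # a tree has no triangle, hence no candidate clique and no complex
  tree <- ppi_network(rbind(c("r", "s"), c("r", "t"), c("t", "u")))
  res_tree <- run_hlca(tree, seed = 2)
  expect_equal(res_tree$report$n_complexes, 0L)

  # identical reruns produce identical output files
  sim <- generate_synthetic_ppi(synthetic_spec(n_nodes = 60L, n_complexes = 5L))
  r1 <- run_hlca(sim$network, seed = 11)
  r2 <- run_hlca(sim$network, seed = 11)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_complexes(r1$complexes, f1); write_complexes(r2$complexes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every emitted complex has at least three members and cores passed the filter", {
  sim <- generate_synthetic_ppi(synthetic_spec(n_nodes = 80L, n_complexes = 6L))
  res <- run_hlca(sim$network, seed = 4)
  expect_true(all(lengths(res$complexes$complexes) >= 3L))
  expect_lte(res$report$n_cores, res$report$n_seeds)
  expect_lte(res$report$n_complexes, res$report$n_cores)
})
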