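test_that("run counting merges adjacent labels and respects cycle parity", {
  ## a clean cycle has no run
  inst <- class_instance("AA:e")
  g <- adjacency_graph(inst$a, inst$b)
  cs <- components(g)
  expect_identical(component_runs(cs[[1]], g)$lambda_count, 0L)

  ## a BB-path whose labels alternate A,B,A,B has four runs
  inst <- instance_genomes(list(component_genomes("BB", c("A", "B", "A", "B"), ns = "t")))
  g <- adjacency_graph(inst$a, inst$b)
  cs <- components(g)
  bb <- cs[[which(vapply(cs, `[[`, character(1), "kind") == "BB")]]
  r <- component_runs(bb, g)
  expect_identical(r$lambda_count, 4L)
  expect_identical(r$tags, c("A", "B", "A", "B"))

  ## labels of the same genome separated only by clean adjacencies merge:
  ## one circular chromosome against two, with content only in B
  ga <- genome(list("g1"), "A", circular = TRUE)
  gb <- genome(list(c("y1", "g1", "y2")), "B")
  g2 <- adjacency_graph(ga, gb)
  cs2 <- components(g2)
  r2 <- component_runs(cs2[[1]], g2)
  expect_identical(r2$lambda_count, 1L)   # y2 and y1 form one run

  ## a cycle labeled in one genome only has a single run
  inst3 <- instance_genomes(list(component_genomes("cycle", "A", ns = "t")))
  g3 <- adjacency_graph(inst3$a, inst3$b)
  r3 <- component_runs(components(g3)[[1]], g3)
  expect_identical(r3$lambda_count, 1L)
  ## cycles have 0, 1 or an even number of runs on random instances
  set.seed(31)
  for (rep in 1:40) {
    gp <- rand_small_pair(sample(2:4, 1), sample(0:2, 1), sample(0:2, 1))
    gg <- adjacency_graph(gp$a, gp$b)
    for (cc in components(gg)) {
      if (cc$kind != "cycle") next
      L <- component_runs(cc, gg)$lambda_count
      expect_true(L <= 1L || L %% 2L == 0L)
    }
  }
})

test_that("indel- and substitution-potentials follow the closed forms", {
  expect_identical(indel_potential(0L), 0L)
  expect_identical(indel_potential(1L), 1L)
  expect_identical(indel_potential(4L), 3L)
  expect_identical(substitution_potential(0L), 0L)
  expect_identical(substitution_potential(2L), 1L)
  expect_identical(substitution_potential(4L), 2L)
  for (L in 0:12) {
    lam <- indel_potential(L); sig <- substitution_potential(L)
    expect_true(sig <= lam)
    expect_identical(sig == 0L, L == 0L)
  }
})

test_that("potentials are certified by exhaustive sorting of constructed components", {
  ## single-component instances: total distance = d_DCJ + sigma
  for (tg in list(character(0), "A", c("A", "B"), c("B", "A", "B"))) {
    inst <- instance_genomes(list(component_genomes("AA", tg, ns = "s")))
    g <- adjacency_graph(inst$a, inst$b)
    pot <- potential_summary(g)
    d_expected <- dcj_distance(g) + pot$sum_sigma
    expect_identical(oracle_distance(inst$a, inst$b, max_depth = d_expected),
                     d_expected)
  }
})

test_that("singleton pairing and the separate-sorting bound behave as stated", {
  ## 2 linear singletons in A, 1 in B: one disjoint pair
  ga <- genome(list(c("g1", "g2"), "x1", "x2"), "A")
  gb <- genome(list(c("g1", "g2"), "y1"), "B")
  g <- adjacency_graph(ga, gb)
  pp <- singleton_pairs(components(g))
  expect_identical(pp$P_L, 1L)
  expect_identical(pp$P_C, 0L)

  ## pairing never mixes topologies
  ga2 <- genome(list(c("g1"), "x1"), "A")
  gb2 <- genome(list(c("g1"), "y1"), "B", circular = c(FALSE, TRUE))
  pp2 <- singleton_pairs(components(adjacency_graph(ga2, gb2)))
  expect_identical(pp2$P_L, 0L)
  expect_identical(pp2$P_C, 0L)

  ## equal content: bound equals the DCJ distance
  gs <- parse_genomes(">A\n1 2 3 $\n", ">B\n-3 1 2 $\n")
  g3 <- adjacency_graph(gs$a, gs$b)
  expect_identical(upper_bound_distance(g3), dcj_distance(g3))

  ## one 2-edge cycle with two runs: bound 0 + 1; certified by search
  fig <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
  g4 <- adjacency_graph(fig$a, fig$b)
  expect_identical(upper_bound_distance(g4), 1L)
  expect_identical(oracle_distance(fig$a, fig$b), 1L)

  ## extra chromosomes (x),(y) against (z): one substitution + one deletion
  ga5 <- genome(list(c("1", "2"), "x", "y"), "A")
  gb5 <- genome(list(c("1", "2"), "z"), "B")
  g5 <- adjacency_graph(ga5, gb5)
  expect_identical(upper_bound_distance(g5), 2L)
  expect_identical(oracle_distance(ga5, gb5), 2L)
})

test_that("co-tailed distance is the bound exactly, otherwise not applicable", {
  g1 <- genome(list(c("1", "2", "3")), "A", circular = TRUE)
  expect_identical(cotailed_distance(g1, g1), 0L)
  ## co-tailed pair: circular ancestor, planted inversions + substitution
  sim <- random_genome_pair(5, 1, 1, n_dcj = 2, n_subst = 1, seed = 42,
                            circular = TRUE)
  d <- cotailed_distance(sim$a, sim$b)
  expect_false(is.na(d))
  expect_identical(d, dcjsub_distance(sim$a, sim$b)$distance)
  ## non-co-tailed: different tails
  gs <- parse_genomes(">A\n1 2 $\n", ">B\n2 1 $\n")
  expect_true(is.na(cotailed_distance(gs$a, gs$b)))
})

test_that("no single DCJ removes more than two runs", {
  set.seed(13)
  for (rep in 1:30) {
    gp <- rand_small_pair(sample(1:3, 1), sample(0:2, 1), sample(0:2, 1))
    if (!length(gp$a$chromosomes) || !length(gp$b$chromosomes)) next
    before <- potential_summary(adjacency_graph(gp$a, gp$b))$sum_Lambda
    s <- genome_adjset(gp$a)
    for (op in enumerate_dcjs(s)) {
      a2 <- adjset_genome(apply_dcj(s, op), name = "A")
      after <- potential_summary(adjacency_graph(a2, gp$b))$sum_Lambda
      expect_gte(after - before, -2L)
    }
  }
})
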