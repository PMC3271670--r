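test_that("labeled adjacencies carry unique markers between common extremities", {
  gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
  p <- partition_markers(gs$a, gs$b)
  adj <- build_adjacencies(gs$a, p)
  expect_length(adj, 3L)
  expect_true(is.na(adj[[1]]$g1))                       # telomere
  expect_identical(adj[[1]]$g2, "a:t")
  expect_identical(adj[[2]]$g1, "a:h")
  expect_identical(adj[[2]]$label, c("s", "u"))
  expect_identical(adj[[2]]$g2, "b:t")
  expect_true(is.na(adj[[3]]$g2))

  ## clean circular chromosome over two common markers
  g2 <- genome(list(c("1", "2")), "A", circular = TRUE)
  p2 <- partition_markers(g2, genome(list(c("1", "2")), "B", circular = TRUE))
  a2 <- build_adjacencies(g2, p2)
  expect_length(a2, 2L)
  expect_setequal(vapply(a2, function(v) paste(sort(c(v$g1, v$g2)), collapse = "+"),
                         character(1)),
                  c("1:h+2:t", "1:t+2:h"))

  ## a circular chromosome of unique markers is one circular singleton
  g3 <- genome(list("x"), "A", circular = TRUE)
  p3 <- partition_markers(g3, genome(list("1"), "B"))
  a3 <- build_adjacencies(g3, p3)
  expect_length(a3, 1L)
  expect_true(a3[[1]]$cs)
  expect_identical(a3[[1]]$label, "x")
})

test_that("graph components match hand enumeration", {
  ## identical linear genomes over 1..3: two 2-edge cycles + two AB-paths
  gs <- parse_genomes(">A\n1 2 3 $\n", ">B\n1 2 3 $\n")
  g <- adjacency_graph(gs$a, gs$b)
  cs <- components(g)
  expect_identical(sort(vapply(cs, `[[`, character(1), "kind")),
                   c("AB", "AB", "cycle", "cycle"))
  expect_identical(dcj_distance(g, cs), 0L)

  ## an inversion leaves one 4-edge cycle and two 1-edge AB-paths
  gs2 <- parse_genomes(">A\n1 2 3 $\n", ">B\n1 -2 3 $\n")
  g2 <- adjacency_graph(gs2$a, gs2$b)
  cs2 <- components(g2)
  kinds <- vapply(cs2, `[[`, character(1), "kind")
  expect_identical(sort(kinds), c("AB", "AB", "cycle"))
  expect_identical(cs2[[which(kinds == "cycle")]]$n_edges, 4L)
  expect_identical(dcj_distance(g2, cs2), 1L)

  ## empty genomes give an empty graph
  g3 <- adjacency_graph(genome(list(), "A"), genome(list(), "B"))
  expect_length(components(g3), 0L)
  expect_identical(dcj_distance(g3), 0L)

  ## a lone linear chromosome of unique markers is a linear singleton
  g4 <- adjacency_graph(genome(list("x"), "A"), genome(list("1"), "B"))
  expect_true("lin_singleton_A" %in% vapply(components(g4), `[[`, character(1), "kind"))
})

test_that("edge count, AB-path parity and distance symmetry hold on random pairs", {
  set.seed(77)
  for (r in 1:60) {
    gp <- rand_small_pair(sample(0:4, 1), sample(0:2, 1), sample(0:2, 1))
    if (!length(gp$a$chromosomes) || !length(gp$b$chromosomes)) next
    g <- adjacency_graph(gp$a, gp$b)
    cs <- components(g)
    expect_identical(nrow(g$edges), 2L * g$partition$n)
    expect_identical(dcjsub:::count_kind(cs, "AB") %% 2L, 0L)
    ## every vertex appears in exactly one component
    na <- sum(vapply(cs, function(cc)
      sum(cc$side == "A"), integer(1)))
    expect_identical(na, length(g$va))
    g_rev <- adjacency_graph(gp$b, gp$a)
    expect_identical(dcj_distance(g), dcj_distance(g_rev))
  }
})

test_that("DCJ distance agrees with exhaustive search on equal content", {
  set.seed(5)
  for (r in 1:25) {
    n <- sample(2:4, 1)
    ga <- rand_genome(paste0("g", 1:n), "A", p_circ = 0.4)
    gb <- rand_genome(paste0("g", 1:n), "B", p_circ = 0.4)
    d1 <- dcj_distance(adjacency_graph(ga, gb))
    d2 <- oracle_distance(ga, gb, dcj_only = TRUE, max_depth = 8L)
    expect_identical(as.integer(d1), d2)
  }
  ## a fission of one circular chromosome costs one operation
  gA <- genome(list(c("1", "2")), "A", circular = TRUE)
  gB <- genome(list("1", "2"), "B", circular = c(TRUE, TRUE))
  expect_identical(dcj_distance(adjacency_graph(gA, gB)), 1L)
})
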