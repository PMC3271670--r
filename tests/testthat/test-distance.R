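test_that("distance handles the canonical worked examples", {
  gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
  x <- dcjsub_distance(gs$a, gs$b)
  expect_identical(x$distance, 1L)          # one substitution
  expect_identical(x$d_dcj, 0L)
  expect_identical(x$d_indel_upper, 2L)     # deletion + insertion under indels

  id <- parse_genomes(">A\n1 2 3 $\n", ">B\n1 2 3 $\n")
  expect_identical(dcjsub_distance(id$a, id$b)$distance, 0L)

  ## content-free comparison: whole-chromosome substitution
  ga <- genome(list("x1"), "A")
  gb <- genome(list("y1"), "B")
  expect_identical(dcjsub_distance(ga, gb)$distance, 1L)
  ## but only within the same topology
  gc <- genome(list("y1"), "B", circular = TRUE)
  expect_identical(dcjsub_distance(ga, gc)$distance, 2L)
})

test_that("distance equals d_DCJ on equal content and respects the bound chain", {
  set.seed(15)
  for (r in 1:40) {
    sim <- random_genome_pair(sample(3:7, 1), 0, 0, n_dcj = sample(0:4, 1),
                              n_subst = 0, seed = 2000 + r)
    x <- dcjsub_distance(sim$a, sim$b)
    expect_identical(x$distance, x$d_dcj)
    expect_identical(x$sum_sigma, 0L)
  }
  for (r in 1:40) {
    na <- sample(0:3, 1); nb <- sample(0:3, 1)
    ns <- if (na + nb > 0) sample(seq_len(na + nb), 1) else 0
    sim <- random_genome_pair(sample(2:6, 1), na, nb, n_dcj = sample(0:3, 1),
                              n_subst = ns, seed = 3000 + r,
                              chromosomes = sample(1:2, 1))
    x <- dcjsub_distance(sim$a, sim$b)
    expect_gte(x$distance, x$d_dcj)
    expect_lte(x$distance, x$d_upper)
    expect_lte(x$d_upper, x$d_indel_upper)
    if (x$co_tailed)
      expect_identical(x$distance, cotailed_distance(sim$a, sim$b))
  }
})

test_that("report object carries consistent fields and printing works", {
  sim <- random_genome_pair(5, 2, 2, n_dcj = 2, n_subst = 2, seed = 77)
  x <- dcjsub_distance(sim$a, sim$b)
  expect_identical(x$deduction,
                   2L * x$groups[["U"]] + 3L * x$groups[["V"]] +
                   2L * x$groups[["W"]] + x$groups[["X"]] +
                   2L * x$groups[["Y"]] + x$groups[["Z"]])
  expect_identical(x$distance,
                   x$d_dcj + x$sum_sigma - x$P_L - x$P_C - x$deduction)
  f <- report_fields(x)
  expect_identical(f$d_dcjsub, x$distance)
  expect_output(print(x), "DCJ-substitution distance")
  expect_output(summary(x), "recombination groups")
})
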