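test_that("the brute-force oracle solves the worked examples", {
  gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
  expect_identical(oracle_distance(gs$a, gs$b), 1L)     # one substitution
  g1 <- genome(list(c("1", "2", "3")), "A")
  g2 <- genome(list(c("1", "-2", "3")), "B")
  expect_identical(oracle_distance(g1, g2), 1L)         # one inversion
  expect_identical(oracle_distance(g1, g1), 0L)
  expect_true(is.na(oracle_distance(g1, g2, max_depth = 0L)))
})

test_that("the oracle refuses instances beyond its marker cap", {
  ga <- genome(list(paste0("m", 1:5)), "A")
  gb <- genome(list(paste0("n", 1:5)), "B")
  expect_error(oracle_distance(ga, gb), "exceed the cap")
})

test_that("planted operation counts upper-bound the oracle distance", {
  for (k in 1:15) {
    sim <- random_genome_pair(n_common = 3, n_unique_a = 1, n_unique_b = 1,
                              n_dcj = k %% 3L, n_subst = 1L, seed = 100 + k)
    od <- oracle_distance(sim$a, sim$b, max_depth = sim$planted)
    expect_false(is.na(od))
    expect_lte(od, sim$planted)
  }
})
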