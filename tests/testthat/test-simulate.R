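test_that("the simulator is deterministic under its seed", {
  s1 <- random_genome_pair(5, 2, 2, n_dcj = 3, n_subst = 2, seed = 7)
  s2 <- random_genome_pair(5, 2, 2, n_dcj = 3, n_subst = 2, seed = 7)
  expect_identical(write_genome(s1$a), write_genome(s2$a))
  expect_identical(write_genome(s1$b), write_genome(s2$b))
  s3 <- random_genome_pair(5, 2, 2, n_dcj = 3, n_subst = 2, seed = 8)
  expect_false(identical(write_genome(s3$b), write_genome(s1$b)))
})

test_that("planted operations bound the computed distance", {
  for (r in 1:40) {
    na <- r %% 3L; nb <- (r + 1L) %% 3L
    ns <- if (na + nb > 0L) 1L + (r %% min(2L, na + nb)) else 0L
    sim <- random_genome_pair(3L + r %% 4L, na, nb,
                              n_dcj = r %% 4L, n_subst = ns, seed = 1000L + r)
    d <- dcjsub_distance(sim$a, sim$b)$distance
    expect_lte(d, sim$planted)
    ## content comes out as requested
    p <- partition_markers(sim$a, sim$b)
    expect_identical(length(p$unique_a), na)
    expect_identical(length(p$unique_b), nb)
  }
})

test_that("no planted operations means identical genomes", {
  sim <- random_genome_pair(6, 0, 0, n_dcj = 0, n_subst = 0, seed = 3)
  expect_true(genomes_equal(sim$a, sim$b))
  expect_identical(dcjsub_distance(sim$a, sim$b)$distance, 0L)
})

test_that("infeasible substitution counts are rejected", {
  expect_error(random_genome_pair(3, 0, 0, n_subst = 1, seed = 1),
               "insufficient unique markers")
  expect_error(random_genome_pair(3, 1, 1, n_subst = 3, seed = 1),
               "insufficient unique markers")
  expect_error(random_genome_pair(3, 1, 0, n_subst = 0, seed = 1),
               "insufficient unique markers")
})

test_that("circular simulation keeps the pair co-tailed", {
  for (r in 1:10) {
    sim <- random_genome_pair(4, 1, 1, n_dcj = 2, n_subst = 1,
                              seed = 40 + r, circular = TRUE)
    expect_true(all(vapply(sim$b$chromosomes, `[[`, logical(1), "circular")))
    expect_false(is.na(cotailed_distance(sim$a, sim$b)))
  }
})
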