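test_that("GRIMM-dialect parsing handles linear, circular and malformed input", {
  gs <- parse_genomes(">A\n1 2 3 $\n", ">B\n1 -2 @\n")
  expect_length(gs$a$chromosomes, 1L)
  expect_false(gs$a$chromosomes[[1]]$circular)
  expect_identical(gs$a$chromosomes[[1]]$markers, c("1", "2", "3"))
  expect_true(gs$b$chromosomes[[1]]$circular)
  expect_identical(gs$b$chromosomes[[1]]$markers, c("1", "-2"))

  expect_error(parse_genomes(">A\n1 2 1 $\n", ">B\n1 $\n"), "duplicated marker '1'")
  expect_error(parse_genomes(">A\n1 2 3\n", ">B\n1 $\n"), "line 2")
  expect_error(parse_genomes(">A\n$\n", ">B\n1 $\n"), "empty chromosome")
  ## comments and blank lines are ignored; headers are optional
  g <- parse_genomes("# a comment\n\n1 2 $\n", "1 $")$a
  expect_identical(g$name, "A")
  expect_length(g$chromosomes, 1L)
})

test_that("write/parse round-trips up to rotation and reversal", {
  set.seed(11)
  for (r in 1:25) {
    g <- rand_genome(paste0("m", 1:sample(1:6, 1)), "G", p_circ = 0.5)
    if (length(g$chromosomes) == 0L) next
    g2 <- parse_genomes(write_genome(g), "1 $")$a
    g2$name <- g$name
    expect_true(genomes_equal(g, g2))
  }
  ## a rotated circular chromosome parses equal to the original
  g1 <- genome(list(c("1", "2", "3")), "C", circular = TRUE)
  g2 <- genome(list(c("3", "1", "2")), "C", circular = TRUE)
  g3 <- genome(list(c("-3", "-2", "-1")), "C", circular = TRUE)
  expect_true(genomes_equal(g1, g2))
  expect_true(genomes_equal(g1, g3))
  ## two chromosomes emit two chromosome lines
  out <- write_genome(genome(list("1", "2"), "G"), header = FALSE)
  expect_length(strsplit(trimws(out), "\n")[[1]], 2L)
})

test_that("marker partition splits content into common and unique sets", {
  gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
  p <- partition_markers(gs$a, gs$b)
  expect_identical(p$common, c("a", "b"))
  expect_identical(p$unique_a, c("s", "u"))
  expect_identical(p$unique_b, c("x", "y"))
  expect_identical(p$n, 2L)

  eq <- parse_genomes(">A\n1 2 3 $\n", ">B\n3 1 2 $\n")
  peq <- partition_markers(eq$a, eq$b)
  expect_identical(peq$common, c("1", "2", "3"))
  expect_length(peq$unique_a, 0L)

  dj <- partition_markers(genome(list("1"), "A"), genome(list("2"), "B"))
  expect_identical(dj$n, 0L)
  ## symmetry: swapping the genomes swaps the unique sets
  set.seed(4)
  for (r in 1:10) {
    gp <- rand_small_pair(sample(0:3, 1), sample(0:2, 1), sample(0:2, 1))
    if (!length(gp$a$chromosomes) || !length(gp$b$chromosomes)) next
    p1 <- partition_markers(gp$a, gp$b)
    p2 <- partition_markers(gp$b, gp$a)
    expect_identical(p1$common, p2$common)
    expect_identical(p1$unique_a, p2$unique_b)
    expect_identical(p1$unique_b, p2$unique_a)
  }
})
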