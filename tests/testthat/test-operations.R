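test_that("DCJ application realises inversions, fissions and inverses", {
  gA <- genome(list(c("1", "2", "3")), "A")
  s <- genome_adjset(gA)
  targets <- list(genome(list(c("1", "-2", "3")), "T"))
  hit <- FALSE
  for (op in enumerate_dcjs(s))
    if (genomes_equal(adjset_genome(apply_dcj(s, op)), targets[[1]])) hit <- TRUE
  expect_true(hit)

  ## fission of a circular chromosome into two
  gC <- genome(list(c("1", "2")), "C", circular = TRUE)
  sC <- genome_adjset(gC)
  tC <- genome(list("1", "2"), "T", circular = c(TRUE, TRUE))
  expect_true(any(vapply(enumerate_dcjs(sC), function(op)
    genomes_equal(adjset_genome(apply_dcj(sC, op)), tC), logical(1))))

  ## every DCJ admits an inverse DCJ restoring the genome
  set.seed(3)
  g <- rand_genome(paste0("m", 1:4), "G", p_circ = 0.4)
  s2 <- genome_adjset(g)
  ops <- enumerate_dcjs(s2)
  for (op in ops[sample.int(length(ops), min(20L, length(ops)))]) {
    s3 <- apply_dcj(s2, op)
    back <- any(vapply(enumerate_dcjs(s3), function(o2)
      genomes_equal(adjset_genome(apply_dcj(s3, o2)), g), logical(1)))
    expect_true(back)
  }
})

test_that("substitutions replace, insert and delete blocks with validation", {
  gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
  out <- apply_substitution(gs$a, list(removed = c("s", "u"), inserted = c("x", "y")))
  expect_true(genomes_equal(out, genome(list(c("a", "x", "y", "b")), "T")))
  ## substituting then substituting back restores the genome
  back <- apply_substitution(out, list(removed = c("x", "y"), inserted = c("s", "u")))
  expect_true(genomes_equal(back, gs$a))

  ins <- apply_substitution(gs$a, list(removed = character(0), inserted = "z",
                                       at = list(chr = 1, after = 4)))
  expect_identical(ins$chromosomes[[1]]$markers, c("a", "s", "u", "b", "z"))
  del <- apply_substitution(gs$a, list(removed = "s", inserted = character(0)))
  expect_identical(del$chromosomes[[1]]$markers, c("a", "u", "b"))

  ## a block may match in reverse orientation
  rev_out <- apply_substitution(gs$a, list(removed = c("-u", "-s"), inserted = "w"))
  expect_true(genomes_equal(rev_out, genome(list(c("a", "-w", "b")), "T")))

  expect_error(apply_substitution(gs$a, list(removed = c("s", "b"), inserted = "z")),
               "not a contiguous segment")
  expect_error(apply_substitution(gs$a, list(removed = "s", inserted = "a")),
               "already present")
  ## whole-chromosome substitution preserves topology
  gc <- genome(list(c("g1"), c("u", "v")), "C", circular = c(FALSE, TRUE))
  swapped <- apply_substitution(gc, list(removed = c("u", "v"), inserted = "w"))
  expect_true(swapped$chromosomes[[2]]$circular)
  expect_error(apply_substitution(gc, list(removed = c("u", "v"), inserted = "w",
                                           topology = "linear")),
               "cannot substitute")
})

test_that("delta metrics classify operations and respect the single-step bounds", {
  ## an optimal DCJ extracting a clean 2-edge cycle has delta_dcj = 0
  gs <- parse_genomes(">A\n1 2 3 $\n", ">B\n1 -2 3 $\n")
  s <- genome_adjset(gs$a)
  found_optimal <- FALSE
  for (op in enumerate_dcjs(s)) {
    md <- measure_deltas(gs$a, gs$b, op)
    expect_gte(md$delta_lambda_runs, -2L)
    if (md$dcj_class == "optimal") {
      found_optimal <- TRUE
      expect_identical(md$delta_dcj, 0L)
    }
    ## neutral DCJs acting on a single component never decrease the distance
    if (md$dcj_class == "neutral" &&
        length(unique(md$source_components)) == 1L)
      expect_gte(md$delta_d, 0L)
  }
  expect_true(found_optimal)

  ## substitutions report run/sigma changes
  md2 <- measure_deltas(parse_genomes(">A\na s b $\n", ">B\na b $\n")$a,
                        genome(list(c("a", "b")), "B"),
                        list(substitution = TRUE, removed = "s",
                             inserted = character(0)))
  expect_identical(md2$delta_lambda_runs, -1L)
  expect_identical(md2$delta_sigma, -1L)
})
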