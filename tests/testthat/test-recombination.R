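test_that("path classification follows the run-structure taxonomy", {
  inst <- class_instance(c("AB:e", "BB:E4", "AA:A1"))
  g <- adjacency_graph(inst$a, inst$b)
  cs <- components(g)
  cls <- vapply(cs, function(cc) {
    if (cc$kind %in% c("cycle", "circ_singleton_A", "circ_singleton_B")) ""
    else classify_path(cc, g)$class
  }, character(1))
  expect_true("AB:e" %in% cls)
  expect_true("BB:E4" %in% cls)
  expect_true("AA:A1" %in% cls)
  bb <- classify_path(cs[[which(cls == "BB:E4")[1]]], g)
  expect_identical(bb$k, 4L)
  expect_identical(bb$i, 0L)

  ## cycles cannot be classified as paths
  cyc <- instance_genomes(list(component_genomes("cycle", c("A", "B"), ns = "c")))
  gc <- adjacency_graph(cyc$a, cyc$b)
  expect_error(classify_path(components(gc)[[1]], gc), "cannot classify")
})

test_that("the rule table loads, validates, and rejects corrupted rows", {
  rules <- load_rule_table()
  expect_true(all(c("U", "V", "W", "X", "Y", "Z") %in% rules$group))
  t1 <- rules[rules$table == 1L, ]
  expect_true(all(t1$delta_d <= -1L))
  expect_identical(sum(t1$delta_d == -2L), 1L)          # the single U operation
  u <- t1[t1$delta_d == -2L, ]
  expect_setequal(c(u$source1, u$source2), c("AA:E4", "BB:E4"))
  expect_identical(u$delta_sigma, -2L)
  expect_identical(u$delta_dcj, 0L)
  expect_true(all(rules$delta_sigma[rules$table != 3L] >= -2L))
  t3v <- rules[rules$group == "V", ]
  expect_true(all(t3v$delta_d == -3L))

  ## a corrupted transcription is refused, naming the row
  tmp <- tempfile(fileext = ".tsv")
  lines <- readLines(system.file("extdata", "recombination_rules.tsv",
                                 package = "dcjsub"))
  i <- grep("^1\tX", lines)[1]
  f <- strsplit(lines[i], "\t")[[1]]
  f[8] <- "3"                                           # delta_d inconsistent
  lines[i] <- paste(f, collapse = "\t")
  writeLines(lines, tmp)
  expect_error(load_rule_table(tmp), "delta_d is not delta_sigma")
})

test_that("group counting matches hand-worked cases and ignores input order", {
  empty <- greedy_groups(character(0))
  expect_identical(empty$deduction, 0L)
  u <- greedy_groups(c("AA:E4", "BB:E4"))
  expect_identical(u$U, 1L)
  expect_identical(u$deduction, 2L)
  v <- greedy_groups(c("AA:E4", "AA:E4", "BB:A1", "BB:B1"))
  expect_identical(v$V, 1L)
  expect_identical(v$deduction, 3L)
  w <- greedy_groups(c("AA:E4", "AB:A4", "BB:A1"))
  expect_identical(w$W, 1L)
  expect_identical(w$deduction, 2L)
  y <- greedy_groups(c("AB:A4", "AB:A4", "AA:B1", "BB:A1"))
  expect_identical(y$Y, 1L)
  expect_identical(y$deduction, 2L)
  z <- greedy_groups(c("AB:A4", "AB:A4", "BB:A1"))
  expect_identical(z$deduction, 1L)
  x <- greedy_groups(c("AA:A1", "BB:A1"))
  expect_identical(x$X, 1L)

  set.seed(8)
  for (r in 1:10) {
    cls <- sample(dcjsub:::all_path_classes(), sample(2:5, 1), replace = TRUE)
    g1 <- greedy_groups(cls)
    g2 <- greedy_groups(sample(cls))
    expect_identical(g1$deduction, g2$deduction)
  }
})

test_that("the distance is symmetric in the two genomes", {
  set.seed(99)
  for (r in 1:20) {
    na <- sample(0:2, 1); nb <- sample(0:2, 1)
    ns <- if (na + nb > 0) sample(seq_len(na + nb), 1) else 0
    sim <- random_genome_pair(sample(3:6, 1), na, nb, n_dcj = sample(0:3, 1),
                              n_subst = ns, seed = 700 + r)
    d1 <- dcjsub_distance(sim$a, sim$b)$distance
    d2 <- dcjsub_distance(sim$b, sim$a)$distance
    expect_identical(d1, d2)
  }
})
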