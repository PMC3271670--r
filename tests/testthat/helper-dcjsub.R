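## shared test utilities: random genomes, component instances, and a
## genome-level exhaustive recombination optimizer used as an independent
## check of the group-counting machinery

rand_genome <- function(markers, name, p_circ = 0.3, max_chrom = 2L) {
  if (length(markers) == 0L) return(genome(list(), name))
  m <- sample(markers)
  toks <- paste0(sample(c("", "-"), length(m), replace = TRUE), m)
  k <- sample.int(min(max_chrom, length(toks)), 1L)
  cuts <- if (k > 1L) sort(sample(seq_len(length(toks) - 1L), k - 1L)) else integer(0)
  parts <- unname(split(toks, findInterval(seq_along(toks), cuts + 0.5)))
  genome(parts, name, circular = stats::runif(length(parts)) < p_circ)
}

rand_small_pair <- function(n_common, n_unique_a, n_unique_b) {
  common <- if (n_common) paste0("g", seq_len(n_common)) else character(0)
  ua <- if (n_unique_a) paste0("x", seq_len(n_unique_a)) else character(0)
  ub <- if (n_unique_b) paste0("y", seq_len(n_unique_b)) else character(0)
  list(a = rand_genome(c(common, ua), "A"), b = rand_genome(c(common, ub), "B"))
}

## instance whose adjacency graph shows the given components
class_instance <- function(classes, i = 0L, pad = FALSE) {
  i <- rep_len(i, length(classes))
  parts <- lapply(seq_along(classes), function(j) {
    kind <- strsplit(classes[j], ":", fixed = TRUE)[[1L]][1L]
    component_genomes(kind, dcjsub:::class_tags(classes[j], i[j]),
                      ns = paste0("c", j), pad = pad)
  })
  instance_genomes(parts)
}

## exhaustive maximum deduction by applying real DCJ recombinations (on
## either genome) with delta_d <= 0; memoised on the genome pair, with a
## metrics cache, and restricted to operations joining two path
## components of which at least one is labeled (cycles are never useful
## sources and recombinations of two clean paths never change sigma)
exhaustive_deduction <- function(a, b, env = NULL) {
  if (is.null(env)) {
    env <- new.env(hash = TRUE)
    env$metrics <- new.env(hash = TRUE)
  }
  met_of <- function(g1, g2) {
    mk <- paste(genome_key(g1), genome_key(g2), sep = " // ")
    m <- env$metrics[[mk]]
    if (is.null(m)) { m <- dcjsub:::graph_metrics(g1, g2); env$metrics[[mk]] <- m }
    m
  }
  key <- paste(genome_key(a), genome_key(b), sep = " :: ")
  v <- env[[key]]
  if (!is.null(v)) return(v)
  env[[key]] <- 0L
  best <- 0L
  for (side in 1:2) {
    g1 <- if (side == 1L) a else b
    g2 <- if (side == 1L) b else a
    met <- met_of(g1, g2)
    path_kinds <- c("AA", "BB", "AB", "lin_singleton_A", "lin_singleton_B")
    is_path <- vapply(met$comps, function(cc) cc$kind %in% path_kinds, logical(1))
    labeled <- vapply(seq_along(met$comps), function(ci)
      dcjsub:::component_runs(met$comps[[ci]], met$graph)$lambda_count > 0L,
      logical(1))
    comp_of <- integer(length(met$graph$va))
    for (ci in seq_along(met$comps))
      comp_of[met$comps[[ci]]$idx[met$comps[[ci]]$side == "A"]] <- ci
    jm <- dcjsub:::junction_vertex_map(g1, met$graph$partition)
    s <- genome_adjset(g1)
    for (op in enumerate_dcjs(s)) {
      keys <- switch(op$type,
        aa = c(dcjsub:::adj_key(s$adjacencies[[op$i]]),
               dcjsub:::adj_key(s$adjacencies[[op$j]])),
        at = c(dcjsub:::adj_key(s$adjacencies[[op$i]]), s$telomeres[[op$t]]),
        tt = c(s$telomeres[[op$t1]], s$telomeres[[op$t2]]),
        split = dcjsub:::adj_key(s$adjacencies[[op$i]]))
      cids <- unique(comp_of[unname(jm[keys])])
      if (length(cids) != 2L) next
      if (!all(is_path[cids]) || !any(labeled[cids])) next
      g1b <- adjset_genome(apply_dcj(s, op), name = g1$name)
      met2 <- met_of(g1b, g2)
      dsig <- met2$pot$sum_sigma - met$pot$sum_sigma
      dc <- met2$c - met$c; db <- met2$b - met$b
      ddcj <- if (dc == 1L || db == 2L) 0L else if (dc == 0L && db == 0L) 1L else 2L
      dd <- ddcj + dsig
      if (dd > 0L) next
      sub <- if (side == 1L) exhaustive_deduction(g1b, g2, env)
             else exhaustive_deduction(g2, g1b, env)
      if (-dd + sub > best) best <- -dd + sub
    }
  }
  env[[key]] <- best
  best
}
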