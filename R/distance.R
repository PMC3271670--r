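## The DCJ-substitution distance.

#' DCJ-substitution distance between two genomes
#'
#' Exact minimum number of double-cut-and-join operations and
#' substitutions of unique-marker blocks transforming one genome into the
#' other.  The computation follows the closed form: the DCJ distance over
#' the common markers, plus the substitution-potential of every component
#' of the adjacency graph, minus the savings from pairing singleton
#' chromosomes and from recombinations between labeled paths.
#'
#' @param a,b \code{dcj_genome} objects (see \code{\link{genome}} and
#'   \code{\link{parse_genomes}}); duplicated markers are rejected.
#' @return an object of class \code{dcjsub_dist}: a list with the distance
#'   \code{distance}, the intermediate quantities (\code{n}, \code{c},
#'   \code{b}, \code{d_dcj}, \code{sum_Lambda}, \code{sum_lambda},
#'   \code{sum_sigma}, \code{P_L}, \code{P_C}, group counts
#'   \code{U}..\code{Z}, \code{deduction}, the indel and separate-sorting upper
#'   bounds, the co-tailed flag) and a per-component table.
#' @examples
#' gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
#' dcjsub_distance(gs$a, gs$b)
#' @export
dcjsub_distance <- function(a, b) {
  validate_genome(a); validate_genome(b)
  p <- partition_markers(a, b)
  adj_a <- build_adjacencies(a, p)
  adj_b <- build_adjacencies(b, p)
  g <- build_graph(adj_a, adj_b, p)
  comps <- components(g)
  pot <- potential_summary(g, comps)
  d_dcj <- dcj_distance(g, comps)
  d_upper <- upper_bound_distance(g, comps, pot)
  co_tailed <- identical(genome_tails(adj_a), genome_tails(adj_b))

  ## circular singletons only pair; linear singletons join the search pool
  p_c <- pot$P_C
  toks <- pool_tokens(g, comps)
  sr <- deduction_search(toks)
  gc <- group_counts(sr$moves)
  deduction <- group_deduction(gc$counts)
  p_l_used <- gc$P_L_used
  stopifnot(p_l_used + deduction == sr$savings)

  distance <- d_dcj + pot$sum_sigma - p_c - sr$savings
  stopifnot(distance >= 0L, distance <= d_upper)

  cls <- vapply(seq_along(comps), function(i) {
    cc <- comps[[i]]
    if (cc$kind %in% c("cycle", "circ_singleton_A", "circ_singleton_B")) ""
    else classify_path(cc, g, pot$runs[[i]])$class
  }, character(1))
  tab <- cbind(pot$table, class = cls)

  structure(list(
    distance = as.integer(distance),
    n = p$n,
    c = count_kind(comps, "cycle"),
    b = count_kind(comps, "AB"),
    d_dcj = d_dcj,
    sum_Lambda = pot$sum_Lambda,
    sum_lambda = pot$sum_lambda,
    sum_sigma = pot$sum_sigma,
    P_L = p_l_used,
    P_C = p_c,
    groups = gc$counts,
    deduction = deduction,
    d_upper = d_upper,
    d_indel_upper = as.integer(d_dcj + pot$sum_lambda),
    co_tailed = co_tailed,
    components = tab,
    genome_names = c(a$name, b$name)),
    class = "dcjsub_dist")
}

#' @export
print.dcjsub_dist <- function(x, ...) {
  cat(sprintf("DCJ-substitution distance between '%s' and '%s': %d\n",
              x$genome_names[1L], x$genome_names[2L], x$distance))
  invisible(x)
}

#' @export
summary.dcjsub_dist <- function(object, ...) {
  x <- object
  cat(sprintf("DCJ-substitution distance: %d\n", x$distance))
  cat(sprintf("  common markers n = %d; cycles c = %d; AB-paths b = %d\n",
              x$n, x$c, x$b))
  cat(sprintf("  d_DCJ = %d; runs = %d; sum lambda = %d; sum sigma = %d\n",
              x$d_dcj, x$sum_Lambda, x$sum_lambda, x$sum_sigma))
  cat(sprintf("  singleton pairs: linear %d, circular %d\n", x$P_L, x$P_C))
  cat(sprintf("  recombination groups: U=%d V=%d W=%d X=%d Y=%d Z=%d (deduction %d)\n",
              x$groups[["U"]], x$groups[["V"]], x$groups[["W"]],
              x$groups[["X"]], x$groups[["Y"]], x$groups[["Z"]], x$deduction))
  cat(sprintf("  upper bounds: separate-sorting %d, DCJ+indel %d\n",
              x$d_upper, x$d_indel_upper))
  cat(sprintf("  co-tailed: %s\n", if (x$co_tailed) "yes (bound is exact)" else "no"))
  if (nrow(x$components)) {
    cat("  components:\n")
    print(x$components, row.names = FALSE)
  }
  invisible(x)
}

#' Report as a flat named list (machine-readable)
#' @param x a \code{dcjsub_dist}.
#' @return named list of scalars plus the component table.
#' @export
report_fields <- function(x) {
  stopifnot(inherits(x, "dcjsub_dist"))
  list(genome_a = x$genome_names[1L], genome_b = x$genome_names[2L],
       n = x$n, c = x$c, b = x$b, d_dcj = x$d_dcj,
       sum_runs = x$sum_Lambda, sum_lambda = x$sum_lambda,
       sum_sigma = x$sum_sigma, P_L = x$P_L, P_C = x$P_C,
       U = x$groups[["U"]], V = x$groups[["V"]], W = x$groups[["W"]],
       X = x$groups[["X"]], Y = x$groups[["Y"]], Z = x$groups[["Z"]],
       deduction = x$deduction, d_upper = x$d_upper,
       d_indel_upper = x$d_indel_upper, co_tailed = x$co_tailed,
       d_dcjsub = x$distance)
}
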