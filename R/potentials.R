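## Runs of unique markers, indel- and substitution-potentials.
##
## Reading the labels of a component in walk order gives a string over the
## two genomes' unique markers; its maximal one-genome substrings are the
## runs.  The indel-potential lambda(C) is the fewest runs reachable by
## optimally DCJ-sorting C alone; the substitution-potential sigma(C) is
## the fewest substitutions, obtained by pairing consecutive runs.  Both
## have closed forms in the run count Lambda(C).

#' Run sequence of a component
#'
#' Collects the genome tag (\code{"A"}/\code{"B"}) of every non-empty label
#' along the component walk and merges consecutive equal tags: a run is a
#' maximal substring of one genome's unique markers, so adjacent labels of
#' the same genome form a single run.  For cycles the merge is circular
#' (the reading may start anywhere; a cycle therefore has zero, one, or an
#' even number of runs).  AB-paths are read from the genome-A endpoint.
#'
#' @param cc a component from \code{\link{components}}.
#' @param g the \code{dcj_graph} it came from.
#' @return a list of class \code{dcj_runs}: \code{tags} (character vector
#'   of \code{"A"}/\code{"B"} in reading order) and \code{lambda_count}
#'   (\code{Lambda(C)}, the number of runs).
#' @export
component_runs <- function(cc, g) {
  labs <- component_label_list(g, cc)
  tags <- character(0)
  for (lv in labs) if (length(lv$label)) tags <- c(tags, lv$side)
  ## merge consecutive equal tags
  if (length(tags) > 1L) tags <- tags[c(TRUE, tags[-1L] != tags[-length(tags)])]
  if (cc$kind == "cycle" && length(tags) > 1L && tags[1L] == tags[length(tags)])
    tags <- tags[-length(tags)]                     # circular merge
  stopifnot(length(tags) <= 1L || all(tags[-1L] != tags[-length(tags)]))
  if (cc$kind == "cycle")
    stopifnot(length(tags) <= 1L || length(tags) %% 2L == 0L)
  structure(list(tags = tags, lambda_count = length(tags)), class = "dcj_runs")
}

#' Indel-potential of a run sequence
#'
#' \code{lambda = ceiling((Lambda + 1) / 2)} for \code{Lambda >= 1}, else 0:
#' optimal DCJ-sorting can halve the number of runs (rounding up) but never
#' do better, and a clean component needs no indels at all.
#'
#' @param r a \code{dcj_runs} object (or a bare run count).
#' @return non-negative integer.
#' @export
indel_potential <- function(r) {
  L <- if (inherits(r, "dcj_runs")) r$lambda_count else as.integer(r)
  if (L == 0L) 0L else as.integer(ceiling((L + 1) / 2))
}

#' Substitution-potential of a run sequence
#'
#' After optimal DCJ-sorting, leftover runs sit in adjacent label pairs and
#' each pair is resolved by one substitution:
#' \code{sigma = ceiling(lambda / 2)} for \code{Lambda >= 1}, else 0.
#' Always \code{sigma(C) <= lambda(C)}.
#'
#' @param r a \code{dcj_runs} object (or a bare run count).
#' @return non-negative integer.
#' @export
substitution_potential <- function(r) {
  L <- if (inherits(r, "dcj_runs")) r$lambda_count else as.integer(r)
  if (L == 0L) return(0L)
  as.integer(ceiling(indel_potential(L) / 2))
}

#' Maximum disjoint singleton pairs
#'
#' A whole-chromosome substitution may replace a singleton of one genome by
#' a singleton of the other, but only when both are linear or both are
#' circular.  Any such pair saves exactly one operation, so the maximum
#' numbers of disjoint pairs are simply the per-topology minima.
#'
#' @param comps component list from \code{\link{components}}.
#' @return list with integers \code{P_L} (linear) and \code{P_C} (circular).
#' @export
singleton_pairs <- function(comps) {
  list(P_L = min(count_kind(comps, "lin_singleton_A"),
                 count_kind(comps, "lin_singleton_B")),
       P_C = min(count_kind(comps, "circ_singleton_A"),
                 count_kind(comps, "circ_singleton_B")))
}

#' Per-component potential summary
#'
#' @param g a \code{dcj_graph}.
#' @param comps optionally, precomputed components.
#' @return a list of class \code{dcj_potentials}: per-component table
#'   (kind, Lambda, lambda, sigma), totals, and the singleton pair counts.
#' @export
potential_summary <- function(g, comps = components(g)) {
  runs <- lapply(comps, component_runs, g = g)
  Lam <- vapply(runs, function(r) r$lambda_count, integer(1))
  lam <- vapply(runs, indel_potential, integer(1))
  sig <- vapply(runs, substitution_potential, integer(1))
  stopifnot(all(sig <= lam), all((sig == 0L) == (Lam == 0L)))
  pp <- singleton_pairs(comps)
  structure(list(
    table = data.frame(kind = vapply(comps, `[[`, character(1), "kind"),
                       Lambda = Lam, lambda = lam, sigma = sig),
    runs = runs,
    sum_Lambda = sum(Lam), sum_lambda = sum(lam), sum_sigma = sum(sig),
    P_L = pp$P_L, P_C = pp$P_C), class = "dcj_potentials")
}

#' Upper bound on the DCJ-substitution distance
#'
#' \code{d_DCJ + sum(sigma) - P_L - P_C}: sort each component separately
#' with optimal DCJs, resolve leftover run pairs by substitutions, and save
#' one operation per matched singleton pair.  Recombinations between
#' components can only improve on this, so it is an upper bound, and it is
#' exact for co-tailed genomes.
#'
#' @param g a \code{dcj_graph}.
#' @param comps optionally, precomputed components.
#' @param pot optionally, a precomputed \code{\link{potential_summary}}.
#' @return non-negative integer.
#' @export
upper_bound_distance <- function(g, comps = components(g),
                                 pot = potential_summary(g, comps)) {
  as.integer(dcj_distance(g, comps) + pot$sum_sigma - pot$P_L - pot$P_C)
}

#' Tails of a genome's linear chromosomes over the common markers
#'
#' A common-marker extremity adjacent to a telomere (possibly across a
#' label of unique markers) is a tail.  Two genomes are co-tailed when
#' their tail sets coincide; genomes made only of circular chromosomes are
#' trivially co-tailed.
#'
#' @param adj an adjacency list from \code{\link{build_adjacencies}}.
#' @return character vector of extremity strings.
#' @export
genome_tails <- function(adj) {
  tails <- character(0)
  for (v in adj) {
    if (v$cs) next
    if (is.na(v$g1) && !is.na(v$g2)) tails <- c(tails, v$g2)
    if (is.na(v$g2) && !is.na(v$g1)) tails <- c(tails, v$g1)
  }
  sort(tails)
}

#' Exact distance for co-tailed genomes
#'
#' For co-tailed genomes the separate-sorting bound of
#' \code{\link{upper_bound_distance}} is the exact DCJ-substitution
#' distance; for any other pair this function signals not-applicable.
#'
#' @param a,b \code{dcj_genome} objects.
#' @return integer distance, or \code{NA_integer_} when the genomes are not
#'   co-tailed.
#' @export
cotailed_distance <- function(a, b) {
  p <- partition_markers(a, b)
  adj_a <- build_adjacencies(a, p)
  adj_b <- build_adjacencies(b, p)
  if (!identical(genome_tails(adj_a), genome_tails(adj_b)))
    return(NA_integer_)
  g <- build_graph(adj_a, adj_b, p)
  upper_bound_distance(g)
}
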