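## Brute-force distance oracle (C++ breadth-first search).

#' Brute-force DCJ-substitution distance on tiny instances
#'
#' Independent check of the closed-form distance: breadth-first search over
#' genome states, applying every DCJ and a restricted but always-sufficient
#' set of substitutions (removed blocks are maximal contiguous blocks of
#' markers absent from the target; inserted blocks appear contiguously,
#' with orientation, in the target and are not yet present).  The search
#' shares no code with the adjacency-graph computation.
#'
#' @param a,b \code{dcj_genome} objects.
#' @param max_depth search depth limit; \code{NA_integer_} is returned when
#'   no path of at most this length exists.
#' @param marker_cap refuse instances with more distinct markers than this
#'   (state space grows super-exponentially).
#' @param dcj_only disable substitutions (equal-content DCJ distance).
#' @param widen also allow non-maximal removed blocks.
#' @param node_cap abort (error) after this many visited states.
#' @return shortest number of operations transforming \code{a} into
#'   \code{b}, or \code{NA_integer_} if beyond \code{max_depth}.
#' @examples
#' gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
#' oracle_distance(gs$a, gs$b)   # 1: one substitution
#' @export
oracle_distance <- function(a, b, max_depth = 8L, marker_cap = 7L,
                            dcj_only = FALSE, widen = FALSE, node_cap = 2e6) {
  validate_genome(a); validate_genome(b)
  ids <- sort(unique(c(genome_markers(a), genome_markers(b))))
  if (length(ids) > marker_cap)
    stop(sprintf("oracle refused: %d distinct markers exceed the cap of %d",
                 length(ids), marker_cap))
  code <- stats::setNames(seq_along(ids), ids)
  enc <- function(g) lapply(g$chromosomes, function(ch)
    as.integer(marker_sign(ch$markers) * code[marker_id(ch$markers)]))
  circ <- function(g) vapply(g$chromosomes, `[[`, logical(1), "circular")
  res <- oracle_search_cpp(enc(a), circ(a), enc(b), circ(b),
                           as.integer(max_depth), isTRUE(dcj_only),
                           isTRUE(widen), node_cap)
  if (res == -3L) stop("oracle aborted: state cap exceeded")
  if (res < 0L) return(NA_integer_)
  as.integer(res)
}
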