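## Seeded genome-pair simulator with planted operations.
##
## Builds an ancestor over the common and A-unique markers, derives the
## second genome by applying a prescribed number of substitutions
## (jointly consuming every A-unique marker and introducing every
## B-unique marker) followed by random DCJ operations.  The number of
## planted operations is an upper bound on the true distance, which makes
## the generator the natural source of bounded validation instances.

#' Generate a random genome pair with a known number of planted operations
#'
#' @param n_common number of markers shared by both genomes.
#' @param n_unique_a,n_unique_b numbers of markers unique to each genome.
#' @param n_dcj number of random DCJ operations planted.
#' @param n_subst number of substitutions planted; these must jointly
#'   remove all A-unique and insert all B-unique markers, so
#'   \code{n_subst} must be between 1 and
#'   \code{n_unique_a + n_unique_b} when either is positive (and 0 when
#'   both are 0).
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments.
#' @param chromosomes number of chromosomes in the ancestor.
#' @param circular make the ancestor chromosomes circular and keep every
#'   derived chromosome circular (the pair is then co-tailed).
#' @return list with \code{a}, \code{b} (\code{dcj_genome}), and
#'   \code{planted = n_dcj + n_subst}, an upper bound on
#'   \code{dcjsub_distance(a, b)}.
#' @examples
#' sim <- random_genome_pair(5, 2, 2, n_dcj = 2, n_subst = 2, seed = 1)
#' sim$planted >= dcjsub_distance(sim$a, sim$b)$distance
#' @export
random_genome_pair <- function(n_common, n_unique_a, n_unique_b,
                               n_dcj = 0L, n_subst = 0L, seed = 1L,
                               chromosomes = 1L, circular = FALSE) {
  stopifnot(n_common >= 0L, n_unique_a >= 0L, n_unique_b >= 0L,
            n_dcj >= 0L, n_subst >= 0L, chromosomes >= 1L)
  r <- n_unique_a; s <- n_unique_b
  if (r + s == 0L) {
    if (n_subst > 0L) stop("insufficient unique markers for requested substitutions")
  } else {
    if (n_subst < 1L || n_subst > r + s)
      stop("insufficient unique markers for requested substitutions")
  }
  if (n_common + r == 0L) stop("ancestor would be empty")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  common <- if (n_common) paste0("g", seq_len(n_common)) else character(0)
  ua <- if (r) paste0("x", seq_len(r)) else character(0)
  ub <- if (s) paste0("y", seq_len(s)) else character(0)

  ## removal blocks: split the A-unique markers into a parts; insertion
  ## blocks: split the B-unique markers into b parts; op j removes block j
  ## (j <= a) and inserts block j - (n_subst - b) (when positive)
  a_parts <- min(r, n_subst); b_parts <- min(s, n_subst)
  split_blocks <- function(x, k) {
    if (k == 0L) return(list())
    x <- sample(x)
    x <- ifelse(stats::runif(length(x)) < 0.5, paste0("-", x), x)
    cuts <- sort(sample(seq_len(length(x) - 1L), k - 1L))
    unname(split(x, findInterval(seq_along(x), cuts + 0.5)))
  }
  rm_blocks <- split_blocks(ua, a_parts)
  ins_blocks <- split_blocks(ub, b_parts)

  ## ancestor: signed common markers with the removal blocks spliced in as
  ## contiguous segments, split over the requested chromosomes
  core <- if (n_common) {
    sgn <- sample(c("", "-"), n_common, replace = TRUE)
    paste0(sgn, sample(common))
  } else character(0)
  ## blocks go into gaps between core markers so that no block is ever
  ## split by a later one (adjacent blocks stay individually contiguous)
  gaps <- if (a_parts) sample.int(length(core) + 1L, a_parts, replace = TRUE) - 1L
          else integer(0)
  anc <- character(0)
  inside_block <- logical(0)     # TRUE when the boundary after a token is internal to a block
  for (pos in 0:length(core)) {
    for (j in which(gaps == pos)) {
      blk <- rm_blocks[[j]]
      anc <- c(anc, blk)
      inside_block <- c(inside_block, rep(TRUE, length(blk) - 1L), FALSE)
    }
    if (pos < length(core)) {
      anc <- c(anc, core[pos + 1L])
      inside_block <- c(inside_block, FALSE)
    }
  }
  ## chromosome splits must not cut through a planted block
  safe_cuts <- which(!inside_block[-length(inside_block)])
  k <- min(chromosomes, length(safe_cuts) + 1L, length(anc))
  cuts <- if (k > 1L) sort(safe_cuts[sample.int(length(safe_cuts), k - 1L)]) else integer(0)
  chrs <- unname(split(anc, findInterval(seq_along(anc), cuts + 0.5)))
  a_genome <- genome(chrs, name = "A", circular = circular)

  ## plant substitutions
  b_genome <- genome(chrs, name = "B", circular = circular)
  for (j in seq_len(n_subst)) {
    removed <- if (j <= a_parts) rm_blocks[[j]] else character(0)
    ins_idx <- j - (n_subst - b_parts)
    inserted <- if (ins_idx >= 1L) ins_blocks[[ins_idx]] else character(0)
    if (length(removed) == 0L && length(inserted) == 0L) next  # unreachable
    op <- list(removed = removed, inserted = inserted)
    if (length(removed) == 0L) {
      if (length(b_genome$chromosomes) == 0L) {
        op$at <- if (circular) "new_circular" else "new_linear"
      } else {
        ch <- sample.int(length(b_genome$chromosomes), 1L)
        op$at <- list(chr = ch,
                      after = sample.int(length(b_genome$chromosomes[[ch]]$markers) + 1L, 1L) - 1L)
      }
    }
    b_genome <- apply_substitution(b_genome, op)
  }
  ## plant DCJs
  for (j in seq_len(n_dcj)) {
    sset <- genome_adjset(b_genome)
    ops <- enumerate_dcjs(sset)
    if (circular) ops <- Filter(function(o) o$type != "split", ops)
    if (!length(ops)) break
    op <- ops[[sample.int(length(ops), 1L)]]
    b_genome <- adjset_genome(apply_dcj(sset, op), name = "B")
  }
  list(a = a_genome, b = b_genome,
       planted = as.integer(n_dcj + n_subst), seed = as.integer(seed))
}
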