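## Constructors for adjacency-graph components with prescribed run
## structure.  Used by the test-suite and by validation sweeps: given a
## component kind and an alternating run-tag sequence, they emit a pair of
## chromosome sets whose adjacency graph contains exactly that component
## (AB-path construction adds one clean one-edge AB-path, which is
## DCJ-sorted and inert).

chrom <- function(markers, circular = FALSE)
  list(markers = as.character(markers), circular = circular)

## place alternating run tags onto an alternating slot-side sequence;
## returns, per slot, the number of the run it carries (0 = empty)
assign_runs <- function(slot_sides, tags) {
  stopifnot(length(tags) <= 1L || all(tags[-1L] != tags[-length(tags)]))
  out <- integer(length(slot_sides))
  pos <- 0L
  for (r in seq_along(tags)) {
    repeat {
      pos <- pos + 1L
      if (pos > length(slot_sides))
        stop("not enough slots for the requested run sequence")
      if (slot_sides[pos] == tags[r]) break
    }
    out[pos] <- r
  }
  out
}

#' Build a genome pair whose adjacency graph is one prescribed component
#'
#' @param kind \code{"AA"}, \code{"BB"}, \code{"AB"} or \code{"cycle"}.
#' @param tags character vector over \code{c("A","B")}, the run sequence
#'   (must alternate); may be empty for a clean component.
#' @param ns namespace prefix for marker names, so several components can
#'   be combined into one instance.
#' @param run_len markers per run.
#' @param pad when \code{TRUE}, surround the runs with clean adjacencies
#'   (no run sits in an end vertex), which exposes every cut position of
#'   the component on both genomes.
#' @return list with \code{a}, \code{b}: lists of chromosomes
#'   (\code{list(markers, circular)}) for the two genomes.
#' @export
component_genomes <- function(kind, tags = character(0), ns = "c1", run_len = 1L,
                              pad = FALSE) {
  tags <- as.character(tags)
  L <- length(tags)
  gmk <- function(j) paste0(ns, ".g", j)
  run_block <- function(r) paste0(ns, ".", tolower(tags[r]), r,
                                  if (run_len > 1L) letters[seq_len(run_len)] else "")
  ## smallest m whose slot sequence can host the run sequence; with pad,
  ## keep the first two and last two slots clean
  fit_m <- function(make_slots) {
    for (m in max(1L, ceiling(L / 2)):(max(1L, L) + 3L)) {
      slots <- make_slots(m)
      runs <- if (pad) {
        if (length(slots) < 5L) NULL
        else {
          inner <- tryCatch(assign_runs(slots[-(1:2)], tags), error = function(e) NULL)
          if (is.null(inner)) NULL
          else {
            r <- c(0L, 0L, inner)
            ## last two slots must stay clean
            if (any(r[(length(r) - 1L):length(r)] > 0L)) NULL else r
          }
        }
      } else {
        tryCatch(assign_runs(slots, tags), error = function(e) NULL)
      }
      if (!is.null(runs)) return(list(m = m, runs = runs, slots = slots))
    }
    stop("cannot host the run sequence")
  }
  if (kind %in% c("AA", "BB")) {
    ## slots: v0 (linear side), circle1, v1, circle2, ..., circlem, vm
    slots_fun <- function(m) rep(c(if (kind == "AA") "A" else "B",
                                   if (kind == "AA") "B" else "A"),
                                 length.out = 2L * m + 1L)
    ft <- fit_m(slots_fun)
    m <- ft$m; slot_sides <- ft$slots; runs <- ft$runs
    lin <- character(0)
    circles <- vector("list", m)
    for (s in seq_along(slot_sides)) {
      blk <- if (runs[s] > 0L) run_block(runs[s]) else character(0)
      if (s %% 2L == 1L) {                 # linear-genome slot v_{(s-1)/2}
        lin <- c(lin, blk, if (s < length(slot_sides)) gmk((s + 1L) %/% 2L))
      } else {                             # circle slot, circle number s/2
        circles[[s %/% 2L]] <- c(gmk(s %/% 2L), blk)
      }
    }
    lin_chr <- list(chrom(lin))
    cir_chr <- lapply(circles, chrom, circular = TRUE)
    if (kind == "AA") list(a = lin_chr, b = cir_chr)
    else list(a = cir_chr, b = lin_chr)
  } else if (kind == "AB") {
    ## slots: v0 (A), circle1 (B), v1 (A), ..., v_{m-1} (A), end slot (B)
    ft <- fit_m(function(m) rep(c("A", "B"), m))
    m <- ft$m; slot_sides <- ft$slots; runs <- ft$runs
    lin_a <- character(0)
    circles <- if (m > 1L) vector("list", m - 1L) else list()
    end_blk <- character(0)
    for (s in seq_along(slot_sides)) {
      blk <- if (runs[s] > 0L) run_block(runs[s]) else character(0)
      if (s %% 2L == 1L) {                 # A slot v_{(s-1)/2}
        lin_a <- c(lin_a, blk, gmk((s + 1L) %/% 2L))
      } else if (s < 2L * m) {             # circle slot s/2
        circles[[s %/% 2L]] <- c(gmk(s %/% 2L), blk)
      } else {                             # B end slot, before g_m
        end_blk <- blk
      }
    }
    list(a = list(chrom(lin_a)),
         b = c(lapply(circles, chrom, circular = TRUE),
               list(chrom(c(end_blk, gmk(m))))))
  } else if (kind == "cycle") {
    ## cyclic slots: adjacency(g1,g2) [A], circle2 [B], adjacency(g2,g3),
    ## circle3, ..., adjacency(gm,g1), circle1
    ft <- fit_m(function(m) rep(c("A", "B"), m))
    m <- ft$m; slot_sides <- ft$slots; runs <- ft$runs
    circ_a <- character(0)
    circles <- vector("list", m)
    for (j in seq_len(m)) {
      sa <- 2L * j - 1L                     # adjacency g_j -> g_{j+1}
      sb <- 2L * j                          # circle for g_{j+1 (cyclic)}
      blk_a <- if (runs[sa] > 0L) run_block(runs[sa]) else character(0)
      blk_b <- if (runs[sb] > 0L) run_block(runs[sb]) else character(0)
      circ_a <- c(circ_a, gmk(j), blk_a)
      circles[[j %% m + 1L]] <- blk_b
    }
    for (j in seq_len(m)) circles[[j]] <- c(gmk(j), circles[[j]])
    list(a = list(chrom(circ_a, circular = TRUE)),
         b = lapply(circles, chrom, circular = TRUE))
  } else if (kind %in% c("lin_singleton_A", "lin_singleton_B",
                         "circ_singleton_A", "circ_singleton_B")) {
    stopifnot(length(tags) == 1L)
    ch <- chrom(run_block(1L), circular = grepl("^circ", kind))
    if (grepl("_A$", kind)) list(a = list(ch), b = list())
    else list(a = list(), b = list(ch))
  } else stop("unknown component kind")
}

#' Combine component constructions into a genome pair
#' @param parts list of results from \code{\link{component_genomes}} (with
#'   distinct namespaces).
#' @param names_ab names for the two genomes.
#' @return list with \code{a}, \code{b}: \code{dcj_genome} objects.
#' @export
instance_genomes <- function(parts, names_ab = c("A", "B")) {
  a <- unlist(lapply(parts, `[[`, "a"), recursive = FALSE)
  b <- unlist(lapply(parts, `[[`, "b"), recursive = FALSE)
  list(a = genome(a, name = names_ab[1L]),
       b = genome(b, name = names_ab[2L]))
}
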