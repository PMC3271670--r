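## Labeled adjacencies and the adjacency graph AG(A, B).
##
## Over the common-marker set, each genome decomposes into adjacencies: a
## pair of marker extremities (or chromosome-end telomeres) together with
## the label of unique markers lying between them.  The bipartite adjacency
## graph has one vertex per adjacency and, for every common marker, one
## edge for its head and one for its tail; it decomposes into cycles,
## AA-/BB-/AB-paths and singleton chromosomes, and carries the whole
## distance computation.

ext_head <- function(id) paste0(id, ":h")
ext_tail <- function(id) paste0(id, ":t")
ext_marker <- function(e) sub(":[ht]$", "", e)

## extremity of a signed token facing left/right in reading direction
left_ext  <- function(tok) if (startsWith(tok, "-")) ext_head(marker_id(tok)) else ext_tail(marker_id(tok))
right_ext <- function(tok) if (startsWith(tok, "-")) ext_tail(marker_id(tok)) else ext_head(marker_id(tok))

new_adjacency <- function(g1, g2, label, circular_singleton = FALSE) {
  list(g1 = g1, g2 = g2, label = label, cs = circular_singleton)
}

#' Build the labeled adjacencies of one genome
#'
#' Walks every chromosome and emits one adjacency per pair of consecutive
#' common-marker extremities (telomeres included for linear chromosomes),
#' with the unique markers in between recorded as the adjacency label.  A
#' chromosome holding no common marker yields a singleton: one
#' telomere-to-telomere adjacency if linear, or a circular label if
#' circular.
#'
#' @param g a \code{dcj_genome}.
#' @param p a \code{dcj_partition} from \code{\link{partition_markers}}.
#' @return a list of adjacencies, each a list with elements \code{g1},
#'   \code{g2} (extremity strings \code{"id:h"}/\code{"id:t"}, or \code{NA}
#'   for a telomere), \code{label} (signed tokens read from \code{g1} to
#'   \code{g2}) and \code{cs} (circular-singleton flag).
#' @export
build_adjacencies <- function(g, p) {
  common <- p$common
  out <- list()
  for (ch in g$chromosomes) {
    m <- ch$markers
    is_c <- marker_id(m) %in% common
    pos <- which(is_c)
    k <- length(pos)
    if (k == 0L) {
      out <- c(out, list(new_adjacency(
        if (ch$circular) NULL else NA_character_,
        if (ch$circular) NULL else NA_character_,
        m, circular_singleton = ch$circular)))
      next
    }
    if (!ch$circular) {
      segs <- vector("list", k + 1L)
      bounds_g1 <- c(NA_character_, unname(vapply(m[pos], right_ext, character(1))))
      bounds_g2 <- c(unname(vapply(m[pos], left_ext, character(1))), NA_character_)
      cuts <- c(0L, pos, length(m) + 1L)
      for (j in seq_len(k + 1L)) {
        lab <- if (cuts[j] + 1L <= cuts[j + 1L] - 1L) m[(cuts[j] + 1L):(cuts[j + 1L] - 1L)] else character(0)
        segs[[j]] <- new_adjacency(bounds_g1[j], bounds_g2[j], lab)
      }
      out <- c(out, segs)
    } else {
      segs <- vector("list", k)
      L <- length(m)
      for (j in seq_len(k)) {
        from <- pos[j]
        to <- pos[if (j == k) 1L else j + 1L]
        idx <- integer(0)
        t <- from
        repeat {
          t <- if (t == L) 1L else t + 1L
          if (t == to) break
          idx <- c(idx, t)
        }
        segs[[j]] <- new_adjacency(right_ext(m[from]), left_ext(m[to]), m[idx])
      }
      out <- c(out, segs)
    }
  }
  ## every label must consist of unique markers only
  for (v in out)
    stopifnot(!any(marker_id(v$label) %in% common))
  out
}

#' Build the adjacency graph of two genomes
#'
#' @param adj_a,adj_b adjacency lists from \code{\link{build_adjacencies}},
#'   computed against the same partition.
#' @param p the \code{dcj_partition}.
#' @return an object of class \code{dcj_graph}: the two vertex lists, the
#'   edge table (one row per common-marker extremity) and the partition.
#' @export
build_graph <- function(adj_a, adj_b, p) {
  locate <- function(adj, side) {
    keys <- character(0); vid <- integer(0)
    for (i in seq_along(adj)) {
      v <- adj[[i]]
      for (e in c(v$g1, v$g2)) {
        if (is.null(e) || is.na(e)) next
        keys <- c(keys, e); vid <- c(vid, i)
      }
    }
    if (anyDuplicated(keys))
      stop(sprintf("extremity '%s' occurs twice in genome %s",
                   keys[duplicated(keys)][1L], side))
    stats::setNames(vid, keys)
  }
  la <- locate(adj_a, "A"); lb <- locate(adj_b, "B")
  exts <- as.vector(rbind(ext_head(p$common), ext_tail(p$common)))
  if (length(p$common)) {
    missing_a <- exts[!exts %in% names(la)]
    missing_b <- exts[!exts %in% names(lb)]
    if (length(missing_a) || length(missing_b))
      stop("common-marker extremity absent from an adjacency list")
  }
  edges <- data.frame(a = unname(la[exts]), b = unname(lb[exts]),
                      ext = exts, stringsAsFactors = FALSE)
  if (length(p$common) == 0L)
    edges <- data.frame(a = integer(0), b = integer(0), ext = character(0))
  structure(list(va = adj_a, vb = adj_b, edges = edges, partition = p),
            class = "dcj_graph")
}

#' Adjacency graph from a genome pair
#' @param a,b \code{dcj_genome} objects.
#' @return a \code{dcj_graph}.
#' @export
adjacency_graph <- function(a, b) {
  p <- partition_markers(a, b)
  build_graph(build_adjacencies(a, p), build_adjacencies(b, p), p)
}

## ---- Connected components -------------------------------------------------

vertex_degree <- function(v) {
  if (v$cs) return(0L)
  sum(!is.na(c(v$g1, v$g2)))
}

#' Connected components of the adjacency graph
#'
#' Cycles and paths alternate vertices of the two genomes; paths are typed
#' by the genome membership of their endpoints (AA, BB or AB).  Whole
#' chromosomes of unique markers appear as linear or circular singletons;
#' linear singletons are degenerate AA-/BB-paths, circular singletons stand
#' outside the path/cycle decomposition.
#'
#' @param g a \code{dcj_graph}.
#' @return a list of components; each has \code{kind} (\code{"cycle"},
#'   \code{"AA"}, \code{"BB"}, \code{"AB"}, \code{"lin_singleton_A"}, ...),
#'   \code{side} and \code{idx} (parallel vectors giving the vertex walk;
#'   AB-paths are listed from the genome-A endpoint), and \code{n_edges}.
#' @export
components <- function(g) {
  va <- g$va; vb <- g$vb
  ## incidence: per vertex, the ids of incident edge rows
  inc_a <- rep(list(integer(0)), length(va))
  inc_b <- rep(list(integer(0)), length(vb))
  if (nrow(g$edges)) for (e in seq_len(nrow(g$edges))) {
    inc_a[[g$edges$a[e]]] <- c(inc_a[[g$edges$a[e]]], e)
    inc_b[[g$edges$b[e]]] <- c(inc_b[[g$edges$b[e]]], e)
  }
  deg <- function(side, i) if (side == "A") length(inc_a[[i]]) else length(inc_b[[i]])
  seen_a <- logical(length(va)); seen_b <- logical(length(vb))
  comps <- list()

  walk <- function(side, i, via) {
    ## follow the path/cycle starting at vertex (side, i), entering via edge
    ## `via` (0 for a fresh endpoint); returns the ordered vertex walk
    sides <- character(0); idxs <- integer(0); used <- integer(0)
    repeat {
      sides <- c(sides, side); idxs <- c(idxs, i)
      if (side == "A") seen_a[i] <<- TRUE else seen_b[i] <<- TRUE
      inc <- if (side == "A") inc_a[[i]] else inc_b[[i]]
      nxt <- setdiff(inc, used)
      if (via != 0L) nxt <- setdiff(nxt, via)
      if (length(nxt) == 0L) break
      e <- nxt[1L]
      used <- c(used, e, via)
      via <- e
      if (side == "A") { i <- g$edges$b[e]; side <- "B" }
      else             { i <- g$edges$a[e]; side <- "A" }
      if ((side == "A" && seen_a[i]) || (side == "B" && seen_b[i])) break  # closed a cycle
    }
    list(sides = sides, idxs = idxs, used = length(used[used != 0L]))
  }

  ## singletons first
  for (i in seq_along(va)) if (vertex_degree(va[[i]]) == 0L) {
    seen_a[i] <- TRUE
    comps <- c(comps, list(list(
      kind = if (va[[i]]$cs) "circ_singleton_A" else "lin_singleton_A",
      side = "A", idx = i, n_edges = 0L)))
  }
  for (i in seq_along(vb)) if (vertex_degree(vb[[i]]) == 0L) {
    seen_b[i] <- TRUE
    comps <- c(comps, list(list(
      kind = if (vb[[i]]$cs) "circ_singleton_B" else "lin_singleton_B",
      side = "B", idx = i, n_edges = 0L)))
  }
  ## open paths from degree-1 vertices
  for (side in c("A", "B")) {
    nv <- if (side == "A") length(va) else length(vb)
    for (i in seq_len(nv)) {
      seen <- if (side == "A") seen_a[i] else seen_b[i]
      if (seen || deg(side, i) != 1L) next
      w <- walk(side, i, 0L)
      ends <- c(w$sides[1L], w$sides[length(w$sides)])
      kind <- if (all(ends == "A")) "AA" else if (all(ends == "B")) "BB" else "AB"
      if (kind == "AB" && w$sides[1L] != "A") {  # read AB-paths from A to B
        w$sides <- rev(w$sides); w$idxs <- rev(w$idxs)
      }
      comps <- c(comps, list(list(kind = kind, side = w$sides, idx = w$idxs,
                                  n_edges = length(w$sides) - 1L)))
    }
  }
  ## remaining vertices lie on cycles
  for (i in seq_along(va)) {
    if (seen_a[i]) next
    w <- walk("A", i, 0L)
    ## walk() stops when it would revisit the start; drop nothing, the walk
    ## lists each cycle vertex exactly once
    comps <- c(comps, list(list(kind = "cycle", side = w$sides, idx = w$idxs,
                                n_edges = length(w$sides))))
  }
  for (i in seq_along(vb)) {
    if (seen_b[i]) next
    w <- walk("B", i, 0L)
    comps <- c(comps, list(list(kind = "cycle", side = w$sides, idx = w$idxs,
                                n_edges = length(w$sides))))
  }
  comps
}

count_kind <- function(comps, kind)
  sum(vapply(comps, function(cc) cc$kind == kind, logical(1)))

#' DCJ distance from the adjacency graph
#'
#' The classical closed form over the common markers: \code{n - (c + b/2)},
#' where \code{c} is the number of cycles and \code{b} the number of
#' AB-paths.  The AB-path count is always even; this is asserted rather
#' than rounded.
#'
#' @param g a \code{dcj_graph}.
#' @param comps optionally, precomputed \code{\link{components}}.
#' @return non-negative integer.
#' @examples
#' gs <- parse_genomes(">A\n1 2 3 $\n", ">B\n1 -2 3 $\n")
#' dcj_distance(adjacency_graph(gs$a, gs$b))   # one inversion
#' @export
dcj_distance <- function(g, comps = components(g)) {
  ccount <- count_kind(comps, "cycle")
  b <- count_kind(comps, "AB")
  stopifnot(b %% 2L == 0L)
  d <- g$partition$n - (ccount + b %/% 2L)
  stopifnot(d >= 0L)
  as.integer(d)
}

component_label_list <- function(g, cc) {
  if (cc$kind %in% c("lin_singleton_A", "lin_singleton_B",
                     "circ_singleton_A", "circ_singleton_B"))
    return(list(list(side = cc$side,
                     label = (if (cc$side == "A") g$va else g$vb)[[cc$idx]]$label)))
  lapply(seq_along(cc$side), function(j) {
    v <- (if (cc$side[j] == "A") g$va else g$vb)[[cc$idx[j]]]
    list(side = cc$side[j], label = v$label)
  })
}
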