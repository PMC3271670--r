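## Operation engine: DCJ and substitution, applied to whole genomes.
##
## For operations a genome is most conveniently a set of adjacencies over
## *all* of its markers (not just the common ones): every marker has a head
## and a tail extremity; consecutive extremities form adjacencies and
## chromosome ends are telomeres.  A DCJ cuts two of these elements and
## rejoins the open ends differently; special cases use one element only
## (joining two telomeres, or splitting one adjacency into two telomeres).

#' Full-resolution adjacency set of a genome
#'
#' @param g a \code{dcj_genome}.
#' @return list with \code{adjacencies} (list of length-2 extremity
#'   vectors), \code{telomeres} (character vector) and \code{markers}
#'   (ids present).
#' @export
genome_adjset <- function(g) {
  adj <- list(); tel <- character(0)
  for (ch in g$chromosomes) {
    m <- ch$markers; L <- length(m)
    if (L > 1L)
      for (i in seq_len(L - 1L))
        adj <- c(adj, list(c(right_ext(m[i]), left_ext(m[i + 1L]))))
    if (ch$circular) {
      adj <- c(adj, list(c(right_ext(m[L]), left_ext(m[1L]))))
    } else {
      tel <- c(tel, left_ext(m[1L]), right_ext(m[L]))
    }
  }
  list(adjacencies = adj, telomeres = tel, markers = sort(genome_markers(g)))
}

#' Rebuild a genome from a full-resolution adjacency set
#'
#' @param s an adjacency set as returned by \code{\link{genome_adjset}}.
#' @param name genome name.
#' @return a \code{dcj_genome}; chromosomes are emitted in a deterministic
#'   order (linear ones from the lexicographically first telomere, then
#'   circular ones from their smallest marker).
#' @export
adjset_genome <- function(s, name = "genome") {
  partner <- character(0)
  for (ad in s$adjacencies) {
    partner[ad[1L]] <- ad[2L]
    partner[ad[2L]] <- ad[1L]
  }
  other_ext <- function(e)
    if (endsWith(e, ":t")) ext_head(ext_marker(e)) else ext_tail(ext_marker(e))
  tok_from_entry <- function(e)
    if (endsWith(e, ":t")) ext_marker(e) else paste0("-", ext_marker(e))
  visited <- character(0)
  chrs <- list(); circ <- logical(0)
  for (t in sort(s$telomeres)) {
    if (ext_marker(t) %in% visited) next
    toks <- character(0); e <- t
    repeat {
      toks <- c(toks, tok_from_entry(e))
      visited <- c(visited, ext_marker(e))
      out <- other_ext(e)
      nxt <- partner[out]
      if (is.na(nxt)) break
      e <- nxt
    }
    chrs <- c(chrs, list(toks)); circ <- c(circ, FALSE)
  }
  for (m in sort(s$markers)) {
    if (m %in% visited) next
    toks <- character(0); e <- ext_tail(m)
    repeat {
      toks <- c(toks, tok_from_entry(e))
      visited <- c(visited, ext_marker(e))
      nxt <- partner[other_ext(e)]
      stopifnot(!is.na(nxt))
      if (ext_marker(nxt) == m && nxt == ext_tail(m)) break
      e <- nxt
    }
    chrs <- c(chrs, list(toks)); circ <- c(circ, TRUE)
  }
  genome(chrs, name = name, circular = circ)
}

adj_key <- function(ad) paste(sort(ad), collapse = "|")

#' Enumerate all DCJ operations on a genome
#'
#' Covers the four forms: two adjacencies rejoined crosswise (two ways),
#' one adjacency against a telomere (two ways), a join of two telomeres,
#' and a split of one adjacency into two telomeres.
#'
#' @param s a full-resolution adjacency set.
#' @return list of DCJ operation descriptors for \code{\link{apply_dcj}}.
#' @export
enumerate_dcjs <- function(s) {
  ops <- list()
  na <- length(s$adjacencies); nt <- length(s$telomeres)
  if (na >= 2L) for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
    ops <- c(ops, list(list(type = "aa", i = i, j = j, mode = 1L),
                       list(type = "aa", i = i, j = j, mode = 2L)))
  }
  if (na >= 1L && nt >= 1L) for (i in seq_len(na)) for (t in seq_len(nt)) {
    ops <- c(ops, list(list(type = "at", i = i, t = t, mode = 1L),
                       list(type = "at", i = i, t = t, mode = 2L)))
  }
  if (nt >= 2L) for (t1 in seq_len(nt - 1L)) for (t2 in (t1 + 1L):nt)
    ops <- c(ops, list(list(type = "tt", t1 = t1, t2 = t2)))
  if (na >= 1L) for (i in seq_len(na))
    ops <- c(ops, list(list(type = "split", i = i)))
  ops
}

#' Apply a DCJ operation
#'
#' @param s a full-resolution adjacency set (see \code{\link{genome_adjset}}).
#' @param op an operation descriptor from \code{\link{enumerate_dcjs}}.
#' @return the new adjacency set.  Applying the inverse DCJ (the same cut
#'   elements with the complementary rejoining) restores the input.
#' @export
apply_dcj <- function(s, op) {
  adj <- s$adjacencies; tel <- s$telomeres
  if (op$type == "aa") {
    stopifnot(op$i <= length(adj), op$j <= length(adj), op$i != op$j)
    a <- adj[[op$i]]; b <- adj[[op$j]]
    new <- if (op$mode == 1L) list(c(a[1L], b[1L]), c(a[2L], b[2L]))
           else               list(c(a[1L], b[2L]), c(a[2L], b[1L]))
    adj <- c(adj[-c(op$i, op$j)], new)
  } else if (op$type == "at") {
    stopifnot(op$i <= length(adj), op$t <= length(tel))
    a <- adj[[op$i]]; t <- tel[[op$t]]
    if (op$mode == 1L) { new <- c(a[1L], t); freed <- a[2L] }
    else               { new <- c(a[2L], t); freed <- a[1L] }
    adj <- c(adj[-op$i], list(new))
    tel <- c(tel[-op$t], freed)
  } else if (op$type == "tt") {
    stopifnot(op$t1 <= length(tel), op$t2 <= length(tel), op$t1 != op$t2)
    adj <- c(adj, list(c(tel[[op$t1]], tel[[op$t2]])))
    tel <- tel[-c(op$t1, op$t2)]
  } else if (op$type == "split") {
    stopifnot(op$i <= length(adj))
    tel <- c(tel, s$adjacencies[[op$i]])
    adj <- adj[-op$i]
  } else stop("unknown DCJ operation type")
  list(adjacencies = adj, telomeres = tel, markers = s$markers)
}

#' Apply a substitution operation to a genome
#'
#' Replaces one contiguous block of markers by another at the same
#' position.  \code{removed} empty gives an insertion (the position is
#' named by \code{at}); \code{inserted} empty gives a deletion.  A whole
#' chromosome may be substituted at once, keeping its topology; converting
#' a linear chromosome into a circular one (or back) is an error.
#'
#' @param g a \code{dcj_genome}.
#' @param op list with \code{removed} (signed block, possibly empty),
#'   \code{inserted} (signed block, possibly empty) and, for pure
#'   insertions, \code{at}: either \code{list(chr =, after =)} (insert into
#'   chromosome \code{chr} after marker position \code{after}, 0 for the
#'   start) or \code{"new_linear"} / \code{"new_circular"}.
#' @return the modified \code{dcj_genome}.
#' @export
apply_substitution <- function(g, op) {
  removed <- as.character(op$removed %||% character(0))
  inserted <- as.character(op$inserted %||% character(0))
  if (length(removed) == 0L && length(inserted) == 0L)
    stop("substitution with both blocks empty")
  if (any(marker_id(inserted) %in% genome_markers(g)) &&
      !all(marker_id(inserted) %in% marker_id(removed)))
    stop("inserted markers already present in the genome")
  chrs <- lapply(g$chromosomes, function(ch) list(markers = ch$markers,
                                                  circular = ch$circular))
  if (length(removed) == 0L) {
    at <- op$at
    if (identical(at, "new_linear")) {
      chrs <- c(chrs, list(list(markers = inserted, circular = FALSE)))
    } else if (identical(at, "new_circular")) {
      chrs <- c(chrs, list(list(markers = inserted, circular = TRUE)))
    } else {
      stopifnot(is.list(at), at$chr <= length(chrs))
      m <- chrs[[at$chr]]$markers
      stopifnot(at$after >= 0L, at$after <= length(m))
      chrs[[at$chr]]$markers <- append(m, inserted, after = at$after)
    }
    return(genome(chrs, name = g$name))
  }
  ## locate the removed block as a contiguous subsequence (either reading
  ## direction; circular chromosomes wrap)
  loc <- NULL
  for (ci in seq_along(chrs)) {
    m <- chrs[[ci]]$markers
    for (blk in list(removed, flip_markers(removed))) {
      hit <- find_block(m, blk, chrs[[ci]]$circular)
      if (!is.null(hit)) { loc <- c(list(chr = ci, flipped = !identical(blk, removed)), hit); break }
    }
    if (!is.null(loc)) break
  }
  if (is.null(loc))
    stop("removed block is not a contiguous segment of the genome")
  ci <- loc$chr
  m <- chrs[[ci]]$markers
  ins <- if (loc$flipped) flip_markers(inserted) else inserted
  if (length(loc$keep) == 0L) {
    ## whole-chromosome substitution: topology preserved
    topo <- chrs[[ci]]$circular
    if (!is.null(op$topology) &&
        !identical(op$topology, if (topo) "circular" else "linear"))
      stop("cannot substitute a linear chromosome by a circular one (or back)")
    if (length(ins) == 0L) chrs <- chrs[-ci]
    else chrs[[ci]]$markers <- ins
  } else {
    chrs[[ci]]$markers <- append(m[loc$keep], ins, after = loc$insert_after)
  }
  genome(chrs, name = g$name)
}

## find `blk` as contiguous subsequence of m (wrapping if circular);
## returns NULL or list(keep = indices of m to keep in order, insert_after)
find_block <- function(m, blk, circular) {
  L <- length(m); k <- length(blk)
  if (k == 0L || k > L) return(NULL)
  starts <- seq_len(if (circular) L else L - k + 1L)
  for (st in starts) {
    idx <- ((st - 1L) + seq_len(k) - 1L) %% L + 1L
    if (!circular && any(idx < st)) next
    if (identical(m[idx], blk)) {
      keep <- setdiff(seq_len(L), idx)
      if (circular && length(keep)) {
        ## rotate so kept markers are consecutive from just after the block
        endpos <- idx[k]
        ord <- order(((keep - endpos - 1L) %% L))
        keep <- keep[ord]
        return(list(keep = keep, insert_after = length(keep)))
      }
      return(list(keep = keep, insert_after = st - 1L))
    }
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- Junction attribution and delta metrics -------------------------------

## Map every full-resolution junction (adjacency pair key or telomere
## extremity) of genome `g` to the index of the labeled adjacency that
## contains it, in build_adjacencies() order.
junction_vertex_map <- function(g, p) {
  common <- p$common
  map <- integer(0)
  base <- 0L
  for (ch in g$chromosomes) {
    m <- ch$markers; L <- length(m)
    is_c <- marker_id(m) %in% common
    k <- sum(is_c)
    cum <- cumsum(is_c)
    if (!ch$circular) {
      nseg <- k + 1L
      if (k == 0L) nseg <- 1L
      map[left_ext(m[1L])] <- base + 1L
      map[right_ext(m[L])] <- base + nseg
      if (L > 1L) for (t in seq_len(L - 1L)) {
        key <- adj_key(c(right_ext(m[t]), left_ext(m[t + 1L])))
        map[key] <- base + (if (k == 0L) 1L else cum[t] + 1L)
      }
      base <- base + nseg
    } else {
      nseg <- max(k, 1L)
      for (t in seq_len(L)) {
        nx <- if (t == L) 1L else t + 1L
        key <- adj_key(c(right_ext(m[t]), left_ext(m[nx])))
        v <- if (k == 0L) 1L else if (t == L || cum[t] == 0L) k else cum[t]
        map[key] <- base + v
      }
      base <- base + nseg
    }
  }
  map
}

graph_metrics <- function(a, b) {
  g <- adjacency_graph(a, b)
  comps <- components(g)
  pot <- potential_summary(g, comps)
  list(graph = g, comps = comps, pot = pot,
       c = count_kind(comps, "cycle"), b = count_kind(comps, "AB"),
       d_dcj = dcj_distance(g, comps))
}

#' Measure the effect of one operation on the graph invariants
#'
#' Applies a DCJ (or substitution) to genome \code{a} and reports the
#' change in run count, substitution-potential total and DCJ class:
#' a DCJ is optimal when it raises the cycle count by one or the AB-path
#' count by two (\code{delta_dcj = 0}), neutral when it changes neither
#' (\code{+1}), counter-optimal otherwise (\code{+2});
#' \code{delta_d = delta_dcj + delta_sigma}.
#'
#' @param a,b \code{dcj_genome} objects (the operation acts on \code{a}).
#' @param op a DCJ descriptor (from \code{\link{enumerate_dcjs}} over
#'   \code{genome_adjset(a)}) or a substitution descriptor with an element
#'   \code{substitution = TRUE}.
#' @return list with \code{delta_lambda_runs}, \code{delta_sigma},
#'   \code{delta_dcj}, \code{delta_d}, \code{dcj_class}, the new genome
#'   \code{a_after}, and \code{source_components} (component ids of the two
#'   cut positions, for DCJs).
#' @export
measure_deltas <- function(a, b, op) {
  before <- graph_metrics(a, b)
  if (isTRUE(op$substitution)) {
    a2 <- apply_substitution(a, op)
    after <- graph_metrics(a2, b)
    return(list(delta_lambda_runs = after$pot$sum_Lambda - before$pot$sum_Lambda,
                delta_sigma = after$pot$sum_sigma - before$pot$sum_sigma,
                delta_dcj = NA_integer_, delta_d = NA_integer_,
                dcj_class = NA_character_, a_after = a2,
                source_components = NULL))
  }
  s <- genome_adjset(a)
  a2 <- adjset_genome(apply_dcj(s, op), name = a$name)
  after <- graph_metrics(a2, b)
  dc <- after$c - before$c; db <- after$b - before$b
  cls <- if (dc == 1L || db == 2L) "optimal"
         else if (dc == 0L && db == 0L) "neutral"
         else "counter-optimal"
  ddcj <- c(optimal = 0L, neutral = 1L, `counter-optimal` = 2L)[[cls]]
  ## attribute the cut positions to components of the graph before the op
  jm <- junction_vertex_map(a, before$graph$partition)
  keys <- switch(op$type,
    aa = c(adj_key(s$adjacencies[[op$i]]), adj_key(s$adjacencies[[op$j]])),
    at = c(adj_key(s$adjacencies[[op$i]]), s$telomeres[[op$t]]),
    tt = c(s$telomeres[[op$t1]], s$telomeres[[op$t2]]),
    split = adj_key(s$adjacencies[[op$i]]))
  vids <- unname(jm[keys])
  comp_of <- integer(length(before$graph$va))
  for (ci in seq_along(before$comps)) {
    cc <- before$comps[[ci]]
    av <- cc$idx[cc$side == "A"]
    comp_of[av] <- ci
  }
  list(delta_lambda_runs = after$pot$sum_Lambda - before$pot$sum_Lambda,
       delta_sigma = after$pot$sum_sigma - before$pot$sum_sigma,
       delta_dcj = ddcj,
       delta_d = ddcj + (after$pot$sum_sigma - before$pot$sum_sigma),
       dcj_class = cls, a_after = a2,
       source_components = comp_of[vids])
}
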