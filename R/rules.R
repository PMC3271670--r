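## Recombination rule engine.
##
## A recombination is a DCJ whose two cut positions (or cut and telomere,
## or two telomeres) lie in two different path components.  At the level
## of run sequences its effect is a splice: each path's run-tag sequence
## is split at a between-run boundary, the pieces are exchanged, and
## adjacent runs of the same genome merge at the junction.  This module
## enumerates every recombination available to a pair of path components
## from their kind, run sequence and singleton status alone, which is
## exactly the information the distance formula is allowed to use.
##
## Conservative availability rules (valid for every representative of a
## class): a cut on genome X exists at any internal between-run boundary;
## at the extreme ends only when the path end or the adjacent run belongs
## to X; runs are never split (splitting raises the run count and never
## helps).  Linear singletons expose only their own genome's positions.

sigma_of_lambda <- function(L) if (L == 0L) 0L else L %/% 4L + 1L

## path token: kind AA/BB/AB, tags (AB-paths stored reading A -> B),
## single = "" (proper path) | "A" | "B" (linear singleton of that genome)
path_token <- function(kind, tags, single = "") {
  list(kind = kind, tags = as.character(tags), single = single)
}

token_ends <- function(tok)
  switch(tok$kind, AA = c("A", "A"), BB = c("B", "B"), AB = c("A", "B"))

token_key <- function(tok) {
  L <- length(tok$tags)
  first <- if (L == 0L) "-" else tok$tags[1L]
  last <- if (L == 0L) "-" else tok$tags[L]
  ## AA/BB paths read either way: canonicalize orientation
  if (tok$kind %in% c("AA", "BB") && L > 0L && last < first) {
    first <- last
  }
  paste(tok$kind, L, first, tok$single, sep = "|")
}

token_sigma <- function(tok) sigma_of_lambda(length(tok$tags))

## splice two tag sequences, merging equal tags at the junction
splice_tags <- function(u, v) {
  if (length(u) && length(v) && u[length(u)] == v[1L]) c(u, v[-1L])
  else c(u, v)
}

rev_tags <- function(u) rev(u)

## cut positions available on genome X (0..Lambda, between runs).  Every
## between-run boundary of a proper path is reachable on either genome:
## runs alternate, so each boundary touches a vertex of each genome or
## lies next to clean vertices of the other genome.  The optimum proved
## for the distance depends only on component types, so positions are
## enumerated in full; a linear singleton only has vertices of its own
## genome and is the one genuinely restricted case.
cut_positions <- function(tok, X) {
  if (tok$single != "" && tok$single != X) return(integer(0))
  0L:length(tok$tags)
}

## orientations under which a path may be read (tags, ends)
token_orientations <- function(tok) {
  o1 <- list(tags = tok$tags, ends = token_ends(tok))
  if (tok$kind == "AB") return(list(o1))
  o2 <- list(tags = rev_tags(tok$tags), ends = token_ends(tok))
  if (identical(o1$tags, o2$tags)) list(o1) else list(o1, o2)
}

make_result_token <- function(left_end, right_end, tags, single) {
  kind <- if (left_end == "A" && right_end == "A") "AA"
          else if (left_end == "B" && right_end == "B") "BB" else "AB"
  if (kind == "AB" && left_end == "B") tags <- rev_tags(tags)
  path_token(kind, tags, single)
}

## singleton flag of a resultant assembled from two pieces; conservative:
## a piece of a singleton stays restricted to its genome unless the other
## contribution carries content of the other source
piece_single <- function(sP, tagsP, sQ, tagsQ) {
  if (length(tagsP) && length(tagsQ)) return("")
  if (length(tagsP) == 0L && length(tagsQ) == 0L) return("")
  if (length(tagsQ) == 0L) sP else sQ
}

#' Enumerate recombinations between two path components
#'
#' All DCJ operations with one cut (or telomere) in each of the two
#' components, described at the run-sequence level: ordinary double cuts
#' with both crosswise rejoinings, cut-plus-telomere operations, and
#' telomere-telomere joins.  Only the component kind, run sequence and
#' singleton status enter, so the output applies to every genome pair
#' presenting these two components.
#'
#' @param tok1,tok2 path tokens from \code{path_token()}.
#' @return list of rows: \code{delta_sigma}, \code{delta_dcj} (0 optimal,
#'   1 neutral, 2 counter-optimal), \code{delta_d}, and \code{res}, the
#'   resultant path tokens (clean resultants are kept; circular pieces
#'   cannot arise from path recombinations).
#' @export
recombination_rows <- function(tok1, tok2, genomes = c("A", "B")) {
  rows <- list()
  b_before <- sum(tok1$kind == "AB", tok2$kind == "AB")
  sig_before <- token_sigma(tok1) + token_sigma(tok2)
  emit <- function(res) {
    b_after <- 0L; sig_after <- 0L
    for (t in res) {
      if (t$kind == "AB") b_after <- b_after + 1L
      L <- length(t$tags)
      if (L > 0L) sig_after <- sig_after + L %/% 4L + 1L
    }
    db <- b_after - b_before
    ddcj <- if (db == 2L) 0L else if (db == 0L) 1L else 2L
    dsig <- sig_after - sig_before
    rows[[length(rows) + 1L]] <<- list(delta_sigma = dsig, delta_dcj = ddcj,
                                       delta_d = ddcj + dsig, res = res)
  }
  for (X in genomes) {
    s1ok <- tok1$single == "" || tok1$single == X
    s2ok <- tok2$single == "" || tok2$single == X
    or1 <- token_orientations(tok1)
    or2 <- token_orientations(tok2)
    ## --- double cut, crosswise rejoin
    if (s1ok && s2ok) for (o1 in or1) for (o2 in or2) {
      p1c <- cut_positions(list(kind = tok1$kind, tags = o1$tags,
                                single = tok1$single), X)
      p2c <- cut_positions(list(kind = tok2$kind, tags = o2$tags,
                                single = tok2$single), X)
      for (cp in p1c) for (cq in p2c) {
        P1 <- o1$tags[seq_len(cp)]
        P2 <- if (cp == 0L) o1$tags else o1$tags[-seq_len(cp)]
        Q1 <- o2$tags[seq_len(cq)]
        Q2 <- if (cq == 0L) o2$tags else o2$tags[-seq_len(cq)]
        ## mode 1: left1+right2, left2+right1
        emit(list(
          make_result_token(o1$ends[1L], o2$ends[2L], splice_tags(P1, Q2),
                            piece_single(tok1$single, P1, tok2$single, Q2)),
          make_result_token(o2$ends[1L], o1$ends[2L], splice_tags(Q1, P2),
                            piece_single(tok2$single, Q1, tok1$single, P2))))
        ## mode 2: left1+rev(left2), rev(right1)+right2
        emit(list(
          make_result_token(o1$ends[1L], o2$ends[1L], splice_tags(P1, rev_tags(Q1)),
                            piece_single(tok1$single, P1, tok2$single, Q1)),
          make_result_token(o1$ends[2L], o2$ends[2L], splice_tags(rev_tags(P2), Q2),
                            piece_single(tok1$single, P2, tok2$single, Q2))))
      }
    }
    ## --- cut in one component, join the other at a telomere
    ## orient Q so that the chosen telomere end sits at the left
    q_left_orients <- function(tokQ) {
      e <- token_ends(tokQ)
      out <- list(list(tags = tokQ$tags, ends = e))
      out <- c(out, list(list(tags = rev_tags(tokQ$tags), ends = rev(e))))
      out[!duplicated(vapply(out, function(o)
        paste(paste(o$tags, collapse = ","), paste(o$ends, collapse = ","), sep = ";"),
        character(1)))]
    }
    cutjoin <- function(tokP, tokQ) {
      if (!(tokP$single == "" || tokP$single == X)) return()
      for (oP in token_orientations(tokP)) {
        pc <- cut_positions(list(kind = tokP$kind, tags = oP$tags,
                                 single = tokP$single), X)
        for (oQ in q_left_orients(tokQ)) {
          if (oQ$ends[1L] != X) next   # the joined telomere must be on genome X
          for (cp in pc) {
            P1 <- oP$tags[seq_len(cp)]
            P2 <- if (cp == 0L) oP$tags else oP$tags[-seq_len(cp)]
            ## P1 + Q; P2 keeps a fresh X telomere on its left
            emit(list(
              make_result_token(oP$ends[1L], oQ$ends[2L], splice_tags(P1, oQ$tags),
                                piece_single(tokP$single, P1, tokQ$single, oQ$tags)),
              make_result_token(X, oP$ends[2L], P2, tokP$single)))
            ## Q + P2; P1 keeps a fresh X telomere on its right
            emit(list(
              make_result_token(oQ$ends[2L], oP$ends[2L],
                                splice_tags(rev_tags(oQ$tags), P2),
                                piece_single(tokQ$single, oQ$tags, tokP$single, P2)),
              make_result_token(oP$ends[1L], X, P1, tokP$single)))
          }
        }
      }
    }
    cutjoin(tok1, tok2)
    cutjoin(tok2, tok1)
    ## --- join two telomeres (merges the two paths)
    for (o1 in q_left_orients(tok1)) for (o2 in q_left_orients(tok2)) {
      if (o1$ends[1L] != X || o2$ends[1L] != X) next
      ## join o1's left telomere to o2's left telomere: rev(o1) + o2
      emit(list(
        make_result_token(o1$ends[2L], o2$ends[2L],
                          splice_tags(rev_tags(o1$tags), o2$tags),
                          piece_single(tok1$single, o1$tags, tok2$single, o2$tags))))
    }
  }
  ## dedupe on (deltas, resultant keys)
  sig <- vapply(rows, function(r) paste(r$delta_sigma, r$delta_dcj,
    paste(sort(vapply(r$res, token_key, character(1))), collapse = "+")),
    character(1))
  rows[!duplicated(sig)]
}
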