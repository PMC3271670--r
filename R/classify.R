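## Path taxonomy for the recombination machinery.
##
## Labeled paths are typed by their kind (AA, BB, AB) and run structure.
## Writing Lambda = 4i + k with k in 1..4, the class keeps k and the first
## run's genome; for odd k the first and last runs share a genome, for
## even k they differ.  AA- and BB-paths may be read in either direction,
## so their even-k classes are unordered ("E"); AB-paths are read from the
## A endpoint, so "A2" (first run in A) and "B2" are distinct.  sigma
## depends on the class as i+1 (k in 1..3) or i+2 (k = 4).

#' Classify a path component by kind and run structure
#'
#' @param cc a component from \code{\link{components}} (paths and linear
#'   singletons only; cycles and circular singletons are rejected).
#' @param g the \code{dcj_graph}.
#' @param r optionally, precomputed \code{\link{component_runs}}.
#' @return list with \code{kind} (\code{AA}/\code{BB}/\code{AB}),
#'   \code{structure} (\code{"e"}, \code{"A1"}, \code{"B3"}, \code{"E4"},
#'   ...), \code{k}, \code{i}, \code{Lambda}, \code{singleton}, and
#'   \code{class} (\code{"kind:structure"}).
#' @export
classify_path <- function(cc, g, r = component_runs(cc, g)) {
  kind <- switch(cc$kind,
                 AA = "AA", BB = "BB", AB = "AB",
                 lin_singleton_A = "AA", lin_singleton_B = "BB",
                 stop(sprintf("cannot classify a %s as a path", cc$kind)))
  L <- r$lambda_count
  if (L == 0L)
    return(list(kind = kind, structure = "e", k = 0L, i = 0L, Lambda = 0L,
                singleton = grepl("singleton", cc$kind),
                class = paste0(kind, ":e")))
  k <- ((L - 1L) %% 4L) + 1L
  i <- (L - k) %/% 4L
  first <- if (k %% 2L == 1L || kind == "AB") r$tags[1L] else "E"
  structure <- paste0(first, k)
  list(kind = kind, structure = structure, k = k, i = i, Lambda = L,
       singleton = grepl("singleton", cc$kind),
       class = paste0(kind, ":", structure))
}

## run-tag sequence representative for a class token like "AA:B3" with a
## given i; used by constructors and validation sweeps
class_tags <- function(class, i = 0L) {
  parts <- strsplit(class, ":", fixed = TRUE)[[1L]]
  structure <- parts[2L]
  if (structure == "e") return(character(0))
  first <- substr(structure, 1L, 1L)
  k <- as.integer(substr(structure, 2L, 2L))
  if (first == "E") first <- "A"
  L <- 4L * i + k
  tags <- rep(c(first, setdiff(c("A", "B"), first)), length.out = L)
  tags
}

## all 23 path classes
all_path_classes <- function() {
  c(paste0("AA:", c("e", "A1", "A3", "B1", "B3", "E2", "E4")),
    paste0("BB:", c("e", "A1", "A3", "B1", "B3", "E2", "E4")),
    paste0("AB:", c("e", "A1", "A3", "B1", "B3", "A2", "A4", "B2", "B4")))
}

## sigma of a class token at index i
class_sigma <- function(class, i = 0L) {
  structure <- strsplit(class, ":", fixed = TRUE)[[1L]][2L]
  if (structure == "e") return(0L)
  k <- as.integer(substr(structure, 2L, 2L))
  as.integer(if (k == 4L) i + 2L else i + 1L)
}

## swap the roles of the two genomes in a class token: kinds AA<->BB; run
## tags flip genome and the reading direction reverses, so odd-k classes
## flip their first letter while even-k classes keep it (for AB-paths the
## reversal restores the original first tag; for AA/BB they are unordered)
mirror_class <- function(class) {
  parts <- strsplit(class, ":", fixed = TRUE)[[1L]]
  kind <- c(AA = "BB", BB = "AA", AB = "AB")[[parts[1L]]]
  st <- parts[2L]
  if (!(st == "e" || startsWith(st, "E"))) {
    k <- as.integer(substr(st, 2L, 2L))
    if (k %% 2L == 1L) st <- paste0(chartr("AB", "BA", substr(st, 1L, 1L)), k)
  }
  paste0(kind, ":", st)
}
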