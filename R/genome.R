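## Genome representation and GRIMM-style gene-order I/O.
##
## A genome is an ordered collection of chromosomes; each chromosome is a
## sequence of signed markers and is either linear or circular.  Markers are
## arbitrary tokens (gene or synteny-block names); a leading "-" denotes
## reverse reading orientation.  Duplicated markers are not allowed: the
## distance model is undefined for them.

MARKER_ID_RE <- "^[A-Za-z0-9_.-]+$"

#' Signed-marker helpers
#'
#' A signed marker is stored as its token with an optional leading \code{-}
#' for reverse orientation.  \code{marker_id} strips the sign,
#' \code{marker_sign} returns \code{+1}/\code{-1}, and \code{flip_markers}
#' reverses a block: it reverses the order and toggles every sign, so
#' flipping twice is the identity.
#'
#' @param x character vector of signed marker tokens.
#' @return \code{marker_id}: character vector of bare ids;
#'   \code{marker_sign}: integer vector of +1/-1; \code{flip_markers}: the
#'   reversed, sign-toggled block.
#' @examples
#' marker_id(c("a", "-b"))
#' flip_markers(c("a", "-b"))   # "b" "-a"
#' @export
marker_id <- function(x) sub("^-", "", x)

#' @rdname marker_id
#' @export
marker_sign <- function(x) ifelse(startsWith(x, "-"), -1L, 1L)

#' @rdname marker_id
#' @export
flip_markers <- function(x) {
  if (length(x) == 0L) return(character(0))
  rev(ifelse(startsWith(x, "-"), sub("^-", "", x), paste0("-", x)))
}

new_chromosome <- function(markers, circular) {
  stopifnot(is.character(markers), is.logical(circular), length(circular) == 1L)
  structure(list(markers = markers, circular = circular), class = "dcj_chromosome")
}

#' Construct a genome
#'
#' @param chromosomes a list; each element is either a character vector of
#'   signed marker tokens (taken as a linear chromosome) or a list with
#'   elements \code{markers} (character) and \code{circular} (logical).
#' @param name genome name used in headers and reports.
#' @param circular optional logical vector recycled over \code{chromosomes}
#'   when they are plain character vectors.
#' @return an object of class \code{dcj_genome}.
#' @examples
#' genome(list(c("1", "2", "3")), name = "A")
#' genome(list(c("1", "-2")), name = "A", circular = TRUE)
#' @export
genome <- function(chromosomes = list(), name = "genome", circular = FALSE) {
  circular <- rep_len(as.logical(circular), max(1L, length(chromosomes)))
  chrs <- vector("list", length(chromosomes))
  for (i in seq_along(chromosomes)) {
    ch <- chromosomes[[i]]
    if (is.list(ch)) {
      chrs[[i]] <- new_chromosome(as.character(ch$markers), isTRUE(ch$circular))
    } else {
      chrs[[i]] <- new_chromosome(as.character(ch), circular[i])
    }
  }
  g <- structure(list(name = as.character(name), chromosomes = chrs),
                 class = "dcj_genome")
  validate_genome(g)
}

validate_genome <- function(g) {
  if (!inherits(g, "dcj_genome")) stop("not a dcj_genome object")
  ids <- character(0)
  for (i in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[i]]
    if (length(ch$markers) == 0L)
      stop(sprintf("genome '%s': chromosome %d is empty", g$name, i))
    id <- marker_id(ch$markers)
    bad <- id[!grepl(MARKER_ID_RE, id)]
    if (length(bad))
      stop(sprintf("genome '%s': invalid marker token '%s'", g$name, bad[1L]))
    ids <- c(ids, id)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("genome '%s': duplicated marker '%s'", g$name, dup[1L]))
  g
}

#' Marker ids occurring in a genome
#' @param g a \code{dcj_genome}.
#' @return character vector of (unsigned) marker ids.
#' @export
genome_markers <- function(g) {
  unlist(lapply(g$chromosomes, function(ch) marker_id(ch$markers)),
         use.names = FALSE)
}

#' @export
print.dcj_genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d chromosome(s), %d marker(s)\n",
              x$name, length(x$chromosomes), length(genome_markers(x))))
  for (ch in x$chromosomes)
    cat(" ", paste(ch$markers, collapse = " "),
        if (ch$circular) "@" else "$", "\n")
  invisible(x)
}

## ---- GRIMM-dialect parsing ------------------------------------------------
##
## Format: an optional ">name" header line; each subsequent non-blank,
## non-comment ("#") line is one chromosome of whitespace-separated signed
## markers, terminated by "$" (linear) or "@" (circular).

parse_genome_text <- function(text, default_name = "genome") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  name <- default_name
  chrs <- list()
  circ <- logical(0)
  seen_header <- FALSE
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      if (seen_header || length(chrs))
        stop(sprintf("line %d: unexpected second header '%s'", ln, line))
      name <- trimws(sub("^>", "", line))
      if (name == "") name <- default_name
      seen_header <- TRUE
      next
    }
    toks <- strsplit(line, "[[:space:]]+")[[1L]]
    term <- toks[length(toks)]
    if (!term %in% c("$", "@"))
      stop(sprintf("line %d: chromosome not terminated by '$' or '@'", ln))
    mk <- toks[-length(toks)]
    if (length(mk) == 0L)
      stop(sprintf("line %d: empty chromosome", ln))
    bad <- mk[!grepl(MARKER_ID_RE, marker_id(mk)) | marker_id(mk) == ""]
    if (length(bad))
      stop(sprintf("line %d: malformed marker token '%s'", ln, bad[1L]))
    chrs <- c(chrs, list(mk))
    circ <- c(circ, term == "@")
  }
  genome(chrs, name = name, circular = circ)
}

#' Parse a pair of genomes from GRIMM-style text
#'
#' Each argument holds the content of one gene-order file: an optional
#' \code{">name"} header, then one chromosome per line, whitespace-separated
#' signed markers terminated by \code{"$"} (linear) or \code{"@"} (circular).
#' Lines starting with \code{"#"} and blank lines are ignored.
#'
#' @param text_a,text_b character scalars (or vectors of lines) with the two
#'   genome file contents.
#' @return a list with elements \code{a} and \code{b}, both \code{dcj_genome}.
#' @examples
#' gs <- parse_genomes(">A\n1 2 3 $\n", ">B\n1 -2 3 $\n")
#' gs$a
#' @export
parse_genomes <- function(text_a, text_b) {
  list(a = parse_genome_text(text_a, "A"), b = parse_genome_text(text_b, "B"))
}

#' Read a genome from a gene-order file
#' @param path file path.
#' @param default_name name used if the file has no \code{">"} header.
#' @return a \code{dcj_genome}.
#' @export
read_genome <- function(path, default_name = sub("\\.[^.]*$", "", basename(path))) {
  parse_genome_text(readLines(path, warn = FALSE), default_name)
}

#' Serialise a genome to GRIMM-style text
#'
#' The output round-trips through \code{\link{parse_genomes}} to an
#' equivalent genome (circular chromosomes compare equal up to rotation and
#' full reversal).
#'
#' @param g a \code{dcj_genome}.
#' @param header emit the \code{">name"} header line?
#' @return a character scalar.
#' @export
write_genome <- function(g, header = TRUE) {
  validate_genome(g)
  body <- vapply(g$chromosomes, function(ch)
    paste(c(ch$markers, if (ch$circular) "@" else "$"), collapse = " "),
    character(1))
  paste0(paste(c(if (header) paste0(">", g$name), body), collapse = "\n"), "\n")
}

## ---- Marker partition -----------------------------------------------------

#' Partition markers into common and unique sets
#'
#' Compares the marker content of two genomes: markers present in both are
#' the common set (the reduced genome over which the adjacency graph is
#' built); the remainder are unique to one genome and enter the model only
#' through adjacency labels and singleton chromosomes.
#'
#' @param a,b \code{dcj_genome} objects.
#' @return a list of class \code{dcj_partition} with character-vector
#'   elements \code{common}, \code{unique_a}, \code{unique_b} and the count
#'   \code{n = length(common)}.
#' @examples
#' gs <- parse_genomes(">A\na s u b $\n", ">B\na x y b $\n")
#' partition_markers(gs$a, gs$b)$common
#' @export
partition_markers <- function(a, b) {
  validate_genome(a); validate_genome(b)
  ma <- genome_markers(a); mb <- genome_markers(b)
  common <- sort(intersect(ma, mb))
  structure(list(common   = common,
                 unique_a = sort(setdiff(ma, mb)),
                 unique_b = sort(setdiff(mb, ma)),
                 n        = length(common)),
            class = "dcj_partition")
}

## Canonical chromosome key: linear chromosomes up to full reversal,
## circular ones up to rotation and reversal.  Used for genome equality.
canonical_chromosome <- function(ch) {
  m <- ch$markers
  if (!ch$circular) {
    a <- paste(m, collapse = " ")
    b <- paste(flip_markers(m), collapse = " ")
    paste0("L ", min(a, b))
  } else {
    n <- length(m)
    best <- NULL
    for (v in list(m, flip_markers(m))) {
      for (r in seq_len(n)) {
        rot <- paste(v[c(r:n, seq_len(r - 1L))], collapse = " ")
        if (is.null(best) || rot < best) best <- rot
      }
    }
    paste0("C ", best)
  }
}

#' Canonical fingerprint of a genome
#'
#' Chromosome order, circular rotation and whole-chromosome reversal do not
#' change a genome; this key is invariant under all three, so two genomes
#' are equal iff their fingerprints match.
#'
#' @param g a \code{dcj_genome}.
#' @return character scalar.
#' @export
genome_key <- function(g) {
  paste(sort(vapply(g$chromosomes, canonical_chromosome, character(1))),
        collapse = " | ")
}

#' Test two genomes for equality up to representation
#' @param a,b \code{dcj_genome} objects.
#' @return logical.
#' @export
genomes_equal <- function(a, b) identical(genome_key(a), genome_key(b))
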