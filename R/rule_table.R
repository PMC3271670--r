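## Shipped recombination rule table: loading and validation.
##
## The package ships inst/extdata/recombination_rules.tsv, the class-level
## summary of all distance-decreasing recombinations (table 1), the
## distance-neutral recombinations that create sources for them (table 2)
## and the greedy groups U..Z with their source multisets (table 3).  The
## table is generated from the operation engine; the loader re-validates
## every pairwise row against it, so a corrupted transcription cannot be
## loaded.

table1_source_classes <- function(rules)
  sort(unique(c(rules$source1[rules$table == 1L], rules$source2[rules$table == 1L])))

#' Load and validate the recombination rule table
#'
#' Checks, row by row: the delta arithmetic
#' (\code{delta_d = delta_sigma + delta_dcj}); that table-1 rows have
#' \code{delta_d <= -1} and table-2 rows \code{delta_d = 0} with a
#' resultant that is a table-1 source; closure of table 1 under swapping
#' the roles of the two genomes; the presence of every group U..Z; the
#' bound \code{delta_sigma >= -2}; and that every pairwise row is
#' reproduced by the operation-level rule generator.
#'
#' @param path path to the rule table; defaults to the shipped file.
#' @return a data frame of rules (invisibly validated).
#' @export
load_rule_table <- function(path = system.file("extdata", "recombination_rules.tsv",
                                               package = "dcjsub")) {
  rules <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("table", "group", "source1", "source2", "resultants",
            "delta_sigma", "delta_dcj", "delta_d", "score")
  if (!all(need %in% names(rules)))
    stop("rule table: missing columns ", paste(setdiff(need, names(rules)), collapse = ", "))
  fail <- function(i, why)
    stop(sprintf("rule table row %d (%s %s): %s", i,
                 rules$source1[i], rules$source2[i], why))
  if (!all(c("U", "V", "W", "X", "Y", "Z") %in% rules$group))
    stop("rule table: a recombination group is missing")
  t1src <- table1_source_classes(rules)
  for (i in seq_len(nrow(rules))) {
    if (!is.na(rules$delta_dcj[i]) &&
        rules$delta_d[i] != rules$delta_sigma[i] + rules$delta_dcj[i])
      fail(i, "delta_d is not delta_sigma + delta_dcj")
    if (rules$table[i] %in% c(1L, 2L) && rules$delta_sigma[i] < -2L)
      fail(i, "delta_sigma below the -2 bound")
    if (rules$table[i] == 1L && rules$delta_d[i] > -1L)
      fail(i, "table-1 row with delta_d > -1")
    if (rules$table[i] == 2L) {
      if (rules$delta_d[i] != 0L) fail(i, "table-2 row with delta_d != 0")
      res <- strsplit(rules$resultants[i], "+", fixed = TRUE)[[1L]]
      if (!any(res %in% t1src)) fail(i, "table-2 row creates no table-1 source")
    }
  }
  ## table-1 closure under genome-role swap
  t1 <- rules[rules$table == 1L, ]
  keyset <- apply(t1, 1L, function(r) paste(sort(c(r[["source1"]], r[["source2"]])),
                                            collapse = "#"))
  for (i in seq_len(nrow(t1))) {
    mk <- paste(sort(c(mirror_class(t1$source1[i]), mirror_class(t1$source2[i]))),
                collapse = "#")
    if (!mk %in% keyset)
      stop(sprintf("rule table: table 1 is not closed under genome swap (%s %s)",
                   t1$source1[i], t1$source2[i]))
  }
  ## reproduce every pairwise row from the operation-level generator
  cls_of_token <- function(tk) {
    L <- length(tk$tags)
    if (L == 0L) return(paste0(tk$kind, ":e"))
    k <- ((L - 1L) %% 4L) + 1L
    first <- if (k %% 2L == 1L || tk$kind == "AB") tk$tags[1L] else "E"
    paste0(tk$kind, ":", first, k)
  }
  tok_of <- function(cls) {
    parts <- strsplit(cls, ":", fixed = TRUE)[[1L]]
    path_token(parts[1L], class_tags(cls, 0L))
  }
  for (i in which(rules$table %in% c(1L, 2L))) {
    rr <- recombination_rows(tok_of(rules$source1[i]), tok_of(rules$source2[i]))
    hit <- any(vapply(rr, function(r) {
      r$delta_sigma == rules$delta_sigma[i] && r$delta_dcj == rules$delta_dcj[i] &&
        identical(sort(vapply(r$res, cls_of_token, character(1))),
                  sort(strsplit(rules$resultants[i], "+", fixed = TRUE)[[1L]]))
    }, logical(1)))
    if (!hit) fail(i, "row not reproduced by the operation engine")
  }
  rules
}

#' Greedy recombination-group counts for a multiset of path classes
#'
#' Counts the recombination groups U..Z over a collection of labeled
#' paths given by class (and run-count index), together with the total
#' deduction \code{2U + 3V + 2W + X + 2Y + Z}.  The result depends only
#' on the composition of the input, not on its order.
#'
#' @param path_classes character vector of class tokens such as
#'   \code{"AA:E4"} (see the rule-table header for the notation).
#' @param i run-count index per class (recycled): a class with structure
#'   \code{k} and index \code{i} has \code{Lambda = 4 i + k} runs.
#' @param rules optional rule table (from \code{\link{load_rule_table}});
#'   accepted for interface compatibility and ignored by the exact
#'   search, which draws its rows from the operation-level generator.
#' @return list with counts \code{U}..\code{Z} and \code{deduction}.
#' @examples
#' greedy_groups(c("AA:E4", "BB:E4"))   # one U recombination: deduction 2
#' @export
greedy_groups <- function(path_classes, i = 0L, rules = NULL) {
  i <- rep_len(as.integer(i), length(path_classes))
  toks <- lapply(seq_along(path_classes), function(j) {
    parts <- strsplit(path_classes[j], ":", fixed = TRUE)[[1L]]
    path_token(parts[1L], class_tags(path_classes[j], i[j]))
  })
  sr <- deduction_search(toks)
  gc <- group_counts(sr$moves)
  stopifnot(gc$P_L_used == 0L)
  out <- as.list(gc$counts)
  out$deduction <- group_deduction(gc$counts)
  out
}
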