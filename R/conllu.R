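#' Read CoNLL-U dependency trees
#'
#' Parses the standard 10-column CoNLL-U format into a list of [dep_tree()]
#' objects, one per sentence block. `#` comment lines are ignored,
#' multiword-token ranges (`1-2`) and empty nodes (`1.1`) are skipped, and
#' `HEAD = 0` marks the root. The FORM, LEMMA, UPOS and DEPREL columns
#' populate the word, lemma, part-of-speech and relation fields.
#'
#' @param file Path to a CoNLL-U file, or a character vector of lines
#'   (anything containing a newline or more than one element is treated as
#'   content rather than a path).
#' @return A list of `dep_tree` objects (empty list for empty input).
#' @examples
#' read_conllu(c(
#'   "1\twait\t_\t_\t_\t_\t2\tnsubj\t_\t_",
#'   "2\tare\t_\t_\t_\t_\t0\troot\t_\t_"
#' ))
#' @export
read_conllu <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines, which = "right")
  blank <- lines == ""
  block_id <- cumsum(blank)
  trees <- list()
  for (b in split(lines[!blank], block_id[!blank])) {
    sent_label <- sub("^# sent_id\\s*=\\s*", "",
                      grep("^# sent_id", b, value = TRUE)[1])
    rows <- b[!startsWith(b, "#")]
    if (length(rows) == 0L) next
    if (is.na(sent_label)) sent_label <- paste0("block ", length(trees) + 1L)
    fields <- strsplit(rows, "\t", fixed = TRUE)
    bad <- lengths(fields) < 8L
    if (any(bad)) {
      stop(sprintf("CoNLL-U format error in sentence '%s': row with fewer than 8 columns",
                   sent_label), call. = FALSE)
    }
    id <- vapply(fields, `[`, character(1), 1L)
    keep <- grepl("^[0-9]+$", id)
    fields <- fields[keep]
    if (length(fields) == 0L) next
    id <- as.integer(vapply(fields, `[`, character(1), 1L))
    form <- vapply(fields, `[`, character(1), 2L)
    lemma <- vapply(fields, `[`, character(1), 3L)
    upos <- vapply(fields, `[`, character(1), 4L)
    head <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 7L)))
    deprel <- vapply(fields, `[`, character(1), 8L)
    n <- length(id)
    if (any(is.na(head)) || any(head < 0L) || any(head > n)) {
      stop(sprintf("CoNLL-U format error in sentence '%s': HEAD out of range",
                   sent_label), call. = FALSE)
    }
    if (sum(head == 0L) != 1L) {
      stop(sprintf("CoNLL-U format error in sentence '%s': expected exactly one root, found %d",
                   sent_label, sum(head == 0L)), call. = FALSE)
    }
    lemma[lemma == "_"] <- NA_character_
    upos[upos == "_"] <- NA_character_
    deprel[head == 0L] <- NA_character_
    t <- tryCatch(
      dep_tree(form, head, deprel, pos = upos, lemma = lemma),
      error = function(e) {
        stop(sprintf("CoNLL-U format error in sentence '%s': %s",
                     sent_label, conditionMessage(e)), call. = FALSE)
      }
    )
    trees[[length(trees) + 1L]] <- t
  }
  trees
}
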