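# Text-query matching against curated descriptions.

#' Construct a text query
#'
#' A query matches a curated description when the description contains the
#' query text as a case-insensitive substring. `%` acts as a wildcard for
#' any run of zero or more characters ("chl%reduct" matches "Perchlorate
#' reductase subunit alpha"); no other character is special. With
#' `word_mode = TRUE` the match must additionally start and end at word
#' boundaries ("chlorate" then matches "Chlorate reductase" but not
#' "Perchlorate reductase"), which makes EC numbers usable as queries.
#'
#' Word characters are letters and digits, plus `.` and `-` when
#' flanked on both sides by letters or digits, so "1.1.1.1" behaves as a
#' single word. When wildcards and word mode combine, the boundaries are
#' required only at the two ends of the overall match (the start of the
#' first literal segment and the end of the last); a leading or trailing
#' `%` therefore carries no boundary requirement of its own.
#'
#' @param text query text; must be non-empty after trimming and must
#'   contain at least one non-wildcard character.
#' @param word_mode logical; require whole-word matches.
#' @return an object of class `cb_query`.
#' @export
cb_query <- function(text, word_mode = FALSE) {
  if (inherits(text, "cb_query")) return(text)
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) {
    cb_error("cb_query_error", "query text is empty")
  }
  if (!nzchar(gsub("%", "", text, fixed = TRUE))) {
    cb_error("cb_query_error", "query consists only of '%' wildcards")
  }
  structure(list(text = text, word_mode = isTRUE(word_mode),
                 has_wildcard = grepl("%", text, fixed = TRUE)),
            class = "cb_query")
}

#' @export
print.cb_query <- function(x, ...) {
  cat(sprintf("Query: \"%s\"%s%s\n", x$text,
              if (x$word_mode) " [whole words]" else "",
              if (x$has_wildcard) " [wildcard]" else ""))
  invisible(x)
}

# character classification for word boundaries: letters/digits are word
# characters; '.' and '-' are word characters only between two
# letters/digits (so EC numbers and hyphenated names are single words)
word_char_mask <- function(chars) {
  n <- length(chars)
  if (n == 0) return(logical(0))
  alnum <- grepl("[A-Za-z0-9]", chars)
  mask <- alnum
  joiner <- chars %in% c(".", "-")
  if (any(joiner)) {
    left <- c(FALSE, alnum[-n])
    right <- c(alnum[-1], FALSE)
    mask[joiner] <- left[joiner] & right[joiner]
  }
  mask
}

# all (possibly overlapping) start positions of fixed `needle` in `hay`
all_starts <- function(needle, hay) {
  m <- gregexpr(paste0("(?=", escape_regex(needle), ")"), hay, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

match_one_word_mode <- function(segs, d) {
  chars <- strsplit(d, "")[[1]]
  n <- length(chars)
  mask <- word_char_mask(chars)
  first <- segs[1]
  last <- segs[length(segs)]
  starts <- all_starts(first, d)
  starts <- starts[starts == 1 | !mask[pmax(starts - 1, 1)]]
  if (!length(starts)) return(FALSE)
  ends <- all_starts(last, d) + nchar(last) - 1L
  ends <- ends[ends == n | !mask[pmin(ends + 1, n)]]
  if (!length(ends)) return(FALSE)
  if (length(segs) == 1) {
    return(any(outer(starts, ends, function(s, e) e - s + 1L == nchar(first))))
  }
  pat <- paste0("^", paste(escape_regex(segs), collapse = ".*"), "$")
  minlen <- sum(nchar(segs))
  for (s in starts) {
    for (e in ends) {
      if (e - s + 1L >= minlen &&
          grepl(pat, substr(d, s, e), perl = TRUE)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Does a description match a query?
#'
#' Vectorized over `descriptions`; matching is case-insensitive. See
#' [cb_query()] for the substring, wildcard and whole-word semantics.
#'
#' @param query a [cb_query] or query string.
#' @param descriptions character vector of curated descriptions.
#' @return logical vector.
#' @export
description_matches <- function(query, descriptions) {
  query <- cb_query(query)
  d <- tolower(descriptions)
  d[is.na(d)] <- ""
  q <- tolower(query$text)
  segs <- strsplit(q, "%", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  if (!query$word_mode) {
    if (!query$has_wildcard) {
      return(grepl(q, d, fixed = TRUE))
    }
    pat <- paste(escape_regex(segs), collapse = ".*")
    return(grepl(pat, d, perl = TRUE))
  }
  vapply(d, function(di) match_one_word_mode(segs, di), NA,
         USE.NAMES = FALSE)
}

#' Select curated sequences matching a query
#'
#' Returns every distinct curated sequence that has at least one entry
#' whose description matches, together with exactly those matching
#' entries. Results are ordered by `seq_id`, so the selection does not
#' depend on the order entries were ingested in.
#'
#' @param db a `curated_db`.
#' @param query a [cb_query] or query string.
#' @return list of elements `list(seq_id, sequence, length, entries)`;
#'   empty list when nothing matches.
#' @export
select_curated <- function(db, query) {
  stopifnot(inherits(db, "curated_db"))
  query <- cb_query(query)
  hit <- description_matches(query, db$entries$description)
  ent <- db$entries[hit, , drop = FALSE]
  if (nrow(ent) == 0) return(list())
  ids <- sort(unique(ent$seq_id))
  lapply(ids, function(id) {
    srow <- db$sequences[db$sequences$seq_id == id, ]
    e <- ent[ent$seq_id == id, , drop = FALSE]
    rownames(e) <- NULL
    list(seq_id = id, sequence = srow$sequence[1],
         length = srow$length[1], entries = e)
  })
}
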