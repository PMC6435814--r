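# Shared helpers: classed errors, seeded RNG scopes, FASTA IO, digests.

cb_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Deterministic sequence digest
#'
#' 64-bit FNV-1a hash of a character vector, as 16 lowercase hex digits.
#' Used to derive stable sequence identifiers so that database builds are
#' reproducible and independent of input order.
#'
#' @param x character vector.
#' @return character vector of 16-character hex digests.
#' @export
seq_digest <- function(x) {
  cpp_fnv1a64(as.character(x))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# FASTA as a named character vector; names are full headers unless
# first_token_id is TRUE, in which case the remainder is kept as an
# attribute "descriptions".
read_fasta_chr <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    cb_error("cb_io_error", sprintf("FASTA file not found: %s", path))
  }
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

write_fasta_chr <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

# split "id description..." headers
split_fasta_headers <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  list(id = id, desc = desc)
}

escape_regex <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}
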