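# Exact k-mer match index.
#
# The re-annotation criterion is perfect 25/25 identity, so an exhaustive
# exact-match index replaces alignment: every k-mer of every target
# sequence is enumerated once (forward strand), and a query hits the minus
# strand of a target exactly when its reverse complement occurs among the
# forward k-mers.

#' Build an exact-match k-mer index over target sequences
#'
#' @param sequences named character vector (or DNAStringSet) of target
#'   sequences over A/C/G/T; other letters are indexed but can never match
#'   an A/C/G/T query. Sequences shorter than \code{k} are accepted but
#'   never matched.
#' @param k k-mer length (default 25, the probe length).
#' @return an object of class \code{match_index}.
#' @export
build_match_index <- function(sequences, k = 25L) {
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stopf("target sequences must have unique names")
  per_target <- lapply(names(sequences), function(nm) {
    s <- sequences[[nm]]
    n <- nchar(s)
    if (n < k) return(NULL)
    st <- seq_len(n - k + 1L)
    data.frame(kmer = substring(s, st, st + k - 1L), target = nm,
               offset = st - 1L, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_target)
  if (is.null(tab))
    tab <- data.frame(kmer = character(), target = character(),
                      offset = integer(), stringsAsFactors = FALSE)
  structure(list(table = tab, k = k, targets = names(sequences)),
            class = "match_index")
}

#' Query an exact-match index
#'
#' Reports every perfect occurrence of each query k-mer in the indexed
#' targets, on both strands: a forward hit means the query appears verbatim
#' in the target; a minus-strand hit means its reverse complement does.
#' Offsets are 0-based positions of the occupied window on the target's
#' forward strand.
#'
#' @param index a [build_match_index()] object.
#' @param kmers character vector of query k-mers (length \code{k} each).
#' @return data.frame: query, target, offset, strand.
#' @export
query_index <- function(index, kmers) {
  stopifnot(inherits(index, "match_index"))
  if (any(nchar(kmers) != index$k))
    stopf("queries must all have length %d", index$k)
  tab <- index$table
  lookup <- function(keys, strand) {
    hit <- tab[tab$kmer %in% keys, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(query = hit$kmer, target = hit$target, offset = hit$offset,
               strand = strand, stringsAsFactors = FALSE)
  }
  fwd <- lookup(unique(kmers), "+")
  rc <- revcomp(unique(kmers))
  rev <- lookup(unique(rc), "-")
  if (!is.null(rev)) rev$query <- unique(kmers)[match(rev$query, rc)]
  out <- rbind(fwd, rev)
  if (is.null(out))
    out <- data.frame(query = character(), target = character(),
                      offset = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.match_index <- function(x, ...) {
  cat("Exact", x$k, "mer match index:", length(x$targets), "targets,",
      nrow(x$table), "indexed k-mers\n")
  invisible(x)
}
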