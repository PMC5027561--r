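# Internal helpers shared across modules.

# Taxonomic ranks, lowest first, as stored in the metadata table.
.RANKS <- c("species", "genus", "family", "order", "class")

# Characters legal in an aligned barcode sequence: the four bases, IUPAC
# ambiguity codes, N, and '-' as the only gap character.
.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-")

# Encode sequences as an n x L integer matrix: A=1, C=2, G=3, T=4, and 0 for
# every gap / N / ambiguity code (treated as missing at all analysis sites).
.encode_sequences <- function(sequences) {
  n <- length(sequences)
  L <- nchar(sequences[[1L]])
  chars <- matrix(unlist(strsplit(toupper(sequences), "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  code <- matrix(0L, nrow = n, ncol = L,
                 dimnames = list(names(sequences), NULL))
  code[chars == "A"] <- 1L
  code[chars == "C"] <- 2L
  code[chars == "G"] <- 3L
  code[chars == "T"] <- 4L
  code
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Percentage with fixed rounding used by every reporting surface.
.pct <- function(x, digits = 2) round(100 * x, digits)

# Connected components of an undirected graph given as a 2-column edge
# matrix over the node names in `nodes`.  Tiny union-find.
.components <- function(nodes, edges) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(match(edges[k, 1L], nodes))
      b <- find(match(edges[k, 2L], nodes))
      if (a != b) parent[[b]] <- a
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  split(nodes, roots)
}
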