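## DNA alignments are stored as plain character matrices (taxa x sites,
## upper case, rownames = labels). Scoring works on column-compressed site
## patterns with IUPAC ambiguity codes expanded to state sets, encoded as
## 4-bit masks over (A, C, G, T).

## IUPAC nucleotide codes as bit masks: A=1, C=2, G=4, T=8
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L, "-" = 15L, "?" = 15L, "." = 15L, X = 15L
)

#' Read a DNA alignment
#'
#' Reads FASTA (multi-line sequences allowed) or relaxed sequential PHYLIP
#' (header `ntax nsites`, then `name sequence` records, whitespace
#' separated, sequence possibly wrapped over lines). Characters are
#' upper-cased and `U` is mapped to `T`. Gaps (`-`), `N` and `?` are kept
#' verbatim and treated as missing data (full ambiguity) by the scoring
#' functions.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (sniff first non-blank character), `"fasta"` or
#'   `"phylip"`.
#' @return A character matrix, taxa in rows (rownames = labels), one column
#'   per aligned site.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop("empty alignment file: '", path, "'")
  if (format == "auto") {
    first <- trimws(lines[nzchar(trimws(lines))][1L])
    format <- if (startsWith(first, ">")) "fasta" else "phylip"
  }
  aln <- if (format == "fasta") parse_fasta(lines) else parse_phylip(lines)
  validate_alignment(aln)
  aln
}

parse_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers ('>') found")
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)   # first token only
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(gsub("\\s", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, character(1))
  make_alignment(labels, seqs)
}

parse_phylip <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head_tok) < 2L || anyNA(suppressWarnings(as.integer(head_tok[1:2]))))
    stop("malformed PHYLIP header: '", lines[1L], "'")
  ntax <- as.integer(head_tok[1L]); nsites <- as.integer(head_tok[2L])
  tok <- unlist(strsplit(trimws(lines[-1L]), "\\s+"))
  tok <- tok[nzchar(tok)]
  labels <- character(ntax); seqs <- character(ntax)
  i <- 1L
  for (s in seq_len(ntax)) {
    if (i > length(tok)) stop("PHYLIP file truncated: expected ", ntax, " sequences")
    labels[s] <- tok[i]; i <- i + 1L
    buf <- character(0)
    while (sum(nchar(buf)) < nsites) {
      if (i > length(tok))
        stop("sequence for '", labels[s], "' shorter than stated length ", nsites)
      buf <- c(buf, tok[i]); i <- i + 1L
    }
    seqs[s] <- paste(buf, collapse = "")
    if (nchar(seqs[s]) != nsites)
      stop("sequence for '", labels[s], "' has length ", nchar(seqs[s]),
           ", header says ", nsites)
  }
  make_alignment(labels, seqs)
}

make_alignment <- function(labels, seqs) {
  if (anyDuplicated(labels))
    stop("duplicate sequence labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
         "): input must be aligned")
  if (lens[1L] == 0L) stop("alignment has zero columns")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  m[m == "U"] <- "T"
  rownames(m) <- labels
  m
}

validate_alignment <- function(aln) {
  if (!is.matrix(aln) || !is.character(aln) || is.null(rownames(aln)))
    stop("alignment must be a character matrix with rownames")
  bad <- setdiff(unique(as.vector(aln)), names(IUPAC_MASK))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  invisible(aln)
}

#' Write an alignment to FASTA
#'
#' @param aln Character matrix as returned by [read_alignment()] or
#'   [simulate_alignment()].
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  validate_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Compress an alignment into weighted site patterns
#'
#' Identical columns are collapsed to one pattern with an integer weight
#' (multiplicity); parsimony and likelihood scores are then linear in the
#' weights, so scoring compressed patterns reproduces scoring the full
#' alignment exactly. Pattern order is first occurrence.
#'
#' @param aln Character matrix (taxa x sites) over IUPAC DNA codes.
#' @return An object of class `"site_patterns"`: a list with `taxa`
#'   (labels), `masks` (integer matrix taxa x patterns, 4-bit state masks
#'   over A/C/G/T), `weights` (integer multiplicities summing to the
#'   alignment length) and `nsites`.
#' @export
compress_patterns <- function(aln) {
  validate_alignment(aln)
  masks <- matrix(IUPAC_MASK[aln], nrow = nrow(aln),
                  dimnames = list(rownames(aln), NULL))
  storage.mode(masks) <- "integer"
  key <- apply(masks, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.integer(table(factor(key, levels = key[first])))
  out <- list(taxa = rownames(aln),
              masks = masks[, first, drop = FALSE],
              weights = weights,
              nsites = ncol(aln))
  class(out) <- "site_patterns"
  out
}

#' @export
print.site_patterns <- function(x, ...) {
  cat("Site patterns:", length(x$weights), "distinct patterns over",
      x$nsites, "sites,", length(x$taxa), "taxa\n")
  invisible(x)
}

## reorder pattern rows to a tree's tip order; errors on mismatch
patterns_for_tree <- function(patterns, tree) {
  idx <- match(tree$tip.label, patterns$taxa)
  if (anyNA(idx))
    stop("tree taxa not found in alignment: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  if (length(tree$tip.label) != length(patterns$taxa))
    stop("tree and alignment have different taxon sets")
  patterns$masks[idx, , drop = FALSE]
}
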