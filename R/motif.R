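#' Construct a motif from aligned sites
#'
#' A motif is a gapless alignment of `N` DNA sequences ("sites") of common
#' length `L`, treated extensionally: the object *is* the collection of
#' sequences, not a probability matrix derived from it. All motif statistics
#' in this package consume this representation.
#'
#' @param sequences Character vector of N sites over the DNA alphabet
#'   `A`, `C`, `G`, `T` (case is folded to upper). All sites must have equal
#'   length; ambiguity codes and gap characters are rejected.
#' @return An object of class `motif`: the uppercased character vector with
#'   attributes `N` (site count) and `L` (width in bp).
#' @examples
#' m <- motif(c("ACGT", "ACGA", "ACTT"))
#' motif_ic(m)
#' @export
motif <- function(sequences) {
  if (length(sequences) == 0L) {
    stop("a motif needs at least one site", call. = FALSE)
  }
  sequences <- toupper(as.character(sequences))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("all sites must have equal length; got widths ",
         paste(sort(unique(widths)), collapse = ", "), call. = FALSE)
  }
  if (widths[1] < 1L) stop("sites must have width >= 1", call. = FALSE)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGT]", "", sequences[bad]), "")))
    stop("sites contain characters outside {A,C,G,T}: ",
         paste(chars, collapse = " "), call. = FALSE)
  }
  structure(sequences, N = length(sequences), L = widths[1], class = "motif")
}

#' @rdname motif
#' @param x Object to coerce or test.
#' @export
as_motif <- function(x) {
  if (inherits(x, "motif")) return(x)
  motif(as.character(x))
}

#' @rdname motif
#' @export
is_motif <- function(x) inherits(x, "motif")

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif: %d sites x %d bp, IC = %.3f bits>\n",
              attr(x, "N"), attr(x, "L"), motif_ic(x)))
  n_show <- min(length(x), 10L)
  cat(paste0("  ", unclass(x)[seq_len(n_show)]), sep = "\n")
  if (length(x) > n_show) cat(sprintf("  ... (%d more sites)\n", length(x) - n_show))
  invisible(x)
}

#' @export
as.matrix.motif <- function(x, ...) {
  matrix(unlist(strsplit(unclass(x), "")), nrow = attr(x, "N"),
         ncol = attr(x, "L"), byrow = TRUE)
}

# N x L letter matrix -> motif
motif_from_matrix <- function(mat) {
  motif(apply(mat, 1L, paste, collapse = ""))
}

#' Read a motif from a file
#'
#' Reads a gapless alignment from either multi-FASTA (`format = "fasta"`) or
#' a one-site-per-line text file (`format = "lines"`, `#`-prefixed comment
#' lines and blank lines ignored). Lowercase input is folded to uppercase;
#' any character outside `{A,C,G,T}` (including `N` and gaps) is an error.
#'
#' @param path Path to the input file (or a connection).
#' @param format `"fasta"` or `"lines"`.
#' @return A [motif].
#' @seealso [write_motifs()]
#' @export
read_motif <- function(path, format = c("fasta", "lines")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") {
    seqs <- parse_fasta(lines)
  } else {
    lines <- trimws(lines)
    seqs <- lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  if (length(seqs) == 0L) stop("no sequences found in input", call. = FALSE)
  motif(seqs)
}

# plain multi-FASTA parser (no wrapping requirement; headers discarded)
parse_fasta <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(character())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA input must start with a '>' header", call. = FALSE)
  rec <- cumsum(is_hdr)
  vapply(split(lines[!is_hdr], rec[!is_hdr]),
         function(x) paste(gsub("\\s", "", x), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

#' Write motifs to a file
#'
#' Serializes one or more motifs as multi-FASTA (headers
#' `>motif{i}_site{j}`, sequences wrapped at 80 columns) or as
#' one-site-per-line blocks separated by `# motif i` comment lines.
#' `read_motif()` on a single-motif output reproduces the motif exactly.
#'
#' @param motifs A [motif] or a list of motifs (must be non-empty).
#' @param path Output path or connection.
#' @param format `"fasta"` or `"lines"`.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path, format = c("fasta", "lines")) {
  format <- match.arg(format)
  if (is_motif(motifs)) motifs <- list(motifs)
  if (length(motifs) == 0L) stop("no motifs to write", call. = FALSE)
  motifs <- lapply(motifs, as_motif)
  out <- unlist(lapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    if (format == "fasta") {
      unlist(lapply(seq_along(m), function(j) {
        c(sprintf(">motif%d_site%d", i, j), wrap_seq(unclass(m)[j], 80L))
      }))
    } else {
      c(sprintf("# motif %d", i), unclass(m))
    }
  }))
  writeLines(out, path)
  invisible(path)
}

wrap_seq <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

# L x 4 base-count matrix of a motif (columns A,C,G,T)
motif_counts <- function(m) {
  mat <- as.matrix.motif(as_motif(m))
  cm <- vapply(DNA_BASES, function(b) colSums(mat == b), numeric(ncol(mat)))
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1L, dimnames = list(NULL, DNA_BASES))
  cm
}

DNA_BASES <- c("A", "C", "G", "T")

# plug-in Shannon entropy (bits) of a count vector; 0 log 0 = 0
counts_entropy_bits <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Motif entropy, information content and GC fraction
#'
#' `motif_entropy()` is the total positional Shannon entropy
#' \eqn{H(M) = -\sum_c \sum_b p_c(b) \log_2 p_c(b)} in bits, using plug-in
#' (maximum-likelihood) column base frequencies with no pseudocounts.
#' `motif_ic()` is the information content \eqn{IC(M) = 2L - H(M)} under a
#' uniform mononucleotide background (2 bits prior uncertainty per position).
#' `motif_gc()` is the fraction of G or C letters among all `N * L` letters.
#'
#' @param m A [motif] (or character vector coercible to one).
#' @return A single number: bits for entropy/IC, a fraction in `[0, 1]` for GC.
#' @examples
#' motif_ic(motif(c("AAAA", "AAAA")))    # fully conserved: 2 * 4 = 8 bits
#' motif_gc(motif(c("AC", "GT")))        # 0.5
#' @export
motif_entropy <- function(m) {
  cm <- motif_counts(m)
  sum(apply(cm, 1L, counts_entropy_bits))
}

#' @rdname motif_entropy
#' @export
motif_ic <- function(m) {
  m <- as_motif(m)
  2 * attr(m, "L") - motif_entropy(m)
}

#' @rdname motif_entropy
#' @export
motif_gc <- function(m) {
  m <- as_motif(m)
  mat <- as.matrix.motif(m)
  mean(mat == "G" | mat == "C")
}

#' Per-column information content profile
#'
#' Column IC is `2 - (column entropy)` bits and lies in `[0, 2]`. The column
#' ICs sum to [motif_ic()] and their disparity is summarized by [igc()].
#'
#' @param m A [motif].
#' @return A tibble with one row per column: `position`, `entropy` (bits),
#'   `ic` (bits). Attributes `total_ic`, `total_entropy` and `gc_fraction`
#'   carry the motif-level summaries.
#' @export
positional_ic <- function(m) {
  m <- as_motif(m)
  cm <- motif_counts(m)                      # L x 4
  h <- apply(cm, 1L, counts_entropy_bits)
  out <- tibble::tibble(position = seq_along(h), entropy = h, ic = 2 - h)
  attr(out, "total_ic") <- sum(out$ic)
  attr(out, "total_entropy") <- sum(h)
  attr(out, "gc_fraction") <- motif_gc(m)
  out
}

#' Informational Gini coefficient
#'
#' The Gini coefficient of the per-column IC vector
#' \eqn{c_1 \le \dots \le c_L} (sorted ascending):
#' \deqn{G(M) = \frac{2 \sum_j j\, c_j}{L \sum_j c_j} - \frac{L+1}{L}.}
#' It is 0 when information is spread evenly across columns and approaches
#' its finite-width maximum `(L - 1) / L` when all information sits in one
#' column. A motif with zero total IC leaves the formula 0/0; by convention
#' the IGC is then 0 (a warning is emitted), since such a motif is maximally
#' even.
#'
#' @param m A [motif].
#' @return IGC in `[0, (L - 1) / L]`.
#' @export
igc <- function(m) {
  ic <- positional_ic(m)$ic
  gini_sorted(ic)
}

# Gini of a nonnegative vector via the sorted rank formula
gini_sorted <- function(x) {
  L <- length(x)
  tot <- sum(x)
  if (tot <= 0) {
    warning("total IC is zero; IGC is undefined and reported as 0")
    return(0)
  }
  cj <- sort(x)
  2 * sum(seq_len(L) * cj) / (L * tot) - (L + 1) / L
}

#' One-row tibble of motif summary statistics
#'
#' @param m A [motif].
#' @return Tibble with columns `n_sites`, `width`, `entropy`, `ic`, `igc`,
#'   `gc`.
#' @export
motif_stats <- function(m) {
  m <- as_motif(m)
  tibble::tibble(
    n_sites = attr(m, "N"), width = attr(m, "L"),
    entropy = motif_entropy(m), ic = motif_ic(m),
    igc = igc(m), gc = motif_gc(m)
  )
}
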