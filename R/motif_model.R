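DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif (position weight matrix)
#'
#' A motif is a per-position probability distribution over the DNA alphabet
#' together with a background model. Columns are positions; rows are the
#' bases A, C, G, T.
#'
#' @param name text label for the motif.
#' @param matrix numeric 4 x L matrix of per-position base probabilities
#'   (rows A, C, G, T); every column must sum to 1.
#' @param background length-4 probability vector over A, C, G, T; all
#'   entries must be strictly positive. Defaults to uniform.
#' @param pseudocount non-negative scalar recorded at construction (used by
#'   [consensus_to_pwm()] and [parse_transfac()] when converting counts).
#' @return An object of class `"motif"`.
#' @export
new_motif <- function(name, matrix, background = rep(0.25, 4), pseudocount = 0) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L)
    stop("motif matrix must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 1L)
    stop("motif matrix must have at least one column")
  if (any(matrix < 0))
    stop("motif matrix entries must be non-negative")
  csums <- colSums(matrix)
  if (any(abs(csums - 1) > 1e-9))
    stop("every motif column must sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be a strictly positive length-4 distribution summing to 1")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a non-negative scalar")
  rownames(matrix) <- DNA_BASES
  names(background) <- DNA_BASES
  structure(
    list(name = as.character(name), matrix = matrix,
         background = background, pseudocount = pseudocount),
    class = "motif"
  )
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif '%s' (length %d, pseudocount %g)\n",
              x$name, motif_length(x), x$pseudocount))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Motif length (number of positions)
#' @param m a `"motif"` object.
#' @return integer number of PWM columns.
#' @export
motif_length <- function(m) ncol(m$matrix)

#' Build a PWM from a consensus sequence
#'
#' Converts a plain A/C/G/T consensus string into a motif by treating each
#' position as a one-hot count smoothed with `pseudocount` distributed
#' according to the background: the consensus base at a position receives
#' probability `(1 + pc * b) / (1 + pc)` and every other base `pc * b / (1 + pc)`.
#' With `pseudocount = 0` the consensus base has probability 1.
#'
#' @param consensus non-empty string over A, C, G, T (case-insensitive).
#' @param pseudocount non-negative smoothing mass.
#' @param background length-4 background distribution (A, C, G, T).
#' @param name motif label; defaults to the consensus string.
#' @return A `"motif"` object of length `nchar(consensus)`.
#' @examples
#' consensus_to_pwm("ACAAAG")
#' consensus_to_pwm("CTTTGT", pseudocount = 0.4)
#' @export
consensus_to_pwm <- function(consensus, pseudocount = 0,
                             background = rep(0.25, 4), name = consensus) {
  if (!is.character(consensus) || length(consensus) != 1L || nchar(consensus) == 0)
    stop("consensus must be a non-empty string")
  bases <- strsplit(toupper(consensus), "")[[1]]
  bad <- which(!bases %in% DNA_BASES)
  if (length(bad) > 0)
    stop(sprintf("non-ACGT character '%s' in consensus at position %d",
                 bases[bad[1]], bad[1]))
  background <- as.numeric(background)
  mat <- vapply(bases, function(b) {
    counts <- as.numeric(DNA_BASES == b) + pseudocount * background
    counts / sum(counts)
  }, numeric(4))
  new_motif(name = name, matrix = unname(mat), background = background,
            pseudocount = pseudocount)
}

#' Parse TRANSFAC-format count matrices
#'
#' Reads the count-matrix dialect of the TRANSFAC flat file: records carry
#' an identifier (`ID` or `NA` tag), a `P0  A  C  G  T` header, numbered
#' rows of four counts, and are delimited by `//`. Counts in each row are
#' converted to probabilities as `(count + pc * b) / (total + pc)`. Tags
#' other than ID/NA/P0/count rows are ignored (a note is emitted once).
#'
#' @param text character vector of lines, or a single string containing
#'   newlines, or a file path (when `is_file = TRUE`).
#' @param pseudocount smoothing mass used in the count-to-probability
#'   conversion.
#' @param background length-4 background distribution.
#' @param is_file if `TRUE`, `text` is a path read with [readLines()].
#' @return A list of `"motif"` objects (empty list for empty input).
#' @export
parse_transfac <- function(text, pseudocount = 0, background = rep(0.25, 4),
                           is_file = FALSE) {
  if (is_file) text <- readLines(text)
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(text)

  motifs <- list()
  cur_name <- NULL
  cur_rows <- list()
  in_matrix <- FALSE
  ignored_note <- FALSE
  col_order <- DNA_BASES

  flush_record <- function() {
    if (length(cur_rows) == 0) {
      if (!is.null(cur_name))
        warning(sprintf("TRANSFAC record '%s' has no count rows; skipped", cur_name))
      return(NULL)
    }
    counts <- do.call(rbind, cur_rows)           # rows = positions
    colnames(counts) <- col_order
    counts <- counts[, DNA_BASES, drop = FALSE]  # reorder to A,C,G,T
    probs <- apply(counts, 1, function(row) {
      (row + pseudocount * background) / (sum(row) + pseudocount)
    })                                           # 4 x L
    new_motif(name = if (is.null(cur_name)) "unnamed" else cur_name,
              matrix = probs, background = background,
              pseudocount = pseudocount)
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" ) next
    if (ln == "//") {
      m <- flush_record()
      if (!is.null(m)) motifs[[length(motifs) + 1L]] <- m
      cur_name <- NULL; cur_rows <- list(); in_matrix <- FALSE
      col_order <- DNA_BASES
      next
    }
    tag <- sub("\\s.*$", "", ln)
    rest <- trimws(sub("^\\S+", "", ln))
    if (tag %in% c("ID", "NA")) {
      if (is.null(cur_name)) cur_name <- rest
    } else if (tag %in% c("P0", "PO")) {
      hdr <- toupper(strsplit(rest, "\\s+")[[1]])
      if (!setequal(hdr, DNA_BASES))
        stop(sprintf("line %d: P0 header must list A C G T, got '%s'", i, rest))
      col_order <- hdr
      in_matrix <- TRUE
    } else if (grepl("^[0-9]+$", tag) && in_matrix) {
      fields <- strsplit(rest, "\\s+")[[1]]
      # TRANSFAC count rows may carry a trailing consensus symbol
      num <- suppressWarnings(as.numeric(fields))
      if (length(fields) >= 5 && is.na(num[length(num)])) {
        fields <- fields[-length(fields)]
        num <- num[-length(num)]
      }
      if (length(num) != 4L || anyNA(num))
        stop(sprintf("line %d: count row must have 4 numeric fields, got '%s'",
                     i, rest))
      if (sum(num) == 0)
        stop(sprintf("line %d: all counts zero in row", i))
      cur_rows[[length(cur_rows) + 1L]] <- num
    } else {
      if (!ignored_note) {
        message("parse_transfac: ignoring unrecognised tags (e.g. '", tag, "')")
        ignored_note <- TRUE
      }
    }
  }
  # trailing record without //
  if (length(cur_rows) > 0) {
    m <- flush_record()
    if (!is.null(m)) motifs[[length(motifs) + 1L]] <- m
  }
  motifs
}

#' Write motifs to TRANSFAC count format
#'
#' Inverse of [parse_transfac()] up to rounding: probabilities are scaled
#' to integer counts (default total 100 per position).
#'
#' @param motifs list of `"motif"` objects.
#' @param path output file path; if `NULL`, returns the lines invisibly.
#' @param scale integer count total per position.
#' @return The text lines, invisibly.
#' @export
write_transfac <- function(motifs, path = NULL, scale = 100L) {
  out <- character(0)
  for (m in motifs) {
    out <- c(out, paste0("ID ", m$name), "P0 A C G T")
    counts <- round(m$matrix * scale)
    for (j in seq_len(ncol(counts))) {
      out <- c(out, paste(c(sprintf("%02d", j), counts[, j]), collapse = " "))
    }
    out <- c(out, "//")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Reverse complement of a motif
#'
#' Columns are reversed and base probabilities swapped A<->T and C<->G.
#' Applying it twice returns the original motif.
#'
#' @param m a `"motif"` object.
#' @return The reverse-complement `"motif"`.
#' @export
reverse_complement_motif <- function(m) {
  stopifnot(inherits(m, "motif"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mat <- m$matrix[comp[DNA_BASES], rev(seq_len(ncol(m$matrix))), drop = FALSE]
  rownames(mat) <- DNA_BASES
  bg <- m$background[comp[DNA_BASES]]
  names(bg) <- DNA_BASES
  new_motif(name = paste0(m$name, "_rc"), matrix = mat, background = bg,
            pseudocount = m$pseudocount)
}

#' Consensus string of a motif (argmax base per position)
#' @param m a `"motif"` object.
#' @return Character string of length `motif_length(m)`.
#' @export
motif_consensus <- function(m) {
  paste(DNA_BASES[apply(m$matrix, 2, which.max)], collapse = "")
}

# log2-odds matrix with probabilities floored at eps (avoids -Inf for
# zero-probability entries of pseudocount-free PWMs)
.log_odds_matrix <- function(m, eps = 1e-4) {
  log2(pmax(m$matrix, eps) / m$background)
}

#' Log-odds score of a site against a motif
#'
#' Sum over positions of `log2(P(base at position) / background(base))`,
#' in bits. Probabilities are floored at `eps` before taking logs.
#'
#' @param m a `"motif"` object.
#' @param site string over A, C, G, T of length `motif_length(m)`.
#' @param eps probability floor applied before the log.
#' @return Score in bits.
#' @export
log_odds_score <- function(m, site, eps = 1e-4) {
  site <- toupper(site)
  L <- motif_length(m)
  if (nchar(site) != L)
    stop(sprintf("site length %d does not match motif length %d",
                 nchar(site), L))
  bases <- strsplit(site, "")[[1]]
  if (any(!bases %in% DNA_BASES))
    stop("site contains non-ACGT characters")
  lom <- .log_odds_matrix(m, eps)
  sum(lom[cbind(match(bases, DNA_BASES), seq_len(L))])
}

#' Maximum attainable log-odds score of a motif
#' @inheritParams log_odds_score
#' @return The sum of per-column maxima, in bits.
#' @export
max_score <- function(m, eps = 1e-4) {
  sum(apply(.log_odds_matrix(m, eps), 2, max))
}

#' Default scan threshold: a fraction of the maximum score
#'
#' No published match cutoff accompanies the motif set, so the default
#' threshold is 80% of the motif's maximum attainable bits score.
#'
#' @inheritParams log_odds_score
#' @param fraction fraction of [max_score()] to use.
#' @return Threshold in bits.
#' @export
default_threshold <- function(m, fraction = 0.8, eps = 1e-4) {
  fraction * max_score(m, eps)
}

# integer encoding of a sequence: A=1 C=2 G=3 T=4, anything else NA
.encode_seq <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
}

# score all plus-strand windows of an encoded sequence against a
# log-odds matrix; windows containing non-ACGT characters score -Inf
.score_windows <- function(enc, lom) {
  L <- ncol(lom)
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (j in seq_len(L)) {
    col <- lom[, j]
    b <- enc[j:(j + n - 1L)]
    contrib <- col[b]
    contrib[is.na(b)] <- -Inf
    scores <- scores + contrib
  }
  scores
}

#' Scan a sequence with a motif on both strands
#'
#' Reports every window whose log-odds score reaches `threshold`, on either
#' strand, in plus-strand 0-based half-open coordinates, sorted by start
#' then strand. Minus-strand hits are windows whose reverse complement
#' matches the motif; their `site` field is given on the motif's strand.
#' Windows containing non-ACGT characters never match.
#'
#' @param sequence_id label copied into the result.
#' @param seq DNA string.
#' @param m a `"motif"` object.
#' @param threshold minimum score in bits (finite).
#' @param eps probability floor for the log-odds matrix.
#' @return A data.frame with columns `sequence_id`, `start`, `end`,
#'   `strand`, `score`, `site`.
#' @examples
#' m <- consensus_to_pwm("CATTGT")
#' scan_sequence("probe", "CCGAACAATGGAAGCATTGTTGCC", m, max_score(m))
#' @export
scan_sequence <- function(sequence_id, seq, m, threshold, eps = 1e-4) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  seq <- toupper(seq)
  L <- motif_length(m)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), site = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq) < L) return(empty)
  enc <- .encode_seq(seq)
  lom_fwd <- .log_odds_matrix(m, eps)
  lom_rev <- .log_odds_matrix(reverse_complement_motif(m), eps)
  sc_fwd <- .score_windows(enc, lom_fwd)
  sc_rev <- .score_windows(enc, lom_rev)  # window matches rc(m) on + strand
  hits_f <- which(sc_fwd >= threshold)
  hits_r <- which(sc_rev >= threshold)
  starts <- c(hits_f, hits_r) - 1L
  strands <- c(rep("+", length(hits_f)), rep("-", length(hits_r)))
  scores <- c(sc_fwd[hits_f], sc_rev[hits_r])
  if (length(starts) == 0) return(empty)
  windows <- substring(seq, starts + 1L, starts + L)
  sites <- ifelse(strands == "+", windows,
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(windows))))
  res <- data.frame(sequence_id = sequence_id, start = starts,
                    end = starts + L, strand = strands, score = scores,
                    site = sites, stringsAsFactors = FALSE)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
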