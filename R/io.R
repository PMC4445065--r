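#' Load a region set from BED + FASTA
#'
#' Reads intervals (0-based half-open BED) and attaches the corresponding
#' upper-cased subsequences of the FASTA contigs. The BED strand column,
#' if present, is ignored (both strands are always scanned downstream);
#' a note is emitted once.
#'
#' @param bed_path path to a BED file.
#' @param fasta_path path to the FASTA file holding the contigs the BED
#'   refers to.
#' @param role `"foreground"` or `"control"`.
#' @param name label for the set; defaults to the BED file name.
#' @return A `"region_set"`.
#' @export
load_region_set <- function(bed_path, fasta_path,
                            role = c("foreground", "control"),
                            name = basename(bed_path)) {
  role <- match.arg(role)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bed <- rtracklayer::import(bed_path, format = "BED")
  if (length(bed) == 0)
    return(region_set(name, data.frame(sequence_id = character(0),
                                       start = integer(0), end = integer(0),
                                       sequence = character(0),
                                       stringsAsFactors = FALSE), role))
  if (any(as.character(GenomicRanges::strand(bed)) != "*"))
    message("load_region_set: BED strand column ignored; both strands are scanned")
  ids <- as.character(GenomicRanges::seqnames(bed))
  missing <- setdiff(unique(ids), names(seqs))
  if (length(missing) > 0)
    stop("sequence id(s) absent from FASTA: ", paste(missing, collapse = ", "))
  start0 <- GenomicRanges::start(bed) - 1L  # back to 0-based half-open
  end <- GenomicRanges::end(bed)
  lens <- Biostrings::width(seqs)[match(ids, names(seqs))]
  bad <- which(end > lens | start0 < 0)
  if (length(bad) > 0)
    stop(sprintf("BED record %d (%s:%d-%d) out of contig bounds (length %d)",
                 bad[1], ids[bad[1]], start0[bad[1]], end[bad[1]],
                 lens[bad[1]]))
  sequence <- vapply(seq_along(ids), function(i)
    toupper(as.character(Biostrings::subseq(seqs[[ids[i]]],
                                            start = start0[i] + 1L,
                                            end = end[i]))), character(1))
  region_set(name, data.frame(sequence_id = ids, start = start0, end = end,
                              sequence = sequence, stringsAsFactors = FALSE),
             role)
}

#' Write a region set to FASTA + BED
#'
#' @param rs a `"region_set"`.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.bed`.
#' @return The two paths, invisibly.
#' @export
write_region_set <- function(rs, prefix) {
  fasta <- paste0(prefix, ".fasta")
  bed <- paste0(prefix, ".bed")
  seqs <- Biostrings::DNAStringSet(rs$regions$sequence)
  names(seqs) <- rs$regions$sequence_id
  Biostrings::writeXStringSet(seqs, fasta)
  write.table(rs$regions[, c("sequence_id", "start", "end")], bed,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(fasta = fasta, bed = bed))
}

# provenance header prepended to every TSV the pipeline writes
.output_header <- function(seed = NULL, params = list()) {
  version <- as.character(utils::packageVersion("dimerscreen"))
  lines <- c(sprintf("# dimerscreen %s", version))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %s", seed))
  if (length(params) > 0)
    lines <- c(lines, sprintf("# params: %s",
                              paste(names(params), unlist(params),
                                    sep = "=", collapse = " ")))
  lines
}

#' Write a results table as TSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed seed recorded in the header (optional).
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, seed = NULL, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.output_header(seed, params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_results_tsv()] (header lines skipped)
#' @param path input path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write an EMSA titration as a lane table TSV
#'
#' Columns: `protein_nM`, `dna_nM`, `f_free`, `f_mono`, `f_dimer`.
#'
#' @param t an `"emsa_titration"`.
#' @param path output path.
#' @inheritParams write_results_tsv
#' @return `path`, invisibly.
#' @export
write_lane_table <- function(t, path, seed = NULL, params = list()) {
  tab <- titration_table(t)
  out <- data.frame(protein_nM = tab$protein_total, dna_nM = tab$dna_total,
                    f_free = tab$f0, f_mono = tab$f1, f_dimer = tab$f2)
  write_results_tsv(out, path, seed = seed, params = params)
}

#' Read an EMSA lane table TSV into a titration
#' @param path TSV with columns `protein_nM`, `dna_nM`, `f_free`,
#'   `f_mono`, `f_dimer` (comment lines starting `#` are skipped).
#' @return An `"emsa_titration"`.
#' @export
read_lane_table <- function(path) {
  tab <- read_results_tsv(path)
  required <- c("protein_nM", "dna_nM", "f_free", "f_mono", "f_dimer")
  if (!all(required %in% names(tab)))
    stop("lane table must have columns ", paste(required, collapse = ", "))
  lanes <- lapply(seq_len(nrow(tab)), function(i)
    emsa_lane(tab$protein_nM[i], tab$dna_nM[i], tab$f_free[i],
              tab$f_mono[i], tab$f_dimer[i]))
  emsa_titration(lanes)
}

#' Full spacing-resolved enrichment screen
#'
#' Enumerates every canonical configuration of the given motifs up to
#' `max_spacer`, counts regions with at least one instance in foreground
#' and control, applies the one-sided exact test per configuration and
#' Bonferroni-corrects over all configurations actually screened (the
#' factor is reported in the output for transparency). Instance totals
#' are reported informationally; the test uses region-level indicators.
#'
#' @param fg,ctrl foreground and control `"region_set"` objects (both
#'   must be non-empty).
#' @param motifs non-empty list of `"motif"` half-site objects.
#' @param max_spacer largest spacer screened (bp).
#' @param threshold_fraction scan threshold as a fraction of each motif's
#'   maximum bits score.
#' @return A list of class `"enrichment_screen"`: `results` (one row per
#'   configuration, ranked by raw p-value), `n_tests`, `thresholds`
#'   (named bits thresholds per motif) and `max_spacer`.
#' @export
run_enrichment_workflow <- function(fg, ctrl, motifs, max_spacer = 10,
                                    threshold_fraction = 0.8) {
  if (length(motifs) == 0) stop("at least one motif is required")
  if (n_regions(fg) == 0 || n_regions(ctrl) == 0)
    stop("foreground and control sets must both contain regions")
  thresholds <- vapply(motifs, function(m)
    default_threshold(m, threshold_fraction), numeric(1))
  names(thresholds) <- vapply(motifs, `[[`, character(1), "name")

  n <- length(motifs)
  pair_rows <- list()
  total_tests <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- motifs[[i]]; b <- motifs[[j]]
      thr <- c(thresholds[i], thresholds[j])
      hits_fg <- .region_hits(fg, a, b, thr, max_spacer)
      hits_ctrl <- .region_hits(ctrl, a, b, thr, max_spacer)
      total_tests <- total_tests + length(hits_fg$configs)
      pair_rows[[length(pair_rows) + 1L]] <-
        list(fg = hits_fg, ctrl = hits_ctrl)
    }
  }

  rows <- list()
  for (pr in pair_rows) {
    for (key in names(pr$fg$configs)) {
      rows[[length(rows) + 1L]] <- .enrichment_row(
        pr$fg$configs[[key]],
        k_fg = pr$fg$regions[[key]], n_fg = n_regions(fg),
        k_ctrl = pr$ctrl$regions[[key]], n_ctrl = n_regions(ctrl),
        inst_fg = pr$fg$instances[[key]],
        inst_ctrl = pr$ctrl$instances[[key]],
        n_tests = total_tests)
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$p_raw, -results$k_fg), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, n_tests = total_tests,
                 thresholds = thresholds, max_spacer = max_spacer),
            class = "enrichment_screen")
}

#' @export
print.enrichment_screen <- function(x, ...) {
  cat(sprintf(
    "enrichment screen: %d configurations (Bonferroni factor %d)\n",
    nrow(x$results), x$n_tests))
  cat("top configurations:\n")
  print(utils::head(x$results[, c("motif_a", "motif_b", "orientation",
                                  "spacer", "k_fg", "expected_fg",
                                  "p_raw", "p_adj")], 5))
  invisible(x)
}
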