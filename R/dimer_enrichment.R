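#' Composite (dimer) motif configuration
#'
#' A composite element is an ordered pair of half-site motifs at a fixed
#' spacer, in one of the canonical orientation classes. Orientations are
#' reverse-complement equivalence classes of strand arrangements, so every
#' configuration equals its own reverse-complement canonical form:
#' for a self-pair, `direct` = {++, --} (tandem), `inverted` = {+-}
#' (head-to-head), `everted` = {-+} (tail-to-tail). For a pair of distinct
#' motifs a fourth class `direct_ba` (tandem with b upstream) exists.
#'
#' @param motif_a,motif_b `"motif"` objects (the two half-sites; pass the
#'   same motif twice for a palindromic self-pair).
#' @param orientation one of `"direct"`, `"inverted"`, `"everted"`,
#'   `"direct_ba"` (`direct_ba` only for distinct motifs).
#' @param spacer gap in bp between the end of the first half-site and the
#'   start of the second (the n in ACAAAG-nnnn-CTTTGT); must be >= 0.
#' @return An object of class `"dimer_config"`.
#' @export
dimer_config <- function(motif_a, motif_b = motif_a,
                         orientation = c("inverted", "direct", "everted",
                                         "direct_ba"),
                         spacer = 0L) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(motif_a, "motif"), inherits(motif_b, "motif"))
  if (!is.numeric(spacer) || length(spacer) != 1L || spacer < 0 ||
      spacer != round(spacer))
    stop("spacer must be a non-negative integer")
  self_pair <- identical(motif_a$matrix, motif_b$matrix)
  if (self_pair && orientation == "direct_ba")
    stop("orientation 'direct_ba' is only defined for distinct motifs")
  structure(
    list(motif_a = motif_a, motif_b = motif_b, orientation = orientation,
         spacer = as.integer(spacer), self_pair = self_pair),
    class = "dimer_config"
  )
}

#' @export
print.dimer_config <- function(x, ...) {
  cat(sprintf("dimer configuration: %s / %s, %s, spacer %d bp\n",
              x$motif_a$name, x$motif_b$name, x$orientation, x$spacer))
  invisible(x)
}

# Composite footprint length in bp
composite_length <- function(c) {
  motif_length(c$motif_a) + c$spacer + motif_length(c$motif_b)
}

#' Region set: named intervals with attached sequence
#'
#' @param name label for the set.
#' @param regions data.frame with columns `sequence_id`, `start`, `end`
#'   (0-based half-open) and `sequence` (attached DNA, length = end - start).
#' @param role `"foreground"` or `"control"`.
#' @return An object of class `"region_set"`.
#' @export
region_set <- function(name, regions, role = c("foreground", "control")) {
  role <- match.arg(role)
  required <- c("sequence_id", "start", "end", "sequence")
  if (!all(required %in% names(regions)))
    stop("regions must have columns ", paste(required, collapse = ", "))
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (nrow(regions) > 0) {
    if (any(regions$end <= regions$start))
      stop("all intervals must satisfy end > start (0-based half-open)")
    if (any(nchar(regions$sequence) != regions$end - regions$start))
      stop("attached sequence length must equal end - start")
    regions$sequence <- toupper(regions$sequence)
  }
  structure(list(name = name, regions = regions, role = role),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region set '%s' (%s): %d regions\n",
              x$name, x$role, nrow(x$regions)))
  invisible(x)
}

#' Number of regions in a region set
#' @param rs a `"region_set"`.
#' @return integer count.
#' @export
n_regions <- function(rs) nrow(rs$regions)

#' Enumerate canonical dimer configurations
#'
#' All (motif pair, orientation, spacer) triples with spacer in
#' `0..max_spacer`, deduplicated under reverse-complement equivalence:
#' 3 orientation classes per self-pair and 4 per distinct pair.
#'
#' @param motifs non-empty list of `"motif"` objects.
#' @param max_spacer maximum spacer in bp (>= 0).
#' @return A list of `"dimer_config"` objects.
#' @examples
#' m <- consensus_to_pwm("ACAAAG")
#' length(enumerate_configurations(list(m), max_spacer = 50))  # 153
#' @export
enumerate_configurations <- function(motifs, max_spacer) {
  if (length(motifs) == 0) stop("motif list must be non-empty")
  if (max_spacer < 0) stop("max_spacer must be >= 0")
  configs <- list()
  n <- length(motifs)
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- motifs[[i]]; b <- motifs[[j]]
      ors <- if (identical(a$matrix, b$matrix))
        c("direct", "inverted", "everted")
      else c("direct", "direct_ba", "inverted", "everted")
      for (o in ors) {
        for (s in 0:max_spacer) {
          configs[[length(configs) + 1L]] <-
            dimer_config(a, b, orientation = o, spacer = s)
        }
      }
    }
  }
  configs
}

# Strand-arrangement patterns realising an orientation class on the plus
# strand. Each row: which motif comes first (a/b), its strand, then the
# second motif and strand. Two rows where the rc-image is a distinct
# arrangement; one row where it is self-symmetric.
.orientation_patterns <- function(c) {
  pats <- switch(c$orientation,
    direct    = list(c("a", "+", "b", "+"), c("b", "-", "a", "-")),
    direct_ba = list(c("b", "+", "a", "+"), c("a", "-", "b", "-")),
    inverted  = list(c("a", "+", "b", "-"), c("b", "+", "a", "-")),
    everted   = list(c("a", "-", "b", "+"), c("b", "-", "a", "+"))
  )
  # for a self-pair the two inverted (or everted) arrangements coincide
  if (c$self_pair && c$orientation %in% c("inverted", "everted"))
    pats <- pats[1]
  pats
}

#' Find composite-motif instances in a sequence
#'
#' Pairs of half-site matches whose strand arrangement realises the
#' configuration's orientation class and whose gap (second start minus
#' first end) equals the spacer exactly. Half-sites never overlap because
#' the spacer is non-negative.
#'
#' @param seq DNA string.
#' @param c a `"dimer_config"`.
#' @param threshold score threshold in bits; scalar (applied to both
#'   half-sites) or length 2 `(threshold_a, threshold_b)`. `NULL` uses
#'   [default_threshold()] of each motif.
#' @param sequence_id label for the scan.
#' @return A data.frame with one row per instance: the coordinates, strands
#'   and scores of both half-sites plus the gap sequence.
#' @export
find_dimer_instances <- function(seq, c, threshold = NULL,
                                 sequence_id = "seq") {
  thr <- .pair_thresholds(c, threshold)
  ma <- scan_sequence(sequence_id, seq, c$motif_a, thr[1])
  mb <- if (c$self_pair) ma else scan_sequence(sequence_id, seq, c$motif_b, thr[2])
  .pair_instances(seq, c, ma, mb)
}

.pair_thresholds <- function(c, threshold) {
  if (is.null(threshold))
    return(c(default_threshold(c$motif_a), default_threshold(c$motif_b)))
  if (length(threshold) == 1L) rep(threshold, 2) else threshold[1:2]
}

# pair pre-computed half-site matches into instances of configuration c
.pair_instances <- function(seq, c, ma, mb) {
  out <- list()
  for (p in .orientation_patterns(c)) {
    first  <- if (p[1] == "a") ma else mb
    second <- if (p[3] == "a") ma else mb
    f <- first[first$strand == p[2], , drop = FALSE]
    s <- second[second$strand == p[4], , drop = FALSE]
    if (nrow(f) == 0 || nrow(s) == 0) next
    for (k in seq_len(nrow(f))) {
      hit <- s[s$start == f$end[k] + c$spacer, , drop = FALSE]
      if (nrow(hit) == 0) next
      gap <- if (c$spacer > 0)
        substring(seq, f$end[k] + 1L, f$end[k] + c$spacer) else ""
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = f$sequence_id[k],
        start = f$start[k], end = hit$end[1],
        strand_first = f$strand[k], strand_second = hit$strand[1],
        score_first = f$score[k], score_second = hit$score[1],
        site_first = f$site[k], site_second = hit$site[1],
        gap = gap, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand_first = character(0),
                      strand_second = character(0), score_first = numeric(0),
                      score_second = numeric(0), site_first = character(0),
                      site_second = character(0), gap = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("start", "end", "strand_first",
                                 "strand_second")]), , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count regions containing at least one composite instance
#'
#' Region-level indicator counting (not instance totals), which avoids
#' region-length bias in the enrichment test.
#'
#' @param rs a `"region_set"`.
#' @param c a `"dimer_config"`.
#' @inheritParams find_dimer_instances
#' @return Integer number of regions with >= 1 instance.
#' @export
count_regions_with_instance <- function(rs, c, threshold = NULL) {
  if (n_regions(rs) == 0) return(0L)
  thr <- .pair_thresholds(c, threshold)
  hits <- 0L
  for (i in seq_len(n_regions(rs))) {
    seq <- rs$regions$sequence[i]
    inst <- find_dimer_instances(seq, c, threshold = thr,
                                 sequence_id = rs$regions$sequence_id[i])
    if (nrow(inst) > 0) hits <- hits + 1L
  }
  hits
}

# Scan every region once per half-site motif and tabulate, per region, the
# distinct (orientation, spacer) combinations present up to max_spacer.
# Returns a list with per-config region counts and instance totals, keyed
# "orientation:spacer". Used by spacing_profile / run_enrichment_workflow
# so a whole profile costs one scan pass.
.region_hits <- function(rs, motif_a, motif_b, threshold, max_spacer) {
  self_pair <- identical(motif_a$matrix, motif_b$matrix)
  orientations <- if (self_pair) c("direct", "inverted", "everted")
                  else c("direct", "direct_ba", "inverted", "everted")
  configs <- list()
  for (o in orientations) for (s in 0:max_spacer)
    configs[[paste(o, s, sep = ":")]] <-
      dimer_config(motif_a, motif_b, orientation = o, spacer = s)

  region_counts <- integer(length(configs))
  instance_counts <- integer(length(configs))
  names(region_counts) <- names(instance_counts) <- names(configs)
  if (n_regions(rs) == 0)
    return(list(regions = region_counts, instances = instance_counts,
                configs = configs))

  thr_a <- if (length(threshold) >= 1) threshold[1] else threshold
  thr_b <- if (length(threshold) >= 2) threshold[2] else thr_a
  for (i in seq_len(n_regions(rs))) {
    seq <- rs$regions$sequence[i]
    ma <- scan_sequence("r", seq, motif_a, thr_a)
    mb <- if (self_pair) ma else scan_sequence("r", seq, motif_b, thr_b)
    if (nrow(ma) == 0 && nrow(mb) == 0) next
    for (key in names(configs)) {
      inst <- .pair_instances(seq, configs[[key]], ma, mb)
      if (nrow(inst) > 0) {
        region_counts[key] <- region_counts[key] + 1L
        instance_counts[key] <- instance_counts[key] + nrow(inst)
      }
    }
  }
  list(regions = region_counts, instances = instance_counts,
       configs = configs)
}

#' One-sided exact enrichment test
#'
#' Hypergeometric tail probability of observing at least `k_fg` positive
#' foreground regions given the pooled 2x2 margins (equivalently the
#' one-sided Fisher exact test for enrichment).
#'
#' @param k_fg,n_fg positive / total region counts in the foreground set.
#' @param k_ctrl,n_ctrl same for the control set.
#' @return Raw one-sided p-value.
#' @examples
#' enrichment_test(3, 5, 1, 5)  # 66/252
#' @export
enrichment_test <- function(k_fg, n_fg, k_ctrl, n_ctrl) {
  if (n_fg <= 0 || n_ctrl <= 0) stop("n_fg and n_ctrl must be positive")
  if (k_fg < 0 || k_fg > n_fg || k_ctrl < 0 || k_ctrl > n_ctrl)
    stop("counts must satisfy 0 <= k <= n")
  stats::phyper(k_fg - 1, m = k_fg + k_ctrl,
                n = (n_fg - k_fg) + (n_ctrl - k_ctrl),
                k = n_fg, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value in `[0, 1]`.
#' @param n_tests number of tests performed (>= 1).
#' @return `min(1, p_raw * n_tests)`.
#' @export
bonferroni_correct <- function(p_raw, n_tests) {
  if (any(n_tests < 1)) stop("n_tests must be >= 1")
  if (any(p_raw < 0 | p_raw > 1)) stop("p_raw must be in [0, 1]")
  pmin(1, p_raw * n_tests)
}

# assemble one enrichment-result row
.enrichment_row <- function(cfg, k_fg, n_fg, k_ctrl, n_ctrl, inst_fg,
                            inst_ctrl, n_tests) {
  rate_ctrl <- if (n_ctrl > 0) k_ctrl / n_ctrl else 0
  # an empty set carries no evidence either way
  p <- if (n_fg > 0 && n_ctrl > 0)
    enrichment_test(k_fg, n_fg, k_ctrl, n_ctrl) else 1
  # continuity guard for the fold estimate only (the test is exact)
  fold <- ((k_fg + 0.5) / (n_fg + 0.5)) / ((k_ctrl + 0.5) / (n_ctrl + 0.5))
  data.frame(
    motif_a = cfg$motif_a$name, motif_b = cfg$motif_b$name,
    orientation = cfg$orientation, spacer = cfg$spacer,
    k_fg = k_fg, n_fg = n_fg, k_ctrl = k_ctrl, n_ctrl = n_ctrl,
    instances_fg = inst_fg, instances_ctrl = inst_ctrl,
    expected_fg = rate_ctrl * n_fg, fold = fold,
    p_raw = p, p_adj = bonferroni_correct(p, n_tests), n_tests = n_tests,
    stringsAsFactors = FALSE)
}

#' Spacing-resolved enrichment profile for one motif pair and orientation
#'
#' Screens spacers `0..max_spacer` of the given orientation class and
#' reports, per spacer, foreground counts, the control-based expectation
#' and raw/Bonferroni-corrected one-sided p-values.
#'
#' @param fg,ctrl foreground and control `"region_set"` objects.
#' @param motif_a,motif_b half-site motifs.
#' @param orientation orientation class (see [dimer_config()]).
#' @param max_spacer largest spacer screened.
#' @param threshold scan threshold in bits (scalar or per-motif length 2);
#'   `NULL` uses [default_threshold()].
#' @param n_tests Bonferroni factor; defaults to the number of rows of the
#'   profile (override with the total number of configurations screened in
#'   a larger run).
#' @return A data.frame with one row per spacer.
#' @export
spacing_profile <- function(fg, ctrl, motif_a, motif_b = motif_a,
                            orientation = "inverted", max_spacer = 10,
                            threshold = NULL, n_tests = NULL) {
  thr <- .pair_thresholds(dimer_config(motif_a, motif_b,
                                       orientation = orientation, spacer = 0L),
                          threshold)
  hits_fg <- .region_hits(fg, motif_a, motif_b, thr, max_spacer)
  hits_ctrl <- .region_hits(ctrl, motif_a, motif_b, thr, max_spacer)
  keys <- paste(orientation, 0:max_spacer, sep = ":")
  if (is.null(n_tests)) n_tests <- length(keys)
  rows <- lapply(keys, function(key) {
    .enrichment_row(hits_fg$configs[[key]],
                    k_fg = hits_fg$regions[[key]], n_fg = n_regions(fg),
                    k_ctrl = hits_ctrl$regions[[key]], n_ctrl = n_regions(ctrl),
                    inst_fg = hits_fg$instances[[key]],
                    inst_ctrl = hits_ctrl$instances[[key]],
                    n_tests = n_tests)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
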