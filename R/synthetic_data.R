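#' Sample a site from a motif's PWM
#'
#' Draws one base per position from the per-position distributions; with a
#' pseudocount-free consensus PWM this returns the consensus itself.
#'
#' @param m a `"motif"` object.
#' @return Character site of length `motif_length(m)`.
#' @export
sample_site <- function(m) {
  paste(apply(m$matrix, 2, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}

# random background sequence of given length
.random_seq <- function(length, base_composition) {
  paste(sample(DNA_BASES, length, replace = TRUE, prob = base_composition),
        collapse = "")
}

# plus-strand text of one planted composite instance; strands chosen
# uniformly among the arrangements of the orientation class so planted
# data have no strand bias
.sample_instance <- function(c, base_composition) {
  pats <- .orientation_patterns(c)
  p <- pats[[sample.int(length(pats), 1)]]
  site_for <- function(which, strand) {
    m <- if (which == "a") c$motif_a else c$motif_b
    s <- sample_site(m)
    if (strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  first <- site_for(p[1], p[2])
  second <- site_for(p[3], p[4])
  gap <- if (c$spacer > 0) .random_seq(c$spacer, base_composition) else ""
  list(text = paste0(first, gap, second), pattern = p)
}

#' Simulate foreground/control region sets with planted composite motifs
#'
#' Generates i.i.d. background sequence for both sets; a fraction
#' `plant_rate` of foreground regions receives exactly one composite
#' instance, sampled from the configuration's PWMs, written (by base
#' replacement, so lengths are preserved) at a uniformly random admissible
#' offset. Control regions are never planted. The returned plant records
#' give the ground-truth coordinates for recall checks.
#'
#' @param n_fg,n_ctrl numbers of foreground and control regions.
#' @param length region length in bp (must fit the composite).
#' @param config a `"dimer_config"` to plant.
#' @param plant_rate probability that a foreground region is planted.
#' @param base_composition background base distribution (A, C, G, T).
#' @param seed integer seed; all randomness flows from it.
#' @return A list with `foreground` and `control` (`"region_set"`
#'   objects) and `plants` (data.frame of plant records: `region_index`,
#'   `start`, `end`, `strand_first`, `strand_second`, `planted_text`).
#' @export
simulate_region_sets <- function(n_fg, n_ctrl, length = 300,
                                 config, plant_rate = 0.5,
                                 base_composition = rep(0.25, 4),
                                 seed = 1) {
  clen <- composite_length(config)
  if (length < clen)
    stop(sprintf("region length %d cannot host the %d bp composite",
                 length, clen))
  if (plant_rate < 0 || plant_rate > 1)
    stop("plant_rate must be a probability")
  set.seed(seed)

  make_regions <- function(n, prefix) {
    if (n == 0)
      return(data.frame(sequence_id = character(0), start = integer(0),
                        end = integer(0), sequence = character(0),
                        stringsAsFactors = FALSE))
    data.frame(
      sequence_id = sprintf("%s_%04d", prefix, seq_len(n)),
      start = 0L, end = as.integer(length),
      sequence = vapply(seq_len(n), function(i)
        .random_seq(length, base_composition), character(1)),
      stringsAsFactors = FALSE)
  }

  fg <- make_regions(n_fg, "fg")
  ctrl <- make_regions(n_ctrl, "ctrl")

  plants <- list()
  planted <- if (n_fg > 0) runif(n_fg) < plant_rate else logical(0)
  for (i in which(planted)) {
    inst <- .sample_instance(config, base_composition)
    offset <- sample.int(length - clen + 1L, 1) - 1L  # 0-based
    seq <- fg$sequence[i]
    fg$sequence[i] <- paste0(
      substring(seq, 1, offset),
      inst$text,
      substring(seq, offset + clen + 1L, length))
    plants[[length(plants) + 1L]] <- data.frame(
      region_index = i, sequence_id = fg$sequence_id[i],
      start = offset, end = offset + clen,
      strand_first = inst$pattern[2], strand_second = inst$pattern[4],
      planted_text = inst$text, stringsAsFactors = FALSE)
  }
  plants <- if (length(plants) > 0) do.call(rbind, plants)
  else data.frame(region_index = integer(0), sequence_id = character(0),
                  start = integer(0), end = integer(0),
                  strand_first = character(0), strand_second = character(0),
                  planted_text = character(0), stringsAsFactors = FALSE)

  list(foreground = region_set("synthetic_foreground", fg, "foreground"),
       control = region_set("synthetic_control", ctrl, "control"),
       plants = plants)
}

# truncated normal on [0,1] by rejection (falls back to clamping after
# many tries, which only triggers at extreme noise levels)
.rtruncnorm01 <- function(mean, sd) {
  if (sd == 0) return(pmin(pmax(mean, 0), 1))
  out <- rnorm(length(mean), mean, sd)
  bad <- which(out < 0 | out > 1)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    out[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- which(out < 0 | out > 1)
    tries <- tries + 1
  }
  pmin(pmax(out, 0), 1)
}

#' Lane concentrations spanning the binding transition
#'
#' EMSA lanes are informative where the bands shift: a titration is
#' designed around the protein concentration at which the dimer band
#' reaches half its plateau. This helper finds that midpoint under mass
#' balance and returns log-spaced total protein concentrations from
#' `mid/span` to `mid*span`, mirroring how gel titrations are laid out.
#'
#' The default `span = 3` keeps every lane inside the window where the
#' monomer band -- the only band separating the cooperativity factor from
#' the binding constant -- is quantifiable: under the two-site model the
#' monomer fraction exceeds half its peak value only while the occupancy
#' variable `q*sqrt(omega)` lies within `2 + sqrt(3)` (about 3.7-fold) of
#' the transition midpoint. Saturating schedules that overshoot this
#' window waste lanes on pure dimer signal and leave omega poorly
#' determined.
#'
#' @param m a `"two_site_model"` used to locate the transition.
#' @param dna_total probe concentration in nM.
#' @param n_lanes number of lanes.
#' @param span fold-range covered on each side of the midpoint.
#' @return Increasing numeric vector of protein concentrations in nM.
#' @export
titration_design <- function(m, dna_total = 50, n_lanes = 8, span = 3) {
  f2_at <- function(ptot) solve_equilibrium(m, ptot, dna_total)$f2
  lo <- 1e-3; hi <- 1e-3
  while (f2_at(hi) < 0.5 && hi < 1e9) hi <- hi * 10
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    if (f2_at(mid) < 0.5) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  10^seq(log10(mid / span), log10(mid * span), length.out = n_lanes)
}

#' Simulate a noisy EMSA titration from the two-site model
#'
#' Band fractions are computed by [solve_equilibrium()] at each protein
#' concentration, perturbed with truncated Gaussian noise (emulating
#' densitometry error) and renormalised to sum to 1.
#'
#' @param m a `"two_site_model"`.
#' @param protein_totals increasing protein concentrations in nM.
#' @param dna_total probe concentration in nM (50 nM is a typical EMSA
#'   condition).
#' @param noise_sd standard deviation of the fraction noise (0 for
#'   noiseless lanes).
#' @param seed integer seed.
#' @return An `"emsa_titration"`.
#' @export
simulate_titration <- function(m, protein_totals, dna_total = 50,
                               noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  eq <- solve_equilibrium(m, protein_totals, dna_total)
  lanes <- lapply(seq_len(nrow(eq)), function(i) {
    fr <- c(eq$f0[i], eq$f1[i], eq$f2[i])
    if (noise_sd > 0) {
      fr <- .rtruncnorm01(fr, noise_sd)
      if (sum(fr) == 0) fr <- c(1, 0, 0)
      fr <- fr / sum(fr)
    }
    emsa_lane(protein_total = eq$protein_total[i], dna_total = dna_total,
              f0 = fr[1], f1 = fr[2], f2 = fr[3])
  })
  emsa_titration(lanes)
}

#' Simulate a block-correlated expression matrix
#'
#' Genes within a block share a latent per-sample factor mixed so that the
#' expected pairwise correlation of the latent (log-scale) profiles is
#' `within_r`; blocks are mutually independent. Values are exponentiated
#' to the positive, right-skewed scale typical of expression data.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param blocks list of integer vectors partitioning `1..n_genes` (genes
#'   not covered by any block are independent).
#' @param within_r target within-block correlation in `[0, 1)`.
#' @param seed integer seed.
#' @param log_mean,log_sd location and scale of the log-normal expression
#'   levels.
#' @return Numeric gene-by-sample matrix with dimnames.
#' @export
simulate_expression <- function(n_genes, n_samples, blocks = list(),
                                within_r = 0.8, seed = 1,
                                log_mean = 3, log_sd = 1) {
  if (within_r < 0 || within_r >= 1) stop("within_r must be in [0, 1)")
  if (n_samples < 3) stop("at least 3 samples are required")
  set.seed(seed)
  y <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  for (b in blocks) {
    z <- rnorm(n_samples)
    for (g in b)
      y[g, ] <- sqrt(within_r) * z + sqrt(1 - within_r) * y[g, ]
  }
  x <- exp(log_mean + log_sd * y)
  dimnames(x) <- list(paste0("gene", seq_len(n_genes)),
                      paste0("sample", seq_len(n_samples)))
  x
}
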