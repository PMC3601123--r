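## Probe-level simulator.  Gene-level truth is additive on the log2 scale;
## probe-level intensities follow the exponential-signal-plus-Gaussian-
## background convolution that RMA assumes, with per-probe affinities
## shared across arrays (affinity is a probe property, matching the
## additive model median polish fits).

#' Configuration of a simulated boutique-array experiment
#'
#' Defaults emulate a boutique defensin-family chip: 500 probe sets of
#' which 170 are invariant anchors and 25 are markers, 11 probe pairs per
#' probe set, two conditions with 3 biological replicates each, and 70\%
#' of the family genes shifted up 2 log2 units in the second condition —
#' the coordinated distribution shift (as when most family members switch
#' on in one tissue) that defeats whole-distribution normalization.
#'
#' @param n_probesets total probe sets on the array.
#' @param n_invariant number of invariant anchor probe sets.
#' @param n_marker number of marker probe sets.
#' @param probes_per_set probe pairs per probe set (11).
#' @param conditions named integer vector of replicate counts per
#'   condition (default \code{c(control = 3, treatment = 3)}).
#' @param frac_shifted fraction of family (defl) genes differentially
#'   expressed in \code{shifted_condition}.
#' @param effect_log2 log2 effect size of shifted genes (all up-shifted).
#' @param frac_silent fraction of family genes that are silent (baseline
#'   at background level) in every condition, as on a real family chip
#'   where many members are not expressed in any sampled tissue; these
#'   probe sets supply the always-Absent anchor RMAPS scales by.  Silent
#'   genes are drawn from the non-shifted family genes.
#' @param silent_log2_mean,silent_log2_sd baseline distribution of silent
#'   genes (default log2 mean 0: a transcript absent from every sampled
#'   tissue contributes essentially zero specific signal, far below the
#'   optical background).
#' @param baseline_log2_mean,baseline_log2_sd normal distribution of
#'   family/marker gene baseline log2 expression.
#' @param invariant_log2_mean,invariant_log2_sd baseline distribution of
#'   invariant genes; defaults span the expressed-intensity range (as real
#'   invariant sets are chosen to do) while staying above background.
#' @param invariant_noise_log2 within-group biological sd of invariant
#'   genes, chosen so their linear-scale CV stays below 10\% (0.05 log2
#'   units corresponds to a CV of about 3.5\%).
#' @param biological_sd_log2 within-group biological sd of all other
#'   genes.
#' @param probe_affinity_sd sd of per-probe multiplicative affinity (log2
#'   units), drawn once per probe and shared across arrays.
#' @param array_effect_log2_sd sd of the per-array global log2 offset
#'   (labeling/scanning efficiency differences that normalization must
#'   remove).
#' @param array_gain_log2_sd sd of the per-array gain applied to log2
#'   signal around the baseline mean: arrays compress or stretch the
#'   dynamic range (dye response and scanner gain are not perfectly
#'   linear in the log domain), a monotone distortion that a quantile map
#'   can straighten but a single additive offset cannot.  A gain g maps
#'   log2 signal x to \code{center + g (x - center)}.
#' @param bg_mu,bg_sd mean and sd of the additive Gaussian optical
#'   background (linear scale).
#' @param bg_array_sd_log2 sd of the per-array log2 multiplier applied to
#'   the background level (and proportionally to its spread): scanner gain
#'   and wash differences make the optical background vary from array to
#'   array, which is what the low-intensity portions of raw density plots
#'   show.
#' @param mm_crosshyb fraction of true signal leaking into the mismatch
#'   probe (plus background).
#' @param shifted_condition condition in which shifted genes change;
#'   defaults to the second condition.
#' @param seed integer seed; the generator is bit-reproducible given
#'   (config, seed).
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_probesets = 500L, n_invariant = 170L,
                             n_marker = 25L, probes_per_set = 11L,
                             conditions = c(control = 3L, treatment = 3L),
                             frac_shifted = 0.7, effect_log2 = 2,
                             frac_silent = 0.15,
                             silent_log2_mean = 0, silent_log2_sd = 1,
                             baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                             invariant_log2_mean = 8, invariant_log2_sd = 1.5,
                             invariant_noise_log2 = 0.05,
                             biological_sd_log2 = 0.25,
                             probe_affinity_sd = 0.7,
                             array_effect_log2_sd = 0.2,
                             array_gain_log2_sd = 0.08,
                             bg_mu = 100, bg_sd = 20,
                             bg_array_sd_log2 = 0.3, mm_crosshyb = 0.05,
                             shifted_condition = NULL, seed = 1L) {
  if (is.null(shifted_condition))
    shifted_condition <- names(conditions)[min(2L, length(conditions))]
  cfg <- list(n_probesets = as.integer(n_probesets),
              n_invariant = as.integer(n_invariant),
              n_marker = as.integer(n_marker),
              probes_per_set = as.integer(probes_per_set),
              conditions = conditions, frac_shifted = frac_shifted,
              effect_log2 = effect_log2, frac_silent = frac_silent,
              silent_log2_mean = silent_log2_mean,
              silent_log2_sd = silent_log2_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              invariant_log2_mean = invariant_log2_mean,
              invariant_log2_sd = invariant_log2_sd,
              invariant_noise_log2 = invariant_noise_log2,
              biological_sd_log2 = biological_sd_log2,
              probe_affinity_sd = probe_affinity_sd,
              array_effect_log2_sd = array_effect_log2_sd,
              array_gain_log2_sd = array_gain_log2_sd,
              bg_mu = bg_mu, bg_sd = bg_sd,
              bg_array_sd_log2 = bg_array_sd_log2,
              mm_crosshyb = mm_crosshyb,
              shifted_condition = shifted_condition,
              seed = as.integer(seed))
  counts <- c(cfg$n_probesets, cfg$n_invariant, cfg$n_marker,
              cfg$probes_per_set, unlist(conditions))
  if (any(counts <= 0) || cfg$n_invariant + cfg$n_marker >= cfg$n_probesets)
    bnStop("bn_config_error",
           "counts must be positive and invariant+marker < n_probesets")
  if (cfg$frac_shifted < 0 || cfg$frac_shifted > 1 ||
      cfg$frac_silent < 0 || cfg$frac_silent > 1 ||
      cfg$mm_crosshyb < 0 || cfg$mm_crosshyb > 1)
    bnStop("bn_config_error", "fractions must lie in [0, 1]")
  if (cfg$frac_shifted + cfg$frac_silent > 1)
    bnStop("bn_config_error",
           "frac_shifted + frac_silent cannot exceed 1")
  sds <- c(baseline_log2_sd, invariant_log2_sd, invariant_noise_log2,
           biological_sd_log2, probe_affinity_sd, array_effect_log2_sd,
           bg_sd, bg_array_sd_log2, silent_log2_sd, array_gain_log2_sd)
  if (any(sds < 0) || bg_mu <= 0)
    bnStop("bn_config_error", "sds must be >= 0 and bg_mu > 0")
  if (!cfg$shifted_condition %in% names(conditions))
    bnStop("bn_config_error", "shifted_condition must name a condition")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a probe-level boutique-array experiment with ground truth
#'
#' Draws gene baselines, assigns up-shift effects to a fraction of the
#' family genes in one condition, adds per-replicate biological noise and
#' per-array global offsets on the log2 scale, then renders probe-level PM
#' intensities as \code{2^(theta + affinity) + N(bg_mu, bg_sd)} and MM as
#' a cross-hybridized signal fraction plus the same background, both
#' truncated at 1 to keep intensities positive.  Bit-reproducible for a
#' fixed config.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A list with \code{plm} (\linkS4class{ProbeLevelMatrix}),
#'   \code{annotation} (\linkS4class{ProbeSetAnnotation}) and \code{truth}
#'   (\linkS4class{SimulationTruth}).
#' @examples
#' sim <- simulateExperiment(simulationConfig(n_probesets = 40,
#'   n_invariant = 12, n_marker = 3, seed = 7))
#' sim$plm
#' @export
simulateExperiment <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    bnStop("bn_config_error", "config must come from simulationConfig()")
  set.seed(config$seed)
  n_defl <- config$n_probesets - config$n_invariant - config$n_marker
  ids <- c(sprintf("DEFL%05d_at", seq_len(n_defl)),
           sprintf("MRK%04d_at", seq_len(config$n_marker)),
           sprintf("INV%04d_at", seq_len(config$n_invariant)))
  category <- rep(c("defl", "marker", "invariant"),
                  c(n_defl, config$n_marker, config$n_invariant))
  annot <- probeSetAnnotation(ids, category = category)
  is_inv <- category == "invariant"
  baseline <- ifelse(is_inv,
                     stats::rnorm(length(ids), config$invariant_log2_mean,
                                  config$invariant_log2_sd),
                     stats::rnorm(length(ids), config$baseline_log2_mean,
                                  config$baseline_log2_sd))
  shifted <- sort(sample(ids[category == "defl"],
                         round(config$frac_shifted * n_defl)))
  silent <- sort(sample(setdiff(ids[category == "defl"], shifted),
                        round(config$frac_silent * n_defl)))
  baseline[match(silent, ids)] <-
    stats::rnorm(length(silent), config$silent_log2_mean,
                 config$silent_log2_sd)
  effects <- stats::setNames(numeric(length(ids)), ids)
  effects[shifted] <- config$effect_log2
  conds <- names(config$conditions)
  truthmat <- outer(baseline, rep(1, length(conds))) +
    outer(effects, conds == config$shifted_condition)
  dimnames(truthmat) <- list(ids, conds)
  samples <- do.call(rbind, lapply(conds, function(cn)
    data.frame(sample_id = sprintf("%s_%d", cn,
                                   seq_len(config$conditions[[cn]])),
               tissue = cn, condition = cn, replicate_group = cn,
               replicate_index = seq_len(config$conditions[[cn]]))))
  n_arrays <- nrow(samples)
  noise_sd <- ifelse(is_inv, config$invariant_noise_log2,
                     config$biological_sd_log2)
  array_eff <- stats::rnorm(n_arrays, 0, config$array_effect_log2_sd)
  biol <- truthmat[, match(samples$condition, conds), drop = FALSE] +
    matrix(stats::rnorm(length(ids) * n_arrays, 0, noise_sd),
           length(ids), n_arrays)
  colnames(biol) <- samples$sample_id
  gain <- 1 + stats::rnorm(n_arrays, 0, config$array_gain_log2_sd)
  center <- config$baseline_log2_mean
  theta <- center + (biol - center) * rep(gain, each = length(ids)) +
    rep(array_eff, each = length(ids))
  k <- config$probes_per_set
  affinity <- stats::rnorm(length(ids) * k, 0, config$probe_affinity_sd)
  sig <- 2^(theta[rep(seq_along(ids), each = k), , drop = FALSE] + affinity)
  bg_scale <- 2^stats::rnorm(n_arrays, 0, config$bg_array_sd_log2)
  bg_mu_a <- rep(config$bg_mu * bg_scale, each = nrow(sig))
  bg_sd_a <- rep(config$bg_sd * bg_scale, each = nrow(sig))
  pmm <- pmax(sig + stats::rnorm(length(sig), bg_mu_a, bg_sd_a), 1)
  mmm <- pmax(config$mm_crosshyb * sig +
                stats::rnorm(length(sig), bg_mu_a, bg_sd_a), 1)
  plm <- probeLevelMatrix(pmm, mmm, annotation = annot, samples = samples,
                          probeset_id = ids, probes_per_set = k)
  names(affinity) <- rownames(rowData(plm))
  truth <- new("SimulationTruth", trueExpression = truthmat,
               sampleExpression = biol, shifted = shifted, silent = silent,
               effects = effects, affinities = affinity,
               config = unclass(config))
  list(plm = plm, annotation = annot, truth = truth)
}

#' Extract a boutique subset from a simulated whole-array experiment
#'
#' Models a boutique chip as a biased subset of a whole-genome array: it
#' keeps \code{invariant_keep} invariant anchors plus a sample of the
#' remaining probe sets in which shifted genes are deliberately
#' over-represented at fraction \code{frac_shifted} of the non-invariant
#' slots (the family-biased composition that makes whole-distribution
#' normalization fail on the subset).  Sampling uses the current RNG
#' state.
#'
#' @param sim output of \code{\link{simulateExperiment}}.
#' @param subset_size total probe sets to retain.
#' @param invariant_keep number of invariant probe sets to retain.
#' @param frac_shifted fraction of the non-invariant slots filled with
#'   shifted genes (default 0.6).
#' @return A list with \code{plm}, \code{annotation} and \code{truth}
#'   restricted to the subset (probe-set-major structure preserved).
#' @export
makeBoutiqueSubset <- function(sim, subset_size, invariant_keep,
                               frac_shifted = 0.6) {
  annot <- sim$annotation
  truth <- sim$truth
  inv_ids <- annot$probeset_id[annot$category == "invariant"]
  if (invariant_keep > length(inv_ids))
    bnStop("bn_subset_too_large",
           sprintf("requested %d invariants but only %d available",
                   invariant_keep, length(inv_ids)))
  slots <- subset_size - invariant_keep
  if (slots < 0L)
    bnStop("bn_subset_too_large", "invariant_keep exceeds subset_size")
  n_shift <- round(frac_shifted * slots)
  shifted_pool <- truth@shifted
  other_pool <- setdiff(annot$probeset_id[annot$category != "invariant"],
                        shifted_pool)
  if (n_shift > length(shifted_pool) || slots - n_shift > length(other_pool))
    bnStop("bn_subset_too_large",
           "not enough shifted or unshifted probe sets to fill the subset")
  keep <- c(if (invariant_keep > 0L) sample(inv_ids, invariant_keep),
            sample(shifted_pool, n_shift),
            sample(other_pool, slots - n_shift))
  keep <- annot$probeset_id[annot$probeset_id %in% keep]   # annotation order
  sub_annot <- new("ProbeSetAnnotation",
                   annot[match(keep, annot$probeset_id), , drop = FALSE])
  k <- probesPerSet(sim$plm)
  rows <- as.vector(outer(seq_len(k),
                          (match(keep, probeSets(sim$plm)) - 1L) * k, "+"))
  plm <- probeLevelMatrix(pm(sim$plm)[rows, , drop = FALSE],
                          mm(sim$plm)[rows, , drop = FALSE],
                          annotation = sub_annot,
                          samples = sampleMeta(sim$plm),
                          probeset_id = keep, probes_per_set = k)
  sub_truth <- new("SimulationTruth",
                   trueExpression = truth@trueExpression[keep, , drop = FALSE],
                   sampleExpression =
                     truth@sampleExpression[keep, , drop = FALSE],
                   shifted = intersect(truth@shifted, keep),
                   silent = intersect(truth@silent, keep),
                   effects = truth@effects[keep],
                   affinities = truth@affinities[rownames(rowData(plm))],
                   config = truth@config)
  list(plm = plm, annotation = sub_annot, truth = sub_truth)
}
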