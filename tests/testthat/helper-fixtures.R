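# Small fixtures built in code.

# A ProbeLevelMatrix from explicit pm/mm matrices (probe-set-major rows).
tinyPlm <- function(pm, mm = pm / 2, n_sets = nrow(pm) %/% 11L,
                    probes_per_set = nrow(pm) %/% n_sets,
                    category = "defl",
                    conditions = NULL) {
  ids <- sprintf("PS%03d_at", seq_len(n_sets))
  annot <- probeSetAnnotation(ids, category = rep_len(category, n_sets))
  n <- ncol(pm)
  if (is.null(conditions)) conditions <- rep("c1", n)
  reps <- stats::ave(seq_len(n), conditions, FUN = seq_along)
  samples <- data.frame(sample_id = paste0("A", seq_len(n)),
                        tissue = conditions, condition = conditions,
                        replicate_group = conditions,
                        replicate_index = reps)
  probeLevelMatrix(pm, mm, annotation = annot, samples = samples,
                   probeset_id = ids, probes_per_set = probes_per_set)
}

# A small simulated experiment for integration-style tests; dots override
# the small-chip defaults.
tinySim <- function(seed = 42L, ...) {
  args <- utils::modifyList(
    list(n_probesets = 60L, n_invariant = 20L, n_marker = 4L, seed = seed),
    list(...))
  simulateExperiment(do.call(simulationConfig, args))
}

# ExpressionMatrix straight from a numeric matrix.
tinyExpr <- function(m, conditions = NULL, tag = "raw_summary") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d_at", seq_len(nrow(m)))
  n <- ncol(m)
  if (is.null(conditions)) conditions <- rep("c1", n)
  reps <- stats::ave(seq_len(n), conditions, FUN = seq_along)
  samples <- data.frame(sample_id = paste0("A", seq_len(n)),
                        tissue = conditions, condition = conditions,
                        replicate_group = conditions, replicate_index = reps)
  expressionMatrix(m, samples = samples, method_tag = tag)
}
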